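quantity,unit,group,n,mean,sd
nv_fibroblast,1e3 cells/mm3,control,12,284.5,32.6
nv_fibroblast,1e3 cells/mm3,hp5,12,454.1,117.61
nv_fibroblast,1e3 cells/mm3,hp10,12,429.8,37.6
nv_fibroblast,1e3 cells/mm3,gel_base,12,231.1,11.9
vv_collagen_pct,percent,control,12,47.4,4.9
vv_collagen_pct,percent,hp5,12,73.1,9.2
vv_collagen_pct,percent,hp10,12,74.3,1.9
vv_collagen_pct,percent,gel_base,12,48.1,4.7
vv_hair_pct,percent,control,12,2.6,1.2
vv_hair_pct,percent,hp5,12,2.8,1.6
vv_hair_pct,percent,hp10,12,2.9,1.2
vv_hair_pct,percent,gel_base,12,2.4,1.3
vv_vessel_pct,percent,control,12,3.3,2.75
vv_vessel_pct,percent,hp5,12,3.1,1.4
vv_vessel_pct,percent,hp10,12,5.1,2.2
vv_vessel_pct,percent,gel_base,12,4.1,0.7
lv_vessel,mm/mm3,control,12,17.2,8.1
lv_vessel,mm/mm3,hp5,12,29.3,6.1
lv_vessel,mm/mm3,hp10,12,32.9,16.6
lv_vessel,mm/mm3,gel_base,12,14.1,1.4
vessel_diameter_um,um,control,12,11.7,3.1
vessel_diameter_um,um,hp5,12,17.1,5.5
vessel_diameter_um,um,hp10,12,26.6,9.4
vessel_diameter_um,um,gel_base,12,11.2,1.8
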