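field_count_cols <- c(
  "animal_id", "group", "p_collagen", "p_vessel", "p_hair", "p_dermis",
  "q_minus", "frame_area_mm2", "height_mm", "vessel_transects", "diameters_um"
)

#' Read and write field-count tables
#'
#' The on-disk schema is one CSV row per microscopic field with columns
#' `animal_id, group, p_collagen, p_vessel, p_hair, p_dermis, q_minus,
#' frame_area_mm2, height_mm, vessel_transects, diameters_um`; the last
#' column is a semicolon-joined list of per-profile diameters in um (empty
#' when no profile was measured). Units are fixed per column and named in
#' the header; no autodetection is attempted.
#'
#' Reading validates every row: missing columns are a hard error, and
#' negative counts or phase counts exceeding the dermis reference
#' (`p_collagen + p_vessel + p_hair <= p_dermis`) are errors naming the
#' offending row.
#'
#' @param path CSV file path.
#' @return `read_field_counts()`: a validated tibble with `diameters_um`
#'   as a numeric list-column. `write_field_counts()`: `path`, invisibly.
#' @export
read_field_counts <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  missing <- setdiff(field_count_cols, names(raw))
  if (length(missing)) {
    abort(paste0("missing required column(s): ", paste(missing, collapse = ", ")))
  }
  num <- function(col) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(x) & !is.na(raw[[col]]) & raw[[col]] != "")
    if (length(bad)) {
      abort(sprintf("non-numeric value in column '%s' at data row %d", col, bad[1]))
    }
    x
  }
  fields <- tibble::tibble(
    animal_id = raw$animal_id,
    group = raw$group,
    p_collagen = as.integer(num("p_collagen")),
    p_vessel = as.integer(num("p_vessel")),
    p_hair = as.integer(num("p_hair")),
    p_dermis = as.integer(num("p_dermis")),
    q_minus = as.integer(num("q_minus")),
    frame_area_mm2 = num("frame_area_mm2"),
    height_mm = num("height_mm"),
    vessel_transects = as.integer(num("vessel_transects")),
    diameters_um = lapply(raw$diameters_um, function(s) {
      if (is.na(s) || s == "") numeric(0) else
        as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
    })
  )
  validate_field_counts(fields)
  fields
}

validate_field_counts <- function(fields) {
  count_cols <- c("p_collagen", "p_vessel", "p_hair", "p_dermis", "q_minus",
                  "vessel_transects")
  for (col in count_cols) {
    bad <- which(is.na(fields[[col]]) | fields[[col]] < 0)
    if (length(bad)) {
      abort(sprintf("negative or missing count in column '%s' at data row %d",
                    col, bad[1]))
    }
  }
  over <- which(fields$p_collagen + fields$p_vessel + fields$p_hair >
                  fields$p_dermis)
  if (length(over)) {
    abort(sprintf(paste0(
      "invariant violated at data row %d: ",
      "p_collagen + p_vessel + p_hair must not exceed p_dermis"
    ), over[1]))
  }
  bad_h <- which(!(fields$height_mm > 0) | !(fields$frame_area_mm2 > 0))
  if (length(bad_h)) {
    abort(sprintf("non-positive frame area or dissector height at data row %d",
                  bad_h[1]))
  }
  invisible(fields)
}

#' @rdname read_field_counts
#' @param fields a field-count tibble.
#' @export
write_field_counts <- function(fields, path) {
  out <- fields[, setdiff(field_count_cols, "diameters_um")]
  out$diameters_um <- vapply(fields$diameters_um, function(d) {
    paste(format(d, trim = TRUE, digits = 15, scientific = FALSE),
          collapse = ";")
  }, character(1))
  out$diameters_um[!vapply(fields$diameters_um, length, 0L)] <- ""
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a wound-area series table
#'
#' CSV schema: `animal_id, group, day, area_mm2`. Each animal must carry a
#' day-0 visit with strictly increasing days and non-negative areas.
#'
#' @param path CSV file path.
#' @return tidy tibble.
#' @export
read_wound_areas <- function(path) {
  series <- readr::read_csv(path, show_col_types = FALSE,
                            col_types = readr::cols(
                              animal_id = "c", group = "c",
                              day = "d", area_mm2 = "d"
                            ))
  if (any(series$area_mm2 < 0, na.rm = TRUE)) {
    abort("wound areas must be non-negative")
  }
  check_series(series)
  series
}

#' Pipeline configuration defaults
#'
#' @param ... overrides of the default configuration entries.
#' @return a named list understood by [run_pipeline()].
#' @export
default_config <- function(...) {
  cfg <- list(
    mode = "full",
    out_dir = "stereowound-output",
    seed = 1L,
    n_animals = 3L,
    n_fields = 12L,
    extent_um = c(400, 400, 400),
    grid_spacing_mm = 0.02,
    section_thickness_um = 15,
    guard_um = 5,
    frame_um = 150,
    rate_convention = "final",
    reference_groups = c("control", "gel_base"),
    field_counts_csv = NULL,
    wound_areas_csv = NULL
  )
  utils::modifyList(cfg, list(...))
}

read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(default_config, cfg)
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full analysis pipeline
#'
#' Modes: `"simulate"` writes a synthetic fixture bundle (field counts +
#' wound areas); `"estimate"` turns field counts into per-animal
#' estimates; `"timecourse"` summarizes wound closure; `"compare"` builds
#' the group report; `"full"` chains all stages on synthetic inputs.
#' Outputs are CSV/Markdown files plus a JSON run manifest recording the
#' seed, package version and a configuration hash, so a run is
#' reproducible bit-for-bit from its manifest. Any stage error aborts
#' with a stage-named message and removes partial outputs.
#'
#' @param config a configuration list from [default_config()], or a path
#'   to a YAML/JSON file of overrides.
#' @return invisibly, a named list of the files written.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- read_config(config)
  cfg <- do.call(default_config, config)
  mode <- match.arg(cfg$mode, c("simulate", "estimate", "timecourse",
                                "compare", "full"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(name, writer) {
    path <- file.path(cfg$out_dir, name)
    writer(path)
    written <<- c(written, path)
    path
  }
  on_fail <- function(stage, e) {
    unlink(written)
    abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  }

  frame <- dissector_spec(
    section_thickness = cfg$section_thickness_um,
    guard_top = cfg$guard_um, guard_bottom = cfg$guard_um,
    frame_width = cfg$frame_um, frame_height = cfg$frame_um
  )
  grid <- point_grid(cfg$grid_spacing_mm)

  fields <- NULL
  series <- NULL
  if (mode %in% c("simulate", "full")) {
    tryCatch({
      log_stage("simulate", "cohort: %d animals/group, %d fields/animal, seed %d",
                cfg$n_animals, cfg$n_fields, cfg$seed)
      cohort <- simulate_cohort(
        n_animals = cfg$n_animals, n_fields = cfg$n_fields, grid = grid,
        frame = frame, extent = cfg$extent_um, seed = cfg$seed
      )
      fields <- cohort$fields
      series <- simulate_wound_study(n_animals = cfg$n_animals,
                                     seed = derive_seed(cfg$seed, 77))
      emit("field_counts.csv", function(p) write_field_counts(fields, p))
      emit("wound_areas.csv", function(p) {
        readr::write_csv(series[, c("animal_id", "group", "day", "area_mm2")], p)
      })
      emit("truth.csv", function(p) readr::write_csv(cohort$truth, p))
    }, error = function(e) on_fail("simulate", e))
  }
  if (mode %in% c("estimate", "compare") && !is.null(cfg$field_counts_csv)) {
    tryCatch(fields <- read_field_counts(cfg$field_counts_csv),
             error = function(e) on_fail("read", e))
  }
  if (mode == "timecourse" && !is.null(cfg$wound_areas_csv)) {
    tryCatch(series <- read_wound_areas(cfg$wound_areas_csv),
             error = function(e) on_fail("read", e))
  }

  estimates <- NULL
  if (mode %in% c("estimate", "compare", "full")) {
    if (is.null(fields)) abort("pipeline stage 'estimate' failed: no field counts supplied")
    tryCatch({
      log_stage("estimate", "summarizing %d fields from %d animals",
                nrow(fields), length(unique(fields$animal_id)))
      estimates <- summarize_animals(fields)
      emit("estimates.csv", function(p) readr::write_csv(estimates, p))
    }, error = function(e) on_fail("estimate", e))
  }

  if (mode %in% c("timecourse", "full") && !is.null(series)) {
    tryCatch({
      log_stage("timecourse", "closure for %d animals",
                length(unique(series$animal_id)))
      rec <- closure_records(series)
      cs <- group_closure_table(series, convention = cfg$rate_convention)
      emit("closure_records.csv", function(p) readr::write_csv(rec, p))
      emit("closure_by_group.csv", function(p) readr::write_csv(cs$by_group, p))
      emit("closure_by_visit.csv", function(p) readr::write_csv(cs$by_visit, p))
    }, error = function(e) on_fail("timecourse", e))
  }

  if (mode %in% c("compare", "full")) {
    tryCatch({
      log_stage("compare", "group report over %d animals", nrow(estimates))
      rep <- table1_report(estimates, reference_groups = cfg$reference_groups)
      emit("table1.md", function(p) writeLines(table1_markdown(rep), p))
      emit("table1_summary.csv", function(p) readr::write_csv(rep$summary, p))
      emit("comparisons.csv", function(p) readr::write_csv(rep$comparisons, p))
      pct <- percent_difference_table(
        rep$summary[, c("quantity", "group", "mean")],
        baselines = cfg$reference_groups
      )
      emit("percent_differences.csv", function(p) readr::write_csv(pct, p))
    }, error = function(e) on_fail("compare", e))
  }

  tryCatch({
    manifest <- list(
      package = "stereowound",
      version = as.character(utils::packageVersion("stereowound")),
      seed = cfg$seed,
      mode = mode,
      config_hash = digest::digest(cfg),
      config = cfg[setdiff(names(cfg), "out_dir")],
      files = basename(written)
    )
    emit("manifest.json", function(p) {
      jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
    })
  }, error = function(e) on_fail("manifest", e))

  log_stage("done", "%d files in %s", length(written), cfg$out_dir)
  invisible(setNames(as.list(written), basename(written)))
}

#' Read a binary wound mask image
#'
#' Loads a PNG or TIFF mask (any non-zero pixel counts as wound) for
#' [area_from_mask()]. Pixels are row-major with top-left origin; the
#' mm-per-pixel scale comes from the calibration config, not the file.
#'
#' @param path PNG or TIFF file.
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = {
      if (!requireNamespace("png", quietly = TRUE)) abort("package 'png' required")
      png::readPNG(path)
    },
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) abort("package 'tiff' required")
      tiff::readTIFF(path)
    },
    abort("mask must be a .png or .tif/.tiff file")
  )
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0
}
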