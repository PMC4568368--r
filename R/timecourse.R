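#' Wound closure percentage
#'
#' `closure (%) = 100 * (area at first visit - area at visit t) / area at
#' first visit`. Negative values mean the wound grew relative to day 0
#' (seen in untreated wounds during the early inflammatory phase) and are
#' deliberately kept, not clipped.
#'
#' @param area_day0 wound area at the first visit, mm^2 (> 0); vectorized.
#' @param area_t wound area at the visit of interest, mm^2 (>= 0).
#' @return closure percentage (100 at full closure, 0 at day 0, negative
#'   when the wound enlarged).
#' @examples
#' closure_percent(100, 50)   # 50
#' closure_percent(100, 110)  # -10
#' @export
closure_percent <- function(area_day0, area_t) {
  if (any(area_day0 <= 0)) abort("initial wound area must be positive")
  if (any(area_t < 0)) abort("wound areas must be non-negative")
  100 * (area_day0 - area_t) / area_day0
}

check_series <- function(series) {
  stopifnot(is.data.frame(series),
            all(c("animal_id", "day", "area_mm2") %in% names(series)))
  bad <- series |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::summarise(
      no_day0 = !any(.data$day == 0),
      unsorted = is.unsorted(.data$day, strictly = TRUE),
      .groups = "drop"
    )
  if (any(bad$no_day0)) {
    abort(paste0("missing day-0 visit for: ",
                 paste(bad$animal_id[bad$no_day0], collapse = ", ")))
  }
  if (any(bad$unsorted)) {
    abort("visit days must be strictly increasing within each animal")
  }
  invisible(series)
}

#' Per-visit closure records for a wound series table
#'
#' Adds `closure_pct` (relative to each animal's day-0 area) to a tidy
#' wound-area table.
#'
#' @param series tibble with `animal_id`, `group` (optional), `day`,
#'   `area_mm2`; each animal must have a day-0 visit and strictly
#'   increasing days.
#' @return the input with a `closure_pct` column.
#' @export
closure_records <- function(series) {
  check_series(series)
  series |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::mutate(closure_pct = closure_percent(
      .data$area_mm2[.data$day == 0], .data$area_mm2
    )) |>
    dplyr::ungroup()
}

#' Per-day wound closure rate
#'
#' Two conventions are provided because the averaging behind published
#' "%/day" figures is rarely stated: `"final"` (default) divides the final
#' closure percentage by the elapsed days; `"ols"` takes the least-squares
#' slope of closure percentage against day. The two agree exactly when
#' closure is linear in time.
#'
#' @param series tidy wound-area tibble (see [closure_records()]); each
#'   animal needs at least two visits.
#' @param convention `"final"` or `"ols"`.
#' @return tibble with one row per animal: `animal_id`, `group` (if
#'   present), `rate_pct_per_day`.
#' @export
closure_rate_per_day <- function(series, convention = c("final", "ols")) {
  convention <- match.arg(convention)
  rec <- closure_records(series)
  nv <- dplyr::count(rec, .data$animal_id)
  if (any(nv$n < 2)) {
    abort(paste0("at least two visits required; offending animal(s): ",
                 paste(nv$animal_id[nv$n < 2], collapse = ", ")))
  }
  keys <- intersect(c("animal_id", "group"), names(rec))
  rec |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      rate_pct_per_day = if (convention == "final") {
        .data$closure_pct[which.max(.data$day)] /
          (max(.data$day) - min(.data$day))
      } else {
        unname(coef(lm(closure_pct ~ day,
                       data = data.frame(closure_pct = .data$closure_pct,
                                         day = .data$day)))[2])
      },
      .groups = "drop"
    )
}

#' Group-level closure summary
#'
#' Mean and SD (sample, n-1 convention) by group of the initial wound
#' area, the per-visit closure percentage, and the per-day closure rate.
#' Groups of a single animal report SD = 0 and are flagged
#' (`sd_degenerate`).
#'
#' @inheritParams closure_rate_per_day
#' @return object of class `closure_summary`: a list with `by_group`
#'   (group, n, initial area and rate mean/SD, `sd_degenerate` flag) and
#'   `by_visit` (group, day, closure mean/SD). [tidy()] returns
#'   `by_visit`, [glance()] returns `by_group`, and [autoplot()] draws the
#'   closure timecourse.
#' @export
group_closure_table <- function(series, convention = c("final", "ols")) {
  convention <- match.arg(convention)
  stopifnot("group" %in% names(series))
  rec <- closure_records(series)
  rates <- closure_rate_per_day(series, convention)

  sd0 <- function(x) if (length(x) < 2) 0 else sd(x)
  by_group <- rec |>
    dplyr::filter(.data$day == 0) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      initial_area_mean = mean(.data$area_mm2),
      initial_area_sd = sd0(.data$area_mm2),
      sd_degenerate = dplyr::n() < 2,
      .groups = "drop"
    ) |>
    dplyr::left_join(
      rates |>
        dplyr::group_by(.data$group) |>
        dplyr::summarise(rate_mean = mean(.data$rate_pct_per_day),
                         rate_sd = sd0(.data$rate_pct_per_day),
                         .groups = "drop"),
      by = "group"
    )
  by_visit <- rec |>
    dplyr::group_by(.data$group, .data$day) |>
    dplyr::summarise(closure_mean = mean(.data$closure_pct),
                     closure_sd = sd0(.data$closure_pct),
                     n = dplyr::n(), .groups = "drop")
  structure(
    list(by_group = by_group, by_visit = by_visit, convention = convention),
    class = "closure_summary"
  )
}

#' @export
print.closure_summary <- function(x, ...) {
  cat(sprintf("<closure_summary> (%s convention)\n", x$convention))
  print(x$by_group)
  invisible(x)
}
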