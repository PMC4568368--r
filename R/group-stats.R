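#' Percent difference between two group means
#'
#' `100 * (mean_a - mean_b) / mean_b`: how much higher (or lower) group A
#' is than baseline group B. Vectorized. Full precision is returned;
#' published tables conventionally show two decimals, for which
#' [percent_difference_table()] truncates (see its details).
#'
#' @param mean_a,mean_b group means; `mean_b` (the baseline) must be > 0.
#' @return percent difference(s).
#' @examples
#' percent_difference(454.1, 284.5)  # 59.613...
#' @export
percent_difference <- function(mean_a, mean_b) {
  if (any(mean_b <= 0)) abort("baseline mean must be positive")
  100 * (mean_a - mean_b) / mean_b
}

#' Percent-difference table against baseline groups
#'
#' Applies [percent_difference()] to a long summary table (columns
#' `quantity`, `group`, `mean`), comparing every non-baseline group with
#' every baseline group within each quantity.
#'
#' The two-decimal column truncates toward zero rather than rounding:
#' published stereology tables of this design report percent differences
#' truncated at the second decimal, and truncation reproduces them
#' exactly from the printed group means.
#'
#' @param summaries tibble with `quantity`, `group`, `mean`.
#' @param baselines character vector of baseline group labels.
#' @return tibble: `quantity`, `group_a`, `group_b`, `pct_diff` (full
#'   precision), `pct_diff_2dp` (truncated to two decimals).
#' @export
percent_difference_table <- function(summaries,
                                     baselines = c("control", "gel_base")) {
  stopifnot(all(c("quantity", "group", "mean") %in% names(summaries)))
  treated <- dplyr::filter(summaries, !.data$group %in% baselines)
  base <- dplyr::filter(summaries, .data$group %in% baselines)
  dplyr::inner_join(
    dplyr::select(treated, "quantity", group_a = "group", mean_a = "mean"),
    dplyr::select(base, "quantity", group_b = "group", mean_b = "mean"),
    by = "quantity", relationship = "many-to-many"
  ) |>
    dplyr::mutate(
      # undefined against a zero/missing baseline: NA rather than an error,
      # so one degenerate quantity does not sink a whole report
      pct_diff = ifelse(
        !is.na(.data$mean_b) & .data$mean_b > 0 & !is.na(.data$mean_a),
        100 * (.data$mean_a - .data$mean_b) / .data$mean_b, NA_real_
      ),
      pct_diff_2dp = trunc_digits(.data$pct_diff, 2)
    ) |>
    dplyr::select(-"mean_a", -"mean_b")
}

#' Mann-Whitney U test with an exact small-sample path
#'
#' Computes the Mann-Whitney U statistic (for `x` against `y`) with the
#' exact permutation null distribution — full enumeration over all
#' `choose(nx + ny, nx)` group assignments, valid with ties — when the
#' combined sample size is at most 12, and the tie-corrected normal
#' approximation with continuity correction otherwise.
#'
#' @param x,y numeric samples.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param exact force (`TRUE`/`FALSE`) or auto-select (`NULL`) the exact
#'   path.
#' @return list with `statistic` (U), `p_value`, `method`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6), alternative = "less")$p_value
#' @export
mann_whitney_u <- function(x, y, alternative = c("two.sided", "greater", "less"),
                           exact = NULL) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y); n <- nx + ny
  if (nx < 1 || ny < 1) abort("both samples must be non-empty")
  exact <- exact %||% (n <= 12)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  eps <- 1e-9

  if (exact) {
    u_all <- combn(n, nx, FUN = function(ix) sum(r[ix])) - nx * (nx + 1) / 2
    p <- switch(alternative,
      two.sided = mean(abs(u_all - mu) >= abs(u_obs - mu) - eps),
      greater = mean(u_all >= u_obs - eps),
      less = mean(u_all <= u_obs + eps)
    )
    method <- "Mann-Whitney U (exact permutation)"
  } else {
    nties <- table(r)
    sigma <- sqrt((nx * ny / 12) *
                    ((n + 1) - sum(nties^3 - nties) / (n * (n - 1))))
    z <- u_obs - mu
    corr <- switch(alternative,
      two.sided = sign(z) * 0.5, greater = 0.5, less = -0.5
    )
    z <- (z - corr) / sigma
    p <- switch(alternative,
      two.sided = 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)),
      greater = pnorm(z, lower.tail = FALSE),
      less = pnorm(z)
    )
    p <- min(1, p)
    method <- "Mann-Whitney U (normal approximation, tie-corrected)"
  }
  list(statistic = u_obs, p_value = p, method = method)
}

#' Nonparametric group comparison: Kruskal-Wallis + pairwise Mann-Whitney
#'
#' Omnibus Kruskal-Wallis test across all groups and pairwise
#' Mann-Whitney U tests for every pair, each reported with the percent
#' difference of group means (later factor level vs earlier, so order the
#' factor baseline-first). Pairwise p-values are unadjusted by default,
#' mirroring common practice in small animal studies; set
#' `p_adjust = "holm"` to correct.
#'
#' @param data a data frame.
#' @param value unquoted column of measurements.
#' @param group unquoted column of group labels (>= 2 groups, each
#'   n >= 2).
#' @param alternative sidedness of the pairwise tests (two-sided default).
#' @param p_adjust p-adjustment method for pairwise tests
#'   (`"none"` default).
#' @param alpha significance threshold recorded in the result (0.05).
#' @param quantity optional quantity label carried into the report.
#' @return object of class `stereo_comparison`; [tidy()] returns the
#'   pairwise table, [glance()] the omnibus row.
#' @examples
#' d <- data.frame(g = rep(c("a", "b"), each = 5), y = c(1:5, 3:7))
#' compare_groups(d, y, g)
#' @export
compare_groups <- function(data, value, group,
                           alternative = c("two.sided", "greater", "less"),
                           p_adjust = "none", alpha = 0.05,
                           quantity = NULL) {
  alternative <- match.arg(alternative)
  df <- dplyr::tibble(
    value = dplyr::pull(data, {{ value }}),
    group = dplyr::pull(data, {{ group }})
  )
  df <- df[complete.cases(df), ]
  if (!is.factor(df$group)) df$group <- factor(df$group, levels = unique(df$group))
  df$group <- droplevels(df$group)
  lev <- levels(df$group)
  sizes <- table(df$group)
  if (length(lev) < 2) abort("at least two groups required")
  if (any(sizes < 2)) {
    abort(paste0("every group needs n >= 2; offending: ",
                 paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  quantity <- quantity %||% as_name(enquo(value))

  kw <- kruskal.test(df$value, df$group)
  # all observations tied: the tie-corrected H is 0/0 in kruskal.test,
  # but H = 0 (no rank variation) is the defined value
  h <- unname(kw$statistic)
  p_h <- unname(kw$p.value)
  if (is.nan(h) && length(unique(df$value)) == 1) {
    h <- 0
    p_h <- 1
  }
  omnibus <- tibble::tibble(
    quantity = quantity,
    method = "Kruskal-Wallis",
    statistic = h,
    df = unname(kw$parameter),
    p_value = p_h,
    n = nrow(df)
  )

  pairs <- combn(seq_along(lev), 2)
  pairwise <- purrr::map(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    xa <- df$value[df$group == lev[j]]  # later level = comparison group
    xb <- df$value[df$group == lev[i]]  # earlier level = baseline
    mw <- mann_whitney_u(xa, xb, alternative = alternative)
    tibble::tibble(
      quantity = quantity,
      group_a = lev[j], group_b = lev[i],
      n_a = length(xa), n_b = length(xb),
      mean_a = mean(xa), mean_b = mean(xb),
      percent_difference = if (mean(xb) > 0) {
        percent_difference(mean(xa), mean(xb))
      } else NA_real_,
      u_statistic = mw$statistic,
      p_value = mw$p_value,
      method = mw$method
    )
  }) |> purrr::list_rbind()
  pairwise$p_value <- stats::p.adjust(pairwise$p_value, method = p_adjust)

  structure(
    list(omnibus = omnibus, pairwise = pairwise, alpha = alpha),
    class = "stereo_comparison"
  )
}

#' @export
print.stereo_comparison <- function(x, ...) {
  cat(sprintf("<stereo_comparison> alpha = %g\n", x$alpha))
  cat(sprintf("Kruskal-Wallis H = %.3f (df = %d), p = %.4g\n",
              x$omnibus$statistic, x$omnibus$df, x$omnibus$p_value))
  print(x$pairwise[, c("group_a", "group_b", "percent_difference",
                       "u_statistic", "p_value")])
  invisible(x)
}

quantity_labels <- c(
  nv_fibroblast = "Fibroblast Nv (10^3/mm^3)",
  vv_collagen_pct = "Collagen Vv (%)",
  vv_hair_pct = "Hair follicle Vv (%)",
  vv_vessel_pct = "Vessel Vv (%)",
  lv_vessel = "Vessel Lv (mm/mm^3)",
  vessel_diameter_um = "Vessel diameter (um)"
)

#' Study-style group report: mean (SD) grid with significance stars
#'
#' Builds the classic stereology results grid — quantities by treatment
#' groups, cells formatted `mean (SD)` to one decimal — from per-animal
#' estimates (see [summarize_animals()]), with a star on groups that
#' differ (pairwise Mann-Whitney, p < `alpha`) from *every* reference
#' group present.
#'
#' @param estimates per-animal tibble with a `group` column and the
#'   quantity columns.
#' @param quantities quantity columns to report (defaults to all present
#'   among the standard five-plus-one set).
#' @param reference_groups labels of the comparison baseline groups
#'   (untreated / vehicle); stars are only awarded against these.
#' @param alpha significance threshold for stars.
#' @return object of class `stereo_table1`: `summary` (long), `wide`
#'   (formatted grid), `comparisons` (all pairwise tests). [tidy()]
#'   returns the long summary, [glance()] the omnibus tests.
#' @export
table1_report <- function(estimates, quantities = names(quantity_labels),
                          reference_groups = c("control", "gel_base"),
                          alpha = 0.05) {
  stopifnot("group" %in% names(estimates))
  missing_q <- setdiff(quantities, names(estimates))
  if (length(missing_q)) {
    warn(paste0("quantities absent from estimates, reported blank: ",
                paste(missing_q, collapse = ", ")))
  }
  quantities <- intersect(quantities, names(estimates))
  groups <- if (is.factor(estimates$group)) levels(estimates$group) else
    unique(estimates$group)
  refs <- intersect(reference_groups, groups)
  multi <- length(groups) >= 2 &&
    all(table(estimates$group[!is.na(estimates$group)]) >= 2)

  per_q <- purrr::map(quantities, function(q) {
    vals <- estimates[[q]]
    summ <- estimates |>
      dplyr::filter(!is.na(.data[[q]])) |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(
        n = dplyr::n(),
        mean = mean(.data[[q]]),
        sd = if (dplyr::n() < 2) 0 else sd(.data[[q]]),
        .groups = "drop"
      ) |>
      dplyr::mutate(quantity = q, .before = 1)
    enough <- multi && length(unique(summ$group)) >= 2 && all(summ$n >= 2) &&
      length(unique(estimates$group)) == length(unique(summ$group))
    cmp <- if (enough) {
      compare_groups(estimates[!is.na(vals), ], !!rlang::sym(q), group,
                     alpha = alpha, quantity = q)
    } else {
      if (multi) {
        warn(sprintf(
          "too few non-missing values to compare groups for '%s'; no test run", q
        ))
      }
      NULL
    }
    starred <- character(0)
    if (!is.null(cmp) && length(refs)) {
      sig <- cmp$pairwise |>
        dplyr::filter(.data$p_value < alpha)
      cand <- setdiff(groups, refs)
      starred <- cand[vapply(cand, function(g) {
        all(vapply(refs, function(r) {
          any((sig$group_a == g & sig$group_b == r) |
                (sig$group_a == r & sig$group_b == g))
        }, logical(1)))
      }, logical(1))]
    }
    summ$star <- summ$group %in% starred
    summ$label <- paste0(fmt_mean_sd(summ$mean, summ$sd, 1),
                         ifelse(summ$star, " *", ""))
    list(summary = summ, comparison = cmp)
  })

  summary <- purrr::list_rbind(purrr::map(per_q, "summary"))
  comparisons <- purrr::list_rbind(
    purrr::map(purrr::compact(purrr::map(per_q, "comparison")), "pairwise")
  )
  omnibus <- purrr::list_rbind(
    purrr::map(purrr::compact(purrr::map(per_q, "comparison")), "omnibus")
  )
  wide <- summary |>
    dplyr::select("quantity", "group", "label") |>
    tidyr::pivot_wider(names_from = "quantity", values_from = "label")
  for (q in missing_q) wide[[q]] <- ""

  structure(
    list(summary = summary, wide = wide, comparisons = comparisons,
         omnibus = omnibus, alpha = alpha,
         reference_groups = refs),
    class = "stereo_table1"
  )
}

#' @export
print.stereo_table1 <- function(x, ...) {
  cat("<stereo_table1> mean (SD); * = p <", x$alpha,
      "vs", paste(x$reference_groups, collapse = " and "), "\n")
  print(as.data.frame(x$wide))
  invisible(x)
}

#' Render a study-style report as Markdown lines
#'
#' @param report a [table1_report()] result.
#' @return character vector of Markdown table lines.
#' @export
table1_markdown <- function(report) {
  stopifnot(inherits(report, "stereo_table1"))
  w <- report$wide
  qn <- setdiff(names(w), "group")
  hdr <- c("Group", unname(quantity_labels[qn] %||% qn))
  hdr[is.na(hdr)] <- qn[is.na(hdr[-1])]
  lines <- c(
    paste0("| ", paste(hdr, collapse = " | "), " |"),
    paste0("|", paste(rep("---", length(hdr)), collapse = "|"), "|")
  )
  for (i in seq_len(nrow(w))) {
    lines <- c(lines, paste0("| ", paste(unlist(w[i, c("group", qn)]),
                                         collapse = " | "), " |"))
  }
  c(lines, "", sprintf("`*` p < %g (Mann-Whitney U) vs %s.", report$alpha,
                       paste(report$reference_groups, collapse = " and ")))
}

#' Reference group-summary table of the emulated study
#'
#' Group means and SDs of the five stereological quantities in the
#' four-arm diabetic-rat excisional wound study that the package's
#' synthetic defaults emulate (untreated control, vehicle gel, and 5 %
#' and 10 % herbal-gel arms, n = 12 each). Used as the calibration target
#' for the synthetic cohort and as the worked input for
#' [percent_difference_table()].
#'
#' @return tibble: `quantity`, `unit`, `group`, `n`, `mean`, `sd`.
#' @export
reference_group_summaries <- function() {
  path <- system.file("extdata", "group_summaries_reference.csv",
                      package = "stereowound", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    quantity = "c", unit = "c", group = "c",
                    n = "i", mean = "d", sd = "d"
                  ))
}

#' Default group-level tissue truths for the synthetic cohort
#'
#' Converts [reference_group_summaries()] into the group specification
#' consumed by [simulate_cohort()] (absolute units: cells/mm^3 and
#' volume fractions).
#'
#' @return tibble, one row per group.
#' @export
default_group_tissue <- function() {
  ref <- reference_group_summaries()
  wide <- function(q, col) {
    v <- ref[ref$quantity == q, ]
    setNames(v[[col]], v$group)
  }
  groups <- unique(ref$group)
  pull <- function(q, col) unname(wide(q, col)[groups])
  tibble::tibble(
    group = groups,
    nv_mean = pull("nv_fibroblast", "mean") * 1e3,
    nv_sd = pull("nv_fibroblast", "sd") * 1e3,
    vv_collagen_mean = pull("vv_collagen_pct", "mean") / 100,
    vv_collagen_sd = pull("vv_collagen_pct", "sd") / 100,
    vv_hair_mean = pull("vv_hair_pct", "mean") / 100,
    vv_hair_sd = pull("vv_hair_pct", "sd") / 100,
    lv_mean = pull("lv_vessel", "mean"),
    lv_sd = pull("lv_vessel", "sd"),
    diam_mean = pull("vessel_diameter_um", "mean"),
    diam_sd = pull("vessel_diameter_um", "sd")
  )
}
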