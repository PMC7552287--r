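# Descriptive group summaries and rank-based comparisons for exposure
# experiments (temperature series, dose series).

#' Per-group mean and standard error
#'
#' Experiment tables report one metric value per animal per group; the
#' conventional descriptive summary is mean +/- SEM with `SEM = SD / sqrt(n)`
#' (sample SD, n - 1 denominator). A single-animal group has an undefined SEM
#' and is reported as `NA`.
#'
#' @param data A data frame with one row per animal.
#' @param group Grouping column (tidy-eval).
#' @param value Metric column (tidy-eval), e.g. bpm or cardiac output.
#' @return A tibble with `group`, `n`, `mean`, `sem`.
#' @examples
#' df <- data.frame(g = rep(c("ctrl", "dosed"), each = 3), v = c(1, 2, 3, 4, 5, 6))
#' summarize_groups(df, g, v)
#' @export
summarize_groups <- function(data, group, value) {
  stopifnot(is.data.frame(data))
  if (!nrow(data)) stop("empty table", call. = FALSE)
  data |>
    dplyr::group_by(group = {{ group }}) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean({{ value }}),
      sem = ifelse(dplyr::n() > 1, stats::sd({{ value }}) / sqrt(dplyr::n()),
                   NA_real_),
      .groups = "drop"
    )
}

#' Two-group Mann–Whitney comparison
#'
#' Two-sided Mann–Whitney U (Wilcoxon rank-sum). For tie-free samples with
#' both groups of size <= 8 the exact permutation distribution is used;
#' otherwise the normal approximation with tie correction (and continuity
#' correction). Requires at least 3 values per group — below that the test
#' carries no information.
#'
#' @param a,b Numeric vectors of metric values for the two groups.
#' @return A one-row tibble: `u` (the U statistic for `a` vs `b`),
#'   `p_value`, `n_a`, `n_b`, `exact` (logical).
#' @examples
#' compare_groups(c(1, 2, 3), c(10, 11, 12))  # U = 0, exact p = 0.1
#' @export
compare_groups <- function(a, b) {
  if (length(a) < 3 || length(b) < 3) {
    stop("each group needs >= 3 values", call. = FALSE)
  }
  has_ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- !has_ties && length(a) <= 8 && length(b) <= 8
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = TRUE)
  )
  tibble::tibble(u = unname(wt$statistic), p_value = wt$p.value,
                 n_a = length(a), n_b = length(b), exact = use_exact)
}

#' Compare every group against a control
#'
#' Convenience wrapper running [compare_groups()] of each non-control group
#' against the control, with optional Bonferroni adjustment of p-values
#' across the comparisons.
#'
#' @param data A data frame with one row per animal.
#' @param group,value Grouping and metric columns (tidy-eval).
#' @param control The label of the control group.
#' @param adjust `"none"` (default) or `"bonferroni"`.
#' @return A tibble with one row per non-control group.
#' @export
compare_to_control <- function(data, group, value, control,
                               adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  g <- dplyr::pull(data, {{ group }})
  v <- dplyr::pull(data, {{ value }})
  if (!control %in% g) stop("control group \"", control, "\" not found", call. = FALSE)
  others <- setdiff(unique(g), control)
  res <- purrr::map_dfr(others, function(lab) {
    cmp <- compare_groups(v[g == lab], v[g == control])
    dplyr::mutate(cmp, group = lab, .before = 1)
  })
  if (adjust == "bonferroni") {
    res$p_adjusted <- pmin(1, res$p_value * nrow(res))
  }
  res
}

#' Normalise metric values to a control group
#'
#' Divides every value by the mean of the control group, so the control mean
#' maps to exactly 1 (the "relative heartbeat" convention of dose-series
#' figures).
#'
#' @inheritParams compare_to_control
#' @return `data` with an added column `relative`.
#' @export
relative_to_control <- function(data, group, value, control) {
  g <- dplyr::pull(data, {{ group }})
  if (!control %in% g) stop("control group \"", control, "\" not found", call. = FALSE)
  ctrl_mean <- mean(dplyr::pull(data, {{ value }})[g == control])
  dplyr::mutate(data, relative = {{ value }} / ctrl_mean)
}
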