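#' Stand-in biomarker centile tables for the case and control arms
#'
#' Builds percentile tables of two log-normal biomarker laws sharing a
#' log-scale SD, with the control median a fixed fraction below the case
#' median (default 15%). These tables stand in for published case/control
#' centiles of a biomarker such as Lp(a), which are access-restricted; the
#' two printed facts they preserve are log-normality and the median gap.
#'
#' @param params A [generator_params()] list; uses `median_case`,
#'   `median_ratio`, `sigma_log` and `percentiles`.
#' @return A tibble with columns `percentile`, `value` (mg/dl) and `arm`
#'   (`"case"` or `"control"`), one row per arm x percentile.
#' @examples
#' make_standin_centiles(generator_params())
#' @export
make_standin_centiles <- function(params = generator_params()) {
  stopifnot(inherits(params, "tempbias_params"))
  mu_case <- log(params$median_case)
  mu_ctrl <- log(params$median_case * params$median_ratio)
  p <- params$percentiles
  dplyr::bind_rows(
    tibble::tibble(percentile = p,
                   value = stats::qlnorm(p, mu_case, params$sigma_log),
                   arm = "case"),
    tibble::tibble(percentile = p,
                   value = stats::qlnorm(p, mu_ctrl, params$sigma_log),
                   arm = "control")
  )
}

# Internal validity check shared by centile consumers.
validate_centile_table <- function(table) {
  req <- c("percentile", "value")
  if (!is.data.frame(table) || !all(req %in% names(table))) {
    abort("a centile table needs `percentile` and `value` columns.",
          class = "tempbias_invalid_input")
  }
  if (nrow(table) < 3) {
    abort("a centile table needs at least 3 percentile points.",
          class = "tempbias_invalid_input")
  }
  if (any(table$percentile <= 0 | table$percentile >= 1)) {
    abort("percentiles must lie strictly inside (0, 1).",
          class = "tempbias_invalid_input")
  }
  if (is.unsorted(table$percentile, strictly = TRUE)) {
    abort("percentiles must be strictly increasing.",
          class = "tempbias_invalid_input")
  }
  if (any(table$value <= 0)) {
    abort("centile values must be strictly positive.",
          class = "tempbias_invalid_input")
  }
  if (is.unsorted(table$value, strictly = TRUE)) {
    abort("centile values must be strictly increasing in percentile.",
          class = "tempbias_invalid_input")
  }
  invisible(table)
}
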