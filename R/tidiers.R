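#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname tempbias-tidiers
#' @export
tidy.tb_effect <- function(x, ...) {
  tibble::tibble(term = "biomarker", estimate = x$coefficient,
                 std.error = x$se, design = x$design,
                 method = x$method, shape = x$shape,
                 shape_param = x$shape_param)
}

#' Tidiers for tempbias result objects
#'
#' `tidy()` returns one row per estimated quantity; `glance()` returns a
#' one-row summary of the whole fit or experiment.
#'
#' @param x A `tb_effect`, `tb_releffect`, `tb_design_study` or
#'   `tb_lookback` object.
#' @param ... Unused.
#' @return A tibble.
#' @name tempbias-tidiers
NULL

#' @rdname tempbias-tidiers
#' @export
glance.tb_effect <- function(x, ...) {
  tibble::tibble(coefficient = x$coefficient, se = x$se,
                 n_case = x$n_case, n_control = x$n_control)
}

#' @rdname tempbias-tidiers
#' @export
tidy.tb_releffect <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tempbias-tidiers
#' @export
tidy.tb_design_study <- function(x, ...) {
  x$auroc
}

#' @rdname tempbias-tidiers
#' @export
glance.tb_design_study <- function(x, ...) {
  cm <- x$confusion
  tibble::tibble(
    train_anchor = x$train_design$anchor,
    eval_anchor = x$eval_design$anchor,
    mean_auroc = mean(x$auroc$auroc),
    sd_auroc = sd(x$auroc$auroc),
    n_models = nrow(x$auroc),
    false_negative_rate = cm["case", "control"] / sum(cm["case", ]),
    false_positive_rate = cm["control", "case"] / sum(cm["control", ])
  )
}

#' @rdname tempbias-tidiers
#' @export
tidy.tb_lookback <- function(x, ...) {
  x$results
}

#' @rdname tempbias-tidiers
#' @export
glance.tb_lookback <- function(x, ...) {
  x$summary
}

#' @rdname tempbias-tidiers
#' @export
tidy.tb_selection <- function(x, ...) {
  tibble::as_tibble(x)
}
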