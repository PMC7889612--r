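#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_errorbar
#'   geom_line geom_boxplot geom_hline facet_wrap labs theme_minimal
#'   position_dodge scale_y_continuous
#' @export
ggplot2::autoplot

#' Plot relative prospective effect sizes
#'
#' Dot-and-interval plot of the attenuation table: one point per
#' (imputation method, trajectory shape) cell with its empirical 95%
#' interval, against the no-attenuation reference at 1.
#'
#' @param object A `tb_releffect` tibble from [relative_effect_summary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tb_releffect <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$cell <- ifelse(d$shape == "heaviside",
                   sprintf("heaviside p=%g", d$shape_param), d$shape)
  ggplot(d, aes(x = .data$cell, y = .data$ratio_mean,
                colour = .data$method)) +
    geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    geom_point(position = position_dodge(width = 0.5)) +
    geom_errorbar(aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                  width = 0.2, position = position_dodge(width = 0.5)) +
    labs(x = "trajectory", y = "effect size relative to biased baseline",
         colour = "start imputation") +
    theme_minimal()
}

#' Plot AUROC distributions of a design study
#'
#' @param object A `tb_design_study` from [run_design_study()], or a named
#'   list of them for a side-by-side comparison.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tb_design_study <- function(object, ...) {
  plot_design_studies(list(study = object))
}

#' @rdname autoplot.tb_design_study
#' @param studies Named list of `tb_design_study` objects.
#' @export
plot_design_studies <- function(studies, ...) {
  d <- dplyr::bind_rows(
    purrr::imap(studies, function(s, nm) {
      tibble::tibble(study = nm, auroc = s$auroc$auroc)
    })
  )
  ggplot(d, aes(x = .data$study, y = .data$auroc)) +
    geom_boxplot() +
    scale_y_continuous(limits = c(0, 1)) +
    labs(x = NULL, y = "validation AUROC") +
    theme_minimal()
}

#' Plot a lookback sweep
#'
#' Boxplots of per-trial normalized effect sizes by lookback length, with
#' the fraction of FDR-significant trials annotated by colour.
#'
#' @param object A `tb_lookback` from [lookback_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tb_lookback <- function(object, ...) {
  d <- object$results
  ggplot(d, aes(x = factor(.data$lookback_years),
                y = .data$normalized_effect)) +
    geom_boxplot(outlier.shape = NA) +
    geom_point(aes(colour = .data$significant_fdr),
               position = ggplot2::position_jitter(width = 0.15),
               size = 0.6, alpha = 0.5) +
    geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    labs(x = "lookback (years)", y = "effect normalized to 1-year mean",
         colour = "significant (FDR)") +
    theme_minimal()
}
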