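#' Synthetic claims cohort with a gestation-locked code signature
#'
#' Generates a claims-like cohort of one calendar year (2015, whole-month
#' granularity) for the delivery-prediction experiments. Cases experience a
#' delivery in a month drawn uniformly from February to December; controls
#' never deliver. Two code classes are emitted:
#'
#' * background codes: a homogeneous monthly Poisson stream, all year, for
#'   every patient (rate `background_rate`), codes uniform over the
#'   background vocabulary;
#' * gestational codes: emitted only inside the gestation span, the
#'   `gestation_months` months preceding (and including) the delivery
#'   month, at a monthly rate that ramps linearly from
#'   `gestational_rate_min` at conception to `gestational_rate` at
#'   delivery. Each gestational code is tied to a gestation stage and is
#'   emitted only when the pregnancy is within `stage_band` stages of it,
#'   so every gestation month has its own code signature and the stream
#'   becomes progressively denser (and stage-distinctive) as the event
#'   approaches — the time-varying signal that temporal bias exploits.
#'
#' All patients are female (sex is constant by construction and is not a
#' feature); ages and region codes are drawn independently of case status
#' so that exact matching succeeds.
#'
#' @param params A [generator_params()] list.
#' @param seed Seed; defaults to `params$seed`.
#' @return A list of class `claims_cohort` with tibbles `patients`
#'   (`patient_id`, `age`, `region`, `delivery_month` — `NA` for controls,
#'   2..12 for cases) and `events` (`patient_id`, `month` 1..12, `code`,
#'   `code_class`). The code vocabulary is kept in
#'   `attr(x, "vocabulary")`.
#' @examples
#' cc <- gen_claims_cohort(generator_params(n_cases = 50, n_controls = 50))
#' head(cc$patients)
#' @export
gen_claims_cohort <- function(params = generator_params(), seed = params$seed) {
  stopifnot(inherits(params, "tempbias_params"))
  if (params$n_cases < 1 || params$n_controls < 1) {
    abort("cohort sizes must be at least 1.", class = "tempbias_invalid_parameter")
  }
  seed_rng(seed)
  g <- params$gestation_months
  n_pool <- ceiling(params$control_pool_factor * params$n_controls)
  n <- params$n_cases + n_pool

  patients <- tibble::tibble(
    patient_id = sprintf("P%06d", seq_len(n)),
    age = sample_vec(seq(params$age_range[1], params$age_range[2]), n),
    region = sprintf("R%02d", sample.int(params$n_regions, n, replace = TRUE)),
    delivery_month = c(sample(2:12, params$n_cases, replace = TRUE),
                       rep(NA_integer_, n_pool))
  )

  vocab <- claims_vocabulary(params)

  # Background stream: homogeneous over the 12 months for everyone.
  n_bg <- rpois(n, 12 * params$background_rate)
  bg <- tibble::tibble(
    patient_id = rep(patients$patient_id, n_bg),
    month = sample.int(12L, sum(n_bg), replace = TRUE),
    code = sample(vocab$code[vocab$code_class == "background"],
                  sum(n_bg), replace = TRUE),
    code_class = "background"
  )

  # Gestational stream: for each case and each in-year gestation month,
  # Poisson counts at the ramped stage rate. Codes are stage-specific:
  # an event at stage s draws uniformly among the codes of stages within
  # `stage_band` of s, so each gestation month has its own code signature
  # (prenatal care looks different in the first and third trimester).
  cases <- patients[!is.na(patients$delivery_month), ]
  gest <- tidyr::crossing(
    dplyr::select(cases, "patient_id", "delivery_month"),
    stage = 0:g
  )
  gest$month <- gest$delivery_month - g + gest$stage
  gest <- gest[gest$month >= 1, ]
  rate <- params$gestational_rate_min +
    (params$gestational_rate - params$gestational_rate_min) * gest$stage / g
  gest$n_ev <- rpois(nrow(gest), rate)
  gest <- gest[gest$n_ev > 0, ]
  gcodes <- vocab[vocab$code_class == "gestational", ]
  ev_stage <- rep(gest$stage, gest$n_ev)
  n_per_stage <- params$codes_per_stage
  band <- params$stage_band
  lo <- pmax(ev_stage - band, 0L)
  hi <- pmin(ev_stage + band, g)
  pick_stage <- lo + floor(runif(length(ev_stage)) * (hi - lo + 1L))
  code_idx <- pick_stage * n_per_stage +
    sample.int(n_per_stage, length(ev_stage), replace = TRUE)
  ge <- tibble::tibble(
    patient_id = rep(gest$patient_id, gest$n_ev),
    month = rep(gest$month, gest$n_ev),
    code = gcodes$code[code_idx],
    code_class = "gestational"
  )

  events <- dplyr::arrange(dplyr::bind_rows(bg, ge),
                           .data$patient_id, .data$month, .data$code)
  out <- list(patients = patients, events = events)
  attr(out, "vocabulary") <- vocab
  attr(out, "params") <- params
  class(out) <- "claims_cohort"
  out
}

# Fixed code vocabulary: background codes B01.. and gestational codes
# G<stage><letter>, `codes_per_stage` codes tied to each gestation stage
# 0..gestation_months, ordered by stage.
claims_vocabulary <- function(params) {
  bg <- tibble::tibble(
    code = sprintf("B%02d", seq_len(params$n_background_codes)),
    code_class = "background", stage = NA_integer_
  )
  stages <- rep(0:params$gestation_months, each = params$codes_per_stage)
  ge <- tibble::tibble(
    code = sprintf("G%02d%s", stages,
                   rep(letters[seq_len(params$codes_per_stage)],
                       params$gestation_months + 1L)),
    code_class = "gestational", stage = stages
  )
  dplyr::bind_rows(bg, ge)
}

#' @export
print.claims_cohort <- function(x, ...) {
  nc <- sum(!is.na(x$patients$delivery_month))
  cat(sprintf("<claims_cohort> %d patients (%d cases), %d events, %d codes\n",
              nrow(x$patients), nc, nrow(x$events),
              nrow(attr(x, "vocabulary"))))
  invisible(x)
}
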