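# Small parameter presets shared across test files.

tiny_claims_params <- function(...) {
  generator_params(n_cases = 120, n_controls = 120, ...)
}

# A hand-built claims cohort for matcher edge cases.
manual_claims_cohort <- function(patients) {
  out <- list(patients = patients,
              events = tibble::tibble(patient_id = character(),
                                      month = integer(),
                                      code = character(),
                                      code_class = character()))
  attr(out, "vocabulary") <- tempbias:::claims_vocabulary(generator_params())
  class(out) <- "claims_cohort"
  out
}

# Independent rejection-sampling oracle for weighted-sampling imputation:
# draw from the control law, keep draws below the case value.
rejection_start_oracle <- function(n, case_value, control) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rlnorm(4 * n, control$mu, control$sigma)
    out <- c(out, draw[draw < case_value])
  }
  out[seq_len(n)]
}

# Independent maximum-likelihood oracle for a logistic fit of y on x:
# direct minimization of the negative log-likelihood.
logit_mle_oracle <- function(x, y) {
  nll <- function(b) {
    eta <- b[1] + b[2] * x
    sum(log1p(exp(eta))) - sum(y * eta)
  }
  optim(c(0, 0), nll, method = "BFGS")$par[2]
}
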