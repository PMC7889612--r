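#' Observation-window study designs
#'
#' Names how a study anchors its observation window:
#'
#' * `event_indexed` — the single month `offset_months` before the
#'   patient's delivery (cases) or inherited baseline month (matched
#'   controls). This is the case-control window: it tracks the event, so it
#'   samples one fixed slice of the trajectory and cannot be reproduced
#'   prospectively.
#' * `calendar_fixed` — a fixed calendar month (default January),
#'   identical for everyone and deployable in real time; the cohort window.
#'
#' @param anchor `"event_indexed"` or `"calendar_fixed"`.
#' @param offset_months Months before the event/baseline month
#'   (event-indexed only), at least 1.
#' @param fixed_month Calendar month 1..12 (calendar-fixed only).
#' @return A list of class `study_design`.
#' @examples
#' study_design("event_indexed", offset_months = 3)
#' study_design("calendar_fixed")
#' @export
study_design <- function(anchor = c("event_indexed", "calendar_fixed"),
                         offset_months = 3L, fixed_month = 1L) {
  anchor <- match.arg(anchor)
  if (anchor == "event_indexed" && offset_months < 1) {
    abort("`offset_months` must be at least 1.",
          class = "tempbias_invalid_parameter")
  }
  if (anchor == "calendar_fixed" && !(fixed_month %in% 1:12)) {
    abort("`fixed_month` must be a calendar month 1..12.",
          class = "tempbias_invalid_parameter")
  }
  structure(list(anchor = anchor,
                 offset_months = as.integer(offset_months),
                 fixed_month = as.integer(fixed_month),
                 window_length_months = 1L),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  if (x$anchor == "event_indexed") {
    cat(sprintf("<study_design> event-indexed, %d month(s) before event\n",
                x$offset_months))
  } else {
    cat(sprintf("<study_design> calendar-fixed, month %d\n", x$fixed_month))
  }
  invisible(x)
}

#' Match controls to cases on exact keys
#'
#' Greedy 1:1 exact matching without replacement on the given patient
#' columns (default age and region). Each matched control inherits its
#' case's delivery month as a `baseline_month`, the index date to which
#' its observation window is anchored in event-indexed designs. Cases
#' whose stratum runs out of controls are dropped with a warning; more
#' than 20% dropped is an error.
#'
#' @param cohort A [gen_claims_cohort()] result.
#' @param keys Character vector of patient columns to match on exactly.
#' @param seed Optional seed (matching shuffles within strata).
#' @return A `claims_cohort` whose `patients` tibble is restricted to the
#'   matched pairs and gains `is_case` and `baseline_month` columns;
#'   events are filtered accordingly. `attr(x, "n_dropped")` counts
#'   unmatched cases.
#' @examples
#' cc <- gen_claims_cohort(generator_params(n_cases = 80, n_controls = 120))
#' m <- match_controls(cc, seed = 1)
#' table(m$patients$is_case)
#' @export
match_controls <- function(cohort, keys = c("age", "region"), seed = NULL) {
  stopifnot(inherits(cohort, "claims_cohort"))
  seed_rng(seed)
  pts <- cohort$patients
  if (!all(keys %in% names(pts))) {
    abort("matching keys must be patient columns.",
          class = "tempbias_invalid_input")
  }
  pts$.stratum <- do.call(paste, c(pts[keys], sep = "\r"))
  cases <- pts[!is.na(pts$delivery_month), ]
  ctrls <- pts[is.na(pts$delivery_month), ]

  picked_case <- vector("list", 0L)
  picked_ctrl <- vector("list", 0L)
  for (s in unique(cases$.stratum)) {
    cs <- cases[cases$.stratum == s, ]
    av <- ctrls[ctrls$.stratum == s, ]
    k <- min(nrow(cs), nrow(av))
    if (k == 0) next
    cs <- cs[sample.int(nrow(cs), k), ]
    av <- av[sample.int(nrow(av), k), ]
    av$baseline_month <- cs$delivery_month
    picked_case[[s]] <- cs
    picked_ctrl[[s]] <- av
  }
  mc <- dplyr::bind_rows(picked_case)
  mt <- dplyr::bind_rows(picked_ctrl)
  n_dropped <- nrow(cases) - nrow(mc)
  if (n_dropped > 0.2 * nrow(cases)) {
    abort(sprintf("matching dropped %d of %d cases (> 20%%).",
                  n_dropped, nrow(cases)),
          class = "tempbias_matching_error")
  }
  if (n_dropped > 0) {
    warn(sprintf("%d case(s) dropped: no control left in their stratum.",
                 n_dropped))
  }
  mc$baseline_month <- mc$delivery_month
  mc$is_case <- 1L
  mt$is_case <- 0L
  patients <- dplyr::select(dplyr::bind_rows(mc, mt), -".stratum")
  out <- list(patients = patients,
              events = cohort$events[cohort$events$patient_id %in%
                                       patients$patient_id, ])
  attr(out, "vocabulary") <- attr(cohort, "vocabulary")
  attr(out, "params") <- attr(cohort, "params")
  attr(out, "n_dropped") <- n_dropped
  class(out) <- "claims_cohort"
  out
}

#' Assign observation windows under a study design
#'
#' @param patients Patients tibble of a matched cohort (needs
#'   `baseline_month` for event-indexed designs).
#' @param design A [study_design()].
#' @return The patients tibble with a `window_month` column (calendar
#'   month 1..12, `NA` when the event-indexed window would fall before the
#'   data year) and a logical `window_valid`.
#' @examples
#' cc <- match_controls(gen_claims_cohort(
#'   generator_params(n_cases = 50, n_controls = 50)), seed = 1)
#' head(assign_window(cc$patients, study_design("event_indexed")))
#' @export
assign_window <- function(patients, design) {
  stopifnot(inherits(design, "study_design"))
  if (design$anchor == "event_indexed") {
    if (!"baseline_month" %in% names(patients)) {
      abort("event-indexed designs need a `baseline_month` column (match first).",
            class = "tempbias_invalid_input")
    }
    wm <- patients$baseline_month - design$offset_months
    wm[!is.na(wm) & wm < 1] <- NA_integer_
  } else {
    wm <- rep(design$fixed_month, nrow(patients))
  }
  patients$window_month <- as.integer(wm)
  patients$window_valid <- !is.na(wm)
  patients
}

#' Binary occurrence features inside each patient's window
#'
#' One row per patient with a valid window: a 0/1 indicator per vocabulary
#' code for at least one occurrence of that code inside the patient's
#' window month, plus `age` and the case label.
#'
#' @param cohort A matched `claims_cohort`.
#' @param windows Patients tibble from [assign_window()].
#' @return A tibble with `patient_id`, `label`, `baseline_month`, `age`
#'   and one 0/1 column per code.
#' @examples
#' cc <- match_controls(gen_claims_cohort(
#'   generator_params(n_cases = 50, n_controls = 50)), seed = 1)
#' w <- assign_window(cc$patients, study_design("calendar_fixed"))
#' dim(extract_features(cc, w))
#' @export
extract_features <- function(cohort, windows) {
  stopifnot(inherits(cohort, "claims_cohort"))
  vocab <- attr(cohort, "vocabulary")$code
  pts <- windows[windows$window_valid, ]
  ev <- dplyr::inner_join(cohort$events,
                          dplyr::select(pts, "patient_id", "window_month"),
                          by = "patient_id")
  ev <- ev[ev$month == ev$window_month, c("patient_id", "code")]
  ev <- dplyr::distinct(ev)
  mat <- matrix(0L, nrow(pts), length(vocab),
                dimnames = list(pts$patient_id, vocab))
  if (nrow(ev) > 0) {
    mat[cbind(match(ev$patient_id, pts$patient_id),
              match(ev$code, vocab))] <- 1L
  }
  out <- tibble::tibble(
    patient_id = pts$patient_id,
    label = if ("is_case" %in% names(pts)) pts$is_case
            else as.integer(!is.na(pts$delivery_month)),
    baseline_month = if ("baseline_month" %in% names(pts)) pts$baseline_month
                     else pts$delivery_month,
    age = pts$age
  )
  dplyr::bind_cols(out, tibble::as_tibble(mat))
}

# Reference classifier: ridge-free logistic regression on the binary
# occurrence matrix + age. Returns a scoring closure. Codes absent from
# the training window get a zero weight.
logistic_classifier <- function(x_train, y_train) {
  keep <- c(TRUE, colSums(abs(x_train[, -1, drop = FALSE])) > 0)
  fit <- suppressWarnings(glm.fit(x_train[, keep, drop = FALSE], y_train,
                                  family = binomial()))
  beta <- rep(0, ncol(x_train))
  beta[keep] <- coef(fit)
  beta[is.na(beta)] <- 0
  function(x_new) as.numeric(plogis(x_new %*% beta))
}

#' Train under one design, evaluate under another
#'
#' The core of the prediction-window experiment. Patients are split
#' 80/20 at the patient level (before any windowing, so no patient can
#' appear in both sets); `n_models` models are trained on features
#' extracted under `train_design` and evaluated on features extracted
#' under `eval_design`, each model with its own split. The three canonical
#' studies are CC-CC (event-indexed / event-indexed), CC-Cohort
#' (event-indexed / calendar-fixed) and Cohort-Cohort
#' (calendar-fixed / calendar-fixed).
#'
#' @param cohort A matched `claims_cohort` (see [match_controls()]).
#' @param train_design,eval_design [study_design()] objects.
#' @param n_models Number of independently split/trained models.
#' @param prop_train Fraction of patients in the training set.
#' @param threshold Score threshold for the pooled confusion matrix.
#' @param classifier A function `(x_train, y_train) -> function(x_new)`
#'   returning scores in \[0, 1\]; the default is logistic regression on
#'   the binary occurrence matrix plus age.
#' @param seed Seed fixing all splits.
#' @return A list of class `tb_design_study`: `auroc` (tibble, one row per
#'   model), `confusion` (2x2 matrix pooled over models at `threshold`),
#'   `scores` (per evaluated patient and model: score, label, baseline
#'   month), plus the two designs.
#' @examples
#' \donttest{
#' cc <- match_controls(gen_claims_cohort(
#'   generator_params(n_cases = 400, n_controls = 400)), seed = 1)
#' rs <- run_design_study(cc, study_design("event_indexed"),
#'                        study_design("calendar_fixed"),
#'                        n_models = 2, seed = 1)
#' mean(rs$auroc$auroc)
#' }
#' @export
run_design_study <- function(cohort, train_design, eval_design,
                             n_models = 10L, prop_train = 0.8,
                             threshold = 0.5,
                             classifier = logistic_classifier,
                             seed = NULL) {
  stopifnot(inherits(cohort, "claims_cohort"),
            inherits(train_design, "study_design"),
            inherits(eval_design, "study_design"))
  if (!"is_case" %in% names(cohort$patients)) {
    abort("cohort must be matched first (see match_controls()).",
          class = "tempbias_invalid_input")
  }
  seed_rng(seed)
  pts <- cohort$patients
  feat_cols <- function(f) as.matrix(cbind(1, f[, -(1:3), drop = FALSE]))

  train_feat_all <- extract_features(cohort, assign_window(pts, train_design))
  eval_feat_all <- extract_features(cohort, assign_window(pts, eval_design))

  aurocs <- numeric(n_models)
  conf <- matrix(0, 2, 2, dimnames = list(truth = c("control", "case"),
                                          predicted = c("control", "case")))
  scores <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    idx <- sample.int(nrow(pts))
    n_tr <- floor(prop_train * nrow(pts))
    train_ids <- pts$patient_id[idx[seq_len(n_tr)]]
    eval_ids <- pts$patient_id[idx[-seq_len(n_tr)]]
    if (length(intersect(train_ids, eval_ids)) > 0) {
      abort("leakage guard tripped: a patient sits in both splits.",
            class = "tempbias_internal_error")
    }
    tr <- train_feat_all[train_feat_all$patient_id %in% train_ids, ]
    ev <- eval_feat_all[eval_feat_all$patient_id %in% eval_ids, ]
    if (length(unique(tr$label)) < 2 || length(unique(ev$label)) < 2) {
      abort("degenerate single-class split.",
            class = "tempbias_estimation_failure")
    }
    score_fn <- classifier(feat_cols(tr), tr$label)
    sc <- score_fn(feat_cols(ev))
    aurocs[m] <- as.numeric(pROC::auc(pROC::roc(ev$label, sc, quiet = TRUE,
                                                direction = "<")))
    pred <- as.integer(sc >= threshold)
    conf <- conf + table(factor(ev$label, 0:1), factor(pred, 0:1))
    scores[[m]] <- tibble::tibble(model = m, patient_id = ev$patient_id,
                                  label = ev$label,
                                  baseline_month = ev$baseline_month,
                                  score = sc)
  }
  structure(
    list(auroc = tibble::tibble(model = seq_len(n_models), auroc = aurocs),
         confusion = conf,
         scores = dplyr::bind_rows(scores),
         train_design = train_design, eval_design = eval_design,
         threshold = threshold, seed = seed),
    class = "tb_design_study"
  )
}

#' @export
print.tb_design_study <- function(x, ...) {
  cat(sprintf("<tb_design_study> train %s / eval %s\n",
              x$train_design$anchor, x$eval_design$anchor))
  cat(sprintf("  mean AUROC %.3f over %d models (range %.3f-%.3f)\n",
              mean(x$auroc$auroc), nrow(x$auroc),
              min(x$auroc$auroc), max(x$auroc$auroc)))
  print(x$confusion)
  invisible(x)
}
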