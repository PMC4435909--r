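#' Fit an intercept adjustment (recalibration-in-the-large)
#'
#' The correction factor is the log odds ratio of the observed outcome
#' prevalence to the mean predicted risk in the validation set:
#' `delta = log(prev / (1 - prev)) - log(pbar / (1 - pbar))`. Added to
#' every linear predictor it shifts the mean predicted risk towards the
#' population prevalence while leaving the ranking of participants — and
#' hence discrimination — unchanged.
#'
#' Because the logistic transform is nonlinear, a single adjustment does
#' not make the mean predicted risk exactly equal to the prevalence;
#' `iterate = TRUE` repeats fit-and-apply until they agree to `tol`
#' (provided as a numerical cross-check, not as the primary method).
#'
#' @param p Predicted probabilities.
#' @param y 0/1 outcomes.
#' @param iterate Iterate the adjustment to convergence (default `FALSE`:
#'   the one-shot published formula).
#' @param tol,max_iter Convergence control for `iterate = TRUE`.
#' @return List of class `intercept_adjustment` with `delta`,
#'   `observed_prev`, `mean_predicted` and `iterations`.
#' @export
fit_intercept_adjustment <- function(p, y, iterate = FALSE, tol = 1e-8,
                                     max_iter = 50) {
  .check_preds(p, y)
  prev <- mean(y)
  pbar <- mean(p)
  if (prev <= 0 || prev >= 1) {
    stop("intercept adjustment undefined: observed prevalence is ", prev,
         call. = FALSE)
  }
  if (pbar <= 0 || pbar >= 1) {
    stop("intercept adjustment undefined: mean predicted risk is ", pbar,
         call. = FALSE)
  }
  delta <- stats::qlogis(prev) - stats::qlogis(pbar)
  iters <- 1L
  if (iterate) {
    total <- delta
    p_cur <- stats::plogis(stats::qlogis(p) + delta)
    while (abs(mean(p_cur) - prev) > tol && iters < max_iter) {
      step <- stats::qlogis(prev) - stats::qlogis(mean(p_cur))
      total <- total + step
      p_cur <- stats::plogis(stats::qlogis(p) + total)
      iters <- iters + 1L
    }
    delta <- total
  }
  structure(list(delta = delta, observed_prev = prev, mean_predicted = pbar,
                 iterations = iters),
            class = "intercept_adjustment")
}

#' Apply an intercept adjustment to a model specification
#'
#' Returns a new model with the correction factor added to the intercept
#' (for point-score models, to the score-to-logit mapping intercept so the
#' adjustment acts on the logit scale); coefficients are untouched. The
#' adjusted model's provenance note records the source model and delta.
#'
#' @param spec A [model_spec] with the logistic link.
#' @param adj An [fit_intercept_adjustment()] result (or a number, taken
#'   as delta).
#' @return The adjusted [model_spec].
#' @export
apply_intercept_adjustment <- function(spec, adj) {
  validate_model_spec(spec)
  if (!identical(spec$link, "logistic")) {
    stop("intercept adjustment requires the logistic link", call. = FALSE)
  }
  delta <- if (is.numeric(adj)) adj else adj$delta
  out <- spec
  if (is.null(out$score_to_lp)) {
    out$intercept <- out$intercept + delta
  } else {
    out$score_to_lp$intercept <- out$score_to_lp$intercept + delta
  }
  out$source_ref <- paste0(spec$source_ref %||% spec$name,
                           " [intercept adjusted, delta = ",
                           signif(delta, 6), "]")
  validate_model_spec(out)
  out
}

#' Shift predicted probabilities on the logit scale
#'
#' Convenience for recalibrating probabilities directly (equivalent to
#' rescoring with the adjusted model): `plogis(qlogis(p) + delta)`.
#'
#' @param p Probabilities strictly inside (0, 1).
#' @param delta Logit-scale shift.
#' @return Adjusted probabilities.
#' @export
adjust_probabilities <- function(p, delta) {
  stats::plogis(stats::qlogis(p) + delta)
}
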