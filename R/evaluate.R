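#' Voting-stage score of a model for one stimulus
#'
#' Each detector casts its binary detection, weighted by its
#' log-likelihood weight.  The raw score is the weighted sum; the
#' normalized score divides the sum of detected weights by the sum of all
#' weights, so it lies in \[0, 1\] (0: nothing detected, 1: everything
#' detected).
#'
#' @param model a fitted `mif_model` (non-empty).
#' @param coch a cochleagram.
#' @param mode normalization mode (defaults to the training mode).
#' @param kappa top-down threshold scale.
#' @return List with `raw`, `normalized`, and the binary `detections`.
#' @export
voting_score <- function(model, coch, mode = model$mode, kappa = 1) {
  assert_that(inherits(model, "mif_model"), "model must be a mif_model")
  assert_that(length(model$fds) > 0, "cannot score with an empty model")
  det <- vapply(model$fds, function(fd) fd_detect(fd, coch, mode, kappa),
                integer(1))
  w <- vapply(model$fds, function(fd) fd$weight, numeric(1))
  list(raw = sum(w * det), normalized = sum(w * det) / sum(w),
       detections = det)
}

#' Rank-based area under the ROC curve
#'
#' The probability that a randomly drawn within-class score exceeds a
#' randomly drawn outside-class score, with ties counted one half --
#' identical to brute-force pairwise comparison, computed from ranks.
#'
#' @param scores_within,scores_outside numeric score vectors.
#' @return AUC in \[0, 1\].
#' @export
auc_from_scores <- function(scores_within, scores_outside) {
  w <- as.numeric(scores_within); o <- as.numeric(scores_outside)
  assert_that(length(w) > 0 && length(o) > 0, "both score sets must be non-empty")
  r <- rank(c(w, o), ties.method = "average")
  (sum(r[seq_along(w)]) - length(w) * (length(w) + 1) / 2) /
    (length(w) * length(o))
}

#' Sensitivity index from an AUC
#'
#' `d' = sqrt(2) * qnorm(AUC)`.  Degenerate AUCs of exactly 0 or 1 are
#' clipped to `[eps, 1 - eps]` before the probit; when the number of
#' score pairs behind the AUC is supplied, `eps = 1 / (2 * n_pairs)` (half
#' a pairwise-comparison resolution step).
#'
#' @param auc AUC in \[0, 1\].
#' @param n_pairs optional number of within-by-outside score pairs used to
#'   estimate the AUC.
#' @param eps clipping bound used when `n_pairs` is not given.
#' @return d-prime (scalar).
#' @export
dprime_from_auc <- function(auc, n_pairs = NULL, eps = 1e-6) {
  assert_that(is_scalar_number(auc) && auc >= 0 && auc <= 1,
              "auc must be in [0, 1]")
  if (!is.null(n_pairs)) eps <- 1 / (2 * n_pairs)
  sqrt(2) * stats::qnorm(min(max(auc, eps), 1 - eps))
}

#' Winner-take-all go/no-go read-out
#'
#' The difference between the normalized target-model and distractor-model
#' responses, in \[-1, 1\]: 1 when every target feature and no distractor
#' feature is detected, -1 in the opposite case.  The ideal observer goes
#' iff the value is strictly positive.
#'
#' @param target_model,distractor_model fitted `mif_model`s.
#' @param coch a cochleagram.
#' @param mode normalization mode.
#' @param kappa top-down threshold scale.
#' @return List with `value` and `decision` (`"go"` / `"no-go"`).
#' @export
wta_response <- function(target_model, distractor_model, coch,
                         mode = target_model$mode, kappa = 1) {
  vt <- voting_score(target_model, coch, mode, kappa)$normalized
  vd <- voting_score(distractor_model, coch, mode, kappa)$normalized
  value <- vt - vd
  list(value = value, decision = if (value > 0) "go" else "no-go")
}

#' Two-parameter logistic decision map
#'
#' `F(x; k, lambda) = lambda + (1 - 2*lambda) / (1 + exp(-k*x))`: maps a
#' winner-take-all output in \[-1, 1\] to a go probability bounded
#' symmetrically in `[lambda, 1 - lambda]`.  `F(0) = 0.5` for every
#' `(k, lambda)`.
#'
#' @param x winner-take-all output value(s).
#' @param k slope.
#' @param lambda symmetric floor/ceiling in `[0, 0.5)`.
#' @return Go probability/probabilities.
#' @export
logistic_go_rate <- function(x, k, lambda) {
  lambda + (1 - 2 * lambda) / (1 + exp(-k * x))
}

# go/no-go d' from WTA values through the logistic map: the go rate is
# averaged over targets (hit) and distractors (false alarm), then
# d' = qnorm(hit) - qnorm(fa)
behavior_dprime <- function(wta_target, wta_distractor, k, lambda,
                            eps = 1e-6) {
  hit <- mean(logistic_go_rate(wta_target, k, lambda))
  fa <- mean(logistic_go_rate(wta_distractor, k, lambda))
  stats::qnorm(min(max(hit, eps), 1 - eps)) -
    stats::qnorm(min(max(fa, eps), 1 - eps))
}

#' Fit the behavior-matching logistic map
#'
#' Learns `(k, lambda)` so that the model's go/no-go performance on clean
#' stimuli matches behavioral performance; the fitted map is then applied
#' unchanged to degraded conditions.  Two objectives are available:
#'
#' * d-prime matching (the default when only `target_dprime` is given):
#'   minimizes `|model d' - behavioral d'|`, with the model's hit (false
#'   alarm) rate the mean mapped go-rate over target (distractor) stimuli
#'   and `d' = qnorm(hit) - qnorm(fa)`.  A single scalar constraint does
#'   not pin down both parameters, so ties are resolved by the search
#'   order; any returned pair reproduces the behavioral d'.
#' * rate matching (when `target_hit` and `target_fa` are given): matches
#'   the behavioral hit and false-alarm rates jointly.  Note that even two
#'   rates may not pin down both parameters: slope and floor trade off
#'   along a near-exact ridge for typical output distributions.
#' * curve matching (when `target_go_rates` is given): least-squares fit of
#'   the full psychometric curve to per-stimulus go probabilities (ordered
#'   as `c(wta_target, wta_distractor)`).  This is the identifiable
#'   objective: it recovers a planted `(k, lambda)` pair.
#'
#' The fit is a coarse grid search refined by bounded optimization.  If the
#' behavioral target is unattainable within the bounds, the boundary fit is
#' returned with a warning.
#'
#' @param wta_target,wta_distractor clean-condition winner-take-all outputs
#'   for target and distractor stimuli.
#' @param target_dprime behavioral d-prime to match.
#' @param target_hit,target_fa behavioral hit and false-alarm rates to
#'   match (both or neither).
#' @param target_go_rates per-stimulus go probabilities to match, ordered
#'   as `c(wta_target, wta_distractor)`.
#' @return An object of class `behavior_map`: list with `k`, `lambda`,
#'   `achieved_dprime`, `objective`.  `predict(map, x)` returns go rates.
#' @export
fit_behavior_map <- function(wta_target, wta_distractor,
                             target_dprime = NULL, target_hit = NULL,
                             target_fa = NULL, target_go_rates = NULL) {
  curve_match <- !is.null(target_go_rates)
  rate_match <- !curve_match && !is.null(target_hit) && !is.null(target_fa)
  assert_that(curve_match || rate_match || !is.null(target_dprime),
              "supply target_dprime, target_hit with target_fa, or target_go_rates")
  # objectives are scaled up so the optimizer resolves the shallow ridge
  # along which k and lambda trade off almost exactly
  obj <- if (curve_match) {
    x_all <- c(wta_target, wta_distractor)
    assert_that(length(target_go_rates) == length(x_all),
                "target_go_rates must cover every stimulus")
    function(p)
      1e8 * mean((logistic_go_rate(x_all, exp(p[1]), p[2]) -
                    target_go_rates)^2)
  } else if (rate_match) {
    td <- stats::qnorm(min(max(target_hit, 1e-6), 1 - 1e-6))
    tf <- stats::qnorm(min(max(target_fa, 1e-6), 1 - 1e-6))
    function(p) {
      hit <- mean(logistic_go_rate(wta_target, exp(p[1]), p[2]))
      fa <- mean(logistic_go_rate(wta_distractor, exp(p[1]), p[2]))
      1e8 * ((stats::qnorm(min(max(hit, 1e-6), 1 - 1e-6)) - td)^2 +
               (stats::qnorm(min(max(fa, 1e-6), 1 - 1e-6)) - tf)^2)
    }
  } else {
    function(p)
      1e8 * (behavior_dprime(wta_target, wta_distractor, exp(p[1]), p[2]) -
               target_dprime)^2
  }
  grid <- expand.grid(logk = log(c(0.2, 0.5, 1, 2, 5, 10, 25, 60, 150)),
                      lambda = seq(0.005, 0.45, by = 0.037))
  vals <- apply(grid, 1, obj)
  # refine from the few best grid cells; the objective has a shallow
  # ridge (k and lambda partly trade off), so polish tightly
  starts <- order(vals)[1:4]
  fits <- lapply(starts, function(i) {
    f1 <- stats::optim(as.numeric(grid[i, ]), obj, method = "L-BFGS-B",
                       lower = c(log(1e-3), 1e-6),
                       upper = c(log(1e4), 0.499),
                       control = list(factr = 1, pgtol = 1e-14, maxit = 1000))
    stats::optim(f1$par, obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 2000))
  })
  fit <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  k <- exp(fit$par[1])
  lambda <- min(max(fit$par[2], 0), 0.499)
  achieved <- behavior_dprime(wta_target, wta_distractor, k, lambda)
  if (!rate_match && !curve_match && abs(achieved - target_dprime) > 0.05)
    warning("behavioral d-prime not attainable within the map's bounds; returning boundary fit")
  structure(list(k = k, lambda = lambda, achieved_dprime = achieved,
                 objective = if (curve_match) "curve" else
                   if (rate_match) "rates" else "dprime"),
            class = "behavior_map")
}

#' @export
print.behavior_map <- function(x, ...) {
  cat(sprintf("<behavior_map> k = %.4g, lambda = %.4g (achieved d' = %.3f, %s objective)\n",
              x$k, x$lambda, x$achieved_dprime, x$objective))
  invisible(x)
}

#' @export
predict.behavior_map <- function(object, newdata, ...) {
  logistic_go_rate(newdata, object$k, object$lambda)
}
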