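#' Akaike weights from AICc values
#'
#' wi = exp(-(AICci - min AICc)/2) / sum_j exp(-(AICcj - min AICc)/2); the
#' min-subtraction makes the computation overflow-free for any finite input.
#' Here the "models" are fits of the same model to alternative trees of a
#' calibration sample.
#'
#' @param aicc Numeric vector of finite AICc values.
#' @return Weights summing to 1.
#' @examples
#' akaike_weights(c(0, 2)) # ~0.7311, 0.2689
#' @export
akaike_weights <- function(aicc) {
  if (!length(aicc)) stop("empty AICc vector")
  if (any(!is.finite(aicc))) stop("non-finite AICc values")
  d <- aicc - min(aicc)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Fisher z-transform of a correlation (and inverse)
#'
#' z = atanh(r) stabilizes the variance of a Pearson correlation so that
#' averaging happens on an approximately normal scale; `fisher_inv` maps back
#' with tanh. Values with |r| >= 1 are rejected unless `clamp = TRUE`, which
#' clamps to 1 - 1e-12 (opt-in, never silent default).
#'
#' @param r Correlation(s), |r| < 1.
#' @param z Fisher z value(s).
#' @param clamp Clamp |r| >= 1 to the open interval instead of erroring.
#' @return Transformed value(s).
#' @export
fisher_z <- function(r, clamp = FALSE) {
  if (any(abs(r) >= 1)) {
    if (!clamp) stop("|r| >= 1: Fisher z undefined (set clamp = TRUE to clamp)")
    r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  }
  atanh(r)
}

#' @rdname fisher_z
#' @export
fisher_inv <- function(z) tanh(z)

#' Weighted empirical quantile (inclusive cumulative-weight convention)
#'
#' Quantile q is the smallest value whose cumulative weight reaches q; this
#' convention is stated so ensemble CIs are bit-stable across platforms.
#'
#' @param x Numeric values.
#' @param w Nonnegative weights (normalized internally).
#' @param probs Probabilities.
#' @return Quantiles, one per element of `probs`.
#' @export
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0)
  o <- order(x)
  x <- x[o]
  cw <- cumsum(w[o]) / sum(w)
  vapply(probs, function(q) x[which(cw >= q - 1e-12)[1]], numeric(1))
}

#' Combine per-tree rate-matrix fits into one correlation estimate
#'
#' Per-tree correlations are Fisher-transformed, averaged with Akaike weights
#' computed from the per-tree AICc, and back-transformed; the 95% interval is,
#' by default, the weighted empirical 2.5/97.5 percentile of the per-tree r
#' distribution (the across-tree uncertainty a calibration sample targets).
#' The alternative `"fisher-se"` interval is tanh(z-bar +/- 1.96 * SE) with SE
#' from the weighted variance of the per-tree z values.
#'
#' @param fits List of [fit_rate_matrix()] results (or a data frame with
#'   columns `r` and `AICc`).
#' @param ci_method `"quantile"` (default) or `"fisher-se"`.
#' @param level Interval level, default 0.95.
#' @return Object of class `ensemble_result`: `mean_r`, `ci` (lower, upper),
#'   `per_tree` data frame (r, AICc, weight), `n_trees`, `ci_method`, `level`.
#' @examples
#' f <- data.frame(r = c(0.6, 0.8), AICc = c(10, 10))
#' summarize_ensemble(f)$mean_r # tanh(mean(atanh(r))) ~= 0.71205
#' @export
summarize_ensemble <- function(fits, ci_method = c("quantile", "fisher-se"),
                               level = 0.95) {
  ci_method <- match.arg(ci_method)
  if (is.data.frame(fits)) {
    r <- fits$r; aicc <- fits$AICc
  } else {
    r <- vapply(fits, `[[`, numeric(1), "r")
    aicc <- vapply(fits, `[[`, numeric(1), "AICc")
  }
  if (!length(r)) stop("no fits supplied")
  level_stated <- level
  if (all(r == r[1])) {
    # unanimous sample (including the degenerate |r| = 1 case): the weighted
    # mean and both interval bounds are that value, no transform needed
    w <- akaike_weights(aicc)
    return(structure(
      list(mean_r = r[1], ci = c(lower = r[1], upper = r[1]),
           per_tree = data.frame(r = r, AICc = aicc, weight = w),
           n_trees = length(r), ci_method = ci_method, level = level_stated),
      class = "ensemble_result"))
  }
  if (any(abs(r) >= 1)) stop("per-tree |r| >= 1; cannot Fisher-average")
  w <- akaike_weights(aicc)
  z <- fisher_z(r)
  zbar <- sum(w * z)
  mean_r <- fisher_inv(zbar)
  alpha <- (1 - level) / 2
  ci <- if (ci_method == "quantile") {
    weighted_quantile(r, w, c(alpha, 1 - alpha))
  } else {
    se <- sqrt(sum(w * (z - zbar)^2))
    fisher_inv(zbar + stats::qnorm(c(alpha, 1 - alpha)) * se)
  }
  names(ci) <- c("lower", "upper")
  structure(
    list(mean_r = mean_r, ci = ci,
         per_tree = data.frame(r = r, AICc = aicc, weight = w),
         n_trees = length(r), ci_method = ci_method, level = level),
    class = "ensemble_result"
  )
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat("Ensemble over", x$n_trees, "tree(s):\n")
  cat(sprintf("  weighted mean r = %.4f, %d%% CI [%.4f, %.4f] (%s)\n",
              x$mean_r, round(100 * x$level), x$ci[1], x$ci[2], x$ci_method))
  invisible(x)
}
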