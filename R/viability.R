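## Calibration of MTT viability on PARAFAC scores: multiple linear
## regression, leave-one-out cross-validation, and the predicted-vs-
## reference accordance line.

#' Regress viability on PARAFAC component scores
#'
#' Ordinary least squares of viability (% of control) on the score
#' matrix, with intercept. One model is fitted per cell line in the
#' surrounding pipeline; this function fits one set of samples.
#'
#' @param scores I x F matrix of component scores
#' @param viability length-I numeric vector of viability (\% of control)
#' @param cell_line optional label stored with the model
#' @param max_condition condition number of the design above which the
#'   fit is refused as collinear
#' @return object of class \code{viability_model}: coefficients
#'   (intercept first), fitted values, training R2/RMSE and
#'   leave-one-out R2cv/RMSECV
#' @export
fit_mlr <- function(scores, viability, cell_line = NA_character_,
                    max_condition = 1e10) {
  scores <- as.matrix(scores)
  I <- nrow(scores); F <- ncol(scores)
  stopifnot(length(viability) == I)
  if (I <= F + 1)
    stop("need more samples (", I, ") than coefficients (", F + 1, ")")
  X <- cbind(`(Intercept)` = 1, scores)
  kap <- kappa(X, exact = TRUE)
  if (qr(X)$rank < ncol(X) || kap > max_condition)
    stop("collinear score columns (design condition number ",
         format(kap, digits = 4), ")")
  fit <- stats::lm.fit(X, viability)
  fitted <- viability - fit$residuals
  tss <- sum((viability - mean(viability))^2)
  r2 <- if (tss > 0) 1 - sum(fit$residuals^2) / tss else NA_real_
  cv <- loocv_predict(scores, viability)
  structure(
    list(cell_line = cell_line, F = F,
         coefficients = fit$coefficients,
         fitted = fitted,
         r_squared = r2,
         rmse = sqrt(mean(fit$residuals^2)),
         r_squared_cv = cv$r_squared_cv,
         rmsecv = cv$rmsecv),
    class = "viability_model")
}

#' @export
print.viability_model <- function(x, ...) {
  cat("Viability MLR model",
      if (!is.na(x$cell_line)) paste0("(", x$cell_line, ")"),
      "on", x$F, "component scores\n")
  cat(sprintf("  R2 = %.4f  RMSE = %.3f  R2cv = %.4f  RMSECV = %.3f\n",
              x$r_squared, x$rmse, x$r_squared_cv, x$rmsecv))
  invisible(x)
}

#' Predict viability from scores with a fitted MLR model
#'
#' @param object a \code{viability_model}
#' @param scores I x F score matrix
#' @param ... unused
#' @return numeric vector of predicted viability (\%); predictions
#'   outside 0-100 are flagged via the \code{"out_of_range"} attribute
#'   but deliberately not clipped, preserving linearity for the
#'   accordance analysis
#' @export
predict.viability_model <- function(object, scores, ...) {
  scores <- as.matrix(scores)
  stopifnot(ncol(scores) == object$F)
  pred <- drop(cbind(1, scores) %*% object$coefficients)
  oor <- which(pred < 0 | pred > 100)
  if (length(oor)) attr(pred, "out_of_range") <- oor
  pred
}

#' Leave-one-out cross-validation of the viability regression
#'
#' Each sample's prediction comes from the model refitted without it.
#' For OLS this is computed exactly through the hat-matrix identity
#' \code{e_loo = e / (1 - h)}, equivalent to refitting per fold.
#'
#' @inheritParams fit_mlr
#' @return list with \code{predictions} (out-of-fold), \code{r_squared_cv}
#'   (\code{1 - PRESS/TSS}) and \code{rmsecv}
#' @export
loocv_predict <- function(scores, viability) {
  scores <- as.matrix(scores)
  I <- nrow(scores)
  stopifnot(length(viability) == I, I > ncol(scores) + 1)
  X <- cbind(1, scores)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) stop("collinear score columns")
  res <- qr.resid(qrx, viability)
  h <- rowSums(qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]^2)
  if (any(h >= 1 - 1e-12))
    stop("a sample with leverage 1 cannot be cross-validated")
  e_loo <- res / (1 - h)
  pred <- viability - e_loo
  tss <- sum((viability - mean(viability))^2)
  list(predictions = pred,
       r_squared_cv = if (tss > 0) 1 - sum(e_loo^2) / tss else NA_real_,
       rmsecv = sqrt(mean(e_loo^2)))
}

#' Accordance line between reference and predicted viability
#'
#' Fits predicted group means against reference (MTT) group means by
#' ordinary least squares and reports the slope \code{a} and intercept
#' \code{b} with 95\% confidence halfwidths from the t distribution.
#' Perfect accordance between the two methods is the identity line
#' \code{y = x}; the fit is flagged ideal-consistent when 1 lies in the
#' slope CI and 0 in the intercept CI, i.e. when the deviation from
#' identity is not statistically significant at alpha = 0.05.
#'
#' @param reference_means per-dose-group reference viability means (\%)
#' @param predicted_means per-dose-group predicted viability means (\%)
#' @param weights optional per-group weights (e.g. \code{1/sd^2});
#'   default unweighted
#' @param conf_level confidence level for the intervals
#' @return object of class \code{accordance_result}: slope, intercept,
#'   their CI halfwidths, R2 and the ideal-consistency flag
#' @export
accordance_fit <- function(reference_means, predicted_means,
                           weights = NULL, conf_level = 0.95) {
  x <- as.numeric(reference_means); y <- as.numeric(predicted_means)
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3) stop("need at least 3 dose groups for the accordance fit")
  fit <- if (is.null(weights)) stats::lm(y ~ x)
         else stats::lm(y ~ x, weights = weights)
  sm <- summary(fit)
  co <- sm$coefficients
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 2)
  a <- co["x", "Estimate"]; b <- co["(Intercept)", "Estimate"]
  ci_a <- tq * co["x", "Std. Error"]
  ci_b <- tq * co["(Intercept)", "Std. Error"]
  structure(
    list(slope = a, slope_ci_halfwidth = ci_a,
         intercept = b, intercept_ci_halfwidth = ci_b,
         r_squared = sm$r.squared,
         conf_level = conf_level, n_groups = n,
         ideal_consistent = (abs(a - 1) <= ci_a) && (abs(b) <= ci_b)),
    class = "accordance_result")
}

#' @export
print.accordance_result <- function(x, ...) {
  cat(sprintf("Accordance fit over %d dose groups:\n", x$n_groups))
  cat(sprintf("  a = %.2f ± %.2f, b = %.2f ± %.2f, R2 = %.3f\n",
              x$slope, x$slope_ci_halfwidth,
              x$intercept, x$intercept_ci_halfwidth, x$r_squared))
  cat("  consistent with the ideal y = x:",
      if (x$ideal_consistent) "yes" else "no", "\n")
  invisible(x)
}
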