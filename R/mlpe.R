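#' Maximum-likelihood population-effects (MLPE) regression
#'
#' Fits the pairwise mixed model
#' \deqn{y_{ij} = \beta_0 + \sum_k \beta_k x_{k,ij} + u_i + u_j +
#'   \varepsilon_{ij}}
#' for a response distance matrix (e.g. pairwise GST') and predictor
#' distance matrices (e.g. effective resistances), where each group
#' contributes a random effect `u ~ N(0, sigma_u^2)` that enters every pair
#' containing it — the population-effects structure that accounts for the
#' non-independence of pairwise data. The likelihood is profiled over the
#' variance ratio and maximised by bounded quasi-Newton search on the log
#' scale with two starts; the covariance `sigma_u^2 Z Z' + sigma^2 I` is
#' handled through the Woodbury identity, so only group-sized matrices are
#' ever factorised.
#'
#' Pairs with a non-finite predictor (disconnected resistances) are
#' excluded; remaining predictor entries must be finite.
#'
#' @param y response [pairwise_matrix].
#' @param predictors named list of predictor [pairwise_matrix] objects with
#'   the same labels (may be empty for the intercept-only model).
#' @param standardize z-score the predictors over included pairs (default
#'   `TRUE`, giving standardized coefficients).
#' @param method `"ML"` (default; required for AIC comparison of models
#'   with different fixed effects) or `"REML"`.
#' @param conf_level confidence level for Wald intervals.
#' @return an `mlpe_fit`: coefficients with SEs and CIs, variance
#'   components, log-likelihood, AIC and AICc (with
#'   `p = n_fixed + 2` parameters and `n = n_pairs`).
#' @export
fit_mlpe <- function(y, predictors = list(), standardize = TRUE,
                     method = c("ML", "REML"), conf_level = 0.95) {
  method <- match.arg(method)
  labs <- do.call(check_aligned, c(list(y), unname(predictors)))
  g <- length(labs)
  if (g < 3L) stop("need at least three groups", call. = FALSE)
  idx <- which(upper.tri(y), arr.ind = TRUE)
  yv <- y[upper.tri(y)]
  Xraw <- if (length(predictors))
    vapply(predictors, function(p) p[upper.tri(p)], numeric(length(yv)))
  else matrix(numeric(0), nrow = length(yv), ncol = 0)
  if (is.null(dim(Xraw))) Xraw <- matrix(Xraw, ncol = length(predictors))
  keep <- is.finite(yv) & (if (ncol(Xraw)) apply(is.finite(Xraw), 1, all)
                           else TRUE)
  if (any(!is.finite(yv)))
    stop("response contains non-finite pairs", call. = FALSE)
  n_dropped <- sum(!keep)
  idx <- idx[keep, , drop = FALSE]; yv <- yv[keep]
  Xraw <- Xraw[keep, , drop = FALSE]
  n <- length(yv)
  if (n < 3L) stop("too few usable pairs", call. = FALSE)
  scales <- rep(1, ncol(Xraw)); centers <- rep(0, ncol(Xraw))
  if (standardize && ncol(Xraw)) {
    centers <- colMeans(Xraw)
    scales <- apply(Xraw, 2, stats::sd)
    scales[scales == 0] <- 1
    Xraw <- sweep(sweep(Xraw, 2, centers), 2, scales, "/")
  }
  X <- cbind(`(Intercept)` = 1, Xraw)
  if (ncol(Xraw))
    colnames(X)[-1] <- names(predictors)
  # incidence: each pair loads groups i and j
  Z <- Matrix::sparseMatrix(i = rep(seq_len(n), 2L),
                            j = c(idx[, 1], idx[, 2]),
                            x = 1, dims = c(n, g))
  ZtZ <- as.matrix(Matrix::crossprod(Z))
  Zd <- as.matrix(Z)
  p_fix <- ncol(X)

  prof <- function(lambda) {
    # W = (I + lambda Z Z')^{-1} via Woodbury; returns profiled quantities
    M <- diag(g) + lambda * ZtZ
    cM <- chol(M)
    Wmult <- function(B) {
      B - lambda * Zd %*% backsolve(cM, backsolve(cM, crossprod(Zd, B),
                                                  transpose = TRUE))
    }
    WX <- Wmult(X); Wy <- Wmult(yv)
    XtWX <- crossprod(X, WX)
    XtWy <- crossprod(X, Wy)
    beta <- solve(XtWX, XtWy)
    r <- yv - X %*% beta
    rWr <- sum(r * Wmult(r))
    logdet <- 2 * sum(log(diag(cM)))     # log|I + lambda ZZ'|
    if (method == "ML") {
      s2 <- rWr / n
      ll <- -0.5 * (n * log(2 * pi) + n * log(s2) + logdet + n)
    } else {
      s2 <- rWr / (n - p_fix)
      ll <- -0.5 * ((n - p_fix) * log(2 * pi) +
                    (n - p_fix) * log(s2) + logdet +
                    determinant(XtWX, logarithm = TRUE)$modulus +
                    (n - p_fix))
    }
    list(ll = as.numeric(ll), beta = as.numeric(beta), s2 = as.numeric(s2),
         XtWX = XtWX, lambda = lambda)
  }

  obj <- function(loglam) -prof(exp(loglam))$ll
  best <- NULL
  for (start in c(-2, 2)) {
    op <- stats::optim(start, obj, method = "L-BFGS-B",
                       lower = -25, upper = 25,
                       control = list(factr = 1e4))
    if (is.null(best) || op$value < best$value) best <- op
  }
  cand <- prof(exp(best$par))
  at_zero <- prof(0)                     # boundary sigma_u^2 = 0
  if (at_zero$ll >= cand$ll) { fit <- at_zero; lambda <- 0 }
  else { fit <- cand; lambda <- fit$lambda }
  sigma2 <- fit$s2
  sigma_u2 <- lambda * sigma2
  vcov_beta <- solve(fit$XtWX) * sigma2
  se <- sqrt(diag(vcov_beta))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  coefs <- data.frame(
    term = colnames(X), estimate = fit$beta, se = se,
    ci_lower = fit$beta - zq * se, ci_upper = fit$beta + zq * se,
    stringsAsFactors = FALSE)
  ll <- fit$ll
  p <- p_fix + 2                         # fixed effects + two variances
  aic <- -2 * ll + 2 * p
  aicc <- if (n - p - 1 > 0) aic + 2 * p * (p + 1) / (n - p - 1) else Inf
  structure(list(
    coefficients = coefs, sigma_u2 = sigma_u2, sigma2 = sigma2,
    log_likelihood = ll, n_pairs = n, n_groups = g, n_dropped = n_dropped,
    AIC = aic, AICc = aicc, method = method, p = p,
    standardize = standardize, centers = centers, scales = scales,
    predictor_names = names(predictors)),
    class = "mlpe_fit")
}

#' @export
print.mlpe_fit <- function(x, ...) {
  cat(sprintf("<mlpe_fit> %s, %d pairs over %d groups\n", x$method,
              x$n_pairs, x$n_groups))
  print(x$coefficients, row.names = FALSE, digits = 4)
  cat(sprintf("  sigma_u^2 = %.5g, sigma^2 = %.5g\n", x$sigma_u2, x$sigma2))
  cat(sprintf("  logLik = %.4f, AIC = %.3f, AICc = %.3f\n",
              x$log_likelihood, x$AIC, x$AICc))
  invisible(x)
}

#' Predict pairwise values from an MLPE fit (fixed effects only)
#'
#' @param object an `mlpe_fit`.
#' @param newdata matrix/data.frame of raw predictor values, columns in the
#'   fitted predictor order.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.mlpe_fit <- function(object, newdata, ...) {
  b <- object$coefficients$estimate
  if (length(b) == 1L) return(rep(b, nrow(as.matrix(newdata))))
  Xn <- as.matrix(newdata)
  Xn <- sweep(sweep(Xn, 2, object$centers), 2, object$scales, "/")
  as.numeric(b[1] + Xn %*% b[-1])
}

#' AICc model-selection table
#'
#' Ranks a set of MLPE fits of the same response by AICc, reporting
#' delta-AICc, Akaike weights and cumulative weights, with the
#' distance-only null model included as its own row.
#'
#' @param fits named list of `mlpe_fit` objects.
#' @param null_fit optional distance-only `mlpe_fit`, added under the label
#'   `"distance"`.
#' @return a `model_table` data.frame sorted by AICc.
#' @export
model_table <- function(fits, null_fit = NULL) {
  if (!is.null(null_fit)) fits <- c(fits, list(distance = null_fit))
  if (!length(fits)) stop("no fits", call. = FALSE)
  np <- vapply(fits, function(f) f$n_pairs, numeric(1))
  if (length(unique(np)) != 1L)
    stop("fits use different pair sets", call. = FALSE)
  aicc <- vapply(fits, function(f) f$AICc, numeric(1))
  ll <- vapply(fits, function(f) f$log_likelihood, numeric(1))
  ord <- order(aicc, names(fits))
  aicc <- aicc[ord]; ll <- ll[ord]
  delta <- aicc - aicc[1]
  w <- exp(-delta / 2); w <- w / sum(w)
  out <- data.frame(model = names(fits)[ord], AICc = aicc,
                    delta_AICc = delta, weight = w,
                    cum_weight = cumsum(w), log_likelihood = ll,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("model_table", "data.frame")
  out
}

#' Two-model significance rule for a resistance predictor
#'
#' A resistance surface is judged to affect gene flow over-and-above
#' distance when the standardized resistance coefficient has a positive
#' 95% confidence interval in *both* the single-predictor model
#' (`GenDist ~ RD`) and the model that also includes the geographic-null
#' distance (`GenDist ~ RD + distance`). Near-perfect collinearity between
#' the resistance and the null distance (|r| > 0.999) is flagged and the
#' variable declared non-significant, since the two effects cannot be
#' separated.
#'
#' @param y response [pairwise_matrix] (differentiation).
#' @param rd resistance [pairwise_matrix].
#' @param geo_null geographic-null [pairwise_matrix].
#' @param conf_level CI level (default 0.95).
#' @return list: `significant`, `collinear`, the two fits and the two
#'   resistance-coefficient CIs.
#' @export
significance_over_distance <- function(y, rd, geo_null,
                                       conf_level = 0.95) {
  check_aligned(y, rd, geo_null)
  ut <- upper.tri(rd)
  ok <- is.finite(rd[ut]) & is.finite(geo_null[ut])
  r <- suppressWarnings(stats::cor(rd[ut][ok], geo_null[ut][ok]))
  collinear <- is.na(r) || abs(r) > 0.999
  fit1 <- fit_mlpe(y, list(rd = rd), conf_level = conf_level)
  ci1 <- fit1$coefficients[fit1$coefficients$term == "rd",
                           c("ci_lower", "ci_upper")]
  if (collinear) {
    return(list(significant = FALSE, collinear = TRUE, fit_rd = fit1,
                fit_rd_distance = NULL, ci_rd = ci1, ci_rd_with_distance =
                  NULL, cor_rd_distance = r))
  }
  fit2 <- fit_mlpe(y, list(rd = rd, distance = geo_null),
                   conf_level = conf_level)
  ci2 <- fit2$coefficients[fit2$coefficients$term == "rd",
                           c("ci_lower", "ci_upper")]
  list(significant = ci1$ci_lower > 0 && ci2$ci_lower > 0,
       collinear = FALSE, fit_rd = fit1, fit_rd_distance = fit2,
       ci_rd = ci1, ci_rd_with_distance = ci2, cor_rd_distance = r)
}

#' Within-variable resistance-surface selection
#'
#' For one landscape variable, ranks its candidate resistance matrices
#' (typically 3 thresholds x 2 resistance values) by the AIC of
#' `GenDist ~ RD`, reports the best candidate's improvement over the
#' distance-only null, tests it with the two-model significance rule, and
#' audits each candidate's correlation with the null distance.
#'
#' @param y response [pairwise_matrix].
#' @param candidates named list of candidate resistance matrices.
#' @param geo_null geographic-null matrix.
#' @return list: `best` (label), `best_fit`, `delta_AIC_vs_distance`,
#'   `significance` (from [significance_over_distance]), `table`
#'   (per-candidate AIC audit with null-distance correlations).
#' @export
within_variable_selection <- function(y, candidates, geo_null) {
  stopifnot(length(candidates) >= 1L)
  labs0 <- names(candidates)
  if (is.null(labs0)) names(candidates) <- labs0 <-
      sprintf("cand%02d", seq_along(candidates))
  fits <- lapply(candidates, function(m) fit_mlpe(y, list(rd = m)))
  aic <- vapply(fits, function(f) f$AIC, numeric(1))
  cors <- vapply(candidates, function(m) {
    ut <- upper.tri(m)
    ok <- is.finite(m[ut]) & is.finite(geo_null[ut])
    suppressWarnings(stats::cor(m[ut][ok], geo_null[ut][ok]))
  }, numeric(1))
  ord <- order(aic, labs0)               # ties broken by label order
  best <- labs0[ord[1]]
  null_fit <- fit_mlpe(y, list(distance = geo_null))
  sig <- significance_over_distance(y, candidates[[best]], geo_null)
  audit <- data.frame(candidate = labs0, AIC = aic,
                      delta_AIC = aic - min(aic),
                      cor_with_distance = cors,
                      stringsAsFactors = FALSE)[order(aic, labs0), ]
  rownames(audit) <- NULL
  list(best = best, best_fit = fits[[best]],
       delta_AIC_vs_distance = null_fit$AIC - aic[ord[1]],
       null_AIC = null_fit$AIC, significance = sig, table = audit)
}

#' Between-variable model comparison
#'
#' Compares the best resistance matrix of every significant variable, the
#' additive combined landscape surface and the habitat-derived predictors
#' against the distance-only null in a single AICc table.
#'
#' @param y response [pairwise_matrix].
#' @param candidates named list of resistance matrices (best per variable,
#'   combined surface, habitat predictors).
#' @param geo_null geographic-null matrix.
#' @return a `model_table`.
#' @export
between_variable_selection <- function(y, candidates, geo_null) {
  stopifnot(length(candidates) >= 1L)
  fits <- lapply(candidates, function(m) fit_mlpe(y, list(rd = m)))
  null_fit <- fit_mlpe(y, list(distance = geo_null))
  model_table(fits, null_fit)
}
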