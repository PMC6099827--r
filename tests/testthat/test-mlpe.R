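# MLPE fitting, model tables and the selection procedures.

# simulate a pairwise response with the MLPE error structure
sim_mlpe_y <- function(x_pm, beta0, beta1, sigma_u, sigma_e,
                       standardized = TRUE) {
  g <- nrow(x_pm)
  idx <- which(upper.tri(x_pm), arr.ind = TRUE)
  xv <- x_pm[upper.tri(x_pm)]
  if (standardized) xv <- as.numeric(scale(xv))
  u <- rnorm(g, sd = sigma_u)
  yv <- beta0 + beta1 * xv + u[idx[, 1]] + u[idx[, 2]] +
    rnorm(nrow(idx), sd = sigma_e)
  make_pm(yv, rownames(x_pm), "gst_prime")
}

test_that("the profiled ML likelihood matches a dense MVN oracle", {
  set.seed(51)
  for (g in c(5, 8, 10)) {
    labs <- sprintf("G%02d", seq_len(g))
    x <- make_pm(runif(choose(g, 2)), labs)
    y <- sim_mlpe_y(x, 0.2, 0.1, 0.05, 0.03)
    fit <- fit_mlpe(y, list(rd = x))
    idx <- which(upper.tri(x), arr.ind = TRUE)
    n <- nrow(idx)
    Z <- matrix(0, n, g); for (r in seq_len(n)) Z[r, idx[r, ]] <- 1
    X <- cbind(1, scale(x[upper.tri(x)]))
    V <- fit$sigma_u2 * tcrossprod(Z) + fit$sigma2 * diag(n)
    r <- y[upper.tri(y)] - X %*% fit$coefficients$estimate
    ll <- -0.5 * (n * log(2 * pi) +
                  as.numeric(determinant(V)$modulus) +
                  as.numeric(t(r) %*% solve(V, r)))
    expect_equal(fit$log_likelihood, ll, tolerance = 1e-6)
    # and no non-boundary candidate beats the optimum nearby
    expect_gte(fit$sigma_u2, 0)
    expect_gt(fit$sigma2, 0)
  }
})

test_that("with no group variance the slope collapses to OLS", {
  set.seed(52)
  labs <- sprintf("G%02d", 1:12)
  x <- make_pm(runif(choose(12, 2)), labs)
  yv <- 0.1 + 0.5 * as.numeric(scale(x[upper.tri(x)])) +
    rnorm(choose(12, 2), sd = 0.05)
  y <- make_pm(yv, labs, "gst_prime")
  fit <- fit_mlpe(y, list(rd = x))
  ols <- stats::lm(yv ~ scale(x[upper.tri(x)]))
  if (fit$sigma_u2 < 1e-10)
    expect_equal(fit$coefficients$estimate[2],
                 unname(coef(ols)[2]), tolerance = 1e-6)
  # AIC formula: -2 ll + 2 p with p = 2 fixed + 2 variances
  expect_equal(fit$AIC, -2 * fit$log_likelihood + 2 * 4)
  expect_gte(fit$AICc, fit$AIC)
})

test_that("slope recovery: standardized beta close to truth across
           replicates", {
  set.seed(53)
  labs <- sprintf("G%02d", 1:40)
  hits <- 0L
  for (rep in 1:30) {
    x <- make_pm(runif(choose(40, 2)), labs)
    y <- sim_mlpe_y(x, 0.2, 0.5, 0.02, 0.02)
    fit <- fit_mlpe(y, list(rd = x))
    b1 <- fit$coefficients$estimate[2]
    hits <- hits + (abs(b1 - 0.5) < 0.1)
  }
  expect_gte(hits, 27L)                  # >= 90% of replicates
})

test_that("model tables rank by AICc with normalised weights", {
  set.seed(54)
  labs <- sprintf("G%02d", 1:10)
  x <- make_pm(runif(choose(10, 2)), labs)
  d <- make_pm(runif(choose(10, 2)), labs, "geo_null")
  y <- sim_mlpe_y(x, 0.2, 0.4, 0.02, 0.02)
  tab <- model_table(list(rd = fit_mlpe(y, list(rd = x))),
                     null_fit = fit_mlpe(y, list(distance = d)))
  expect_equal(tab$model[1], "rd")
  expect_equal(sum(tab$weight), 1, tolerance = 1e-9)
  expect_true(all(diff(tab$AICc) >= 0))
  expect_true(all(diff(tab$cum_weight) >= 0))
  expect_equal(tab$delta_AICc[1], 0)

  # weight formula at fixed deltas: (0, 2) -> (0.731, 0.269)
  w <- exp(-c(0, 2) / 2); w <- w / sum(w)
  expect_equal(round(w, 3), c(0.731, 0.269))
})

test_that("the two-model significance rule controls the null and detects
           a real landscape effect", {
  set.seed(55)
  labs <- sprintf("G%02d", 1:25)
  sig_true <- 0L; sig_null <- 0L
  n_rep <- 20
  for (rep in seq_len(n_rep)) {
    d <- make_pm(runif(choose(25, 2)), labs, "geo_null")
    rd <- make_pm(runif(choose(25, 2)), labs)       # decorrelated from d
    # response from distance only: rd must usually be non-significant
    y_null <- sim_mlpe_y(d, 0.2, 0.4, 0.02, 0.02)
    s1 <- significance_over_distance(y_null, rd, d)
    sig_null <- sig_null + s1$significant
    # response from rd with strong slope: usually significant
    y_eff <- sim_mlpe_y(rd, 0.2, 0.4, 0.02, 0.02)
    s2 <- significance_over_distance(y_eff, rd, d)
    sig_true <- sig_true + s2$significant
  }
  expect_lte(sig_null, 2L)               # type-I control
  expect_gte(sig_true, 18L)              # power

  # perfect collinearity: flagged, not significant
  d2 <- make_pm(runif(choose(25, 2)), labs, "geo_null")
  rd2 <- pairwise_matrix(unclass(d2), labs, "resistance")
  yy <- sim_mlpe_y(d2, 0.2, 0.4, 0.02, 0.02)
  sc <- significance_over_distance(yy, rd2, d2)
  expect_true(sc$collinear)
  expect_false(sc$significant)
})

test_that("significance decisions are invariant to predictor rescaling", {
  set.seed(56)
  labs <- sprintf("G%02d", 1:15)
  d <- make_pm(runif(choose(15, 2)), labs, "geo_null")
  rd <- make_pm(runif(choose(15, 2)), labs)
  y <- sim_mlpe_y(rd, 0.2, 0.4, 0.02, 0.02)
  s_raw <- significance_over_distance(y, rd, d)
  rd_scaled <- pairwise_matrix(unclass(rd) * 1000, labs, "resistance")
  d_scaled <- pairwise_matrix(unclass(d) * 250 , labs, "geo_null")
  s_scaled <- significance_over_distance(y, rd_scaled, d_scaled)
  expect_identical(s_raw$significant, s_scaled$significant)
  expect_equal(s_raw$fit_rd$coefficients$estimate,
               s_scaled$fit_rd$coefficients$estimate, tolerance = 1e-6)
})

test_that("AICc converges to AIC as the number of pairs grows", {
  set.seed(57)
  labs <- sprintf("G%03d", 1:142)        # ~1e4 pairs
  x <- make_pm(runif(choose(142, 2)), labs)
  y <- sim_mlpe_y(x, 0.2, 0.3, 0.02, 0.02)
  fit <- fit_mlpe(y, list(rd = x))
  expect_lt(fit$AICc - fit$AIC, 0.01)
})

test_that("within-variable selection breaks ties deterministically and
           reports the audit", {
  set.seed(58)
  labs <- sprintf("G%02d", 1:12)
  x <- make_pm(runif(choose(12, 2)), labs)
  d <- make_pm(runif(choose(12, 2)), labs, "geo_null")
  y <- sim_mlpe_y(x, 0.2, 0.4, 0.02, 0.02)
  # identical candidates: first by label order wins
  w <- within_variable_selection(y, list(b_cand = x, a_cand = x), d)
  expect_equal(w$best, "a_cand")
  expect_equal(nrow(w$table), 2L)
  expect_true("cor_with_distance" %in% names(w$table))
})
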