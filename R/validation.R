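#' Monte Carlo cross-validation of predictive differentiation
#'
#' Validates a selected resistance surface by repeated random train/test
#' splits of the pairwise data. At each iteration the pairs are split
#' (default 80% train / 20% test), MLPE models `GenDist ~ RD` and
#' `GenDist ~ distance` are fitted on the training pairs, test-pair
#' differentiation is predicted from the fixed effects only (the random
#' effects of held-out structure are unavailable by construction), and
#' absolute prediction errors are grouped into equal-width bins of observed
#' differentiation (default 5 bins over the full observed range, shared
#' across iterations).
#'
#' @param y observed differentiation [pairwise_matrix].
#' @param rd_top selected resistance [pairwise_matrix].
#' @param geo_null geographic-null [pairwise_matrix].
#' @param iterations number of random splits (default 100).
#' @param train_fraction fraction of pairs used for training (default 0.8).
#' @param n_bins number of differentiation bins (default 5).
#' @param seed RNG seed for the splits.
#' @param split_unit `"pair"` (default: split the pairwise observations)
#'   or `"cluster"` (hold out whole clusters, avoiding shared-population
#'   leakage between train and test pairs).
#' @return a `cv_result`: `summary` (bin x model mean/sd absolute error
#'   over iterations; bins empty in every iteration are `NA`), `bins`
#'   (edges), `errors` (tidy per-iteration records), `pooled` (per-model
#'   pooled mean absolute error).
#' @export
monte_carlo_cv <- function(y, rd_top, geo_null, iterations = 100,
                           train_fraction = 0.8, n_bins = 5, seed = 1,
                           split_unit = c("pair", "cluster")) {
  split_unit <- match.arg(split_unit)
  labs <- check_aligned(y, rd_top, geo_null)
  ut <- upper.tri(y)
  idx <- which(ut, arr.ind = TRUE)
  ok <- is.finite(rd_top[ut]) & is.finite(geo_null[ut])
  idx <- idx[ok, , drop = FALSE]
  yv <- y[ut][ok]; rv <- rd_top[ut][ok]; dv <- geo_null[ut][ok]
  n <- length(yv)
  if (n < 20L) stop("need at least 20 usable pairs", call. = FALSE)
  edges <- seq(min(yv), max(yv), length.out = n_bins + 1L)
  edges[n_bins + 1L] <- edges[n_bins + 1L] + 1e-12
  bin_of <- function(v) pmin(findInterval(v, edges), n_bins)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  recs <- vector("list", iterations)
  for (it in seq_len(iterations)) {
    if (split_unit == "pair") {
      train <- sort(sample.int(n, size = round(train_fraction * n)))
    } else {
      gtrain <- sample(seq_along(labs),
                       size = max(3L, round(train_fraction * length(labs))))
      train <- which(idx[, 1] %in% gtrain & idx[, 2] %in% gtrain)
    }
    test <- setdiff(seq_len(n), train)
    if (length(test) == 0L || length(train) < 3L) next
    tm <- train_matrices(labs, idx, train, yv, rv, dv)
    fit_rd <- fit_mlpe(tm$y, list(rd = tm$rd))
    fit_d <- fit_mlpe(tm$y, list(distance = tm$d))
    pr_rd <- predict(fit_rd, matrix(rv[test], ncol = 1))
    pr_d <- predict(fit_d, matrix(dv[test], ncol = 1))
    recs[[it]] <- data.frame(
      iteration = it, bin = bin_of(yv[test]),
      err_rd = abs(pr_rd - yv[test]), err_distance = abs(pr_d - yv[test]))
  }
  errors <- do.call(rbind, recs)
  summ <- expand.grid(bin = seq_len(n_bins),
                      model = c("resistance", "distance"),
                      stringsAsFactors = FALSE)
  summ$mean_abs_error <- NA_real_; summ$sd_abs_error <- NA_real_
  for (r in seq_len(nrow(summ))) {
    col <- if (summ$model[r] == "resistance") "err_rd" else "err_distance"
    vals <- errors[errors$bin == summ$bin[r], col]
    if (length(vals)) {
      summ$mean_abs_error[r] <- mean(vals)
      summ$sd_abs_error[r] <- stats::sd(vals)
    }
  }
  pooled <- c(resistance = mean(errors$err_rd),
              distance = mean(errors$err_distance))
  structure(list(summary = summ, bins = edges, errors = errors,
                 pooled = pooled, iterations = iterations,
                 train_fraction = train_fraction, seed = seed,
                 split_unit = split_unit),
            class = "cv_result")
}

# rebuild label-complete pairwise matrices holding only the training pairs:
# held-out pairs get NA predictors (so fit_mlpe drops them) and a finite
# placeholder response (never used, since the predictor is NA)
train_matrices <- function(labs, idx, train, yv, rv, dv) {
  fill <- function(vals, init, statistic) {
    m <- matrix(init, length(labs), length(labs))
    diag(m) <- 0
    ii <- idx[train, , drop = FALSE]
    m[ii] <- vals[train]
    m[ii[, c(2, 1), drop = FALSE]] <- vals[train]
    pairwise_matrix(m, labs, statistic)
  }
  list(y = fill(yv, 0, "gst_prime"),
       rd = fill(rv, NA_real_, "resistance"),
       d = fill(dv, NA_real_, "geo_null"))
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d iterations, %d%% train, %s split\n",
              x$iterations, round(100 * x$train_fraction), x$split_unit))
  print(x$summary, row.names = FALSE, digits = 4)
  cat(sprintf("pooled mean abs error: resistance %.4g, distance %.4g\n",
              x$pooled["resistance"], x$pooled["distance"]))
  invisible(x)
}

#' Individual-based rerun of the between-variable analysis
#'
#' Repeats the between-variable comparison with individual Bray-Curtis
#' dissimilarity as the response: cluster-level resistance predictors are
#' expanded to individual pairs by looking up each pair's cluster pair,
#' within-cluster pairs are excluded (they carry no between-cluster
#' resistance), and MLPE random effects are per individual.
#'
#' @param individual_bc individual [pairwise_matrix]
#'   (`statistic = "bray_curtis"`).
#' @param cluster_of named character vector mapping individual id ->
#'   cluster id; every individual in `individual_bc` must be mapped.
#' @param candidates named list of cluster-level resistance matrices.
#' @param geo_null cluster-level geographic-null matrix.
#' @return list: `table` (the individual-based `model_table`),
#'   `n_within_excluded`.
#' @export
individual_rerun <- function(individual_bc, cluster_of, candidates,
                             geo_null) {
  ids <- rownames(individual_bc)
  cl <- cluster_of[ids]
  if (anyNA(cl))
    stop("individual without a cluster assignment", call. = FALSE)
  clabs <- rownames(geo_null)
  if (!all(cl %in% clabs))
    stop("cluster ids missing from predictor matrices", call. = FALSE)
  n <- length(ids)
  expand <- function(cm) {
    m <- unclass(cm)[cl, cl, drop = FALSE]
    dimnames(m) <- list(ids, ids)
    m
  }
  within <- outer(cl, cl, "==") & upper.tri(individual_bc)
  n_within <- sum(within)
  mask_na <- function(m, statistic) {
    m[outer(cl, cl, "==")] <- NA_real_
    diag(m) <- 0
    pairwise_matrix(m, ids, statistic)
  }
  cands_i <- lapply(candidates, function(cm)
    mask_na(expand(cm), "resistance"))
  null_i <- mask_na(expand(geo_null), "geo_null")
  bc <- individual_bc
  tab <- between_variable_selection(bc, cands_i, null_i)
  list(table = tab, n_within_excluded = n_within)
}
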