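#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the synthetic study system: a spatially
#' autocorrelated habitat-index raster with a known habitat/nonhabitat
#' threshold, clustered lek-style sampling nodes placed in habitat, and
#' genotypes whose pairwise differentiation follows an MLPE-structured
#' function of effective resistance. Defaults describe a desk-scale analog
#' of one management zone: a 100 x 100 grid of 1.2 km cells (120 km
#' extent), 8 lek clusters at least 30 km apart (so a 25 km clustering cut
#' keeps them distinct), 15 microsatellite-style loci with up to 6 alleles,
#' and weak population/pair noise around the resistance-differentiation
#' line.
#'
#' @param grid_rows,grid_cols raster dimensions (cells).
#' @param cell_size cell edge length in metres (default 1200, the analysis
#'   resolution).
#' @param autocorr_range spatial correlation length of the habitat field,
#'   in cells (Gaussian smoothing kernel sd; 1 = white noise).
#' @param true_threshold habitat-index value separating habitat from
#'   nonhabitat in the generating process, in (0, 1).
#' @param true_resistance resistance of nonhabitat cells (> 1).
#' @param n_clusters number of lek clusters.
#' @param cluster_spacing minimum centroid separation between clusters
#'   (metres); keep above the downstream clustering cut.
#' @param inds_per_cluster individuals sampled per cluster.
#' @param n_loci,alleles_per_locus marker panel size.
#' @param drift_scale multiplier mapping effective resistance to expected
#'   pairwise GST' (dimensionless).
#' @param mlpe_sigma_u,mlpe_sigma_e standard deviations of the per-cluster
#'   and per-pair noise added to the expected differentiation.
#' @param seed RNG seed; identical configurations give bit-identical
#'   output.
#' @return a `synth_config` list.
#' @export
synth_config <- function(grid_rows = 100, grid_cols = 100,
                         cell_size = 1200, autocorr_range = 5,
                         true_threshold = 0.5, true_resistance = 10,
                         n_clusters = 8, cluster_spacing = 30000,
                         inds_per_cluster = 15, n_loci = 15,
                         alleles_per_locus = 6, drift_scale = 0.15,
                         mlpe_sigma_u = 0.01, mlpe_sigma_e = 0.01,
                         seed = 42) {
  cfg <- list(grid_rows = as.integer(grid_rows),
              grid_cols = as.integer(grid_cols),
              cell_size = cell_size, autocorr_range = autocorr_range,
              true_threshold = true_threshold,
              true_resistance = true_resistance,
              n_clusters = as.integer(n_clusters),
              cluster_spacing = cluster_spacing,
              inds_per_cluster = as.integer(inds_per_cluster),
              n_loci = as.integer(n_loci),
              alleles_per_locus = as.integer(alleles_per_locus),
              drift_scale = drift_scale, mlpe_sigma_u = mlpe_sigma_u,
              mlpe_sigma_e = mlpe_sigma_e, seed = as.integer(seed))
  with(cfg, {
    if (grid_rows < 1 || grid_cols < 1)
      stop("grid dimensions must be positive", call. = FALSE)
    if (true_threshold <= 0 || true_threshold >= 1)
      stop("true_threshold must be in (0, 1)", call. = FALSE)
    if (true_resistance <= 1)
      stop("true_resistance must be > 1", call. = FALSE)
    if (drift_scale < 0) stop("drift_scale must be >= 0", call. = FALSE)
    if (min(inds_per_cluster, n_loci, alleles_per_locus) < 1)
      stop("counts must be >= 1", call. = FALSE)
  })
  structure(cfg, class = "synth_config")
}

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a spatially autocorrelated habitat raster
#'
#' Draws Gaussian white noise on the grid, smooths it with a separable
#' Gaussian kernel of standard deviation `autocorr_range` cells
#' (boundary-renormalised, so edges are unbiased), and rank-transforms the
#' result to the uniform scale, yielding a habitat-index field with values
#' spanning (0, 1) and spatial correlation decaying at the configured
#' range — a stand-in for a breeding-habitat probability layer.
#'
#' @param config a [synth_config].
#' @return an [lg_raster] with values in (0, 1).
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    nr <- config$grid_rows; nc <- config$grid_cols
    z <- matrix(stats::rnorm(nr * nc), nr, nc)
    if (config$autocorr_range > 1) {
      sdk <- config$autocorr_range
      half <- ceiling(3 * sdk)
      k <- stats::dnorm(-half:half, sd = sdk)
      smooth1 <- function(m) {          # smooth along rows of m
        out <- matrix(0, nrow(m), ncol(m))
        wsum <- matrix(0, nrow(m), ncol(m))
        for (o in -half:half) {
          w <- k[o + half + 1L]
          src <- seq_len(nrow(m)) + o
          okk <- src >= 1L & src <= nrow(m)
          out[okk, ] <- out[okk, ] + w * m[src[okk], ]
          wsum[okk, ] <- wsum[okk, ] + w
        }
        out / wsum
      }
      z <- smooth1(z)
      z <- t(smooth1(t(z)))
    }
    u <- matrix((rank(z, ties.method = "first") - 0.5) / length(z), nr, nc)
    lg_raster(u, cell_size = config$cell_size)
  })
}

#' Place clustered lek sampling nodes in habitat
#'
#' Samples `n_clusters` cluster centroids on cells whose habitat index
#' exceeds the grid median (leks sit in high-index habitat), enforcing a
#' minimum pairwise centroid separation of `cluster_spacing`, then places
#' 1-5 lek points per cluster in the centroid's immediate habitat
#' neighbourhood. Placement is greedy with bounded retries; if the spacing
#' constraint cannot be met a generation error is thrown.
#'
#' @param raster habitat [lg_raster] (from [generate_landscape]).
#' @param config a [synth_config].
#' @param max_retries attempts before giving up.
#' @return named list of data.frames (`cluster_id`, `row`, `col`, `x`,
#'   `y`, `cell`), one per cluster; empty list when `n_clusters = 0`.
#' @export
generate_lek_clusters <- function(raster, config, max_retries = 50) {
  stopifnot(inherits(raster, "lg_raster"), inherits(config, "synth_config"))
  if (config$n_clusters == 0L) return(list())
  with_seed(config$seed + 1L, {
    v <- raster$values
    nr <- nrow(v); nc <- ncol(v)
    med <- stats::median(v, na.rm = TRUE)
    cand <- which(!is.na(v) & v > med)
    if (length(cand) < config$n_clusters)
      stop("not enough habitat cells to place clusters", call. = FALSE)
    spacing_cells <- config$cluster_spacing / raster$cell_size
    centroids <- NULL
    for (try in seq_len(max_retries)) {
      ordc <- sample(cand)
      acc <- integer(0)
      rc_acc <- NULL
      for (cell in ordc) {
        rc <- arrayInd(cell, c(nr, nc))
        if (length(acc)) {
          dd <- sqrt((rc_acc[, 1] - rc[1])^2 + (rc_acc[, 2] - rc[2])^2)
          if (any(dd <= spacing_cells)) next
        }
        acc <- c(acc, cell)
        rc_acc <- rbind(rc_acc, rc)
        if (length(acc) == config$n_clusters) break
      }
      if (length(acc) == config$n_clusters) { centroids <- acc; break }
    }
    if (is.null(centroids))
      stop("could not place clusters with the required spacing",
           call. = FALSE)
    out <- list()
    for (ci in seq_along(centroids)) {
      rc <- arrayInd(centroids[ci], c(nr, nc))
      n_leks <- sample.int(5L, 1L)
      # habitat cells within a 2-cell neighbourhood of the centroid
      nb_r <- pmax(1L, rc[1] - 2L):pmin(nr, rc[1] + 2L)
      nb_c <- pmax(1L, rc[2] - 2L):pmin(nc, rc[2] + 2L)
      nb <- as.matrix(expand.grid(row = nb_r, col = nb_c))
      nb_cell <- nb[, 1] + (nb[, 2] - 1L) * nr
      okh <- !is.na(v[nb_cell]) & v[nb_cell] > med
      pool <- setdiff(nb_cell[okh], centroids[ci])
      picks <- centroids[ci]
      if (n_leks > 1L && length(pool))
        picks <- c(picks, sample(pool, min(n_leks - 1L, length(pool))))
      prc <- arrayInd(picks, c(nr, nc))
      xy <- cell_xy(raster, prc[, 1], prc[, 2])
      cid <- sprintf("C%02d", ci)
      out[[cid]] <- data.frame(cluster_id = cid, row = prc[, 1],
                               col = prc[, 2], x = xy$x, y = xy$y,
                               cell = picks)
    }
    out
  })
}

#' Cell-index sets of lek clusters
#'
#' @param node_sets output of [generate_lek_clusters].
#' @return named list of integer raster cell indices, the node-set format
#'   consumed by the circuit engine.
#' @export
lek_cell_sets <- function(node_sets) {
  lapply(node_sets, function(df) df$cell)
}

#' Write lek node sets as a delimited table
#' @param node_sets output of [generate_lek_clusters].
#' @param path file path.
#' @export
write_lek_clusters <- function(node_sets, path) {
  utils::write.csv(do.call(rbind, node_sets), path, row.names = FALSE)
  invisible(path)
}

# ---- target-GST' -> logit-frequency divergence calibration -------------
# The generator controls differentiation through the variance s of the
# between-cluster difference of per-allele log-frequency deviations.  The
# map s -> E[GST'] has no convenient closed form under the softmax
# frequency model, so it is built once by simulation on frequency draws
# (no individual sampling) over a grid of s values and inverted by
# monotone interpolation.  Memoised per allele count.
.calib_env <- new.env(parent = emptyenv())

divergence_calibration <- function(alleles_per_locus, n_loci_sim = 400) {
  key <- as.character(alleles_per_locus)
  if (!is.null(.calib_env[[key]])) return(.calib_env[[key]])
  s_grid <- c(0, 0.02, 0.05, 0.1, 0.2, 0.35, 0.6, 1, 1.6, 2.5, 4, 6, 9,
              14, 20, 30, 45, 70, 100)
  gst <- with_seed(20200615L, {
    vapply(s_grid, function(s) {
      A <- alleles_per_locus
      base <- matrix(stats::rgamma(n_loci_sim * A, shape = 2), n_loci_sim)
      base <- base / rowSums(base)
      d1 <- matrix(stats::rnorm(n_loci_sim * A, sd = sqrt(s / 2)),
                   n_loci_sim)
      d2 <- matrix(stats::rnorm(n_loci_sim * A, sd = sqrt(s / 2)),
                   n_loci_sim)
      p1 <- exp(log(base) + d1); p1 <- p1 / rowSums(p1)
      p2 <- exp(log(base) + d2); p2 <- p2 / rowSums(p2)
      hs <- rowMeans(cbind(1 - rowSums(p1^2), 1 - rowSums(p2^2)))
      ht <- 1 - rowSums(((p1 + p2) / 2)^2)
      HS <- mean(hs); HT <- mean(ht)
      if (HT <= 0) return(0)
      (HT - HS) / HT * (1 + HS) / (1 - HS)
    }, numeric(1))
  })
  gst <- cummax(gst)                     # enforce monotone non-decreasing
  cal <- list(s = s_grid, gst = gst, max_gst = max(gst))
  .calib_env[[key]] <- cal
  cal
}

target_to_s <- function(target, cal) {
  target <- pmin(pmax(target, 0), cal$max_gst * 0.999)
  stats::approx(cal$gst, cal$s, xout = target, ties = "ordered",
                rule = 2)$y
}

#' Simulate genotypes with resistance-structured differentiation
#'
#' Draws per-cluster allele frequencies so that the expected pairwise GST'
#' between clusters i and j is
#' `clamp(drift_scale * R_ij + u_i + u_j + eps_ij, 0, 0.95)` with
#' `u ~ N(0, mlpe_sigma_u^2)` per cluster and `eps ~ N(0, mlpe_sigma_e^2)`
#' per pair — exactly the error structure the downstream MLPE model
#' assumes. Targets are translated into between-cluster log-frequency
#' divergence variances by a precomputed monotone simulation-built
#' calibration, the divergences are realised as correlated multivariate
#' normal deviations across clusters (covariance from the classical
#' multidimensional-scaling construction, eigenvalue-clipped to positive
#' semidefinite), and individuals are drawn by Hardy-Weinberg sampling
#' from the cluster frequencies.
#'
#' @param node_sets lek cluster list from [generate_lek_clusters] (the
#'   cluster ids and lek coordinates used for the individuals).
#' @param effective_resistance [pairwise_matrix] of effective resistances
#'   between the clusters (labels matching `names(node_sets)`); must be
#'   finite, symmetric, zero-diagonal.
#' @param config a [synth_config].
#' @return a [genotype_table] with `inds_per_cluster * n_clusters` rows,
#'   zone `"Z1"` and `cluster_id` set, plus attributes `target_gst`
#'   (the pairwise target matrix) and `cluster_freqs`.
#' @export
simulate_genotypes <- function(node_sets, effective_resistance, config) {
  stopifnot(inherits(config, "synth_config"))
  R <- effective_resistance
  k <- length(node_sets)
  cids <- names(node_sets)
  if (!identical(rownames(R), cids))
    stop("resistance labels must match node sets", call. = FALSE)
  if (any(!is.finite(R)))
    stop("effective resistance must be finite", call. = FALSE)
  if (max(abs(unclass(R) - t(unclass(R)))) > 1e-8)
    stop("resistance matrix not symmetric", call. = FALSE)
  cal <- divergence_calibration(config$alleles_per_locus)
  with_seed(config$seed + 2L, {
    u <- stats::rnorm(k, sd = config$mlpe_sigma_u)
    eps <- matrix(0, k, k)
    eps[upper.tri(eps)] <- stats::rnorm(k * (k - 1) / 2,
                                        sd = config$mlpe_sigma_e)
    eps <- eps + t(eps)
    target <- config$drift_scale * unclass(R) + outer(u, u, "+") + eps
    target <- pmin(pmax(target, 0), 0.95)
    diag(target) <- 0
    S <- matrix(target_to_s(target, cal), k, k)
    diag(S) <- 0
    # covariance across clusters with Var(d_i - d_j) = S_ij:
    # v_i = s_max / 2 on the diagonal, c_ij = (s_max - S_ij) / 2 off it,
    # then clip negative eigenvalues
    s_max <- max(S, 0)
    C <- (s_max - S) / 2
    diag(C) <- s_max / 2
    eg <- eigen(C, symmetric = TRUE)
    lam <- pmax(eg$values, 0)
    Croot <- eg$vectors %*% (sqrt(lam) * t(eg$vectors))
    A <- config$alleles_per_locus; L <- config$n_loci
    base <- matrix(stats::rgamma(L * A, shape = 2), L)
    base <- base / rowSums(base)
    freqs <- array(0, dim = c(k, L, A))
    for (l in seq_len(L)) {
      d <- Croot %*% matrix(stats::rnorm(k * A), k, A)
      eta <- sweep(d, 2, log(base[l, ]), "+")
      p <- exp(eta - apply(eta, 1, max))
      freqs[, l, ] <- p / rowSums(p)
    }
    rows <- list()
    for (ci in seq_len(k)) {
      leks <- node_sets[[ci]]
      for (ind in seq_len(config$inds_per_cluster)) {
        lk <- leks[1 + (ind - 1) %% nrow(leks), ]
        al <- integer(2 * L)
        for (l in seq_len(L)) {
          dr <- sample.int(A, 2L, replace = TRUE, prob = freqs[ci, l, ])
          al[c(2 * l - 1, 2 * l)] <- dr
        }
        rows[[length(rows) + 1L]] <- list(
          id = sprintf("%s_i%03d", cids[ci], ind), x = lk$x, y = lk$y,
          cluster = cids[ci], alleles = al)
      }
    }
    tab <- genotype_table(
      individual_id = vapply(rows, `[[`, character(1), "id"),
      x = vapply(rows, `[[`, numeric(1), "x"),
      y = vapply(rows, `[[`, numeric(1), "y"),
      zone = "Z1",
      alleles = do.call(rbind, lapply(rows, `[[`, "alleles")),
      cluster_id = vapply(rows, `[[`, character(1), "cluster"))
    attr(tab, "target_gst") <- pairwise_matrix(target, cids, "gst_prime")
    attr(tab, "cluster_freqs") <- freqs
    tab
  })
}
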