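# Shared fixture builders and independent oracles.

# symmetric pairwise matrix from upper-triangle values
make_pm <- function(vals, labels, statistic = "resistance") {
  g <- length(labels)
  m <- matrix(0, g, g)
  m[upper.tri(m)] <- vals
  m <- m + t(m)
  pairwise_matrix(m, labels, statistic)
}

# genotype table from a list of per-individual allele vectors
make_gt <- function(allele_rows, ids = NULL, zone = "Z", cluster = NULL,
                    x = NULL, y = NULL) {
  n <- length(allele_rows)
  if (is.null(ids)) ids <- sprintf("i%02d", seq_len(n))
  if (is.null(x)) x <- seq_len(n)
  if (is.null(y)) y <- rep(0, n)
  genotype_table(ids, x, y, zone, do.call(rbind, allele_rows),
                 cluster_id = cluster)
}

# independent dense oracle: effective resistance via Laplacian pseudo-inverse
dense_reff <- function(W, s, t) {
  L <- diag(rowSums(W)) - W
  Lp <- MASS::ginv(L)
  e <- numeric(nrow(W)); e[s] <- 1; e[t] <- -1
  as.numeric(t(e) %*% Lp %*% e)
}

# dense conductance matrix of a resistance raster, mirroring the stated
# edge rule (mean conductance, sqrt(2) diagonal scaling) by enumeration
dense_conductance <- function(values, neighborhood = 8) {
  nr <- nrow(values); nc <- ncol(values)
  cells <- which(!is.na(values))
  id <- match(seq_len(nr * nc), cells)
  n <- length(cells)
  W <- matrix(0, n, n)
  offs <- if (neighborhood == 8)
    list(c(0,1,1), c(1,0,1), c(1,1,1/sqrt(2)), c(1,-1,1/sqrt(2)))
  else list(c(0,1,1), c(1,0,1))
  for (cell in cells) {
    r <- (cell - 1) %% nr + 1; cc <- (cell - 1) %/% nr + 1
    for (o in offs) {
      r2 <- r + o[1]; c2 <- cc + o[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      cell2 <- r2 + (c2 - 1) * nr
      if (is.na(values[cell2])) next
      w <- (1 / values[cell] + 1 / values[cell2]) / 2 * o[3]
      W[id[cell], id[cell2]] <- w
      W[id[cell2], id[cell]] <- w
    }
  }
  list(W = W, cells = cells, id = id)
}

# independent complete-linkage oracle: greedy agglomeration where every
# merge height is recomputed exactly from the raw distance matrix
# (max over cross-cluster pairs), no Lance-Williams recurrence
brute_complete_linkage <- function(d, cut) {
  n <- nrow(d)
  memb <- seq_len(n)
  repeat {
    ks <- sort(unique(memb))
    best <- NULL
    for (a in seq_along(ks)) for (b in seq_len(a - 1)) {
      ia <- which(memb == ks[a]); ib <- which(memb == ks[b])
      h <- max(d[ia, ib])                # complete-linkage merge height
      if (is.null(best) || h < best$h) best <- list(a = ks[a], b = ks[b],
                                                    h = h)
    }
    if (is.null(best) || best$h > cut) break
    memb[memb == best$a] <- best$b
    if (length(unique(memb)) == 1L) break
  }
  match(memb, unique(memb))
}

# small synthetic study system reused across tests
small_system <- function(seed = 3, drift = NULL, n_clusters = 6,
                         sigma_u = 0.01, sigma_e = 0.01,
                         inds = 20, loci = 20, drift_span = 0.4) {
  cfg <- synth_config(grid_rows = 50, grid_cols = 50, n_clusters =
                        n_clusters, cluster_spacing = 15000,
                      inds_per_cluster = inds, n_loci = loci,
                      mlpe_sigma_u = sigma_u, mlpe_sigma_e = sigma_e,
                      seed = seed)
  ras <- generate_landscape(cfg)
  leks <- generate_lek_clusters(ras, cfg)
  Rn <- null_distance_matrix(ras, lek_cell_sets(leks))
  if (is.null(drift)) drift <- drift_span / max(Rn[upper.tri(Rn)])
  cfg$drift_scale <- drift
  list(cfg = cfg, raster = ras, leks = leks, null = Rn)
}
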