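# Sparse circuit engine vs closed forms and the dense pseudo-inverse oracle.

test_that("graph construction uses mean conductance and sqrt(2) diagonals", {
  r <- lg_raster(matrix(c(1, 1, 4, 1), 1, 4))
  g <- build_graph(r, neighborhood = 4)
  A <- as.matrix(g$adjacency)
  expect_equal(A[1, 2], 1)                       # mean(1, 1)
  expect_equal(A[2, 3], (1 + 0.25) / 2)          # mean(1, 1/4) = 0.625
  g8 <- build_graph(lg_raster(matrix(1, 2, 2)), neighborhood = 8)
  A8 <- as.matrix(g8$adjacency)
  expect_equal(A8[1, 4], 1 / sqrt(2))            # diagonal pair
  expect_error(build_graph(lg_raster(matrix(NA_real_, 2, 2))), "unmasked")
})

test_that("effective resistance matches series/parallel closed forms", {
  chain <- build_graph(lg_raster(matrix(1, 1, 3)), neighborhood = 4)
  R <- effective_resistance_pairwise(chain, list(a = 1L, b = 3L))
  expect_equal(R["a", "b"], 2, tolerance = 1e-10)  # two unit resistors

  sq <- build_graph(lg_raster(matrix(1, 2, 2)), neighborhood = 4)
  R2 <- effective_resistance_pairwise(sq, list(a = 1L, b = 2L))
  expect_equal(R2["a", "b"], 0.75, tolerance = 1e-10)  # 1 || 3
})

test_that("sparse solver equals the dense Laplacian pseudo-inverse on
           random small graphs", {
  skip_if_not_installed("MASS")
  set.seed(41)
  for (rep in 1:25) {
    nr <- sample(3:9, 1); nc <- sample(3:9, 1)      # up to 81 nodes
    v <- matrix(sample(c(1, 2, 5, 10), nr * nc, replace = TRUE), nr, nc)
    ras <- lg_raster(v)
    nb <- sample(c(4, 8), 1)
    g <- build_graph(ras, neighborhood = nb)
    picks <- sample(nr * nc, 3)
    R <- effective_resistance_pairwise(
      g, list(a = picks[1], b = picks[2], c = picks[3]))
    dc <- dense_conductance(v, nb)
    for (pp in list(c(1, 2), c(1, 3), c(2, 3))) {
      want <- dense_reff(dc$W, dc$id[picks[pp[1]]], dc$id[picks[pp[2]]])
      expect_equal(R[pp[1], pp[2]], want, tolerance = 1e-8,
                   ignore_attr = TRUE)
    }
  }
})

test_that("scaling all resistances scales every effective resistance", {
  set.seed(42)
  v <- matrix(runif(100, 1, 10), 10, 10)
  nodes <- list(a = 1L, b = 100L, c = 55L)
  R1 <- effective_resistance_pairwise(build_graph(lg_raster(v)), nodes)
  R2 <- effective_resistance_pairwise(build_graph(lg_raster(2 * v)), nodes)
  expect_equal(unclass(R2), 2 * unclass(R1), tolerance = 1e-9)
})

test_that("Rayleigh monotonicity holds under single-cell increases", {
  set.seed(43)
  v <- matrix(sample(c(1, 5), 225, replace = TRUE, prob = c(0.8, 0.2)),
              15, 15)
  nodes <- list(a = 1L, b = 225L, c = 113L)
  base <- effective_resistance_pairwise(build_graph(lg_raster(v)), nodes)
  for (rep in 1:20) {
    v2 <- v
    cell <- sample(225, 1)
    v2[cell] <- v2[cell] * runif(1, 1.5, 10)
    up <- effective_resistance_pairwise(build_graph(lg_raster(v2)), nodes)
    expect_true(all(up[upper.tri(up)] >= base[upper.tri(base)] - 1e-10))
  }
})

test_that("effective resistance obeys the triangle inequality", {
  set.seed(44)
  v <- matrix(runif(64, 1, 20), 8, 8)
  nodes <- list(a = 3L, b = 30L, c = 64L, d = 22L)
  R <- effective_resistance_pairwise(build_graph(lg_raster(v)), nodes)
  labs <- rownames(R)
  for (i in labs) for (j in labs) for (k in labs)
    if (i != j && j != k && i != k)
      expect_lte(R[i, k], R[i, j] + R[j, k] + 1e-10)
})

test_that("supernode contraction equals the large-conductance limit", {
  v <- matrix(1, 5, 5)
  ras <- lg_raster(v)
  g <- build_graph(ras, neighborhood = 4)
  setA <- c(1L, 2L); setB <- c(24L, 25L)
  R <- effective_resistance_pairwise(g, list(A = setA, B = setB))
  # oracle: join each set's cells with conductance 1e6 instead of merging,
  # ground the target and solve the reduced dense Laplacian directly
  dc <- dense_conductance(v, 4)
  W <- dc$W
  W[dc$id[setA[1]], dc$id[setA[2]]] <- 1e6
  W[dc$id[setA[2]], dc$id[setA[1]]] <- 1e6
  W[dc$id[setB[1]], dc$id[setB[2]]] <- 1e6
  W[dc$id[setB[2]], dc$id[setB[1]]] <- 1e6
  L <- diag(rowSums(W)) - W
  s <- dc$id[setA[1]]; t <- dc$id[setB[1]]
  keep <- setdiff(seq_len(nrow(W)), t)
  e <- numeric(length(keep)); e[match(s, keep)] <- 1
  want <- solve(L[keep, keep], e)[match(s, keep)]
  expect_equal(R["A", "B"], want, tolerance = 1e-4)
})

test_that("null distances are Rayleigh-dominated by any habitat surface and
           grow with separation", {
  sys <- small_system(seed = 45, n_clusters = 5)
  nodes <- lek_cell_sets(sys$leks)
  null <- sys$null
  s <- threshold_surface(sys$raster, 0.5, "positive", 10)
  rd <- effective_resistance_pairwise(build_graph(s), nodes)
  ut <- upper.tri(null)
  expect_true(all(null[ut] <= rd[ut] + 1e-10))

  # uniform square: resistance increases with node separation
  uni <- lg_raster(matrix(1, 20, 20))
  sep_nodes <- list(a = 1L, b = 5L, c = 10L, d = 20L)  # column 1, rows 1..20
  Rn <- effective_resistance_pairwise(build_graph(uni), sep_nodes)
  expect_true(Rn["a", "b"] < Rn["a", "c"])
  expect_true(Rn["a", "c"] < Rn["a", "d"])
})

test_that("disconnected node pairs are flagged NA with a warning", {
  v <- matrix(1, 3, 7); v[, 4] <- NA                  # two islands
  g <- build_graph(lg_raster(v))
  expect_warning(
    R <- effective_resistance_pairwise(g, list(a = 1L, b = 2L, c = 19L)),
    "disconnected")
  expect_true(is.na(R["a", "c"]))
  expect_false(is.na(R["a", "b"]))
})

test_that("all-to-one flow conserves current and respects mirror symmetry", {
  v <- matrix(1, 9, 15)
  ras <- lg_raster(v)
  g <- build_graph(ras, neighborhood = 4)
  nodes <- list(L = 5L + 1L * 9L, R = 5L + 13L * 9L)  # mirror positions
  fm <- all_to_one_flow(g, nodes)
  m <- fm$values
  expect_true(all(m >= 0))
  # mirror symmetry about the vertical midline
  expect_equal(m, m[, ncol(m):1], tolerance = 1e-9)
  # and about the horizontal midline (nodes sit on the centre row)
  expect_equal(m, m[nrow(m):1, ], tolerance = 1e-9)

  # conservation on a 1-D chain: the full unit of injected current passes
  # through every interior cell (half-sum of two incident edge currents),
  # while source/ground cells carry half (one incident edge)
  chain <- build_graph(lg_raster(matrix(1, 1, 9)), neighborhood = 4)
  fc <- all_to_one_flow(chain, list(a = 1L, b = 9L))
  expect_equal(as.numeric(fc$values[1, 2:8]), rep(1, 7), tolerance = 1e-9)
  expect_equal(fc$values[1, 1], 0.5, tolerance = 1e-9)
  expect_equal(fc$values[1, 9], 0.5, tolerance = 1e-9)
})

test_that("flow concentrates at the lowest-resistance gap in a barrier", {
  v <- matrix(1, 15, 21)
  v[, 11] <- 1000                                    # barrier column
  v[8, 11] <- 1                                      # single gap
  g <- build_graph(lg_raster(v), neighborhood = 4)
  nodes <- list(a = 8L + 2L * 15L, b = 8L + 18L * 15L)
  fm <- all_to_one_flow(g, nodes)
  barrier_col <- fm$values[, 11]
  expect_equal(which.max(barrier_col), 8L)           # argmax at the gap
})
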