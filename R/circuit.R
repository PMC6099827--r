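#' Build the conductance graph of a resistance surface
#'
#' Converts a raster resistance surface into the weighted graph on which
#' circuit-theory quantities are computed. Nodes are the non-masked cells;
#' neighbouring cells a, b are joined by an edge of conductance
#' `mean(1/r_a, 1/r_b)`, with diagonal edges (8-neighbourhood only)
#' divided by `sqrt(2)` to account for the longer centre-to-centre
#' distance. Connected components are labelled so that disconnected node
#' pairs can be flagged downstream.
#'
#' @param surface a `resistance_surface` (or any [lg_raster] of cell
#'   resistances >= 1).
#' @param neighborhood 4 (rook) or 8 (queen, default) cell adjacency.
#' @return a `resistance_graph`: node/cell index maps, sparse edge list
#'   with conductances, component labels.
#' @export
build_graph <- function(surface, neighborhood = 8) {
  stopifnot(inherits(surface, "lg_raster"))
  if (!neighborhood %in% c(4, 8))
    stop("neighborhood must be 4 or 8", call. = FALSE)
  v <- surface$values
  nr <- nrow(v); nc <- ncol(v)
  ok <- !is.na(v)
  if (!any(ok)) stop("surface has no unmasked cells", call. = FALSE)
  node_of_cell <- matrix(NA_integer_, nr, nc)
  cells <- which(ok)                     # column-major cell index
  node_of_cell[cells] <- seq_along(cells)
  n <- length(cells)
  cond <- 1 / v[cells]                   # per-node conductance

  offs <- list(c(0L, 1L), c(1L, 0L))
  scale <- c(1, 1)
  if (neighborhood == 8) {
    offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
    scale <- c(scale, 1 / sqrt(2), 1 / sqrt(2))
  }
  rows_all <- integer(0); cols_all <- integer(0); w_all <- numeric(0)
  rc <- arrayInd(cells, c(nr, nc))
  for (k in seq_along(offs)) {
    dr <- offs[[k]][1]; dc <- offs[[k]][2]
    r2 <- rc[, 1] + dr; c2 <- rc[, 2] + dc
    valid <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    idx <- which(valid)
    if (!length(idx)) next
    nb <- node_of_cell[cbind(r2[idx], c2[idx])]
    keep <- !is.na(nb)
    a <- node_of_cell[cells[idx[keep]]]
    b <- nb[keep]
    w <- (cond[a] + cond[b]) / 2 * scale[k]
    rows_all <- c(rows_all, a); cols_all <- c(cols_all, b)
    w_all <- c(w_all, w)
  }
  adj <- Matrix::sparseMatrix(i = c(rows_all, cols_all),
                              j = c(cols_all, rows_all),
                              x = c(w_all, w_all), dims = c(n, n))
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(
    adj > 0, mode = "undirected"))$membership
  structure(list(adjacency = adj, cells = cells, node_of_cell = node_of_cell,
                 nrow = nr, ncol = nc, component = comp,
                 cell_size = surface$cell_size, xll = surface$xll,
                 yll = surface$yll),
            class = "resistance_graph")
}

#' @export
print.resistance_graph <- function(x, ...) {
  cat(sprintf(
    "<resistance_graph> %d nodes, %d edges, %d component(s)\n",
    length(x$cells), length(x$adjacency@x) / 2,
    max(x$component)))
  invisible(x)
}

# Contract each node set (list of cell indices, column-major in the raster)
# into one supernode; returns the contracted Laplacian pieces.
contract_graph <- function(graph, node_sets) {
  n <- length(graph$cells)
  set_nodes <- lapply(node_sets, function(cells) {
    nodes <- graph$node_of_cell[cells]
    if (anyNA(nodes))
      stop("node set contains masked cells", call. = FALSE)
    unique(nodes)
  })
  # mapping node -> contracted index; supernodes first, in set order
  grp <- seq_len(n)                      # tentative: identity
  map <- integer(n)
  k <- length(set_nodes)
  assigned <- rep(FALSE, n)
  for (s in seq_len(k)) {
    nd <- set_nodes[[s]]
    if (any(assigned[nd]))
      stop("node sets overlap", call. = FALSE)
    map[nd] <- s
    assigned[nd] <- TRUE
  }
  free <- which(!assigned)
  map[free] <- k + seq_along(free)
  m <- k + length(free)
  P <- Matrix::sparseMatrix(i = seq_len(n), j = map, x = 1, dims = c(n, m))
  A2 <- Matrix::t(P) %*% graph$adjacency %*% P
  Matrix::diag(A2) <- 0                  # drop intra-supernode self-loops
  A2 <- Matrix::drop0(A2)
  list(adjacency = A2, n = m, k = k, map = map,
       comp_all = {
         cm <- integer(m); cm[map] <- graph$component; cm
       })
}

laplacian_of <- function(A) {
  d <- Matrix::rowSums(A)
  Matrix::Diagonal(x = d) - A
}

#' Pairwise effective resistance between cluster supernodes
#'
#' Contracts each node set (all lek cells of a cluster) into a single
#' supernode with zero internal resistance, then computes the two-point
#' effective resistance for every supernode pair by solving the graph
#' Laplacian with one node grounded: for nodes s, t in the same component,
#' `R_eff(s, t) = (e_s - e_t)' L_g^{-1} (e_s - e_t)` where `L_g` is the
#' Laplacian with the ground row/column removed. One sparse Cholesky
#' factorisation per component is reused for all pairs. Pairs in different
#' components are returned as `NA` (disconnected) with a warning.
#'
#' @param graph a `resistance_graph` from [build_graph].
#' @param node_sets named list (cluster id -> integer vector of raster cell
#'   indices, column-major) with at least two sets.
#' @param statistic statistic tag for the result (`"resistance"` or
#'   `"geo_null"`).
#' @return a [pairwise_matrix] (`statistic = "resistance"`).
#' @export
effective_resistance_pairwise <- function(graph, node_sets,
                                          statistic = "resistance") {
  stopifnot(inherits(graph, "resistance_graph"))
  k <- length(node_sets)
  if (k < 2L) stop("need at least two node sets", call. = FALSE)
  labs <- names(node_sets)
  if (is.null(labs)) labs <- sprintf("S%02d", seq_len(k))
  ctr <- contract_graph(graph, node_sets)
  L <- laplacian_of(ctr$adjacency)
  comp <- ctr$comp_all
  res <- matrix(NA_real_, k, k)
  diag(res) <- 0
  for (cc in unique(comp[seq_len(k)])) {
    sup <- which(comp[seq_len(k)] == cc)          # supernodes in component
    if (length(sup) < 2L) next
    members <- which(comp == cc)
    ground <- members[length(members)]            # ground the last node
    keep <- setdiff(members, ground)
    Lg <- L[keep, keep, drop = FALSE]
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(Lg), LDL = FALSE,
                           perm = TRUE)
    pos <- match(sup, keep)                       # NA if a supernode is ground
    rhs <- Matrix::sparseMatrix(
      i = pos[!is.na(pos)], j = seq_len(sum(!is.na(pos))), x = 1,
      dims = c(length(keep), sum(!is.na(pos))))
    X <- as.matrix(Matrix::solve(ch, as(rhs, "CsparseMatrix"),
                                 system = "A"))
    # G[i,j] = e_i' Lg^-1 e_j over the supernodes present in `keep`
    present <- which(!is.na(pos))
    G <- X[pos[present], , drop = FALSE]
    for (ii in seq_along(sup)) for (jj in seq_len(ii - 1L)) {
      si <- sup[ii]; sj <- sup[jj]
      gi <- match(ii, present); gj <- match(jj, present)
      if (is.na(gi) && is.na(gj)) next
      r <- if (is.na(gi)) {           # si is the ground node
        G[gj, gj]
      } else if (is.na(gj)) {
        G[gi, gi]
      } else {
        G[gi, gi] + G[gj, gj] - 2 * G[gi, gj]
      }
      res[si, sj] <- res[sj, si] <- r
    }
  }
  if (any(is.na(res[upper.tri(res)])))
    warning("some node-set pairs are in different components; ",
            "their resistances are NA (disconnected)", call. = FALSE)
  pairwise_matrix(res, labs, statistic)
}

#' Geographic-null resistance distances
#'
#' Effective resistances computed on the undifferentiated landscape (every
#' non-masked cell resistance 1) over the same study-area mask: a null
#' "distance" that respects the study-extent constraints, used as the
#' distance-only predictor in all model comparisons.
#'
#' @param raster an [lg_raster] supplying the grid and mask.
#' @param node_sets as in [effective_resistance_pairwise].
#' @param neighborhood stencil for [build_graph].
#' @return a [pairwise_matrix] (`statistic = "geo_null"`).
#' @export
null_distance_matrix <- function(raster, node_sets, neighborhood = 8) {
  g <- build_graph(uniform_surface(raster), neighborhood = neighborhood)
  effective_resistance_pairwise(g, node_sets, statistic = "geo_null")
}

#' All-to-one current-flow connectivity map
#'
#' For each focal cluster in turn, grounds the focal supernode and injects
#' one unit of current at every other supernode in its component, solves
#' for the node potentials, and accumulates per-cell current as half the
#' sum of the absolute currents on the edges incident to the cell. The map
#' is the mean over all focal solves, mirroring the all-to-one mode used
#' to average gene-flow current over every cluster.
#'
#' @param graph a `resistance_graph`.
#' @param node_sets named list of >= 2 cluster cell-index sets.
#' @return a `flow_map`: an [lg_raster] of mean current density plus
#'   percentile bin edges (5% steps) for display.
#' @export
all_to_one_flow <- function(graph, node_sets) {
  stopifnot(inherits(graph, "resistance_graph"))
  k <- length(node_sets)
  if (k < 2L) stop("need at least two node sets", call. = FALSE)
  ctr <- contract_graph(graph, node_sets)
  L <- laplacian_of(ctr$adjacency)
  A <- ctr$adjacency
  comp <- ctr$comp_all
  m <- ctr$n
  trip <- Matrix::summary(Matrix::triu(A))
  acc <- numeric(m)
  n_solves <- 0L
  for (f in seq_len(k)) {
    cc <- comp[f]
    others <- setdiff(which(comp[seq_len(k)] == cc), f)
    if (length(others) == 0L) next
    members <- which(comp == cc)
    keep <- setdiff(members, f)
    Lg <- L[keep, keep, drop = FALSE]
    rhs <- numeric(length(keep))
    rhs[match(others, keep)] <- 1
    vkeep <- as.numeric(Matrix::solve(
      Matrix::Cholesky(Matrix::forceSymmetric(Lg), LDL = FALSE,
                       perm = TRUE),
      rhs, system = "A"))
    v <- numeric(m)
    v[keep] <- vkeep                      # ground potential 0 at f
    cur <- abs(v[trip$i] - v[trip$j]) * trip$x
    node_cur <- numeric(m)
    tab_i <- tapply(cur, trip$i, sum)
    tab_j <- tapply(cur, trip$j, sum)
    node_cur[as.integer(names(tab_i))] <- tab_i
    node_cur[as.integer(names(tab_j))] <-
      node_cur[as.integer(names(tab_j))] + tab_j
    acc <- acc + node_cur / 2
    n_solves <- n_solves + 1L
  }
  if (n_solves == 0L)
    stop("no component holds two node sets", call. = FALSE)
  acc <- acc / n_solves
  # map contracted-node currents back to cells (supernode members share
  # their supernode's value)
  cell_cur <- acc[ctr$map]
  vmat <- matrix(NA_real_, graph$nrow, graph$ncol)
  vmat[graph$cells] <- cell_cur
  ras <- lg_raster(vmat, cell_size = graph$cell_size, xll = graph$xll,
                   yll = graph$yll)
  qs <- stats::quantile(cell_cur, probs = seq(0, 1, 0.05))
  structure(c(unclass(ras), list(percentiles = qs,
                                 normalization = "mean_per_focal")),
            class = c("flow_map", "lg_raster"))
}
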