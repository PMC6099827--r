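#' Euclidean distances between sampling locations
#'
#' @param points data.frame with columns `id`, `x`, `y` (projected planar
#'   coordinates; geodesic coordinates must be projected beforehand).
#' @return a [pairwise_matrix] (`statistic = "geo_distance"`).
#' @export
geographic_distances <- function(points) {
  if (!all(c("id", "x", "y") %in% names(points)))
    stop("points needs columns id, x, y", call. = FALSE)
  if (anyDuplicated(points$id))
    stop("duplicated location ids", call. = FALSE)
  d <- as.matrix(stats::dist(points[, c("x", "y")]))
  pairwise_matrix(d, as.character(points$id), "geo_distance")
}

#' Group sampling locations into lek clusters
#'
#' Agglomerative complete-linkage hierarchical clustering (the
#' Lance-Williams recurrence with \eqn{\alpha_i=\alpha_j=0.5,\ \beta=0,
#' \gamma=0.5}), with the tree cut so that locations whose complete-linkage
#' merge height exceeds `cut` fall in different clusters. Every output
#' cluster therefore has pairwise diameter at most `cut`. The default cut
#' of 25 km matches the maximum average seasonal movement distance used to
#' delineate lek clusters in sage-grouse work.
#'
#' @param distances a [pairwise_matrix] of geographic distances.
#' @param cut distance cut (same units as the distances; default 25000 m).
#' @param points optional data.frame (`id`, `x`, `y`) used to attach
#'   cluster centroids to the result.
#' @return a `cluster_set`: data.frame of memberships (`cluster_id`, `id`)
#'   with a `centroids` attribute, or an empty set for empty input.
#' @export
cluster_locations <- function(distances, cut = 25000, points = NULL) {
  if (is.null(distances) || nrow(distances) == 0L)
    return(new_cluster_set(data.frame(cluster_id = character(),
                                      id = character()), NULL))
  labs <- rownames(distances)
  if (length(labs) == 1L) {
    memb <- stats::setNames(1L, labs)
  } else {
    hc <- stats::hclust(stats::as.dist(unclass(distances)),
                        method = "complete")
    memb <- stats::cutree(hc, h = cut)
  }
  # deterministic ids ordered by first appearance of each cluster
  first <- tapply(seq_along(memb), memb, min)
  ord <- rank(first)
  cid <- sprintf("C%02d", ord[as.character(memb)])
  df <- data.frame(cluster_id = cid, id = labs, stringsAsFactors = FALSE)
  df <- df[order(df$cluster_id, match(df$id, labs)), , drop = FALSE]
  rownames(df) <- NULL
  new_cluster_set(df, points)
}

new_cluster_set <- function(membership, points) {
  cent <- NULL
  if (!is.null(points) && nrow(membership) > 0L) {
    m <- merge(membership, points, by = "id", sort = FALSE)
    cent <- do.call(rbind, lapply(split(m, m$cluster_id), function(s)
      data.frame(cluster_id = s$cluster_id[1], x = mean(s$x),
                 y = mean(s$y), n_locations = nrow(s))))
    cent <- cent[order(cent$cluster_id), , drop = FALSE]
    rownames(cent) <- NULL
  }
  structure(membership, centroids = cent,
            class = c("cluster_set", "data.frame"))
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d locations in %d clusters\n",
              nrow(x), length(unique(x$cluster_id))))
  invisible(x)
}

#' Assign individuals to location clusters
#'
#' Joins a [genotype_table] to a `cluster_set` by location id and fills the
#' table's `cluster_id` column.
#'
#' @param table a [genotype_table].
#' @param clusters a `cluster_set`.
#' @param location_id location id per individual (defaults to
#'   `individual_id`, for individually georeferenced samples).
#' @return the [genotype_table] with `cluster_id` set; individuals at
#'   locations absent from the cluster set get `NA`.
#' @export
assign_clusters <- function(table, clusters,
                            location_id = table$individual_id) {
  idx <- match(as.character(location_id), clusters$id)
  table$cluster_id <- clusters$cluster_id[idx]
  table
}

#' Remove clusters below the minimum sample size
#'
#' Applies the minimum-individuals rule (default 8 per genetic cluster):
#' clusters with fewer genotyped individuals are removed, and their
#' individuals are excluded from all downstream analyses.
#'
#' @param table a [genotype_table] with `cluster_id` assigned.
#' @param min_individuals minimum retained cluster size.
#' @return the filtered [genotype_table].
#' @export
filter_clusters <- function(table, min_individuals = 8) {
  stopifnot(inherits(table, "genotype_table"))
  cl <- table$cluster_id
  keep_cl <- names(which(table(cl) >= min_individuals))
  if (length(keep_cl) == 0L)
    warning("all clusters below the minimum sample size; empty result",
            call. = FALSE)
  gt_subset(table, !is.na(cl) & cl %in% keep_cl)
}

#' Cluster centroids
#' @param table a [genotype_table] with `cluster_id` assigned.
#' @return data.frame `cluster_id`, `x`, `y`, `n_individuals`.
#' @export
cluster_centroids <- function(table) {
  s <- split(seq_len(nrow(table)), table$cluster_id)
  out <- do.call(rbind, lapply(names(s), function(cid)
    data.frame(cluster_id = cid, x = mean(table$x[s[[cid]]]),
               y = mean(table$y[s[[cid]]]),
               n_individuals = length(s[[cid]]))))
  out[order(out$cluster_id), , drop = FALSE]
}
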