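#' Labelled symmetric pairwise matrix
#'
#' Container shared by every pairwise quantity in the pipeline: genetic
#' differentiation (GST', GST, Jost's D, Bray-Curtis), effective resistance,
#' the geographic-null resistance and plain geographic distance. The matrix
#' is symmetric with a zero diagonal; for `statistic = "resistance"` (and
#' `"geo_null"`) a pair in a different graph component may be `NA`, flagging
#' it as disconnected.
#'
#' @param values square numeric matrix.
#' @param labels character ids for the rows/columns (groups or individuals).
#' @param statistic one of `"gst_prime"`, `"gst"`, `"jost_d"`,
#'   `"bray_curtis"`, `"resistance"`, `"geo_null"`, `"geo_distance"`.
#' @return a `pairwise_matrix` (numeric matrix with attributes).
#' @export
pairwise_matrix <- function(values, labels,
                            statistic = c("gst_prime", "gst", "jost_d",
                                          "bray_curtis", "resistance",
                                          "geo_null", "geo_distance")) {
  statistic <- match.arg(statistic)
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != n) stop("values must be square", call. = FALSE)
  if (length(labels) != n) stop("labels must match matrix size", call. = FALSE)
  if (anyDuplicated(labels)) stop("duplicated labels", call. = FALSE)
  # resistance-type pairs may be disconnected; Bray-Curtis pairs with no
  # shared called loci are flagged missing
  finite_ok <- statistic %in% c("resistance", "geo_null", "bray_curtis")
  if (!finite_ok && any(!is.finite(values)))
    stop("non-finite entries not allowed for statistic ", statistic,
         call. = FALSE)
  if (max(abs(values - t(values)), na.rm = TRUE) > 1e-8)
    stop("matrix not symmetric", call. = FALSE)
  values <- (values + t(values)) / 2
  diag(values) <- 0
  dimnames(values) <- list(labels, labels)
  structure(values, statistic = statistic, class = c("pairwise_matrix",
                                                     "matrix", "array"))
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat(sprintf("<pairwise_matrix> statistic=%s, %d labels\n",
              attr(x, "statistic"), nrow(x)))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  invisible(x)
}

pm_labels <- function(x) rownames(x)

#' Upper-triangle values of a pairwise matrix
#'
#' @param x a [pairwise_matrix].
#' @return data.frame `id1`, `id2`, `value` in column-major upper-triangle
#'   order (the pair ordering used throughout model fitting).
#' @export
pairs_long <- function(x) {
  labs <- rownames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  data.frame(id1 = labs[idx[, 1]], id2 = labs[idx[, 2]],
             value = x[idx], stringsAsFactors = FALSE)
}

check_aligned <- function(...) {
  ms <- list(...)
  labs <- rownames(ms[[1]])
  for (m in ms[-1])
    if (!identical(rownames(m), labs))
      stop("pairwise matrices are not label-aligned", call. = FALSE)
  invisible(labs)
}

#' Write / read a pairwise matrix as labelled CSV
#'
#' The square form has ids as the first column and as the header; the long
#' form has columns `id1`, `id2`, `value`.
#'
#' @param x a [pairwise_matrix].
#' @param path file path.
#' @param statistic statistic tag to attach on reading.
#' @param long write/read long format instead of square.
#' @export
write_pairwise_csv <- function(x, path, long = FALSE) {
  if (long) {
    utils::write.csv(pairs_long(x), path, row.names = FALSE)
  } else {
    df <- data.frame(id = rownames(x), unclass(x), check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_pairwise_csv
#' @export
read_pairwise_csv <- function(path, statistic = "resistance") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (identical(names(df)[1:3], c("id1", "id2", "value"))) {
    labs <- sort(unique(c(df$id1, df$id2)))
    m <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
    m[cbind(match(df$id1, labs), match(df$id2, labs))] <- df$value
    m[cbind(match(df$id2, labs), match(df$id1, labs))] <- df$value
    return(pairwise_matrix(m, labs, statistic))
  }
  labs <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  pairwise_matrix(m, labs, statistic)
}
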