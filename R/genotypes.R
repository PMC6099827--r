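#' Build a multilocus codominant genotype table
#'
#' The central genetic data structure: one row per individual with projected
#' coordinates, a management-zone label, an optional lek-cluster assignment,
#' and two integer allele calls per locus (microsatellite allele sizes).
#' Missing data are `NA` and must occur in pairs: a half-called locus (one
#' allele observed, the other missing) is invalid.
#'
#' @param individual_id character, unique.
#' @param x,y projected planar coordinates (same CRS as the rasters).
#' @param zone zone label per individual.
#' @param alleles integer matrix with `2 * n_loci` columns
#'   (`locus1_a1, locus1_a2, locus2_a1, ...`); `NA` = missing.
#' @param loci locus names; defaults to `L1..Lk`.
#' @param cluster_id optional cluster assignment per individual.
#' @return a `genotype_table` (a data.frame with a `loci` attribute).
#' @export
genotype_table <- function(individual_id, x, y, zone, alleles,
                           loci = NULL, cluster_id = NULL) {
  individual_id <- as.character(individual_id)
  n <- length(individual_id)
  if (anyDuplicated(individual_id))
    stop("individual_id values must be unique", call. = FALSE)
  alleles <- as.matrix(alleles)
  if (ncol(alleles) %% 2L != 0L)
    stop("alleles must have an even number of columns", call. = FALSE)
  if (nrow(alleles) != n)
    stop("alleles rows must match individuals", call. = FALSE)
  nloc <- ncol(alleles) / 2L
  if (nloc < 1L) stop("at least one locus required", call. = FALSE)
  if (is.null(loci)) loci <- paste0("L", seq_len(nloc))
  storage.mode(alleles) <- "integer"
  half <- xor(is.na(alleles[, 2L * seq_len(nloc) - 1L, drop = FALSE]),
              is.na(alleles[, 2L * seq_len(nloc), drop = FALSE]))
  if (any(half)) {
    bad <- which(half, arr.ind = TRUE)[1, ]
    stop(sprintf("half-called locus %s for individual %s",
                 loci[bad[2]], individual_id[bad[1]]), call. = FALSE)
  }
  colnames(alleles) <- paste0(rep(loci, each = 2L), c("_a1", "_a2"))
  df <- data.frame(individual_id = individual_id, x = as.numeric(x),
                   y = as.numeric(y), zone = as.character(zone),
                   cluster_id = if (is.null(cluster_id)) NA_character_
                                else as.character(cluster_id),
                   alleles, stringsAsFactors = FALSE)
  structure(df, loci = loci, class = c("genotype_table", "data.frame"))
}

gt_loci <- function(table) attr(table, "loci")

gt_alleles <- function(table) {
  loci <- gt_loci(table)
  as.matrix(table[, paste0(rep(loci, each = 2L), c("_a1", "_a2")),
                  drop = FALSE])
}

gt_subset <- function(table, keep) {
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, loci = gt_loci(table),
            class = c("genotype_table", "data.frame"))
}

#' Number of missing loci per individual
#' @param table a [genotype_table].
#' @return integer vector.
#' @export
missing_loci_count <- function(table) {
  a <- gt_alleles(table)
  nloc <- ncol(a) / 2L
  rowSums(is.na(a[, 2L * seq_len(nloc) - 1L, drop = FALSE]))
}

#' Quality-control filter for genotype tables
#'
#' Applies the sample-retention rule used before any differentiation
#' analysis: individuals missing genotypes at more than `max_missing_loci`
#' loci are removed, and exact duplicate multilocus genotypes (identical
#' allele calls at every locus, missingness included) are reduced to their
#' first occurrence. Row order is otherwise preserved.
#'
#' @param table a [genotype_table].
#' @param max_missing_loci maximum number of missing loci tolerated
#'   (default 5, the standard panel rule for 15-locus data).
#' @return the filtered [genotype_table]; may be empty.
#' @export
qc_filter <- function(table, max_missing_loci = 5) {
  stopifnot(inherits(table, "genotype_table"))
  keep <- missing_loci_count(table) <= max_missing_loci
  out <- gt_subset(table, keep)
  if (nrow(out) > 1L) {
    key <- apply(gt_alleles(out), 1L, function(r)
      paste(ifelse(is.na(r), ".", r), collapse = "/"))
    out <- gt_subset(out, !duplicated(key))
  }
  out
}

#' Read genotypes from delimited text or Genepop files
#'
#' The delimited dialect is a header-led table with columns
#' `individual_id, x, y, zone, [cluster_id], locus1_a1, locus1_a2, ...`
#' and empty fields for missing alleles. The Genepop dialect uses 2- or
#' 3-digit concatenated allele codes with `00`/`000` as the missing
#' sentinel; `POP` blocks become zones and coordinates default to zero
#' (Genepop carries none).
#'
#' @param path file path.
#' @param dialect `"delimited"` or `"genepop"`.
#' @param sep field separator for the delimited dialect.
#' @return a [genotype_table].
#' @export
read_genotypes <- function(path, dialect = c("delimited", "genepop"),
                           sep = ",") {
  dialect <- match.arg(dialect)
  if (dialect == "delimited") read_genotypes_delim(path, sep)
  else read_genotypes_genepop(path)
}

read_genotypes_delim <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("", "NA"))
  need <- c("individual_id", "x", "y", "zone")
  if (!all(need %in% names(df)))
    stop("delimited genotype file must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  has_cluster <- "cluster_id" %in% names(df)
  acols <- setdiff(names(df), c(need, "cluster_id"))
  if (length(acols) %% 2L != 0L)
    stop("odd number of allele columns", call. = FALSE)
  loci <- unique(sub("_a[12]$", "", acols))
  alleles <- as.matrix(df[, acols, drop = FALSE])
  genotype_table(df$individual_id, df$x, df$y, df$zone, alleles,
                 loci = loci,
                 cluster_id = if (has_cluster) df$cluster_id else NULL)
}

read_genotypes_genepop <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("not a Genepop file: ", path, call. = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  body <- lines[-1]                      # first line is the title
  pop_idx <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (length(pop_idx) == 0L)
    stop("no POP line found in Genepop file", call. = FALSE)
  loc_lines <- body[seq_len(pop_idx[1] - 1L)]
  loci <- trimws(unlist(strsplit(loc_lines, ",")))
  loci <- loci[nzchar(loci)]
  ids <- character(); zones <- character(); rows <- list()
  pop <- 0L
  for (k in seq((pop_idx[1]), length(body))) {
    ln <- body[k]
    if (grepl("^\\s*pop\\s*$", ln, ignore.case = TRUE)) {
      pop <- pop + 1L
      next
    }
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2L)
      stop(sprintf("malformed Genepop row at line %d", k + 1L),
           call. = FALSE)
    id <- trimws(parts[1])
    calls <- strsplit(trimws(paste(parts[-1], collapse = " ")),
                      "\\s+")[[1]]
    if (length(calls) != length(loci))
      stop(sprintf("Genepop row at line %d has %d genotypes, expected %d",
                   k + 1L, length(calls), length(loci)), call. = FALSE)
    dig <- nchar(calls[1]) / 2L
    if (!dig %in% c(2L, 3L))
      stop("Genepop allele codes must be 2- or 3-digit", call. = FALSE)
    a <- unlist(lapply(calls, function(g) {
      a1 <- as.integer(substr(g, 1L, dig))
      a2 <- as.integer(substr(g, dig + 1L, 2L * dig))
      c(if (a1 == 0L) NA_integer_ else a1,
        if (a2 == 0L) NA_integer_ else a2)
    }))
    ids <- c(ids, id); zones <- c(zones, paste0("pop", pop))
    rows[[length(rows) + 1L]] <- a
  }
  alleles <- do.call(rbind, rows)
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
  genotype_table(ids, x = 0, y = 0, zone = zones, alleles, loci = loci)
}

#' Write a genotype table as delimited text
#'
#' @param table a [genotype_table].
#' @param path file path.
#' @param sep field separator.
#' @export
write_genotypes <- function(table, path, sep = ",") {
  stopifnot(inherits(table, "genotype_table"))
  utils::write.table(as.data.frame(table), path, sep = sep,
                     row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
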