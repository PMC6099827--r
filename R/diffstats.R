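#' Allele frequencies by group
#'
#' Tabulates per-locus allele frequencies for each group (lek cluster or
#' management zone), using observed alleles only: individuals missing a
#' locus do not contribute to that locus's sample size.
#'
#' @param table a [genotype_table].
#' @param group_by `"cluster"` or `"zone"`; every individual must carry the
#'   chosen label.
#' @return an `allele_frequencies` object: for each group and locus, the
#'   named frequency vector (`freq`) and the diploid sample count with data
#'   (`n`).
#' @export
allele_frequencies <- function(table, group_by = c("cluster", "zone")) {
  stopifnot(inherits(table, "genotype_table"))
  group_by <- match.arg(group_by)
  g <- if (group_by == "cluster") table$cluster_id else table$zone
  if (anyNA(g))
    stop("every individual needs a ", group_by, " label", call. = FALSE)
  loci <- gt_loci(table)
  a <- gt_alleles(table)
  groups <- unique(g)
  freq <- list(); nmat <- matrix(0L, length(groups), length(loci),
                                 dimnames = list(groups, loci))
  for (gi in seq_along(groups)) {
    rows <- which(g == groups[gi])
    fl <- list()
    for (li in seq_along(loci)) {
      al <- c(a[rows, 2L * li - 1L], a[rows, 2L * li])
      al <- al[!is.na(al)]
      nmat[gi, li] <- length(al) %/% 2L
      fl[[loci[li]]] <- if (length(al) == 0L) numeric(0)
                        else table(al) / length(al)
    }
    if (all(nmat[gi, ] == 0L))
      stop("group ", groups[gi], " has no called alleles at any locus",
           call. = FALSE)
    freq[[groups[gi]]] <- fl
  }
  structure(list(freq = freq, n = nmat, groups = groups, loci = loci),
            class = "allele_frequencies")
}

#' @export
print.allele_frequencies <- function(x, ...) {
  cat(sprintf("<allele_frequencies> %d groups x %d loci\n",
              length(x$groups), length(x$loci)))
  invisible(x)
}

expected_het <- function(p) 1 - sum(p^2)

# per-pair multilocus H_S and H_T (plug-in or Nei-Chesser style corrected)
pair_hs_ht <- function(freqs, g1, g2, bias_correct = FALSE) {
  hs_num <- 0; ht_num <- 0; used <- 0L
  for (li in seq_along(freqs$loci)) {
    loc <- freqs$loci[li]
    n1 <- freqs$n[g1, li]; n2 <- freqs$n[g2, li]
    if (n1 == 0L || n2 == 0L) next
    p1 <- freqs$freq[[g1]][[loc]]; p2 <- freqs$freq[[g2]][[loc]]
    alleles <- union(names(p1), names(p2))
    v1 <- stats::setNames(rep(0, length(alleles)), alleles)
    v2 <- v1
    v1[names(p1)] <- p1; v2[names(p2)] <- p2
    h1 <- expected_het(v1); h2 <- expected_het(v2)
    if (bias_correct) {
      h1 <- h1 * 2 * n1 / (2 * n1 - 1)
      h2 <- h2 * 2 * n2 / (2 * n2 - 1)
    }
    hs <- (h1 + h2) / 2
    ht <- expected_het((v1 + v2) / 2)
    if (bias_correct) {
      nh <- 2 / (1 / n1 + 1 / n2)       # harmonic mean sample size
      ht <- ht + hs / (2 * nh * 2)
    }
    hs_num <- hs_num + hs; ht_num <- ht_num + ht; used <- used + 1L
  }
  if (used == 0L) return(c(hs = NA_real_, ht = NA_real_))
  c(hs = hs_num / used, ht = ht_num / used)
}

#' Pairwise genetic differentiation
#'
#' Computes pairwise differentiation between all group pairs from allele
#' frequencies. For a pair (k = 2 groups), per-locus H_S is the mean of the
#' two within-group expected heterozygosities and H_T the expected
#' heterozygosity of the mean frequencies; the multilocus values average
#' H_S and H_T across loci with data in both groups before forming ratios.
#' The statistics are
#' \deqn{G_{ST} = (H_T - H_S)/H_T}
#' \deqn{G'_{ST} = G_{ST}\,(k - 1 + H_S) / ((k-1)(1 - H_S))}{GST' = GST (k-1+HS)/((k-1)(1-HS))}
#' (Hedrick's standardized GST) and Jost's
#' \deqn{D = \frac{H_T - H_S}{1 - H_S}\cdot\frac{k}{k-1}.}
#' Point estimates are clamped to [0, 1]; a pair with H_T = 0 (both groups
#' monomorphic and identical) is defined as 0.
#'
#' @param freqs an [allele_frequencies] object with at least two groups.
#' @param statistic `"gst_prime"`, `"gst"` or `"jost_d"`.
#' @param bias_correct apply a Nei-Chesser-style small-sample correction to
#'   H_S and H_T instead of the plug-in estimators (default `FALSE`).
#' @return a [pairwise_matrix] over the groups.
#' @export
pairwise_differentiation <- function(freqs,
                                     statistic = c("gst_prime", "gst",
                                                   "jost_d"),
                                     bias_correct = FALSE) {
  stopifnot(inherits(freqs, "allele_frequencies"))
  statistic <- match.arg(statistic)
  groups <- freqs$groups
  if (length(groups) < 2L)
    stop("need at least two groups", call. = FALSE)
  k <- 2
  m <- matrix(0, length(groups), length(groups))
  for (i in seq_along(groups)) for (j in seq_len(i - 1L)) {
    h <- pair_hs_ht(freqs, groups[i], groups[j], bias_correct)
    hs <- h["hs"]; ht <- h["ht"]
    val <- if (!is.finite(ht) || ht <= 0) {
      0
    } else {
      gst <- (ht - hs) / ht
      switch(statistic,
        gst = gst,
        gst_prime = if (hs >= 1) 0
                    else gst * (k - 1 + hs) / ((k - 1) * (1 - hs)),
        jost_d = if (hs >= 1) 0
                 else (ht - hs) / (1 - hs) * k / (k - 1))
    }
    m[i, j] <- m[j, i] <- min(max(val, 0), 1)
  }
  pairwise_matrix(m, groups, statistic)
}

#' Individual-based Bray-Curtis genetic dissimilarity
#'
#' Treats each individual as a vector of allele counts over all loci (a
#' called locus contributes two counts) and computes the Bray-Curtis
#' percentage dissimilarity
#' \deqn{BC_{ij} = 1 - 2\sum_a \min(c_{ia}, c_{ja}) / (\sum_a c_{ia} + \sum_a c_{ja})}
#' restricted, for each pair, to the loci called in both individuals
#' (pairwise deletion). Identical genotypes give 0; individuals sharing no
#' alleles give 1; a pair with no shared called loci is `NA`.
#'
#' @param table a [genotype_table] with at least two individuals.
#' @return a [pairwise_matrix] (`statistic = "bray_curtis"`) over
#'   individuals.
#' @export
bray_curtis_individual <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  n <- nrow(table)
  if (n < 2L) stop("need at least two individuals", call. = FALSE)
  loci <- gt_loci(table)
  a <- gt_alleles(table)
  nloc <- length(loci)
  called <- !is.na(a[, 2L * seq_len(nloc) - 1L, drop = FALSE])
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    shared <- which(called[i, ] & called[j, ])
    if (length(shared) == 0L) { m[i, j] <- m[j, i] <- NA_real_; next }
    num <- 0
    for (li in shared) {
      ai <- a[i, c(2L * li - 1L, 2L * li)]
      aj <- a[j, c(2L * li - 1L, 2L * li)]
      ci <- table(ai); cj <- table(aj)
      common <- intersect(names(ci), names(cj))
      if (length(common))
        num <- num + sum(pmin(as.numeric(ci[common]),
                              as.numeric(cj[common])))
    }
    tot <- 4 * length(shared)            # 2 alleles from each individual
    m[i, j] <- m[j, i] <- 1 - 2 * num / tot
  }
  pairwise_matrix(m, table$individual_id, "bray_curtis")
}

#' Probability of identity of a marker panel
#'
#' The probability that two individuals drawn at random share the same
#' multilocus genotype, computed from pooled allele frequencies as
#' \deqn{PID_\ell = \sum_i p_i^4 + \sum_{i<j} (2 p_i p_j)^2}
#' per locus, with the overall panel value the product over loci. Used to
#' quantify the power of a panel to discern individuals.
#'
#' @param freqs an [allele_frequencies] object; groups are pooled by
#'   averaging their frequency vectors weighted by sample size.
#' @return list with `per_locus` (named vector) and `overall`.
#' @export
probability_identity <- function(freqs) {
  stopifnot(inherits(freqs, "allele_frequencies"))
  per <- stats::setNames(numeric(length(freqs$loci)), freqs$loci)
  for (li in seq_along(freqs$loci)) {
    loc <- freqs$loci[li]
    alleles <- unique(unlist(lapply(freqs$groups, function(g)
      names(freqs$freq[[g]][[loc]]))))
    if (length(alleles) == 0L) { per[li] <- 1; next }
    acc <- stats::setNames(rep(0, length(alleles)), alleles)
    wtot <- 0
    for (g in freqs$groups) {
      w <- freqs$n[g, li]
      if (w == 0L) next
      p <- freqs$freq[[g]][[loc]]
      acc[names(p)] <- acc[names(p)] + w * p
      wtot <- wtot + w
    }
    p <- acc / wtot
    pid <- sum(p^4)
    if (length(p) > 1L) {
      pp <- outer(p, p)
      pid <- pid + sum((2 * pp[upper.tri(pp)])^2)
    }
    per[li] <- pid
  }
  list(per_locus = per, overall = prod(per))
}
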