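# Genotype QC and the differentiation statistics.

test_that("qc filter enforces the missing-loci rule and drops duplicates", {
  full <- rep(c(1L, 2L), 15)                      # 15 loci, all called
  miss6 <- full; miss6[1:12] <- NA                # 6 loci missing
  miss5 <- full; miss5[1:10] <- NA                # 5 loci missing
  gt <- make_gt(list(full, miss6, miss5, full),
                ids = c("ok", "m6", "m5", "dup"))
  out <- qc_filter(gt)
  expect_identical(out$individual_id, c("ok", "m5"))  # m6 removed, dup removed
  out2 <- qc_filter(gt, max_missing_loci = 4)
  expect_identical(out2$individual_id, "ok")
})

test_that("half-called loci are rejected with a named error", {
  expect_error(make_gt(list(c(1L, NA, 2L, 2L))), "half-called.*L1")
})

test_that("allele frequencies count observed alleles only", {
  gt <- make_gt(list(c(1L, 1L, 3L, 4L), c(1L, 2L, NA, NA)))
  f <- allele_frequencies(gt, "zone")
  expect_equal(as.numeric(f$freq$Z$L1), c(0.75, 0.25))
  expect_equal(unname(f$n["Z", ]), c(2L, 1L))     # missing pair excluded
  gt2 <- make_gt(list(c(1L, 1L), c(2L, 2L)), zone = c("A", "B"))
  f2 <- allele_frequencies(gt2, "zone")
  expect_identical(f2$groups, c("A", "B"))
})

test_that("differentiation statistics hit their closed forms", {
  # two groups fixed for different alleles: maximal differentiation
  fixed <- make_gt(list(c(1L, 1L), c(2L, 2L)), zone = c("A", "B"))
  f <- allele_frequencies(fixed, "zone")
  for (s in c("gst", "gst_prime", "jost_d"))
    expect_equal(pairwise_differentiation(f, s)["A", "B"], 1,
                 tolerance = 1e-12)

  # identical frequencies: zero for all three
  same <- make_gt(list(c(1L, 2L), c(1L, 2L)), zone = c("A", "B"))
  fs <- allele_frequencies(same, "zone")
  for (s in c("gst", "gst_prime", "jost_d"))
    expect_equal(pairwise_differentiation(fs, s)["A", "B"], 0,
                 tolerance = 1e-12)

  # worked case: p = (0.7, 0.3) vs (0.3, 0.7), one locus, plug-in
  # HS = 0.42, HT = 0.5 -> GST = 0.16,
  # GST' = 0.16 * 1.42 / 0.58, D = 2 * 0.08 / 0.58
  g1 <- list(c(1L,1L), c(1L,1L), c(1L,1L), c(1L,2L), c(2L,2L))  # 7A 3B
  g2 <- list(c(2L,2L), c(2L,2L), c(2L,2L), c(1L,2L), c(1L,1L))  # 3A 7B
  gt <- make_gt(c(g1, g2), zone = rep(c("A", "B"), each = 5))
  fw <- allele_frequencies(gt, "zone")
  expect_equal(pairwise_differentiation(fw, "gst")["A", "B"], 0.16,
               tolerance = 1e-12)
  expect_equal(pairwise_differentiation(fw, "gst_prime")["A", "B"],
               0.16 * 1.42 / 0.58, tolerance = 1e-12)
  expect_equal(pairwise_differentiation(fw, "jost_d")["A", "B"],
               2 * 0.08 / 0.58, tolerance = 1e-12)
})

test_that("multilocus GST matches a brute-force two-group oracle", {
  # oracle: direct evaluation from raw allele counts, written against the
  # definitions (mean per-locus HS/HT averaged before the ratio)
  oracle_gst <- function(rows1, rows2, nloc) {
    hs <- numeric(0); ht <- numeric(0)
    for (l in seq_len(nloc)) {
      a1 <- unlist(lapply(rows1, function(r) r[c(2*l-1, 2*l)]))
      a2 <- unlist(lapply(rows2, function(r) r[c(2*l-1, 2*l)]))
      a1 <- a1[!is.na(a1)]; a2 <- a2[!is.na(a2)]
      if (!length(a1) || !length(a2)) next
      all_a <- union(a1, a2)
      p1 <- sapply(all_a, function(a) mean(a1 == a))
      p2 <- sapply(all_a, function(a) mean(a2 == a))
      hs <- c(hs, mean(c(1 - sum(p1^2), 1 - sum(p2^2))))
      ht <- c(ht, 1 - sum(((p1 + p2) / 2)^2))
    }
    (mean(ht) - mean(hs)) / mean(ht)
  }
  set.seed(11)
  for (rep in 1:5) {
    nloc <- sample(2:3, 1)
    draw <- function() lapply(1:6, function(i)
      as.integer(sample(1:4, 2 * nloc, replace = TRUE)))
    r1 <- draw(); r2 <- draw()
    gt <- make_gt(c(r1, r2), zone = rep(c("A", "B"), each = 6))
    f <- allele_frequencies(gt, "zone")
    got <- pairwise_differentiation(f, "gst")["A", "B"]
    expect_equal(got, max(0, oracle_gst(r1, r2, nloc)), tolerance = 1e-12)
  }
})

test_that("GST' dominates GST and the statistics are rank-concordant", {
  sys <- small_system(seed = 5)
  gt <- simulate_genotypes(sys$leks, sys$null, sys$cfg)
  f <- allele_frequencies(gt, "cluster")
  gp <- pairwise_differentiation(f, "gst_prime")
  gs <- pairwise_differentiation(f, "gst")
  jd <- pairwise_differentiation(f, "jost_d")
  ut <- upper.tri(gp)
  expect_true(all(gp[ut] >= gs[ut] - 1e-12))
  expect_gt(cor(gp[ut], gs[ut], method = "spearman"), 0.9)
  expect_gt(cor(gp[ut], jd[ut], method = "spearman"), 0.9)
})

test_that("individual permutation leaves matrices unchanged up to labels", {
  sys <- small_system(seed = 6, inds = 8, loci = 10)
  gt <- simulate_genotypes(sys$leks, sys$null, sys$cfg)
  perm <- sample(nrow(gt))
  gtp <- gt[perm, , drop = FALSE]
  attr(gtp, "loci") <- attr(gt, "loci")
  class(gtp) <- class(gt)
  g1 <- pairwise_differentiation(allele_frequencies(gt, "cluster"))
  g2 <- pairwise_differentiation(allele_frequencies(gtp, "cluster"))
  labs <- rownames(g1)
  expect_equal(unclass(g1)[labs, labs], unclass(g2)[labs, labs],
               tolerance = 1e-12)
})

test_that("Bray-Curtis handles identity, disjoint support and the worked
           case, and matches vegan on complete data", {
  gt <- make_gt(list(c(1L,1L, 2L,2L), c(1L,1L, 2L,2L),
                     c(3L,3L, 4L,4L), c(1L,3L, 4L,4L)))
  bc <- bray_curtis_individual(gt)
  expect_equal(bc["i01", "i02"], 0)               # identical genotypes
  expect_equal(bc["i01", "i03"], 1)               # no shared alleles
  # {A/A, B/B} vs {A/C, D/D}: 1 - 2*1/8
  expect_equal(bc["i01", "i04"], 0.75)

  skip_if_not_installed("vegan")
  sys <- small_system(seed = 9, inds = 5, loci = 8, n_clusters = 4)
  g <- simulate_genotypes(sys$leks, sys$null, sys$cfg)
  bc2 <- bray_curtis_individual(g)
  # vegan oracle on allele-count vectors (complete data, no missing loci)
  a <- as.matrix(g[, grep("_a[12]$", names(g))])
  loci <- attr(g, "loci")
  alle <- sort(unique(as.vector(a)))
  counts <- matrix(0, nrow(g), length(loci) * length(alle))
  for (i in seq_len(nrow(g))) for (l in seq_along(loci)) {
    for (al in a[i, c(2*l-1, 2*l)]) {
      k <- (l - 1) * length(alle) + match(al, alle)
      counts[i, k] <- counts[i, k] + 1
    }
  }
  vb <- as.matrix(vegan::vegdist(counts, method = "bray"))
  expect_equal(unclass(bc2), vb, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("pairs sharing no called loci are flagged missing", {
  gt <- make_gt(list(c(1L,1L, NA,NA), c(NA,NA, 2L,2L), c(1L,2L, 2L,2L)))
  bc <- bray_curtis_individual(gt)
  expect_true(is.na(bc["i01", "i02"]))
  expect_false(is.na(bc["i01", "i03"]))
})

test_that("probability of identity follows the Evett-Weir formula", {
  # biallelic p = q = 0.5: 2 * 0.0625 + 0.25 = 0.375
  gt <- make_gt(list(c(1L,1L, 1L,1L), c(2L,2L, 2L,2L),
                     c(1L,2L, 1L,2L), c(1L,2L, 2L,1L)))
  f <- allele_frequencies(gt, "zone")
  pid <- probability_identity(f)
  expect_equal(unname(pid$per_locus), c(0.375, 0.375), tolerance = 1e-12)
  expect_equal(pid$overall, 0.375^2, tolerance = 1e-12)  # product rule

  mono <- make_gt(list(c(1L, 1L), c(1L, 1L)))
  expect_equal(probability_identity(
    allele_frequencies(mono, "zone"))$overall, 1)
})
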