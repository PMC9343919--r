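# two-genotype NB counts; a fraction of features is shifted in group P so
# that normalization still has a stable unshifted majority
sim_two_group <- function(n, mu_b_over_a = 1, frac_shifted = 0.3,
                          mean0 = 100, alpha = 0.05, reps = 3, seed = 1) {
  set.seed(seed)
  if (mu_b_over_a == 1) frac_shifted <- 0
  mu <- rlnorm(n, log(mean0), 0.5)
  shifted <- seq_len(n) <= round(frac_shifted * n)
  mu_b <- mu * ifelse(shifted, mu_b_over_a, 1)
  counts <- cbind(
    matrix(rnbinom(n * reps, mu = mu, size = 1 / alpha), n),
    matrix(rnbinom(n * reps, mu = mu_b, size = 1 / alpha), n))
  colnames(counts) <- c(paste0("A_", 1:reps), paste0("P_", 1:reps))
  list(counts = dplyr::bind_cols(tibble::tibble(feature = paste0("f", 1:n)),
                                 tibble::as_tibble(counts)),
       design = tibble::tibble(sample = colnames(counts),
                               genotype = rep(c("A", "P"), each = reps),
                               replicate = rep(1:reps, 2)),
       shifted = shifted)
}

test_that("median-of-ratios size factors are scale-equivariant", {
  m <- tibble::tibble(feature = paste0("g", 1:3),
                      s1 = c(10L, 100L, 40L), s2 = c(20L, 200L, 80L))
  sf <- normalize_counts(m)$size_factors
  expect_equal(sf$size_factor[2] / sf$size_factor[1], 2)

  # identical samples -> equal factors
  m2 <- tibble::tibble(feature = paste0("g", 1:4),
                       a = c(5L, 9L, 30L, 2L), b = c(5L, 9L, 30L, 2L))
  expect_equal(normalize_counts(m2)$size_factors$size_factor, c(1, 1))

  # hand-computed median of ratios on a 3-feature matrix
  m3 <- tibble::tibble(feature = c("g1", "g2", "g3"),
                       x = c(8L, 16L, 100L), y = c(2L, 4L, 25L))
  ref <- exp(rowMeans(log(cbind(m3$x, m3$y))))
  expect_equal(normalize_counts(m3)$size_factors$size_factor,
               c(median(m3$x / ref), median(m3$y / ref)))
})

test_that("the NB test controls the null and detects a 4-fold shift", {
  null <- sim_two_group(2000, 1, seed = 21)
  de0 <- nb_pairwise_test(null$counts, null$design, "A", "P")
  p <- de0$p[!is.na(de0$p)]
  # p-values uniform-ish: type-I near nominal, no gross KS departure
  expect_lt(mean(p < 0.05), 0.09)
  expect_gt(mean(p < 0.05), 0.015)
  expect_lt(suppressWarnings(stats::ks.test(p, "punif")$statistic), 0.1)
  expect_equal(sum(de0$significant), 0)

  shift <- sim_two_group(600, 4, frac_shifted = 0.1, seed = 22)
  de1 <- nb_pairwise_test(shift$counts, shift$design, "A", "P")
  expect_gt(mean(de1$significant[shift$shifted]), 0.9)  # power at |lfc| = 2
  expect_lt(abs(median(de1$log2fc[shift$shifted]) - 2), 0.25)
  expect_lt(mean(de1$significant[!shift$shifted]), 0.02)

  # q < fdr alone is not enough: the fold-change cutoff binds
  strong_small <- de1$q < 0.05 & abs(de1$log2fc) < 1
  expect_true(all(!de1$significant[strong_small]))

  # all-zero features are reported untested
  z <- sim_two_group(10, 1, seed = 23)
  z$counts[1, -1] <- 0L
  dez <- nb_pairwise_test(z$counts, z$design, "A", "P")
  expect_true(is.na(dez$p[1]))
})

test_that("the NB engine agrees with DESeq2 on simulated data", {
  skip_if_not_installed("DESeq2")
  x <- sim_two_group(300, 3, mean0 = 80, seed = 31)
  de <- nb_pairwise_test(x$counts, x$design, "A", "P")
  mat <- as.matrix(x$counts[, -1])
  rownames(mat) <- x$counts$feature
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      mat, S4Vectors::DataFrame(condition = factor(x$design$genotype,
                                                   levels = c("A", "P"))),
      ~condition)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    ref <- as.data.frame(DESeq2::results(dds))
  })
  ok <- !is.na(ref$padj) & !is.na(de$q)
  expect_gt(cor(de$log2fc[ok], ref$log2FoldChange[ok]), 0.95)
  sig_mine <- de$q[ok] < 0.05 & abs(de$log2fc[ok]) >= 1
  sig_ref <- ref$padj[ok] < 0.05 & abs(ref$log2FoldChange[ok]) >= 1
  agree <- mean(sig_mine == sig_ref)
  expect_gt(agree, 0.9)
})

test_that("pattern classification is total, deterministic and order-faithful", {
  rels <- c("<", "=", ">")
  triads <- expand.grid(ap = rels, ah = rels, ph = rels,
                        stringsAsFactors = FALSE)
  feats <- sprintf("t%02d", seq_len(nrow(triads)))
  calls <- classify_pattern(de_from_rel(feats, triads$ap),
                            de_from_rel(feats, triads$ah),
                            de_from_rel(feats, triads$ph))
  expect_equal(nrow(calls), 27)
  expect_true(all(!is.na(calls$fine_pattern)))
  expect_true(all(!is.na(calls$coarse_class)))
  expect_equal(sum(calls$consistent), 13)
  expect_equal(dplyr::n_distinct(calls$fine_pattern[calls$consistent]), 13)

  calls2 <- classify_pattern(de_from_rel(feats, triads$ap),
                             de_from_rel(feats, triads$ah),
                             de_from_rel(feats, triads$ph))
  expect_identical(calls, calls2)

  pick <- function(ap, ah, ph) {
    calls[triads$ap == ap & triads$ah == ah & triads$ph == ph, ]
  }
  none <- pick("=", "=", "=")
  expect_equal(none$fine_pattern, "A=H=P")
  expect_equal(none$coarse_class, "equal")
  # A<P, A<H and P>H all significant: the strict chain A<H<P
  chain <- pick("<", "<", ">")
  expect_equal(chain$fine_pattern, "A<H<P")
  expect_equal(chain$coarse_class, "peach_up")
  trans <- pick("=", "<", "<")
  expect_equal(trans$fine_pattern, "(A=P)<H")
  expect_equal(trans$coarse_class, "hybrid_up")
  # hybrid above both parents dominates a parental difference
  expect_equal(pick("<", "<", "<")$coarse_class, "hybrid_up")
  # order-inconsistent triad resolves by the parental contrast
  incons <- pick("<", "=", "=")
  expect_false(incons$consistent)
  expect_equal(incons$coarse_class, "peach_up")

  expect_error(
    classify_pattern(de_from_rel(c("a", "b"), c("<", "=")),
                     de_from_rel(c("a", "c"), c("<", "=")),
                     de_from_rel(c("a", "b"), c("<", "="))),
    "missing a contrast")
})

test_that("pattern summaries give percentages of the expressed total", {
  counts <- c(equal = 17439, peach_up = 2389, almond_up = 2234,
              hybrid_up = 152, hybrid_down = 60)
  calls <- tibble::tibble(coarse_class = rep(names(counts), counts))
  s <- summarize_patterns(calls)
  expect_equal(sum(s$n), 22274)
  expect_equal(s$pct[match(c("equal", "peach_up", "almond_up", "hybrid_up",
                             "hybrid_down"), s$coarse_class)],
               c(78.3, 10.7, 10.0, 0.7, 0.3))

  one <- summarize_patterns(tibble::tibble(coarse_class = "equal"))
  expect_equal(one$pct[one$coarse_class == "equal"], 100)
  expect_equal(nrow(summarize_patterns(tibble::tibble(
    coarse_class = character()))), 0)
})

test_that("coarse-class recovery on simulated counts exceeds 90%", {
  feats <- tibble::tibble(id = sprintf("gene_%03d", 1:400), chrom = "chr1",
                          start = 1L, end = 2L, strand = "+", kind = "gene",
                          te_class = NA_character_, family = NA_character_)
  cfg <- sim_config(seed = 77L)
  sc <- simulate_counts(feats, cfg)
  nc <- normalize_counts(sc$counts)
  de <- lapply(list(c("A", "P"), c("A", "H"), c("P", "H")), function(g) {
    nb_pairwise_test(sc$counts, sc$design, g[1], g[2],
                     size_factors = nc$size_factors)
  })
  calls <- classify_pattern(de[[1]], de[[2]], de[[3]])
  m <- dplyr::inner_join(calls, sc$truth, by = "feature")
  expect_gt(mean(m$coarse_class.x == m$coarse_class.y), 0.9)
})

test_that("family representatives respect the kind-specific cutoffs", {
  tab <- tibble::tibble(
    family = c("LTR_1", "LTR_1", "TIR_1", "LTR_2"),
    copy = c("c1", "c2", "c3", "c4"),
    te_kind = c("retrotransposon", "retrotransposon", "dna_transposon",
                "retrotransposon"),
    coverage = c(0.85, 0.79, 0.45, 0.79))
  suppressMessages(rep_ <- select_family_representative(tab))
  expect_equal(rep_$copy[rep_$family == "LTR_1"], "c1")
  expect_true("TIR_1" %in% rep_$family)            # 0.45 >= 0.40
  expect_false("LTR_2" %in% rep_$family)           # 0.79 < 0.80
})

test_that("ortholog correlation hits the closed-form extremes", {
  ea <- tibble::tibble(feature = paste0("a", 1:5), s1 = 1:5 + 0.0,
                       s2 = 1:5 + 0.0)
  eb <- tibble::tibble(feature = paste0("b", 1:5), s1 = 1:5 + 0.0,
                       s2 = 1:5 + 0.0)
  pairs <- tibble::tibble(feature_a = paste0("a", 1:5),
                          feature_b = paste0("b", 1:5))
  expect_equal(ortholog_correlation(ea, eb, pairs)$r, 1)
  eb_rev <- dplyr::mutate(eb, s1 = rev(s1), s2 = rev(s2))
  expect_equal(ortholog_correlation(ea, eb_rev, pairs)$r, -1)
  expect_error(ortholog_correlation(ea, eb, pairs[1:2, ]), "at least 3")
})

test_that("ddCt quantification matches closed forms and ignores plate offsets", {
  expr <- tibble::tibble(gene = rep(c("TEF2", "RPII", "t1"), each = 3),
                         genotype = rep(c("A", "P", "H"), 3),
                         expression = c(rep(1, 6), 1, 4, 2))
  ct <- simulate_qpcr(expr, sim_config(seed = 3L), noise_sd = 0)
  rel <- ddct_quantify(ct, c("TEF2", "RPII"), calibrator = "A")
  expect_equal(rel$rel_expr[rel$genotype == "A"], 1)      # self-calibration
  expect_equal(rel$rel_expr[rel$genotype == "P"], 4)      # ddCt = -2
  expect_equal(rel$rel_expr[rel$genotype == "H"], 2)

  rel_off <- ddct_quantify(dplyr::mutate(ct, ct = ct + 3.7),
                           c("TEF2", "RPII"), calibrator = "A")
  expect_equal(rel$rel_expr, rel_off$rel_expr)
  expect_equal(rel$dct_sd, rel_off$dct_sd)

  broken <- dplyr::filter(ct, !(gene == "TEF2" & sample == "A_1"))
  expect_error(ddct_quantify(broken, c("TEF2", "RPII"), "A"), "A_1")
})
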