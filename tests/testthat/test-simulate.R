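test_that("genome pair is deterministic under a fixed seed and diverges as configured", {
  cfg <- sim_config(seed = 5L, genome_length = 2e5, n_te_per_class = 4,
                    n_genes = 10, chloroplast_length = 3000)
  s1 <- simulate_genome_pair(cfg)
  s2 <- simulate_genome_pair(cfg)
  expect_identical(as.character(s1$genomes$almond),
                   as.character(s2$genomes$almond))
  expect_identical(as.character(s1$genomes$peach),
                   as.character(s2$genomes$peach))
  expect_identical(s1$features, s2$features)

  # expected 20 SNPs/kb; binomial sd at 200 kb is ~0.3/kb
  expect_lt(abs(s1$truth$snp_per_kb - 20), 1)

  s3 <- simulate_genome_pair(sim_config(seed = 6L, genome_length = 2e5,
                                        n_te_per_class = 4, n_genes = 10,
                                        chloroplast_length = 3000))
  expect_false(identical(as.character(s1$genomes$almond),
                         as.character(s3$genomes$almond)))
})

test_that("zero divergence gives identical parents and the chloroplast is shared", {
  cfg <- sim_config(seed = 2L, genome_length = 4e4, divergence = 0,
                    n_te_per_class = 2, n_genes = 5,
                    chloroplast_length = 2000)
  s <- simulate_genome_pair(cfg)
  expect_identical(as.character(s$genomes$almond[["chr1"]]),
                   as.character(s$genomes$peach[["chr1"]]))
  expect_identical(as.character(s$genomes$almond[["chloroplast"]]),
                   as.character(s$genomes$peach[["chloroplast"]]))
  expect_equal(nrow(s$truth$snp_positions), 0)
})

test_that("an undersized genome raises a sizing error naming the deficit", {
  expect_error(
    simulate_genome_pair(sim_config(seed = 1L, genome_length = 5000,
                                    n_te_per_class = 5, n_genes = 10,
                                    chloroplast_length = 1000)),
    "genome too small")
})

test_that("features are non-overlapping and upstream regions sit 1 kb before the ATG", {
  feats <- tiny_sim$features
  placed <- dplyr::filter(feats, kind %in% c("te", "gene")) |>
    dplyr::arrange(start)
  expect_true(all(placed$start[-1] > placed$end[-nrow(placed)]))
  expect_true(all(placed$start <= placed$end))

  up <- dplyr::filter(feats, kind == "upstream")
  genes <- dplyr::filter(feats, kind == "gene")
  m <- match(sub("_up$", "", up$id), genes$id)
  plus <- genes$strand[m] == "+"
  expect_true(all(up$end[plus] == genes$start[m][plus] - 1))
  expect_true(all(up$start[!plus] == genes$end[m][!plus] + 1))
  interior <- up$start > 1 & up$end < tiny_cfg$genome_length
  expect_true(all((up$end - up$start + 1)[interior] == 1000))
})

test_that("spiked DMRs are disjoint, grid-aligned and carried into the truth", {
  sp <- tiny_meth$truth$spiked_dmrs
  expect_equal(nrow(sp), tiny_cfg$n_spiked_dmrs)
  sp <- dplyr::arrange(sp, start)
  if (nrow(sp) > 1) expect_true(all(sp$start[-1] > sp$end[-nrow(sp)]))
  expect_true(all((sp$start - 1) %% 50 == 0))
  expect_true(all(sp$direction %in% c("hybrid_up", "hybrid_down")))
})

test_that("methylome reports are seed-deterministic and respect conversion", {
  m2 <- simulate_methylomes(tiny_sim, tiny_cfg)
  expect_identical(tiny_meth$reports$almond$almond, m2$reports$almond$almond)
  expect_identical(tiny_meth$reports$peach$hybrid, m2$reports$peach$hybrid)

  # perfect conversion + truly unmethylated chloroplast => no C calls
  cfg1 <- sim_config(seed = 9L, genome_length = 4e4, conversion_rate = 1,
                     n_te_per_class = 2, n_genes = 5,
                     chloroplast_length = 3000, n_spiked_dmrs = 0)
  s1 <- simulate_genome_pair(cfg1)
  m1 <- simulate_methylomes(s1, cfg1)
  cp <- dplyr::filter(m1$reports$almond$almond, chrom == "chloroplast")
  expect_true(all(cp$count_meth == 0))

  # with conversion 0.98, ~2% of unmethylated calls read as C
  cp98 <- dplyr::filter(tiny_meth$reports$almond$almond,
                        chrom == "chloroplast")
  frac <- sum(cp98$count_meth) / sum(cp98$count_meth + cp98$count_unmeth)
  expect_lt(abs(frac - 0.02), 0.005)
})

test_that("observed methylation converges to the conversion-adjusted truth", {
  # E[p_obs] = m + (1 - m) (1 - conversion)
  lev <- tiny_meth$truth$levels
  rep_a <- tiny_meth$reports$almond$almond
  for (ctx in c("CG", "CHG", "CHH")) {
    r <- dplyr::filter(rep_a, context == ctx, chrom == "chr1")
    obs <- sum(r$count_meth) / sum(r$count_meth + r$count_unmeth)
    blk <- dplyr::filter(lev, context == ctx, chrom == "chr1")
    w <- blk$end - blk$start + 1
    m_true <- sum(blk$level_almond * w) / sum(w)
    expected <- m_true + (1 - m_true) * (1 - tiny_cfg$conversion_rate)
    expect_lt(abs(obs - expected), 0.02)
  }
})

test_that("count simulation encodes patterns in genotype means", {
  cfg <- sim_config(seed = 13L, genome_length = 5e4, n_te_per_class = 3,
                    n_genes = 40, chloroplast_length = 2000)
  sc <- simulate_counts(tiny_sim$features, cfg)
  expect_true(all(c("A_1", "P_3", "H_2") %in% names(sc$counts)))
  expect_true(all(sc$truth$coarse_class %in%
                    c("equal", "peach_up", "almond_up", "hybrid_up",
                      "hybrid_down")))
  eq <- sc$truth$coarse_class == "equal"
  expect_true(all(sc$truth$mu_A[eq] == sc$truth$mu_P[eq]))
  pu <- sc$truth$coarse_class == "peach_up"
  expect_true(all(sc$truth$mu_P[pu] / sc$truth$mu_A[pu] ==
                    2^cfg$lfc_effect))

  # null simulation: zero effect size collapses every pattern to "equal"
  cfg0 <- sim_config(seed = 13L, lfc_effect = 0)
  sc0 <- simulate_counts(tiny_sim$features, cfg0)
  expect_true(all(sc0$truth$coarse_class == "equal"))
  expect_true(all(sc0$truth$fine_intent == "A=H=P"))
})

test_that("qPCR simulation follows the amplification model and rejects bad input", {
  expr <- tibble::tibble(gene = rep(c("TEF2", "RPII", "t"), each = 3),
                         genotype = rep(c("A", "P", "H"), 3),
                         expression = c(rep(1, 6), 2, 8, 4))
  ct <- simulate_qpcr(expr, tiny_cfg, noise_sd = 0)
  t_a <- ct$ct[ct$gene == "t" & ct$genotype == "A"][1]
  t_p <- ct$ct[ct$gene == "t" & ct$genotype == "P"][1]
  expect_equal(t_a - t_p, log2(8 / 2))
  expect_error(simulate_qpcr(dplyr::mutate(expr, expression = 0), tiny_cfg),
               "positive")
})
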