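ctx_report <- function(pos, meth, unmeth, context = "CG") {
  tibble::tibble(chrom = "chr1", pos = as.integer(pos), strand = "+",
                 count_meth = as.integer(meth),
                 count_unmeth = as.integer(unmeth),
                 context = context, trinucleotide = "NNN")
}

test_that("window tiling covers chromosomes with a retained partial tail", {
  expect_equal(tile_windows(c(chr1 = 150))$start, c(1L, 51L, 101L))
  w <- tile_windows(c(chr1 = 120))
  expect_equal(w$end, c(50L, 100L, 120L))
  expect_error(tile_windows(c(chr1 = 0)), "positive")
  expect_error(tile_windows(150), "named")
})

test_that("Fisher p-values agree with stats::fisher.test", {
  expect_lt(abs(fisher_p(10, 0, 0, 10) - 2 / choose(20, 10)), 1e-12)
  set.seed(31)
  for (i in 1:200) {
    tab <- matrix(rpois(4, 12), 2)
    p_mine <- fisher_p(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    p_ref <- stats::fisher.test(t(tab))$p.value
    expect_lt(abs(p_mine - p_ref), 1e-10)
  }
  # no association: identical rows
  expect_equal(fisher_p(7, 3, 7, 3), 1)
})

test_that("window statistics apply the three filters before testing", {
  a <- ctx_report(1:10, 18, 2)
  b <- ctx_report(1:10, 2, 18)
  ws <- window_stats(a, b, "CG")
  expect_equal(nrow(ws), 1)
  expect_true(ws$tested)
  expect_equal(ws$diff, 0.1 - 0.9)
  expect_equal(ws$avg_reads, 20)
  expect_lt(ws$q, 1e-10)

  # fewer than three context cytosines
  ws2 <- window_stats(ctx_report(1:2, 18, 2), ctx_report(1:2, 2, 18), "CG")
  expect_false(ws2$tested)
  # small difference
  ws3 <- window_stats(ctx_report(1:10, 10, 10), ctx_report(1:10, 12, 8),
                      "CG")
  expect_false(ws3$tested)
  # low coverage: 3 reads/position on average
  ws4 <- window_stats(ctx_report(1:10, 3, 0), ctx_report(1:10, 0, 3), "CG")
  expect_false(ws4$tested)
  # identical counts: p = 1, diff = 0
  ws5 <- window_stats(ctx_report(1:10, 15, 5), ctx_report(1:10, 15, 5),
                      "CG", dmr_params(min_diff = 0))
  expect_equal(ws5$p, 1)
  expect_equal(ws5$diff, 0)
})

test_that("BH q-values reproduce the classic step-up rejection set", {
  set.seed(17)
  pos <- seq(1L, by = 3L, length.out = 120)
  meth_a <- rbinom(120, 20, 0.5)
  meth_b <- rbinom(120, 20, c(rep(0.5, 80), rep(0.95, 40)))
  a <- ctx_report(pos, meth_a, 20 - meth_a)
  b <- ctx_report(pos, meth_b, 20 - meth_b)
  ws <- window_stats(a, b, "CG", dmr_params(min_diff = 0, min_avg_reads = 0))
  tested <- dplyr::filter(ws, tested)
  expect_gt(nrow(tested), 5)
  expect_true(all(tested$q >= tested$p - 1e-12))
  for (alpha in c(0.01, 0.05, 0.2)) {
    expect_identical(tested$q < alpha,
                     oracle_bh_reject(tested$p, alpha))
  }
})

test_that("bins merge below 300 bp gaps, stay separate at 300+, idempotently", {
  bins <- tibble::tibble(chrom = "chr1",
                         start = c(1L, 251L, 651L),
                         end = c(50L, 300L, 700L),
                         context = "CG", direction = "hybrid_up",
                         prop_a = 0.2, prop_b = 0.7, q = 0.01)
  m <- merge_dmr_bins(bins)                 # gaps: 200 then 350
  expect_equal(nrow(m), 2)
  expect_equal(m$start, c(1L, 651L))
  expect_equal(m$end, c(300L, 700L))
  expect_equal(m$n_windows, c(2L, 1L))

  # boundary: gap of exactly 300 stays split, 299 joins
  b2 <- dplyr::mutate(bins[1:2, ], start = c(1L, 351L), end = c(50L, 400L))
  expect_equal(nrow(merge_dmr_bins(b2)), 2)
  b3 <- dplyr::mutate(bins[1:2, ], start = c(1L, 350L), end = c(50L, 400L))
  expect_equal(nrow(merge_dmr_bins(b3)), 1)

  # opposite directions never merge
  b4 <- dplyr::mutate(bins[1:2, ], direction = c("hybrid_up", "almond_up"))
  expect_equal(nrow(merge_dmr_bins(b4)), 2)

  # idempotence
  expect_equal(merge_dmr_bins(m), m)
})

test_that("call_dmrs returns nothing under the exact null and on identical reports", {
  a <- ctx_report(seq(1L, 600L, by = 3L), 15, 5)
  expect_warning(d0 <- call_dmrs(a, a, "CG"), "zero windows")
  expect_equal(nrow(d0), 0)
})

test_that("called DMRs have direction-homogeneous member windows", {
  rep_a <- filter_positions(tiny_meth$reports$almond$almond)
  rep_h <- filter_positions(tiny_meth$reports$almond$hybrid)
  for (ctx in c("CG", "CHH")) {
    d <- suppressWarnings(call_dmrs(rep_a, rep_h, ctx, label_a = "almond", label_b = "hybrid"))
    ws <- attr(d, "windows")
    if (nrow(d) == 0) next
    for (i in seq_len(nrow(d))) {
      members <- dplyr::filter(ws, tested, q < 0.05,
                               start >= d$start[i], end <= d$end[i])
      expect_gt(nrow(members), 0)
      want <- if (d$direction[i] == "hybrid_up") 1 else -1
      expect_true(all(sign(members$diff) == want))
    }
    # merging the output again changes nothing
    expect_equal(merge_dmr_bins(tidy(d))$start, d$start)
    expect_equal(merge_dmr_bins(tidy(d))$end, d$end)
  }
})

test_that("DMR annotation double-counts categories and keeps orphans", {
  feats <- tibble::tibble(
    id = c("g1", "ltr1"), chrom = "chr1",
    start = c(100L, 180L), end = c(200L, 400L),
    strand = "+", kind = c("gene", "te"),
    te_class = c(NA, "ltr_retrotransposon"),
    family = c(NA, "LTR_1"))
  dmrs <- tibble::tibble(chrom = "chr1",
                         start = c(150L, 190L, 900L),
                         end = c(160L, 210L, 950L),
                         context = "CG",
                         direction = c("hybrid_up", "parent_up",
                                       "hybrid_up"))
  ann <- annotate_dmrs(dmrs, feats)
  # DMR 1 inside the gene (an intron is still between ATG and stop)
  expect_equal(dplyr::filter(ann, category == "gene",
                             direction == "hybrid_up")$n, 1L)
  # DMR 2 overlaps both the gene and the LTR copy: counted in both rows
  expect_equal(dplyr::filter(ann, category == "gene",
                             direction == "parent_up")$n, 1L)
  expect_equal(dplyr::filter(ann, category == "ltr_retrotransposon")$n, 1L)
  expect_equal(dplyr::filter(ann, category == "unassigned")$n, 1L)
  expect_equal(sum(dplyr::filter(ann, category == "gene")$pct), 100)
})

test_that("family summaries keep only families with at least 5 DMRs", {
  te <- tibble::tibble(id = paste0("c", 1:2), chrom = "chr1",
                       start = c(1L, 2000L), end = c(1000L, 3000L),
                       strand = "+", kind = "te",
                       te_class = "ltr_retrotransposon",
                       family = c("LTR_1", "LTR_2"))
  mk_dmrs <- function(n, offset) {
    tibble::tibble(chrom = "chr1", start = offset + (0:(n - 1)) * 100L,
                   end = offset + (0:(n - 1)) * 100L + 50L,
                   context = "CHG", direction = "parent_up",
                   mean_prop_a = 0.8, mean_prop_b = 0.4, min_q = 0.01)
  }
  # 5 DMRs on LTR_1, 4 on LTR_2
  dmrs <- dplyr::bind_rows(mk_dmrs(5, 1L), mk_dmrs(4, 2000L))
  fam <- family_dmr_summary(dmrs, te)
  expect_identical(unique(fam$family), "LTR_1")
  expect_equal(unique(fam$n_dmrs), 5L)
  expect_equal(nrow(family_dmr_summary(dmrs[0, ], te)), 0)
})
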