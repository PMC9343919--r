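#' Estimate the bisulfite conversion rate from an unmethylated control
#'
#' The chloroplast genome is unmethylated, so every cytosine read as C there
#' is a conversion failure. The rate is the coverage-weighted fraction of
#' calls read as T: `sum(count_unmeth) / sum(count_meth + count_unmeth)`.
#'
#' @param report Cytosine-report tibble (columns `count_meth`,
#'   `count_unmeth`, optionally `chrom`). Pass only control positions, or
#'   use `chrom` to restrict.
#' @param chrom Optional contig name to restrict to (e.g. "chloroplast").
#' @return One-row tibble: `conversion_rate`, `n_calls`, `n_positions`.
#' @examples
#' estimate_conversion_rate(
#'   tibble::tibble(count_meth = c(1, 1), count_unmeth = c(49, 49)))
#' @export
estimate_conversion_rate <- function(report, chrom = NULL) {
  if (!is.null(chrom)) report <- filter(report, .data$chrom %in% !!chrom)
  total <- sum(report$count_meth) + sum(report$count_unmeth)
  if (nrow(report) == 0L || total == 0L) {
    abort("cannot estimate a conversion rate from zero cytosine calls")
  }
  tibble(conversion_rate = sum(report$count_unmeth) / total,
         n_calls = total, n_positions = nrow(report))
}

#' Drop cytosine positions below a coverage floor
#'
#' Retains positions sequenced at least `min_reads` times
#' (`count_meth + count_unmeth >= min_reads`).
#'
#' @param report Cytosine-report tibble.
#' @param min_reads Inclusive coverage floor (default 3).
#' @return Filtered tibble.
#' @export
filter_positions <- function(report, min_reads = 3L) {
  filter(report, .data$count_meth + .data$count_unmeth >= min_reads)
}

#' Per-feature weighted methylation levels
#'
#' Computes, for every feature and context, the coverage-weighted
#' methylation level `sum(count_meth) / sum(count_meth + count_unmeth)`
#' over the covered cytosines of that context inside the feature (both
#' strands pooled). A feature is `included` when at least
#' `min_coverage_fraction` of its cytosine positions (all contexts pooled)
#' carry data in the report — the observable proxy, at cytosine resolution,
#' for "covered in at least 25% of the feature length". Pass a report that
#' has already been through [filter_positions()].
#'
#' @param report Position-filtered cytosine-report tibble (`chrom`, `pos`,
#'   `strand`, `count_meth`, `count_unmeth`, `context`).
#' @param features Feature tibble (`id`, `chrom`, `start`, `end`, `kind`,
#'   `te_class`, `family`).
#' @param contexts Per-position context map from [assign_contexts()] for
#'   the same reference; supplies the denominator of `coverage_fraction`.
#' @param context `"all"` (one profile row per feature per context) or one
#'   of `"CG"`, `"CHG"`, `"CHH"`.
#' @param min_coverage_fraction Inclusion threshold (default 0.25,
#'   boundary inclusive).
#' @return Tibble of class `meth_profiles`: `feature_id`, `kind`,
#'   `te_class`, `family`, `context`, `weighted_level`, `n_positions`,
#'   `coverage_fraction`, `included`. `weighted_level` is `NA` when no
#'   covered position of that context lies in the feature.
#' @export
feature_methylation <- function(report, features, contexts,
                                context = c("all", "CG", "CHG", "CHH"),
                                min_coverage_fraction = 0.25) {
  context <- match.arg(context)
  wanted <- if (context == "all") c("CG", "CHG", "CHH") else context

  fg <- GenomicRanges::GRanges(features$chrom,
                               IRanges::IRanges(features$start, features$end))

  # denominator: all cytosine positions per feature (any context)
  cg <- GenomicRanges::GRanges(contexts$chrom,
                               IRanges::IRanges(contexts$pos, width = 1L))
  hits_all <- GenomicRanges::findOverlaps(fg, cg)
  denom <- tabulate(S4Vectors::queryHits(hits_all), nbins = nrow(features))

  rg <- GenomicRanges::GRanges(report$chrom,
                               IRanges::IRanges(report$pos, width = 1L))
  hits_cov <- GenomicRanges::findOverlaps(fg, rg)
  covered <- tabulate(S4Vectors::queryHits(hits_cov), nbins = nrow(features))

  assigned <- tibble(
    fi = S4Vectors::queryHits(hits_cov),
    context = report$context[S4Vectors::subjectHits(hits_cov)],
    count_meth = report$count_meth[S4Vectors::subjectHits(hits_cov)],
    count_unmeth = report$count_unmeth[S4Vectors::subjectHits(hits_cov)]) %>%
    filter(.data$context %in% wanted) %>%
    group_by(.data$fi, .data$context) %>%
    summarise(weighted_level = sum(.data$count_meth) /
                sum(.data$count_meth + .data$count_unmeth),
              n_positions = n(), .groups = "drop")

  out <- crossing(fi = seq_len(nrow(features)), context = wanted) %>%
    left_join(assigned, by = c("fi", "context")) %>%
    mutate(n_positions = ifelse(is.na(.data$n_positions), 0L,
                                .data$n_positions),
           feature_id = features$id[.data$fi],
           kind = features$kind[.data$fi],
           te_class = features$te_class[.data$fi],
           family = features$family[.data$fi],
           coverage_fraction = ifelse(denom[.data$fi] > 0,
                                      covered[.data$fi] / denom[.data$fi], 0),
           included = .data$coverage_fraction >= min_coverage_fraction) %>%
    select("feature_id", "kind", "te_class", "family", "context",
           "weighted_level", "n_positions", "coverage_fraction", "included") %>%
    arrange(.data$feature_id, .data$context)
  class(out) <- c("meth_profiles", class(out))
  out
}

#' Compare per-class methylation between two genotypes
#'
#' For each TE class (plus a pooled `"total"` row over all TE copies) and
#' context, compares the weighted methylation levels of features included
#' in both genotypes with a two-sided unpaired Wilcoxon rank-sum test, and
#' reports means in percent and their difference (`b - a`, in percentage
#' points).
#'
#' @param profiles_a,profiles_b [feature_methylation()] outputs for the two
#'   genotypes on a shared reference.
#' @param label_a,label_b Genotype labels used in the output.
#' @return Tibble of class `meth_class_summary`: `te_class`, `context`,
#'   `genotype_a`, `genotype_b`, `mean_a`, `mean_b`, `mean_difference`
#'   (percentage points), `wilcoxon_p` (`NA` when either group has n < 2),
#'   `n`.
#' @export
summarize_by_class <- function(profiles_a, profiles_b,
                               label_a = "a", label_b = "b") {
  paired <- inner_join(
    filter(profiles_a, .data$kind == "te", .data$included,
           !is.na(.data$weighted_level)),
    filter(profiles_b, .data$kind == "te", .data$included,
           !is.na(.data$weighted_level)),
    by = c("feature_id", "context", "te_class"), suffix = c("_a", "_b"))
  paired <- bind_rows(paired, mutate(paired, te_class = "total"))

  out <- paired %>%
    group_by(.data$te_class, .data$context) %>%
    summarise(
      mean_a = 100 * mean(.data$weighted_level_a),
      mean_b = 100 * mean(.data$weighted_level_b),
      mean_difference = .data$mean_b - .data$mean_a,
      wilcoxon_p = if (n() >= 2L) {
        suppressWarnings(wilcox.test(.data$weighted_level_b,
                                     .data$weighted_level_a,
                                     exact = FALSE, correct = TRUE)$p.value)
      } else NA_real_,
      n = n(), .groups = "drop") %>%
    mutate(genotype_a = label_a, genotype_b = label_b, .before = "mean_a")
  if (any(is.na(out$wilcoxon_p))) {
    inform("some class/context cells had n < 2; Wilcoxon p set to NA")
  }
  class(out) <- c("meth_class_summary", class(out))
  out
}
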