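#' Two-sided Fisher's exact p-value for 2x2 tables, vectorized
#'
#' Enumerates the hypergeometric distribution over all tables with the
#' observed margins and sums the probabilities of tables no more probable
#' than the observed one (with the standard relative tolerance guard,
#' `1 + 1e-7`, against floating-point ties). Vectorized over parallel count
#' vectors; equivalent to `stats::fisher.test()$p.value` on each table.
#'
#' @param a,b First row of each table (e.g. methylated/unmethylated,
#'   condition A).
#' @param c,d Second row (condition B).
#' @return Numeric vector of two-sided p-values in (0, 1].
#' @examples
#' fisher_p(10, 0, 0, 10)
#' @export
fisher_p <- function(a, b, c, d) {
  n <- length(a)
  stopifnot(length(b) == n, length(c) == n, length(d) == n)
  vapply(seq_len(n), function(i) {
    m <- a[i] + c[i]            # first-column margin
    nn <- b[i] + d[i]
    k <- a[i] + b[i]            # first-row margin
    lo <- max(0L, k - nn)
    hi <- min(k, m)
    dens <- dhyper(lo:hi, m, nn, k)
    min(1, sum(dens[dens <= dens[a[i] - lo + 1L] * (1 + 1e-7)]))
  }, numeric(1))
}

#' Tile chromosomes into fixed windows
#'
#' Adjacent, non-overlapping windows of `params$window` bp covering each
#' chromosome; the final partial window is retained.
#'
#' @param chrom_lengths Named vector of chromosome lengths (> 0).
#' @param params A [dmr_params()].
#' @return Tibble: `chrom`, `start`, `end` (1-based inclusive).
#' @examples
#' tile_windows(c(chr1 = 120))
#' @export
tile_windows <- function(chrom_lengths, params = dmr_params()) {
  if (is.null(names(chrom_lengths))) abort("chrom_lengths must be named")
  if (any(chrom_lengths <= 0)) abort("chromosome lengths must be positive")
  map_dfr(names(chrom_lengths), function(ch) {
    L <- as.integer(chrom_lengths[[ch]])
    s <- seq.int(1L, L, by = params$window)
    tibble(chrom = ch, start = s, end = pmin(s + params$window - 1L, L))
  })
}

#' Per-window differential methylation statistics
#'
#' Restricts both position-filtered reports to one context, keeps the
#' cytosine positions with data in *both* conditions, pools counts within
#' each fixed window, and computes the 2x2 Fisher's exact test
#' (methylated/unmethylated x condition) per window. Windows failing any of
#' the three filters — fewer than `min_cytosines` context cytosines, an
#' absolute methylation-proportion difference below `min_diff`, or an
#' average read count per cytosine below `min_avg_reads` — are marked
#' `tested = FALSE` and excluded from multiple testing; BH-adjusted
#' q-values are computed across the tested windows only.
#'
#' @param report_a,report_b Position-filtered cytosine reports on one
#'   reference (see [filter_positions()]).
#' @param context One of `"CG"`, `"CHG"`, `"CHH"`.
#' @param params A [dmr_params()].
#' @return Tibble of window statistics: `chrom`, `start`, `end`,
#'   `context`, `n_cytosines`, `meth_a`, `unmeth_a`, `meth_b`, `unmeth_b`,
#'   `prop_a`, `prop_b`, `diff` (`prop_b - prop_a`), `avg_reads`,
#'   `tested`, `p`, `q`. Windows with no jointly covered position are
#'   absent.
#' @export
window_stats <- function(report_a, report_b, context,
                         params = dmr_params()) {
  ctx <- context
  a <- filter(report_a, .data$context == ctx)
  b <- filter(report_b, .data$context == ctx)
  joint <- inner_join(
    select(a, "chrom", "pos", "strand", ma = "count_meth",
           ua = "count_unmeth"),
    select(b, "chrom", "pos", "strand", mb = "count_meth",
           ub = "count_unmeth"),
    by = c("chrom", "pos", "strand"))
  if (nrow(joint) == 0L) {
    warn("no jointly covered positions for this context")
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  context = character(), n_cytosines = integer(),
                  meth_a = integer(), unmeth_a = integer(),
                  meth_b = integer(), unmeth_b = integer(),
                  prop_a = double(), prop_b = double(), diff = double(),
                  avg_reads = double(), tested = logical(), p = double(),
                  q = double()))
  }
  w <- params$window
  ws <- joint %>%
    mutate(start = ((.data$pos - 1L) %/% w) * w + 1L) %>%
    group_by(.data$chrom, .data$start) %>%
    summarise(n_cytosines = n_distinct(.data$pos, .data$strand),
              meth_a = sum(.data$ma), unmeth_a = sum(.data$ua),
              meth_b = sum(.data$mb), unmeth_b = sum(.data$ub),
              .groups = "drop") %>%
    mutate(end = .data$start + w - 1L, context = ctx,
           prop_a = .data$meth_a / (.data$meth_a + .data$unmeth_a),
           prop_b = .data$meth_b / (.data$meth_b + .data$unmeth_b),
           diff = .data$prop_b - .data$prop_a,
           avg_reads = (.data$meth_a + .data$unmeth_a + .data$meth_b +
                          .data$unmeth_b) / (2 * .data$n_cytosines),
           tested = .data$n_cytosines >= params$min_cytosines &
             abs(.data$diff) >= params$min_diff &
             .data$avg_reads >= params$min_avg_reads,
           p = NA_real_, q = NA_real_)
  if (any(ws$tested)) {
    i <- which(ws$tested)
    ws$p[i] <- fisher_p(ws$meth_a[i], ws$unmeth_a[i],
                        ws$meth_b[i], ws$unmeth_b[i])
    ws$q[i] <- p.adjust(ws$p[i], method = "BH")
  }
  select(ws, "chrom", "start", "end", "context", "n_cytosines",
         "meth_a", "unmeth_a", "meth_b", "unmeth_b", "prop_a", "prop_b",
         "diff", "avg_reads", "tested", "p", "q") %>%
    arrange(.data$chrom, .data$start)
}

#' Merge candidate bins into DMRs
#'
#' Joins significant bins of identical chromosome, context and direction
#' whose gap (bases strictly between consecutive bins) is smaller than
#' `join_distance`. Idempotent: merging the output again changes nothing.
#'
#' @param bins Tibble with `chrom`, `start`, `end`, `context`,
#'   `direction`, and optionally `n_windows`, `prop_a`/`mean_prop_a`,
#'   `prop_b`/`mean_prop_b`, `q`/`min_q`.
#' @param join_distance Merge threshold in bp (gap < `join_distance`).
#' @return Tibble with one row per merged region: `chrom`, `start`, `end`,
#'   `context`, `direction`, `n_windows`, `mean_prop_a`, `mean_prop_b`,
#'   `min_q`, sorted by coordinate.
#' @export
merge_dmr_bins <- function(bins, join_distance = 300L) {
  if (nrow(bins) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  context = character(), direction = character(),
                  n_windows = integer(), mean_prop_a = double(),
                  mean_prop_b = double(), min_q = double()))
  }
  b <- bins
  if (!"n_windows" %in% names(b)) b$n_windows <- 1L
  if (!"mean_prop_a" %in% names(b)) b$mean_prop_a <- b$prop_a
  if (!"mean_prop_b" %in% names(b)) b$mean_prop_b <- b$prop_b
  if (!"min_q" %in% names(b)) b$min_q <- b$q
  b %>%
    arrange(.data$chrom, .data$context, .data$direction, .data$start) %>%
    group_by(.data$chrom, .data$context, .data$direction) %>%
    mutate(gap = .data$start - lag(.data$end) - 1L,
           new_run = is.na(.data$gap) | .data$gap >= join_distance,
           run = cumsum(.data$new_run)) %>%
    group_by(.data$chrom, .data$context, .data$direction, .data$run) %>%
    summarise(start = min(.data$start), end = max(.data$end),
              mean_prop_a = sum(.data$mean_prop_a * .data$n_windows) /
                sum(.data$n_windows),
              mean_prop_b = sum(.data$mean_prop_b * .data$n_windows) /
                sum(.data$n_windows),
              min_q = min(.data$min_q), n_windows = sum(.data$n_windows),
              .groups = "drop") %>%
    select("chrom", "start", "end", "context", "direction", "n_windows",
           "mean_prop_a", "mean_prop_b", "min_q") %>%
    arrange(.data$chrom, .data$start)
}

#' Call differentially methylated regions between two conditions
#'
#' The full windowed procedure: fixed 50-bp windows, per-window two-sided
#' Fisher's exact test on pooled counts, the three bin filters, BH
#' correction per context across tested windows, selection of windows with
#' `q < fdr`, and merging of same-direction bins separated by less than
#' `join_distance` bp.
#'
#' @param report_a,report_b Position-filtered cytosine reports on the same
#'   reference (condition A, e.g. a parent; condition B, e.g. the hybrid).
#' @param context One of `"CG"`, `"CHG"`, `"CHH"`.
#' @param params A [dmr_params()].
#' @param label_a,label_b Condition labels; DMR `direction` is
#'   `"<label_b>_up"` when condition B is more methylated and
#'   `"<label_a>_up"` otherwise.
#' @return Tibble of class `dmr_set` (see [merge_dmr_bins()] for columns),
#'   with the window statistics available as `attr(, "windows")`.
#' @export
call_dmrs <- function(report_a, report_b, context, params = dmr_params(),
                      label_a = "a", label_b = "b") {
  ws <- window_stats(report_a, report_b, context, params)
  if (!any(ws$tested)) {
    warn("zero windows passed the filters; returning no DMRs")
    out <- merge_dmr_bins(ws[0, c("chrom", "start", "end", "context")] %>%
                            mutate(direction = character(0)))
  } else {
    cand <- ws %>%
      filter(.data$tested, .data$q < params$fdr) %>%
      mutate(direction = ifelse(.data$diff > 0, paste0(label_b, "_up"),
                                paste0(label_a, "_up")))
    out <- merge_dmr_bins(cand, params$join_distance)
  }
  attr(out, "windows") <- ws
  attr(out, "labels") <- c(a = label_a, b = label_b)
  attr(out, "params") <- params
  class(out) <- c("dmr_set", class(out))
  out
}

#' Count DMRs by genomic region category and direction
#'
#' Assigns every DMR to each feature category it overlaps by at least 1 bp
#' (TE classes from `te_class`; `"gene"` = ATG-to-stop span including
#' introns; `"upstream"` = the 1000 bp upstream of the ATG). A DMR
#' overlapping several categories is counted once in each; DMRs touching
#' nothing fall into `"unassigned"`.
#'
#' @param dmrs A [call_dmrs()] result (or any tibble with `chrom`,
#'   `start`, `end`, `context`, `direction`).
#' @param features Feature tibble.
#' @return Tibble: `context`, `category`, `direction`, `n`, `pct`
#'   (percentage of that context x category's DMRs in each direction).
#' @export
annotate_dmrs <- function(dmrs, features) {
  if (nrow(dmrs) == 0L) {
    return(tibble(context = character(), category = character(),
                  direction = character(), n = integer(), pct = double()))
  }
  cat_of <- case_when(features$kind == "te" ~ features$te_class,
                      features$kind == "gene" ~ "gene",
                      .default = "upstream")
  dg <- GenomicRanges::GRanges(dmrs$chrom,
                               IRanges::IRanges(dmrs$start, dmrs$end))
  fg <- GenomicRanges::GRanges(features$chrom,
                               IRanges::IRanges(features$start, features$end))
  hits <- GenomicRanges::findOverlaps(dg, fg)
  assign <- tibble(di = S4Vectors::queryHits(hits),
                   category = cat_of[S4Vectors::subjectHits(hits)]) %>%
    distinct()
  lonely <- setdiff(seq_len(nrow(dmrs)), assign$di)
  assign <- bind_rows(assign, tibble(di = lonely, category = "unassigned"))
  assign %>%
    mutate(context = dmrs$context[.data$di],
           direction = dmrs$direction[.data$di]) %>%
    count(.data$context, .data$category, .data$direction, name = "n") %>%
    group_by(.data$context, .data$category) %>%
    mutate(pct = 100 * .data$n / sum(.data$n)) %>%
    ungroup()
}

#' Per-family DMR summary for TE families
#'
#' Overlaps DMRs with TE copies, counts distinct DMRs per family, keeps
#' families with at least `min_dmrs` of them, and retains per-DMR mean
#' methylation in both conditions for plotting.
#'
#' @param dmrs A [call_dmrs()] result.
#' @param te_features Feature tibble rows with `kind == "te"` and family
#'   labels.
#' @param min_dmrs Family inclusion threshold (default 5, inclusive).
#' @return Tibble of class `dmr_family_summary`: one row per
#'   (family, DMR) pair — `family`, `te_class`, `n_dmrs`, `chrom`,
#'   `start`, `end`, `context`, `direction`, `mean_prop_a`, `mean_prop_b`.
#' @export
family_dmr_summary <- function(dmrs, te_features, min_dmrs = 5L) {
  te <- filter(te_features, .data$kind == "te", !is.na(.data$family))
  empty <- tibble(family = character(), te_class = character(),
                  n_dmrs = integer(), chrom = character(),
                  start = integer(), end = integer(), context = character(),
                  direction = character(), mean_prop_a = double(),
                  mean_prop_b = double())
  if (nrow(dmrs) == 0L || nrow(te) == 0L) {
    class(empty) <- c("dmr_family_summary", class(empty))
    return(empty)
  }
  dg <- GenomicRanges::GRanges(dmrs$chrom,
                               IRanges::IRanges(dmrs$start, dmrs$end))
  fg <- GenomicRanges::GRanges(te$chrom, IRanges::IRanges(te$start, te$end))
  hits <- GenomicRanges::findOverlaps(dg, fg)
  out <- tibble(di = S4Vectors::queryHits(hits),
                family = te$family[S4Vectors::subjectHits(hits)],
                te_class = te$te_class[S4Vectors::subjectHits(hits)]) %>%
    distinct(.data$di, .data$family, .keep_all = TRUE) %>%
    group_by(.data$family) %>%
    mutate(n_dmrs = n_distinct(.data$di)) %>%
    ungroup() %>%
    filter(.data$n_dmrs >= min_dmrs)
  if (nrow(out) == 0L) {
    class(empty) <- c("dmr_family_summary", class(empty))
    return(empty)
  }
  out <- bind_cols(select(out, "family", "te_class", "n_dmrs"),
                   dmrs[out$di, c("chrom", "start", "end", "context",
                                  "direction", "mean_prop_a",
                                  "mean_prop_b")]) %>%
    arrange(.data$family, .data$chrom, .data$start)
  class(out) <- c("dmr_family_summary", class(out))
  out
}
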