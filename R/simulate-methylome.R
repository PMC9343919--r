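#' Generate the ground-truth methylation landscape for a simulated trio
#'
#' Partitions the nuclear chromosome into blocks (each placed TE copy or
#' gene is one block; the intergenic gaps between them are blocks too) and
#' draws, per block and context, a true methylation level for each parent
#' from a beta distribution with the configured context mean and
#' concentration. The hybrid level is the 50:50 allelic mixture
#' `(almond + peach) / 2`, except inside spiked DMRs where it is shifted by
#' `spike_delta` in a feasible direction. The chloroplast is a single block
#' with true methylation 0 in all contexts.
#'
#' @param sim A [simulate_genome_pair()] result.
#' @param config The [sim_config()] used.
#' @return List of class `meth_truth`: `levels` (tibble: chrom, block_id,
#'   start, end, context, level_almond, level_peach, level_hybrid) and
#'   `spiked_dmrs` (tibble: chrom, start, end, context, direction, delta;
#'   pairwise disjoint, window-grid aligned).
#' @export
methylation_truth <- function(sim, config) {
  set.seed(stage_seed(config$seed, "methylome"))
  feats <- filter(sim$features, .data$kind %in% c("te", "gene")) %>%
    arrange(.data$start)
  L <- config$genome_length
  bounds <- sort(unique(c(1L, feats$start, feats$end + 1L, L + 1L)))
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1L] - 1L
  keep <- starts <= ends
  starts <- starts[keep]; ends <- ends[keep]
  idx <- match(starts, feats$start)
  block_id <- ifelse(is.na(idx), paste0("gap_", seq_along(starts)),
                     feats$id[idx])

  blocks <- tibble(chrom = "chr1", block_id = block_id,
                   start = starts, end = ends)
  blocks <- bind_rows(blocks,
                      tibble(chrom = "chloroplast", block_id = "chloroplast",
                             start = 1L, end = config$chloroplast_length))

  levels <- expand_grid(blocks, context = c("CG", "CHG", "CHH")) %>%
    mutate(
      level_almond = draw_level(.data$context, .data$chrom, config),
      level_peach = draw_level(.data$context, .data$chrom, config),
      level_hybrid = (.data$level_almond + .data$level_peach) / 2)

  spikes <- place_spikes(config)
  structure(list(levels = levels, spiked_dmrs = spikes),
            class = "meth_truth")
}

draw_level <- function(context, chrom, config) {
  m <- config$context_means[context]
  conc <- config$context_concentration[context]
  lv <- rbeta(length(context), m * conc, (1 - m) * conc)
  ifelse(chrom == "chloroplast", 0, lv)
}

# window-grid-aligned, widely spaced spike intervals with feasible direction
place_spikes <- function(config, window = 50L) {
  n <- config$n_spiked_dmrs
  if (n == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  context = character(), direction = character(),
                  delta = double()))
  }
  len_w <- ceiling(config$spike_length / window)
  pitch <- (len_w * window) + config$spike_spacing
  max_slots <- (config$genome_length - len_w * window) %/% pitch
  if (max_slots < n) {
    abort(sprintf("genome too small for %d spiked DMRs: room for %d",
                  n, max_slots))
  }
  slots <- sort(sample.int(max_slots, n))
  start <- (slots - 1L) * pitch + 1L
  # snap to the window grid
  start <- ((start - 1L) %/% window) * window + 1L
  end <- start + len_w * window - 1L
  context <- sample(c("CG", "CHG", "CHH"), n, replace = TRUE)
  m <- config$context_means[context]
  up_ok <- m + config$spike_delta <= 0.98
  dn_ok <- m - config$spike_delta >= 0.02
  direction <- ifelse(up_ok & dn_ok,
                      sample(c("hybrid_up", "hybrid_down"), n, replace = TRUE),
                      ifelse(up_ok, "hybrid_up", "hybrid_down"))
  tibble(chrom = "chr1", start = start, end = end, context = context,
         direction = direction, delta = config$spike_delta)
}

#' Draw one cytosine report from a ground-truth methylome
#'
#' Simulates per-position coverage (Poisson) and methylated counts
#' (binomial) for one genotype on one parental reference. The observed
#' methylation probability folds in bisulfite conversion failure:
#' `p_obs = m + (1 - m) * (1 - conversion_rate)` — an unmethylated C is
#' read as C with probability `1 - conversion_rate`. Hybrid reports apply
#' the spiked-DMR shifts of the truth object. Positions drawing zero
#' coverage are absent from the report.
#'
#' @param truth A [methylation_truth()] object.
#' @param contexts Context map of the reference genome
#'   ([assign_contexts()]).
#' @param genotype One of `"almond"`, `"peach"`, `"hybrid"`.
#' @param config The [sim_config()].
#' @param seed Seed for this draw; two draws with different seeds from one
#'   truth are independent samples of the same generative methylome.
#' @return Cytosine-report tibble: `chrom`, `pos`, `strand`, `count_meth`,
#'   `count_unmeth`, `context`, `trinucleotide`.
#' @export
simulate_report <- function(truth, contexts,
                            genotype = c("almond", "peach", "hybrid"),
                            config, seed) {
  genotype <- match.arg(genotype)
  set.seed(as.integer(seed))
  lev_col <- paste0("level_", genotype)

  pos_level <- rep(NA_real_, nrow(contexts))
  for (ch in unique(contexts$chrom)) {
    ci <- which(contexts$chrom == ch)
    for (ctx in c("CG", "CHG", "CHH")) {
      blk <- filter(truth$levels, .data$chrom == ch, .data$context == ctx) %>%
        arrange(.data$start)
      sel <- ci[contexts$context[ci] == ctx]
      if (!length(sel) || !nrow(blk)) next
      bi <- findInterval(contexts$pos[sel], blk$start)
      bi[bi < 1L] <- 1L
      pos_level[sel] <- blk[[lev_col]][bi]
    }
  }

  if (genotype == "hybrid" && nrow(truth$spiked_dmrs)) {
    sp <- truth$spiked_dmrs
    for (k in seq_len(nrow(sp))) {
      hit <- contexts$chrom == sp$chrom[k] & contexts$pos >= sp$start[k] &
        contexts$pos <= sp$end[k] & contexts$context == sp$context[k]
      shift <- if (sp$direction[k] == "hybrid_up") sp$delta[k] else -sp$delta[k]
      pos_level[hit] <- pmin(0.99, pmax(0.01, pos_level[hit] + shift))
    }
  }

  p_obs <- pos_level + (1 - pos_level) * (1 - config$conversion_rate)
  cov <- rpois(nrow(contexts), config$mean_coverage)
  meth <- rbinom(nrow(contexts), cov, p_obs)
  out <- contexts %>%
    mutate(count_meth = meth, count_unmeth = cov - meth) %>%
    filter(.data$count_meth + .data$count_unmeth > 0L) %>%
    select("chrom", "pos", "strand", "count_meth", "count_unmeth",
           "context", "trinucleotide")
  out
}

#' Simulate bisulfite methylomes for the hybrid trio
#'
#' Produces the standard four cytosine reports of the study design: each
#' parent on its own reference, and the hybrid on *both* parental
#' references (its reads map to either subgenome; the simulator emits the
#' 50:50 allelic mixture directly on each coordinate system, bypassing
#' alignment). All reports include the shared chloroplast contig with true
#' methylation 0, which anchors conversion-rate estimation.
#'
#' @param sim A [simulate_genome_pair()] result.
#' @param config The [sim_config()].
#' @return List of class `sim_methylomes`: `reports` (nested list,
#'   `reports[[reference]][[genotype]]`), `contexts` (per-reference context
#'   maps), `truth` (the [methylation_truth()] object).
#' @examples
#' cfg <- sim_config(seed = 1, genome_length = 2e4, n_te_per_class = 2,
#'                   n_genes = 3, chloroplast_length = 2000,
#'                   n_spiked_dmrs = 2)
#' sim <- simulate_genome_pair(cfg)
#' meth <- simulate_methylomes(sim, cfg)
#' names(meth$reports$almond)
#' @export
simulate_methylomes <- function(sim, config) {
  truth <- methylation_truth(sim, config)
  ctx <- list(almond = assign_contexts(sim$genomes$almond),
              peach = assign_contexts(sim$genomes$peach))
  s0 <- stage_seed(config$seed, "methylome")
  reports <- list(
    almond = list(
      almond = simulate_report(truth, ctx$almond, "almond", config, s0 + 1L),
      hybrid = simulate_report(truth, ctx$almond, "hybrid", config, s0 + 3L)),
    peach = list(
      peach = simulate_report(truth, ctx$peach, "peach", config, s0 + 2L),
      hybrid = simulate_report(truth, ctx$peach, "hybrid", config, s0 + 4L))
  )
  structure(list(reports = reports, contexts = ctx, truth = truth),
            class = "sim_methylomes")
}
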