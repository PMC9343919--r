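#' Simulation configuration
#'
#' Builds the parameter set for the synthetic hybrid-trio generator. The
#' defaults describe the study system the package targets: two parental
#' genomes diverged by about 20 substitutions per kilobase, TE copies of the
#' four major classes (LTR retrotransposon, LINE, MITE, TIR) grouped into
#' families, feature-level methylation centred near 90% (CG), 60% (CHG) and
#' 15% (CHH), an unmethylated chloroplast contig, ~98% bisulfite conversion,
#' ~20x per-position coverage, and negative-binomial RNA-seq counts over
#' three genotypes (A = almond-like parent, P = peach-like parent,
#' H = their F1 hybrid) with three replicates each.
#'
#' @param seed Integer seed; every stochastic output of the generator is a
#'   deterministic function of it.
#' @param genome_length Nuclear chromosome length in bp.
#' @param divergence Expected pairwise substitutions/site between the two
#'   parents (0.02 = 20 SNPs/kb). Must lie in \[0, 0.2\].
#' @param n_te_per_class TE copies simulated per class.
#' @param n_families Total number of TE families across the four classes.
#' @param n_genes Number of genes.
#' @param chloroplast_length Chloroplast contig length in bp; its true
#'   methylation is zero in every context.
#' @param mean_coverage Mean reads per cytosine position (Poisson).
#' @param conversion_rate Probability that an unmethylated cytosine is read
#'   as T after bisulfite treatment.
#' @param context_means Named numeric, mean true methylation per context.
#' @param context_concentration Named numeric, beta-distribution
#'   concentration (shape1 + shape2) per context; larger = tighter spread
#'   of feature-level methylation around the context mean.
#' @param n_spiked_dmrs Number of differentially methylated regions spiked
#'   into the hybrid methylome.
#' @param spike_delta Methylation-proportion shift of each spiked DMR.
#' @param spike_length Spike length in bp (aligned to the 50-bp DMR grid).
#' @param spike_spacing Minimum bp between spiked DMRs.
#' @param nb_dispersion Negative-binomial dispersion alpha for RNA-seq
#'   counts (var = mu + alpha mu^2).
#' @param pattern_mix Named fractions of features assigned to each coarse
#'   expression-pattern class; must sum to 1.
#' @param lfc_effect log2 effect size separating genotypes in non-equal
#'   patterns.
#' @param replicates RNA-seq replicates per genotype (>= 2).
#' @param te_length_means Named mean TE lengths (bp) per class.
#' @param gene_length_range Min/max gene length in bp.
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1, genome_length = 5e4)
#' cfg$divergence
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 1.5e5,
                       divergence = 0.02,
                       n_te_per_class = 12L,
                       n_families = 16L,
                       n_genes = 25L,
                       chloroplast_length = 15000L,
                       mean_coverage = 20,
                       conversion_rate = 0.98,
                       context_means = c(CG = 0.90, CHG = 0.60, CHH = 0.15),
                       context_concentration = c(CG = 20, CHG = 12, CHH = 30),
                       n_spiked_dmrs = 12L,
                       spike_delta = 0.40,
                       spike_length = 300L,
                       spike_spacing = 1000L,
                       nb_dispersion = 0.05,
                       pattern_mix = c(equal = 0.783, peach_up = 0.107,
                                       almond_up = 0.100, hybrid_up = 0.007,
                                       hybrid_down = 0.003),
                       lfc_effect = 2,
                       replicates = 3L,
                       te_length_means = c(ltr_retrotransposon = 2000,
                                           line = 1500, mite = 300, tir = 800),
                       gene_length_range = c(900, 2400)) {
  cfg <- list(
    seed = as.integer(seed), genome_length = as.integer(genome_length),
    divergence = divergence, n_te_per_class = as.integer(n_te_per_class),
    n_families = as.integer(n_families), n_genes = as.integer(n_genes),
    chloroplast_length = as.integer(chloroplast_length),
    mean_coverage = mean_coverage, conversion_rate = conversion_rate,
    context_means = context_means,
    context_concentration = context_concentration,
    n_spiked_dmrs = as.integer(n_spiked_dmrs), spike_delta = spike_delta,
    spike_length = as.integer(spike_length),
    spike_spacing = as.integer(spike_spacing),
    nb_dispersion = nb_dispersion, pattern_mix = pattern_mix,
    lfc_effect = lfc_effect, replicates = as.integer(replicates),
    te_length_means = te_length_means,
    gene_length_range = gene_length_range
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$seed) == 1L, is.finite(cfg$seed))
  probs <- c(cfg$conversion_rate, cfg$context_means, cfg$pattern_mix,
             cfg$spike_delta)
  if (any(probs < 0 | probs > 1)) {
    abort("all probabilities in a sim_config must lie in [0, 1]")
  }
  if (cfg$divergence < 0 || cfg$divergence > 0.2) {
    abort("divergence must lie in [0, 0.2]")
  }
  if (cfg$replicates < 2L) abort("at least 2 replicates per genotype required")
  if (abs(sum(cfg$pattern_mix) - 1) > 1e-8) {
    abort("pattern_mix fractions must sum to 1")
  }
  required <- c("CG", "CHG", "CHH")
  if (!all(required %in% names(cfg$context_means)) ||
      !all(required %in% names(cfg$context_concentration))) {
    abort("context_means and context_concentration need CG, CHG and CHH entries")
  }
  if (!all(c("equal", "peach_up", "almond_up", "hybrid_up", "hybrid_down")
           %in% names(cfg$pattern_mix))) {
    abort("pattern_mix must name the five coarse classes")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  seed:", x$seed, " genome:", x$genome_length, "bp  divergence:",
      x$divergence, "\n")
  cat("  coverage:", x$mean_coverage, " conversion:", x$conversion_rate, "\n")
  cat("  context means:",
      paste(names(x$context_means), round(x$context_means, 2),
            sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' DMR-calling parameters
#'
#' Parameters of the windowed differential-methylation procedure: the genome
#' is cut into fixed non-overlapping windows, each window is tested with a
#' two-sided Fisher's exact test on pooled methylated/unmethylated counts,
#' p-values are Benjamini-Hochberg adjusted per context, and windows failing
#' any of three filters (too few context cytosines, too small a methylation
#' difference, too few reads) are discarded before multiple testing.
#' Significant same-direction windows closer than `join_distance` are merged
#' into DMRs.
#'
#' @param window,step Window size and step in bp (equal by default:
#'   adjacent non-overlapping tiles).
#' @param min_cytosines Minimum cytosines of the tested context with data in
#'   both conditions (windows with fewer are discarded).
#' @param min_diff Minimum absolute methylation-proportion difference.
#' @param min_avg_reads Minimum average reads per cytosine (mean of the two
#'   conditions) in the window.
#' @param fdr Benjamini-Hochberg q-value cutoff for candidate windows.
#' @param join_distance Bins separated by less than this many bp are joined.
#' @return A list of class `dmr_params`.
#' @examples
#' dmr_params(fdr = 0.01)
#' @export
dmr_params <- function(window = 50L, step = 50L, min_cytosines = 3L,
                       min_diff = 0.25, min_avg_reads = 8, fdr = 0.05,
                       join_distance = 300L) {
  if (!(window >= step && step > 0)) abort("need window >= step > 0")
  if (min_cytosines < 0 || min_diff < 0 || min_avg_reads < 0 ||
      join_distance < 0) {
    abort("thresholds must be non-negative")
  }
  structure(list(window = as.integer(window), step = as.integer(step),
                 min_cytosines = as.integer(min_cytosines),
                 min_diff = min_diff, min_avg_reads = min_avg_reads,
                 fdr = fdr, join_distance = as.integer(join_distance)),
            class = "dmr_params")
}

#' @export
print.dmr_params <- function(x, ...) {
  cat("<dmr_params> window", x$window, "bp, >=", x$min_cytosines,
      "cytosines, diff >=", x$min_diff, ", reads >=", x$min_avg_reads,
      ", q <", x$fdr, ", join <", x$join_distance, "bp\n")
  invisible(x)
}

# deterministic child seed for a named stage, kept within 32-bit range
stage_seed <- function(seed, stage) {
  offsets <- c(genome = 101L, methylome = 211L, counts = 307L, qpcr = 401L,
               report = 503L)
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[stage]]
}
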