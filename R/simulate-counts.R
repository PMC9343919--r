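#' Simulate an RNA-seq count matrix with known expression patterns
#'
#' Features are the simulated genes plus one representative per TE family.
#' Each feature is assigned a coarse expression-pattern class from
#' `pattern_mix`; genotype means encode the class at `lfc_effect` log2
#' units (for parent-up classes the hybrid is, with equal probability,
#' intermediate or equal to either parent — the configurations the study
#' design distinguishes). Counts are negative binomial,
#' `NB(mean = s_j * mu, var = mu + alpha mu^2)`, with per-sample size
#' factors drawn around 1.
#'
#' @param features Feature tibble from [simulate_genome_pair()].
#' @param config The [sim_config()].
#' @return List of class `sim_counts`: `counts` (tibble, `feature` +
#'   one column per sample), `design` (tibble: sample, genotype in
#'   A/P/H, replicate), `truth` (tibble: feature, coarse_class,
#'   fine_intent, mu_A, mu_P, mu_H), `size_factors` (tibble).
#' @examples
#' cfg <- sim_config(seed = 1, genome_length = 3e4, n_te_per_class = 3,
#'                   n_genes = 10, chloroplast_length = 2000)
#' sc <- simulate_counts(simulate_genome_pair(cfg)$features, cfg)
#' head(sc$counts)
#' @export
simulate_counts <- function(features, config) {
  set.seed(stage_seed(config$seed, "counts"))
  fams <- sort(unique(features$family[!is.na(features$family)]))
  ids <- c(sort(unique(features$id[features$kind == "gene"])), fams)
  nf <- length(ids)

  cls <- sample(names(config$pattern_mix), nf, replace = TRUE,
                prob = config$pattern_mix)
  base <- rlnorm(nf, log(100), 1)
  eff <- 2 ^ config$lfc_effect
  half <- 2 ^ (config$lfc_effect / 2)
  h_mode <- sample(c("mid", "low_parent", "high_parent"), nf, replace = TRUE)

  mu_A <- base
  mu_P <- base
  mu_H <- base
  up <- cls == "peach_up"
  mu_P[up] <- base[up] * eff
  mu_H[up] <- base[up] * c(mid = half, low_parent = 1, high_parent = eff)[h_mode[up]]
  dn <- cls == "almond_up"
  mu_A[dn] <- base[dn] * eff
  mu_H[dn] <- base[dn] * c(mid = half, low_parent = 1, high_parent = eff)[h_mode[dn]]
  mu_H[cls == "hybrid_up"] <- base[cls == "hybrid_up"] * eff
  mu_H[cls == "hybrid_down"] <- base[cls == "hybrid_down"] / eff

  genotypes <- c("A", "P", "H")
  design <- crossing(genotype = factor(genotypes, levels = genotypes),
                     replicate = seq_len(config$replicates)) %>%
    mutate(genotype = as.character(.data$genotype),
           sample = paste0(.data$genotype, "_", .data$replicate)) %>%
    select("sample", "genotype", "replicate")
  sf <- exp(rnorm(nrow(design), 0, 0.1))
  names(sf) <- design$sample

  mu <- cbind(A = mu_A, P = mu_P, H = mu_H)
  counts <- vapply(seq_len(nrow(design)), function(j) {
    m <- mu[, design$genotype[j]] * sf[j]
    as.numeric(rnbinom(nf, mu = m, size = 1 / config$nb_dispersion))
  }, numeric(nf))
  storage.mode(counts) <- "integer"
  colnames(counts) <- design$sample

  # the truth is what the means actually encode (with lfc_effect = 0 every
  # pattern collapses to "equal")
  cls <- case_when(
    mu_H > pmax(mu_A, mu_P) ~ "hybrid_up",
    mu_H < pmin(mu_A, mu_P) ~ "hybrid_down",
    mu_P > mu_A ~ "peach_up",
    mu_A > mu_P ~ "almond_up",
    .default = "equal")
  fine_intent <- case_when(
    cls == "equal" ~ "A=H=P",
    cls == "hybrid_up" ~ "(A=P)<H",
    cls == "hybrid_down" ~ "(A=P)>H",
    cls == "peach_up" & h_mode == "mid" ~ "A<H<P",
    cls == "peach_up" & h_mode == "low_parent" ~ "(A=H)<P",
    cls == "peach_up" & h_mode == "high_parent" ~ "A<(H=P)",
    cls == "almond_up" & h_mode == "mid" ~ "A>H>P",
    cls == "almond_up" & h_mode == "low_parent" ~ "A>(H=P)",
    .default = "(A=H)>P")

  structure(list(
    counts = bind_cols(tibble(feature = ids), as_tibble(counts)),
    design = design,
    truth = tibble(feature = ids, coarse_class = cls,
                   fine_intent = fine_intent,
                   mu_A = mu_A, mu_P = mu_P, mu_H = mu_H),
    size_factors = tibble(sample = design$sample, size_factor = sf)),
    class = "sim_counts")
}

#' Simulate a qPCR Ct table from known expression levels
#'
#' Cycle thresholds follow the standard amplification model
#' `Ct = intercept - log2(expression) + noise`; reference genes share one
#' expression level across genotypes, so downstream ddCt quantification
#' against them recovers the target fold changes.
#'
#' @param expression Tibble with columns `gene`, `genotype`, `expression`
#'   (> 0). Must include the reference genes at a genotype-constant level.
#' @param config The [sim_config()] (supplies seed and replicate number).
#' @param noise_sd Gaussian Ct noise per well (cycles).
#' @param intercept Ct of a notional 1-unit template.
#' @return Ct tibble: `sample`, `genotype`, `replicate`, `gene`, `ct`.
#' @examples
#' expr <- tibble::tibble(gene = rep(c("TEF2", "RPII", "LTR_9"), each = 3),
#'                        genotype = rep(c("A", "P", "H"), 3),
#'                        expression = c(1, 1, 1, 1, 1, 1, 2, 8, 4))
#' simulate_qpcr(expr, sim_config(seed = 2), noise_sd = 0)
#' @export
simulate_qpcr <- function(expression, config, noise_sd = 0.2,
                          intercept = 28) {
  if (any(expression$expression <= 0)) {
    abort("qPCR simulation requires strictly positive expression levels")
  }
  set.seed(stage_seed(config$seed, "qpcr"))
  expand_grid(expression, replicate = seq_len(config$replicates)) %>%
    mutate(sample = paste0(.data$genotype, "_", .data$replicate),
           ct = intercept - log2(.data$expression) +
             rnorm(n(), 0, noise_sd)) %>%
    select("sample", "genotype", "replicate", "gene", "ct") %>%
    arrange(.data$sample, .data$gene)
}
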