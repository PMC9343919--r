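#' Simulate a diverged parental genome pair with annotated features
#'
#' Generates one ancestral nuclear chromosome, derives the two parental
#' genomes ("almond" and "peach") by independent lineage substitutions, and
#' places non-overlapping TE copies (four classes, grouped into families)
#' and intron-containing genes along it. A shared chloroplast contig is
#' appended to both genomes as the unmethylated conversion control.
#' Upstream regions (the 1000 bp upstream of each gene's ATG, truncated at
#' the contig edge) are derived from the gene coordinates.
#'
#' The per-lineage substitution probability `p` is solved from
#' `2p - (4/3)p^2 = divergence` so that the *expected pairwise* difference
#' per site equals `divergence` after accounting for sites hit in both
#' lineages. Substitutions only — both parents share one coordinate system.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_genomes` with elements
#'   `genomes` (named list of two [Biostrings::DNAStringSet] objects,
#'   `almond` and `peach`, each containing `chr1` and `chloroplast`),
#'   `features` (tibble: id, chrom, start, end, strand, kind, te_class,
#'   family), and `truth` (list with `snp_positions`, the per-lineage rate,
#'   and observed SNP density per kb).
#' @examples
#' sim <- simulate_genome_pair(sim_config(seed = 1, genome_length = 3e4,
#'                                        n_te_per_class = 3, n_genes = 5,
#'                                        chloroplast_length = 2000))
#' sim$truth$snp_per_kb
#' @export
simulate_genome_pair <- function(config) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, "genome"))
  L <- config$genome_length
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, L, replace = TRUE)
  cp <- sample(bases, config$chloroplast_length, replace = TRUE)

  # per-lineage rate so expected pairwise divergence matches the config
  d <- config$divergence
  p <- if (d == 0) 0 else (2 - sqrt(4 - 16 * d / 3)) * 3 / 8
  mutate_lineage <- function(x) {
    idx <- which(runif(length(x)) < p)
    if (length(idx)) {
      x[idx] <- vapply(x[idx], function(b) sample(setdiff(bases, b), 1L), "")
    }
    list(seq = x, sites = idx)
  }
  la <- mutate_lineage(anc)
  lp <- mutate_lineage(anc)
  diff_pos <- which(la$seq != lp$seq)

  features <- place_features(config)

  genomes <- list(
    almond = Biostrings::DNAStringSet(c(
      chr1 = paste(la$seq, collapse = ""),
      chloroplast = paste(cp, collapse = ""))),
    peach = Biostrings::DNAStringSet(c(
      chr1 = paste(lp$seq, collapse = ""),
      chloroplast = paste(cp, collapse = "")))
  )

  truth <- list(
    snp_positions = tibble(chrom = "chr1", pos = diff_pos,
                           almond = la$seq[diff_pos],
                           peach = lp$seq[diff_pos]),
    per_lineage_rate = p,
    snp_per_kb = 1000 * length(diff_pos) / L
  )
  structure(list(genomes = genomes, features = features, truth = truth),
            class = "sim_genomes")
}

# non-overlapping placement of TEs and genes by stick-breaking the free space
place_features <- function(config) {
  classes <- names(config$te_length_means)
  te_len <- unlist(lapply(classes, function(cl) {
    m <- config$te_length_means[[cl]]
    pmax(100L, as.integer(round(rlnorm(config$n_te_per_class,
                                       log(m), 0.25))))
  }))
  te_class <- rep(classes, each = config$n_te_per_class)
  gene_len <- as.integer(round(runif(config$n_genes,
                                     config$gene_length_range[1],
                                     config$gene_length_range[2])))
  lens <- c(te_len, gene_len)
  kind <- c(rep("te", length(te_len)), rep("gene", length(gene_len)))

  total <- sum(lens)
  free <- config$genome_length - total
  if (free < 0.05 * config$genome_length) {
    abort(sprintf(
      "genome too small to place requested features: need >= %d bp, have %d",
      as.integer(ceiling(total / 0.95)), config$genome_length))
  }

  ord <- sample.int(length(lens))
  lens <- lens[ord]; kind <- kind[ord]; te_class <- c(te_class, rep(NA, length(gene_len)))[ord]
  n <- length(lens)
  gaps <- as.vector(stats::rmultinom(1, free, rep(1, n + 1L)))
  starts <- cumsum(gaps[seq_len(n)] + c(0L, lens[-n])) + 1L
  ends <- starts + lens - 1L

  # family labels per class, sizes skewed like a truncated geometric
  fam_per_class <- max(1L, round(config$n_families / length(classes)))
  fam_of <- integer(n)
  for (cl in classes) {
    i <- which(!is.na(te_class) & te_class == cl)
    w <- 0.6 ^ (seq_len(fam_per_class) - 1L)
    fam_of[i] <- sample.int(fam_per_class, length(i), replace = TRUE,
                            prob = w / sum(w))
  }
  fam_prefix <- c(ltr_retrotransposon = "LTR", line = "LINE", mite = "MITE",
                  tir = "TIR")[te_class]
  family <- ifelse(kind == "te", paste0(fam_prefix, "_", fam_of), NA)

  strand <- sample(c("+", "-"), n, replace = TRUE)
  te_i <- cumsum(kind == "te"); gene_i <- cumsum(kind == "gene")
  id <- ifelse(kind == "te", paste0(family, "_c", te_i),
               sprintf("gene_%03d", gene_i))

  feats <- tibble(id = id, chrom = "chr1", start = starts, end = ends,
                  strand = strand, kind = kind, te_class = te_class,
                  family = family)
  bind_rows(feats, upstream_regions(feats, config$genome_length))
}

#' Derive upstream regions from gene features
#'
#' Upstream regions are exactly 1000 bp ending at the base before the ATG
#' (i.e. before `start` for + genes, after `end` for - genes), truncated at
#' the contig edge.
#'
#' @param features Feature tibble containing `kind == "gene"` rows.
#' @param chrom_length Contig length used for truncation.
#' @param width Upstream width in bp.
#' @return Tibble of `kind == "upstream"` features (`id` = gene id +
#'   `"_up"`).
#' @export
upstream_regions <- function(features, chrom_length, width = 1000L) {
  genes <- filter(features, .data$kind == "gene")
  if (nrow(genes) == 0L) return(genes)
  up_start <- ifelse(genes$strand == "+", genes$start - width, genes$end + 1L)
  up_end <- ifelse(genes$strand == "+", genes$start - 1L, genes$end + width)
  tibble(id = paste0(genes$id, "_up"), chrom = genes$chrom,
         start = pmax(1L, as.integer(up_start)),
         end = pmin(as.integer(chrom_length), as.integer(up_end)),
         strand = genes$strand, kind = "upstream",
         te_class = NA_character_, family = NA_character_) %>%
    filter(.data$start <= .data$end)
}
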