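# Shared small-simulation fixtures and independent oracles.

tiny_cfg <- sim_config(seed = 42L, genome_length = 5e4, n_te_per_class = 3,
                       n_genes = 8, chloroplast_length = 4000,
                       n_spiked_dmrs = 3)
tiny_sim <- simulate_genome_pair(tiny_cfg)
tiny_meth <- simulate_methylomes(tiny_sim, tiny_cfg)

# context of a trinucleotide read 5'->3' on the cytosine's own strand
oracle_context <- function(tri) {
  b <- strsplit(tri, "")[[1]]
  if (b[1] != "C") return(NA_character_)
  if (length(b) >= 2 && b[2] == "G") return("CG")
  if (length(b) >= 3 && b[3] == "G") return("CHG")
  "CHH"
}

revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# classic Benjamini-Hochberg step-up rejection set, computed from scratch
oracle_bh_reject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  k <- max(c(0L, which(p[o] <= alpha * seq_len(m) / m)))
  rejected <- rep(FALSE, m)
  if (k > 0L) rejected[o[seq_len(k)]] <- TRUE
  rejected
}

# normal-approximation rank-sum p-value with continuity correction,
# derived from first principles
oracle_ranksum_p <- function(x, y) {
  r <- rank(c(x, y))
  n1 <- length(x); n2 <- length(y)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  sig2 <- n1 * n2 / 12 *
    ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sig2)
  2 * stats::pnorm(-abs(z))
}

# build an nb_de-shaped tibble directly from relation codes, for driving
# classify_pattern through all triads
de_from_rel <- function(feature, rel) {
  tibble::tibble(feature = feature,
                 significant = rel != "=",
                 log2fc = ifelse(rel == "<", 2, ifelse(rel == ">", -2, 0)))
}
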