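#' Median-of-ratios normalization of a count matrix
#'
#' Size factors are the per-sample median of count ratios to the
#' geometric-mean reference feature, computed over features positive in
#' all samples. If no feature is positive everywhere, total-count scaling
#' (relative library size) is used instead, with a message.
#'
#' @param counts Tibble with a `feature` column and one integer column per
#'   sample.
#' @return List of class `norm_counts`: `size_factors` (tibble: sample,
#'   size_factor), `normalized` (counts / size factor), `log2` (log2 of
#'   normalized + 1).
#' @examples
#' m <- tibble::tibble(feature = c("g1", "g2"), s1 = c(10L, 20L),
#'                     s2 = c(20L, 40L))
#' normalize_counts(m)$size_factors
#' @export
normalize_counts <- function(counts) {
  mat <- as.matrix(counts[, setdiff(names(counts), "feature")])
  rownames(mat) <- counts$feature
  pos <- rowSums(mat > 0) == ncol(mat)
  if (any(pos)) {
    logref <- rowMeans(log(mat[pos, , drop = FALSE]))
    sf <- apply(mat[pos, , drop = FALSE], 2,
                function(col) exp(median(log(col) - logref)))
  } else {
    inform("no feature positive in all samples; using total-count scaling")
    tot <- colSums(mat)
    sf <- tot / exp(mean(log(tot)))
  }
  norm <- sweep(mat, 2, sf, "/")
  structure(list(
    size_factors = tibble(sample = colnames(mat), size_factor = unname(sf)),
    normalized = bind_cols(tibble(feature = counts$feature),
                           as_tibble(norm)),
    log2 = bind_cols(tibble(feature = counts$feature),
                     as_tibble(log2(norm + 1)))),
    class = "norm_counts")
}

#' Pairwise negative-binomial differential expression test
#'
#' A compact NB differential test between two genotypes: median-of-ratios
#' size factors (computed over all supplied samples), per-feature
#' method-of-moments dispersion shrunk on the log scale toward a fitted
#' `a0 + a1/mu` mean-dispersion trend, and a Wald-type test of the log2
#' fold change with a moderated t reference distribution (residual plus
#' prior degrees of freedom, guarding the small replicate numbers typical
#' of these designs). BH correction across tested features; a feature is
#' `significant` only if `q < fdr` *and* `|log2fc| >= lfc_threshold`
#' (log-fold-change cutoff of one by default). All-zero features are
#' reported untested (`p = NA`).
#'
#' @param counts Count tibble (`feature` + sample columns).
#' @param design Tibble mapping `sample` to `genotype`.
#' @param genotype_a,genotype_b The two genotype labels to compare;
#'   `log2fc` is `log2(b / a)`.
#' @param fdr q-value cutoff.
#' @param lfc_threshold Absolute log2 fold-change cutoff.
#' @param size_factors Optional precomputed size-factor tibble.
#' @return Tibble of class `nb_de`: `feature`, `contrast`, `base_mean`,
#'   `log2fc`, `se`, `stat`, `p`, `q`, `significant`.
#' @export
nb_pairwise_test <- function(counts, design, genotype_a, genotype_b,
                             fdr = 0.05, lfc_threshold = 1,
                             size_factors = NULL) {
  if (is.null(size_factors)) size_factors <- normalize_counts(counts)$size_factors
  sa <- design$sample[design$genotype == genotype_a]
  sb <- design$sample[design$genotype == genotype_b]
  if (length(sa) < 2L || length(sb) < 2L) {
    abort("need at least 2 replicates per genotype")
  }
  sf <- setNames(size_factors$size_factor, size_factors$sample)
  na_ <- length(sa); nb_ <- length(sb)
  ka <- as.matrix(counts[, sa]) ; kb <- as.matrix(counts[, sb])
  xa <- sweep(ka, 2, sf[sa], "/"); xb <- sweep(kb, 2, sf[sb], "/")

  mu_a <- rowMeans(xa); mu_b <- rowMeans(xb)
  va <- apply(xa, 1, var); vb <- apply(xb, 1, var)
  tested <- rowSums(ka) + rowSums(kb) > 0

  # method-of-moments dispersion pooled over the two groups
  alpha_of <- function(v, mu) ifelse(mu > 0, pmax((v - mu) / mu^2, 0), 0)
  alpha_mom <- (alpha_of(va, mu_a) * (na_ - 1) +
                  alpha_of(vb, mu_b) * (nb_ - 1)) / (na_ + nb_ - 2)
  mu0 <- (mu_a + mu_b) / 2
  trend <- fit_dispersion_trend(alpha_mom[tested], mu0[tested])
  alpha_tr <- pmax(trend$a0 + trend$a1 / pmax(mu0, 0.5), 1e-6)
  alpha <- exp(0.5 * log(pmax(alpha_mom, 1e-8)) + 0.5 * log(alpha_tr))
  alpha <- pmin(pmax(alpha, 1e-8), 5)

  eps <- 0.5
  log2fc <- log2((mu_b + eps) / (mu_a + eps))
  v_lfc <- ((mu_a + alpha * mu_a^2) / na_ / (mu_a + eps)^2 +
              (mu_b + alpha * mu_b^2) / nb_ / (mu_b + eps)^2) / log(2)^2
  se <- sqrt(pmax(v_lfc, 1e-12))
  stat <- log2fc / se
  # moderated reference df: residual df plus prior df reflecting the
  # information borrowed through the dispersion-trend shrinkage
  prior_df <- 2L
  p <- 2 * pt(-abs(stat), df = na_ + nb_ - 2L + prior_df)
  p[!tested] <- NA_real_
  q <- rep(NA_real_, length(p))
  q[tested] <- p.adjust(p[tested], method = "BH")

  out <- tibble(feature = counts$feature,
                contrast = paste0(genotype_a, "-vs-", genotype_b),
                base_mean = mu0, log2fc = log2fc, se = se, stat = stat,
                p = p, q = q,
                significant = !is.na(q) & q < fdr &
                  abs(log2fc) >= lfc_threshold)
  attr(out, "fdr") <- fdr
  attr(out, "lfc_threshold") <- lfc_threshold
  attr(out, "dispersion_trend") <- trend
  class(out) <- c("nb_de", class(out))
  out
}

# robust a0 + a1/mu fit to method-of-moments dispersions
fit_dispersion_trend <- function(alpha_mom, mu) {
  ok <- is.finite(alpha_mom) & is.finite(mu) & mu > 0
  alpha_mom <- alpha_mom[ok]; mu <- mu[ok]
  if (length(mu) < 10L) {
    return(list(a0 = max(median(alpha_mom), 0.01), a1 = 0))
  }
  hi <- mu >= quantile(mu, 2 / 3)
  a0 <- max(median(alpha_mom[hi]), 1e-4)
  a1 <- max(median((alpha_mom - a0) * mu), 0)
  list(a0 = a0, a1 = a1)
}

#' Select the representative genomic copy of each TE family
#'
#' Given per-copy alignment coverage of each family's assembled contig,
#' picks the highest-coverage copy passing the kind-specific length
#' cutoff: 80% for retrotransposons, 40% for DNA transposons. Families
#' with no copy passing are dropped (with a message).
#'
#' @param coverage_table Tibble: `family`, `copy`, `te_kind`
#'   (`"retrotransposon"` or `"dna_transposon"`), `coverage` in \[0, 1\],
#'   optionally `contig`.
#' @param cutoffs Named coverage cutoffs per kind.
#' @return Tibble with one row per represented family.
#' @export
select_family_representative <- function(coverage_table,
                                         cutoffs = c(retrotransposon = 0.80,
                                                     dna_transposon = 0.40)) {
  if (nrow(coverage_table) == 0L) {
    inform("empty coverage table: no representatives selected")
    return(coverage_table)
  }
  stopifnot(all(coverage_table$coverage >= 0 & coverage_table$coverage <= 1),
            all(coverage_table$te_kind %in% names(cutoffs)))
  passed <- filter(coverage_table,
                   .data$coverage >= cutoffs[.data$te_kind])
  dropped <- setdiff(unique(coverage_table$family), unique(passed$family))
  if (length(dropped)) {
    inform(sprintf("%d families had no copy passing the coverage cutoff",
                   length(dropped)))
  }
  passed %>%
    group_by(.data$family) %>%
    arrange(dplyr::desc(.data$coverage), .data$copy, .by_group = TRUE) %>%
    dplyr::slice(1L) %>%
    ungroup()
}

#' Cross-reference correlation of ortholog expression profiles
#'
#' Pearson correlation of per-feature mean log2-normalized expression
#' between analyses run against two different reference annotations,
#' restricted to ortholog pairs.
#'
#' @param expr_a,expr_b Log2-expression tibbles (`feature` + numeric
#'   sample columns), one per reference.
#' @param pairs Tibble of ortholog pairs: `feature_a`, `feature_b`.
#' @return One-row tibble: `r`, `n_pairs`.
#' @export
ortholog_correlation <- function(expr_a, expr_b, pairs) {
  mean_of <- function(x) {
    num <- x[, vapply(x, is.numeric, TRUE)]
    tibble(feature = x$feature, mean_expr = rowMeans(num))
  }
  joined <- pairs %>%
    inner_join(mean_of(expr_a), by = c(feature_a = "feature")) %>%
    inner_join(mean_of(expr_b), by = c(feature_b = "feature"),
               suffix = c("_a", "_b"))
  if (nrow(joined) < 3L) {
    abort("ortholog correlation needs at least 3 matched pairs")
  }
  tibble(r = cor(joined$mean_expr_a, joined$mean_expr_b),
         n_pairs = nrow(joined))
}
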