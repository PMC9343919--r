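#' Relative qPCR quantification by the 2^-ddCt method
#'
#' For each sample, the target Ct is normalized to the mean Ct of the
#' reference genes (`dCt = Ct_target - mean(Ct_refs)`); per genotype, the
#' mean dCt is referenced to the calibrator genotype
#' (`ddCt = mean dCt(genotype) - mean dCt(calibrator)`) and the relative
#' expression level is `2^-ddCt`. The replicate SD of dCt is propagated
#' into a `rel_lo`/`rel_hi` range (`2^-(ddCt +/- sd)`). Adding a constant
#' to every Ct (a plate offset) leaves all results unchanged.
#'
#' @param ct Ct tibble: `sample`, `genotype`, `gene`, `ct` (one row per
#'   well; technical replicates may repeat rows).
#' @param reference_genes Internal-control gene names (e.g. the
#'   translation elongation factor TEF2 and RNA polymerase II RPII
#'   homologues); every sample must have a Ct for each.
#' @param calibrator Genotype used as the 1x baseline.
#' @return Tibble: `gene`, `genotype`, `n`, `dct_mean`, `dct_sd`, `ddct`,
#'   `rel_expr`, `rel_lo`, `rel_hi`.
#' @examples
#' ct <- tibble::tibble(sample = rep(c("A_1", "A_2"), each = 2),
#'                      genotype = "A",
#'                      gene = rep(c("TEF2", "tgt"), 2),
#'                      ct = c(20, 18, 20, 18))
#' ddct_quantify(ct, reference_genes = "TEF2", calibrator = "A")
#' @export
ddct_quantify <- function(ct, reference_genes = c("TEF2", "RPII"),
                          calibrator = "A") {
  refs <- filter(ct, .data$gene %in% reference_genes) %>%
    group_by(.data$sample) %>%
    summarise(ref_ct = mean(.data$ct), n_refs = n_distinct(.data$gene),
              .groups = "drop")
  bad <- union(setdiff(unique(ct$sample), refs$sample),
               refs$sample[refs$n_refs < length(reference_genes)])
  if (length(bad)) {
    abort(paste0("missing reference-gene Ct in sample(s): ",
                 paste(sort(bad), collapse = ", ")))
  }
  if (!calibrator %in% ct$genotype) {
    abort(sprintf("calibrator genotype '%s' absent from the Ct table",
                  calibrator))
  }
  dct <- ct %>%
    filter(!.data$gene %in% reference_genes) %>%
    inner_join(select(refs, "sample", "ref_ct"), by = "sample") %>%
    mutate(dct = .data$ct - .data$ref_ct) %>%
    group_by(.data$gene, .data$genotype) %>%
    summarise(n = n(), dct_mean = mean(.data$dct),
              dct_sd = ifelse(n() > 1L, sd(.data$dct), 0),
              .groups = "drop")
  cal <- dct %>%
    filter(.data$genotype == calibrator) %>%
    select("gene", cal_dct = "dct_mean")
  dct %>%
    inner_join(cal, by = "gene") %>%
    mutate(ddct = .data$dct_mean - .data$cal_dct,
           rel_expr = 2 ^ (-.data$ddct),
           rel_lo = 2 ^ (-(.data$ddct + .data$dct_sd)),
           rel_hi = 2 ^ (-(.data$ddct - .data$dct_sd))) %>%
    select(-"cal_dct") %>%
    arrange(.data$gene, .data$genotype)
}
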