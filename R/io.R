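#' Read and write Bismark-style cytosine reports
#'
#' Tab-separated, no header: chrom, 1-based position, strand, count
#' methylated, count unmethylated, context, trinucleotide. Gzipped files
#' are handled transparently.
#'
#' @param path File path.
#' @return `read_cytosine_report()` returns the report tibble.
#' @export
read_cytosine_report <- function(path) {
  readr::read_tsv(path,
                  col_names = c("chrom", "pos", "strand", "count_meth",
                                "count_unmeth", "context", "trinucleotide"),
                  col_types = "cicincc", progress = FALSE)
}

#' @rdname read_cytosine_report
#' @param report Cytosine-report tibble.
#' @export
write_cytosine_report <- function(report, path) {
  readr::write_tsv(report[, c("chrom", "pos", "strand", "count_meth",
                              "count_unmeth", "context", "trinucleotide")],
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read and write feature annotations as GFF3
#'
#' TE records carry `te_class` and `family` attributes; the feature kind
#' is stored in the GFF3 type column (`transposable_element`, `gene`,
#' `upstream_region`).
#'
#' @param features Feature tibble.
#' @param path File path.
#' @export
write_features_gff3 <- function(features, path) {
  type_of <- c(te = "transposable_element", gene = "gene",
               upstream = "upstream_region")
  gr <- GenomicRanges::GRanges(
    features$chrom,
    IRanges::IRanges(features$start, features$end),
    strand = features$strand)
  S4Vectors::mcols(gr)$type <- unname(type_of[features$kind])
  S4Vectors::mcols(gr)$ID <- features$id
  S4Vectors::mcols(gr)$te_class <- features$te_class
  S4Vectors::mcols(gr)$family <- features$family
  S4Vectors::mcols(gr)$source <- "hybridmeth"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_features_gff3
#' @export
read_features_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  kind_of <- c(transposable_element = "te", gene = "gene",
               upstream_region = "upstream")
  m <- S4Vectors::mcols(gr)
  tibble(id = as.character(m$ID),
         chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
         strand = as.character(GenomicRanges::strand(gr)),
         kind = unname(kind_of[as.character(m$type)]),
         te_class = if ("te_class" %in% names(m)) {
           as.character(m$te_class)
         } else NA_character_,
         family = if ("family" %in% names(m)) {
           as.character(m$family)
         } else NA_character_)
}

#' Export DMRs as BED6
#'
#' 0-based half-open coordinates; `name` = `context:direction`; `score` =
#' `-10 log10(min_q)` capped at 1000.
#'
#' @param dmrs A [call_dmrs()] result.
#' @param path Output path.
#' @export
write_dmrs_bed <- function(dmrs, path) {
  score <- pmin(round(-10 * log10(pmax(dmrs$min_q, 1e-100))), 1000)
  bed <- tibble(chrom = dmrs$chrom, start = dmrs$start - 1L,
                end = dmrs$end,
                name = paste0(dmrs$context, ":", dmrs$direction),
                score = score, strand = ".")
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a count matrix and its design sidecar
#'
#' The count matrix is TSV with a `feature` column and one column per
#' sample; the design TSV maps `sample` to `genotype` and `replicate`.
#'
#' @param counts_path,design_path File paths.
#' @return List with `counts` and `design` tibbles.
#' @export
read_count_matrix <- function(counts_path, design_path) {
  counts <- readr::read_tsv(counts_path, show_col_types = FALSE,
                            progress = FALSE)
  design <- readr::read_tsv(design_path, show_col_types = FALSE,
                            progress = FALSE)
  missing <- setdiff(design$sample, names(counts))
  if (length(missing)) {
    abort(paste0("samples in design absent from counts: ",
                 paste(missing, collapse = ", ")))
  }
  list(counts = counts, design = design)
}
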