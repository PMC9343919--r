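#' Assign CG/CHG/CHH context to every cytosine of a genome
#'
#' Labels each cytosine (C on the plus strand, G on the minus strand, read
#' as C 5'->3' on its own strand) with its plant methylation context from
#' the 3-base window starting at the cytosine: `CG` if the next base is G,
#' `CHG` if the base after next is G (the middle base is then necessarily
#' H = A/C/T, since CG was checked first), otherwise `CHH`. Windows
#' truncated at a contig end fall through the same cascade, so a terminal
#' `CG` is still called CG while an undecidable truncated window defaults
#' to CHH. Ambiguity codes (e.g. N) never match G/C and therefore also fall
#' through to CHH; a count of non-ACGT bases encountered is reported via a
#' message.
#'
#' @param genome A [Biostrings::DNAStringSet], a named character vector of
#'   sequences, or the path to a FASTA file.
#' @return Tibble with columns `chrom`, `pos` (1-based), `strand`,
#'   `context`, `trinucleotide` (read 5'->3' on the cytosine's strand,
#'   padded with N at contig ends).
#' @examples
#' assign_contexts(c(chrX = "CCGGAT"))
#' @export
assign_contexts <- function(genome) {
  seqs <- as_genome_charlist(genome)
  n_bad <- 0L
  out <- imap(seqs, function(s, nm) {
    x <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    n_bad <<- n_bad + sum(!x %in% c("A", "C", "G", "T", "N"))
    pad <- function(v) ifelse(is.na(v), "N", v)
    L <- length(x)
    ip <- which(x == "C")
    im <- which(x == "G")
    plus <- NULL
    if (length(ip)) {
      n1 <- pad(x[ip + 1L][seq_along(ip)])
      n2 <- if (L >= 3L) pad(c(x, NA, NA)[ip + 2L]) else rep("N", length(ip))
      ctx <- ifelse(n1 == "G", "CG", ifelse(n2 == "G", "CHG", "CHH"))
      plus <- tibble(chrom = nm, pos = ip, strand = "+", context = ctx,
                     trinucleotide = paste0("C", n1, n2))
    }
    minus <- NULL
    if (length(im)) {
      comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
      p1 <- ifelse(im >= 2L, x[pmax(im - 1L, 1L)], "N")
      p1 <- pad(p1)
      p2 <- ifelse(im >= 3L, x[pmax(im - 2L, 1L)], "N")
      p2 <- pad(p2)
      ctx <- ifelse(p1 == "C", "CG", ifelse(p2 == "C", "CHG", "CHH"))
      minus <- tibble(chrom = nm, pos = im, strand = "-", context = ctx,
                      trinucleotide = paste0("C", comp[p1], comp[p2]))
    }
    bind_rows(plus, minus)
  }) %>% bind_rows()
  if (n_bad > 0L) inform(sprintf("%d non-ACGTN bases skipped", n_bad))
  arrange(out, .data$chrom, .data$pos, .data$strand)
}

as_genome_charlist <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    setNames(as.character(genome), names(genome))
  } else if (is.character(genome) && length(genome) == 1L &&
             file.exists(genome)) {
    x <- Biostrings::readDNAStringSet(genome)
    names(x) <- sub("\\s.*$", "", names(x))
    setNames(as.character(x), names(x))
  } else if (is.character(genome)) {
    if (is.null(names(genome))) abort("genome sequences must be named")
    genome
  } else {
    abort("genome must be a DNAStringSet, named character vector, or FASTA path")
  }
}
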