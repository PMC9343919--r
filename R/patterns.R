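# --- the three-genotype ordering algebra -----------------------------------
#
# Each pairwise DE contrast yields a relation in {<, =, >}. A triad of
# relations over (A,P), (A,H), (P,H) is *consistent* when some weak
# ordering of {A, H, P} induces it; there are 13 such weak orderings
# (1 all-tied, 6 one-tie, 6 strict) and 27 triads, so 14 triads are
# order-inconsistent (possible with thresholded tests) and are resolved
# with the A-vs-P contrast as primary.

rel_of <- function(sig, lfc) ifelse(!sig, "=", ifelse(lfc > 0, "<", ">"))

# canonical pattern string for a rank assignment (larger rank = higher
# expression): monotone chain with A's group first; ties in (A,H,P) order.
pattern_string <- function(rank) {
  names(rank) <- c("A", "H", "P")
  groups <- split(names(rank), -rank)        # descending expression
  groups <- lapply(groups, sort)
  if (length(groups) == 1L) return(paste(groups[[1]], collapse = "="))
  fmt <- function(g) if (length(g) > 1L) {
    paste0("(", paste(g, collapse = "="), ")")
  } else g
  a_grp <- which(vapply(groups, function(g) "A" %in% g, TRUE))
  if (a_grp == length(groups) && length(groups) > 1L) {
    paste(rev(vapply(groups, fmt, "")), collapse = "<")
  } else {
    paste(vapply(groups, fmt, ""), collapse = ">")
  }
}

# relations induced by a rank assignment, as c(AP, AH, PH)
rel_from_rank <- function(rank) {
  cmp <- function(x, y) if (rank[x] == rank[y]) "=" else {
    if (rank[x] < rank[y]) "<" else ">"
  }
  names(rank) <- c("A", "H", "P")
  c(cmp("A", "P"), cmp("A", "H"), cmp("P", "H"))
}

coarse_of <- function(ap, ah, ph) {
  case_when(ah == "<" & ph == "<" ~ "hybrid_up",
            ah == ">" & ph == ">" ~ "hybrid_down",
            ap == "<" ~ "peach_up",
            ap == ">" ~ "almond_up",
            .default = "equal")
}

# lookup over all 27 triads, built once per session
pattern_lookup <- local({
  tbl <- NULL
  function() {
    if (!is.null(tbl)) return(tbl)
    ranks <- expand.grid(A = 1:3, H = 1:3, P = 1:3)
    consistent <- unique(t(apply(ranks, 1, function(r) {
      match(r, sort(unique(r)))  # dense ranks
    })))
    lk <- expand.grid(ap = c("<", "=", ">"), ah = c("<", "=", ">"),
                      ph = c("<", "=", ">"), stringsAsFactors = FALSE)
    lk$fine <- NA_character_
    lk$consistent <- FALSE
    for (i in seq_len(nrow(consistent))) {
      r <- consistent[i, ]
      key <- rel_from_rank(r)
      j <- lk$ap == key[1] & lk$ah == key[2] & lk$ph == key[3]
      lk$fine[j] <- pattern_string(r)
      lk$consistent[j] <- TRUE
    }
    bad <- !lk$consistent
    lk$fine[bad] <- paste0("A", lk$ap[bad], "P,A", lk$ah[bad], "H,P",
                           lk$ph[bad], "H")
    lk$coarse <- coarse_of(lk$ap, lk$ah, lk$ph)
    tbl <<- lk
    tbl
  }
})

#' Classify three-genotype expression patterns
#'
#' Combines the three pairwise differential-expression calls per feature
#' (almond vs peach, almond vs hybrid, peach vs hybrid) into a canonical
#' fine ordering pattern (e.g. `"A<H<P"`, `"(A=H)>P"`, `"A=H=P"`) and a
#' coarse class. The coarse class is `hybrid_up`/`hybrid_down` when the
#' hybrid is significantly above/below *both* parents (transgressive
#' expression), otherwise `peach_up`/`almond_up` by the parental contrast,
#' and `equal` when nothing separates the parents or the hybrid from them.
#' Significance triads no weak ordering of the genotypes can induce
#' (possible with thresholded tests) get `consistent = FALSE`, a coarse
#' class anchored on the A-vs-P call, and a lossless fine string listing
#' the raw pairwise relations.
#'
#' @param de_ap,de_ah,de_ph [nb_pairwise_test()] results for the contrasts
#'   A-vs-P, A-vs-H and P-vs-H (in that orientation: `log2fc > 0` means
#'   the second genotype is higher).
#' @return Tibble of class `pattern_calls`: `feature`, `fine_pattern`,
#'   `coarse_class`, `consistent`.
#' @export
classify_pattern <- function(de_ap, de_ah, de_ph) {
  stopifnot(nrow(de_ap) == nrow(de_ah), nrow(de_ap) == nrow(de_ph))
  x <- de_ap %>%
    select("feature", sig_ap = "significant", lfc_ap = "log2fc") %>%
    inner_join(select(de_ah, "feature", sig_ah = "significant",
                      lfc_ah = "log2fc"), by = "feature") %>%
    inner_join(select(de_ph, "feature", sig_ph = "significant",
                      lfc_ph = "log2fc"), by = "feature")
  if (nrow(x) != nrow(de_ap)) {
    missing <- setdiff(de_ap$feature, x$feature)
    abort(paste0("features missing a contrast: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  lk <- pattern_lookup()
  key_x <- paste(rel_of(x$sig_ap, x$lfc_ap), rel_of(x$sig_ah, x$lfc_ah),
                 rel_of(x$sig_ph, x$lfc_ph))
  key_lk <- paste(lk$ap, lk$ah, lk$ph)
  i <- match(key_x, key_lk)
  out <- tibble(feature = x$feature, fine_pattern = lk$fine[i],
                coarse_class = lk$coarse[i], consistent = lk$consistent[i])
  class(out) <- c("pattern_calls", class(out))
  out
}

#' Summarize expression-pattern calls into category counts
#'
#' Counts features per coarse pattern class and reports each as a
#' percentage of the total, rounded to one decimal.
#'
#' @param calls A [classify_pattern()] result (pre-filter to expressed
#'   features if an expression floor applies).
#' @return Tibble of class `pattern_summary`: `coarse_class`, `n`, `pct`,
#'   in canonical class order.
#' @examples
#' calls <- tibble::tibble(coarse_class = c("equal", "equal", "peach_up"))
#' summarize_patterns(calls)
#' @export
summarize_patterns <- function(calls) {
  lev <- c("equal", "peach_up", "almond_up", "hybrid_up", "hybrid_down")
  if (nrow(calls) == 0L) {
    out <- tibble(coarse_class = character(), n = integer(), pct = double())
  } else {
    out <- calls %>%
      count(coarse_class = factor(.data$coarse_class, levels = lev),
            name = "n", .drop = FALSE) %>%
      mutate(coarse_class = as.character(.data$coarse_class),
             pct = round(100 * .data$n / sum(.data$n), 1))
  }
  class(out) <- c("pattern_summary", class(out))
  out
}

#' Features expressed in at least one genotype
#'
#' Applies the expression floor defining the denominator of pattern
#' percentages: a feature counts as expressed when its mean normalized
#' count reaches `min_mean` in at least one genotype.
#'
#' @param normalized Normalized count tibble
#'   (`normalize_counts()$normalized`).
#' @param design Sample-to-genotype design tibble.
#' @param min_mean Expression floor on the mean normalized count.
#' @return Character vector of expressed feature ids.
#' @export
expressed_features <- function(normalized, design, min_mean = 5) {
  long <- pivot_longer(normalized, -"feature", names_to = "sample",
                       values_to = "x") %>%
    inner_join(design, by = "sample") %>%
    group_by(.data$feature, .data$genotype) %>%
    summarise(m = mean(.data$x), .groups = "drop_last") %>%
    summarise(expressed = any(.data$m >= min_mean), .groups = "drop")
  long$feature[long$expressed]
}
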