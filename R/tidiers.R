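#' Tidy and glance methods
#'
#' `tidy()` returns the per-row result table as a plain tibble; `glance()`
#' returns a one-row summary of the analysis.
#'
#' @param x An `nb_de` or `dmr_set` object.
#' @param ... Unused.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.nb_de <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "nb_de")
  as_tibble(out)
}

#' @rdname tidiers
#' @export
glance.nb_de <- function(x, ...) {
  tibble(contrast = x$contrast[1],
         n_features = nrow(x),
         n_tested = sum(!is.na(x$p)),
         n_significant = sum(x$significant),
         fdr = attr(x, "fdr"),
         lfc_threshold = attr(x, "lfc_threshold"))
}

#' @rdname tidiers
#' @export
tidy.dmr_set <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "dmr_set")
  attr(out, "windows") <- NULL
  as_tibble(out)
}

#' @rdname tidiers
#' @export
glance.dmr_set <- function(x, ...) {
  ws <- attr(x, "windows")
  labels <- attr(x, "labels")
  tibble(context = if (nrow(x)) x$context[1] else
           if (!is.null(ws) && nrow(ws)) ws$context[1] else NA_character_,
         n_windows = if (is.null(ws)) NA_integer_ else nrow(ws),
         n_tested = if (is.null(ws)) NA_integer_ else sum(ws$tested),
         n_dmrs = nrow(x),
         n_b_up = sum(grepl(paste0("^", labels[["b"]]), x$direction)),
         fdr = attr(x, "params")$fdr)
}
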