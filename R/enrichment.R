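#' Read a GMT annotation
#'
#' Term-to-feature annotation in GMT format (term, description, then
#' member features, tab-separated). Parsing is delegated to
#' [fgsea::gmtPathways()]; empty terms are dropped.
#'
#' @param path GMT file path.
#' @param universe background feature universe; defaults to the union of
#'   all term members. The recommended universe is the set of features
#'   surviving the expression filter.
#' @return list of class `Annotation`: `terms` (named list of feature
#'   vectors) and `universe`.
#' @export
read_gmt <- function(path, universe = NULL) {
  terms <- fgsea::gmtPathways(path)
  annotation(terms, universe)
}

#' Build an annotation object
#'
#' @param terms named list of feature-id vectors.
#' @param universe background universe (default: union of all members).
#' @return list of class `Annotation`.
#' @export
annotation <- function(terms, universe = NULL) {
  terms <- lapply(terms, unique)
  terms <- terms[lengths(terms) > 0L]
  if (!length(terms)) stop("annotation holds no nonempty term")
  if (is.null(universe)) universe <- unique(unlist(terms))
  terms <- lapply(terms, intersect, universe)
  terms <- terms[lengths(terms) > 0L]
  structure(list(terms = terms, universe = universe), class = "Annotation")
}

#' Hypergeometric term enrichment
#'
#' Upper-tail hypergeometric test per term: the probability of observing
#' at least `k` study features in a term of size `K` when `n` features
#' are drawn from a universe of `N`. Only terms hit at least once are
#' tested; BH correction runs across the tested terms. Study features
#' outside the universe are dropped with a warning.
#'
#' @param study character vector of feature ids.
#' @param annot an [annotation()].
#' @return data.frame sorted by p: `term`, `k`, `n`, `K`, `N`, `p`,
#'   `fdr`.
#' @export
hypergeom_enrich <- function(study, annot) {
  stopifnot(inherits(annot, "Annotation"))
  study <- unique(study)
  outside <- setdiff(study, annot$universe)
  if (length(outside)) {
    warning(length(outside), " study feature(s) outside the universe dropped")
    study <- intersect(study, annot$universe)
  }
  if (!length(study)) stop("empty study set after intersecting the universe")
  N <- length(annot$universe); n <- length(study)
  out <- NULL
  for (term in names(annot$terms)) {
    members <- annot$terms[[term]]
    K <- length(members)
    k <- length(intersect(study, members))
    if (k == 0L) next
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    out <- rbind(out, data.frame(term = term, k = k, n = n, K = K, N = N,
                                 p = p, stringsAsFactors = FALSE))
  }
  if (is.null(out))
    return(data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p = numeric(0),
                      fdr = numeric(0), stringsAsFactors = FALSE))
  out$fdr <- bh_adjust(out$p)
  out[order(out$p), , drop = FALSE]
}

#' Filter enrichment results at a raw-P cut
#'
#' Strict inequality on the raw p (the study's GO cut is P < 0.05, KEGG
#' P < 0.01); results come back sorted by ascending p. BH values remain
#' in the table for reference.
#'
#' @param results a [hypergeom_enrich()] table.
#' @param p_cut raw p threshold.
#' @return the filtered, sorted subset.
#' @export
filter_enrichment <- function(results, p_cut = 0.05) {
  out <- results[!is.na(results$p) & results$p < p_cut, , drop = FALSE]
  out[order(out$p), , drop = FALSE]
}
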