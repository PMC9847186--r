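#' Feature-by-sample omics matrix
#'
#' Light container for a numeric feature x sample matrix tagged with the
#' scale ("layer") it lives on. All downstream stages declare which layer
#' they expect; normalizers change the tag so mistakes surface early.
#'
#' @param values numeric matrix, features in rows, samples in columns, with
#'   rownames (feature ids) and colnames (sample ids).
#' @param layer one of `"counts"`, `"cpm"`, `"fpkm"`, `"abundance"`,
#'   `"log_abundance"`. The `counts` layer must hold nonnegative integers.
#' @return an object of class `OmicsMatrix`: a list with elements `values`
#'   and `layer`.
#' @export
omics_matrix <- function(values, layer = c("counts", "cpm", "fpkm",
                                           "abundance", "log_abundance")) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  fid <- rownames(values); sid <- colnames(values)
  if (is.null(fid) || is.null(sid))
    stop("'values' must carry feature rownames and sample colnames")
  if (anyDuplicated(fid))
    stop("duplicate feature id: ", fid[duplicated(fid)][1L])
  if (anyDuplicated(sid))
    stop("duplicate sample id: ", sid[duplicated(sid)][1L])
  if (!all(is.finite(values)))
    stop("non-finite value in matrix")
  if (layer != "log_abundance" && any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop("negative value at feature '", fid[bad[1L]], "', sample '",
         sid[bad[2L]], "'")
  }
  if (layer == "counts" && any(values != round(values)))
    stop("counts layer must contain integers")
  structure(list(values = values, layer = layer), class = "OmicsMatrix")
}

#' @export
print.OmicsMatrix <- function(x, ...) {
  cat(sprintf("OmicsMatrix [%s]: %d features x %d samples\n",
              x$layer, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.OmicsMatrix <- function(x) dim(x$values)

feature_ids <- function(m) rownames(m$values)
sample_ids  <- function(m) colnames(m$values)

#' Read a feature x sample matrix from TSV
#'
#' Expects a tab-separated file whose header row holds sample ids (first
#' cell `feature_id`) and whose first column holds feature ids.
#'
#' @param path file path.
#' @inheritParams omics_matrix
#' @return an [omics_matrix()].
#' @export
read_matrix <- function(path, layer = "counts") {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("matrix file needs a feature_id column and >=1 sample")
  fid <- df[[1L]]
  if (anyDuplicated(fid))
    stop("duplicate feature id: ", fid[duplicated(fid)][1L])
  sid <- colnames(df)[-1L]
  v <- suppressWarnings(vapply(df[-1L], as.numeric, numeric(nrow(df))))
  v <- matrix(v, nrow = nrow(df), dimnames = list(fid, sid))
  if (anyNA(v)) {
    bad <- which(is.na(v), arr.ind = TRUE)[1L, ]
    stop("non-numeric cell at feature '", fid[bad[1L]], "', sample '",
         sid[bad[2L]], "'")
  }
  omics_matrix(v, layer)
}

#' Write a feature x sample matrix as TSV
#'
#' Inverse of [read_matrix()]: floats are written with round-trip ("%.17g")
#' precision so `read_matrix(write_matrix(m))` reproduces `m` exactly.
#'
#' @param m an [omics_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  stopifnot(inherits(m, "OmicsMatrix"))
  v <- m$values
  fmt <- if (m$layer == "counts") function(x) sprintf("%d", as.integer(x))
         else function(x) sprintf("%.17g", x)
  lines <- c(paste(c("feature_id", colnames(v)), collapse = "\t"),
             vapply(seq_len(nrow(v)), function(i)
               paste(c(rownames(v)[i], fmt(v[i, ])), collapse = "\t"),
               character(1L)))
  writeLines(lines, path)
  invisible(path)
}

#' Counts-per-million normalization
#'
#' @param m an [omics_matrix()] on the `counts` layer.
#' @return an `OmicsMatrix` on the `cpm` layer; every column sums to 1e6.
#' @export
cpm_normalize <- function(m) {
  stopifnot(inherits(m, "OmicsMatrix"))
  if (m$layer != "counts") stop("cpm_normalize expects the counts layer")
  libsize <- colSums(m$values)
  if (any(libsize == 0))
    stop("zero library size for sample '", colnames(m$values)[libsize == 0][1L], "'")
  v <- sweep(m$values, 2L, libsize, "/") * 1e6
  omics_matrix(v, "cpm")
}

#' FPKM normalization
#'
#' Fragments per kilobase of transcript per million mapped reads:
#' `counts * 1e9 / (library size * length in bp)`.
#'
#' @inheritParams cpm_normalize
#' @param lengths named numeric vector of feature lengths in base pairs,
#'   covering every feature of `m` (see [read_gene_lengths()]).
#' @return an `OmicsMatrix` on the `fpkm` layer.
#' @export
fpkm_normalize <- function(m, lengths) {
  stopifnot(inherits(m, "OmicsMatrix"))
  if (m$layer != "counts") stop("fpkm_normalize expects the counts layer")
  fid <- rownames(m$values)
  missing <- setdiff(fid, names(lengths))
  if (length(missing))
    stop("no length for feature '", missing[1L], "'")
  len <- lengths[fid]
  if (any(len <= 0)) stop("nonpositive gene length")
  libsize <- colSums(m$values)
  if (any(libsize == 0))
    stop("zero library size for sample '", colnames(m$values)[libsize == 0][1L], "'")
  v <- m$values * 1e9 / outer(len, libsize)
  omics_matrix(v, "fpkm")
}

#' Read gene lengths from a two-column TSV
#'
#' @param path TSV with columns `feature_id` and `length` (bp).
#' @return named numeric vector of lengths.
#' @export
read_gene_lengths <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("gene length file needs two columns")
  len <- as.numeric(df[[2L]])
  if (anyNA(len) || any(len <= 0)) stop("gene lengths must be positive numbers")
  if (anyDuplicated(df[[1L]]))
    stop("duplicate feature id: ", df[[1L]][duplicated(df[[1L]])][1L])
  stats::setNames(len, df[[1L]])
}

#' Remove weakly expressed genes
#'
#' Keeps genes whose CPM reaches `cfg$cpm_min` (inclusive) in at least
#' `min_samples` samples; everything else is dropped. The CPM scale is
#' computed on the fly, the returned matrix stays on the counts layer.
#'
#' @inheritParams cpm_normalize
#' @param cfg a [threshold_config()].
#' @param min_samples minimum number of samples at or above the CPM cut.
#'   When `sheet` is supplied and `min_samples` is `NULL`, the smallest
#'   genotype x condition replicate-group size is used.
#' @param sheet optional [sample_sheet()] used to derive `min_samples`.
#' @return filtered `OmicsMatrix` on the counts layer.
#' @export
filter_low_expression <- function(m, cfg = threshold_config(),
                                  min_samples = NULL, sheet = NULL) {
  stopifnot(inherits(m, "OmicsMatrix"))
  if (is.null(min_samples)) {
    min_samples <- if (is.null(sheet)) 1L else
      min(table(paste(sheet$genotype, sheet$condition)))
  }
  if (min_samples < 1L) stop("min_samples must be >= 1")
  cpm <- cpm_normalize(m)$values
  keep <- rowSums(cpm >= cfg$cpm_min) >= min_samples
  if (!any(keep)) warning("no gene passes the expression filter")
  omics_matrix(m$values[keep, , drop = FALSE], "counts")
}

#' Analysis thresholds
#'
#' Bundles every calling threshold used across the pipeline: fold-change
#' cut 1.5 with FDR < 0.3 for genes, VIP > 1 with FDR < 0.05 for
#' metabolites, the CPM >= 10 expression filter, and the raw-P cuts used
#' for GO (0.05) and KEGG (0.01) enrichment reporting.
#'
#' @param fc_cut linear fold-change cut (> 1).
#' @param fdr_genes BH-FDR cut for gene calls.
#' @param vip_cut VIP cut for metabolite calls (strict `>`).
#' @param fdr_metab BH-FDR cut for metabolite calls.
#' @param cpm_min CPM needed to count a sample as expressing a gene.
#' @param go_p,kegg_p raw enrichment P cuts (strict `<`).
#' @return a list of class `ThresholdConfig`.
#' @export
threshold_config <- function(fc_cut = 1.5, fdr_genes = 0.3, vip_cut = 1.0,
                             fdr_metab = 0.05, cpm_min = 10,
                             go_p = 0.05, kegg_p = 0.01) {
  if (fc_cut <= 1) stop("fc_cut must exceed 1")
  for (p in c(fdr_genes, fdr_metab, go_p, kegg_p))
    if (p <= 0 || p >= 1) stop("FDR / P cuts must lie in (0, 1)")
  structure(list(fc_cut = fc_cut, fdr_genes = fdr_genes, vip_cut = vip_cut,
                 fdr_metab = fdr_metab, cpm_min = cpm_min,
                 go_p = go_p, kegg_p = kegg_p),
            class = "ThresholdConfig")
}
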