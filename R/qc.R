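#' Replicate-concordance summary
#'
#' Pairwise Pearson correlation between biological replicates of each
#' genotype x condition group, reported both as r and r squared. By
#' default values are log2(x+1)-transformed first (variance
#' stabilization); pass `log2 = FALSE` to correlate the layer as given.
#'
#' @param m an [omics_matrix()] (any normalized layer).
#' @param sheet a [sample_sheet()] covering the samples of `m`.
#' @param log2 transform values to log2(x+1) before correlating.
#' @return data.frame with one row per group: `genotype`, `condition`,
#'   `n_pairs`, `mean_r`, `mean_r_squared`; attribute `"pairs"` holds the
#'   per-pair values.
#' @export
replicate_correlation <- function(m, sheet, log2 = TRUE) {
  stopifnot(inherits(m, "OmicsMatrix"), inherits(sheet, "SampleSheet"))
  v <- m$values[, sheet$sample_id, drop = FALSE]
  if (log2) v <- log2(v + 1)
  key <- paste(sheet$genotype, sheet$condition, sep = "\r")
  out <- NULL; pairs <- NULL
  for (g in unique(key)) {
    ids <- sheet$sample_id[key == g]
    if (length(ids) < 2L)
      stop("group '", gsub("\r", " / ", g), "' has fewer than 2 replicates")
    cmb <- utils::combn(ids, 2L)
    r <- numeric(0)
    for (j in seq_len(ncol(cmb))) {
      x <- v[, cmb[1L, j]]; y <- v[, cmb[2L, j]]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        warning("zero-variance sample in pair ", cmb[1L, j], " / ", cmb[2L, j],
                "; pair excluded")
        rj <- NA_real_
      } else rj <- stats::cor(x, y)
      r <- c(r, rj)
      pairs <- rbind(pairs, data.frame(
        genotype = sheet$genotype[sheet$sample_id == ids[1L]],
        condition = sheet$condition[sheet$sample_id == ids[1L]],
        sample_a = cmb[1L, j], sample_b = cmb[2L, j], r = rj,
        stringsAsFactors = FALSE))
    }
    r_ok <- r[!is.na(r)]
    out <- rbind(out, data.frame(
      genotype = sheet$genotype[sheet$sample_id == ids[1L]],
      condition = sheet$condition[sheet$sample_id == ids[1L]],
      n_pairs = length(r), mean_r = mean(r_ok),
      mean_r_squared = mean(r_ok^2), stringsAsFactors = FALSE))
  }
  attr(out, "pairs") <- pairs
  out
}

#' Principal component analysis of samples
#'
#' Features are centered across samples, then samples are projected on the
#' leading principal components of the sample covariance.
#'
#' @param m an [omics_matrix()].
#' @param n_components number of components to retain.
#' @return list of class `PCAResult`: `scores` (samples x components) and
#'   `variance_fraction` per component.
#' @export
pca_samples <- function(m, n_components = 2L) {
  stopifnot(inherits(m, "OmicsMatrix"))
  v <- t(m$values)                      # samples x features
  if (all(apply(v, 2L, stats::sd) == 0)) stop("no variance in matrix")
  if (n_components > min(dim(v))) stop("n_components exceeds matrix rank bound")
  fit <- stats::prcomp(v, center = TRUE, scale. = FALSE)
  vf <- fit$sdev^2 / sum(fit$sdev^2)
  k <- min(n_components, ncol(fit$x))
  structure(list(scores = fit$x[, seq_len(k), drop = FALSE],
                 variance_fraction = vf[seq_len(k)]),
            class = "PCAResult")
}

#' Average-linkage clustering of sample profiles
#'
#' Samples are agglomerated on the correlation distance
#' d = 1 - Pearson r between profiles.
#'
#' @param m an [omics_matrix()] with at least two samples.
#' @return an [stats::hclust] tree.
#' @export
cluster_samples <- function(m) {
  stopifnot(inherits(m, "OmicsMatrix"))
  v <- m$values
  if (ncol(v) < 2L) stop("need at least 2 samples")
  sds <- apply(v, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance sample(s): ",
         paste(colnames(v)[sds == 0], collapse = ", "))
  d <- stats::as.dist(1 - stats::cor(v))
  stats::hclust(d, method = "average")
}
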