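#' Mid-parent value profile
#'
#' Builds pseudo-replicates of the expected additive hybrid: pseudo-
#' replicate i is the arithmetic mean of female replicate i and male
#' replicate i (replicates paired in replicate-index order, truncated to
#' the smaller parental replicate count). Averaging on the normalized
#' scale keeps the MPV mean equal to the mean of the two parental means
#' when replicate counts are equal.
#'
#' @param norm an [omics_matrix()] on a normalized layer (cpm / fpkm /
#'   abundance).
#' @param trio a [trio_design()].
#' @return list of class `MidParentProfile`: `values` (feature x
#'   pseudo-replicate matrix) and `provenance` (which parental replicates
#'   were averaged).
#' @export
midparent_profile <- function(norm, trio) {
  stopifnot(inherits(norm, "OmicsMatrix"), inherits(trio, "TrioDesign"))
  if (!norm$layer %in% c("cpm", "fpkm", "abundance"))
    stop("midparent_profile expects a normalized layer, got '", norm$layer, "'")
  f <- trio$female_samples; m <- trio$male_samples
  if (!length(f) || !length(m)) stop("both parents must be present")
  k <- min(length(f), length(m))
  f <- f[seq_len(k)]; m <- m[seq_len(k)]
  v <- (norm$values[, f, drop = FALSE] + norm$values[, m, drop = FALSE]) / 2
  colnames(v) <- paste0("MPV_", seq_len(k))
  structure(list(values = v,
                 provenance = data.frame(pseudo_replicate = seq_len(k),
                                         female_sample = f, male_sample = m,
                                         stringsAsFactors = FALSE)),
            class = "MidParentProfile")
}

#' Test the hybrid against its expected mid-parent value
#'
#' Welch t-test per feature of log2(x+1) hybrid replicates against
#' log2(x+1) MPV pseudo-replicates, BH-corrected across features, with
#' directional calls at the gene thresholds (FC >= `fc_cut` or <=
#' 1/`fc_cut`, FDR < `fdr_genes`). `mean_a` is the MPV mean, `mean_b` the
#' hybrid mean, both on the normalized (unlogged) scale.
#'
#' @inheritParams midparent_profile
#' @param cfg a [threshold_config()].
#' @return data.frame as in [nb_test()].
#' @export
f1_vs_mpv <- function(norm, trio, cfg = threshold_config()) {
  mpv <- midparent_profile(norm, trio)
  h <- norm$values[, trio$hybrid_samples, drop = FALSE]
  if (ncol(h) < 2L || ncol(mpv$values) < 2L)
    stop("need >= 2 hybrid replicates and >= 2 MPV pseudo-replicates")
  lh <- log2(h + 1); lm <- log2(mpv$values + 1)
  p <- vapply(seq_len(nrow(h)), function(i)
    welch_t_test(lm[i, ], lh[i, ])$p, numeric(1L))
  mA <- rowMeans(mpv$values); mB <- rowMeans(h)
  pad <- mA == 0 | mB == 0
  log2fc <- log2((mB + 0.5 * pad) / (mA + 0.5 * pad))
  fdr <- bh_adjust(p)
  data.frame(feature_id = rownames(h), mean_a = mA, mean_b = mB,
             log2fc = log2fc, p = p, fdr = fdr,
             call = make_calls(log2fc, fdr, cfg$fc_cut, cfg$fdr_genes),
             stringsAsFactors = FALSE, row.names = NULL)
}

TYPE_LEVELS <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX",
                 "X", "XI", "XII", "unclassified")

type_to_category <- function(type) {
  map <- c(I = "additive", II = "additive",
           III = "ELD_M", IV = "ELD_M",
           V = "ELD_F", VI = "ELD_F",
           VII = "overdominant", VIII = "overdominant", IX = "overdominant",
           X = "overdominant", XI = "overdominant", XII = "overdominant",
           unclassified = "unclassified")
  unname(map[type])
}

#' Classify one feature into the twelve F-H-M inheritance types
#'
#' Decision table over the three pairwise differential calls and the group
#' means (F = female parent, H = hybrid, M = male parent). Call semantics:
#' `hf` is the hybrid-vs-female call (`"up"` means H above F), `hm` the
#' hybrid-vs-male call, `fm` the female-vs-male call (`"up"` means F
#' above M); `"ns"` means not significant at the shared FC/FDR
#' thresholds.
#'
#' * additive (I / II): H differs from both parents, the parents differ,
#'   and H lies strictly between them; I when the female parent is the
#'   higher parent.
#' * ELD-M (III / IV): H indistinguishable from the male parent and
#'   different from the female; III when the male (the resembled parent)
#'   is the higher parent.
#' * ELD-F (V / VI): mirror image toward the female parent; V when the
#'   female (the resembled parent) is the higher parent. Keying the
#'   III/IV and V/VI splits to the resembled parent makes the labels
#'   covariant under a parent swap (III <-> V, IV <-> VI), so the same
#'   biology reads as type V in one cross and type III in the reciprocal.
#' * overdominant low (VII / VIII / IX): H below both parents; VII when M
#'   is significantly above F, IX when F is significantly above M, VIII
#'   when the parents do not differ.
#' * overdominant high (X / XI / XII): H above both parents, split the
#'   same way (X male-higher, XII female-higher, XI parents similar).
#' * anything else: unclassified.
#'
#' @param hf,hm,fm pairwise calls, each `"up"`, `"down"` or `"ns"`.
#' @param f_mean,h_mean,m_mean group means on the normalized scale.
#' @return the type as a string (`"I"` .. `"XII"` or `"unclassified"`).
#' @export
classify_inheritance <- function(hf, hm, fm, f_mean, h_mean, m_mean) {
  ok <- c("up", "down", "ns")
  for (cl in list(hf, hm, fm))
    if (length(cl) != 1L || !cl %in% ok)
      stop("calls must be one of 'up', 'down', 'ns'")
  if (hf == "down" && hm == "down")           # below both parents
    return(switch(fm, down = "VII", up = "IX", ns = "VIII"))
  if (hf == "up" && hm == "up")               # above both parents
    return(switch(fm, down = "X", up = "XII", ns = "XI"))
  if (hm == "ns" && hf != "ns")               # like male, unlike female
    return(if (m_mean > f_mean) "III" else "IV")
  if (hf == "ns" && hm != "ns")               # like female, unlike male
    return(if (f_mean > m_mean) "V" else "VI")
  if (hf != "ns" && hm != "ns" && fm != "ns" &&
      h_mean > min(f_mean, m_mean) && h_mean < max(f_mean, m_mean))
    return(if (f_mean > m_mean) "I" else "II")
  "unclassified"
}

#' Classify every feature of a trio from its three differential tables
#'
#' Joins the hybrid-vs-female, hybrid-vs-male and female-vs-male result
#' tables (as produced by [nb_test()] with groups ordered so that
#' `mean_b` is the hybrid for the first two and the female parent for the
#' third) and applies [classify_inheritance()] per feature.
#'
#' @param de_hf `nb_test(m, female, hybrid, ...)` result.
#' @param de_hm `nb_test(m, male, hybrid, ...)` result.
#' @param de_fm `nb_test(m, male, female, ...)` result.
#' @return data.frame of class `InheritanceCall`: `feature_id`, `type`,
#'   `category`, the three calls, and per-contrast `log2fc` / `fdr`.
#' @export
classify_trio <- function(de_hf, de_hm, de_fm) {
  if (!identical(de_hf$feature_id, de_hm$feature_id) ||
      !identical(de_hf$feature_id, de_fm$feature_id))
    stop("the three tables must cover the same features in the same order")
  type <- vapply(seq_len(nrow(de_hf)), function(i)
    classify_inheritance(de_hf$call[i], de_hm$call[i], de_fm$call[i],
                         f_mean = de_hf$mean_a[i], h_mean = de_hf$mean_b[i],
                         m_mean = de_hm$mean_a[i]),
    character(1L))
  out <- data.frame(feature_id = de_hf$feature_id,
                    type = type, category = type_to_category(type),
                    call_hf = de_hf$call, call_hm = de_hm$call,
                    call_fm = de_fm$call,
                    log2fc_hf = de_hf$log2fc, fdr_hf = de_hf$fdr,
                    log2fc_hm = de_hm$log2fc, fdr_hm = de_hm$fdr,
                    log2fc_fm = de_fm$log2fc, fdr_fm = de_fm$fdr,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("InheritanceCall", "data.frame")
  out
}

#' Tally inheritance types and categories
#'
#' @param calls an [classify_trio()] table (or anything with `type`).
#' @return list: `type_counts` over I..XII + unclassified,
#'   `category_counts` over additive / ELD_F / ELD_M / overdominant /
#'   unclassified, and `non_additive` (ELD_F + ELD_M + overdominant).
#' @export
categorize <- function(calls) {
  type <- factor(calls$type, levels = TYPE_LEVELS)
  tc <- table(type)
  cat <- factor(type_to_category(as.character(type)),
                levels = c("additive", "ELD_F", "ELD_M", "overdominant",
                           "unclassified"))
  cc <- table(cat)
  list(type_counts = tc, category_counts = cc,
       non_additive = sum(cc[c("ELD_F", "ELD_M", "overdominant")]))
}

#' Exclusive intersection counts for a family of feature sets
#'
#' UpSet-style decomposition: every feature of the union is assigned to
#' exactly one membership signature (set names joined by `&`), plus the
#' plain pairwise intersection counts used by Venn summaries.
#'
#' @param sets named list (>= 2) of character vectors.
#' @return list of class `OverlapTable`: `exclusive` (data.frame
#'   `signature`, `count`), `pairwise` (matrix of intersection sizes),
#'   `union_size`.
#' @export
set_overlaps <- function(sets) {
  if (length(sets) < 2L || is.null(names(sets)) || any(names(sets) == ""))
    stop("need >= 2 named sets")
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  member <- matrix(member, nrow = length(universe),
                   dimnames = list(universe, names(sets)))
  sig <- apply(member, 1L, function(row)
    paste(names(sets)[row], collapse = "&"))
  tab <- table(sig)
  pairwise <- crossprod(member)
  structure(list(exclusive = data.frame(signature = names(tab),
                                        count = as.integer(tab),
                                        stringsAsFactors = FALSE),
                 pairwise = pairwise, union_size = length(universe)),
            class = "OverlapTable")
}

#' Chi-square test of up/down asymmetry
#'
#' Goodness-of-fit of the observed up/down split against 50:50, df = 1.
#'
#' @param n_up,n_down nonnegative counts, not both zero.
#' @return list with `chi2` and `p`.
#' @export
updown_asymmetry <- function(n_up, n_down) {
  if (n_up < 0 || n_down < 0) stop("counts must be nonnegative")
  if (n_up + n_down == 0) stop("no calls to test")
  fit <- stats::chisq.test(c(n_up, n_down), p = c(0.5, 0.5))
  list(chi2 = unname(fit$statistic), p = fit$p.value)
}
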