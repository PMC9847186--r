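#' Median-of-ratios size factors
#'
#' Per-sample scaling factors computed as the median, over genes with
#' nonzero counts in every sample, of the ratio of the gene's count to its
#' geometric mean across samples. Factors are rescaled to geometric mean 1.
#' If no gene is nonzero in all samples the library-size factors (column
#' sums scaled to geometric mean 1) are used instead, with a warning.
#'
#' @param m an [omics_matrix()] on the counts layer.
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(m) {
  stopifnot(inherits(m, "OmicsMatrix"))
  if (m$layer != "counts") stop("size_factors expects the counts layer")
  v <- m$values
  loggeo <- rowMeans(log(v))
  use <- is.finite(loggeo)
  if (!any(use)) {
    warning("no gene with nonzero counts in all samples; ",
            "falling back to library-size factors")
    sf <- colSums(v)
  } else {
    geo <- exp(loggeo[use])
    sf <- apply(v[use, , drop = FALSE], 2L, function(col)
      stats::median(col / geo))
  }
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(v))
}

make_calls <- function(log2fc, fdr, fc_cut, fdr_cut) {
  fc <- 2^log2fc
  ifelse(fdr < fdr_cut & fc >= fc_cut, "up",
         ifelse(fdr < fdr_cut & fc <= 1 / fc_cut, "down", "ns"))
}

#' Negative-binomial Wald test for two groups of count samples
#'
#' Counts are normalized by [size_factors()] (computed on the two groups
#' unless `sf` is given); per-gene dispersion is estimated by method of
#' moments on the normalized counts within each group (pooled across
#' groups, floored at 1e-8); the log2 fold change of group-B mean over
#' group-A mean is tested with a delta-method standard error. The Wald
#' statistic is referred to a t distribution with `nA + nB - 2` degrees of
#' freedom, which keeps the test calibrated at the small replicate numbers
#' this design uses (a normal reference is anticonservative at n = 3).
#'
#' @param m an [omics_matrix()] on the counts layer.
#' @param group_a,group_b disjoint character vectors of sample ids.
#' @param cfg a [threshold_config()]; sets the FC / FDR calling cuts.
#' @param sf optional named size factors covering both groups.
#' @return data.frame (one row per gene): `feature_id`, `mean_a`,
#'   `mean_b`, `log2fc`, `p`, `fdr`, `call`.
#' @export
nb_test <- function(m, group_a, group_b, cfg = threshold_config(), sf = NULL) {
  stopifnot(inherits(m, "OmicsMatrix"))
  if (m$layer != "counts") stop("nb_test expects the counts layer")
  if (length(intersect(group_a, group_b)))
    stop("groups overlap: ", intersect(group_a, group_b)[1L])
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("need >= 2 samples per group")
  ids <- c(group_a, group_b)
  missing <- setdiff(ids, colnames(m$values))
  if (length(missing)) stop("sample not in matrix: ", missing[1L])
  sub <- omics_matrix(m$values[, ids, drop = FALSE], "counts")
  if (is.null(sf)) sf <- size_factors(sub)
  sf <- sf[ids]
  q <- sweep(sub$values, 2L, sf, "/")
  qa <- q[, group_a, drop = FALSE]; qb <- q[, group_b, drop = FALSE]
  na <- length(group_a); nb <- length(group_b)
  mA <- rowMeans(qa); mB <- rowMeans(qb)
  vA <- apply(qa, 1L, stats::var); vB <- apply(qb, 1L, stats::var)
  # Poisson part of Var(K/s) = mu/s + alpha*mu^2, averaged over samples
  cA <- mean(1 / sf[group_a]); cB <- mean(1 / sf[group_b])
  alA <- ifelse(mA > 0, (vA - mA * cA) / mA^2, NA_real_)
  alB <- ifelse(mB > 0, (vB - mB * cB) / mB^2, NA_real_)
  wA <- ifelse(is.na(alA), 0, na - 1L); wB <- ifelse(is.na(alB), 0, nb - 1L)
  alpha <- (ifelse(is.na(alA), 0, alA) * wA + ifelse(is.na(alB), 0, alB) * wB) /
    pmax(wA + wB, 1L)
  alpha <- pmax(alpha, 1e-8)
  zero_pair <- mA == 0 & mB == 0
  pad <- mA == 0 | mB == 0            # pseudocount only when a mean is 0
  mAe <- mA + 0.5 * pad; mBe <- mB + 0.5 * pad
  log2fc <- log2(mBe / mAe)
  varA <- mAe * sum(1 / sf[group_a]) / na^2 + alpha * mAe^2 / na
  varB <- mBe * sum(1 / sf[group_b]) / nb^2 + alpha * mBe^2 / nb
  se <- sqrt(varA / mAe^2 + varB / mBe^2) / log(2)
  t <- ifelse(se > 0, log2fc / se, 0)
  p <- 2 * stats::pt(-abs(t), df = na + nb - 2L)
  log2fc[zero_pair] <- 0; p[zero_pair] <- 1
  fdr <- bh_adjust(p)
  data.frame(feature_id = rownames(q), mean_a = mA, mean_b = mB,
             log2fc = log2fc, p = p, fdr = fdr,
             call = make_calls(log2fc, fdr, cfg$fc_cut, cfg$fdr_genes),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR q-values in the input order. NaN/NA p-values propagate with
#' a warning.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values.
#' @export
bh_adjust <- function(p) {
  bad <- is.na(p)
  if (any(bad)) warning("NaN/NA p-value(s) propagated")
  if (any(p[!bad] < 0 | p[!bad] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom and
#' a two-sided p. Degenerate inputs are resolved by convention: both
#' vectors constant with equal means gives p = 1; constant with unequal
#' means gives p = 0 (with a warning).
#'
#' @param x,y numeric replicate vectors (>= 2 values each).
#' @return list with `t`, `df`, `p`.
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("need >= 2 values per vector")
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = NA_real_, p = 1))
    warning("zero variance with unequal means; p = 0")
    return(list(t = sign(mean(y) - mean(x)) * Inf, df = NA_real_, p = 0))
  }
  fit <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value)
}

#' PLS-DA variable importance in projection
#'
#' Fits a discriminant partial-least-squares model by NIPALS on
#' autoscaled columns (two classes coded as a centered indicator) and
#' returns the VIP score per feature:
#' `VIP_j = sqrt(p * sum_a SSY_a w_aj^2 / sum_a SSY_a)` with `p` the
#' number of features, `w_a` the unit-norm weight vectors and `SSY_a` the
#' class-indicator variance explained by component `a`. Mean squared VIP
#' is 1 by construction.
#'
#' @param X samples x features numeric matrix.
#' @param y class labels, exactly two levels.
#' @param n_components number of PLS components (<= min(dim) - 1).
#' @param drop_constant drop zero-variance feature columns with a warning
#'   instead of erroring.
#' @return named numeric vector of VIP scores (dropped features absent).
#' @export
plsda_vip <- function(X, y, n_components = 2L, drop_constant = FALSE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("feature", seq_len(ncol(X)))
  y <- as.factor(y)
  if (nlevels(y) != 2L) stop("y must have exactly two classes")
  if (n_components > min(nrow(X) - 1L, ncol(X)))
    stop("n_components must be <= min(samples - 1, features)")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    if (!drop_constant)
      stop("constant feature column: ", colnames(X)[sds == 0][1L])
    warning("dropping constant feature(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  Xs <- scale(X)
  yy <- as.numeric(y) - mean(as.numeric(y))
  p <- ncol(Xs)
  W <- matrix(0, p, n_components)
  ssy <- numeric(n_components)
  E <- Xs; f <- yy
  for (a in seq_len(n_components)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { W <- W[, seq_len(a - 1L), drop = FALSE]
                      ssy <- ssy[seq_len(a - 1L)]; break }
    w <- w / nw
    t <- drop(E %*% w)
    tt <- sum(t^2)
    pl <- drop(crossprod(E, t)) / tt
    qa <- sum(f * t) / tt
    ssy[a] <- qa^2 * tt
    W[, a] <- w
    E <- E - tcrossprod(t, pl)
    f <- f - qa * t
  }
  if (sum(ssy) == 0) stop("no class variance explained; check inputs")
  vip <- sqrt(p * drop(W^2 %*% ssy) / sum(ssy))
  stats::setNames(vip, colnames(Xs))
}

#' Metabolite differential-abundance table
#'
#' Combines [plsda_vip()] scores with per-feature [welch_t_test()]s
#' (on log2(x+1) by default; pair by replicate order with
#' `paired = TRUE`) and BH correction into one table, then applies the
#' VIP > cut AND FDR < cut rule via [call_dams()].
#'
#' @param m an [omics_matrix()] on the abundance layer.
#' @param group_a,group_b disjoint sample id vectors (>= 2 each).
#' @param cfg a [threshold_config()].
#' @param n_components PLS components for the VIP fit.
#' @param log2 test log2(x+1) values (recommended for LC-MS abundances).
#' @param paired pair replicates by position instead of Welch.
#' @return data.frame: `feature_id`, `mean_a`, `mean_b`, `log2fc`, `p`,
#'   `fdr`, `vip`, `call`.
#' @export
vip_test <- function(m, group_a, group_b, cfg = threshold_config(),
                     n_components = 2L, log2 = TRUE, paired = FALSE) {
  stopifnot(inherits(m, "OmicsMatrix"))
  if (length(intersect(group_a, group_b))) stop("groups overlap")
  va <- m$values[, group_a, drop = FALSE]
  vb <- m$values[, group_b, drop = FALSE]
  lt <- function(x) if (log2) base::log2(x + 1) else x
  X <- t(cbind(lt(va), lt(vb)))
  y <- rep(c("a", "b"), c(length(group_a), length(group_b)))
  vip <- plsda_vip(X, y, n_components = n_components, drop_constant = TRUE)
  pv <- vapply(rownames(m$values), function(g) {
    xa <- lt(va[g, ]); xb <- lt(vb[g, ])
    if (paired) {
      if (length(xa) != length(xb)) stop("paired mode needs equal replicates")
      d <- xb - xa
      if (stats::sd(d) == 0) return(if (mean(d) == 0) 1 else 0)
      stats::t.test(d)$p.value
    } else welch_t_test(xa, xb)$p
  }, numeric(1L))
  mA <- rowMeans(va); mB <- rowMeans(vb)
  pad <- mA == 0 | mB == 0
  fdr <- bh_adjust(unname(pv))
  out <- data.frame(feature_id = rownames(m$values),
                    mean_a = mA, mean_b = mB,
                    log2fc = base::log2((mB + 0.5 * pad) / (mA + 0.5 * pad)),
                    p = unname(pv), fdr = fdr,
                    vip = unname(vip[rownames(m$values)]),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$call <- call_dams(out, cfg, calls_only = TRUE)
  out
}

#' Call differentially accumulated metabolites
#'
#' Keeps features with VIP strictly above `cfg$vip_cut` and FDR below
#' `cfg$fdr_metab`; direction comes from the sign of the mean difference.
#'
#' @param tbl a [vip_test()] table (columns `vip`, `fdr`, `mean_a`,
#'   `mean_b`).
#' @param cfg a [threshold_config()].
#' @param calls_only return the per-feature call vector instead of the
#'   filtered table.
#' @return the called subset of `tbl` (or a call vector).
#' @export
call_dams <- function(tbl, cfg = threshold_config(), calls_only = FALSE) {
  kept <- !is.na(tbl$vip) & tbl$vip > cfg$vip_cut & tbl$fdr < cfg$fdr_metab
  call <- ifelse(kept & tbl$mean_b > tbl$mean_a, "up",
                 ifelse(kept & tbl$mean_b < tbl$mean_a, "down", "ns"))
  if (calls_only) return(call)
  out <- tbl[kept, , drop = FALSE]
  out$call <- call[kept]
  out
}

#' Two-way analysis of variance (Type II)
#'
#' F tests for the two main effects and their interaction from Type-II
#' sums of squares, for complete (balanced or unbalanced) designs with
#' replication.
#'
#' @param values numeric response, one per observation.
#' @param factor_a,factor_b factor labels, >= 2 levels each.
#' @return data.frame with rows `A`, `B`, `A:B`: columns `term`, `F`, `p`.
#' @export
two_way_anova <- function(values, factor_a, factor_b) {
  A <- factor(factor_a); B <- factor(factor_b)
  if (nlevels(A) < 2L || nlevels(B) < 2L) stop("need >= 2 levels per factor")
  cells <- table(A, B)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    stop("empty design cell(s): ",
         paste(rownames(cells)[empty[, 1L]], colnames(cells)[empty[, 2L]],
               sep = " x ", collapse = ", "))
  }
  terms <- c("A", "B", "A:B")
  if (stats::var(values) == 0)
    return(data.frame(term = terms, F = 0, p = 1, stringsAsFactors = FALSE))
  fit <- stats::lm(values ~ A * B)
  aa <- car::Anova(fit, type = 2)
  data.frame(term = terms,
             F = aa[terms, "F value"], p = aa[terms, "Pr(>F)"],
             stringsAsFactors = FALSE, row.names = NULL)
}
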