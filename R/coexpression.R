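#' Co-expression network parameters
#'
#' @param beta soft-threshold power (>= 1); the trio study uses 18 for
#'   genes and 17 for metabolites.
#' @param network_type `"unsigned"` (|cor|^beta) or `"signed"`
#'   (((1+cor)/2)^beta).
#' @param min_module_size branches smaller than this become grey
#'   (unassigned).
#' @param merge_cut_height modules whose eigengene dissimilarity
#'   (1 - cor) falls below this are merged; 0.25 per the study.
#' @param static_cut_height dendrogram cut height; `NULL` means 0.99 of
#'   the tallest merge.
#' @return a list of class `NetworkConfig`.
#' @export
network_config <- function(beta = 18, network_type = c("unsigned", "signed"),
                           min_module_size = 30, merge_cut_height = 0.25,
                           static_cut_height = NULL) {
  network_type <- match.arg(network_type)
  if (beta < 1) stop("beta must be >= 1")
  if (merge_cut_height < 0 || merge_cut_height >= 1)
    stop("merge_cut_height must lie in [0, 1)")
  structure(list(beta = beta, network_type = network_type,
                 min_module_size = min_module_size,
                 merge_cut_height = merge_cut_height,
                 static_cut_height = static_cut_height),
            class = "NetworkConfig")
}

#' Soft-threshold adjacency
#'
#' Pairwise feature correlation raised to the power beta; unsigned
#' networks use |cor|^beta, signed networks ((1+cor)/2)^beta. Diagonal is
#' 1. Zero-variance features are dropped with a warning.
#'
#' @param expr feature x sample numeric matrix (>= 3 samples).
#' @param cfg a [network_config()].
#' @return adjacency matrix over the retained features.
#' @export
soft_adjacency <- function(expr, cfg = network_config()) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3L) stop("need >= 3 samples")
  sds <- apply(expr, 1L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance feature(s): ",
            paste(rownames(expr)[sds == 0], collapse = ", "))
    expr <- expr[sds > 0, , drop = FALSE]
  }
  r <- stats::cor(t(expr))
  a <- if (cfg$network_type == "unsigned") abs(r)^cfg$beta
       else ((1 + r) / 2)^cfg$beta
  diag(a) <- 1
  a
}

#' Topological overlap similarity
#'
#' `TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 -
#' a_ij)` with `k_i = sum_{u != i} a_iu`; the diagonal is 1. Credits
#' shared neighborhoods so that the clustering distance 1 - TOM is
#' robust to single weak edges.
#'
#' @param a symmetric adjacency with entries in `[0, 1]` and unit
#'   diagonal.
#' @return the TOM matrix (same dimensions, entries in `[0, 1]`).
#' @export
tom_similarity <- function(a) {
  a <- as.matrix(a)
  if (nrow(a) != ncol(a)) stop("adjacency must be square")
  if (max(abs(a - t(a))) > 1e-10) stop("adjacency not symmetric")
  if (any(a < 0) || any(a > 1)) stop("adjacency entries must lie in [0, 1]")
  if (max(abs(diag(a) - 1)) > 1e-10) stop("adjacency diagonal must be 1")
  a0 <- a; diag(a0) <- 0
  shared <- a0 %*% a0                  # sum over u != i, j (diag of a0 is 0)
  k <- rowSums(a0)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (shared + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

MODULE_PALETTE <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                    "black", "pink", "magenta", "purple", "greenyellow",
                    "tan", "salmon", "cyan", "midnightblue", "lightcyan",
                    "grey60", "lightgreen", "lightyellow", "royalblue")

module_names <- function(n) {
  if (n <= length(MODULE_PALETTE)) MODULE_PALETTE[seq_len(n)]
  else c(MODULE_PALETTE, paste0("module", seq_len(n - length(MODULE_PALETTE))))
}

#' Cut the TOM dendrogram into modules and merge similar ones
#'
#' Average-linkage clustering of 1 - TOM, a static branch cut (default at
#' 0.99 of the tallest merge), small branches set to grey, then iterative
#' merging of modules whose eigengenes are closer than
#' `merge_cut_height` in 1 - cor distance. Module labels are WGCNA-style
#' color names ordered by decreasing size; `"grey"` marks unassigned
#' features.
#'
#' @param expr feature x sample matrix (rows aligned with `diss`).
#' @param diss square dissimilarity matrix, typically `1 -
#'   tom_similarity(a)`.
#' @param cfg a [network_config()].
#' @return list of class `ModuleResult`: `labels` (named by feature),
#'   `eigengenes` (module x sample), `sizes`, `dendrogram`.
#' @export
cut_modules <- function(expr, diss, cfg = network_config()) {
  expr <- as.matrix(expr)
  if (nrow(expr) != nrow(diss)) stop("expr rows must match diss rows")
  if (is.null(rownames(expr))) rownames(expr) <- paste0("f", seq_len(nrow(expr)))
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  h <- if (is.null(cfg$static_cut_height)) 0.99 * max(hc$height)
       else cfg$static_cut_height
  branch <- stats::cutree(hc, h = h)
  sizes <- table(branch)
  keep <- names(sizes)[sizes >= cfg$min_module_size]
  labels <- rep("grey", nrow(expr))
  names(labels) <- rownames(expr)
  if (length(keep)) {
    ord <- keep[order(-sizes[keep])]
    cols <- module_names(length(ord))
    for (i in seq_along(ord)) labels[branch == as.integer(ord[i])] <- cols[i]
  } else warning("all features unassigned (grey)")
  # eigengene-based merging, closest pair first, until stable
  repeat {
    mods <- setdiff(unique(labels), "grey")
    if (length(mods) < 2L) break
    me <- module_eigengene(expr, labels)
    dme <- 1 - stats::cor(t(me))
    diag(dme) <- Inf
    if (min(dme) >= cfg$merge_cut_height || cfg$merge_cut_height == 0) break
    idx <- which(dme == min(dme), arr.ind = TRUE)[1L, ]
    a <- rownames(dme)[idx[1L]]; b <- rownames(dme)[idx[2L]]
    into <- if (sum(labels == a) >= sum(labels == b)) a else b
    from <- if (into == a) b else a
    labels[labels == from] <- into
  }
  me <- if (length(setdiff(unique(labels), "grey")))
    module_eigengene(expr, labels) else
    matrix(numeric(0), 0, ncol(expr), dimnames = list(NULL, colnames(expr)))
  structure(list(labels = labels, eigengenes = me,
                 sizes = table(labels), dendrogram = hc),
            class = "ModuleResult")
}

#' Module eigengenes
#'
#' One summary profile per non-grey module: the leading left singular
#' vector (over samples) of the standardized member submatrix, scaled to
#' unit norm and sign-oriented so that its mean correlation with the
#' member profiles is nonnegative. A single-feature module falls back to
#' that feature's standardized profile.
#'
#' @param expr feature x sample matrix.
#' @param labels module label per feature (grey = unassigned).
#' @return module x sample eigengene matrix.
#' @export
module_eigengene <- function(expr, labels) {
  expr <- as.matrix(expr)
  mods <- setdiff(unique(labels), "grey")
  if (!length(mods)) stop("no non-grey module")
  out <- matrix(NA_real_, length(mods), ncol(expr),
                dimnames = list(mods, colnames(expr)))
  for (mod in mods) {
    sub <- expr[labels == mod, , drop = FALSE]
    z <- t(apply(sub, 1L, function(x) {
      s <- stats::sd(x)
      if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
    }))
    if (nrow(sub) == 1L) {
      e <- z[1L, ]
      n <- sqrt(sum(e^2))
      e <- if (n > 0) e / n else e
    } else {
      e <- svd(t(z), nu = 1L, nv = 0L)$u[, 1L]
    }
    ok <- apply(sub, 1L, stats::sd) > 0
    if (any(ok) && stats::sd(e) > 0) {
      orient <- mean(stats::cor(e, t(sub[ok, , drop = FALSE])))
      if (!is.na(orient) && orient < 0) e <- -e
    }
    out[mod, ] <- e
  }
  out
}

#' Module-trait correlation against a binary trait
#'
#' Pearson correlation of each module eigengene with a per-sample 0/1
#' trait (parents coded 0, hybrids 1 in the trio design) and the t-based
#' correlation-test p. A module is flagged significant at |r| > 0.6 and
#' p < 0.05.
#'
#' @param eigengenes module x sample matrix from [module_eigengene()].
#' @param trait numeric or logical per-sample vector with both levels
#'   present.
#' @return data.frame: `module`, `trait_r`, `p`, `significant`, `flag`.
#' @export
module_trait_correlation <- function(eigengenes, trait) {
  trait <- as.numeric(trait)
  if (length(unique(trait)) < 2L) stop("trait must have both levels")
  if (length(trait) != ncol(eigengenes))
    stop("trait length must match eigengene samples")
  out <- NULL
  for (mod in rownames(eigengenes)) {
    e <- eigengenes[mod, ]
    if (stats::sd(e) == 0) {
      out <- rbind(out, data.frame(module = mod, trait_r = NA_real_,
                                   p = NA_real_, significant = FALSE,
                                   flag = "constant eigengene",
                                   stringsAsFactors = FALSE))
      next
    }
    fit <- stats::cor.test(e, trait)
    r <- unname(fit$estimate)
    out <- rbind(out, data.frame(module = mod, trait_r = r, p = fit$p.value,
                                 significant = abs(r) > 0.6 &&
                                   fit$p.value < 0.05,
                                 flag = "", stringsAsFactors = FALSE))
  }
  out
}

#' Scale-free-fit diagnostic for candidate soft powers
#'
#' For each power, fits log10 p(k) against log10 k over 10 connectivity
#' bins and reports the fit R^2 (signed negative when the slope is
#' positive, i.e. not scale-free) and mean connectivity. Advisory only;
#' the pipeline never picks beta automatically.
#'
#' @param expr feature x sample matrix.
#' @param powers candidate beta values.
#' @param network_type as in [network_config()].
#' @return data.frame: `beta`, `r_squared`, `slope`, `mean_connectivity`.
#' @export
pick_soft_threshold <- function(expr, powers = c(1:10, 12, 14, 16, 18, 20),
                                network_type = "unsigned") {
  out <- NULL
  for (b in powers) {
    a <- soft_adjacency(expr, network_config(beta = b,
                                             network_type = network_type))
    k <- rowSums(a) - 1
    brk <- unique(stats::quantile(k, probs = seq(0, 1, length.out = 11L)))
    if (length(brk) < 3L) { r2 <- NA_real_; sl <- NA_real_ }
    else {
      bin <- cut(k, breaks = brk, include.lowest = TRUE)
      dk <- tapply(k, bin, mean)
      pk <- tapply(k, bin, length) / length(k)
      ok <- dk > 0 & pk > 0
      fit <- stats::lm(log10(pk[ok]) ~ log10(dk[ok]))
      sl <- unname(stats::coef(fit)[2L])
      r2 <- summary(fit)$r.squared * ifelse(sl < 0, 1, -1)
    }
    out <- rbind(out, data.frame(beta = b, r_squared = r2, slope = sl,
                                 mean_connectivity = mean(k),
                                 stringsAsFactors = FALSE))
  }
  out
}
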