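# Independent oracles, coded from first principles and kept separate from
# the package's implementation paths.

# step-up FDR by explicit enumeration: q_(i) = min_{j >= i} m * p_(j) / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, m * p[o[i]] / i)
    q_sorted[i] <- min(running, 1)
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# topological overlap by triple loop
oracle_tom <- function(a) {
  n <- nrow(a)
  k <- numeric(n)
  for (i in seq_len(n)) for (u in seq_len(n)) if (u != i) k[i] <- k[i] + a[i, u]
  tom <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { tom[i, j] <- 1; next }
    num <- a[i, j]
    for (u in seq_len(n)) if (u != i && u != j) num <- num + a[i, u] * a[u, j]
    tom[i, j] <- num / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# hypergeometric upper tail by enumerating every n-subset of the universe
oracle_hypergeom <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)       # term members are items 1..K
  mean(hits >= k)
}

# Welch statistic straight from the textbook formula
oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# one-component PLS VIP in closed form: w ~ Xs' y, VIP_j = sqrt(p)|w_j|/||w||
oracle_vip_1comp <- function(X, y) {
  Xs <- scale(X)
  yy <- as.numeric(as.factor(y)); yy <- yy - mean(yy)
  w <- drop(crossprod(Xs, yy))
  sqrt(ncol(Xs)) * abs(w) / sqrt(sum(w^2))
}

# median-of-ratios size factors by explicit loops
oracle_size_factors <- function(counts) {
  n <- nrow(counts)
  geo <- apply(counts, 1L, function(r) exp(mean(log(r))))
  use <- which(apply(counts, 1L, function(r) all(r > 0)))
  sf <- apply(counts[use, , drop = FALSE], 2L, function(col)
    stats::median(col / geo[use]))
  sf / exp(mean(log(sf)))
}

# average-linkage agglomeration on a distance matrix; returns merge heights
oracle_average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dij <- mean(d[clusters[[i]], clusters[[j]]])
      if (dij < bestd) { bestd <- dij; best <- c(i, j) }
    }
    heights <- c(heights, bestd)
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  heights
}

# twelve-type table as one predicate per type, matched with explicit
# precedence (overdominance, then ELD, then additive)
oracle_classify <- function(hf, hm, fm, f, h, m) {
  sig_hf <- hf != "ns"; sig_hm <- hm != "ns"; sig_fm <- fm != "ns"
  preds <- list(
    VII  = hf == "down" && hm == "down" && fm == "down",
    VIII = hf == "down" && hm == "down" && fm == "ns",
    IX   = hf == "down" && hm == "down" && fm == "up",
    X    = hf == "up" && hm == "up" && fm == "down",
    XI   = hf == "up" && hm == "up" && fm == "ns",
    XII  = hf == "up" && hm == "up" && fm == "up",
    III  = sig_hf && !sig_hm && m > f,
    IV   = sig_hf && !sig_hm && m <= f,
    V    = sig_hm && !sig_hf && f > m,
    VI   = sig_hm && !sig_hf && f <= m,
    I    = sig_hf && sig_hm && sig_fm && hf != hm &&
             h > min(f, m) && h < max(f, m) && f > m,
    II   = sig_hf && sig_hm && sig_fm && hf != hm &&
             h > min(f, m) && h < max(f, m) && m > f
  )
  hit <- names(preds)[vapply(preds, isTRUE, logical(1L))]
  if (length(hit)) hit[1L] else "unclassified"
}

# Type-II two-way ANOVA from residual sums of squares of nested fits
oracle_two_way_anova <- function(y, A, B) {
  A <- factor(A); B <- factor(B)
  rss <- function(form) sum(stats::lm.fit(stats::model.matrix(form),
                                          y)$residuals^2)
  rss_full <- rss(~ A * B); rss_ab <- rss(~ A + B)
  rss_a <- rss(~ A); rss_b <- rss(~ B)
  df_a <- nlevels(A) - 1L; df_b <- nlevels(B) - 1L
  df_int <- df_a * df_b
  df_res <- length(y) - nlevels(A) * nlevels(B)
  ms_res <- rss_full / df_res
  f <- c((rss_b - rss_ab) / df_a,
         (rss_a - rss_ab) / df_b,
         (rss_ab - rss_full) / df_int) / ms_res
  p <- stats::pf(f, c(df_a, df_b, df_int), df_res, lower.tail = FALSE)
  data.frame(term = c("A", "B", "A:B"), F = f, p = p,
             stringsAsFactors = FALSE)
}
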