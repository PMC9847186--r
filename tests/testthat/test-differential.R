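test_that("size factors match median-of-ratios and scale equivariance", {
  v <- matrix(rep(c(10, 20, 30), 4), 4, 3, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  v[, ] <- 50
  expect_equal(unname(size_factors(omics_matrix(v, "counts"))), rep(1, 3),
               tolerance = 1e-12)
  # identical samples with one exactly doubled
  v2 <- matrix(rep(make_counts(100, 1, mu = 200)$values + 1, 4), 100, 4,
               dimnames = list(paste0("g", 1:100), paste0("s", 1:4)))
  v2[, 3] <- v2[, 3] * 2
  sf <- size_factors(omics_matrix(v2, "counts"))
  expect_equal(unname(sf[3] / sf[1]), 2, tolerance = 1e-10)
  # brute-force oracle on a random NB matrix
  m <- make_counts(200, 6, mu = 50, seed = 11)
  expect_equal(size_factors(m), oracle_size_factors(m$values),
               tolerance = 1e-12)
})

test_that("size factors are proportional to the DESeq2 reference", {
  skip_if_not_installed("DESeq2")
  m <- make_counts(300, 6, mu = 80, seed = 5)
  ours <- size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m$values)
  # same estimator up to median interpolation convention (ratio-scale vs
  # log-scale median), so agreement is to ~1%, not machine precision
  expect_equal(unname(ours / ref), rep(unname(ours[1] / ref[1]), 6),
               tolerance = 0.01)
})

test_that("nb_test is exact on duplicated groups and symmetric under swap", {
  m <- make_counts(50, 3, mu = 100, seed = 2)
  v <- cbind(m$values, m$values)
  colnames(v) <- paste0("s", 1:6)
  dup <- omics_matrix(v, "counts")
  res <- nb_test(dup, paste0("s", 1:3), paste0("s", 4:6))
  expect_equal(res$log2fc, rep(0, 50))
  expect_true(all(res$p > 0.999))
  expect_error(nb_test(dup, paste0("s", 1:3), paste0("s", 3:5)), "overlap")
  m2 <- make_counts(100, 6, mu = 150, seed = 3)
  a <- paste0("s0", 1:3); b <- paste0("s0", 4:6)
  fwd <- nb_test(m2, a, b); rev <- nb_test(m2, b, a)
  expect_equal(fwd$log2fc, -rev$log2fc, tolerance = 1e-12)
  expect_equal(fwd$p, rev$p, tolerance = 1e-12)
})

test_that("nb_test finds planted four-fold changes at the study thresholds", {
  set.seed(21)
  n <- 1000
  v <- cbind(matrix(stats::rnbinom(n * 3, mu = 200, size = 20), n),
             matrix(stats::rnbinom(n * 3, mu = 800, size = 20), n))
  dimnames(v) <- list(sprintf("g%04d", 1:n), paste0("s", 1:6))
  res <- nb_test(omics_matrix(v, "counts"), paste0("s", 1:3),
                 paste0("s", 4:6), sf = stats::setNames(rep(1, 6),
                                                        paste0("s", 1:6)))
  expect_gte(mean(res$call == "up"), 0.8)
})

test_that("BH adjustment reproduces the step-up enumeration", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(8)
  for (i in 1:20) {
    p <- stats::runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
  expect_warning(bh_adjust(c(0.1, NaN)), "propagated")
  # discoveries nonincreasing in the FDR cut
  q <- bh_adjust(stats::runif(200))
  cuts <- seq(0.05, 0.5, by = 0.05)
  disc <- vapply(cuts, function(cc) sum(q < cc), integer(1))
  expect_true(all(diff(disc) >= 0))
})

test_that("Welch test matches the textbook formula and its conventions", {
  expect_equal(welch_t_test(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_equal(welch_t_test(c(1, 2, 3), c(1, 2, 3))$p, 1)
  shifted <- welch_t_test(c(1, 2, 3), c(11.0001, 12.0002, 13.0001))
  expect_lt(shifted$p, 1e-3)
  expect_equal(welch_t_test(c(2, 2, 2), c(2, 2))$p, 1)
  expect_warning(res0 <- welch_t_test(c(2, 2, 2), c(3, 3)), "zero variance")
  expect_equal(res0$p, 0)
  set.seed(13)
  for (i in 1:10) {
    x <- stats::rnorm(sample(3:9, 1)); y <- stats::rnorm(sample(3:9, 1), 0.5)
    got <- welch_t_test(x, y); want <- oracle_welch(x, y)
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(got$df, want$df, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
})

test_that("VIP scores obey the normalization identities and the 1-component oracle", {
  set.seed(6)
  X1 <- matrix(stats::rnorm(12), 12, 1)
  y <- rep(c("a", "b"), each = 6)
  expect_equal(unname(plsda_vip(X1, y, 1)), 1.0, tolerance = 1e-12)
  # exact duplicate features get equal VIPs
  X <- matrix(stats::rnorm(12 * 4), 12, 4)
  X[, 4] <- X[, 1]
  vip <- plsda_vip(X, y, 2)
  expect_equal(unname(vip[1]), unname(vip[4]), tolerance = 1e-10)
  expect_equal(mean(vip^2), 1, tolerance = 1e-8)
  # independent matrix-algebra oracle at one component
  X2 <- matrix(stats::rnorm(12 * 8), 12, 8,
               dimnames = list(NULL, paste0("f", 1:8)))
  expect_equal(unname(plsda_vip(X2, y, 1)), unname(oracle_vip_1comp(X2, y)),
               tolerance = 1e-10)
  X3 <- X2; X3[, 2] <- 5
  expect_error(plsda_vip(X3, y, 1), "f2")
  expect_warning(plsda_vip(X3, y, 1, drop_constant = TRUE), "f2")
})

test_that("DAM calling enforces strict VIP and FDR cuts", {
  tbl <- data.frame(feature_id = c("a", "b", "c", "d"),
                    mean_a = c(1, 1, 1, 1), mean_b = c(2, 0.5, 2, 2),
                    vip = c(1.0, 2.0, 2.0, 1.4),
                    fdr = c(0.01, 0.2, 0.01, 0.04))
  got <- call_dams(tbl, threshold_config())
  expect_identical(got$feature_id, c("c", "d"))   # vip==1 and fdr 0.2 excluded
  expect_identical(got$call, c("up", "up"))
  # brute-force agreement on a random table
  set.seed(10)
  tb <- data.frame(feature_id = paste0("m", 1:200), mean_a = stats::runif(200),
                   mean_b = stats::runif(200), vip = stats::rchisq(200, 1),
                   fdr = stats::runif(200))
  got2 <- call_dams(tb, threshold_config())
  want <- tb$feature_id[tb$vip > 1 & tb$fdr < 0.05]
  expect_identical(got2$feature_id, want)
})

test_that("vip_test pipeline calls planted metabolite shifts", {
  set.seed(30)
  v <- matrix(stats::rlnorm(40 * 12, meanlog = 6, sdlog = 0.15), 40, 12,
              dimnames = list(paste0("m", 1:40), paste0("s", 1:12)))
  v[1:5, 7:12] <- v[1:5, 7:12] * 8               # strong planted shift
  res <- vip_test(omics_matrix(v, "abundance"), paste0("s", 1:6),
                  paste0("s", 7:12))
  expect_true(all(res$call[1:5] == "up"))
  expect_true(mean(res$call[6:40] == "ns") > 0.8)
})

test_that("two-way ANOVA handles degenerate and constructed designs, matches oracle", {
  A <- rep(c("x", "y"), each = 8); B <- rep(c("p", "q", "r", "s"), 4)
  const <- two_way_anova(rep(5, 16), A, B)
  expect_equal(const$F, rep(0, 3))
  expect_equal(const$p, rep(1, 3))
  set.seed(12)
  y <- as.numeric(factor(A)) * 2 + as.numeric(factor(B)) * 3 +
    stats::rnorm(16, 0, 1e-3)
  add <- two_way_anova(y, A, B)
  expect_lt(add$p[1], 1e-10); expect_lt(add$p[2], 1e-10)
  # the interaction carries only the noise: orders of magnitude below the
  # main effects and nowhere near significance
  expect_gt(add$p[3], 0.01)
  expect_gt(add$F[1] / add$F[3], 1e4)
  # random balanced 2 x 4 with 6 replicates against the projection oracle
  A2 <- rep(c("x", "y"), each = 24); B2 <- rep(rep(letters[1:4], each = 6), 2)
  y2 <- stats::rnorm(48, as.numeric(factor(A2)) + as.numeric(factor(B2)))
  got <- two_way_anova(y2, A2, B2)
  want <- oracle_two_way_anova(y2, A2, B2)
  expect_equal(got$F, want$F, tolerance = 1e-8)
  expect_equal(got$p, want$p, tolerance = 1e-8)
  expect_error(two_way_anova(y[1:6], rep("x", 6),
                             c("p", "p", "q", "q", "r", "r")), "levels")
  expect_error(two_way_anova(c(y, 1), c(A, "x"), c(B, "t")), "y x t")
})
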