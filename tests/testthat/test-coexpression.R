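test_that("soft adjacency is the powered correlation", {
  set.seed(25)
  base <- stats::rnorm(10)
  expr <- rbind(f1 = 3 * base + 1, f2 = 5 * base - 2)   # perfectly correlated
  for (b in c(1, 6, 18))
    expect_equal(soft_adjacency(expr, network_config(beta = b))[1, 2], 1,
                 tolerance = 1e-12)
  # cor 0.5, beta 2 -> 0.25 (construct exact correlation 0.5)
  x <- stats::rnorm(50); y <- stats::rnorm(50)
  y <- stats::residuals(stats::lm(y ~ x))
  xs <- scale(x)[, 1]; ys <- scale(y)[, 1]
  z <- 0.5 * xs + sqrt(1 - 0.25) * ys
  expr2 <- rbind(a = xs, b = z)
  expect_equal(soft_adjacency(expr2, network_config(beta = 2))[1, 2],
               0.25, tolerance = 1e-10)
  # elementwise oracle on a random 20-feature matrix
  expr3 <- matrix(stats::rnorm(20 * 12), 20, 12,
                  dimnames = list(paste0("f", 1:20), NULL))
  a <- soft_adjacency(expr3, network_config(beta = 7))
  want <- abs(stats::cor(t(expr3)))^7; diag(want) <- 1
  expect_equal(a, want, tolerance = 1e-12)
  expect_error(network_config(beta = 0.5), "beta")
})

test_that("TOM matches its definition on edge cases and random graphs", {
  id <- diag(5)
  tom0 <- tom_similarity(id)
  expect_equal(tom0, diag(5))
  ones <- matrix(1, 6, 6)
  expect_equal(tom_similarity(ones), ones)
  # two-feature systems have TOM == adjacency
  a2 <- matrix(c(1, 0.3, 0.3, 1), 2)
  expect_equal(tom_similarity(a2), a2, tolerance = 1e-12)
  for (n in c(6, 12)) {
    a <- make_adjacency(n, seed = n)
    tom <- tom_similarity(a)
    expect_equal(tom, oracle_tom(a), tolerance = 1e-12)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    expect_equal(tom, t(tom), tolerance = 1e-12)
  }
  bad <- make_adjacency(4); bad[1, 2] <- bad[1, 2] + 1e-3
  expect_error(tom_similarity(bad), "symmetric")
})

test_that("planted correlation blocks come back as exactly two modules", {
  expr <- planted_expr(c(40, 40))
  cfg <- network_config(beta = 6, min_module_size = 30)
  tom <- tom_similarity(soft_adjacency(expr, cfg))
  res <- cut_modules(expr, 1 - tom, cfg)
  mods <- setdiff(unique(res$labels), "grey")
  expect_equal(length(mods), 2L)
  expect_equal(unname(res$sizes[mods]), c(40L, 40L), ignore_attr = TRUE)
  # each planted block maps to a single label
  expect_equal(length(unique(res$labels[1:40])), 1L)
  expect_equal(length(unique(res$labels[41:80])), 1L)
  # labels permute with features
  perm <- sample(nrow(expr))
  res_p <- cut_modules(expr[perm, ], (1 - tom)[perm, perm], cfg)
  expect_true(all(table(res$labels[perm], res_p$labels) %in%
                    c(0L, 40L)))
})

test_that("module-size floor and merge height behave as documented", {
  expr <- planted_expr(c(10, 10))
  cfg_big <- network_config(beta = 6, min_module_size = 25)
  tom <- tom_similarity(soft_adjacency(expr, cfg_big))
  expect_warning(res <- cut_modules(expr, 1 - tom, cfg_big), "grey")
  expect_true(all(res$labels == "grey"))
  # merge_cut_height = 0 never merges; raising it never adds modules
  expr2 <- planted_expr(c(30, 30, 30), rho = 0.8, seed = 33)
  counts <- vapply(c(0, 0.25, 0.6, 0.9), function(h) {
    cfg <- network_config(beta = 6, min_module_size = 20,
                          merge_cut_height = h)
    tom2 <- tom_similarity(soft_adjacency(expr2, cfg))
    res2 <- cut_modules(expr2, 1 - tom2, cfg)
    length(setdiff(unique(res2$labels), "grey"))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("eigengenes are unit-norm oriented leading components", {
  profile <- stats::rnorm(15)
  expr <- t(vapply(1:5, function(i) 2 * profile + i, numeric(15)))
  rownames(expr) <- paste0("f", 1:5)
  me <- module_eigengene(expr, rep("blue", 5))
  expect_equal(sum(me["blue", ]^2), 1, tolerance = 1e-12)
  expect_gt(stats::cor(me["blue", ], profile), 0.999)
  # svd oracle up to sign on a random module
  set.seed(35)
  expr2 <- matrix(stats::rnorm(8 * 12), 8, 12,
                  dimnames = list(paste0("f", 1:8), NULL))
  me2 <- module_eigengene(expr2, rep("red", 8))
  z <- t(apply(expr2, 1, function(x) (x - mean(x)) / stats::sd(x)))
  u1 <- svd(t(z))$u[, 1]
  expect_equal(abs(unname(me2["red", ])), abs(u1), tolerance = 1e-10)
  # eigengene explains at least as much variance as any member profile
  var_along <- function(dir) sum((z %*% dir)^2) / sum(dir^2)
  for (i in 1:8) expect_gte(var_along(unname(me2["red", ])) + 1e-9,
                            var_along(z[i, ]))
})

test_that("module-trait correlation flags planted hybrid suppression", {
  trait <- rep(c(0, 1), each = 10)                 # parents 0, hybrids 1
  expr <- planted_expr(c(40, 40), shift_hybrid = 2, hybrid_idx = 11:20)
  cfg <- network_config(beta = 6, min_module_size = 30)
  tom <- tom_similarity(soft_adjacency(expr, cfg))
  res <- cut_modules(expr, 1 - tom, cfg)
  mt <- module_trait_correlation(res$eigengenes, trait)
  suppressed_mod <- res$labels[1]
  row <- mt[mt$module == suppressed_mod, ]
  expect_lt(row$trait_r, -0.6)
  expect_lt(row$p, 0.05)
  expect_true(row$significant)
  # exact trait eigengene gives r = 1
  eg <- matrix(scale(trait)[, 1] / sqrt(sum(scale(trait)[, 1]^2)), 1,
               dimnames = list("m1", NULL))
  mt2 <- module_trait_correlation(eg, trait)
  expect_equal(mt2$trait_r, 1, tolerance = 1e-12)
  # orthogonal eigengene is null
  orth <- rep(c(1, -1), 10)
  mt3 <- module_trait_correlation(matrix(orth / sqrt(20), 1,
                                         dimnames = list("m2", NULL)), trait)
  expect_equal(mt3$trait_r, 0, tolerance = 1e-12)
  expect_false(mt3$significant)
})
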