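test_that("mid-parent profiles average paired parental replicates", {
  sheet <- tiny_sheet()
  v <- matrix(stats::rlnorm(60 * 12, 4), 60, 12,
              dimnames = list(paste0("g", 1:60), sheet$sample_id))
  m <- omics_matrix(v, "abundance")
  trio <- trio_design(sheet, "BM", "Dk")
  mp <- midparent_profile(m, trio)
  expect_equal(ncol(mp$values), 3)
  expect_equal(rowMeans(mp$values),
               (rowMeans(v[, trio$female_samples]) +
                  rowMeans(v[, trio$male_samples])) / 2, tolerance = 1e-12)
  # female == male -> MPV == either parent
  v2 <- v; v2[, trio$male_samples] <- v2[, trio$female_samples]
  mp2 <- midparent_profile(omics_matrix(v2, "abundance"), trio)
  expect_equal(unname(mp2$values), unname(v2[, trio$female_samples]))
  # constants: F 10, M 20 -> MPV 15
  v3 <- v; v3[, trio$female_samples] <- 10; v3[, trio$male_samples] <- 20
  expect_true(all(midparent_profile(omics_matrix(v3, "abundance"),
                                    trio)$values == 15))
  expect_error(midparent_profile(omics_matrix(round(v), "counts"), trio),
               "normalized layer")
})

test_that("hybrid-vs-MPV testing is silent under additivity, loud at 2x", {
  sheet <- tiny_sheet()
  trio <- trio_design(sheet, "BM", "Dk")
  set.seed(17)
  gene_level <- stats::rlnorm(80, 5)              # tight replicates per gene
  v <- matrix(gene_level, 80, 12) *
    matrix(stats::rlnorm(80 * 12, 0, 0.01), 80)
  dimnames(v) <- list(paste0("g", 1:80), sheet$sample_id)
  # hybrid replicates exactly equal the MPV pseudo-replicates
  fem <- v[, trio$female_samples]; mal <- v[, trio$male_samples]
  v[, trio$hybrid_samples] <- (fem + mal) / 2
  res <- f1_vs_mpv(omics_matrix(v, "abundance"), trio)
  expect_true(all(res$call == "ns"))
  # hybrid at 2x MPV with tiny noise is called up everywhere
  v[, trio$hybrid_samples] <- (fem + mal) *
    (1 + matrix(stats::rnorm(80 * 3, 0, 1e-4), 80))
  res2 <- f1_vs_mpv(omics_matrix(v, "abundance"), trio)
  expect_true(all(res2$call == "up"))
})

test_that("canonical patterns hit all twelve types and the reciprocal-cross view", {
  cl <- function(hf, hm, fm, f, h, m)
    classify_inheritance(hf, hm, fm, f, h, m)
  expect_equal(cl("down", "up", "up", 30, 20, 10), "I")    # between, F higher
  expect_equal(cl("up", "down", "down", 10, 20, 30), "II")
  expect_equal(cl("down", "ns", "down", 10, 32, 30), "III") # like male, M higher
  expect_equal(cl("up", "ns", "up", 30, 11, 10), "IV")
  expect_equal(cl("ns", "up", "up", 30, 31, 10), "V")       # like female, F higher
  expect_equal(cl("ns", "down", "down", 10, 11, 30), "VI")
  expect_equal(cl("down", "down", "down", 10, 2, 30), "VII")
  expect_equal(cl("down", "down", "ns", 10, 2, 10), "VIII")
  expect_equal(cl("down", "down", "up", 30, 2, 10), "IX")
  expect_equal(cl("up", "up", "down", 10, 99, 30), "X")
  expect_equal(cl("up", "up", "ns", 10, 99, 10), "XI")
  expect_equal(cl("up", "up", "up", 30, 99, 10), "XII")
  expect_equal(cl("ns", "ns", "ns", 10, 10, 10), "unclassified")
  expect_error(cl("sideways", "ns", "ns", 1, 1, 1), "calls")
  # hybrid expression pinned to B73: ELD-F (type V) when B73 is the female
  # parent (cross BM), ELD-M (type III) in the reciprocal cross MB
  b73 <- 40; mo17 <- 10; hyb <- 41
  expect_equal(cl("ns", "up", "up", f = b73, h = hyb, m = mo17), "V")
  expect_equal(cl("up", "ns", "down", f = mo17, h = hyb, m = b73), "III")
})

test_that("category roll-up is the fixed total function of type", {
  one_each <- data.frame(type = c("I", "II", "III", "IV", "V", "VI", "VII",
                                  "VIII", "IX", "X", "XI", "XII"))
  tall <- categorize(one_each)
  expect_equal(as.integer(tall$category_counts[c("additive", "ELD_F",
                                                 "ELD_M", "overdominant")]),
               c(2L, 2L, 2L, 6L))
  expect_equal(tall$non_additive, 10L)
  none <- categorize(data.frame(type = rep("unclassified", 5)))
  expect_equal(as.integer(none$category_counts["unclassified"]), 5L)
  expect_equal(none$non_additive, 0L)
})

test_that("set overlaps decompose unions exactly", {
  both <- set_overlaps(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(both$exclusive$signature, "A&B")
  expect_equal(both$exclusive$count, 2L)
  disj <- set_overlaps(list(A = c("x"), B = c("y", "z")))
  expect_setequal(disj$exclusive$signature, c("A", "B"))
  expect_equal(disj$union_size, 3L)
  set.seed(14)
  sets <- lapply(1:4, function(i) sample(paste0("f", 1:100), 40))
  names(sets) <- LETTERS[1:4]
  got <- set_overlaps(sets)
  expect_equal(sum(got$exclusive$count), got$union_size)
  # brute-force membership enumeration
  uni <- unique(unlist(sets))
  want <- table(vapply(uni, function(f)
    paste(names(sets)[vapply(sets, function(s) f %in% s, logical(1))],
          collapse = "&"), character(1)))
  expect_equal(stats::setNames(got$exclusive$count, got$exclusive$signature),
               stats::setNames(as.integer(want), names(want))[
                 got$exclusive$signature])
  expect_equal(got$pairwise["A", "B"], length(intersect(sets$A, sets$B)))
})

test_that("up/down asymmetry statistic matches the worked cases", {
  even <- updown_asymmetry(50, 50)
  expect_equal(even$chi2, 0)
  expect_equal(even$p, 1)
  skew <- updown_asymmetry(60, 40)
  expect_equal(skew$chi2, 4.0, tolerance = 1e-12)
  expect_equal(skew$p, 0.0455, tolerance = 1e-3)
  # asymptotic agreement with the exact binomial at n = 10,000
  big <- updown_asymmetry(5120, 4880)
  binom <- stats::binom.test(5120, 10000)$p.value
  expect_equal(big$p, binom, tolerance = 0.02)
  expect_error(updown_asymmetry(0, 0), "no calls")
})
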