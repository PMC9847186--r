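# small fixtures built in code

make_counts <- function(n_genes = 50, n_samples = 6, mu = 100, disp = 0.05,
                        seed = 1) {
  set.seed(seed)
  v <- matrix(stats::rnbinom(n_genes * n_samples, mu = mu, size = 1 / disp),
              n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  omics_matrix(v, "counts")
}

make_abundance <- function(n = 20, samples = 6, seed = 1) {
  set.seed(seed)
  v <- matrix(stats::rlnorm(n * samples, meanlog = 5), n, samples,
              dimnames = list(sprintf("m%03d", seq_len(n)),
                              sprintf("s%02d", seq_len(samples))))
  omics_matrix(v, "abundance")
}

# valid random adjacency: symmetric, [0,1], unit diagonal
make_adjacency <- function(n, seed = 1) {
  set.seed(seed)
  a <- matrix(stats::runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  a
}

# two-condition four-genotype sheet matching simulate_trio_counts naming
tiny_sheet <- function(conditions = "Dk", reps = 3) {
  grid <- expand.grid(replicate = seq_len(reps),
                      genotype = c("B73", "Mo17", "BM", "MB"),
                      condition = conditions, stringsAsFactors = FALSE)
  role <- c(B73 = "femaleParent", Mo17 = "maleParent",
            BM = "hybrid", MB = "hybrid")
  cross <- c(B73 = NA, Mo17 = NA, BM = "BM", MB = "MB")
  sample_sheet(data.frame(
    sample_id = paste(grid$condition, grid$genotype, grid$replicate, sep = "_"),
    genotype = grid$genotype, role = unname(role[grid$genotype]),
    cross = unname(cross[grid$genotype]), condition = grid$condition,
    replicate = grid$replicate, stringsAsFactors = FALSE))
}

# enumeration grid for the classifier: every call combination x every
# assignment of {1,2,3} values to the three group means
classifier_grid <- function() {
  calls <- c("up", "down", "ns")
  vals <- expand.grid(f = 1:3, h = 1:3, m = 1:3)
  combos <- expand.grid(hf = calls, hm = calls, fm = calls,
                        stringsAsFactors = FALSE)
  merge(combos, vals)
}

# correlated block generator: rho within blocks, 0 across
planted_expr <- function(block_sizes, rho = 0.9, n_samples = 20, seed = 31,
                         shift_hybrid = NULL, hybrid_idx = NULL) {
  set.seed(seed)
  expr <- NULL
  for (b in seq_along(block_sizes)) {
    z <- stats::rnorm(n_samples)
    block <- t(vapply(seq_len(block_sizes[b]), function(i)
      sqrt(rho) * z + sqrt(1 - rho) * stats::rnorm(n_samples),
      numeric(n_samples)))
    if (!is.null(shift_hybrid) && b == 1L)
      block[, hybrid_idx] <- block[, hybrid_idx] - shift_hybrid
    expr <- rbind(expr, block)
  }
  rownames(expr) <- paste0("f", seq_len(nrow(expr)))
  expr
}
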