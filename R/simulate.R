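#' Synthetic trio-omics study design
#'
#' Parameters of the seeded generator. Defaults emulate the maize
#' reciprocal-cross study this package is built around: parents B73 and
#' Mo17 with hybrids BM and MB, four light conditions (darkness, far-red,
#' red, blue), three RNA-seq replicates and six metabolome replicates,
#' negative-binomial counts (dispersion 0.05) and log-normal metabolite
#' abundances (CV 0.2), with inheritance modes planted at a log2 parental
#' effect of 2.
#'
#' @param n_genes,n_metabolites feature counts.
#' @param conditions condition labels.
#' @param rna_reps,metab_reps biological replicates per genotype and
#'   condition.
#' @param mode_proportions named proportions over `additive`, `ELD_F`,
#'   `ELD_M`, `over_high`, `over_low`, `null`; must sum to 1. Features
#'   are allocated to modes in these exact proportions (largest
#'   remainder) and shuffled.
#' @param effect_log2fc planted log2 parental fold change (and hybrid
#'   displacement for the overdominant modes).
#' @param nb_dispersion negative-binomial dispersion of counts.
#' @param base_mean_log_range log2 range the per-gene base mean is drawn
#'   from (uniform).
#' @param library_size expected column sum of the count matrix.
#' @param metab_cv coefficient of variation of metabolite replicates.
#' @param condition_effect_sd sd of the per-gene, per-condition log2
#'   multiplier shared by all genotypes (mode-preserving).
#' @param module_spec optional list of planted co-expression modules,
#'   each a list with `size`, `cor` (within-module correlation) and
#'   `hybrid_shift` (log2 depression of members in hybrid samples).
#' @param seed RNG seed used by the simulators.
#' @return a list of class `SimulationDesign`.
#' @export
simulation_design <- function(n_genes = 6000, n_metabolites = 300,
                              conditions = c("Dk", "FR", "R", "B"),
                              rna_reps = 3, metab_reps = 6,
                              mode_proportions = c(additive = 1/6,
                                                   ELD_F = 1/6, ELD_M = 1/6,
                                                   over_high = 1/6,
                                                   over_low = 1/6,
                                                   null = 1/6),
                              effect_log2fc = 2.0, nb_dispersion = 0.05,
                              base_mean_log_range = c(5, 10),
                              library_size = 1e6, metab_cv = 0.2,
                              condition_effect_sd = 0.3,
                              module_spec = NULL, seed = 1L) {
  modes <- c("additive", "ELD_F", "ELD_M", "over_high", "over_low", "null")
  if (!setequal(names(mode_proportions), modes))
    stop("mode_proportions must be named over: ", paste(modes, collapse = ", "))
  mode_proportions <- mode_proportions[modes]
  if (abs(sum(mode_proportions) - 1) > 1e-8)
    stop("mode proportions must sum to 1")
  if (any(c(n_genes, n_metabolites, rna_reps, metab_reps, effect_log2fc >= 0,
            nb_dispersion, library_size) <= 0))
    stop("design parameters must be positive")
  structure(list(n_genes = n_genes, n_metabolites = n_metabolites,
                 conditions = conditions, rna_reps = rna_reps,
                 metab_reps = metab_reps,
                 mode_proportions = mode_proportions,
                 effect_log2fc = effect_log2fc,
                 nb_dispersion = nb_dispersion,
                 base_mean_log_range = base_mean_log_range,
                 library_size = library_size, metab_cv = metab_cv,
                 condition_effect_sd = condition_effect_sd,
                 module_spec = module_spec, seed = seed),
            class = "SimulationDesign")
}

# exact largest-remainder allocation of n features to modes, shuffled
allocate_modes <- function(n, prop) {
  base <- floor(n * prop)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- n * prop - base
    extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  sample(rep(names(prop), base))
}

# per-genotype expected values for one feature given its mode
mode_means <- function(mode, mu0, effect, female_higher) {
  s <- if (female_higher) 1 else -1
  if (mode == "null") return(c(F = mu0, M = mu0, H = mu0))
  muF <- mu0 * 2^(s * effect / 2)
  muM <- mu0 * 2^(-s * effect / 2)
  muH <- switch(mode,
    additive  = (muF + muM) / 2,
    ELD_F     = muF,
    ELD_M     = muM,
    over_high = max(muF, muM) * 2^effect,
    over_low  = min(muF, muM) / 2^effect)
  c(F = muF, M = muM, H = muH)
}

build_truth <- function(ids, modes, female_higher, means) {
  data.frame(feature_id = ids, mode = modes,
             higher_parent = ifelse(modes == "null", "none",
                                    ifelse(female_higher, "female", "male")),
             true_parental_log2fc = log2(means[, "F"] / means[, "M"]),
             true_hybrid_log2fc = log2(means[, "H"] /
                                         ((means[, "F"] + means[, "M"]) / 2)),
             module = "none", stringsAsFactors = FALSE, row.names = NULL)
}

trio_sheet <- function(conditions, reps, genotypes = c("B73", "Mo17", "BM", "MB")) {
  role <- c(B73 = "femaleParent", Mo17 = "maleParent",
            BM = "hybrid", MB = "hybrid")
  cross <- c(B73 = NA_character_, Mo17 = NA_character_, BM = "BM", MB = "MB")
  grid <- expand.grid(replicate = seq_len(reps), genotype = genotypes,
                      condition = conditions, stringsAsFactors = FALSE)
  sample_sheet(data.frame(
    sample_id = paste(grid$condition, grid$genotype, grid$replicate, sep = "_"),
    genotype = grid$genotype, role = unname(role[grid$genotype]),
    cross = unname(cross[grid$genotype]), condition = grid$condition,
    replicate = grid$replicate, stringsAsFactors = FALSE))
}

#' Simulate a reciprocal-cross trio RNA-seq count experiment
#'
#' Draws per-gene base means, plants the designed inheritance mode per
#' gene (see [simulation_design()] for the mode rules), applies a shared
#' per-condition multiplier, optionally superimposes correlated
#' co-expression modules, scales expected values to the target library
#' size and samples negative-binomial counts. Reciprocal hybrids (BM,
#' MB) share the hybrid mean.
#'
#' @param design a [simulation_design()].
#' @return list: `counts` (an [omics_matrix()]), `sheet`
#'   (a [sample_sheet()]), `truth` (feature-level truth table), `design`.
#' @export
simulate_trio_counts <- function(design) {
  stopifnot(inherits(design, "SimulationDesign"))
  if (!is.null(design$seed)) set.seed(design$seed)
  n <- design$n_genes
  ids <- sprintf("gene%05d", seq_len(n))
  modes <- allocate_modes(n, design$mode_proportions)
  female_higher <- sample(c(TRUE, FALSE), n, replace = TRUE)
  mu0 <- 2^stats::runif(n, design$base_mean_log_range[1L],
                        design$base_mean_log_range[2L])
  means <- t(vapply(seq_len(n), function(i)
    mode_means(modes[i], mu0[i], design$effect_log2fc, female_higher[i]),
    numeric(3L)))
  dimnames(means) <- list(ids, c("F", "M", "H"))
  truth <- build_truth(ids, modes, female_higher, means)
  sheet <- trio_sheet(design$conditions, design$rna_reps)
  geno_col <- c(B73 = "F", Mo17 = "M", BM = "H", MB = "H")
  condmult <- matrix(2^stats::rnorm(n * length(design$conditions), 0,
                                    design$condition_effect_sd),
                     n, length(design$conditions),
                     dimnames = list(ids, design$conditions))
  mu <- means[, geno_col[sheet$genotype], drop = FALSE] *
    condmult[, sheet$condition, drop = FALSE]
  colnames(mu) <- sheet$sample_id
  if (!is.null(design$module_spec)) {
    free <- which(modes == "null")    # keep modules orthogonal to modes
    if (sum(vapply(design$module_spec, `[[`, numeric(1), "size")) >
        length(free))
      stop("module_spec needs more null-mode genes than the design provides")
    is_hybrid <- sheet$role == "hybrid"
    for (mi in seq_along(design$module_spec)) {
      ms <- design$module_spec[[mi]]
      if (ms$size > length(free)) stop("module_spec exceeds gene count")
      pick <- free[seq_len(ms$size)]
      free <- free[-seq_len(ms$size)]
      z <- stats::rnorm(nrow(sheet))
      e <- matrix(stats::rnorm(ms$size * nrow(sheet)), ms$size)
      lmult <- 0.75 * (sqrt(ms$cor) * matrix(z, ms$size, nrow(sheet),
                                             byrow = TRUE) +
                         sqrt(1 - ms$cor) * e)
      shift <- if (is.null(ms$hybrid_shift)) 0 else ms$hybrid_shift
      lmult[, is_hybrid] <- lmult[, is_hybrid] - shift
      mu[pick, ] <- mu[pick, ] * 2^lmult
      truth$module[pick] <- paste0("planted", mi)
    }
  }
  mu <- sweep(mu, 2L, colSums(mu), "/") * design$library_size
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / design$nb_dispersion),
                   nrow(mu), dimnames = dimnames(mu))
  list(counts = omics_matrix(counts, "counts"), sheet = sheet,
       truth = truth, design = design)
}

DEFAULT_METAB_CLASSES <- c(lipids = 0.3004, organoheterocyclic = 0.0773,
                           acids = 0.0529, benzenoids = 0.0469,
                           oxygen = 0.0280, phenylpropanoids = 0.0156,
                           nucleosides = 0.0152, `not annotated` = 0.4497)

#' Simulate a trio metabolome experiment
#'
#' Same mode machinery as [simulate_trio_counts()] on the abundance
#' scale: log-normal replicate noise with the designed coefficient of
#' variation (mean-preserving, so CV = 0 reproduces the group means
#' exactly) and six replicates by default. Metabolites get class labels
#' (lipids, phenylpropanoids, ...) drawn at the approximate frequencies
#' of a maize seedling metabolome so class-level MPH summaries can be
#' exercised.
#'
#' @param design a [simulation_design()].
#' @param class_proportions named class-frequency vector.
#' @return list: `abundance` (an [omics_matrix()]), `sheet`, `truth`
#'   (with a `class` column), `design`.
#' @export
simulate_metabolites <- function(design,
                                 class_proportions = DEFAULT_METAB_CLASSES) {
  stopifnot(inherits(design, "SimulationDesign"))
  if (!is.null(design$seed)) set.seed(design$seed + 1L)
  n <- design$n_metabolites
  ids <- sprintf("metab%04d", seq_len(n))
  modes <- allocate_modes(n, design$mode_proportions)
  female_higher <- sample(c(TRUE, FALSE), n, replace = TRUE)
  mu0 <- 2^stats::runif(n, 10, 18)
  means <- t(vapply(seq_len(n), function(i)
    mode_means(modes[i], mu0[i], design$effect_log2fc, female_higher[i]),
    numeric(3L)))
  dimnames(means) <- list(ids, c("F", "M", "H"))
  truth <- build_truth(ids, modes, female_higher, means)
  truth$class <- sample(names(class_proportions), n, replace = TRUE,
                        prob = class_proportions)
  sheet <- trio_sheet(design$conditions, design$metab_reps)
  geno_col <- c(B73 = "F", Mo17 = "M", BM = "H", MB = "H")
  condmult <- matrix(2^stats::rnorm(n * length(design$conditions), 0,
                                    design$condition_effect_sd),
                     n, length(design$conditions),
                     dimnames = list(ids, design$conditions))
  mu <- means[, geno_col[sheet$genotype], drop = FALSE] *
    condmult[, sheet$condition, drop = FALSE]
  colnames(mu) <- sheet$sample_id
  sigma <- sqrt(log(1 + design$metab_cv^2))
  noise <- exp(sigma * matrix(stats::rnorm(length(mu)), nrow(mu)) -
                 sigma^2 / 2)
  v <- mu * noise
  dimnames(v) <- dimnames(mu)
  list(abundance = omics_matrix(v, "abundance"), sheet = sheet,
       truth = truth, design = design)
}

#' Simulate a biomass table with planted mid-parent heterosis
#'
#' Parent weights are multiplicative-noise replicates around fixed means;
#' the hybrid mean is the mid-parent value scaled by the target MPH, for
#' fresh weight and (at one tenth the mass) dry weight.
#'
#' @param target_mph target MPH in percent: a single number, or a
#'   data.frame with columns `cross`, `condition`, `target`.
#' @param noise_cv replicate coefficient of variation.
#' @param reps replicates per genotype and condition.
#' @param seed RNG seed.
#' @param conditions condition labels.
#' @param crosses cross table as in [default_crosses()].
#' @param parent_means named fresh-weight means (g) for the two parents.
#' @return biomass data.frame as consumed by [biomass_mph()].
#' @export
simulate_biomass <- function(target_mph = 55, noise_cv = 0.05, reps = 3,
                             seed = 1L, conditions = c("Dk", "FR", "R", "B"),
                             crosses = default_crosses(),
                             parent_means = c(B73 = 0.8, Mo17 = 1.0)) {
  if (!is.null(seed)) set.seed(seed)
  lookup <- function(cross, cond) {
    if (is.data.frame(target_mph)) {
      hit <- target_mph$target[target_mph$cross == cross &
                                 target_mph$condition == cond]
      if (!length(hit)) stop("no target for ", cross, " / ", cond)
      hit[1L]
    } else target_mph
  }
  if (any((if (is.data.frame(target_mph)) target_mph$target
           else target_mph) <= -100))
    stop("target MPH must exceed -100%")
  draw <- function(mean, n) mean * (1 + noise_cv * stats::rnorm(n))
  out <- NULL
  emit <- function(geno, cond, fresh_mean) {
    fresh <- draw(fresh_mean, reps)
    dry <- draw(fresh_mean / 10, reps)
    data.frame(genotype = geno, condition = cond, replicate = seq_len(reps),
               fresh_weight_g = fresh, dry_weight_g = dry,
               stringsAsFactors = FALSE)
  }
  for (cond in conditions) {
    for (p in names(parent_means))
      out <- rbind(out, emit(p, cond, parent_means[[p]]))
    for (i in seq_len(nrow(crosses))) {
      mid <- mean(parent_means[c(crosses$female[i], crosses$male[i])])
      tgt <- lookup(crosses$cross[i], cond)
      out <- rbind(out, emit(crosses$hybrid[i], cond, mid * (1 + tgt / 100)))
    }
  }
  out
}
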