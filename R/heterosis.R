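#' Mid-parent heterosis percentage
#'
#' `MPH = 100 * (F1 - A) / A` with `A = (female + male) / 2` the
#' mid-parent value; all inputs are group means. Vectorized.
#'
#' @param f1_mean hybrid mean(s).
#' @param female_mean,male_mean parental means; the mid-parent must be
#'   positive.
#' @return MPH in percent.
#' @export
mph <- function(f1_mean, female_mean, male_mean) {
  a <- (female_mean + male_mean) / 2
  if (any(a <= 0)) stop("mid-parent mean must be positive")
  100 * (f1_mean - a) / a
}

#' Per-class MPH distribution with one-sample tests
#'
#' Groups per-item MPH values by annotation class and tests each class
#' mean against 0 with a two-sided one-sample t-test. Items missing from
#' `classes` fall into `"not annotated"`. Degenerate classes are flagged:
#' fewer than two items (no test) or zero variance (p reported as 1, no
#' significance claim from constant data).
#'
#' @param records data.frame with columns `item` and `mph` (percent), as
#'   built from [mph()] or [biomass_mph()].
#' @param classes named character vector mapping item -> class.
#' @return data.frame: `class`, `n`, `mean_mph`, `median_mph`, `t`, `p`,
#'   `signif` (`"**"` p < 0.01, `"*"` p < 0.05, else `""`), `flag`.
#' @export
class_mph_distribution <- function(records, classes = NULL) {
  stopifnot(all(c("item", "mph") %in% colnames(records)))
  cls <- if (is.null(classes)) rep("not annotated", nrow(records)) else {
    z <- unname(classes[records$item])
    z[is.na(z)] <- "not annotated"
    z
  }
  out <- NULL
  for (cl in unique(cls)) {
    x <- records$mph[cls == cl]
    n <- length(x)
    flag <- ""
    if (n < 2L) { t <- NA_real_; p <- NA_real_; flag <- "n<2" }
    else if (stats::sd(x) == 0) { t <- 0; p <- 1; flag <- "zero variance" }
    else { fit <- stats::t.test(x, mu = 0)
           t <- unname(fit$statistic); p <- fit$p.value }
    signif <- if (!is.na(p) && flag == "" && p < 0.01) "**"
              else if (!is.na(p) && flag == "" && p < 0.05) "*" else ""
    out <- rbind(out, data.frame(class = cl, n = n, mean_mph = mean(x),
                                 median_mph = stats::median(x), t = t, p = p,
                                 signif = signif, flag = flag,
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Read a biomass table from TSV
#'
#' @param path TSV with columns `genotype`, `condition`, `replicate`,
#'   `fresh_weight_g`, `dry_weight_g`.
#' @return validated data.frame.
#' @export
read_biomass <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("genotype", "condition", "replicate", "fresh_weight_g",
            "dry_weight_g")
  missing <- setdiff(need, colnames(df))
  if (length(missing))
    stop("biomass table lacks column(s): ", paste(missing, collapse = ", "))
  df
}

#' Biomass mid-parent heterosis per cross, condition and trait
#'
#' Computes genotype means per condition and applies [mph()] to fresh and
#' dry weight for every cross of the design. Conditions where a trio
#' member is missing are skipped with a warning.
#'
#' @param weights biomass table as in [read_biomass()].
#' @param crosses cross table as in [default_crosses()].
#' @return data.frame: `cross`, `condition`, `trait`, `f1_mean`,
#'   `midparent_mean`, `mph` (percent), `item` (cross/condition/trait key).
#' @export
biomass_mph <- function(weights, crosses = default_crosses()) {
  traits <- c(fresh = "fresh_weight_g", dry = "dry_weight_g")
  out <- NULL
  for (cond in unique(weights$condition)) {
    sub <- weights[weights$condition == cond, ]
    gmean <- function(geno, col) {
      x <- sub[[col]][sub$genotype == geno]
      if (!length(x)) NA_real_ else mean(x)
    }
    for (i in seq_len(nrow(crosses))) {
      for (tr in names(traits)) {
        f1 <- gmean(crosses$hybrid[i], traits[[tr]])
        fp <- gmean(crosses$female[i], traits[[tr]])
        mp <- gmean(crosses$male[i], traits[[tr]])
        if (anyNA(c(f1, fp, mp))) {
          warning("missing genotype for cross ", crosses$cross[i],
                  " under condition ", cond, "; record skipped")
          next
        }
        out <- rbind(out, data.frame(
          cross = crosses$cross[i], condition = cond, trait = tr,
          f1_mean = f1, midparent_mean = (fp + mp) / 2,
          mph = mph(f1, fp, mp),
          item = paste(crosses$cross[i], cond, tr, sep = "/"),
          stringsAsFactors = FALSE))
      }
    }
  }
  out
}
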