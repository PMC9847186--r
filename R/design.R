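#' Sample sheet
#'
#' Validates the experiment layout: one row per sample with its genotype,
#' its role in the crossing design (`femaleParent`, `maleParent`,
#' `hybrid`), the cross it belongs to (parents shared by reciprocal
#' crosses may carry `NA`), the condition label and the replicate index.
#'
#' @param df data.frame with columns `sample_id`, `genotype`, `role`,
#'   `cross`, `condition`, `replicate`.
#' @return the validated data.frame, classed `SampleSheet`.
#' @export
sample_sheet <- function(df) {
  need <- c("sample_id", "genotype", "role", "cross", "condition", "replicate")
  missing <- setdiff(need, colnames(df))
  if (length(missing))
    stop("sample sheet lacks column(s): ", paste(missing, collapse = ", "))
  df <- as.data.frame(df)[need]
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ", df$sample_id[duplicated(df$sample_id)][1L])
  ok_role <- df$role %in% c("femaleParent", "maleParent", "hybrid")
  if (!all(ok_role))
    stop("unknown role '", df$role[!ok_role][1L], "'")
  df$replicate <- as.integer(df$replicate)
  if (any(is.na(df$replicate)) || any(df$replicate < 1L))
    stop("replicate indices must be positive integers")
  grp <- split(df$replicate, paste(df$genotype, df$condition, sep = "\r"))
  for (g in names(grp)) {
    r <- sort(grp[[g]])
    if (!identical(r, seq_along(r)))
      stop("replicate indices for group '", gsub("\r", " / ", g),
           "' are not 1..k without gaps")
  }
  class(df) <- c("SampleSheet", "data.frame")
  df
}

#' Read a sample sheet from TSV
#'
#' @param path TSV with the columns documented in [sample_sheet()].
#' @return a `SampleSheet`.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  sample_sheet(df)
}

#' Default reciprocal-cross table
#'
#' The maize design this package emulates: BM = B73 (female) x Mo17
#' (male) and the reciprocal MB = Mo17 (female) x B73 (male).
#'
#' @return data.frame with columns `cross`, `female`, `male`, `hybrid`.
#' @export
default_crosses <- function() {
  data.frame(cross  = c("BM", "MB"),
             female = c("B73", "Mo17"),
             male   = c("Mo17", "B73"),
             hybrid = c("BM", "MB"),
             stringsAsFactors = FALSE)
}

#' Resolve a female-hybrid-male trio
#'
#' Maps samples of one cross under one condition to the three roles of the
#' F-H-M comparison. Parents shared by reciprocal crosses are resolved by
#' genotype through the `crosses` table, so the same B73 samples serve as
#' female of BM and male of MB.
#'
#' @param sheet a [sample_sheet()].
#' @param cross cross label (e.g. `"BM"`).
#' @param condition condition label (e.g. `"Dk"`).
#' @param crosses cross definition table as in [default_crosses()].
#' @return a list of class `TrioDesign` with elements `cross`,
#'   `condition`, `female_samples`, `male_samples`, `hybrid_samples`.
#' @export
trio_design <- function(sheet, cross, condition, crosses = default_crosses()) {
  stopifnot(inherits(sheet, "SampleSheet"))
  row <- crosses[crosses$cross == cross, ]
  if (nrow(row) != 1L) stop("unknown cross '", cross, "'")
  sub <- sheet[sheet$condition == condition, ]
  pick <- function(genotype) {
    s <- sub$sample_id[sub$genotype == genotype]
    s[order(sub$replicate[sub$genotype == genotype])]
  }
  trio <- list(cross = cross, condition = condition,
               female_samples = pick(row$female),
               male_samples   = pick(row$male),
               hybrid_samples = pick(row$hybrid))
  for (part in c("female_samples", "male_samples", "hybrid_samples"))
    if (!length(trio[[part]]))
      stop("no ", sub("_samples", "", part), " samples for cross '", cross,
           "' under condition '", condition, "'")
  if (anyDuplicated(unlist(trio[3:5])))
    stop("trio roles overlap for cross '", cross, "'")
  class(trio) <- "TrioDesign"
  trio
}

#' @export
print.TrioDesign <- function(x, ...) {
  cat(sprintf("TrioDesign %s / %s: %d female, %d male, %d hybrid samples\n",
              x$cross, x$condition, length(x$female_samples),
              length(x$male_samples), length(x$hybrid_samples)))
  invisible(x)
}
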