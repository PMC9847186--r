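write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

cfg_stop <- function(...) stop(errorCondition(paste0(...),
                                              class = "triomics_config_error"))

stage_run <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "triomics_config_error")) stop(e)
    stop(errorCondition(paste0("stage '", stage, "' failed: ",
                               conditionMessage(e)),
                        class = "triomics_data_error"))
  })
}

log_msg <- function(...) message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "),
                                 ...)

#' Run the full trio-omics pipeline
#'
#' Config-driven end-to-end run: expression filtering and QC, the three
#' pairwise differential tests per cross and condition, the twelve-type
#' inheritance classification with category roll-up, hybrid-vs-mid-parent
#' testing with up/down asymmetry, overlap tables across conditions,
#' co-expression modules with a hybrid-vs-parent trait correlation,
#' optional term enrichment, and optional metabolite / biomass MPH
#' stages. Every stage writes a TSV under `out_dir`; a deterministic JSON
#' manifest records parameters and md5 hashes of every output (no
#' timestamps, so identical inputs reproduce identical manifests).
#'
#' @param config either a YAML file path or a list with elements:
#'   `out_dir` (required); `seed`; `simulate` (logical; when TRUE the
#'   synthetic generator supplies all inputs and `design` overrides
#'   [simulation_design()] defaults); otherwise `counts` and
#'   `sample_sheet` paths, plus optional `annotation` (GMT),
#'   `metabolites`, `biomass` paths; `thresholds` and `network` lists
#'   override [threshold_config()] / [network_config()]; `enrichment`
#'   (logical) requires `annotation` unless simulating (then it is
#'   skipped); `with_metabolites` toggles the metabolite stage when
#'   simulating.
#' @return invisibly, a list with the stage outputs and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) cfg_stop("missing config field 'out_dir'")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  cfg <- do.call(threshold_config,
                 if (is.null(config$thresholds)) list() else config$thresholds)
  simulate <- isTRUE(config$simulate)
  outputs <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write_tsv(df, path)
    outputs[[length(outputs) + 1L]] <<- path
    path
  }

  ## ---- inputs -----------------------------------------------------------
  metab <- NULL; biomass <- NULL; annot <- NULL
  if (simulate) {
    log_msg("simulating trio experiment")
    design <- do.call(simulation_design,
                      c(if (is.null(config$design)) list() else config$design,
                        list(seed = seed)))
    sim <- stage_run("simulate", simulate_trio_counts(design))
    counts <- sim$counts; sheet <- sim$sheet
    emit(sim$truth, "truth_genes.tsv")
    if (!isFALSE(config$with_metabolites)) {
      msim <- stage_run("simulate", simulate_metabolites(design))
      metab <- msim
      emit(msim$truth, "truth_metabolites.tsv")
    }
    biomass <- stage_run("simulate",
                         simulate_biomass(seed = seed,
                                          conditions = design$conditions))
  } else {
    for (field in c("counts", "sample_sheet"))
      if (is.null(config[[field]]))
        cfg_stop("missing config field '", field, "'")
    if (isTRUE(config$enrichment) && is.null(config$annotation))
      cfg_stop("enrichment enabled but config field 'annotation' is missing")
    counts <- stage_run("load", read_matrix(config$counts, "counts"))
    sheet <- stage_run("load", read_sample_sheet(config$sample_sheet))
    if (!is.null(config$metabolites))
      metab <- list(abundance = stage_run("load",
                      read_matrix(config$metabolites, "abundance")),
                    sheet = sheet)
    if (!is.null(config$biomass))
      biomass <- stage_run("load", read_biomass(config$biomass))
  }
  if (!is.null(config$annotation))
    annot <- stage_run("load", read_gmt(config$annotation))
  crosses <- default_crosses()
  conditions <- unique(sheet$condition)

  ## ---- filter + qc ------------------------------------------------------
  log_msg("filtering and QC")
  filtered <- stage_run("filter",
                        filter_low_expression(counts, cfg, sheet = sheet))
  cpm <- cpm_normalize(filtered)
  # median-of-ratios normalization for cross-sample comparisons: immune to
  # the compositional shifts that strong overdominant genes induce in CPM
  sf <- stage_run("filter", size_factors(filtered))
  norm <- omics_matrix(sweep(filtered$values, 2L, sf, "/"), "abundance")
  qc_tab <- stage_run("qc", replicate_correlation(cpm, sheet))
  emit(qc_tab, "qc_replicate_correlation.tsv")
  pca <- stage_run("qc", pca_samples(cpm, n_components = 2L))
  emit(data.frame(sample_id = rownames(pca$scores), pca$scores,
                  stringsAsFactors = FALSE), "qc_pca_scores.tsv")

  ## ---- per-trio differential + classification ---------------------------
  summary_rows <- NULL; mpv_sets <- list(); class_tables <- list()
  for (cr in crosses$cross) {
    for (cond in conditions) {
      log_msg("trio ", cr, " / ", cond)
      trio <- stage_run("trio", trio_design(sheet, cr, cond, crosses))
      de_hf <- stage_run("de", nb_test(filtered, trio$female_samples,
                                       trio$hybrid_samples, cfg))
      de_hm <- stage_run("de", nb_test(filtered, trio$male_samples,
                                       trio$hybrid_samples, cfg))
      de_fm <- stage_run("de", nb_test(filtered, trio$male_samples,
                                       trio$female_samples, cfg))
      calls <- stage_run("classify", classify_trio(de_hf, de_hm, de_fm))
      class_tables[[paste(cr, cond, sep = "_")]] <- calls
      emit(calls, sprintf("inheritance_%s_%s.tsv", cr, cond))
      tall <- categorize(calls)
      mpv <- stage_run("mpv", f1_vs_mpv(norm, trio, cfg))
      emit(mpv, sprintf("f1_vs_mpv_%s_%s.tsv", cr, cond))
      up <- sum(mpv$call == "up"); down <- sum(mpv$call == "down")
      asym <- if (up + down > 0) updown_asymmetry(up, down)
              else list(chi2 = NA_real_, p = NA_real_)
      mpv_sets[[paste(cr, cond, sep = "_")]] <-
        mpv$feature_id[mpv$call != "ns"]
      deg <- calls$type != "unclassified"
      summary_rows <- rbind(summary_rows, data.frame(
        cross = cr, condition = cond, n_genes = nrow(calls),
        n_classified = sum(deg),
        additive = unname(tall$category_counts["additive"]),
        ELD_F = unname(tall$category_counts["ELD_F"]),
        ELD_M = unname(tall$category_counts["ELD_M"]),
        overdominant = unname(tall$category_counts["overdominant"]),
        non_additive_pct = 100 * tall$non_additive / max(sum(deg), 1L),
        mpv_up = up, mpv_down = down, updown_chi2 = asym$chi2,
        updown_p = asym$p, stringsAsFactors = FALSE))
    }
  }
  emit(summary_rows, "category_summary.tsv")
  overlaps <- NULL
  nonempty <- mpv_sets[lengths(mpv_sets) > 0]
  if (length(nonempty) >= 2L) {
    overlaps <- stage_run("overlap", set_overlaps(nonempty))
    emit(overlaps$exclusive, "f1_mpv_overlaps.tsv")
  }

  ## ---- co-expression on F1-MPV DEGs -------------------------------------
  net_cfg <- do.call(network_config,
                     if (is.null(config$network)) list() else config$network)
  deg_union <- unique(unlist(mpv_sets))
  net <- NULL; trait_tab <- NULL
  if (length(deg_union) >= net_cfg$min_module_size) {
    log_msg("co-expression network on ", length(deg_union), " F1-MPV DEGs")
    expr <- log2(norm$values[deg_union, , drop = FALSE] + 1)
    net <- stage_run("network", {
      a <- soft_adjacency(expr, net_cfg)
      tom <- tom_similarity(a)
      cut_modules(expr[rownames(a), , drop = FALSE], 1 - tom, net_cfg)
    })
    emit(data.frame(feature_id = names(net$labels), module = net$labels,
                    stringsAsFactors = FALSE), "modules.tsv")
    if (nrow(net$eigengenes)) {
      trait <- as.numeric(sheet$role[match(colnames(net$eigengenes),
                                           sheet$sample_id)] == "hybrid")
      trait_tab <- stage_run("network",
                             module_trait_correlation(net$eigengenes, trait))
      emit(trait_tab, "module_trait.tsv")
    }
  } else log_msg("too few F1-MPV DEGs for a network; stage skipped")

  ## ---- enrichment -------------------------------------------------------
  enrich_tab <- NULL
  if (!is.null(annot) && length(deg_union)) {
    log_msg("enrichment on ", length(deg_union), " features")
    enrich_tab <- stage_run("enrich", hypergeom_enrich(deg_union, annot))
    emit(enrich_tab, "enrichment.tsv")
    emit(filter_enrichment(enrich_tab, cfg$go_p), "enrichment_significant.tsv")
  }

  ## ---- metabolites + heterosis ------------------------------------------
  dam_tabs <- list()
  if (!is.null(metab)) {
    msheet <- metab$sheet %||% sheet
    for (cr in crosses$cross) {
      for (cond in unique(msheet$condition)) {
        trio <- trio_design(msheet, cr, cond, crosses)
        dam <- stage_run("dam", vip_test(metab$abundance,
                                         c(trio$female_samples,
                                           trio$male_samples),
                                         trio$hybrid_samples, cfg))
        dam_tabs[[paste(cr, cond, sep = "_")]] <- dam
        emit(dam, sprintf("dam_%s_%s.tsv", cr, cond))
      }
    }
  }
  mph_tab <- NULL
  if (!is.null(biomass)) {
    mph_tab <- stage_run("mph", biomass_mph(biomass, crosses))
    emit(mph_tab, "biomass_mph.tsv")
  }

  ## ---- manifest ---------------------------------------------------------
  manifest <- list(
    parameters = list(seed = seed,
                      thresholds = unclass(cfg),
                      network = unclass(net_cfg),
                      simulate = simulate),
    outputs = lapply(stats::setNames(outputs, basename(unlist(outputs))),
                     function(p) unname(tools::md5sum(p))))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  log_msg("done; manifest at ", manifest_path)
  invisible(list(summary = summary_rows, inheritance = class_tables,
                 overlaps = overlaps, network = net, module_trait = trait_tab,
                 enrichment = enrich_tab, dams = dam_tabs, biomass_mph = mph_tab,
                 manifest = manifest, manifest_path = manifest_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
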