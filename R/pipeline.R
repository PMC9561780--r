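#' Pipeline run configuration
#'
#' Collects everything a run needs: the master seed (fanned out to child
#' seeds per stage via \code{\link{derive_seed}}), bin geometry and QC
#' thresholds, classifier and gate parameters, and the output directory.
#'
#' @param out_dir output directory for the run.
#' @param seed master seed.
#' @param bin_size spots per bin side for the analysis unit.
#' @param min_umi,min_median_genes QC thresholds (see \code{\link{qc_bins}}).
#' @param k extreme-class size for \code{\link{classify_metabolic}}.
#' @param mia_alpha,expr_quantile,marker_gene myCAF gate parameters.
#' @param engine signature-scoring engine.
#' @param layout a \code{\link{region_layout}} for the simulated chip.
#' @param n_cells_per_type cells per type for the companion cell matrix.
#' @param pathway_fold planted metabolic fold change.
#' @return object of class \code{run_config}.
#' @export
run_config <- function(out_dir, seed = 1, bin_size = 2, min_umi = 200,
                       min_median_genes = 100, k = 3, mia_alpha = 0.05,
                       expr_quantile = 0.75, marker_gene = "POSTN",
                       engine = "module",
                       layout = region_layout(width = 80, height = 80,
                                              n_tumor = 6, n_ring = 2,
                                              seed = seed),
                       n_cells_per_type = 150, pathway_fold = 4) {
  structure(list(out_dir = out_dir, seed = seed, bin_size = bin_size,
                 min_umi = min_umi, min_median_genes = min_median_genes,
                 k = k, mia_alpha = mia_alpha, expr_quantile = expr_quantile,
                 marker_gene = marker_gene, engine = engine, layout = layout,
                 n_cells_per_type = n_cells_per_type,
                 pathway_fold = pathway_fold),
            class = "run_config")
}

#' Run the full synthetic analysis pipeline
#'
#' Chains the stages end-to-end: simulate a chip and a companion labeled
#' cell matrix; bin, QC and normalize the chip; score the six metabolic
#' pathway signatures per bin; aggregate per tumor area and classify
#' hyper/hypometabolic areas; derive cell-type and region marker sets by
#' differential expression; run the MIA grid and the joint myCAF gate; and
#' contrast myCAF-positive against myCAF-negative tumor bins. Every stage
#' writes its table into the run directory and the run ends with a
#' \code{manifest.json} listing each output with its md5 checksum plus an
#' echo of the configuration. Deterministic given the seed.
#'
#' @param config a \code{\link{run_config}}.
#' @return the manifest, invisibly (list with \code{outputs}, \code{config},
#'   \code{seed}).
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(name) outputs <<- c(outputs, file.path(config$out_dir, name))
  stage <- function(name, expr) {
    message(sprintf("[%s] stage %s", format(Sys.time(), "%H:%M:%S"), name))
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }

  universe <- default_universe()
  profiles <- default_profiles(universe)
  pathways <- default_pathways(universe)

  chip <- stage("simulate", {
    ids <- sort(unique(stats::na.omit(as.vector(config$layout$area_map))))
    tumor_ids <- grep("^tumor", ids, value = TRUE)
    n_half <- floor(length(tumor_ids) / 2)
    plant <- metabolic_plant(tumor_ids[seq_len(n_half)],
                             tumor_ids[seq.int(n_half + 1, length(tumor_ids))],
                             pathway_fold = config$pathway_fold)
    sim <- simulate_chip(config$layout, profiles, plant, pathways,
                         seed = derive_seed(config$seed, "chip"))
    write_gem(sim$spots, file.path(config$out_dir, "chip.gem.tsv"))
    emit("chip.gem.tsv")
    write_truth(sim$truth, file.path(config$out_dir, "truth.tsv"))
    emit("truth.tsv")
    c(sim, list(plant = plant))
  })

  cells <- stage("cells", {
    simulate_cells(profiles, config$n_cells_per_type,
                   seed = derive_seed(config$seed, "cells"))
  })

  binned <- stage("bin", {
    bm <- bin_spots(chip$spots, config$bin_size)
    bm <- annotate_bins(bm, chip$truth)
    qc <- qc_bins(bm, min_umi = config$min_umi,
                  min_median_genes = config$min_median_genes)
    jsonlite::write_json(c(qc$report,
                           list(bin_edge_um = physical_bin_edge(
                             config$bin_size, chip$spots$geometry))),
                         file.path(config$out_dir, "qc_report.json"),
                         auto_unbox = TRUE, digits = NA)
    emit("qc_report.json")
    write_bin_matrix(qc$binmat, file.path(config$out_dir, "bins"))
    qc$binmat
  })

  expr <- stage("normalize", log_normalize(binned))

  scores <- stage("score", {
    sc <- score_matrix(expr, pathways, engine = config$engine,
                       seed = derive_seed(config$seed, "score"))
    write_scores(sc, file.path(config$out_dir, "pathway_scores.tsv"))
    emit("pathway_scores.tsv")
    sc
  })

  calls <- stage("classify", {
    areas <- tumor_areas(binned)
    area_sc <- area_pathway_scores(scores, areas)
    cl <- classify_metabolic(area_sc, k = config$k)
    write_tsv(cl, file.path(config$out_dir, "metabolic_calls.tsv"))
    emit("metabolic_calls.tsv")
    cl
  })

  mia_gate <- stage("mia", {
    cell_markers <- markers_for(log_normalize(cells$counts), cells$cell_type,
                                max_genes = 100)
    regions <- binned$annotations$region
    # region areas (tumor blobs, rings) keep their ids; diffuse regions pooled
    region_lab <- ifelse(is.na(binned$annotations$area_id), regions,
                         binned$annotations$area_id)
    region_markers <- markers_for(expr, region_lab, max_genes = 100)
    bg <- intersect(rownames(cells$counts), rownames(expr))
    keep_c <- lapply(cell_markers, intersect, bg)
    keep_r <- lapply(region_markers, intersect, bg)
    keep_r <- keep_r[vapply(keep_r, length, 0L) > 0]
    grid <- mia_matrix(keep_c, keep_r, bg)
    write_tsv(grid, file.path(config$out_dir, "mia_grid.tsv"))
    emit("mia_grid.tsv")
    gate <- call_mycaf_regions(grid, expr, region_lab,
                               marker_gene = config$marker_gene,
                               mia_alpha = config$mia_alpha,
                               expr_quantile = config$expr_quantile)
    write_tsv(gate, file.path(config$out_dir, "mycaf_regions.tsv"))
    emit("mycaf_regions.tsv")
    list(grid = grid, gate = gate, region_lab = region_lab)
  })

  stage("de", {
    flagged_rings <- mia_gate$gate$region[mia_gate$gate$flagged]
    ring_of <- sub("^ring", "tumor", flagged_rings)
    tumor_bins <- which(binned$annotations$region == "tumor")
    pos <- tumor_bins[binned$annotations$area_id[tumor_bins] %in% ring_of]
    neg <- setdiff(tumor_bins, pos)
    if (length(pos) >= 2 && length(neg) >= 2) {
      de <- de_test(expr, colnames(expr)[pos], colnames(expr)[neg])
      write_de(de, file.path(config$out_dir, "mycaf_de.tsv"))
      emit("mycaf_de.tsv")
    } else {
      writeLines("# no myCAF+ vs myCAF- contrast possible on this chip",
                 file.path(config$out_dir, "mycaf_de.tsv"))
      emit("mycaf_de.tsv")
    }
  })

  manifest <- list(
    seed = config$seed,
    bin_edge_um = physical_bin_edge(config$bin_size, chip$spots$geometry),
    outputs = lapply(setNames(nm = basename(outputs)), function(f)
      unname(tools::md5sum(file.path(config$out_dir, f)))),
    config = list(bin_size = config$bin_size, min_umi = config$min_umi,
                  min_median_genes = config$min_median_genes, k = config$k,
                  mia_alpha = config$mia_alpha,
                  expr_quantile = config$expr_quantile,
                  marker_gene = config$marker_gene, engine = config$engine))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
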