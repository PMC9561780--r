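#' Default synthetic gene universe
#'
#' A 2000-gene universe. Most genes are anonymous (\code{G0001}...), but the
#' canonical marker genes of the modeled cell types (cancer squamous cells,
#' fibroblasts, myCAFs, immune cells, glandular columnar cells) are given
#' their field names (e.g. \emph{SERPINB3}, \emph{LAMA2}, \emph{ACTA2},
#' \emph{POSTN}, \emph{ITGB4}, \emph{FAP}, \emph{PTPRC}, \emph{MUC5B}) so
#' downstream marker-based gates address them naturally.
#'
#' @param n_genes universe size (default 2000).
#' @return character vector of gene names.
#' @export
default_universe <- function(n_genes = 2000) {
  named <- unlist(default_marker_sets(), use.names = FALSE)
  if (n_genes < length(named) + 6 * 30 + 100)
    stopf("universe too small for the default marker and pathway sets")
  c(named, sprintf("G%04d", seq_len(n_genes - length(named))))
}

#' Default cell-type marker sets
#'
#' Twelve genes per type; the leading genes are the canonical markers of
#' each type, the rest synthetic fillers reserved to that type.
#'
#' @return named list of character vectors.
#' @export
default_marker_sets <- function() {
  list(
    cancer = c("SERPINB3", "KRT5", "CDKN2A", "TP63",
               sprintf("CANC%02d", 1:8)),
    fibroblast = c("LAMA2", "VIM", "COL1A1", "PDGFRA",
                   sprintf("FIBR%02d", 1:8)),
    myCAF = c("ACTA2", "POSTN", "ITGB4", "FAP", sprintf("MCAF%02d", 1:8)),
    immune = c("PTPRC", "CD3E", "CD8A", "MS4A1", sprintf("IMMU%02d", 1:8)),
    gland = c("MUC5B", "WFDC2", "TFF3", "AGR2", sprintf("GLND%02d", 1:8))
  )
}

#' Default metabolic pathway signatures
#'
#' Six disjoint 30-gene signatures named after the modeled pathways:
#' hypoxia, lactic acid, glycolysis, lipid metabolism, pentose phosphate,
#' oxidative phosphorylation. Members are synthetic genes drawn from the
#' tail of the default universe, so pathway activity is a plantable ground
#' truth rather than a biological claim.
#'
#' @param universe gene universe the signatures draw from.
#' @param n_genes_each genes per signature (default 30).
#' @return named list of \code{\link{gene_signature}} objects.
#' @export
default_pathways <- function(universe = default_universe(),
                             n_genes_each = 30) {
  nm <- c("hypoxia", "lactic_acid", "glycolysis", "lipid_metabolism",
          "pentose_phosphate", "oxidative_phosphorylation")
  anon <- grep("^G\\d+$", universe, value = TRUE)
  if (length(anon) < length(nm) * n_genes_each)
    stopf("universe too small for %d pathway signatures", length(nm))
  sigs <- lapply(seq_along(nm), function(i) {
    gene_signature(nm[i],
                   anon[((i - 1) * n_genes_each + 1):(i * n_genes_each)])
  })
  setNames(sigs, nm)
}

#' Expression profile of one synthetic cell type
#'
#' Counts for a cell of this type are drawn from a negative binomial with
#' variance mu + mu^2/theta (mean/dispersion parameterization; Poisson as
#' theta grows). The type's own marker genes have their means multiplied by
#' \code{marker_fold}.
#'
#' @param cell_type type name.
#' @param baseline_mean named per-gene expected count (>= 0, finite).
#' @param dispersion per-gene NB dispersion theta (> 0); scalar recycled.
#' @param marker_genes character vector, subset of the gene universe.
#' @param marker_fold fold elevation of marker means (>= 1).
#' @return object of class \code{cell_profile_spec}.
#' @export
cell_profile_spec <- function(cell_type, baseline_mean, dispersion = 2,
                              marker_genes = character(0), marker_fold = 8) {
  genes <- names(baseline_mean)
  if (is.null(genes)) stopf("baseline_mean must be named by gene")
  if (any(!is.finite(baseline_mean)) || any(baseline_mean < 0))
    stopf("baseline means must be finite and >= 0")
  if (any(dispersion <= 0)) stopf("dispersion must be > 0")
  unknown <- setdiff(marker_genes, genes)
  if (length(unknown))
    stopf("unknown marker gene(s) for type '%s': %s", cell_type,
          paste(unknown, collapse = ", "))
  if (marker_fold < 1) stopf("marker_fold must be >= 1")
  mu <- baseline_mean
  mu[marker_genes] <- mu[marker_genes] * marker_fold
  structure(list(cell_type = cell_type, baseline_mean = baseline_mean,
                 mean = mu,
                 dispersion = rep_len(dispersion, length(genes)),
                 marker_genes = marker_genes, marker_fold = marker_fold),
            class = "cell_profile_spec")
}

#' Default cell-type profiles over the default universe
#'
#' @param universe gene universe.
#' @param baseline mean count per gene for non-marker genes.
#' @param marker_fold fold elevation of each type's markers.
#' @param dispersion NB dispersion.
#' @return named list of \code{\link{cell_profile_spec}} objects.
#' @export
default_profiles <- function(universe = default_universe(), baseline = 0.25,
                             marker_fold = 8, dispersion = 2) {
  markers <- default_marker_sets()
  mu <- setNames(rep(baseline, length(universe)), universe)
  lapply(setNames(nm = names(markers)), function(ct)
    cell_profile_spec(ct, mu, dispersion, markers[[ct]], marker_fold))
}

#' Simulate a labeled cell-by-gene count matrix
#'
#' A synthetic stand-in for a single-nucleus expression matrix:
#' \code{n_per_type} cells per profile, counts drawn NB(mean, dispersion)
#' with each type's markers elevated by its \code{marker_fold}. Fully
#' reproducible from the seed.
#'
#' @param specs list of \code{\link{cell_profile_spec}} (shared universe).
#' @param n_per_type cells per type (>= 1).
#' @param seed integer seed.
#' @return list with \code{counts} (sparse genes x cells) and
#'   \code{cell_type} (label per cell).
#' @export
simulate_cells <- function(specs, n_per_type, seed) {
  if (n_per_type < 1) stopf("n_per_type must be >= 1")
  genes <- names(specs[[1]]$baseline_mean)
  for (s in specs) if (!identical(names(s$baseline_mean), genes))
    stopf("profiles must share one gene universe")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  blocks <- lapply(specs, function(s) {
    m <- rnbinom(length(genes) * n_per_type,
                 mu = rep(s$mean, n_per_type),
                 size = rep(s$dispersion, n_per_type))
    matrix(m, nrow = length(genes))
  })
  counts <- methods::as(Matrix::Matrix(do.call(cbind, blocks), sparse = TRUE),
                        "CsparseMatrix")
  labels <- rep(vapply(specs, `[[`, "", "cell_type"), each = n_per_type)
  dimnames(counts) <- list(genes,
                           paste0(labels, "_",
                                  sequence(rep(n_per_type, length(specs)))))
  list(counts = counts, cell_type = labels)
}

#' Synthetic tissue layout on a spot lattice
#'
#' Places \code{n_tumor} roughly circular tumor blobs on a jittered grid,
#' surrounds the first \code{n_ring} of them with a myCAF annulus of
#' configurable width (the ribbon-like band hugging a tumor nest), adds a
#' few inflammation patches, and fills the rest with stroma. Tumor blobs
#' and rings carry area ids (\code{tumor_01}, \code{ring_01}, ...).
#'
#' @param width,height lattice extents in spots.
#' @param n_tumor number of tumor blobs.
#' @param n_ring how many of them get a myCAF annulus (<= n_tumor).
#' @param blob_radius tumor blob radius in spots.
#' @param ring_width annulus width in spots (1-3 is realistic).
#' @param n_inflammation number of inflammation patches.
#' @param composition per-region named list of cell-type mixing
#'   probabilities (each summing to 1).
#' @param abundance_factor per-region RNA depth multiplier; tumor must
#'   exceed stroma (tumor areas are markedly RNA-richer than stroma).
#' @param seed integer seed for the jitter.
#' @return object of class \code{region_layout}: list with \code{region_map}
#'   and \code{area_map} (width x height character matrices),
#'   \code{composition}, \code{abundance_factor}, \code{width, height}.
#' @export
region_layout <- function(width = 120, height = 120, n_tumor = 10,
                          n_ring = 0, blob_radius = 7, ring_width = 2,
                          n_inflammation = 2,
                          composition = default_composition(),
                          abundance_factor = c(tumor = 3, mycaf_ring = 1.5,
                                               inflammation = 1.2,
                                               stroma = 1),
                          seed = 1) {
  if (n_ring > n_tumor) stopf("n_ring cannot exceed n_tumor")
  for (r in names(composition)) {
    if (length(composition[[r]]) == 0) stopf("region '%s' has an empty composition", r)
    if (abs(sum(composition[[r]]) - 1) > 1e-9)
      stopf("composition of region '%s' does not sum to 1", r)
  }
  if (abundance_factor[["tumor"]] <= abundance_factor[["stroma"]])
    stopf("abundance_factor(tumor) must exceed abundance_factor(stroma)")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  region <- matrix("stroma", nrow = width, ncol = height)
  area <- matrix(NA_character_, nrow = width, ncol = height)
  # centers on a jittered grid, spaced so blob + ring + 1 never collide
  margin <- blob_radius + ring_width + 2
  ng <- ceiling(sqrt(n_tumor + n_inflammation))
  step_x <- (width - 2 * margin) / max(1, ng - 1)
  step_y <- (height - 2 * margin) / max(1, ng - 1)
  if (step_x < 2 * margin - 2 || step_y < 2 * margin - 2)
    warnf("lattice is crowded; blobs may touch")
  grid <- expand.grid(gx = seq_len(ng), gy = seq_len(ng))
  grid <- grid[sample(nrow(grid)), , drop = FALSE]
  jit <- function() round(runif(1, -1, 1))
  xs <- seq(width); ys <- seq(height)
  place_disc <- function(cx, cy, r) {
    dx <- outer(xs - cx, rep(1, height))
    dy <- outer(rep(1, width), ys - cy)
    sqrt(dx^2 + dy^2) <= r
  }
  for (i in seq_len(n_tumor)) {
    cx <- round(margin + (grid$gx[i] - 1) * step_x) + jit()
    cy <- round(margin + (grid$gy[i] - 1) * step_y) + jit()
    d <- place_disc(cx, cy, blob_radius)
    region[d] <- "tumor"
    area[d] <- sprintf("tumor_%02d", i)
    if (i <= n_ring) {
      ring <- place_disc(cx, cy, blob_radius + ring_width) & !d
      region[ring] <- "mycaf_ring"
      area[ring] <- sprintf("ring_%02d", i)
    }
  }
  for (j in seq_len(n_inflammation)) {
    i <- n_tumor + j
    if (i > nrow(grid)) break
    cx <- round(margin + (grid$gx[i] - 1) * step_x) + jit()
    cy <- round(margin + (grid$gy[i] - 1) * step_y) + jit()
    d <- place_disc(cx, cy, max(2, blob_radius - 2)) &
      region == "stroma"
    region[d] <- "inflammation"
  }
  used <- unique(as.vector(region))
  miss <- setdiff(used, names(composition))
  if (length(miss)) stopf("no composition for region(s): %s",
                          paste(miss, collapse = ", "))
  structure(list(width = width, height = height, region_map = region,
                 area_map = area,
                 composition = composition[used],
                 abundance_factor = abundance_factor[used]),
            class = "region_layout")
}

#' Default per-region cell-type composition
#'
#' @return named list of probability vectors over the default cell types.
#' @export
default_composition <- function() {
  list(
    tumor = c(cancer = 0.70, immune = 0.15, fibroblast = 0.10, myCAF = 0.05),
    stroma = c(fibroblast = 0.65, immune = 0.20, gland = 0.10, myCAF = 0.05),
    mycaf_ring = c(myCAF = 0.60, fibroblast = 0.30, immune = 0.10),
    inflammation = c(immune = 0.75, fibroblast = 0.25)
  )
}

#' Planted metabolic structure for a chip
#'
#' Designates disjoint sets of tumor areas as hyper- and hypometabolic; in
#' hyper areas the means of all six pathway-signature genes are multiplied
#' by \code{pathway_fold} before counts are drawn.
#'
#' @param hyper_area_ids,hypo_area_ids disjoint tumor area ids.
#' @param pathway_fold fold elevation in hyper areas (> 1).
#' @return object of class \code{metabolic_plant}.
#' @export
metabolic_plant <- function(hyper_area_ids, hypo_area_ids, pathway_fold = 4) {
  if (length(intersect(hyper_area_ids, hypo_area_ids)))
    stopf("hyper and hypo area sets must be disjoint")
  if (pathway_fold <= 1) stopf("pathway_fold must be > 1")
  structure(list(hyper_area_ids = hyper_area_ids,
                 hypo_area_ids = hypo_area_ids,
                 pathway_fold = pathway_fold),
            class = "metabolic_plant")
}

#' Simulate a spatial chip with ground truth
#'
#' Per-spot counts are whole mixture draws: the expected count of gene g at
#' a spot in region r is \code{abundance_factor[r] * sum_t composition[r][t]
#' * mean_t(g)}, drawn from a negative binomial with per-gene dispersion
#' averaged over the profiles. Spots in planted hypermetabolic tumor areas
#' additionally have all pathway-signature gene means multiplied by the
#' plant's \code{pathway_fold}.
#'
#' @param layout a \code{\link{region_layout}}.
#' @param specs cell-type profiles (shared universe).
#' @param plant optional \code{\link{metabolic_plant}}.
#' @param pathways pathway signatures (used only when \code{plant} given).
#' @param seed integer seed.
#' @param geometry chip geometry attached to the result.
#' @return list with \code{spots} (a \code{\link{spot_matrix}}) and
#'   \code{truth} (data.frame \code{x, y, region, area_id}).
#' @export
simulate_chip <- function(layout, specs, plant = NULL,
                          pathways = NULL, seed = 1,
                          geometry = chip_geometry()) {
  genes <- names(specs[[1]]$baseline_mean)
  type_means <- matrix(vapply(specs, `[[`, numeric(length(genes)), "mean"),
                       nrow = length(genes))
  colnames(type_means) <- vapply(specs, `[[`, "", "cell_type")
  disp <- rowMeans(matrix(
    vapply(specs, `[[`, numeric(length(genes)), "dispersion"),
    nrow = length(genes)))
  if (!is.null(plant)) {
    if (is.null(pathways)) stopf("a metabolic plant needs pathway signatures")
    path_genes <- intersect(unique(unlist(lapply(pathways, sig_genes))), genes)
  }
  reg <- as.vector(layout$region_map)
  ar <- as.vector(layout$area_map)
  xy <- expand.grid(x = seq_len(layout$width) - 1L,
                    y = seq_len(layout$height) - 1L)
  # spots in a hyper area form their own mean stratum
  hyper <- if (is.null(plant)) rep(FALSE, length(ar)) else
    !is.na(ar) & ar %in% plant$hyper_area_ids
  stratum <- paste(reg, ifelse(hyper, "hyper", "base"))

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  ii <- list(); jj <- list(); vv <- list()
  for (s in unique(stratum)) {
    r <- sub(" (hyper|base)$", "", s)
    comp <- layout$composition[[r]]
    if (is.null(comp) || length(comp) == 0)
      stopf("region '%s' has an empty composition", r)
    mu <- layout$abundance_factor[[r]] *
      as.numeric(type_means[, names(comp), drop = FALSE] %*% comp)
    if (endsWith(s, " hyper")) {
      idx <- match(path_genes, genes)
      mu[idx] <- mu[idx] * plant$pathway_fold
    }
    cols <- which(stratum == s)
    draws <- rnbinom(length(genes) * length(cols),
                     mu = rep(mu, length(cols)),
                     size = rep(disp, length(cols)))
    nz <- which(draws > 0)
    ii[[s]] <- ((nz - 1) %% length(genes)) + 1
    jj[[s]] <- cols[((nz - 1) %/% length(genes)) + 1]
    vv[[s]] <- draws[nz]
  }
  counts <- Matrix::sparseMatrix(i = unlist(ii, use.names = FALSE),
                                 j = unlist(jj, use.names = FALSE),
                                 x = unlist(vv, use.names = FALSE),
                                 dims = c(length(genes), length(reg)),
                                 dimnames = list(genes, NULL))
  spots <- spot_matrix(counts, xy, geometry)
  truth <- data.frame(x = xy$x, y = xy$y, region = reg, area_id = ar)
  list(spots = spots, truth = truth)
}

#' Attach ground-truth annotations to a binned matrix
#'
#' Assigns each bin the majority region (and, among its spots of that
#' region, the majority area id) of the truth table, so planted labels
#' survive binning.
#'
#' @param binmat a \code{bin_matrix}.
#' @param truth the \code{truth} data.frame from \code{\link{simulate_chip}}.
#' @return the bin matrix with an \code{annotations} data.frame
#'   (\code{region, area_id}).
#' @export
annotate_bins <- function(binmat, truth) {
  bs <- binmat$bin_size
  tb <- bin_id(truth$x %/% bs, truth$y %/% bs)
  majority <- function(v) names(which.max(table(v)))
  ids <- colnames(binmat$counts)
  reg <- vapply(split(truth$region, tb)[ids], majority, "")
  area_by_bin <- split(truth$area_id, tb)[ids]
  region_by_bin <- split(truth$region, tb)[ids]
  area <- vapply(seq_along(ids), function(i) {
    a <- area_by_bin[[i]][region_by_bin[[i]] == reg[i]]
    a <- a[!is.na(a)]
    if (length(a) == 0) NA_character_ else majority(a)
  }, "")
  binmat$annotations <- data.frame(region = unname(reg), area_id = area)
  binmat
}

#' Write chip ground truth as TSV
#'
#' @param truth truth data.frame from \code{\link{simulate_chip}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_truth <- function(truth, path) write_tsv(truth, path)

#' Simulate a per-base viral depth vector
#'
#' Exactly \code{round(covered_fraction * genome_len)} positions (sampled
#' uniformly) receive positive depth, drawn as 1 + Poisson(mean_depth - 1)
#' so the mean per covered base is \code{mean_depth}; all other positions
#' are zero.
#'
#' @param genome_len reference length (>= 1).
#' @param covered_fraction fraction of covered bases in [0, 1].
#' @param mean_depth mean depth of covered bases (>= 1 unless 0 covered).
#' @param seed integer seed.
#' @param hpv_type type name for the profile.
#' @return a \code{\link{coverage_profile}}.
#' @export
simulate_viral_depth <- function(genome_len, covered_fraction, mean_depth,
                                 seed, hpv_type = "HPV16") {
  if (genome_len < 1) stopf("genome_len must be >= 1")
  if (covered_fraction < 0 || covered_fraction > 1)
    stopf("covered_fraction must lie in [0, 1]")
  if (mean_depth < 0) stopf("mean_depth must be non-negative")
  n_cov <- round(covered_fraction * genome_len)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  depth <- numeric(genome_len)
  if (n_cov > 0) {
    pos <- sample(genome_len, n_cov)
    depth[pos] <- 1 + rpois(n_cov, max(mean_depth - 1, 0))
  }
  coverage_profile(hpv_type, depth, genome_len)
}

#' Simulate an IHC cohort with a planted score-stage association
#'
#' Stage is drawn from {I, II, III}; the probability that a sample's
#' composite score is high (final >= 4) follows a logistic model with the
#' given log-odds increase per stage step. Positivity percentage and
#' intensity are then drawn uniformly among the combinations consistent
#' with the sampled high/low status, and the remaining clinical covariates
#' are drawn independently. Missing values can be injected at a fixed rate.
#'
#' @param n cohort size (>= 10).
#' @param effect log-odds of a high score per stage step (0 = null).
#' @param seed integer seed.
#' @param na_rate probability a covariate value is missing.
#' @param p_high_base probability of a high score at stage II under the
#'   null.
#' @return data.frame with \code{sample_id, positivity_pct, intensity,
#'   stage, nodal, differentiation, tumor_size, scc_antigen, age}.
#' @export
simulate_ihc_cohort <- function(n = 71, effect = 0, seed = 1, na_rate = 0,
                                p_high_base = 0.38) {
  if (n < 10) stopf("cohort size must be >= 10")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  stage_num <- sample(1:3, n, replace = TRUE, prob = c(0.45, 0.30, 0.25))
  p_high <- plogis(qlogis(p_high_base) + effect * (stage_num - 2))
  high <- rbinom(n, 1, p_high) == 1
  # (positivity score, intensity) combos by product
  combos <- expand.grid(ps = 0:4, it = 0:3)
  combos$final <- combos$ps * combos$it
  hi <- combos[combos$final >= 4, ]
  lo <- combos[combos$final < 4, ]
  pick <- function(is_high) {
    pool <- if (is_high) hi else lo
    pool[sample(nrow(pool), 1), ]
  }
  drawn <- do.call(rbind, lapply(high, pick))
  # place the percentage uniformly inside the drawn score's bin
  lowb <- c(0, 6, 26, 51, 76); upb <- c(5, 25, 50, 75, 100)
  pct <- vapply(drawn$ps + 1, function(b)
    sample(seq(lowb[b], upb[b]), 1), 0)
  inject_na <- function(v) {
    if (na_rate > 0) v[runif(n) < na_rate] <- NA
    v
  }
  data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    positivity_pct = pct,
    intensity = drawn$it,
    stage = inject_na(c("I", "II", "III")[stage_num]),
    nodal = inject_na(sample(c("N0", ">=N1"), n, TRUE, prob = c(0.6, 0.4))),
    differentiation = inject_na(sample(c("low", "well_moderate"), n, TRUE,
                                       prob = c(0.4, 0.6))),
    tumor_size = inject_na(sample(c("<4cm", ">=4cm"), n, TRUE,
                                  prob = c(0.65, 0.35))),
    scc_antigen = inject_na(sample(c("<=1.5", ">1.5"), n, TRUE,
                                   prob = c(0.4, 0.6))),
    age = inject_na(sample(c("<=50", ">50"), n, TRUE, prob = c(0.45, 0.55))),
    row.names = NULL)
}
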