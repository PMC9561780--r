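test_that("all generators are deterministic in the seed", {
  prof <- default_profiles(default_universe(500))
  c1 <- simulate_cells(prof, 20, seed = 42)
  c2 <- simulate_cells(prof, 20, seed = 42)
  expect_identical(as.matrix(c1$counts), as.matrix(c2$counts))
  c3 <- simulate_cells(prof, 20, seed = 43)
  expect_false(identical(as.matrix(c1$counts), as.matrix(c3$counts)))

  lay <- region_layout(width = 40, height = 40, n_tumor = 2, n_ring = 1,
                       blob_radius = 4, seed = 5)
  s1 <- simulate_chip(lay, prof, seed = 9)
  s2 <- simulate_chip(lay, prof, seed = 9)
  expect_identical(as.matrix(s1$spots$counts), as.matrix(s2$spots$counts))
  expect_identical(s1$truth, s2$truth)

  v1 <- simulate_viral_depth(1000, 0.3, 40, seed = 7)
  v2 <- simulate_viral_depth(1000, 0.3, 40, seed = 7)
  expect_identical(v1$depth, v2$depth)

  i1 <- simulate_ihc_cohort(71, effect = 0.5, seed = 3)
  i2 <- simulate_ihc_cohort(71, effect = 0.5, seed = 3)
  expect_identical(i1, i2)
})

test_that("profile validation catches unknown markers and bad folds", {
  mu <- setNames(rep(0.2, 10), sprintf("g%02d", 1:10))
  expect_error(cell_profile_spec("t", mu, marker_genes = "gXX"), "gXX")
  expect_error(cell_profile_spec("t", mu, marker_genes = "g01",
                                 marker_fold = 0.5), "marker_fold")
  expect_error(cell_profile_spec("t", c(mu, gNA = Inf)), "finite")
  specs <- default_profiles(default_universe(500))
  expect_error(simulate_cells(specs, 0, seed = 1), "n_per_type")
})

test_that("marker elevation lands on the right genes and types", {
  uni <- default_universe(500)
  prof <- default_profiles(uni, baseline = 0.5, marker_fold = 8)
  cells <- simulate_cells(prof, 200, seed = 11)
  m <- cells$counts
  my <- Matrix::rowMeans(m[, cells$cell_type == "myCAF"])
  other <- Matrix::rowMeans(m[, cells$cell_type != "myCAF"])
  markers <- default_marker_sets()$myCAF
  expect_gt(min(my[markers] / pmax(other[markers], 0.01)), 3)
  # null case: no fold, no systematic marker difference
  prof0 <- default_profiles(uni, marker_fold = 1)
  cells0 <- simulate_cells(prof0, 200, seed = 12)
  p <- wilcox.test(
    as.numeric(cells0$counts[markers, cells0$cell_type == "myCAF"]),
    as.numeric(cells0$counts[markers, cells0$cell_type == "fibroblast"]))$p.value
  expect_gt(p, 0.01)
})

test_that("chip composition: expected counts follow the mixture analytically", {
  # 1-gene toy: mean = abundance * sum_t comp_t * mu_t, checked analytically
  mu <- c(gene = 10)
  specs <- list(cell_profile_spec("a", mu * 0 + 2, dispersion = 50),
                cell_profile_spec("b", mu * 0 + 8, dispersion = 50))
  lay <- structure(list(
    width = 60, height = 60,
    region_map = matrix(rep(c("tumor", "stroma"), each = 1800), 60, 60),
    area_map = matrix(NA_character_, 60, 60),
    composition = list(tumor = c(a = 0.25, b = 0.75),
                       stroma = c(a = 1)),
    abundance_factor = c(tumor = 3, stroma = 1)), class = "region_layout")
  sim <- simulate_chip(lay, specs, seed = 19)
  reg <- sim$truth$region
  tumor_mean <- mean(sim$spots$counts[1, reg == "tumor"])
  stroma_mean <- mean(sim$spots$counts[1, reg == "stroma"])
  expect_equal(tumor_mean, 3 * (0.25 * 2 + 0.75 * 8), tolerance = 0.05)
  expect_equal(stroma_mean, 1 * 2, tolerance = 0.05)
})

test_that("tumor/stroma RNA abundance ratio matches the planted factor", {
  uni <- default_universe(500)
  prof <- default_profiles(uni)
  lay <- region_layout(width = 110, height = 110, n_tumor = 9, n_ring = 0,
                       blob_radius = 9, n_inflammation = 0, seed = 23)
  sim <- simulate_chip(lay, prof, seed = 29)
  umi <- Matrix::colSums(sim$spots$counts)
  ratio <- mean(umi[sim$truth$region == "tumor"]) /
    mean(umi[sim$truth$region == "stroma"])
  expect_gt(ratio, 2.5)
  expect_lt(ratio, 3.5)
})

test_that("layouts validate compositions and keep rings around their tumors", {
  expect_error(region_layout(composition = list(tumor = c(a = 0.5),
                                                stroma = c(a = 1))),
               "sum to 1")
  expect_error(region_layout(abundance_factor = c(tumor = 1, stroma = 2,
                                                  mycaf_ring = 1,
                                                  inflammation = 1)),
               "exceed")
  lay <- region_layout(width = 60, height = 60, n_tumor = 3, n_ring = 2,
                       blob_radius = 5, ring_width = 2, seed = 2)
  # every ring spot is adjacent to the annulus of exactly one tumor blob:
  # its area id names the tumor it encloses, and it touches that tumor
  rid <- which(lay$region_map == "mycaf_ring", arr.ind = TRUE)
  expect_gt(nrow(rid), 0)
  for (i in seq_len(nrow(rid))) {
    ring_area <- lay$area_map[rid[i, 1], rid[i, 2]]
    expect_match(ring_area, "^ring_0[12]$")
  }
  # ring areas enclose their tumor: some ring spot is lattice-adjacent to it
  for (rn in c("01", "02")) {
    ring_cells <- which(lay$area_map == paste0("ring_", rn), arr.ind = TRUE)
    tumor_cells <- which(lay$area_map == paste0("tumor_", rn), arr.ind = TRUE)
    d <- as.matrix(dist(rbind(ring_cells, tumor_cells)))
    cross <- d[seq_len(nrow(ring_cells)),
               nrow(ring_cells) + seq_len(nrow(tumor_cells))]
    expect_lt(min(cross), 1.5) # touching under 8-connectivity
  }
})

test_that("zero-ring layouts flag nothing downstream", {
  grid <- data.frame(cell_type = "myCAF", region = c("tumor_01", "stroma"),
                     p_adj = c(0.9, 0.9))
  expr <- rbind(POSTN = c(1, 1, 1, 1))
  colnames(expr) <- sprintf("b%d", 1:4)
  gate <- call_mycaf_regions(grid, expr,
                             c("tumor_01", "tumor_01", "stroma", "stroma"))
  expect_false(any(gate$flagged))
})

test_that("viral depth generator hits the requested coverage exactly", {
  expect_equal(sum(simulate_viral_depth(500, 0, 60, seed = 1)$depth), 0)
  full <- simulate_viral_depth(7906, 1.0, 60, seed = 2)
  expect_equal(sum(full$depth > 0), 7906)
  part <- simulate_viral_depth(7906, 0.08, 60, seed = 3)
  expect_equal(sum(part$depth > 0), round(0.08 * 7906))
  expect_true(call_hpv(part)$positive) # 8% at 60x clears both thresholds
  expect_error(simulate_viral_depth(100, 0.5, -3, seed = 1), "mean_depth")
  expect_error(simulate_viral_depth(100, 1.2, 3, seed = 1), "covered_fraction")
})

test_that("IHC cohort: planted effect raises rejections, null stays flat", {
  # power at a strong planted effect
  rej <- vapply(1:40, function(s) {
    coh <- simulate_ihc_cohort(200, effect = 2, seed = 2000 + s)
    p <- table1_report(coh, covariates = "stage")$stage$p
    p < 0.05
  }, TRUE)
  expect_gte(mean(rej), 0.8)
  # missing values are injectable and excluded listwise
  coh <- simulate_ihc_cohort(100, effect = 0, seed = 1, na_rate = 0.2)
  expect_true(any(is.na(coh$stage)))
  rep_ <- table1_report(coh, covariates = c("stage", "nodal"))
  expect_equal(sum(rep_$stage$table), sum(!is.na(coh$stage)))
})
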