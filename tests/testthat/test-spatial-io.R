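test_that("GEM parsing sums duplicates, keeps gene order, and round-trips", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("geneID\tx\ty\tMIDCount",
               "GENE1\t3\t5\t2",
               "GENE2\t0\t0\t1",
               "GENE1\t3\t5\t1",
               "GENE1\t4\t5\t4"), path)
  sm <- read_gem(path)
  expect_equal(rownames(sm$counts), c("GENE1", "GENE2"))
  expect_equal(as.numeric(sm$counts["GENE1", "3_5"]), 3) # 2 + 1 summed
  expect_equal(as.numeric(sm$counts["GENE1", "4_5"]), 4)

  out <- withr::local_tempfile(fileext = ".tsv")
  write_gem(sm, out)
  rt <- read_gem(out)
  expect_equal(as.matrix(rt$counts)[, colnames(sm$counts)],
               as.matrix(sm$counts))

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("geneID\tx\ty\tMIDCount", empty)
  e <- read_gem(empty)
  expect_equal(ncol(e$counts), 0)
  out2 <- withr::local_tempfile(fileext = ".tsv")
  write_gem(e, out2)
  expect_equal(ncol(read_gem(out2)$counts), 0)
})

test_that("GEM parse errors name the offending line", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("geneID\tx\ty\tMIDCount", "G1\t1\t1\t2", "G1\t1.5\t2\t1"), path)
  expect_error(read_gem(path), "line 3")
  writeLines(c("geneID\tx\ty\tMIDCount", "G1\t1\t1\t-2"), path)
  expect_error(read_gem(path), "line 2")
  writeLines(c("geneID\tx\tMIDCount", "G1\t1\t2"), path)
  expect_error(read_gem(path), "missing column")
})

test_that("physical bin edge reproduces the platform bin footprints", {
  expect_equal(physical_bin_edge(100), 49.72)
  expect_equal(physical_bin_edge(200), 99.72)
  g <- chip_geometry(spot_diameter_nm = 180, pitch_nm = 600)
  expect_equal(physical_bin_edge(1, g), 0.180) # single spot: its diameter
  expect_error(physical_bin_edge(0), "bin_size")
  # strictly increasing with slope = pitch
  edges <- vapply(1:50, physical_bin_edge, 0)
  expect_true(all(diff(edges) > 0))
  expect_equal(unique(round(diff(edges), 10)), 0.5)
})

test_that("binning uses floor division and conserves counts exactly", {
  counts <- matrix(c(5, 3, 7), nrow = 1, dimnames = list("g1", NULL))
  sm <- spot_matrix(counts, data.frame(x = c(0, 99, 100), y = c(0, 99, 0)))
  bm <- bin_spots(sm, 100)
  expect_equal(as.numeric(bm$counts["g1", "0_0"]), 8)
  expect_equal(as.numeric(bm$counts["g1", "1_0"]), 7)

  sm2 <- make_spots(n_genes = 15, n_spots = 500, seed = 42)
  ident <- bin_spots(sm2, 1)
  expect_equal(sort(Matrix::colSums(ident$counts)),
               sort(Matrix::colSums(sm2$counts)))
  for (bs in c(3, 7, 10)) {
    bm2 <- bin_spots(sm2, bs)
    expect_equal(Matrix::rowSums(bm2$counts), Matrix::rowSums(sm2$counts))
    expect_equal(sum(bm2$counts), sum(sm2$counts))
  }
})

test_that("bin QC thresholds are strict and QC is idempotent", {
  # three bins with totals 200, 201, 1000 (bin size 10 keeps spots apart)
  counts <- matrix(0, nrow = 300, ncol = 3,
                   dimnames = list(sprintf("g%03d", 1:300), NULL))
  counts[1:100, 1] <- 2                      # 200 UMIs over 100 genes
  counts[1:201, 2] <- 1                      # 201 UMIs over 201 genes
  counts[1:250, 3] <- 4                      # 1000 UMIs over 250 genes
  sm <- spot_matrix(counts, data.frame(x = c(0, 10, 20), y = c(0, 0, 0)))
  bm <- bin_spots(sm, 10)
  qc <- qc_bins(bm, min_umi = 200, min_median_genes = 100)
  expect_equal(qc$report$n_bins_kept, 2) # the 200-UMI bin is removed
  expect_true(all(Matrix::colSums(qc$binmat$counts) > 200))
  # median distinct genes = (201 + 250)/2 = 225.5 > 100 -> pass
  expect_true(qc$report$chip_pass)
  # a chip whose retained median is exactly the threshold fails (strict >)
  qc2 <- qc_bins(bm, min_umi = 200, min_median_genes = 225.5)
  expect_false(qc2$report$chip_pass)
  # idempotence
  qc3 <- qc_bins(qc$binmat, min_umi = 200, min_median_genes = 100)
  expect_equal(as.matrix(qc3$binmat$counts), as.matrix(qc$binmat$counts))
  # removing everything is loud, not silent
  expect_warning(qc4 <- qc_bins(bm, min_umi = 1e6), "every bin")
  expect_equal(qc4$report$status, "EMPTY")
})

test_that("log-normalization matches direct arithmetic and its invariances", {
  counts <- matrix(c(1, 1, 2), ncol = 1,
                   dimnames = list(c("a", "b", "c"), "u1"))
  norm <- log_normalize(counts)
  expect_equal(as.numeric(norm["a", 1]), log(2501), tolerance = 1e-12)
  counts2 <- cbind(counts, u2 = c(0, 4, 4))
  norm2 <- log_normalize(counts2)
  expect_equal(as.numeric(norm2["a", "u2"]), 0) # zero count stays zero
  # per-unit scale invariance
  expect_equal(as.matrix(log_normalize(counts2 * 7)), as.matrix(norm2))
  # monotone in counts within a unit
  expect_true(norm2["c", "u1"] > norm2["a", "u1"])
  expect_error(log_normalize(cbind(counts, u3 = c(0, 0, 0))), "zero total")
})

test_that("bin matrix export writes MTX plus sidecars", {
  sm <- make_spots(seed = 9)
  bm <- bin_spots(sm, 5)
  dir <- withr::local_tempdir()
  write_bin_matrix(bm, dir)
  m <- Matrix::readMM(file.path(dir, "counts.mtx"))
  expect_equal(sum(m), sum(bm$counts))
  bins <- read.delim(file.path(dir, "bins.tsv"))
  expect_equal(nrow(bins), ncol(bm$counts))
})
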