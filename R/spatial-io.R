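#' Chip geometry of a sub-micron spatial capture array
#'
#' Describes the physical layout of the capture spots: their diameter and the
#' center-to-center pitch between adjacent spots. The defaults are the
#' platform values used throughout the package: 220 nm spots at a 500 nm
#' pitch.
#'
#' @param spot_diameter_nm spot diameter in nanometres.
#' @param pitch_nm center-to-center distance between adjacent spots (nm).
#' @return an object of class \code{chip_geometry}.
#' @export
chip_geometry <- function(spot_diameter_nm = 220, pitch_nm = 500) {
  if (!(spot_diameter_nm > 0 && pitch_nm > 0 && spot_diameter_nm <= pitch_nm))
    stopf("require 0 < spot_diameter <= pitch (got %s, %s)",
          spot_diameter_nm, pitch_nm)
  structure(list(spot_diameter_nm = spot_diameter_nm, pitch_nm = pitch_nm),
            class = "chip_geometry")
}

#' Physical edge length of a square bin
#'
#' A bin of \code{bin_size} x \code{bin_size} spots spans
#' \code{(bin_size - 1) * pitch + spot_diameter} from the outer edge of the
#' first spot to the outer edge of the last, returned in micrometres. With
#' the default geometry, bin100 covers 49.72 um and bin200 covers 99.72 um
#' per side.
#'
#' @param bin_size number of spots per bin side (>= 1).
#' @param geometry a \code{\link{chip_geometry}}.
#' @return edge length in micrometres.
#' @export
physical_bin_edge <- function(bin_size, geometry = chip_geometry()) {
  if (length(bin_size) != 1L || is.na(bin_size) || bin_size < 1 ||
      bin_size != round(bin_size))
    stopf("bin_size must be a single integer >= 1")
  ((bin_size - 1) * geometry$pitch_nm + geometry$spot_diameter_nm) / 1000
}

spot_id <- function(x, y) paste(x, y, sep = "_")

#' Construct a spot-level count matrix
#'
#' @param counts sparse or dense genes x spots matrix of non-negative
#'   integer counts; column names must be \code{"x_y"} spot ids.
#' @param coords data.frame with integer columns \code{x}, \code{y}, one row
#'   per spot, in column order of \code{counts}.
#' @param geometry a \code{\link{chip_geometry}}.
#' @return an object of class \code{spot_matrix}.
#' @export
spot_matrix <- function(counts, coords, geometry = chip_geometry()) {
  if (is.matrix(counts)) counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (ncol(counts) != nrow(coords)) stopf("counts/coords dimension mismatch")
  if (any(counts@x < 0)) stopf("negative counts")
  if (anyDuplicated(spot_id(coords$x, coords$y)))
    stopf("duplicate spot coordinates")
  colnames(counts) <- spot_id(coords$x, coords$y)
  structure(list(counts = counts,
                 coords = data.frame(x = as.integer(coords$x),
                                     y = as.integer(coords$y)),
                 geometry = geometry),
            class = "spot_matrix")
}

#' @export
print.spot_matrix <- function(x, ...) {
  cat(sprintf("spot_matrix: %d genes x %d spots, %d UMIs\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Read a GEM-format spot table
#'
#' The GEM dialect is a TSV with header columns \code{geneID}, \code{x},
#' \code{y}, \code{MIDCount}: one row per (gene, spot) observation.
#' Duplicate (gene, x, y) rows are summed. Gene order follows first
#' appearance in the file.
#'
#' @param path file path.
#' @param geometry a \code{\link{chip_geometry}} attached to the result.
#' @return a \code{\link{spot_matrix}}.
#' @export
read_gem <- function(path, geometry = chip_geometry()) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  need <- c("geneID", "x", "y", "MIDCount")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stopf("GEM file %s is missing column(s): %s", path,
          paste(miss, collapse = ", "))
  tab <- tab[need]
  bad_coord <- which(tab$x != round(tab$x) | tab$y != round(tab$y) |
                     is.na(tab$x) | is.na(tab$y))
  if (length(bad_coord))
    stopf("non-integer coordinate at line %d of %s", bad_coord[1] + 1L, path)
  bad_cnt <- which(is.na(tab$MIDCount) | tab$MIDCount < 0 |
                   tab$MIDCount != round(tab$MIDCount))
  if (length(bad_cnt))
    stopf("invalid count at line %d of %s", bad_cnt[1] + 1L, path)

  genes <- unique(tab$geneID)
  sid <- spot_id(tab$x, tab$y)
  spots <- unique(sid)
  if (nrow(tab) == 0) {
    counts <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                   x = numeric(0), dims = c(0, 0))
    return(spot_matrix(counts, data.frame(x = integer(0), y = integer(0)),
                       geometry))
  }
  counts <- Matrix::sparseMatrix(
    i = match(tab$geneID, genes), j = match(sid, spots), x = tab$MIDCount,
    dims = c(length(genes), length(spots)),
    dimnames = list(genes, spots))
  xy <- do.call(rbind, strsplit(spots, "_", fixed = TRUE))
  spot_matrix(counts,
              data.frame(x = as.integer(xy[, 1]), y = as.integer(xy[, 2])),
              geometry)
}

#' Write a spot matrix as GEM TSV
#'
#' @param spots a \code{\link{spot_matrix}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_gem <- function(spots, path) {
  m <- methods::as(spots$counts, "TsparseMatrix")
  df <- data.frame(geneID = as.character(rownames(spots$counts))[m@i + 1L],
                   x = spots$coords$x[m@j + 1L],
                   y = spots$coords$y[m@j + 1L],
                   MIDCount = as.integer(m@x))
  df <- df[order(match(df$geneID, rownames(spots$counts)), df$x, df$y), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

bin_id <- function(bx, by) paste(bx, by, sep = "_")

#' Aggregate capture spots into square bins
#'
#' Spots are assigned to bins by floor division of their 0-based lattice
#' coordinates: spot (x, y) belongs to bin (floor(x/s), floor(y/s)) for bin
#' size s, so each bin footprint is the half-open square
#' [k*s, (k+1)*s) x [l*s, (l+1)*s). Counts are summed within bins; per-gene
#' totals are conserved exactly.
#'
#' @param spots a \code{\link{spot_matrix}}.
#' @param bin_size spots per bin side (>= 1); 100 reproduces the standard
#'   "bin100" unit, 200 "bin200".
#' @return an object of class \code{bin_matrix} with fields \code{counts}
#'   (genes x bins sparse matrix), \code{bins} (data.frame \code{bx, by}),
#'   \code{bin_size}, \code{geometry} and optional \code{annotations}.
#' @export
bin_spots <- function(spots, bin_size) {
  if (bin_size < 1 || bin_size != round(bin_size))
    stopf("bin_size must be an integer >= 1")
  bx <- spots$coords$x %/% bin_size
  by <- spots$coords$y %/% bin_size
  bid <- bin_id(bx, by)
  ubid <- unique(bid)
  # spot -> bin aggregation as a sparse indicator product
  agg <- Matrix::sparseMatrix(i = seq_along(bid), j = match(bid, ubid),
                              x = 1, dims = c(length(bid), length(ubid)))
  counts <- spots$counts %*% agg
  colnames(counts) <- ubid
  xy <- do.call(rbind, strsplit(ubid, "_", fixed = TRUE))
  structure(list(counts = methods::as(counts, "CsparseMatrix"),
                 bins = data.frame(bx = as.integer(xy[, 1]),
                                   by = as.integer(xy[, 2])),
                 bin_size = as.integer(bin_size),
                 geometry = spots$geometry,
                 annotations = NULL),
            class = "bin_matrix")
}

#' @export
print.bin_matrix <- function(x, ...) {
  cat(sprintf("bin_matrix: %d genes x %d bins (bin size %d, edge %.2f um)\n",
              nrow(x$counts), ncol(x$counts), x$bin_size,
              physical_bin_edge(x$bin_size, x$geometry)))
  invisible(x)
}

#' Bin-level quality control
#'
#' Removes bins whose total UMI count is not strictly greater than
#' \code{min_umi} (default 200), optionally drops genes detected in fewer
#' than \code{min_bins_expressed} retained bins, and flags the chip as
#' failing QC unless the median number of distinct genes per retained bin is
#' strictly greater than \code{min_median_genes} (default 1000). Both
#' thresholds are strict inequalities: a bin with exactly 200 UMIs is
#' removed and a chip with a median of exactly 1000 gene types fails.
#'
#' @param binmat a \code{\link{bin_spots}} result.
#' @param min_umi minimum (exclusive) UMI total per bin.
#' @param min_median_genes minimum (exclusive) median distinct-gene count.
#' @param min_bins_expressed drop genes detected in fewer than this many
#'   retained bins (default 1, i.e. only never-detected genes go).
#' @return list with \code{binmat} (filtered) and \code{report} (list with
#'   counts, the median gene number, \code{chip_pass}, and a \code{status}
#'   of \code{"OK"} or \code{"EMPTY"} when no bin survives).
#' @export
qc_bins <- function(binmat, min_umi = 200, min_median_genes = 1000,
                    min_bins_expressed = 1) {
  if (ncol(binmat$counts) == 0) stopf("qc_bins: empty bin matrix")
  umi <- Matrix::colSums(binmat$counts)
  keep <- umi > min_umi
  out <- binmat
  out$counts <- binmat$counts[, keep, drop = FALSE]
  out$bins <- binmat$bins[keep, , drop = FALSE]
  if (!is.null(binmat$annotations))
    out$annotations <- binmat$annotations[keep, , drop = FALSE]
  if (!any(keep)) {
    report <- list(status = "EMPTY", n_bins_in = length(umi), n_bins_kept = 0L,
                   median_genes = NA_real_, chip_pass = FALSE,
                   min_umi = min_umi, min_median_genes = min_median_genes)
    warnf("qc_bins removed every bin (min_umi = %d)", min_umi)
    return(list(binmat = out, report = report))
  }
  gene_bins <- Matrix::rowSums(out$counts > 0)
  gkeep <- gene_bins >= min_bins_expressed
  out$counts <- out$counts[gkeep, , drop = FALSE]
  med_genes <- median(Matrix::colSums(out$counts > 0))
  report <- list(status = "OK",
                 n_bins_in = length(umi),
                 n_bins_kept = sum(keep),
                 n_genes_kept = sum(gkeep),
                 median_genes = as.numeric(med_genes),
                 chip_pass = med_genes > min_median_genes,
                 min_umi = min_umi, min_median_genes = min_median_genes)
  list(binmat = out, report = report)
}

#' Library-size log-normalization
#'
#' Each count is scaled to \code{scale} total counts per unit and
#' log-transformed: \code{ln(count * scale / unit_total + 1)}. Zero counts
#' map to zero, so sparsity is preserved. Values are invariant to
#' multiplying all counts of a unit by a constant and monotone in counts
#' within a unit.
#'
#' @param x a \code{bin_matrix}, or any genes x units count matrix.
#' @param scale target library size (default 1e4).
#' @return sparse genes x units matrix of normalized values.
#' @export
log_normalize <- function(x, scale = 1e4) {
  counts <- if (inherits(x, "bin_matrix")) x$counts else {
    if (is.matrix(x)) x <- Matrix::Matrix(x, sparse = TRUE)
    methods::as(methods::as(x, "CsparseMatrix"), "generalMatrix")
  }
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) stopf("log_normalize: unit with zero total counts")
  m <- methods::as(counts, "TsparseMatrix")
  m@x <- log(m@x * scale / totals[m@j + 1L] + 1)
  methods::as(m, "CsparseMatrix")
}

#' Export a bin matrix as MatrixMarket + TSV sidecars
#'
#' Writes \code{counts.mtx} (sparse, genes x bins), \code{genes.tsv} and
#' \code{bins.tsv} (with region annotations when present) into \code{dir}.
#'
#' @param binmat a \code{bin_matrix}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_bin_matrix <- function(binmat, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(binmat$counts, file.path(dir, "counts.mtx"))
  write_tsv(data.frame(gene = rownames(binmat$counts)),
            file.path(dir, "genes.tsv"))
  bins <- binmat$bins
  bins$bin <- colnames(binmat$counts)
  if (!is.null(binmat$annotations)) bins <- cbind(bins, binmat$annotations)
  write_tsv(bins, file.path(dir, "bins.tsv"))
  invisible(dir)
}
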