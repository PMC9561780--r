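#' Multimodal intersection analysis (MIA) test
#'
#' Hypergeometric test of the overlap between a cell-type marker set (from
#' the dissociated single-nucleus data) and a spatial-region marker set
#' (from the spatial data), over a shared background universe of N genes.
#' With m cell-type markers, n region markers, and k genes in common, the
#' enrichment p-value is the upper tail P(X >= k) and the depletion p-value
#' the lower tail P(X <= k) of Hypergeometric(N, m, n). The smaller the
#' enrichment p-value (the "MIA score", reported as -log10 p), the stronger
#' the correspondence between cell type and region.
#'
#' @param cell_set,region_set character gene vectors (or
#'   \code{\link{gene_signature}}s).
#' @param background either the character gene universe or its size N.
#'   When a universe is given, both sets must be subsets of it.
#' @return object of class \code{mia_result}: list with \code{k, m, n, N,
#'   p_enrich, p_deplete, neg_log10_p}.
#' @export
mia_test <- function(cell_set, region_set, background) {
  cs <- unique(sig_genes(cell_set))
  rs <- unique(sig_genes(region_set))
  if (is.character(background)) {
    bg <- unique(background)
    out_cs <- setdiff(cs, bg); out_rs <- setdiff(rs, bg)
    if (length(out_cs) || length(out_rs))
      stopf("marker genes outside the background universe: %s",
            paste(head(c(out_cs, out_rs), 3), collapse = ", "))
    N <- length(bg)
    k <- length(intersect(cs, rs))
    m <- length(cs); n <- length(rs)
  } else {
    N <- as.integer(background)
    m <- length(cs); n <- length(rs)
    k <- length(intersect(cs, rs))
  }
  if (N < max(m, n)) stopf("background N = %d smaller than a set (m=%d, n=%d)",
                           N, m, n)
  if (k < m + n - N)
    stopf("infeasible overlap: k=%d < m+n-N = %d", k, m + n - N)
  p_enrich <- phyper(k - 1, m, N - m, n, lower.tail = FALSE)
  p_deplete <- phyper(k, m, N - m, n)
  structure(list(k = k, m = m, n = n, N = N,
                 p_enrich = p_enrich, p_deplete = p_deplete,
                 neg_log10_p = -log10(p_enrich)),
            class = "mia_result")
}

#' @export
print.mia_result <- function(x, ...) {
  cat(sprintf("MIA: k=%d of m=%d x n=%d in N=%d; p_enrich=%.3g (score %.2f)\n",
              x$k, x$m, x$n, x$N, x$p_enrich, x$neg_log10_p))
  invisible(x)
}

#' All pairwise MIA tests with FDR adjustment
#'
#' Runs \code{\link{mia_test}} for every (cell type, region) pair and
#' adjusts the enrichment p-values across the whole grid by
#' Benjamini-Hochberg.
#'
#' @param cell_sets named list of cell-type marker gene vectors.
#' @param region_sets named list of region marker gene vectors.
#' @param background gene universe (character) or its size N.
#' @return data.frame with one row per pair: \code{cell_type, region, k, m,
#'   n, N, p_enrich, p_deplete, neg_log10_p, p_adj}.
#' @export
mia_matrix <- function(cell_sets, region_sets, background) {
  if (length(cell_sets) == 0 || length(region_sets) == 0)
    stopf("need at least one marker set on each side")
  if (anyDuplicated(names(cell_sets)) || anyDuplicated(names(region_sets)))
    stopf("duplicate marker-set owners")
  grid <- expand.grid(cell_type = names(cell_sets),
                      region = names(region_sets),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    r <- mia_test(cell_sets[[grid$cell_type[i]]],
                  region_sets[[grid$region[i]]], background)
    data.frame(cell_type = grid$cell_type[i], region = grid$region[i],
               k = r$k, m = r$m, n = r$n, N = r$N,
               p_enrich = r$p_enrich, p_deplete = r$p_deplete,
               neg_log10_p = r$neg_log10_p)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p_enrich)
  out
}

#' Joint MIA + marker-expression gate for myCAF regions
#'
#' A region is called myCAF-positive only when both conditions hold
#' simultaneously: (1) its adjusted MIA enrichment p-value for the myCAF
#' cell type is below \code{mia_alpha}, and (2) its mean normalized
#' expression of the marker gene (periostin, \emph{POSTN}, by default) is
#' above the \code{expr_quantile} quantile of all region means. The
#' conjunction guards against spurious MIA hits in regions with low RNA
#' abundance.
#'
#' @param mia a \code{\link{mia_matrix}} result.
#' @param expr genes x bins normalized expression matrix.
#' @param regions per-bin region label vector (named by bin id, or in column
#'   order of \code{expr}).
#' @param cell_type name of the myCAF cell type in \code{mia}.
#' @param marker_gene marker gene (default \code{"POSTN"}).
#' @param mia_alpha threshold on the adjusted enrichment p (default 0.05).
#' @param expr_quantile quantile of region means the marker expression must
#'   exceed (default 0.75).
#' @return data.frame with one row per region: \code{region, p_adj,
#'   marker_mean, pass_mia, pass_marker, flagged}.
#' @export
call_mycaf_regions <- function(mia, expr, regions, cell_type = "myCAF",
                               marker_gene = "POSTN", mia_alpha = 0.05,
                               expr_quantile = 0.75) {
  if (!(mia_alpha > 0 && mia_alpha < 1) ||
      !(expr_quantile > 0 && expr_quantile < 1))
    stopf("gate thresholds must lie strictly in (0, 1)")
  if (!marker_gene %in% rownames(expr))
    stopf("marker gene '%s' absent from expression table", marker_gene)
  if (length(regions) != ncol(expr)) stopf("one region label per bin required")
  sub <- mia[mia$cell_type == cell_type, , drop = FALSE]
  if (nrow(sub) == 0) stopf("cell type '%s' not present in MIA grid", cell_type)
  marker <- as.numeric(expr[marker_gene, ])
  reg_means <- tapply(marker, regions, mean)
  thr <- quantile(reg_means, expr_quantile, names = FALSE)
  out <- data.frame(region = sub$region,
                    p_adj = sub$p_adj,
                    marker_mean = as.numeric(reg_means[sub$region]),
                    stringsAsFactors = FALSE)
  out$pass_mia <- out$p_adj < mia_alpha
  out$pass_marker <- !is.na(out$marker_mean) & out$marker_mean > thr
  out$flagged <- out$pass_mia & out$pass_marker
  attr(out, "marker_threshold") <- thr
  out
}
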