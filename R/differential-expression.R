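#' Benjamini-Hochberg adjustment with input validation
#'
#' Step-up false discovery rate adjustment; values are monotone in the
#' sorted input, elementwise at least the raw p, and capped at 1.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stopf("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

# exact two-sided rank-sum p by enumerating all assignments of the observed
# ranks to group 1; symmetric deviation from the permutation mean. Handles
# ties because the observed (midrank) values are permuted as-is.
rank_sum_exact_p <- function(r_all, n1) {
  n <- length(r_all)
  combos <- utils::combn(n, n1)
  w_all <- colSums(matrix(r_all[combos], nrow = n1))
  mu <- mean(w_all)
  w_obs <- sum(r_all[seq_len(n1)])
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

# normal-approximation two-sided rank-sum p with tie correction and
# continuity correction; w1 = rank sum of group 1 within the pooled sample
rank_sum_normal_p <- function(w1, n1, n2, tie_term) {
  n <- n1 + n2
  mu <- n1 * (n + 1) / 2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (abs(w1 - mu) - 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(-max(z, 0)))
}

#' Two-group differential expression with rank-sum tests and filters
#'
#' Per gene: a two-sided Wilcoxon rank-sum test of group 1 versus group 2
#' (exact enumeration of all assignments when the pooled size is <= 10,
#' otherwise the normal approximation with tie correction), a log2 fold
#' change computed on de-logged means with a +1 pseudocount,
#' \code{log2((mean(expm1(x1)) + 1) / (mean(expm1(x2)) + 1))}, and the
#' fraction of expressing (> 0) units per group. P-values are adjusted
#' across all tested genes (Benjamini-Hochberg by default) and the standard
#' filter is applied: |log2FC| strictly > \code{fc_threshold}, expressed
#' fraction in the target group strictly > \code{pct_threshold}, adjusted p
#' strictly < \code{alpha}.
#'
#' @param expr genes x units normalized (log) expression matrix.
#' @param group1,group2 unit ids (column names) of the two disjoint groups;
#'   group 1 is the target group for the expressed-fraction filter.
#' @param fc_threshold,pct_threshold,alpha filter thresholds (all strict).
#' @param adjust multiple-testing method passed to \code{p.adjust}.
#' @return data.frame with columns \code{gene, log2fc, pct1, pct2, p, p_adj,
#'   passes_filter}, one row per gene in input order. The adjustment method
#'   is recorded in \code{attr(, "adjust")}.
#' @export
de_test <- function(expr, group1, group2, fc_threshold = 0.25,
                    pct_threshold = 0.25, alpha = 0.05, adjust = "BH") {
  if (length(intersect(group1, group2)) > 0)
    stopf("groups overlap: %s",
          paste(head(intersect(group1, group2), 3), collapse = ", "))
  if (length(group1) < 2 || length(group2) < 2)
    stopf("each group needs at least 2 units")
  miss <- setdiff(c(group1, group2), colnames(expr))
  if (length(miss)) stopf("unknown unit id(s): %s",
                          paste(head(miss, 3), collapse = ", "))
  x1 <- as_dense(expr[, group1, drop = FALSE])
  x2 <- as_dense(expr[, group2, drop = FALSE])
  n1 <- ncol(x1); n2 <- ncol(x2); n <- n1 + n2
  pooled <- cbind(x1, x2)

  m1 <- rowMeans(expm1(x1)); m2 <- rowMeans(expm1(x2))
  log2fc <- log2((m1 + 1) / (m2 + 1))
  pct1 <- rowMeans(x1 > 0); pct2 <- rowMeans(x2 > 0)

  if (n <= 10) {
    p <- apply(pooled, 1, function(v) rank_sum_exact_p(rank(v), n1))
  } else {
    rk <- t(apply(pooled, 1, rank))
    w1 <- rowSums(rk[, seq_len(n1), drop = FALSE])
    tie_term <- apply(pooled, 1, function(v) {
      tl <- table(v); sum(tl^3 - tl)
    })
    p <- vapply(seq_len(nrow(pooled)), function(i)
      rank_sum_normal_p(w1[i], n1, n2, tie_term[i]), 0)
  }
  p_adj <- if (identical(adjust, "BH")) bh_adjust(p) else
    p.adjust(p, method = adjust)
  res <- data.frame(gene = rownames(expr), log2fc = log2fc,
                    pct1 = pct1, pct2 = pct2, p = p, p_adj = p_adj,
                    passes_filter = abs(log2fc) > fc_threshold &
                      pct1 > pct_threshold & p_adj < alpha,
                    row.names = NULL)
  attr(res, "adjust") <- adjust
  res
}

# fast one-vs-rest path: ranks over all units are computed once per gene and
# reused for every label's rank-sum statistic
de_one_vs_rest <- function(expr, labels, fc_threshold, pct_threshold, alpha,
                           adjust) {
  dense <- as_dense(expr)
  n <- ncol(dense)
  rk <- t(apply(dense, 1, rank))
  tie_term <- apply(dense, 1, function(v) {
    tl <- table(v); sum(tl^3 - tl)
  })
  em <- expm1(dense)
  lapply(setNames(nm = unique(labels)), function(lab) {
    in1 <- labels == lab
    n1 <- sum(in1); n2 <- n - n1
    w1 <- rowSums(rk[, in1, drop = FALSE])
    p <- vapply(seq_len(nrow(dense)), function(i)
      rank_sum_normal_p(w1[i], n1, n2, tie_term[i]), 0)
    m1 <- rowMeans(em[, in1, drop = FALSE])
    m2 <- rowMeans(em[, !in1, drop = FALSE])
    log2fc <- log2((m1 + 1) / (m2 + 1))
    pct1 <- rowMeans(dense[, in1, drop = FALSE] > 0)
    pct2 <- rowMeans(dense[, !in1, drop = FALSE] > 0)
    p_adj <- if (identical(adjust, "BH")) bh_adjust(p) else
      p.adjust(p, method = adjust)
    res <- data.frame(gene = rownames(dense), log2fc = log2fc, pct1 = pct1,
                      pct2 = pct2, p = p, p_adj = p_adj,
                      passes_filter = abs(log2fc) > fc_threshold &
                        pct1 > pct_threshold & p_adj < alpha,
                      row.names = NULL)
    attr(res, "adjust") <- adjust
    res
  })
}

#' Marker genes per label
#'
#' In \code{one_vs_rest} mode each label is contrasted against the union of
#' all other labels; in \code{pairwise} mode only the two given labels are
#' compared. Markers are the up-regulated genes passing the standard filter
#' (|log2FC| > 0.25 with positive sign, expressed fraction > 25% in the
#' target group, adjusted p < 0.05), sorted by decreasing log2 fold change
#' and optionally capped at \code{max_genes}.
#'
#' @param expr genes x units normalized expression matrix.
#' @param labels per-unit label vector (length \code{ncol(expr)}).
#' @param mode \code{"one_vs_rest"} or \code{"pairwise"}.
#' @param pair for pairwise mode, character vector of the two labels.
#' @param max_genes cap on marker-set size (default unlimited).
#' @param ... thresholds passed to \code{\link{de_test}}.
#' @return named list of character marker vectors (and the full DE tables in
#'   \code{attr(, "de")}).
#' @export
markers_for <- function(expr, labels, mode = c("one_vs_rest", "pairwise"),
                        pair = NULL, max_genes = Inf, ...) {
  mode <- match.arg(mode)
  if (length(labels) != ncol(expr)) stopf("one label per unit required")
  tab <- table(labels)
  if (length(tab) < 2) stopf("need at least 2 labels")
  if (any(tab < 2))
    stopf("label '%s' has fewer than 2 units", names(tab)[which(tab < 2)[1]])
  dots <- list(...)
  fc <- dots$fc_threshold %||% 0.25
  pct <- dots$pct_threshold %||% 0.25
  alpha <- dots$alpha %||% 0.05
  adjust <- dots$adjust %||% "BH"
  if (mode == "one_vs_rest") {
    de <- de_one_vs_rest(expr, labels, fc, pct, alpha, adjust)
  } else {
    if (is.null(pair) || length(pair) != 2)
      stopf("pairwise mode needs pair = c(labelA, labelB)")
    units <- colnames(expr)
    res <- de_test(expr, units[labels == pair[1]], units[labels == pair[2]],
                   fc_threshold = fc, pct_threshold = pct, alpha = alpha,
                   adjust = adjust)
    de <- setNames(list(res), pair[1])
  }
  markers <- lapply(de, function(res) {
    up <- res[res$passes_filter & res$log2fc > 0, ]
    up <- up[order(-up$log2fc), ]
    if (is.finite(max_genes)) head(up$gene, max_genes) else up$gene
  })
  attr(markers, "de") <- de
  markers
}

#' Write a DE table as TSV
#'
#' The multiple-testing method used is recorded in a header comment line.
#'
#' @param res a \code{\link{de_test}} result.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_de <- function(res, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# p_adj method: %s", attr(res, "adjust") %||% "BH"), con)
  write.table(format(res, digits = 6), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
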