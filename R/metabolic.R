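#' Tumor areas from bin annotations
#'
#' Returns the tumor "areas" (contiguous tumor territories) as a named list
#' of member bin ids. When the bin annotations carry an \code{area_id}
#' column, those ids are used directly; otherwise areas are the connected
#' components of tumor-annotated bins on the bin lattice under
#' 8-connectivity (bins touching by edge or corner belong to one area).
#'
#' @param binmat a \code{bin_matrix} with an \code{annotations} data.frame
#'   holding at least a \code{region} column.
#' @param region_label label marking tumor bins (default \code{"tumor"}).
#' @return named list mapping area id to character vector of bin ids.
#' @export
tumor_areas <- function(binmat, region_label = "tumor") {
  ann <- binmat$annotations
  if (is.null(ann) || is.null(ann$region))
    stopf("bin matrix carries no region annotations")
  idx <- which(ann$region == region_label)
  if (length(idx) == 0) return(list())
  ids <- colnames(binmat$counts)[idx]
  if (!is.null(ann$area_id) && !all(is.na(ann$area_id[idx]))) {
    return(split(ids, ann$area_id[idx]))
  }
  bx <- binmat$bins$bx[idx]; by <- binmat$bins$by[idx]
  key <- paste(bx, by)
  # 8-connectivity: link each tumor bin to its present lattice neighbours
  offs <- expand.grid(dx = -1:1, dy = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0), ]
  edges <- do.call(rbind, lapply(seq_len(nrow(offs)), function(i) {
    nb <- match(paste(bx + offs$dx[i], by + offs$dy[i]), key)
    ok <- !is.na(nb)
    cbind(which(ok), nb[ok])
  }))
  if (is.null(edges) || nrow(edges) == 0) {
    comp <- seq_along(idx)
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
  }
  split(ids, sprintf("area_%02d", comp))
}

#' Per-area mean pathway scores
#'
#' Averages per-bin signature scores over the member bins of each area, per
#' pathway. The result is invariant to the order of member bins.
#'
#' @param scores units x signatures score matrix (from
#'   \code{\link{score_matrix}}).
#' @param areas named list mapping area id to member bin ids.
#' @return areas x signatures numeric matrix.
#' @export
area_pathway_scores <- function(scores, areas) {
  if (length(areas) == 0) stopf("no areas given")
  out <- t(vapply(names(areas), function(a) {
    bins <- areas[[a]]
    if (length(bins) == 0) stopf("area '%s' has zero bins", a)
    miss <- setdiff(bins, rownames(scores))
    if (length(miss)) stopf("area '%s' has unscored bins: %s", a,
                            paste(head(miss, 3), collapse = ", "))
    colMeans(scores[bins, , drop = FALSE])
  }, numeric(ncol(scores))))
  colnames(out) <- colnames(scores)
  out
}

#' Classify tumor areas as hyper- or hypometabolic
#'
#' The composite metabolic score of an area is the arithmetic mean of its
#' six pathway scores (hypoxia, lactic acid, glycolysis, lipid metabolism,
#' pentose phosphate, oxidative phosphorylation). Areas are ranked by
#' decreasing metabolic score; the top \code{k} are classed hypermetabolic,
#' the bottom \code{k} hypometabolic, the rest intermediate. Ties are broken
#' by area id (stable, documented). When fewer than 2k areas exist, k is
#' shrunk to floor(n/2) with a warning. The classification depends only on
#' the rank order, so any strictly increasing transform of all scores gives
#' identical classes.
#'
#' @param area_scores areas x pathways matrix (from
#'   \code{\link{area_pathway_scores}}), or a named numeric vector of
#'   ready-made metabolic scores.
#' @param k number of areas per extreme class (default 20).
#' @return data.frame with \code{area_id, metabolic_score, rank, class}
#'   (plus the pathway scores when a matrix was given); all-tied inputs are
#'   flagged via \code{attr(, "degenerate")}.
#' @export
classify_metabolic <- function(area_scores, k = 20) {
  if (k <= 0) stopf("k must be positive")
  if (is.matrix(area_scores)) {
    ms <- rowMeans(area_scores)
    extra <- as.data.frame(area_scores)
  } else {
    ms <- area_scores
    extra <- NULL
  }
  n <- length(ms)
  if (n < 2) stopf("need at least 2 areas")
  if (n < 2 * k) {
    k <- floor(n / 2)
    warnf("fewer than 2k areas: k shrunk to %d", k)
  }
  ids <- names(ms) %||% as.character(seq_len(n))
  ord <- order(-ms, ids)
  rk <- integer(n); rk[ord] <- seq_len(n)
  cls <- rep("intermediate", n)
  cls[rk <= k] <- "hyper"
  cls[rk > n - k] <- "hypo"
  out <- data.frame(area_id = ids, metabolic_score = as.numeric(ms),
                    rank = rk, class = cls, row.names = NULL)
  if (!is.null(extra)) out <- cbind(out, extra)
  attr(out, "degenerate") <- length(unique(ms)) == 1L
  if (attr(out, "degenerate"))
    warnf("all metabolic scores identical; classes follow the tie-break only")
  attr(out, "k") <- k
  out
}

star_for <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 1e-4) "****" else if (p < 1e-3) "***" else if (p < 1e-2) "**" else
    if (p < 0.05) "*" else "ns"
}

#' Contrast immune signatures between hyper- and hypometabolic areas
#'
#' For each immune signature, compares the per-area mean scores of the
#' hypermetabolic areas against the hypometabolic areas. The default engine
#' is the unpaired two-sided Wilcoxon rank-sum test (the two classes are
#' unpaired groups); paired signed-rank, Student's t, and Kruskal-Wallis
#' engines are also provided. Significance stars follow the usual
#' convention (ns, * < 0.05, ** < 0.01, *** < 0.001, **** < 0.0001).
#'
#' @param hyper,hypo character vectors of area ids in each class.
#' @param immune_scores areas x signatures matrix of per-area mean immune
#'   signature scores (see \code{\link{area_pathway_scores}}).
#' @param test one of \code{"ranksum"}, \code{"signedrank"}, \code{"ttest"},
#'   \code{"kruskal"}.
#' @return data.frame: \code{signature, n_hyper, n_hypo, statistic, p,
#'   direction, stars}; direction is \code{"up_in_hyper"},
#'   \code{"up_in_hypo"} or \code{"none"} by the difference of group means.
#' @export
contrast_immune <- function(hyper, hypo, immune_scores,
                            test = c("ranksum", "signedrank", "ttest",
                                     "kruskal")) {
  test <- match.arg(test)
  if (length(hyper) < 2 || length(hypo) < 2)
    stopf("need at least 2 areas per class")
  miss <- setdiff(c(hyper, hypo), rownames(immune_scores))
  if (length(miss)) stopf("unscored area(s): %s",
                          paste(head(miss, 3), collapse = ", "))
  rows <- lapply(colnames(immune_scores), function(sig) {
    a <- immune_scores[hyper, sig]
    b <- immune_scores[hypo, sig]
    res <- suppressWarnings(switch(test,
      ranksum = {
        # exact enumeration at small pooled size (handles ties), otherwise
        # normal approximation with tie correction — same engine as de_test
        r <- rank(c(a, b))
        n1 <- length(a); n2 <- length(b)
        p <- if (n1 + n2 <= 10) rank_sum_exact_p(r, n1) else {
          tl <- table(c(a, b))
          rank_sum_normal_p(sum(r[seq_len(n1)]), n1, n2, sum(tl^3 - tl))
        }
        list(statistic = sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2,
             p.value = p)
      },
      signedrank = {
        if (length(a) != length(b))
          stopf("signed-rank engine needs equal group sizes (paired)")
        wilcox.test(a, b, paired = TRUE)
      },
      ttest = t.test(a, b),
      kruskal = kruskal.test(list(a, b))))
    d <- mean(a) - mean(b)
    dir <- if (isTRUE(all.equal(d, 0)) || res$p.value == 1) "none" else
      if (d > 0) "up_in_hyper" else "up_in_hypo"
    data.frame(signature = sig, n_hyper = length(a), n_hypo = length(b),
               statistic = unname(res$statistic), p = res$p.value,
               direction = dir, stars = star_for(res$p.value))
  })
  do.call(rbind, rows)
}
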