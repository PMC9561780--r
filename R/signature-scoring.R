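#' Gene signature
#'
#' A named, non-empty set of gene identifiers.
#'
#' @param name signature name.
#' @param genes character vector of gene names (deduplicated, order kept).
#' @return object of class \code{gene_signature}.
#' @export
gene_signature <- function(name, genes) {
  genes <- unique(as.character(genes))
  if (!nzchar(name)) stopf("signature needs a non-empty name")
  if (length(genes) == 0) stopf("signature '%s' has no genes", name)
  structure(list(name = name, genes = genes), class = "gene_signature")
}

#' Read signatures from a GMT file
#'
#' GMT: one signature per line, tab-separated: name, description, genes...
#'
#' @param path file path.
#' @return named list of \code{\link{gene_signature}} objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sigs <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stopf("malformed GMT line: %s", substr(l, 1, 40))
    gene_signature(f[1], f[-(1:2)])
  })
  names(sigs) <- vapply(sigs, `[[`, "", "name")
  if (anyDuplicated(names(sigs))) stopf("duplicate signature names in %s", path)
  sigs
}

#' Write signatures to a GMT file
#'
#' @param sigs list of \code{\link{gene_signature}} objects.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_gmt <- function(sigs, path) {
  lines <- vapply(sigs, function(s)
    paste(c(s$name, "na", s$genes), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

sig_genes <- function(sig) if (inherits(sig, "gene_signature")) sig$genes else
  unique(as.character(sig))

#' Control-matched module score
#'
#' For each unit (bin or cell), the score is the mean normalized expression
#' of the signature genes minus the mean expression of a control gene set
#' matched for expression level. Genes are ranked by their mean expression
#' across units and cut into \code{n_bins} equal-size expression bins (ties
#' broken by gene order); each signature gene contributes \code{n_ctrl}
#' control genes drawn with replacement from its own bin, and the control
#' mean is taken over the union of distinct sampled controls. Adding a
#' constant to every expression value leaves the score unchanged.
#'
#' @param expr genes x units normalized expression matrix (sparse or dense).
#' @param sig a \code{\link{gene_signature}} or character vector of genes.
#' @param n_bins number of expression bins for control matching.
#' @param n_ctrl controls sampled per signature gene.
#' @param seed integer seed for the control draw.
#' @return named numeric vector of per-unit scores.
#' @export
module_score <- function(expr, sig, n_bins = 24, n_ctrl = 100, seed = 1) {
  genes <- rownames(expr)
  if (is.null(genes)) stopf("expression matrix must have gene rownames")
  if (nrow(expr) <= n_bins)
    stopf("need more genes (%d) than expression bins (%d)", nrow(expr), n_bins)
  want <- sig_genes(sig)
  present <- intersect(want, genes)
  if (length(present) == 0)
    stopf("no signature gene present in expression table; missing: %s",
          paste(want, collapse = ", "))
  avg <- Matrix::rowMeans(expr)
  rk <- rank(avg, ties.method = "first")
  bin_of <- pmax(1L, ceiling(n_bins * rk / length(rk)))
  by_bin <- split(genes, bin_of)

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  ctrl <- unique(unlist(lapply(present, function(g) {
    pool <- by_bin[[as.character(bin_of[match(g, genes)])]]
    sample(pool, n_ctrl, replace = TRUE)
  })))
  sig_mean <- Matrix::colMeans(expr[present, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(expr[ctrl, , drop = FALSE])
  as.numeric(sig_mean - ctrl_mean) |> setNames(colnames(expr))
}

#' Single-sample rank-based enrichment score
#'
#' A one-sample running-sum enrichment statistic. Genes are ordered by
#' decreasing expression (ties broken by the stable input gene order); the
#' gene at position j carries the centered rank statistic
#' r_j = (N - j + 1) - (N + 1)/2, symmetric around zero. The score is the
#' sum over positions of the difference between the weighted in-set
#' empirical CDF (weights |r|^alpha, normalized over the set) and the
#' unweighted out-set ECDF, divided by the number of genes. Centering the
#' rank statistic makes the score of a uniformly random signature
#' mean-zero, while signatures concentrated at the top of the ranking score
#' maximally positive. The statistic depends on the expression vector only
#' through its ranks, so any strictly monotone transform of the input
#' leaves it unchanged.
#'
#' @param expr_vector named numeric vector: one unit's normalized expression.
#' @param sig a \code{\link{gene_signature}} or character vector.
#' @param alpha rank-weighting exponent (default 0.25).
#' @return a single numeric score.
#' @export
ssgsea_score <- function(expr_vector, sig, alpha = 0.25) {
  genes <- names(expr_vector)
  if (is.null(genes)) stopf("expression vector must be named by gene")
  want <- sig_genes(sig)
  inset <- genes %in% want
  m <- sum(inset)
  n <- length(expr_vector)
  if (m == 0) stopf("no signature gene present in expression vector")
  if (m == n) stopf("signature covers the whole gene universe (empty out-set)")
  ord <- order(-expr_vector) # stable: ties keep input gene order
  inset <- inset[ord]
  w <- abs((n - seq_len(n) + 1) - (n + 1) / 2)^alpha
  p_in <- cumsum(w * inset) / sum(w * inset)
  p_out <- cumsum(!inset) / (n - m)
  sum(p_in - p_out) / n
}

#' Score a registry of signatures over all units
#'
#' @param expr genes x units normalized expression matrix.
#' @param registry list of \code{\link{gene_signature}} objects (or named
#'   list of gene vectors); column order of the result follows the registry.
#' @param engine \code{"module"} (control-matched module score) or
#'   \code{"ssgsea"} (rank-based single-sample statistic).
#' @param seed seed for the module-score control draw (one child seed per
#'   signature, derived with \code{\link{derive_seed}}).
#' @param alpha rank exponent for the ssgsea engine.
#' @return units x signatures numeric matrix.
#' @export
score_matrix <- function(expr, registry, engine = c("module", "ssgsea"),
                         seed = 1, alpha = 0.25) {
  engine <- match.arg(engine)
  if (length(registry) == 0) stopf("empty signature registry")
  nm <- vapply(seq_along(registry), function(i) {
    s <- registry[[i]]
    if (inherits(s, "gene_signature")) s$name else names(registry)[i] %||%
      stopf("unnamed signature at position %d", i)
  }, "")
  if (anyDuplicated(nm)) stopf("duplicate signature names: %s",
                               paste(nm[duplicated(nm)], collapse = ", "))
  units <- colnames(expr)
  out <- matrix(NA_real_, nrow = ncol(expr), ncol = length(registry),
                dimnames = list(units, nm))
  if (ncol(expr) == 0) return(out)
  if (engine == "module") {
    for (i in seq_along(registry)) {
      out[, i] <- module_score(expr, registry[[i]],
                               seed = derive_seed(seed, paste0("sig:", nm[i])))
    }
  } else {
    dense <- as_dense(expr)
    # one descending order per unit, shared across signatures
    for (i in seq_along(registry)) {
      gset <- sig_genes(registry[[i]])
      out[, i] <- apply(dense, 2, function(v) {
        names(v) <- rownames(dense)
        ssgsea_score(v, gset, alpha = alpha)
      })
    }
  }
  out
}

#' Write a score table as long TSV (unit, signature, score)
#'
#' @param scores units x signatures matrix from \code{\link{score_matrix}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_scores <- function(scores, path) {
  df <- data.frame(unit = rep(rownames(scores), ncol(scores)),
                   signature = rep(colnames(scores), each = nrow(scores)),
                   score = as.numeric(scores))
  write_tsv(df, path)
}
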