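#' Per-base coverage profile over a viral reference genome
#'
#' @param hpv_type type name, e.g. \code{"HPV16"}.
#' @param depth non-negative integer vector, one entry per reference base.
#' @param genome_len reference length; defaults to \code{length(depth)}.
#' @return object of class \code{coverage_profile}.
#' @export
coverage_profile <- function(hpv_type, depth, genome_len = length(depth)) {
  if (genome_len < 1) stopf("genome_len must be >= 1")
  if (length(depth) != genome_len)
    stopf("depth vector length %d != genome_len %d", length(depth), genome_len)
  if (any(is.na(depth)) || any(depth < 0)) stopf("depths must be >= 0")
  structure(list(hpv_type = hpv_type, genome_len = as.integer(genome_len),
                 depth = as.numeric(depth)),
            class = "coverage_profile")
}

#' Read a per-base depth table
#'
#' Accepts a headerless 2-column TSV (1-based position, depth) or the
#' 3-column samtools-depth dialect (reference, position, depth). Positions
#' absent from the table get depth 0.
#'
#' @param path file path.
#' @param hpv_type type name attached to the profile.
#' @param genome_len reference length; defaults to the maximum position seen.
#' @return a \code{\link{coverage_profile}}.
#' @export
read_depth_table <- function(path, hpv_type, genome_len = NULL) {
  tab <- read.delim(path, header = FALSE, sep = "\t")
  if (ncol(tab) == 3) tab <- tab[, 2:3]
  if (ncol(tab) != 2) stopf("depth table must have 2 or 3 columns")
  names(tab) <- c("pos", "depth")
  if (any(tab$pos < 1 | tab$pos != round(tab$pos)))
    stopf("positions must be 1-based integers")
  genome_len <- genome_len %||% max(tab$pos)
  depth <- numeric(genome_len)
  depth[tab$pos] <- tab$depth
  coverage_profile(hpv_type, depth, genome_len)
}

#' Call HPV positivity from a coverage profile
#'
#' A base is covered when its depth is at least 1. Genome coverage is the
#' covered length divided by the full reference length; effective depth is
#' total mapped bases (the sum of the depth vector) divided by the covered
#' length (0 when nothing is covered). A sample is positive for the type
#' only when coverage is strictly greater than \code{min_cov} (default 5%)
#' AND effective depth strictly greater than \code{min_depth} (default 50x).
#'
#' @param profile a \code{\link{coverage_profile}}.
#' @param min_cov coverage threshold, exclusive (fraction of the genome).
#' @param min_depth effective-depth threshold, exclusive.
#' @return object of class \code{hpv_call}: list with \code{hpv_type,
#'   covered_len, coverage_frac, effective_depth, positive}.
#' @export
call_hpv <- function(profile, min_cov = 0.05, min_depth = 50) {
  if (profile$genome_len == 0) stopf("genome_len must be positive")
  covered <- sum(profile$depth > 0)
  frac <- covered / profile$genome_len
  eff <- if (covered == 0) 0 else sum(profile$depth) / covered
  structure(list(hpv_type = profile$hpv_type,
                 covered_len = as.integer(covered),
                 coverage_frac = frac,
                 effective_depth = eff,
                 positive = frac > min_cov && eff > min_depth),
            class = "hpv_call")
}

#' @export
print.hpv_call <- function(x, ...) {
  cat(sprintf("%s: coverage %.1f%% (%d bp), effective depth %.1fx -> %s\n",
              x$hpv_type, 100 * x$coverage_frac, x$covered_len,
              x$effective_depth, if (x$positive) "POSITIVE" else "negative"))
  invisible(x)
}

#' Per-type HPV prevalence across a cohort
#'
#' @param calls data.frame with columns \code{sample_id, hpv_type,
#'   positive}, one row per (sample, type); a sample may be positive for
#'   more than one type, but duplicated (sample, type) rows are an error.
#' @return data.frame: \code{hpv_type, n_positive, n_samples,
#'   prevalence_pct} (percent of all samples positive for the type).
#' @export
summarize_typing <- function(calls) {
  need <- c("sample_id", "hpv_type", "positive")
  if (!all(need %in% names(calls)))
    stopf("calls must have columns %s", paste(need, collapse = ", "))
  if (nrow(calls) == 0) stopf("need at least one sample")
  if (anyDuplicated(calls[c("sample_id", "hpv_type")]))
    stopf("duplicated sample id within an HPV type")
  n_samples <- length(unique(calls$sample_id))
  pos <- tapply(calls$positive, calls$hpv_type, sum)
  data.frame(hpv_type = names(pos),
             n_positive = as.integer(pos),
             n_samples = n_samples,
             prevalence_pct = round(100 * as.integer(pos) / n_samples, 1),
             row.names = NULL)
}

#' Write HPV calls as JSON
#'
#' @param calls list of \code{\link{call_hpv}} results.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_hpv_calls <- function(calls, path) {
  jsonlite::write_json(lapply(calls, unclass), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
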