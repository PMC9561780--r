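#' @importFrom stats rnbinom rpois rbinom runif quantile median pnorm phyper
#'   p.adjust chisq.test wilcox.test t.test kruskal.test plogis qlogis
#'   setNames dhyper
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Derive a reproducible child seed for a named stage
#'
#' All stochastic stages of the pipeline draw their own seed from the single
#' run seed so that re-running one stage in isolation reproduces exactly what
#' the full pipeline produced. The derivation hashes the stage name into the
#' seed with a Horner scheme modulo the Mersenne prime 2^31 - 1; every
#' intermediate stays below 2^53 so the arithmetic is exact in doubles.
#'
#' @param seed integer master seed.
#' @param stage character stage name (e.g. \code{"simulate"}).
#' @return an integer seed in \code{[1, 2^31 - 2]}.
#' @export
derive_seed <- function(seed, stage) {
  if (length(seed) != 1L || is.na(seed) || seed != round(seed))
    stopf("seed must be a single integer")
  m <- 2147483647 # 2^31 - 1
  x <- abs(as.numeric(seed)) %% m
  for (ch in utf8ToInt(as.character(stage))) {
    x <- (x * 31 + ch) %% m
  }
  as.integer(x %% (m - 2) + 1)
}

# strip sparse/dense distinction: always return base dense matrix
as_dense <- function(x) {
  if (inherits(x, "Matrix")) as.matrix(x) else as.matrix(x)
}

# stable TSV writer used by all exporters: headers, no quoting, 6 signif digits
write_tsv <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2)) {
    if (is.double(df2[[j]])) df2[[j]] <- signif(df2[[j]], 6)
  }
  write.table(df2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
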