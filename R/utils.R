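#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rexp rbinom predict sd quantile glm binomial
#'   plogis qlogis setNames aggregate
#' @importFrom utils head tail write.csv read.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a per-unit random seed from a master seed
#'
#' Deterministic mixing so per-patient substreams are stable when the cohort
#' size changes. Kept within the 32-bit signed-integer range.
#' @param seed master integer seed
#' @param index nonnegative integer index of the substream
#' @return an integer usable with [set.seed()]
#' @keywords internal
mix_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 9973 + 12345) %%
               2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Write a data frame as a canonical CSV
#'
#' Fixed formatting (no row names, no quoting beyond need, 15 significant
#' digits) so identical inputs give byte-identical files.
#' @param df data frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_canonical_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) {
    df[[j]] <- vapply(df[[j]], function(v) {
      if (is.na(v)) "" else format(v, digits = 15, scientific = FALSE, trim = TRUE)
    }, character(1))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

file_md5 <- function(paths) {
  h <- tools::md5sum(paths)
  unname(h)
}
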