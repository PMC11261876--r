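#' @useDynLib methylCUP, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import stats
#' @import utils
NULL

.datatable.aware <- TRUE

#' Deterministic fingerprint of an R object
#'
#' 64-bit FNV-1a hash over the serialized bytes of `x`, returned as a
#' 16-character hex string. Used to tie trained models to the exact panel and
#' pixel-assignment provenance they were built from.
#'
#' @param x Any serialisable R object.
#' @return Character scalar, 16 hex digits.
#' @export
fingerprint <- function(x) {
  bytes <- serialize(x, connection = NULL, version = 3L)
  # drop the serialization header (R version stamps) so equal objects hash
  # equally across patch releases
  bytes <- bytes[-seq_len(14L)]
  fnv1a64(bytes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Round half away from zero
#'
#' Quantisation rule used when scaling beta values onto 0--255: ties at .5
#' round away from zero (so 0.5 * 255 = 127.5 -> 128), unlike base
#' [round()]'s round-half-even. Documented for bit-exact reproducibility.
#'
#' @param x Numeric vector/array.
#' @return `x` rounded to integers (same shape).
#' @keywords internal
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
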