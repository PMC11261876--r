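#' Construct a BetaMatrix
#'
#' The universal carrier between preprocessing stages: a probes x samples
#' matrix of methylation beta values in \[0, 1\], with `NA` marking missing
#' entries. Probe IDs are row names, sample IDs column names; both must be
#' unique. A `stages` attribute records which preprocessing steps have been
#' applied, so stage-order violations can be caught.
#'
#' @param values Numeric matrix, probes in rows, samples in columns, with row
#'   and column names. Entries must lie in \[0, 1\] or be `NA`.
#' @param stages Character vector of preprocessing stages already applied.
#' @return An object of class `BetaMatrix`.
#' @export
BetaMatrix <- function(values, stages = character()) {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("'values' must be a numeric matrix")
  pid <- rownames(values); sid <- colnames(values)
  if (is.null(pid) || is.null(sid))
    stopf("'values' must carry probe IDs as rownames and sample IDs as colnames")
  if (anyDuplicated(pid))
    stopf("duplicate probe IDs: %s",
          paste(unique(pid[duplicated(pid)]), collapse = ", "))
  if (anyDuplicated(sid))
    stopf("duplicate sample IDs: %s",
          paste(unique(sid[duplicated(sid)]), collapse = ", "))
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stopf("beta value out of [0,1] at probe '%s', sample '%s' (value %g)",
          pid[bad[1, 1]], sid[bad[1, 2]], values[bad[1, , drop = FALSE]])
  structure(list(values = values, stages = stages), class = "BetaMatrix")
}

#' @export
print.BetaMatrix <- function(x, ...) {
  v <- x$values
  cat(sprintf("BetaMatrix: %d probes x %d samples (%.1f%% missing)\n",
              nrow(v), ncol(v), 100 * mean(is.na(v))))
  if (length(x$stages))
    cat("  stages applied:", paste(x$stages, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.BetaMatrix <- function(x) dim(x$values)

#' Probe and sample identifiers of a BetaMatrix
#' @param bm A [BetaMatrix].
#' @return Character vector of IDs.
#' @export
probe_ids <- function(bm) rownames(bm$values)

#' @rdname probe_ids
#' @export
sample_ids <- function(bm) colnames(bm$values)

#' Missingness mask of a BetaMatrix
#' @param bm A [BetaMatrix].
#' @return Logical matrix, `TRUE` where the beta value is missing.
#' @export
missing_mask <- function(bm) is.na(bm$values)

#' Subset a BetaMatrix by probes and/or samples
#' @param bm A [BetaMatrix].
#' @param probes,samples Character or integer indices; `NULL` keeps all.
#' @return A [BetaMatrix].
#' @export
subset_beta <- function(bm, probes = NULL, samples = NULL) {
  v <- bm$values
  if (!is.null(probes)) {
    if (is.character(probes) && !all(probes %in% rownames(v)))
      stopf("unknown probe IDs: %s",
            paste(setdiff(probes, rownames(v))[1:3], collapse = ", "))
    v <- v[probes, , drop = FALSE]
  }
  if (!is.null(samples)) {
    if (is.character(samples) && !all(samples %in% colnames(v)))
      stopf("unknown sample IDs: %s",
            paste(setdiff(samples, colnames(v))[1:3], collapse = ", "))
    v <- v[, samples, drop = FALSE]
  }
  BetaMatrix(v, stages = bm$stages)
}

#' Read a beta-value table
#'
#' Reads a delimited probe x sample beta table into a [BetaMatrix]. The first
#' column holds probe IDs and the header row holds sample IDs. Empty cells,
#' `"NA"`, `"na"` and `"null"` are treated as missing. The
#' `geo_series_matrix` dialect skips `!`-prefixed metadata lines and reads the
#' block between the `!series_matrix_table_begin` / `_end` markers.
#'
#' @param path Path to the file.
#' @param dialect One of `"tsv"`, `"csv"`, `"geo_series_matrix"`.
#' @return A [BetaMatrix]. Values outside \[0, 1\] raise an error naming the
#'   offending probe and sample rather than being clamped.
#' @export
read_beta_table <- function(path, dialect = c("tsv", "csv", "geo_series_matrix")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("file not found: %s", path)
  na_tokens <- c("", "NA", "na", "null", "NULL")
  if (dialect == "geo_series_matrix") {
    lines <- readLines(path)
    beg <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(beg) != 1L || length(end) != 1L || end <= beg)
      stopf("malformed GEO series matrix: table begin/end markers not found in %s", path)
    lines <- lines[(beg + 1L):(end - 1L)]
    dt <- data.table::fread(text = lines, sep = "\t", header = TRUE,
                            na.strings = na_tokens, quote = "\"")
  } else {
    sep <- if (dialect == "tsv") "\t" else ","
    dt <- data.table::fread(path, sep = sep, header = TRUE,
                            na.strings = na_tokens)
  }
  if (ncol(dt) < 2L) stopf("malformed header: need a probe-ID column plus >=1 sample column")
  pid <- as.character(dt[[1L]])
  dt[, (1L) := NULL]
  nonnum <- names(dt)[!vapply(dt, is.numeric, logical(1))]
  if (length(nonnum))
    stopf("non-numeric beta values in column(s): %s", paste(nonnum, collapse = ", "))
  v <- as.matrix(dt)
  rownames(v) <- pid
  BetaMatrix(v)
}

#' Write a beta-value table
#'
#' Inverse of [read_beta_table()] for the `tsv`/`csv` dialects; full-precision
#' (`%.17g`) so a write/read round trip is bitwise exact.
#'
#' @param bm A [BetaMatrix].
#' @param path Output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_beta_table <- function(bm, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  dt <- data.table::as.data.table(bm$values, keep.rownames = "probe_id")
  for (j in seq(2L, ncol(dt))) {          # %.17g so re-reading is bitwise exact
    col <- sprintf("%.17g", dt[[j]])
    col[is.na(dt[[j]])] <- NA_character_
    data.table::set(dt, j = j, value = col)
  }
  data.table::fwrite(dt, path, sep = if (dialect == "tsv") "\t" else ",",
                     na = "NA", quote = FALSE)
  invisible(path)
}
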