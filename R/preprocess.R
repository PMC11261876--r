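#' Drop probes measured in too few samples
#'
#' Retains exactly the probes whose non-missing fraction is at least
#' `min_frac` (inclusive at the boundary: a probe present in 80% of samples
#' survives the default threshold). The sample axis is unchanged.
#'
#' @param bm A [BetaMatrix].
#' @param min_frac Minimum fraction of samples with a measured value,
#'   in (0, 1\]. Default 0.8.
#' @param strict If `TRUE`, refuse to filter a matrix that was imputed
#'   without a prior presence filter (imputation erases the missingness the
#'   filter needs, so such a call silently retains every probe); re-running
#'   the correctly ordered pipeline remains legal and is a no-op.
#' @return A [BetaMatrix] with attribute `dropped_probes` listing removed IDs.
#' @export
filter_probes_by_presence <- function(bm, min_frac = 0.8, strict = TRUE) {
  stopifnot(inherits(bm, "BetaMatrix"))
  if (!(min_frac > 0 && min_frac <= 1)) stopf("'min_frac' must be in (0, 1]")
  if (strict && "impute" %in% bm$stages && !("presence_filter" %in% bm$stages))
    stopf("presence filter applied after imputation: pipeline order is filter -> impute -> select")
  present <- rowMeans(!is.na(bm$values))
  keep <- present >= min_frac
  if (!any(keep)) stopf("all %d probes dropped at min_frac = %g", nrow(bm$values), min_frac)
  out <- BetaMatrix(bm$values[keep, , drop = FALSE],
                    stages = union(bm$stages, "presence_filter"))
  attr(out, "dropped_probes") <- rownames(bm$values)[!keep]
  out
}

#' Impute missing beta values with the per-probe median
#'
#' Each missing entry is replaced by the median of that probe's non-missing
#' values across samples; measured entries are untouched.
#'
#' @param bm A [BetaMatrix]; every probe must have at least one measured value
#'   (run [filter_probes_by_presence()] first).
#' @return A [BetaMatrix] with no missing values.
#' @export
impute_missing_median <- function(bm) {
  stopifnot(inherits(bm, "BetaMatrix"))
  v <- bm$values
  nmiss <- rowSums(is.na(v))
  if (any(nmiss == ncol(v)))
    stopf("probe '%s' has no measured values; filter by presence first",
          rownames(v)[which(nmiss == ncol(v))[1L]])
  rows <- which(nmiss > 0L)
  for (i in rows) {
    x <- v[i, ]
    x[is.na(x)] <- median(x, na.rm = TRUE)
    v[i, ] <- x
  }
  BetaMatrix(v, stages = union(bm$stages, "impute"))
}

#' Select the most variable probes
#'
#' Keeps the `k` probes with the largest per-probe variance across samples
#' (uncorrected population variance, i.e. dividing by n). Ties are broken
#' lexicographically by probe ID so the selection is deterministic across
#' platforms. Probes are returned in their original matrix order.
#'
#' @param bm A [BetaMatrix] with no missing values.
#' @param k Number of probes to keep (default 10000).
#' @return A [BetaMatrix] of at most `k` probes; if fewer than `k` probes are
#'   available all are returned with a warning.
#' @export
select_top_variance <- function(bm, k = 10000L) {
  stopifnot(inherits(bm, "BetaMatrix"))
  if (k < 1L) stopf("'k' must be >= 1")
  v <- bm$values
  if (anyNA(v))
    stopf("missing values present; impute before variance selection")
  if (nrow(v) <= k) {
    if (nrow(v) < k)
      warnf("only %d probes available for top-%d variance selection; returning all",
            nrow(v), k)
    return(BetaMatrix(v, stages = union(bm$stages, "variance_select")))
  }
  mu <- rowMeans(v)
  pvar <- rowMeans(v * v) - mu * mu      # population variance
  ord <- order(-pvar, rownames(v), method = "radix")
  keep <- sort(ord[seq_len(k)])
  BetaMatrix(v[keep, , drop = FALSE],
             stages = union(bm$stages, "variance_select"))
}

#' Annotate samples with origin class and histology group
#'
#' Applies a [ClassMap] to a sample-annotation table, assigning each sample an
#' origin class (or `"excluded"` for types on the exclusion list) and a
#' histology group (`"squamous"` or `"non_squamous"`). Unknown cancer-type
#' codes are collected in an `unknown_types` attribute rather than silently
#' dropped.
#'
#' @param annotation_table Data frame with columns `sample_id`, `cancer_type`
#'   and optionally `stage` (`"primary"`, `"metastatic"` or `"unknown"`).
#' @param class_map A [ClassMap].
#' @return Data frame with columns `sample_id`, `cancer_type`, `origin_class`,
#'   `group`, `stage`; attribute `unknown_types` lists unmapped codes.
#' @export
annotate_samples <- function(annotation_table, class_map) {
  stopifnot(inherits(class_map, "ClassMap"))
  need <- c("sample_id", "cancer_type")
  if (!all(need %in% names(annotation_table)))
    stopf("annotation table must have columns: %s", paste(need, collapse = ", "))
  ann <- as.data.frame(annotation_table, stringsAsFactors = FALSE)
  if (anyDuplicated(ann$sample_id)) stopf("duplicate sample IDs in annotation table")
  if (is.null(ann$stage)) ann$stage <- "unknown"
  bad_stage <- setdiff(unique(ann$stage), c("primary", "metastatic", "unknown"))
  if (length(bad_stage))
    stopf("invalid stage value(s): %s", paste(bad_stage, collapse = ", "))
  ct <- as.character(ann$cancer_type)
  known <- ct %in% c(names(class_map$type_to_class), class_map$excluded_types)
  excluded <- ct %in% class_map$excluded_types
  ann$origin_class <- NA_character_
  ann$origin_class[known & !excluded] <- unname(class_map$type_to_class[ct[known & !excluded]])
  ann$origin_class[excluded] <- "excluded"
  ann$group <- ifelse(ct %in% class_map$squamous_types, "squamous", "non_squamous")
  ann$group[excluded | !known] <- NA_character_
  unknown <- sort(unique(ct[!known]))
  ann <- ann[, c("sample_id", "cancer_type", "origin_class", "group", "stage")]
  if (!any(known & !excluded))
    stopf("no samples left after exclusion/unknown-type removal")
  attr(ann, "unknown_types") <- unknown
  ann
}

#' Stratified train/validation/test split
#'
#' Splits the non-excluded samples into disjoint train/validation/test sets,
#' stratified by `origin_class`, with largest-remainder rounding of each
#' class's quota so per-class proportions match the requested fractions within
#' one sample. Reproducible for a fixed seed. Classes with fewer than 3
#' samples go entirely to training, with a warning.
#'
#' @param annotations Annotated sample table from [annotate_samples()]
#'   (excluded/unknown samples are removed here).
#' @param fractions Numeric length-3 vector (train, validation, test) summing
#'   to 1. Default `c(0.6, 0.2, 0.2)`.
#' @param seed Integer seed governing the within-class shuffles.
#' @return A `Partition`: list with `train_ids`, `val_ids`, `test_ids`,
#'   `seed`, `fractions`.
#' @export
split_train_val_test <- function(annotations, fractions = c(0.6, 0.2, 0.2), seed) {
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stopf("'fractions' must be three positive numbers summing to 1")
  ann <- annotations[!is.na(annotations$origin_class) &
                       annotations$origin_class != "excluded", , drop = FALSE]
  if (nrow(ann) == 0L) stopf("no usable samples to split")
  set.seed(seed)
  out <- list(train_ids = character(), val_ids = character(), test_ids = character())
  for (cl in sort(unique(ann$origin_class))) {
    ids <- ann$sample_id[ann$origin_class == cl]
    m <- length(ids)
    if (m < 3L) {
      warnf("class '%s' has %d sample(s) (<3); placed entirely in training", cl, m)
      out$train_ids <- c(out$train_ids, ids)
      next
    }
    ids <- sample(ids)
    quota <- largest_remainder(m, fractions)
    out$train_ids <- c(out$train_ids, ids[seq_len(quota[1L])])
    out$val_ids <- c(out$val_ids, ids[quota[1L] + seq_len(quota[2L])])
    out$test_ids <- c(out$test_ids, ids[quota[1L] + quota[2L] + seq_len(quota[3L])])
  }
  structure(list(train_ids = out$train_ids, val_ids = out$val_ids,
                 test_ids = out$test_ids, seed = seed, fractions = fractions),
            class = "Partition")
}

# integer quotas for m items at the given fractions, largest remainder first;
# ties favour earlier entries (train, then val, then test)
largest_remainder <- function(m, fractions) {
  ideal <- m * fractions
  quota <- floor(ideal)
  rem <- ideal - quota
  left <- m - sum(quota)
  if (left > 0) {
    take <- order(-rem, seq_along(rem))[seq_len(left)]
    quota[take] <- quota[take] + 1L
  }
  as.integer(quota)
}

#' @export
print.Partition <- function(x, ...) {
  cat(sprintf("Partition: %d train / %d val / %d test (seed %d)\n",
              length(x$train_ids), length(x$val_ids), length(x$test_ids), x$seed))
  invisible(x)
}
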