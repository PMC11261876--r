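#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of two samples. The U statistic is reported for the
#' first argument. For arms of at most 20 observations each with no ties the
#' exact null distribution is evaluated (via the Wilcoxon distribution
#' functions); otherwise the normal approximation with tie correction is
#' used, without continuity correction. Two identical, fully tied samples
#' yield p = 1.
#'
#' @param x,y Non-empty numeric vectors.
#' @return List with `u_statistic` and `p_value`.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stopf("both arms must be non-empty")
  r <- rank(c(x, y))
  mw_from_ranks(r, seq_along(x), length(x), length(y))
}

# core test given pooled ranks and the index set of the first arm
mw_from_ranks <- function(r, idx_x, n1, n2) {
  u <- sum(r[idx_x]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1L)
  if (!has_ties && n1 <= 20L && n2 <= 20L) {
    mu <- n1 * n2 / 2
    p <- if (u > mu) 2 * stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE)
         else 2 * stats::pwilcox(u, n1, n2)
    p <- min(1, p)
  } else {
    n <- n1 + n2
    mu <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
  }
  list(u_statistic = as.numeric(u), p_value = p)
}

#' Per-probe differential methylation statistics for one class
#'
#' Compares, within one histology group, the samples of `class_label` against
#' all other samples of the same group (never the whole cohort): per probe,
#' the difference of medians (in-class minus out-of-class) and a two-sided
#' Mann-Whitney U test.
#'
#' @param bm A [BetaMatrix] with no missing values.
#' @param annotations Annotated samples (from [annotate_samples()]).
#' @param class_label Origin class to contrast.
#' @param group `"non_squamous"` or `"squamous"`.
#' @return Data frame: probe_id, class_label, delta_median, u_statistic,
#'   p_value; one row per probe.
#' @export
compute_class_statistics <- function(bm, annotations, class_label,
                                     group = c("non_squamous", "squamous")) {
  group <- match.arg(group)
  if (anyNA(bm$values)) stopf("missing values present; impute first")
  ann <- annotations[!is.na(annotations$group) & annotations$group == group &
                       annotations$sample_id %in% sample_ids(bm), , drop = FALSE]
  in_ids <- ann$sample_id[ann$origin_class == class_label]
  out_ids <- ann$sample_id[ann$origin_class != class_label]
  if (length(in_ids) < 2L)
    stopf("class '%s' has %d sample(s) in the %s group; need >= 2",
          class_label, length(in_ids), group)
  if (length(out_ids) < 2L)
    stopf("the %s group has %d out-of-class sample(s); need >= 2",
          group, length(out_ids))
  v <- bm$values[, c(in_ids, out_ids), drop = FALSE]
  n1 <- length(in_ids); n2 <- length(out_ids)
  in_idx <- seq_len(n1)
  med_in <- apply(v[, in_idx, drop = FALSE], 1L, median)
  med_out <- apply(v[, -in_idx, drop = FALSE], 1L, median)
  stats_list <- apply(v, 1L, function(row) {
    mw_from_ranks(rank(row), in_idx, n1, n2)
  })
  data.frame(probe_id = rownames(v),
             class_label = class_label,
             delta_median = med_in - med_out,
             u_statistic = vapply(stats_list, `[[`, numeric(1), "u_statistic"),
             p_value = vapply(stats_list, `[[`, numeric(1), "p_value"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select a class's differential-probe panel
#'
#' Filters records to `p_value < alpha`, removes probes already claimed by
#' earlier classes, sorts by decreasing absolute median difference (ties:
#' smaller p first, then probe ID), and returns the top `k`.
#'
#' @param records Data frame from [compute_class_statistics()].
#' @param k Panel size.
#' @param alpha Significance threshold (default 0.001, uncorrected).
#' @param already_taken Character vector of probe IDs to exclude.
#' @return Data frame of at most `k` rows with a `rank` column. A shortfall
#'   (fewer than `k` survivors) warns with the achieved count; zero survivors
#'   is an error.
#' @export
select_panel_for_class <- function(records, k, alpha = 0.001,
                                   already_taken = character()) {
  if (k < 1L) stopf("'k' must be >= 1")
  cand <- records[records$p_value < alpha &
                    !(records$probe_id %in% already_taken), , drop = FALSE]
  if (nrow(cand) == 0L)
    stopf("empty panel: no probes pass p < %g for class '%s'",
          alpha, records$class_label[1L] %||% "?")
  ord <- order(-abs(cand$delta_median), cand$p_value, cand$probe_id,
               method = "radix")
  sel <- cand[ord[seq_len(min(k, nrow(cand)))], , drop = FALSE]
  if (nrow(sel) < k)
    warnf("panel shortfall for class '%s': %d of %d requested probes pass the filter",
          sel$class_label[1L], nrow(sel), k)
  sel$rank <- seq_len(nrow(sel))
  rownames(sel) <- NULL
  sel
}

#' Panel-selection configuration
#'
#' @param k_nonsq Probes per non-squamous class (default 136).
#' @param k_sq Probes per squamous class (default 90).
#' @param alpha Mann-Whitney significance threshold (default 0.001).
#' @param min_per_class Hard floor: a class whose panel falls below this
#'   count aborts panel construction (default 1).
#' @return A `PanelConfig` list.
#' @export
panel_config <- function(k_nonsq = 136L, k_sq = 90L, alpha = 0.001,
                         min_per_class = 1L) {
  structure(list(k_nonsq = as.integer(k_nonsq), k_sq = as.integer(k_sq),
                 alpha = alpha, min_per_class = as.integer(min_per_class)),
            class = "PanelConfig")
}

#' Build the per-group differential-probe panels
#'
#' Runs class-specific probe selection separately in the non-squamous and
#' squamous groups. Classes are processed in alphabetical order and each
#' class excludes probes already claimed by earlier classes of its group, so
#' each panel's probe list is duplicate-free and its length is exactly
#' (number of classes) x k when signal is ample. `probes_flat` concatenates
#' the per-class lists in class order; the image layout depends on this
#' ordering, so it is part of the serialised contract.
#'
#' If a `partition` is supplied, selection is restricted to its training
#' samples and any attempt to use samples outside the training list is
#' refused (leakage guard).
#'
#' @param bm A [BetaMatrix] (no missing values).
#' @param annotations Annotated samples (from [annotate_samples()]).
#' @param config A [panel_config()].
#' @param partition Optional `Partition`; only its `train_ids` are used.
#' @return List with elements `non_squamous` and `squamous`, each a
#'   `DMCPanel`: list(group, per_class, probes_flat, k, alpha, class_order).
#' @export
build_group_panels <- function(bm, annotations, config = panel_config(),
                               partition = NULL) {
  stopifnot(inherits(config, "PanelConfig"))
  ann <- annotations[!is.na(annotations$origin_class) &
                       annotations$origin_class != "excluded", , drop = FALSE]
  if (!is.null(partition)) {
    ann <- ann[ann$sample_id %in% partition$train_ids, , drop = FALSE]
    bm <- subset_beta(bm, samples = intersect(sample_ids(bm), ann$sample_id))
  }
  build_one <- function(group, k) {
    gann <- ann[!is.na(ann$group) & ann$group == group, , drop = FALSE]
    cls <- sort(unique(gann$origin_class))
    if (length(cls) < 2L)
      stopf("the %s group has %d class(es); need >= 2 for in/out contrasts",
            group, length(cls))
    taken <- character()
    per_class <- list()
    for (cl in cls) {
      rec <- compute_class_statistics(bm, gann, cl, group)
      sel <- select_panel_for_class(rec, k = k, alpha = config$alpha,
                                    already_taken = taken)
      if (nrow(sel) < config$min_per_class)
        stopf("class '%s' panel has %d probes, below the floor of %d",
              cl, nrow(sel), config$min_per_class)
      per_class[[cl]] <- sel
      taken <- c(taken, sel$probe_id)
    }
    structure(list(group = group, per_class = per_class,
                   probes_flat = taken, k = k, alpha = config$alpha,
                   class_order = cls),
              class = "DMCPanel")
  }
  list(non_squamous = build_one("non_squamous", config$k_nonsq),
       squamous = build_one("squamous", config$k_sq))
}

#' @export
print.DMCPanel <- function(x, ...) {
  cat(sprintf("DMCPanel (%s): %d classes x up to %d probes = %d probes\n",
              x$group, length(x$per_class), x$k, length(x$probes_flat)))
  invisible(x)
}

#' Write / read a DMCPanel as TSV plus JSON sidecar
#'
#' The TSV has columns group, class, rank, probe_id, delta_median,
#' u_statistic, p_value; the sidecar records the class order, panel
#' parameters and a content fingerprint.
#'
#' @param panel A `DMCPanel`.
#' @param path Output TSV path; the sidecar goes to `<path>.json`.
#' @return `path` invisibly; [read_panel()] returns the `DMCPanel`.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "DMCPanel"))
  rows <- do.call(rbind, lapply(panel$class_order, function(cl) {
    d <- panel$per_class[[cl]]
    data.frame(group = panel$group, class = cl, rank = d$rank,
               probe_id = d$probe_id, delta_median = d$delta_median,
               u_statistic = d$u_statistic, p_value = d$p_value,
               stringsAsFactors = FALSE)
  }))
  data.table::fwrite(rows, path, sep = "\t", quote = FALSE)
  jsonlite::write_json(
    list(group = panel$group, k = panel$k, alpha = panel$alpha,
         class_order = panel$class_order,
         fingerprint = fingerprint(panel$probes_flat)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  rows <- data.table::fread(path, sep = "\t", header = TRUE,
                            colClasses = list(character = c("group", "class", "probe_id")))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  per_class <- lapply(meta$class_order, function(cl) {
    d <- as.data.frame(rows[rows$class == cl, ])
    data.frame(probe_id = d$probe_id, class_label = cl,
               delta_median = d$delta_median, u_statistic = d$u_statistic,
               p_value = d$p_value, rank = d$rank, stringsAsFactors = FALSE)
  })
  names(per_class) <- meta$class_order
  structure(list(group = meta$group, per_class = per_class,
                 probes_flat = unlist(lapply(per_class, `[[`, "probe_id"),
                                      use.names = FALSE),
                 k = meta$k, alpha = meta$alpha,
                 class_order = meta$class_order),
            class = "DMCPanel")
}
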