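#' Choose a grid shape for a panel
#'
#' Picks the divisor pair (rows, cols) of `n` whose aspect ratio is closest
#' to `ratio` (default 2:1, the layout used for both image halves: 68 x 34
#' holds a 2,312-probe panel and 30 x 15 a 450-probe panel). With
#' `require_half_square = TRUE` the pair must satisfy rows = 2 * cols
#' exactly, so that merging two halves side by side yields a square image.
#'
#' @param n Panel size (number of probes).
#' @param ratio Target rows / cols ratio.
#' @param require_half_square Require rows == 2 * cols.
#' @return Integer `c(rows, cols)` with `rows * cols == n`.
#' @export
grid_for_panel <- function(n, ratio = 2, require_half_square = FALSE) {
  n <- as.integer(n)
  if (n < 2L) stopf("panel too small for a grid")
  divs <- which(n %% seq_len(n) == 0L)
  rows <- divs; cols <- n %/% divs
  if (require_half_square) {
    ok <- rows == 2L * cols
    if (!any(ok))
      stopf("panel size %d cannot fill a rows = 2*cols grid; choose a per-class k making the panel 2*c^2", n)
    return(c(rows[ok][1L], cols[ok][1L]))
  }
  score <- abs(rows / cols - ratio)
  best <- which.min(score)
  c(rows[best], cols[best])
}

#' Run the full tissue-of-origin pipeline on a cohort
#'
#' Chains every stage: presence filter, median imputation, (optional)
#' top-variance restriction, class-map annotation, stratified splitting of
#' the primary samples, per-group differential-probe panel selection on the
#' training split, IGTD pixel-assignment optimisation of both panels,
#' image rendering for all samples, vision-transformer training, and
#' evaluation on the held-out primary test set and (if present) on the
#' metastatic samples, which are never used for training.
#'
#' @param beta A [BetaMatrix] (may contain missing values).
#' @param annotations Data frame with sample_id, cancer_type, stage.
#' @param class_map A [ClassMap].
#' @param seed Integer seed driving the split, training shuffles and
#'   initialisation.
#' @param min_presence Probe presence threshold (default 0.8).
#' @param top_k_variance If non-NULL, restrict to this many most-variable
#'   probes before panel selection.
#' @param fractions Train/val/test fractions (default 60/20/20).
#' @param panel_cfg A [panel_config()].
#' @param igtd_iterations IGTD outer iterations for each panel.
#' @param vit_cfg A [vit_config()]; default is [vit_config_scaled()] sized
#'   to the merged image.
#' @param verbose Print stage progress.
#' @return List with the fitted objects and a `metrics` element holding
#'   `MetricsReport`s for `test` and (when metastatic samples exist) `meta`.
#' @export
run_cup_pipeline <- function(beta, annotations, class_map, seed,
                             min_presence = 0.8, top_k_variance = NULL,
                             fractions = c(0.6, 0.2, 0.2),
                             panel_cfg = panel_config(),
                             igtd_iterations = 1000L, vit_cfg = NULL,
                             verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  say("preprocessing %d probes x %d samples", nrow(beta$values), ncol(beta$values))
  bm <- filter_probes_by_presence(beta, min_frac = min_presence)
  bm <- impute_missing_median(bm)
  if (!is.null(top_k_variance)) bm <- select_top_variance(bm, top_k_variance)

  ann <- annotate_samples(annotations, class_map)
  ann_use <- ann[!is.na(ann$origin_class) & ann$origin_class != "excluded", ]
  primary <- ann_use[ann_use$stage != "metastatic", ]
  meta <- ann_use[ann_use$stage == "metastatic", ]
  part <- split_train_val_test(primary, fractions, seed = seed)

  say("selecting panels on %d training samples", length(part$train_ids))
  panels <- build_group_panels(bm, ann_use, config = panel_cfg, partition = part)
  n_non <- length(panels$non_squamous$probes_flat)
  n_sq <- length(panels$squamous$probes_flat)
  grid_nonsq <- grid_for_panel(n_non, require_half_square = TRUE)
  grid_sq <- grid_for_panel(n_sq)

  say("IGTD: %d + %d probes onto %sx%s and %sx%s grids",
      n_non, n_sq, grid_nonsq[1], grid_nonsq[2], grid_sq[1], grid_sq[2])
  bm_train <- subset_beta(bm, samples = part$train_ids)
  asg_non <- igtd_optimize(
    feature_rank_matrix(subset_beta(bm_train, probes = panels$non_squamous$probes_flat)),
    pixel_rank_matrix(grid_nonsq), n_iterations = igtd_iterations, seed = seed)
  asg_sq <- igtd_optimize(
    feature_rank_matrix(subset_beta(bm_train, probes = panels$squamous$probes_flat)),
    pixel_rank_matrix(grid_sq), n_iterations = igtd_iterations, seed = seed)

  say("rendering images")
  images <- render_cohort_images(bm, asg_non, asg_sq)
  labels_of <- function(ids) ann_use$origin_class[match(ids, ann_use$sample_id)]
  sub_images <- function(ids) {
    k <- match(ids, images$sample_ids)
    structure(list(pixels = images$pixels[k, , , drop = FALSE],
                   sample_ids = ids, grid_shape = images$grid_shape,
                   provenance = images$provenance),
              class = "MethylationImageSet")
  }

  if (is.null(vit_cfg))
    vit_cfg <- vit_config_scaled(image_size = images$grid_shape[1L],
                                 n_classes = length(unique(ann_use$origin_class)),
                                 seed = seed)
  say("training ViT (%d blocks, %d epochs)", vit_cfg$n_blocks, vit_cfg$epochs)
  model <- build_vit(vit_cfg)
  model <- train_vit(model, sub_images(part$train_ids), labels_of(part$train_ids),
                     sub_images(part$val_ids), labels_of(part$val_ids),
                     verbose = verbose)

  label_order <- sort(unique(ann_use$origin_class))
  evaluate <- function(ids) {
    pred <- predict_vit(model, sub_images(ids))
    cm <- confusion(labels_of(ids), unname(pred$classes), label_order)
    list(confusion = cm, metrics = compute_metrics(cm), predictions = pred)
  }
  res_test <- evaluate(part$test_ids)
  res_meta <- if (nrow(meta) > 0L) evaluate(meta$sample_id)
  say("test accuracy %.3f%s", res_test$metrics$overall_accuracy,
      if (!is.null(res_meta)) sprintf(", metastatic accuracy %.3f",
                                      res_meta$metrics$overall_accuracy) else "")

  list(beta = bm, annotations = ann_use, partition = part, panels = panels,
       assignments = list(non_squamous = asg_non, squamous = asg_sq),
       images = images, model = model,
       metrics = list(test = res_test$metrics,
                      meta = if (!is.null(res_meta)) res_meta$metrics),
       confusion = list(test = res_test$confusion,
                        meta = if (!is.null(res_meta)) res_meta$confusion))
}
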