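#' Configuration for a synthetic methylation cohort
#'
#' Defines a multi-class cohort of beta values with class-specific implanted
#' differentially methylated probes, bimodal beta-distributed baselines,
#' bounded sampling noise, completely-at-random missingness and an optional
#' set of extra "metastatic" samples drawn from the same class distributions.
#'
#' Defaults describe the desk-scale study cohort used throughout the test
#' suite: 6 origin classes of which 3 are squamous-histology, 40 primary
#' samples per class, 5,000 probes with 50 implanted differential probes per
#' class at a methylation shift of 0.4. Both histology groups keep at least
#' 3 classes because a 2-class group makes the in-class/out-of-class
#' contrast symmetric: each class's differential probes are then equally
#' differential for the other class and panel membership becomes arbitrary.
#'
#' @param n_classes Total number of origin classes.
#' @param n_squamous_classes How many of the classes form the squamous group
#'   (the last `n_squamous_classes` class labels).
#' @param samples_per_class Primary samples per class.
#' @param n_probes Total probes; must be >= `n_classes * dmc_per_class`.
#' @param dmc_per_class Implanted differentially methylated probes per class;
#'   implanted sets are disjoint across classes.
#' @param baseline_beta_params Shape parameters `(a, b)` of the Beta
#'   distribution from which probe-level baseline means are drawn;
#'   the default `(0.5, 0.5)` mimics the bimodality of methylation data.
#' @param effect_delta Shift of the in-class mean beta at implanted probes,
#'   in (0, 1\]; direction alternates hyper/hypo within each class's set.
#' @param precision Beta-distribution precision (a+b) of per-sample noise
#'   around the probe mean; larger is less noisy.
#' @param missing_frac Fraction of entries set missing, MCAR.
#' @param metastatic_frac Extra metastatic samples per class, as a fraction
#'   of `samples_per_class` (rounded up); drawn from the same class
#'   distributions with precision scaled by `metastatic_precision_factor`.
#' @param metastatic_precision_factor Multiplier (<= 1 adds noise) on
#'   `precision` for metastatic samples; the class signal itself is retained.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A `SimulationConfig` list.
#' @export
simulation_config <- function(n_classes = 6L, n_squamous_classes = 3L,
                              samples_per_class = 40L, n_probes = 5000L,
                              dmc_per_class = 50L,
                              baseline_beta_params = c(0.5, 0.5),
                              effect_delta = 0.4, precision = 60,
                              missing_frac = 0.02, metastatic_frac = 0.25,
                              metastatic_precision_factor = 0.6,
                              seed = 1L) {
  cfg <- list(n_classes = as.integer(n_classes),
              n_squamous_classes = as.integer(n_squamous_classes),
              samples_per_class = as.integer(samples_per_class),
              n_probes = as.integer(n_probes),
              dmc_per_class = as.integer(dmc_per_class),
              baseline_beta_params = as.numeric(baseline_beta_params),
              effect_delta = effect_delta, precision = precision,
              missing_frac = missing_frac, metastatic_frac = metastatic_frac,
              metastatic_precision_factor = metastatic_precision_factor,
              seed = as.integer(seed))
  if (cfg$n_classes < 2L) stopf("need >= 2 classes")
  if (cfg$n_squamous_classes < 0L || cfg$n_squamous_classes >= cfg$n_classes)
    stopf("'n_squamous_classes' must be in [0, n_classes)")
  if (cfg$dmc_per_class * cfg$n_classes > cfg$n_probes)
    stopf("dmc_per_class * n_classes exceeds n_probes")
  if (!(cfg$effect_delta >= 0 && cfg$effect_delta <= 1))
    stopf("'effect_delta' must be in [0, 1]")
  if (cfg$missing_frac < 0 || cfg$missing_frac >= 1)
    stopf("'missing_frac' must be in [0, 1)")
  structure(cfg, class = "SimulationConfig")
}

#' Generate a synthetic methylation cohort
#'
#' Baseline probe means are drawn from `Beta(a, b)` and squeezed into
#' \[0.05, 0.95\] so sampling noise is non-degenerate. Implanted probes for a
#' class get baseline means drawn away from the boundary so the in-class
#' shift of `effect_delta` (hypermethylated for even-indexed implants,
#' hypomethylated for odd) survives without clipping, making the realised
#' median shift equal the nominal effect. Per-sample values are drawn from a
#' Beta distribution with the probe's (class-adjusted) mean and the
#' configured precision. Metastatic samples reuse the class distributions
#' (noisier by `metastatic_precision_factor`), emulating retention of the
#' primary tumour's methylation profile.
#'
#' @param config A [simulation_config()].
#' @return List with elements `beta` ([BetaMatrix]), `annotations` (data
#'   frame: sample_id, cancer_type, stage), `truth` (per-class implanted
#'   probe data frames with direction, plus per-sample true classes) and
#'   `class_map` (a [ClassMap] with one cancer type per class).
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  nc <- config$n_classes; np <- config$n_probes
  classes <- sprintf("class%02d", seq_len(nc))
  types <- sprintf("T%02d", seq_len(nc))
  squam <- if (config$n_squamous_classes > 0L)
    classes[seq.int(nc - config$n_squamous_classes + 1L, nc)] else character()
  probes <- sprintf("cg%06d", seq_len(np))

  a <- config$baseline_beta_params[1L]; b <- config$baseline_beta_params[2L]
  mu <- pmin(pmax(rbeta(np, a, b), 0.05), 0.95)

  # implanted probe sets: disjoint, alternating direction; baselines kept in
  # a band where +/- effect_delta cannot clip
  truth_sets <- vector("list", nc); names(truth_sets) <- classes
  dir_sign <- numeric(np)
  for (ci in seq_len(nc)) {
    idx <- (ci - 1L) * config$dmc_per_class + seq_len(config$dmc_per_class)
    dirs <- ifelse(seq_along(idx) %% 2L == 1L, 1, -1)
    lo <- ifelse(dirs > 0, 0.05, 0.05 + config$effect_delta)
    hi <- ifelse(dirs > 0, 0.95 - config$effect_delta, 0.95)
    mu[idx] <- runif(length(idx), lo, hi)
    truth_sets[[ci]] <- data.frame(probe_id = probes[idx],
                                   direction = ifelse(dirs > 0, "hyper", "hypo"),
                                   stringsAsFactors = FALSE)
  }

  n_meta <- ceiling(config$metastatic_frac * config$samples_per_class)
  n_per <- config$samples_per_class + n_meta
  n_samples <- nc * n_per
  sample_class <- rep(seq_len(nc), each = n_per)
  stage <- rep(rep(c("primary", "metastatic"),
                   c(config$samples_per_class, n_meta)), nc)
  sample_id <- sprintf("S%04d", seq_len(n_samples))

  draw_beta <- function(mean_vec, phi) {
    rbeta(length(mean_vec), mean_vec * phi, (1 - mean_vec) * phi)
  }
  values <- matrix(NA_real_, np, n_samples, dimnames = list(probes, sample_id))
  for (s in seq_len(n_samples)) {
    ci <- sample_class[s]
    idx <- (ci - 1L) * config$dmc_per_class + seq_len(config$dmc_per_class)
    m <- mu
    dirs <- ifelse(seq_along(idx) %% 2L == 1L, 1, -1)
    m[idx] <- m[idx] + dirs * config$effect_delta
    phi <- if (stage[s] == "metastatic")
      config$precision * config$metastatic_precision_factor else config$precision
    values[, s] <- draw_beta(m, phi)
  }
  values <- pmin(pmax(values, 0), 1)

  if (config$missing_frac > 0) {
    miss <- which(runif(length(values)) < config$missing_frac)
    values[miss] <- NA_real_
  }

  ann <- data.frame(sample_id = sample_id,
                    cancer_type = types[sample_class],
                    stage = stage, stringsAsFactors = FALSE)
  cm <- ClassMap(type_to_class = setNames(classes, types),
                 squamous_types = types[classes %in% squam])
  truth <- list(per_class = truth_sets,
                sample_class = setNames(classes[sample_class], sample_id))
  list(beta = BetaMatrix(values), annotations = ann, truth = truth,
       class_map = cm)
}

#' Synthetic cohort-sized annotation table
#'
#' Builds an annotation table (no beta values) with the full-cohort head
#' count: `total` samples over the class map's types, with fixed counts for
#' the excluded types and the remainder spread over the non-excluded types by
#' largest-remainder rounding of equal weights. Used to exercise cohort
#' arithmetic and stratified splitting at realistic sample counts without a
#' full-size matrix.
#'
#' @param class_map A [ClassMap]; default [default_class_map()].
#' @param total Total number of samples (default 8233).
#' @param excluded_counts Named integer vector of per-type counts for
#'   excluded types (default `c(ACC = 79, UVM = 80)`).
#' @param seed Seed for the type-label shuffle.
#' @return Data frame with columns sample_id, cancer_type, stage.
#' @export
simulate_annotation_profile <- function(class_map = default_class_map(),
                                        total = 8233L,
                                        excluded_counts = c(ACC = 79L, UVM = 80L),
                                        seed = 1L) {
  stopifnot(inherits(class_map, "ClassMap"))
  if (!all(names(excluded_counts) %in% class_map$excluded_types))
    stopf("excluded_counts names must be excluded types")
  types <- names(class_map$type_to_class)
  n_rest <- total - sum(excluded_counts)
  base <- n_rest %/% length(types)
  counts <- rep(base, length(types))
  counts[seq_len(n_rest - base * length(types))] <- base + 1L
  labels <- c(rep(types, counts), rep(names(excluded_counts), excluded_counts))
  set.seed(seed)
  labels <- sample(labels)
  data.frame(sample_id = sprintf("S%05d", seq_along(labels)),
             cancer_type = labels, stage = "primary",
             stringsAsFactors = FALSE)
}

#' Write the small canonical fixture files
#'
#' Emits the plain-text fixtures used by unit tests and documentation
#' examples: a tiny beta TSV with a missing cell, a 12-sample cohort
#' (beta TSV + annotation CSV + ground-truth JSON) and a toy 4x3-grid panel
#' with its pixel assignment. Seeded, so regenerated files are
#' byte-identical across runs.
#'
#' @param out_dir Writable directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
make_fixture_suite <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()

  # tiny 10 x 4 beta matrix with one missing cell
  set.seed(11L)
  v <- matrix(round(runif(40), 6), 10, 4,
              dimnames = list(sprintf("cg%06d", 1:10), sprintf("S%02d", 1:4)))
  v[3, 2] <- NA
  p <- file.path(out_dir, "tiny_beta.tsv")
  write_beta_table(BetaMatrix(v), p); paths <- c(paths, p)

  # 12-sample, 3-class cohort
  cfg <- simulation_config(n_classes = 3L, n_squamous_classes = 1L,
                           samples_per_class = 4L, n_probes = 120L,
                           dmc_per_class = 10L, missing_frac = 0.01,
                           metastatic_frac = 0, seed = 7L)
  sim <- simulate_cohort(cfg)
  p <- file.path(out_dir, "cohort12_beta.tsv")
  write_beta_table(sim$beta, p); paths <- c(paths, p)
  p <- file.path(out_dir, "cohort12_annotations.csv")
  utils::write.csv(sim$annotations, p, row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)
  p <- file.path(out_dir, "cohort12_truth.json")
  jsonlite::write_json(sim$truth, p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  p <- file.path(out_dir, "cohort12_classmap.yaml")
  write_class_map(sim$class_map, p); paths <- c(paths, p)

  # toy 4 x 3 panel assignment (on the imputed matrix)
  probes <- sprintf("cg%06d", 1:12)
  bm_imp <- impute_missing_median(filter_probes_by_presence(sim$beta))
  fr <- feature_rank_matrix(subset_beta(bm_imp, probes = probes))
  pr <- pixel_rank_matrix(c(4L, 3L))
  asg <- igtd_optimize(fr, pr, n_iterations = 100L, seed = 1L,
                       probe_ids = probes)
  p <- file.path(out_dir, "toy_assignment.json")
  write_assignment(asg, p); paths <- c(paths, p)

  invisible(paths)
}
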