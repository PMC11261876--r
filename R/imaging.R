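#' Render one sample's betas onto an optimised grid
#'
#' Cell (r, c) of the result holds the beta value of the probe assigned
#' there. Probes absent from `sample_betas` fall back to `fallback` (intended
#' to carry training-set median betas, for external samples missing panel
#' probes); without a fallback an absent probe is an error naming it.
#'
#' @param sample_betas Named numeric vector, probe ID -> beta.
#' @param assignment A `PixelAssignment`.
#' @param fallback Optional named numeric vector of fallback betas.
#' @return Numeric matrix of dimension `assignment$grid_shape`, values in
#'   \[0, 1\].
#' @export
render_grid <- function(sample_betas, assignment, fallback = NULL) {
  stopifnot(inherits(assignment, "PixelAssignment"))
  probes_rm <- assignment$probe_ids[assignment$order]   # row-major cell order
  vals <- unname(sample_betas[probes_rm])
  absent <- is.na(vals) & !(probes_rm %in% names(sample_betas))
  if (any(absent)) {
    if (!is.null(fallback)) {
      vals[absent] <- unname(fallback[probes_rm[absent]])
      absent <- is.na(vals)
    }
    if (any(absent))
      stopf("no beta value for probe '%s' and no fallback configured",
            probes_rm[which(absent)[1L]])
  }
  matrix(vals, nrow = assignment$grid_shape[1L],
         ncol = assignment$grid_shape[2L], byrow = TRUE)
}

#' Deterministic image resize
#'
#' Nearest-neighbour (default, preserves the blocky per-probe semantics) or
#' bilinear resampling; either way output values stay within the source
#' min/max.
#'
#' @param img 2-D numeric matrix.
#' @param new_shape Target `c(rows, cols)`.
#' @param method `"nearest"` or `"bilinear"`.
#' @return Matrix of dimension `new_shape`.
#' @export
resize_image <- function(img, new_shape, method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  stopifnot(is.matrix(img), all(new_shape >= 1L))
  out <- EBImage::resize(img, w = new_shape[1L], h = new_shape[2L],
                         filter = if (method == "nearest") "none" else "bilinear")
  m <- matrix(as.numeric(out), new_shape[1L], new_shape[2L])
  # bilinear convexity can be violated only by numerical noise; clamp to the
  # source range to keep the contract exact
  pmin(pmax(m, min(img)), max(img))
}

#' Merge the non-squamous and squamous image halves
#'
#' Column-wise concatenation with a fixed, documented orientation: the
#' non-squamous part occupies the left columns and the (resized) squamous
#' part the right columns. With the default 68 x 34 halves the result is the
#' 68 x 68 model input.
#'
#' @param nonsq,sq_resized Matrices of identical dimension.
#' @return Matrix with the same rows and twice the columns.
#' @export
merge_parts <- function(nonsq, sq_resized) {
  if (!identical(dim(nonsq), dim(sq_resized)))
    stopf("part shapes differ: %s vs %s",
          paste(dim(nonsq), collapse = "x"),
          paste(dim(sq_resized), collapse = "x"))
  cbind(nonsq, sq_resized)
}

#' Quantise a beta image to an 8-bit grayscale 3-channel image
#'
#' Each value v in \[0, 1\] maps to `round(v * 255)` with ties rounding half
#' away from zero (so 0.5 -> 128), replicated over three identical channels.
#'
#' @param img Numeric matrix with values in \[0, 1\].
#' @param sample_id Optional sample identifier.
#' @param provenance Optional provenance list (panel/assignment fingerprints).
#' @return A `MethylationImage`: list(sample_id, pixels = H x W x 3 integer
#'   array in \[0, 255\], provenance).
#' @export
to_uint8_grayscale <- function(img, sample_id = NULL, provenance = NULL) {
  stopifnot(is.matrix(img))
  if (anyNA(img) || min(img) < 0 || max(img) > 1)
    stopf("image values must lie in [0, 1]")
  ch <- round_half_away(img * 255)
  storage.mode(ch) <- "integer"
  px <- array(ch, dim = c(dim(img), 3L))
  structure(list(sample_id = sample_id, pixels = px, provenance = provenance),
            class = "MethylationImage")
}

#' Per-class mean methylation image
#'
#' Pixel-wise mean over a list of images of identical shape, re-quantised to
#' 0--255; used for per-class pattern panels.
#'
#' @param images Non-empty list of `MethylationImage`s.
#' @return A `MethylationImage` (sample_id `"class_mean"`).
#' @export
class_mean_image <- function(images) {
  if (length(images) == 0L) stopf("empty image list")
  stopifnot(all(vapply(images, inherits, logical(1), "MethylationImage")))
  dims <- lapply(images, function(im) dim(im$pixels))
  if (length(unique(dims)) != 1L) stopf("images have differing shapes")
  acc <- Reduce(`+`, lapply(images, function(im) im$pixels * 1.0))
  mean_px <- acc / length(images)
  ch <- round_half_away(mean_px)
  storage.mode(ch) <- "integer"
  structure(list(sample_id = "class_mean", pixels = ch,
                 provenance = images[[1L]]$provenance),
            class = "MethylationImage")
}

#' Render the merged methylation image stack for a cohort
#'
#' The full imaging stage: per sample, render the non-squamous and squamous
#' grids, resize the squamous half to the non-squamous grid shape, merge the
#' halves and quantise to 0--255. The result carries a provenance
#' fingerprint of both assignments; models trained on a stack refuse to
#' predict images from a different assignment.
#'
#' @param bm A [BetaMatrix] with no missing values, containing all panel
#'   probes (or see `fallback`).
#' @param assignment_nonsq,assignment_sq `PixelAssignment`s for the two
#'   panels.
#' @param samples Sample IDs to render (default: all in `bm`).
#' @param resize_method Passed to [resize_image()].
#' @param fallback Optional named numeric of fallback betas for absent
#'   probes (e.g. training medians).
#' @return A `MethylationImageSet`: list(pixels = n x H x W integer array,
#'   sample_ids, grid_shape, provenance).
#' @export
render_cohort_images <- function(bm, assignment_nonsq, assignment_sq,
                                 samples = NULL, resize_method = "nearest",
                                 fallback = NULL) {
  stopifnot(inherits(bm, "BetaMatrix"))
  samples <- samples %||% sample_ids(bm)
  shp <- assignment_nonsq$grid_shape
  H <- shp[1L]; W <- 2L * shp[2L]
  prov <- list(
    nonsq = fingerprint(list(assignment_nonsq$probe_ids, assignment_nonsq$order,
                             assignment_nonsq$grid_shape)),
    sq = fingerprint(list(assignment_sq$probe_ids, assignment_sq$order,
                          assignment_sq$grid_shape)),
    resize_method = resize_method)
  px <- array(0L, dim = c(length(samples), H, W))
  for (k in seq_along(samples)) {
    betas <- bm$values[, samples[k]]
    g_non <- render_grid(betas, assignment_nonsq, fallback = fallback)
    g_sq <- render_grid(betas, assignment_sq, fallback = fallback)
    g_sq <- resize_image(g_sq, shp, method = resize_method)
    merged <- merge_parts(g_non, g_sq)
    img <- to_uint8_grayscale(merged)
    px[k, , ] <- img$pixels[, , 1L]
  }
  structure(list(pixels = px, sample_ids = samples,
                 grid_shape = c(H, W), provenance = prov),
            class = "MethylationImageSet")
}

#' @export
print.MethylationImageSet <- function(x, ...) {
  cat(sprintf("MethylationImageSet: %d images of %dx%dx3 (uint8)\n",
              length(x$sample_ids), x$grid_shape[1L], x$grid_shape[2L]))
  invisible(x)
}

#' Extract one image from a MethylationImageSet
#' @param image_set A `MethylationImageSet`.
#' @param sample_id Sample to extract.
#' @return A `MethylationImage`.
#' @export
get_image <- function(image_set, sample_id) {
  k <- match(sample_id, image_set$sample_ids)
  if (is.na(k)) stopf("sample '%s' not in image set", sample_id)
  ch <- image_set$pixels[k, , ]
  px <- array(as.integer(ch), dim = c(dim(ch), 3L))
  structure(list(sample_id = sample_id, pixels = px,
                 provenance = image_set$provenance),
            class = "MethylationImage")
}

#' Write a MethylationImage as an 8-bit PNG
#' @param image A `MethylationImage`.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_methylation_png <- function(image, path) {
  stopifnot(inherits(image, "MethylationImage"))
  png::writePNG(image$pixels / 255, target = path)
  invisible(path)
}
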