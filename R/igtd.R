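# rank matrix from a dist object: smallest distance gets rank 1, average
# ranks on ties; symmetric with zero diagonal
rank_matrix_from_dist <- function(d, n) {
  r <- rank(as.numeric(d))            # ranks of the n(n-1)/2 pairs
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- r
  m <- m + t(m)
  m
}

#' Rank matrix of pairwise feature distances
#'
#' Euclidean distances between probe beta profiles (rows of the panel-
#' restricted matrix, i.e. across training samples), converted to ranks of
#' the n(n-1)/2 pairs with average ranks on ties.
#'
#' @param bm_panel A [BetaMatrix] restricted to a panel's probes, no missing
#'   values, at least 2 probes.
#' @return A `RankMatrix`: list(ranks, size, grid_shape = NULL).
#' @export
feature_rank_matrix <- function(bm_panel) {
  stopifnot(inherits(bm_panel, "BetaMatrix"))
  n <- nrow(bm_panel$values)
  if (n < 2L) stopf("need at least 2 probes")
  if (anyNA(bm_panel$values)) stopf("missing values present")
  d <- dist(bm_panel$values)
  structure(list(ranks = rank_matrix_from_dist(d, n), size = n,
                 grid_shape = NULL, probe_ids = probe_ids(bm_panel)),
            class = "RankMatrix")
}

#' Rank matrix of pairwise pixel distances
#'
#' Euclidean distances between the (row, col) coordinates of the cells of a
#' rows x cols grid, in row-major cell order, ranked as in
#' [feature_rank_matrix()]. A pure function of the grid shape.
#'
#' @param grid_shape Integer vector `c(rows, cols)` with `rows * cols >= 2`.
#' @return A `RankMatrix` carrying `grid_shape`.
#' @export
pixel_rank_matrix <- function(grid_shape) {
  rows <- as.integer(grid_shape[1L]); cols <- as.integer(grid_shape[2L])
  if (rows < 1L || cols < 1L || rows * cols < 2L)
    stopf("grid must have at least 2 cells")
  n <- rows * cols
  cells <- cbind(row = (seq_len(n) - 1L) %/% cols,
                 col = (seq_len(n) - 1L) %% cols)
  d <- dist(cells)
  structure(list(ranks = rank_matrix_from_dist(d, n), size = n,
                 grid_shape = c(rows, cols)),
            class = "RankMatrix")
}

#' Rank-matching error of a pixel assignment
#'
#' Sum over all cell pairs (i < j) of the difference between the
#' feature-distance rank of the assigned probes and the pixel-distance rank
#' of the cells: the absolute difference by default, or its square with
#' `variant = "squared"`.
#'
#' @param feature_ranks,pixel_ranks `RankMatrix` objects of equal size.
#' @param order Integer permutation: grid cell (row-major) -> feature index.
#' @param variant `"abs"` (default) or `"squared"` per-pair error term.
#' @return Non-negative scalar.
#' @export
assignment_error <- function(feature_ranks, pixel_ranks, order,
                             variant = c("abs", "squared")) {
  variant <- match.arg(variant)
  if (feature_ranks$size != pixel_ranks$size)
    stopf("rank-matrix sizes differ (%d vs %d)",
          feature_ranks$size, pixel_ranks$size)
  if (length(order) != pixel_ranks$size || anyDuplicated(order) ||
      !all(sort(order) == seq_len(pixel_ranks$size)))
    stopf("'order' must be a permutation of 1..%d", pixel_ranks$size)
  igtd_error_cpp(feature_ranks$ranks, pixel_ranks$ranks, as.integer(order),
                 squared = variant == "squared")
}

#' Optimise the probe-to-pixel assignment (IGTD)
#'
#' Starting from the identity order (panel concatenation order onto row-major
#' cells), repeatedly selects the grid cell with the largest contribution to
#' the rank-matching error among cells not examined within the last
#' `lookback` iterations, evaluates swapping its probe against every other
#' cell's probe, and applies the best strictly-improving swap; small
#' instances additionally try strictly-improving 3-cycles once pairwise
#' swaps are exhausted. On instances of at most `restart_max` cells the
#' climb is repeated from `restarts` seeded random initial orders and the
#' best assignment is kept, since tiny grids otherwise stall in local
#' optima. The error trajectory records the incumbent best and is therefore
#' non-increasing; all randomness derives from `seed`.
#'
#' @param feature_ranks,pixel_ranks `RankMatrix` objects of equal size;
#'   `pixel_ranks` must carry a `grid_shape`.
#' @param n_iterations Outer iterations per climb (default 5000).
#' @param seed Integer seed for the restart orders.
#' @param lookback Re-examination window; default `floor(n / 2)`.
#' @param patience Early stop after this many iterations without an accepted
#'   swap; 0 (default) disables early stopping so the full iteration budget
#'   is honoured.
#' @param restarts Extra seeded climbs on small instances (default 15).
#' @param restart_max Largest instance size on which restarts run
#'   (default 100 cells; larger panels use the single identity-start climb).
#' @param variant Per-pair error term: `"abs"` (default) or `"squared"`.
#' @param probe_ids Optional probe IDs in feature order; defaults to those
#'   carried by `feature_ranks`.
#' @return A `PixelAssignment`: list(grid_shape, order, probe_ids,
#'   error_trajectory, seed, n_iterations, initial_error, final_error).
#' @export
igtd_optimize <- function(feature_ranks, pixel_ranks, n_iterations = 5000L,
                          seed = 0L, lookback = NULL, patience = 0L,
                          restarts = 15L, restart_max = 100L,
                          variant = c("abs", "squared"), probe_ids = NULL) {
  variant <- match.arg(variant)
  if (feature_ranks$size != pixel_ranks$size)
    stopf("rank-matrix sizes differ (%d vs %d)",
          feature_ranks$size, pixel_ranks$size)
  if (is.null(pixel_ranks$grid_shape))
    stopf("'pixel_ranks' must come from pixel_rank_matrix()")
  if (n_iterations < 1L) stopf("'n_iterations' must be >= 1")
  n <- feature_ranks$size
  if (is.null(lookback)) lookback <- max(1L, n %/% 2L)
  climb <- function(init) {
    igtd_optimize_cpp(feature_ranks$ranks, pixel_ranks$ranks,
                      as.integer(n_iterations), as.integer(lookback),
                      as.integer(patience), init_order = init,
                      squared = variant == "squared")
  }
  best <- climb(NULL)
  traj <- as.numeric(best$trajectory)
  if (n <= restart_max && restarts > 0L) {
    set.seed(seed)
    for (r in seq_len(restarts)) {
      cand <- climb(sample.int(n))
      ct <- as.numeric(cand$trajectory)
      traj <- c(traj, pmin(ct, traj[length(traj)]))   # incumbent-best record
      if (ct[length(ct)] < best$trajectory[length(best$trajectory)])
        best <- cand
    }
  }
  structure(list(grid_shape = pixel_ranks$grid_shape,
                 order = as.integer(best$order),
                 probe_ids = probe_ids %||% feature_ranks$probe_ids,
                 error_trajectory = traj,
                 seed = as.integer(seed),
                 n_iterations = as.integer(n_iterations),
                 initial_error = traj[1L],
                 final_error = traj[length(traj)]),
            class = "PixelAssignment")
}

#' @export
print.PixelAssignment <- function(x, ...) {
  cat(sprintf("PixelAssignment: %dx%d grid, %d features, error %.1f -> %.1f (%d iterations)\n",
              x$grid_shape[1L], x$grid_shape[2L], length(x$order),
              x$initial_error, x$final_error, x$n_iterations))
  invisible(x)
}

#' Write / read a pixel assignment as JSON
#'
#' Stores the grid shape, the probe IDs in row-major cell order, the panel-
#' order probe list, the seed, iteration count and the initial/final error.
#'
#' @param assignment A `PixelAssignment`.
#' @param path Output path.
#' @return `path` invisibly; [read_assignment()] returns the
#'   `PixelAssignment` (without the full trajectory, which is not stored).
#' @export
write_assignment <- function(assignment, path) {
  stopifnot(inherits(assignment, "PixelAssignment"))
  jsonlite::write_json(list(
    grid_shape = assignment$grid_shape,
    order = assignment$order,
    probe_ids = assignment$probe_ids,
    probes_row_major = assignment$probe_ids[assignment$order],
    seed = assignment$seed,
    n_iterations = assignment$n_iterations,
    initial_error = assignment$initial_error,
    final_error = assignment$final_error), path,
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_assignment
#' @export
read_assignment <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(grid_shape = as.integer(j$grid_shape),
                 order = as.integer(j$order),
                 probe_ids = as.character(j$probe_ids),
                 error_trajectory = c(j$initial_error, j$final_error),
                 seed = as.integer(j$seed),
                 n_iterations = as.integer(j$n_iterations),
                 initial_error = j$initial_error,
                 final_error = j$final_error),
            class = "PixelAssignment")
}
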