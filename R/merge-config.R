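#' Configuration for the nuclei-merging algorithm
#'
#' @param distance_threshold Euclidean distance (pixels) within which a
#'   nearest-neighbor pair is considered the same nucleus; the inclusive
#'   bound `d <= D` is applied. Default 10 (chosen in the source study by
#'   profiling centroid distances of overlapping nuclei at 0.263 um/px).
#' @param equivocal_prob_threshold Conflicting pairs in which *both* model
#'   probabilities strictly exceed this value are flagged equivocal and
#'   written to the equivocal report. Default 0.75.
#' @param index_backend `"exact"` (k-d tree; deterministic, default) or
#'   `"approximate"` (Annoy-style random-projection forest).
#' @param n_trees Number of random-projection trees for the approximate
#'   backend. Default 100.
#' @param search_k Candidate budget per approximate query; `-1` (default)
#'   means `n_trees` candidates, mirroring Annoy's default for single-
#'   neighbor queries.
#' @param matching_strategy `"literal"` (default) follows the printed
#'   algorithm with a first-consumption-wins guard: an already-consumed
#'   nearest neighbor is treated as out of range. `"one_to_one"` instead
#'   re-queries for the nearest not-yet-consumed neighbor.
#' @param random_seed Integer seed for the approximate backend's tree
#'   construction. Ignored by the exact backend.
#' @return An object of class `merge_config`.
#' @export
merge_config <- function(distance_threshold = 10,
                         equivocal_prob_threshold = 0.75,
                         index_backend = c("exact", "approximate"),
                         n_trees = 100L,
                         search_k = -1L,
                         matching_strategy = c("literal", "one_to_one"),
                         random_seed = 1L) {
  index_backend <- match.arg(index_backend)
  matching_strategy <- match.arg(matching_strategy)
  if (!is.numeric(distance_threshold) || length(distance_threshold) != 1L ||
      !is.finite(distance_threshold) || distance_threshold <= 0) {
    stop("distance_threshold must be a single positive number")
  }
  if (!is.numeric(equivocal_prob_threshold) ||
      length(equivocal_prob_threshold) != 1L ||
      equivocal_prob_threshold <= 0 || equivocal_prob_threshold >= 1) {
    stop("equivocal_prob_threshold must lie in (0, 1)")
  }
  structure(list(distance_threshold = distance_threshold,
                 equivocal_prob_threshold = equivocal_prob_threshold,
                 index_backend = index_backend,
                 n_trees = as.integer(n_trees),
                 search_k = as.integer(search_k),
                 matching_strategy = matching_strategy,
                 random_seed = as.integer(random_seed)),
            class = "merge_config")
}

#' Build a spatial index over centroid positions
#'
#' @param points Two-column matrix (or data frame) of (x, y) coordinates.
#' @param config A [merge_config()]; its `index_backend`, `n_trees`,
#'   `search_k` and `random_seed` fields select and parameterize the backend.
#' @return An object of class `spatial_index` supporting [query_nearest()].
#'   An empty point set yields a valid index whose queries return the
#'   no-neighbor sentinel (`index = NA`, `distance = Inf`).
#' @export
build_index <- function(points, config = merge_config()) {
  points <- as.matrix(points)
  if (length(points) == 0L) points <- matrix(numeric(0), ncol = 2L)
  if (ncol(points) != 2L) stop("points must have two columns (x, y)")
  if (any(!is.finite(points))) stop("points must be finite")
  handle <- if (config$index_backend == "exact") {
    cpp_kd_build(points[, 1], points[, 2])
  } else {
    cpp_rp_build(points[, 1], points[, 2], config$n_trees, 10L,
                 config$random_seed)
  }
  structure(list(handle = handle, points = points,
                 backend = config$index_backend,
                 search_k = config$search_k, n = nrow(points)),
            class = "spatial_index")
}

#' Nearest-neighbor query against a spatial index
#'
#' @param index A `spatial_index` from [build_index()].
#' @param point Numeric (x, y) pair, or a two-column matrix of query points.
#' @return A list with `index` (1-based position(s) of the neighbor in the
#'   indexed point set; `NA` when the index is empty) and `distance`
#'   (Euclidean; `Inf` when empty). Ties on distance go to the smallest
#'   index under the exact backend.
#' @export
query_nearest <- function(index, point) {
  stopifnot(inherits(index, "spatial_index"))
  pm <- if (is.matrix(point)) point else matrix(point, ncol = 2L)
  res <- if (index$backend == "exact") {
    cpp_kd_query(index$handle, pm[, 1], pm[, 2])
  } else {
    cpp_rp_query(index$handle, pm[, 1], pm[, 2], index$search_k)
  }
  res
}

#' @export
print.merge_config <- function(x, ...) {
  cat("<merge_config> D = ", x$distance_threshold,
      " px, equivocal > ", x$equivocal_prob_threshold,
      ", backend = ", x$index_backend,
      ", strategy = ", x$matching_strategy, "\n", sep = "")
  invisible(x)
}

#' @export
print.spatial_index <- function(x, ...) {
  cat("<spatial_index> ", x$backend, " backend over ", x$n, " points\n",
      sep = "")
  invisible(x)
}
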