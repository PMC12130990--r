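#' Construct a set of nuclei predictions from one model
#'
#' A `prediction_set` holds every nucleus one segmentation model predicted on
#' one slide: centroid, contour polygon, bounding box, predicted cell-type
#' label and prediction probability, together with the model identifier and
#' its cell-type vocabulary. Coordinates are 0-based pixels at scan
#' resolution (x = column, y = row), 0.263 um per pixel at 40x by default.
#'
#' @param model_id Single string naming the model (e.g. `"monusac"`,
#'   `"pannuke"`).
#' @param nuclei A data frame with columns `id` (character, unique), `x`, `y`
#'   (numeric centroid), `type` (character label), `prob` (numeric in
#'   \[0,1\]), and list columns `contour` (n x 2 matrices, >= 3 vertices) and
#'   `bbox` (2 x 2 matrices, rows = min and max corner). Missing `contour` /
#'   `bbox` columns are filled with a small polygon around the centroid.
#' @param vocabulary Character vector of admissible type labels; defaults to
#'   the distinct labels present.
#' @param pixel_scale_um Physical pixel size in micrometers (default 0.263).
#' @return An object of class `prediction_set`.
#' @seealso [read_prediction_set()], [merge_predictions()]
#' @export
prediction_set <- function(model_id, nuclei, vocabulary = NULL,
                           pixel_scale_um = 0.263) {
  stopifnot(is.character(model_id), length(model_id) == 1L)
  nuclei <- as.data.frame(nuclei, stringsAsFactors = FALSE)
  if (nrow(nuclei) == 0L && !all(c("id", "x", "y", "type", "prob") %in% names(nuclei))) {
    nuclei <- empty_nuclei_df()
  }
  required <- c("id", "x", "y", "type", "prob")
  missing_cols <- setdiff(required, names(nuclei))
  if (length(missing_cols)) {
    stop("nuclei data frame lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  nuclei$id <- as.character(nuclei$id)
  nuclei$type <- as.character(nuclei$type)
  if (is.null(nuclei$contour) || is.null(nuclei$bbox)) {
    filled <- default_geometry(nuclei$x, nuclei$y)
    if (is.null(nuclei$contour)) nuclei$contour <- filled$contour
    if (is.null(nuclei$bbox)) nuclei$bbox <- filled$bbox
  }
  if (is.null(vocabulary)) vocabulary <- sort(unique(nuclei$type))
  obj <- structure(
    list(model_id = model_id, vocabulary = vocabulary,
         nuclei = nuclei[c("id", "x", "y", "type", "prob", "contour", "bbox")],
         pixel_scale_um = pixel_scale_um),
    class = "prediction_set")
  validate_prediction_set(obj)
  obj
}

empty_nuclei_df <- function() {
  data.frame(id = character(0), x = numeric(0), y = numeric(0),
             type = character(0), prob = numeric(0),
             contour = I(list()), bbox = I(list()),
             stringsAsFactors = FALSE)
}

# Octagonal stand-in contour of radius 5 px, used when geometry is absent.
default_geometry <- function(x, y, radius = 5) {
  ang <- seq(0, 2 * pi, length.out = 9L)[-9L]
  contour <- mapply(function(cx, cy) {
    cbind(cx + radius * cos(ang), cy + radius * sin(ang))
  }, x, y, SIMPLIFY = FALSE)
  bbox <- lapply(contour, function(cc) {
    rbind(c(min(cc[, 1]), min(cc[, 2])), c(max(cc[, 1]), max(cc[, 2])))
  })
  list(contour = I(contour), bbox = I(bbox))
}

#' Validate a prediction set
#'
#' Checks the structural invariants: unique ids, probabilities in \[0,1\],
#' contours with at least 3 vertices, bounding boxes with min <= max that
#' contain the centroid, and every type label in the declared vocabulary.
#' Called by the constructors and readers; errors name the offending record.
#'
#' @param set A `prediction_set`.
#' @return The set, invisibly, if valid; otherwise an error is signalled.
#' @export
validate_prediction_set <- function(set) {
  stopifnot(inherits(set, "prediction_set"))
  nuc <- set$nuclei
  if (anyDuplicated(nuc$id)) {
    stop("duplicate nucleus id(s): ",
         paste(unique(nuc$id[duplicated(nuc$id)]), collapse = ", "))
  }
  bad <- which(!is.finite(nuc$prob) | nuc$prob < 0 | nuc$prob > 1)
  if (length(bad)) {
    stop("record '", nuc$id[bad[1]], "': prob must lie in [0, 1], got ",
         nuc$prob[bad[1]])
  }
  bad <- which(!is.finite(nuc$x) | !is.finite(nuc$y))
  if (length(bad)) stop("record '", nuc$id[bad[1]], "': non-finite centroid")
  unknown <- setdiff(unique(nuc$type), set$vocabulary)
  if (length(unknown)) {
    stop("type label(s) outside the declared vocabulary: ",
         paste(unknown, collapse = ", "))
  }
  for (i in seq_len(nrow(nuc))) {
    cc <- nuc$contour[[i]]
    if (is.null(cc) || !is.matrix(cc) || nrow(cc) < 3L || ncol(cc) != 2L) {
      stop("record '", nuc$id[i], "': contour must have >= 3 (x, y) vertices")
    }
    bb <- nuc$bbox[[i]]
    if (is.null(bb) || !is.matrix(bb) || !all(dim(bb) == c(2L, 2L))) {
      stop("record '", nuc$id[i], "': bbox must be a 2 x 2 (min, max) matrix")
    }
    if (any(bb[1, ] > bb[2, ])) {
      stop("record '", nuc$id[i], "': bbox min exceeds max")
    }
    if (nuc$x[i] < bb[1, 1] || nuc$x[i] > bb[2, 1] ||
        nuc$y[i] < bb[1, 2] || nuc$y[i] > bb[2, 2]) {
      stop("record '", nuc$id[i], "': centroid outside bbox")
    }
  }
  invisible(set)
}

#' @export
print.prediction_set <- function(x, ...) {
  cat("<prediction_set> model '", x$model_id, "': ", nrow(x$nuclei),
      " nuclei\n", sep = "")
  cat("  vocabulary: ", paste(x$vocabulary, collapse = ", "), "\n", sep = "")
  if (nrow(x$nuclei)) {
    tab <- sort(table(x$nuclei$type), decreasing = TRUE)
    cat("  types: ", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Number of nuclei in a prediction set
#' @param set A `prediction_set`.
#' @return Integer count.
#' @export
n_nuclei <- function(set) nrow(set$nuclei)
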