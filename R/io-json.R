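#' Read a per-slide nuclei prediction file
#'
#' Parses the package's JSON dialect for model predictions: a top-level object
#' mapping nucleus id to a record with keys `centroid` (`[x, y]` pixels),
#' `contour` (list of `[x, y]` vertices, >= 3), `box`
#' (`[[xmin, ymin], [xmax, ymax]]`), `type` (string) and `prob` (number in
#' \[0,1\]). The dialect mirrors the information content of HoVer-Net /
#' TIAToolbox per-nucleus output; records missing an id-key (i.e. a JSON
#' array instead of an object) get ids synthesized from their 1-based
#' insertion index.
#'
#' @param path Path to the JSON file.
#' @param model_id Model identifier to attach to the set.
#' @param vocabulary Optional character vector; when given, labels outside it
#'   are a validation error.
#' @param pixel_scale_um Pixel size in micrometers (default 0.263).
#' @return A [prediction_set()].
#' @export
read_prediction_set <- function(path, model_id, vocabulary = NULL,
                                pixel_scale_um = 0.263) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("cannot parse '", path, "' as JSON: ",
                             conditionMessage(e)))
  ids <- names(raw)
  if (is.null(ids)) ids <- as.character(seq_along(raw))
  nuclei <- parse_nucleus_records(raw, ids)
  prediction_set(model_id, nuclei, vocabulary = vocabulary,
                 pixel_scale_um = pixel_scale_um)
}

parse_nucleus_records <- function(raw, ids) {
  if (length(raw) == 0L) return(empty_nuclei_df())
  recs <- vector("list", length(raw))
  for (i in seq_along(raw)) {
    r <- raw[[i]]
    id <- ids[i]
    for (key in c("centroid", "prob", "type")) {
      if (is.null(r[[key]])) {
        stop("record '", id, "': missing required key '", key, "'")
      }
    }
    centroid <- as.numeric(unlist(r$centroid))
    if (length(centroid) != 2L || anyNA(centroid)) {
      stop("record '", id, "': centroid must be [x, y]")
    }
    contour <- if (is.null(r$contour)) NULL else pair_list_to_matrix(r$contour, id, "contour")
    box <- if (is.null(r$box)) NULL else pair_list_to_matrix(r$box, id, "box")
    recs[[i]] <- list(id = id, x = centroid[1], y = centroid[2],
                      type = as.character(r$type), prob = as.numeric(r$prob),
                      contour = contour, bbox = box)
  }
  df <- data.frame(
    id = vapply(recs, `[[`, "", "id"),
    x = vapply(recs, `[[`, 0, "x"),
    y = vapply(recs, `[[`, 0, "y"),
    type = vapply(recs, `[[`, "", "type"),
    prob = vapply(recs, `[[`, 0, "prob"),
    stringsAsFactors = FALSE)
  contours <- lapply(recs, `[[`, "contour")
  boxes <- lapply(recs, `[[`, "bbox")
  if (!any(vapply(contours, is.null, TRUE))) df$contour <- I(contours)
  if (!any(vapply(boxes, is.null, TRUE))) df$bbox <- I(boxes)
  df
}

pair_list_to_matrix <- function(v, id, what) {
  m <- tryCatch(do.call(rbind, lapply(v, function(p) as.numeric(unlist(p)))),
                error = function(e) NULL)
  if (is.null(m) || ncol(m) != 2L || anyNA(m)) {
    stop("record '", id, "': ", what, " must be a list of [x, y] pairs")
  }
  m
}

#' Write a prediction set to the JSON dialect
#'
#' Inverse of [read_prediction_set()]: the written file round-trips
#' field-for-field (numbers are serialized at full precision).
#'
#' @param set A `prediction_set`.
#' @param path Output path.
#' @return Invisibly, a manifest list with the path and record count.
#' @export
write_prediction_set <- function(set, path) {
  validate_prediction_set(set)
  nuc <- set$nuclei
  recs <- stats::setNames(lapply(seq_len(nrow(nuc)), function(i) {
    list(centroid = c(nuc$x[i], nuc$y[i]),
         contour = matrix_to_pair_list(nuc$contour[[i]]),
         box = matrix_to_pair_list(nuc$bbox[[i]]),
         type = nuc$type[i],
         prob = nuc$prob[i])
  }), nuc$id)
  if (length(recs) == 0L) recs <- stats::setNames(list(), character(0))
  write_json_file(recs, path)
  invisible(list(path = path, n_records = nrow(nuc)))
}

matrix_to_pair_list <- function(m) lapply(seq_len(nrow(m)), function(i) m[i, ])

write_json_file <- function(x, path) {
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) stop("cannot write '", path, "': ",
                                           conditionMessage(e)))
  on.exit(close(con))
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = TRUE)
  writeLines(json, con, useBytes = TRUE)
}

#' Write a merge result as the merged-nuclei JSON file
#'
#' Each output nucleus is serialized with its harmonized type, probability,
#' geometry, provenance tag (`merged`, `conflict_m1`, `conflict_m2`,
#' `unmatched_m1`, `unmatched_m2`), source ids in either input set, pair
#' distance (null when unpaired) and equivocal flag.
#'
#' @param result A `merge_result` from [merge_predictions()].
#' @param path Output path.
#' @return Invisibly, a manifest list with the path and record count.
#' @export
write_merged_set <- function(result, path) {
  stopifnot(inherits(result, "merge_result"))
  nuc <- result$nuclei
  recs <- stats::setNames(lapply(seq_len(nrow(nuc)), function(i) {
    list(centroid = c(nuc$x[i], nuc$y[i]),
         contour = matrix_to_pair_list(nuc$contour[[i]]),
         box = matrix_to_pair_list(nuc$bbox[[i]]),
         type = nuc$type[i],
         prob = nuc$prob[i],
         provenance = nuc$provenance[i],
         source_m1 = if (is.na(nuc$source_m1[i])) NULL else nuc$source_m1[i],
         source_m2 = if (is.na(nuc$source_m2[i])) NULL else nuc$source_m2[i],
         distance = if (is.na(nuc$distance[i])) NULL else nuc$distance[i],
         equivocal = nuc$equivocal[i])
  }), nuc$id)
  if (length(recs) == 0L) recs <- stats::setNames(list(), character(0))
  write_json_file(recs, path)
  invisible(list(path = path, n_records = nrow(nuc)))
}

#' Read back a merged-nuclei JSON file
#'
#' Round-trip companion of [write_merged_set()]; returns the output nuclei
#' as a data frame in file order.
#'
#' @param path Path written by [write_merged_set()].
#' @return A data frame with the merged-nucleus columns.
#' @export
read_merged_set <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  ids <- names(raw)
  if (length(raw) == 0L) return(empty_merged_df())
  df <- data.frame(
    id = ids,
    x = vapply(raw, function(r) as.numeric(r$centroid[[1]]), 0),
    y = vapply(raw, function(r) as.numeric(r$centroid[[2]]), 0),
    type = vapply(raw, function(r) as.character(r$type), ""),
    prob = vapply(raw, function(r) as.numeric(r$prob), 0),
    provenance = vapply(raw, function(r) as.character(r$provenance), ""),
    source_m1 = vapply(raw, function(r) if (is.null(r$source_m1)) NA_character_ else as.character(r$source_m1), ""),
    source_m2 = vapply(raw, function(r) if (is.null(r$source_m2)) NA_character_ else as.character(r$source_m2), ""),
    distance = vapply(raw, function(r) if (is.null(r$distance)) NA_real_ else as.numeric(r$distance), 0),
    equivocal = vapply(raw, function(r) isTRUE(r$equivocal), TRUE),
    stringsAsFactors = FALSE, row.names = NULL)
  df$contour <- I(unname(lapply(raw, function(r) pair_list_to_matrix(r$contour, "?", "contour"))))
  df$bbox <- I(unname(lapply(raw, function(r) pair_list_to_matrix(r$box, "?", "box"))))
  df
}

empty_merged_df <- function() {
  data.frame(id = character(0), x = numeric(0), y = numeric(0),
             type = character(0), prob = numeric(0),
             provenance = character(0), source_m1 = character(0),
             source_m2 = character(0), distance = numeric(0),
             equivocal = logical(0), contour = I(list()), bbox = I(list()),
             stringsAsFactors = FALSE)
}

#' Export merged nuclei contours as GeoJSON
#'
#' Writes a GeoJSON `FeatureCollection` of polygon contours with type,
#' probability and provenance properties, for overlay in slide viewers
#' (e.g. QuPath). Intended for visualization; exact numeric round-tripping
#' is not a goal of this format.
#'
#' @param result A `merge_result`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
export_geojson <- function(result, path) {
  stopifnot(inherits(result, "merge_result"))
  nuc <- result$nuclei
  features <- lapply(seq_len(nrow(nuc)), function(i) {
    cc <- nuc$contour[[i]]
    ring <- rbind(cc, cc[1, , drop = FALSE])  # closed ring per GeoJSON spec
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(matrix_to_pair_list(ring))),
         properties = list(id = nuc$id[i], cell_type = nuc$type[i],
                           prob = nuc$prob[i],
                           provenance = nuc$provenance[i]))
  })
  write_json_file(list(type = "FeatureCollection", features = features), path)
  invisible(path)
}
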