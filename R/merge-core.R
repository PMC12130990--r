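#' Extract one nucleus as a record
#'
#' Convenience accessor returning the i-th nucleus of a set as a plain list
#' (id, x, y, type, prob, contour, bbox, model_id), the currency of
#' [merge_pair()] and [resolve_conflict()].
#'
#' @param set A `prediction_set`.
#' @param i Row index.
#' @return A list of class `nucleus`.
#' @export
nucleus_record <- function(set, i) {
  nuc <- set$nuclei
  structure(list(id = nuc$id[i], x = nuc$x[i], y = nuc$y[i],
                 type = nuc$type[i], prob = nuc$prob[i],
                 contour = nuc$contour[[i]], bbox = nuc$bbox[[i]],
                 model_id = set$model_id),
            class = "nucleus")
}

#' Merge a spatially-coincident, type-concordant pair of nuclei
#'
#' Applies the merge rule for a nearest-neighbor pair whose types agree at
#' match level: the merged centroid is the componentwise midpoint, the
#' probability is the maximum of the two, contour and bounding box are taken
#' from the second (M2) nucleus, and the reported type is the pair's
#' [output_category()] (the more specific label of the two).
#'
#' @param n1,n2 Nucleus records (see [nucleus_record()]); `n1` from the
#'   indexed set M1, `n2` from the query set M2.
#' @param schema A `type_schema` used for the type test and output category.
#' @return A list with the merged nucleus fields and
#'   `provenance = "merged"`.
#' @export
merge_pair <- function(n1, n2, schema) {
  if (!types_match(n1$type, n1$model_id, n2$type, n2$model_id, schema)) {
    stop("merge_pair called on a non-matching pair ('", n1$type, "' vs '",
         n2$type, "'); route it to resolve_conflict()")
  }
  list(x = (n1$x + n2$x) / 2,
       y = (n1$y + n2$y) / 2,
       type = output_category(n1$type, n1$model_id, n2$type, n2$model_id,
                              schema),
       prob = max(n1$prob, n2$prob),
       contour = n2$contour,
       bbox = n2$bbox,
       provenance = "merged",
       source_m1 = n1$id,
       source_m2 = n2$id)
}

#' Resolve a type conflict between overlapping nuclei
#'
#' For a nearest-neighbor pair within the distance threshold whose types do
#' *not* match, the nucleus with the higher prediction probability is
#' retained; a tie keeps the M2 nucleus (the `>=` in the merge rule). The
#' pair is flagged equivocal when both probabilities strictly exceed the
#' equivocal threshold; equivocal pairs are still resolved (the winner enters
#' the merged set) but are recorded for manual review.
#'
#' @param n1,n2 Nucleus records; `n1` from M1, `n2` from M2.
#' @param config A [merge_config()] (supplies `equivocal_prob_threshold`).
#' @return A list with `winner` (the retained record), `winner_model`
#'   (`"m1"` or `"m2"`) and logical `equivocal`.
#' @export
resolve_conflict <- function(n1, n2, config = merge_config()) {
  thr <- config$equivocal_prob_threshold
  keep_m2 <- n2$prob >= n1$prob
  list(winner = if (keep_m2) n2 else n1,
       winner_model = if (keep_m2) "m2" else "m1",
       equivocal = n1$prob > thr && n2$prob > thr)
}

#' Merge two models' nuclei predictions
#'
#' The integration algorithm: a spatial index is built on the M1 centroids;
#' each M2 nucleus is matched to its nearest M1 neighbor. Pairs within the
#' distance threshold merge when their types agree at match level
#' ([merge_pair()]) and otherwise resolve to the higher-probability nucleus
#' ([resolve_conflict()]); out-of-range M2 nuclei are retained as-is, and
#' every M1 nucleus never consumed by a merge or conflict win is retained at
#' the end. The result is a union of both models' detections with overlaps
#' collapsed.
#'
#' Under the default `"literal"` strategy an M1 nucleus consumed by an
#' earlier decision is never output twice: a later M2 nucleus whose nearest
#' neighbor is already consumed is handled as if out of range. Under
#' `"one_to_one"` each M2 nucleus instead takes its nearest *unconsumed* M1
#' neighbor.
#'
#' @param m1 `prediction_set` indexed by the spatial index (HoVer-Net(M) in
#'   the motivating pipeline).
#' @param m2 `prediction_set` whose nuclei drive the merging loop
#'   (HoVer-Net(P)).
#' @param schema A `type_schema`; defaults to [default_type_schema()].
#' @param config A [merge_config()].
#' @return An object of class `merge_result`: list with `nuclei` (data frame
#'   of output nuclei with provenance, source ids, pair distance and
#'   equivocal flag), `equivocal` (data frame of equivocal conflicts),
#'   `match_m1`/`match_m2` (per-input logical match flags), input sizes and
#'   the configuration used.
#' @export
merge_predictions <- function(m1, m2, schema = default_type_schema(),
                              config = merge_config()) {
  validate_prediction_set(m1)
  validate_prediction_set(m2)
  stopifnot(inherits(config, "merge_config"))
  ml1 <- label_match_levels(m1, schema)
  ml2 <- label_match_levels(m2, schema)
  n1 <- nrow(m1$nuclei)
  n2 <- nrow(m2$nuclei)

  if (config$matching_strategy == "literal") {
    nn <- if (n1 > 0L && n2 > 0L) {
      idx <- build_index(cbind(m1$nuclei$x, m1$nuclei$y), config)
      query_nearest(idx, cbind(m2$nuclei$x, m2$nuclei$y))
    } else {
      list(index = rep(NA_integer_, n2), distance = rep(Inf, n2))
    }
    run_merge_loop(m1, m2, schema, config, ml1, ml2,
                   nn_index = nn$index, nn_dist = nn$distance,
                   one_to_one = FALSE)
  } else {
    run_merge_loop(m1, m2, schema, config, ml1, ml2,
                   nn_index = NULL, nn_dist = NULL, one_to_one = TRUE)
  }
}

# Match-level node per nucleus; errors on unmapped labels.
label_match_levels <- function(set, schema) {
  labels <- set$nuclei$type
  if (!length(labels)) return(character(0))
  uniq <- unique(labels)
  nodes <- vapply(uniq, schema_node, "", model_id = set$model_id,
                  schema = schema)
  lev <- unname(schema$match_level[nodes])
  lev[match(labels, uniq)]
}

# Category node (the label's own schema node) per nucleus.
label_nodes <- function(set, schema) {
  labels <- set$nuclei$type
  if (!length(labels)) return(character(0))
  uniq <- unique(labels)
  nodes <- vapply(uniq, schema_node, "", model_id = set$model_id,
                  schema = schema)
  unname(nodes[match(labels, uniq)])
}

run_merge_loop <- function(m1, m2, schema, config, ml1, ml2,
                           nn_index, nn_dist, one_to_one) {
  D <- config$distance_threshold
  thr <- config$equivocal_prob_threshold
  nuc1 <- m1$nuclei
  nuc2 <- m2$nuclei
  n1 <- nrow(nuc1)
  n2 <- nrow(nuc2)
  node1 <- label_nodes(m1, schema)
  node2 <- label_nodes(m2, schema)

  match_m1 <- rep(FALSE, n1)
  match_m2 <- rep(FALSE, n2)

  cap <- n1 + n2
  out <- list(
    x = numeric(cap), y = numeric(cap), type = character(cap),
    prob = numeric(cap), provenance = character(cap),
    source_m1 = rep(NA_character_, cap), source_m2 = rep(NA_character_, cap),
    distance = rep(NA_real_, cap), equivocal = rep(FALSE, cap),
    contour = vector("list", cap), bbox = vector("list", cap))
  k <- 0L
  eq_rows <- list()
  n_decisions <- c(merged = 0L, conflict_m1 = 0L, conflict_m2 = 0L,
                   unmatched_m2 = 0L)

  emit <- function(row) {
    k <<- k + 1L
    out$x[k] <<- row$x; out$y[k] <<- row$y
    out$type[k] <<- row$type; out$prob[k] <<- row$prob
    out$provenance[k] <<- row$provenance
    if (!is.null(row$source_m1)) out$source_m1[k] <<- row$source_m1
    if (!is.null(row$source_m2)) out$source_m2[k] <<- row$source_m2
    if (!is.null(row$distance)) out$distance[k] <<- row$distance
    if (!is.null(row$equivocal)) out$equivocal[k] <<- row$equivocal
    out$contour[[k]] <<- row$contour
    out$bbox[[k]] <<- row$bbox
  }

  for (j in seq_len(n2)) {
    if (one_to_one) {
      alive <- which(!match_m1)
      if (length(alive)) {
        d2 <- (nuc1$x[alive] - nuc2$x[j])^2 + (nuc1$y[alive] - nuc2$y[j])^2
        pos <- which.min(d2)  # first minimum = smallest index tie-break
        i <- alive[pos]
        d <- sqrt(d2[pos])
      } else {
        i <- NA_integer_
        d <- Inf
      }
    } else {
      i <- nn_index[j]
      d <- nn_dist[j]
      # consumed-neighbor guard: first consumption wins, later hits are
      # treated as out of range
      if (!is.na(i) && match_m1[i]) {
        i <- NA_integer_
        d <- Inf
      }
    }

    if (!is.na(i) && d <= D) {
      if (identical(ml1[i], ml2[j])) {
        n1r <- nucleus_record(m1, i)
        n2r <- nucleus_record(m2, j)
        emit(c(merge_pair(n1r, n2r, schema), list(distance = d)))
        match_m1[i] <- TRUE
        match_m2[j] <- TRUE
        n_decisions["merged"] <- n_decisions["merged"] + 1L
      } else {
        keep_m2 <- nuc2$prob[j] >= nuc1$prob[i]
        equiv <- nuc1$prob[i] > thr && nuc2$prob[j] > thr
        if (keep_m2) {
          emit(list(x = nuc2$x[j], y = nuc2$y[j], type = node2[j],
                    prob = nuc2$prob[j], provenance = "conflict_m2",
                    source_m2 = nuc2$id[j], distance = d, equivocal = equiv,
                    contour = nuc2$contour[[j]], bbox = nuc2$bbox[[j]]))
          match_m2[j] <- TRUE
          n_decisions["conflict_m2"] <- n_decisions["conflict_m2"] + 1L
        } else {
          emit(list(x = nuc1$x[i], y = nuc1$y[i], type = node1[i],
                    prob = nuc1$prob[i], provenance = "conflict_m1",
                    source_m1 = nuc1$id[i], distance = d, equivocal = equiv,
                    contour = nuc1$contour[[i]], bbox = nuc1$bbox[[i]]))
          match_m1[i] <- TRUE
          n_decisions["conflict_m1"] <- n_decisions["conflict_m1"] + 1L
        }
        if (equiv) {
          w <- if (keep_m2) j else i
          eq_rows[[length(eq_rows) + 1L]] <- data.frame(
            x = if (keep_m2) nuc2$x[j] else nuc1$x[i],
            y = if (keep_m2) nuc2$y[j] else nuc1$y[i],
            label_m1 = nuc1$type[i], label_m2 = nuc2$type[j],
            prob_m1 = nuc1$prob[i], prob_m2 = nuc2$prob[j],
            winner_model = if (keep_m2) "m2" else "m1",
            winner_label = if (keep_m2) nuc2$type[j] else nuc1$type[i],
            distance = d, stringsAsFactors = FALSE)
        }
      }
    } else {
      emit(list(x = nuc2$x[j], y = nuc2$y[j], type = node2[j],
                prob = nuc2$prob[j], provenance = "unmatched_m2",
                source_m2 = nuc2$id[j],
                contour = nuc2$contour[[j]], bbox = nuc2$bbox[[j]]))
      match_m2[j] <- TRUE
      n_decisions["unmatched_m2"] <- n_decisions["unmatched_m2"] + 1L
    }
  }

  for (i in seq_len(n1)) {
    if (!match_m1[i]) {
      emit(list(x = nuc1$x[i], y = nuc1$y[i], type = node1[i],
                prob = nuc1$prob[i], provenance = "unmatched_m1",
                source_m1 = nuc1$id[i],
                contour = nuc1$contour[[i]], bbox = nuc1$bbox[[i]]))
    }
  }

  nuclei <- data.frame(
    id = as.character(seq_len(k)),
    x = out$x[seq_len(k)], y = out$y[seq_len(k)],
    type = out$type[seq_len(k)], prob = out$prob[seq_len(k)],
    provenance = out$provenance[seq_len(k)],
    source_m1 = out$source_m1[seq_len(k)],
    source_m2 = out$source_m2[seq_len(k)],
    distance = out$distance[seq_len(k)],
    equivocal = out$equivocal[seq_len(k)],
    stringsAsFactors = FALSE)
  nuclei$contour <- I(out$contour[seq_len(k)])
  nuclei$bbox <- I(out$bbox[seq_len(k)])

  equivocal <- if (length(eq_rows)) {
    do.call(rbind, eq_rows)
  } else {
    data.frame(x = numeric(0), y = numeric(0), label_m1 = character(0),
               label_m2 = character(0), prob_m1 = numeric(0),
               prob_m2 = numeric(0), winner_model = character(0),
               winner_label = character(0), distance = numeric(0),
               stringsAsFactors = FALSE)
  }

  result <- structure(
    list(nuclei = nuclei, equivocal = equivocal,
         match_m1 = match_m1, match_m2 = match_m2,
         n_m1 = n1, n_m2 = n2,
         model_m1 = m1$model_id, model_m2 = m2$model_id,
         decisions = n_decisions, config = config),
    class = "merge_result")
  assert_merge_invariants(result)
  result
}

# Bookkeeping identities checked after every run:
#   merged + conflict_m1 + conflict_m2 + unmatched_m2 = |M2|
#     (a conflict_m1 output stands for the M2 nucleus that lost to it),
#   unmatched_m1 = |M1| - distinct M1 nuclei consumed,
#   |output| <= |M1| + |M2|, and no M1 source id appears twice.
assert_merge_invariants <- function(result) {
  prov <- table(factor(result$nuclei$provenance,
                       levels = c("merged", "conflict_m1", "conflict_m2",
                                  "unmatched_m1", "unmatched_m2")))
  d <- result$decisions
  stopifnot(
    sum(d) == result$n_m2,
    prov[["merged"]] == d[["merged"]],
    prov[["conflict_m1"]] == d[["conflict_m1"]],
    prov[["conflict_m2"]] == d[["conflict_m2"]],
    prov[["unmatched_m2"]] == d[["unmatched_m2"]],
    prov[["unmatched_m1"]] == result$n_m1 - sum(result$match_m1),
    nrow(result$nuclei) <= result$n_m1 + result$n_m2,
    !anyDuplicated(stats::na.omit(result$nuclei$source_m1)),
    !anyDuplicated(stats::na.omit(result$nuclei$source_m2)))
  invisible(result)
}

#' Reference merge by exhaustive nearest-neighbor scan
#'
#' Same contract as [merge_predictions()] but every nearest neighbor is found
#' by a plain all-pairs distance scan, with no spatial index and no batched
#' queries. Serves as the independent oracle for the indexed implementation;
#' output is field-for-field identical under the exact backend.
#'
#' @inheritParams merge_predictions
#' @return A `merge_result`.
#' @export
brute_force_merge <- function(m1, m2, schema = default_type_schema(),
                              config = merge_config()) {
  validate_prediction_set(m1)
  validate_prediction_set(m2)
  ml1 <- label_match_levels(m1, schema)
  ml2 <- label_match_levels(m2, schema)
  n1 <- nrow(m1$nuclei)
  n2 <- nrow(m2$nuclei)
  one_to_one <- config$matching_strategy == "one_to_one"
  nn_index <- rep(NA_integer_, n2)
  nn_dist <- rep(Inf, n2)
  if (!one_to_one && n1 > 0L) {
    x1 <- m1$nuclei$x
    y1 <- m1$nuclei$y
    for (j in seq_len(n2)) {
      d2 <- (x1 - m2$nuclei$x[j])^2 + (y1 - m2$nuclei$y[j])^2
      i <- which.min(d2)  # first minimum = smallest index on ties
      nn_index[j] <- i
      nn_dist[j] <- sqrt(d2[i])
    }
  }
  run_merge_loop(m1, m2, schema, config, ml1, ml2,
                 nn_index = nn_index, nn_dist = nn_dist,
                 one_to_one = one_to_one)
}

#' @export
print.merge_result <- function(x, ...) {
  cat("<merge_result> ", nrow(x$nuclei), " output nuclei from |M1| = ",
      x$n_m1, " ('", x$model_m1, "') and |M2| = ", x$n_m2, " ('",
      x$model_m2, "')\n", sep = "")
  prov <- table(x$nuclei$provenance)
  cat("  ", paste(names(prov), prov, sep = "=", collapse = ", "), "\n",
      sep = "")
  if (nrow(x$equivocal)) {
    cat("  equivocal conflicts recorded: ", nrow(x$equivocal), "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.merge_result <- function(object, ...) {
  prov_levels <- c("merged", "conflict_m1", "conflict_m2",
                   "unmatched_m1", "unmatched_m2")
  tab <- table(category = object$nuclei$type,
               provenance = factor(object$nuclei$provenance,
                                   levels = prov_levels))
  out <- list(n_output = nrow(object$nuclei), n_m1 = object$n_m1,
              n_m2 = object$n_m2, by_category = tab,
              n_equivocal = nrow(object$equivocal))
  class(out) <- "summary.merge_result"
  out
}

#' @export
print.summary.merge_result <- function(x, ...) {
  cat("Merge of |M1| = ", x$n_m1, " and |M2| = ", x$n_m2, " -> ",
      x$n_output, " nuclei (", x$n_equivocal, " equivocal)\n", sep = "")
  print(x$by_category)
  invisible(x)
}
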