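#' Per-model degradation profile for the synthetic generator
#'
#' Describes how one segmentation model "sees" the ground-truth field:
#' which truth categories it can label and as what (`label_map`, `NA` for
#' categories the model cannot segment at all), per-category detection
#' probability, a label-confusion matrix over the model vocabulary, centroid
#' jitter, and the Beta distribution its prediction probabilities are drawn
#' from.
#'
#' @param model_id Model identifier (must exist in the schema when the views
#'   are merged).
#' @param label_map Named character vector: truth category -> model raw
#'   label, `NA` = undetectable.
#' @param detection Named numeric vector: truth category -> detection
#'   probability in \[0,1\]. Categories mapped to `NA` labels must have
#'   detection 0.
#' @param confusion Square row-stochastic matrix over the model's vocabulary
#'   (dimnames = labels); default identity (no label confusion).
#' @param jitter_sd Isotropic Gaussian centroid jitter, pixels. Default 1.
#' @param prob_shape1,prob_shape2 Beta parameters for prediction
#'   probabilities. Default Beta(8, 2) -- right-skewed scores typical of
#'   confident segmentation output.
#' @return A list of class `model_profile`.
#' @export
model_profile <- function(model_id, label_map, detection, confusion = NULL,
                          jitter_sd = 1, prob_shape1 = 8, prob_shape2 = 2) {
  stopifnot(is.character(model_id), length(model_id) == 1L)
  if (!all(names(label_map) %in% names(detection))) {
    stop("every mapped truth category needs a detection probability")
  }
  if (any(detection < 0 | detection > 1)) {
    stop("detection probabilities must lie in [0, 1]")
  }
  undetectable <- names(label_map)[is.na(label_map)]
  if (any(detection[undetectable] > 0)) {
    stop("categories with no label mapping must have detection probability 0")
  }
  mapped <- sort(unique(stats::na.omit(unname(label_map))))
  if (is.null(confusion)) {
    confusion <- diag(length(mapped))
    dimnames(confusion) <- list(mapped, mapped)
  }
  if (!identical(rownames(confusion), colnames(confusion))) {
    stop("confusion matrix must be square with identical row/column labels")
  }
  if (!all(mapped %in% rownames(confusion))) {
    stop("confusion matrix must cover every mapped label")
  }
  vocab <- colnames(confusion)  # confusion may widen the vocabulary
  if (any(abs(rowSums(confusion) - 1) > 1e-9)) {
    stop("confusion matrix rows must sum to 1")
  }
  structure(list(model_id = model_id, label_map = label_map,
                 detection = detection, confusion = confusion,
                 jitter_sd = jitter_sd, prob_shape1 = prob_shape1,
                 prob_shape2 = prob_shape2, vocabulary = vocab),
            class = "model_profile")
}

#' Configuration for the synthetic paired-prediction generator
#'
#' The generator emulates the asymmetries of the motivating model pair: the
#' MoNuSAC-trained model cannot segment connective or dead cells (detection
#' probability 0) but labels inflammatory subtypes; the PanNuke-trained model
#' covers every category but under-detects inflammatory cells (its training
#' data are not comprehensive for them). Default ground-truth composition is
#' a normal-prostate-like field of 2,000 nuclei: 50% epithelial (mostly
#' non-neoplastic), 43% connective, 6% inflammatory (mostly lymphocytes), 1%
#' dead.
#'
#' @param field_size Side of the square field, pixels. Default 4096 (a 4x4
#'   block of 1024-pixel tiles at 40x).
#' @param counts Named integer vector of ground-truth nuclei per (leaf)
#'   category.
#' @param min_separation Minimum pairwise center distance, pixels. Default
#'   30 -- adjacent nuclei at typical 40x nucleus size, and comfortably more
#'   than twice the merge threshold so paired detections are unambiguous.
#' @param radius Radius of the circular stand-in contours, pixels. Default 8.
#' @param profiles List of two [model_profile()]s; defaults emulate the
#'   MoNuSAC / PanNuke pair described above (detection 0.9 for covered
#'   categories, 0.25 for inflammatory under the PanNuke-like profile).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(field_size = 4096,
                             counts = c("neoplastic epithelial" = 100L,
                                        "non-neoplastic epithelial" = 900L,
                                        connective = 860L,
                                        lymphocyte = 80L,
                                        neutrophil = 20L,
                                        macrophage = 20L,
                                        dead = 20L),
                             min_separation = 30,
                             radius = 8,
                             profiles = default_profiles()) {
  stopifnot(length(profiles) == 2L,
            all(vapply(profiles, inherits, TRUE, "model_profile")))
  if (any(counts < 0) || is.null(names(counts))) {
    stop("counts must be a named vector of non-negative integers")
  }
  for (p in profiles) {
    miss <- setdiff(names(counts), names(p$label_map))
    if (length(miss)) {
      stop("profile '", p$model_id, "' has no label mapping (or NA) for: ",
           paste(miss, collapse = ", "))
    }
  }
  structure(list(field_size = field_size, counts = counts,
                 min_separation = min_separation, radius = radius,
                 profiles = profiles),
            class = "synthetic_config")
}

#' Default MoNuSAC-like and PanNuke-like degradation profiles
#' @return List of two `model_profile`s named by model id.
#' @export
default_profiles <- function() {
  truth_cats <- c("neoplastic epithelial", "non-neoplastic epithelial",
                  "connective", "lymphocyte", "neutrophil", "macrophage",
                  "dead")
  monusac_map <- c("neoplastic epithelial" = "epithelial",
                   "non-neoplastic epithelial" = "epithelial",
                   connective = NA_character_,
                   lymphocyte = "lymphocyte",
                   neutrophil = "neutrophil",
                   macrophage = "macrophage",
                   dead = NA_character_)
  monusac_det <- c("neoplastic epithelial" = 0.9,
                   "non-neoplastic epithelial" = 0.9,
                   connective = 0, lymphocyte = 0.9, neutrophil = 0.9,
                   macrophage = 0.9, dead = 0)
  pannuke_map <- c("neoplastic epithelial" = "neoplastic epithelial",
                   "non-neoplastic epithelial" = "non-neoplastic epithelial",
                   connective = "connective",
                   lymphocyte = "inflammatory",
                   neutrophil = "inflammatory",
                   macrophage = "inflammatory",
                   dead = "dead")
  pannuke_det <- c("neoplastic epithelial" = 0.9,
                   "non-neoplastic epithelial" = 0.9,
                   connective = 0.9, lymphocyte = 0.25, neutrophil = 0.25,
                   macrophage = 0.25, dead = 0.9)
  stopifnot(setequal(names(monusac_map), truth_cats))
  list(monusac = model_profile("monusac", monusac_map, monusac_det),
       pannuke = model_profile("pannuke", pannuke_map, pannuke_det))
}

#' Generate a ground-truth nucleus field
#'
#' Places the configured number of nuclei per category uniformly at random
#' in the square field, subject to the minimum pairwise center separation
#' (dart-throwing rejection sampling, bounded attempts). Deterministic given
#' the seed; category counts are exact.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return A data frame of class `truth_field` with columns `id`, `x`, `y`,
#'   `category`; the contour radius is carried as an attribute.
#' @export
generate_truth <- function(config, seed = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)
  n <- sum(config$counts)
  fs <- config$field_size
  sep2 <- config$min_separation^2
  xs <- numeric(n)
  ys <- numeric(n)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 1000L * max(n, 1L)
  while (placed < n) {
    if (attempts >= max_attempts) {
      stop("could not place ", n, " nuclei with separation ",
           config$min_separation, " in a ", fs, "-pixel field (",
           attempts, " attempts); loosen the packing")
    }
    attempts <- attempts + 1L
    cx <- stats::runif(1, 0, fs)
    cy <- stats::runif(1, 0, fs)
    if (placed == 0L ||
        min((xs[seq_len(placed)] - cx)^2 + (ys[seq_len(placed)] - cy)^2) >= sep2) {
      placed <- placed + 1L
      xs[placed] <- cx
      ys[placed] <- cy
    }
  }
  category <- sample(rep(names(config$counts), times = config$counts))
  out <- data.frame(id = paste0("t", seq_len(n)), x = xs, y = ys,
                    category = category, stringsAsFactors = FALSE)
  structure(out, radius = config$radius, field_size = fs,
            class = c("truth_field", "data.frame"))
}

#' Degrade a truth field into one model's prediction set
#'
#' Each truth nucleus is independently detected with its category's
#' detection probability; detected nuclei receive a jittered centroid, a
#' label drawn from the confusion matrix row of their mapped label, a
#' probability score from the profile's Beta distribution, and a circular
#' contour at the jittered center. Ids reference the originating truth
#' nucleus.
#'
#' @param truth A `truth_field`.
#' @param profile A [model_profile()].
#' @param seed Integer seed.
#' @return A [prediction_set()] in the model's vocabulary.
#' @export
degrade_to_model_view <- function(truth, profile, seed = 1L) {
  stopifnot(inherits(truth, "truth_field"), inherits(profile, "model_profile"))
  set.seed(seed)
  det_p <- profile$detection[truth$category]
  detected <- stats::runif(nrow(truth)) < det_p
  idx <- which(detected)
  n <- length(idx)
  if (n == 0L) {
    return(prediction_set(profile$model_id, empty_nuclei_df(),
                          vocabulary = profile$vocabulary))
  }
  x <- truth$x[idx] + stats::rnorm(n, 0, profile$jitter_sd)
  y <- truth$y[idx] + stats::rnorm(n, 0, profile$jitter_sd)
  true_label <- unname(profile$label_map[truth$category[idx]])
  cols <- colnames(profile$confusion)
  label <- vapply(true_label, function(lb) {
    p <- profile$confusion[lb, ]
    if (max(p) == 1) cols[which.max(p)]  # deterministic row: no draw needed
    else sample(cols, 1L, prob = p)
  }, "", USE.NAMES = FALSE)
  prob <- stats::rbeta(n, profile$prob_shape1, profile$prob_shape2)
  radius <- attr(truth, "radius")
  ang <- seq(0, 2 * pi, length.out = 13L)[-13L]
  contour <- lapply(seq_len(n), function(i) {
    cbind(x[i] + radius * cos(ang), y[i] + radius * sin(ang))
  })
  bbox <- lapply(seq_len(n), function(i) {
    rbind(c(x[i] - radius, y[i] - radius), c(x[i] + radius, y[i] + radius))
  })
  nuclei <- data.frame(id = truth$id[idx], x = x, y = y, type = label,
                       prob = prob, stringsAsFactors = FALSE)
  nuclei$contour <- I(contour)
  nuclei$bbox <- I(bbox)
  prediction_set(profile$model_id, nuclei, vocabulary = profile$vocabulary)
}

#' Generate a paired synthetic instance with expected merge statistics
#'
#' Draws a truth field and both model views, and computes by construction
#' the statistics the merge should exhibit: which truth nuclei were detected
#' by both models, how many of those carry match-level-concordant labels
#' (the expected merged count when jitter is much smaller than the distance
#' threshold), how many conflict, and how many are single-model detections.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed; the truth field and the two views use
#'   `seed`, `seed + 1`, `seed + 2` respectively.
#' @param schema `type_schema` used to evaluate label concordance of paired
#'   detections; defaults to [default_type_schema()].
#' @return List with `truth`, `m1`, `m2` (prediction sets) and
#'   `expected` (named numeric vector of by-construction statistics).
#' @export
generate_pair <- function(config, seed = 1L, schema = default_type_schema()) {
  truth <- generate_truth(config, seed)
  m1 <- degrade_to_model_view(truth, config$profiles[[1]], seed + 1L)
  m2 <- degrade_to_model_view(truth, config$profiles[[2]], seed + 2L)
  det1 <- truth$id %in% m1$nuclei$id
  det2 <- truth$id %in% m2$nuclei$id
  both <- which(det1 & det2)
  lab1 <- m1$nuclei$type[match(truth$id[both], m1$nuclei$id)]
  lab2 <- m2$nuclei$type[match(truth$id[both], m2$nuclei$id)]
  concordant <- mapply(function(a, b) {
    types_match(a, m1$model_id, b, m2$model_id, schema)
  }, lab1, lab2, USE.NAMES = FALSE)
  if (!length(both)) concordant <- logical(0)
  expected <- c(n_truth = nrow(truth),
                n_m1 = nrow(m1$nuclei),
                n_m2 = nrow(m2$nuclei),
                n_both_detected = length(both),
                n_expected_merged = sum(concordant),
                n_expected_conflicts = sum(!concordant),
                n_only_m1 = sum(det1 & !det2),
                n_only_m2 = sum(det2 & !det1))
  list(truth = truth, m1 = m1, m2 = m2, expected = expected)
}

#' Proportion table of a truth field
#'
#' Category counts/proportions of the ground truth, directly comparable to
#' [compute_proportions()] output on a merge of the degraded views.
#'
#' @param truth A `truth_field`.
#' @param schema `type_schema` providing the category universe.
#' @return A `proportion_table`.
#' @export
truth_proportions <- function(truth, schema = default_type_schema()) {
  compute_proportions(data.frame(type = truth$category,
                                 stringsAsFactors = FALSE), schema)
}
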