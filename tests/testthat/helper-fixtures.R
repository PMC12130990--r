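# Fixture builders shared across test files. All randomness uses the
# caller's RNG stream; tests wrap calls in set.seed() for reproducibility.

monusac_labels <- c("epithelial", "lymphocyte", "neutrophil", "macrophage")
pannuke_labels <- c("neoplastic epithelial", "non-neoplastic epithelial",
                    "connective", "inflammatory", "dead")

# A prediction set of n nuclei with uniform centroids and random labels from
# the model's vocabulary. Labels are weighted toward epithelial-like types so
# same-type matches actually occur.
random_prediction_set <- function(model_id, n, field = 500,
                                  labels = switch(model_id,
                                                  monusac = monusac_labels,
                                                  pannuke = pannuke_labels),
                                  weights = NULL) {
  if (n == 0L) {
    return(prediction_set(model_id,
                          data.frame(id = character(0), x = numeric(0),
                                     y = numeric(0), type = character(0),
                                     prob = numeric(0)),
                          vocabulary = labels))
  }
  if (is.null(weights)) weights <- rep(1, length(labels))
  df <- data.frame(
    id = paste0(substr(model_id, 1, 1), seq_len(n)),
    x = stats::runif(n, 0, field),
    y = stats::runif(n, 0, field),
    type = sample(labels, n, replace = TRUE, prob = weights),
    prob = stats::runif(n),
    stringsAsFactors = FALSE)
  prediction_set(model_id, df, vocabulary = labels)
}

# Minimal one-or-more-nucleus set from parallel vectors.
mk_set <- function(model_id, id, x, y, type, prob, vocabulary = NULL) {
  prediction_set(model_id,
                 data.frame(id = id, x = x, y = y, type = type, prob = prob,
                            stringsAsFactors = FALSE),
                 vocabulary = vocabulary)
}

empty_set <- function(model_id, vocabulary = NULL) {
  prediction_set(model_id,
                 data.frame(id = character(0), x = numeric(0),
                            y = numeric(0), type = character(0),
                            prob = numeric(0)),
                 vocabulary = vocabulary)
}

# Strip class/attrs so expect_equal compares content only.
nuclei_fields <- function(set) {
  df <- set$nuclei
  df$contour <- lapply(df$contour, unclass)
  df$bbox <- lapply(df$bbox, unclass)
  df
}

expect_same_merge <- function(a, b) {
  expect_equal(a$nuclei$provenance, b$nuclei$provenance)
  expect_equal(a$nuclei$x, b$nuclei$x)
  expect_equal(a$nuclei$y, b$nuclei$y)
  expect_equal(a$nuclei$type, b$nuclei$type)
  expect_equal(a$nuclei$prob, b$nuclei$prob)
  expect_equal(a$nuclei$source_m1, b$nuclei$source_m1)
  expect_equal(a$nuclei$source_m2, b$nuclei$source_m2)
  expect_equal(a$nuclei$distance, b$nuclei$distance)
  expect_equal(a$nuclei$equivocal, b$nuclei$equivocal)
  expect_equal(a$equivocal, b$equivocal)
  expect_equal(a$match_m1, b$match_m1)
  expect_equal(a$match_m2, b$match_m2)
}
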