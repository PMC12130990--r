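schema <- default_type_schema()

test_that("merge_pair applies midpoint / max-prob / M2-geometry rules", {
  m1 <- mk_set("monusac", "a1", 10, 10, "epithelial", 0.6)
  m2 <- mk_set("pannuke", "b1", 12, 10, "non-neoplastic epithelial", 0.9)
  n1 <- nucleus_record(m1, 1)
  n2 <- nucleus_record(m2, 1)
  merged <- merge_pair(n1, n2, schema)
  expect_equal(c(merged$x, merged$y), c(11, 10))
  expect_equal(merged$prob, 0.9)
  expect_equal(merged$type, "non-neoplastic epithelial")
  expect_identical(merged$contour, n2$contour)
  expect_identical(merged$bbox, n2$bbox)
  expect_equal(merged$provenance, "merged")

  # idempotent case: identical nuclei
  ma <- mk_set("pannuke", "p1", 5, 5, "connective", 0.5)
  mb <- mk_set("pannuke", "p2", 5, 5, "connective", 0.5)
  same <- merge_pair(nucleus_record(ma, 1), nucleus_record(mb, 1), schema)
  expect_equal(c(same$x, same$y, same$prob), c(5, 5, 0.5))

  # max rule
  hi <- merge_pair(nucleus_record(mk_set("monusac", "a", 0, 0, "epithelial", 0.99), 1),
                   nucleus_record(mk_set("pannuke", "b", 0, 0, "neoplastic epithelial", 0.10), 1),
                   schema)
  expect_equal(hi$prob, 0.99)

  expect_error(merge_pair(nucleus_record(mk_set("monusac", "a", 0, 0, "macrophage", 0.5), 1),
                          nucleus_record(mk_set("pannuke", "b", 0, 0, "connective", 0.5), 1),
                          schema),
               "resolve_conflict")
})

test_that("resolve_conflict keeps the higher probability, M2 on ties", {
  mk1 <- function(p) nucleus_record(mk_set("monusac", "a", 0, 0, "lymphocyte", p), 1)
  mk2 <- function(p) nucleus_record(mk_set("pannuke", "b", 1, 0, "connective", p), 1)

  r <- resolve_conflict(mk1(0.8), mk2(0.8))
  expect_equal(r$winner_model, "m2")
  expect_true(r$equivocal)  # both strictly above 0.75

  r <- resolve_conflict(mk1(0.9), mk2(0.5))
  expect_equal(r$winner_model, "m1")
  expect_false(r$equivocal)

  # strict threshold: 0.75 itself is not "high probability"
  r <- resolve_conflict(mk1(0.75), mk2(0.76))
  expect_equal(r$winner_model, "m2")
  expect_false(r$equivocal)
})

test_that("empty inputs are retained wholesale", {
  m1 <- random_prediction_set("monusac", 5)
  e2 <- empty_set("pannuke", pannuke_labels)
  r <- merge_predictions(m1, e2, schema)
  expect_equal(r$nuclei$provenance, rep("unmatched_m1", 5))
  expect_equal(sort(r$nuclei$source_m1), sort(m1$nuclei$id))

  e1 <- empty_set("monusac", monusac_labels)
  m2 <- random_prediction_set("pannuke", 4)
  r <- merge_predictions(e1, m2, schema)
  expect_equal(r$nuclei$provenance, rep("unmatched_m2", 4))
})

test_that("the distance threshold is inclusive at exactly D", {
  m1 <- mk_set("monusac", "a1", 0, 0, "epithelial", 0.6)
  m2 <- mk_set("pannuke", "b1", 6, 8, "non-neoplastic epithelial", 0.9)
  r <- merge_predictions(m1, m2, schema)  # d = 10.0 = D
  expect_equal(nrow(r$nuclei), 1L)
  expect_equal(r$nuclei$provenance, "merged")
  expect_equal(c(r$nuclei$x, r$nuclei$y), c(3, 4))

  just_past <- mk_set("pannuke", "b1", 6 + 1e-9, 8,
                      "non-neoplastic epithelial", 0.9)
  r2 <- merge_predictions(m1, just_past, schema)
  expect_equal(sort(r2$nuclei$provenance), c("unmatched_m1", "unmatched_m2"))
})

test_that("the consumed-neighbor guard never duplicates an M1 nucleus", {
  # two M2 nuclei whose nearest M1 neighbor is the same nucleus
  m1 <- mk_set("monusac", "a1", 0, 0, "epithelial", 0.6)
  m2 <- mk_set("pannuke", c("b1", "b2"), c(1, -1), c(0, 0),
               c("non-neoplastic epithelial", "neoplastic epithelial"),
               c(0.9, 0.8))
  r <- merge_predictions(m1, m2, schema)
  expect_equal(sum(r$nuclei$source_m1 == "a1", na.rm = TRUE), 1L)
  expect_equal(sort(r$nuclei$provenance), c("merged", "unmatched_m2"))
  # first consumption wins: b1 merged, b2 handled as out of range
  expect_equal(r$nuclei$source_m2[r$nuclei$provenance == "merged"], "b1")
})

test_that("one_to_one re-queries the nearest unconsumed neighbor", {
  m1 <- mk_set("monusac", c("a1", "a2"), c(0, 3), c(0, 0),
               c("epithelial", "epithelial"), c(0.6, 0.6))
  m2 <- mk_set("pannuke", c("b1", "b2"), c(1, -1), c(0, 0),
               c("non-neoplastic epithelial", "neoplastic epithelial"),
               c(0.9, 0.8))
  r <- merge_predictions(m1, m2, schema,
                         merge_config(matching_strategy = "one_to_one"))
  expect_equal(sum(r$nuclei$provenance == "merged"), 2L)
  merged <- r$nuclei[r$nuclei$provenance == "merged", ]
  expect_setequal(merged$source_m1, c("a1", "a2"))
  # b1 takes a1 (d=1); b2's nearest unconsumed is then a2 (d=4)
  expect_equal(merged$source_m1[merged$source_m2 == "b2"], "a2")
})

test_that("conflict outputs and equivocal records flow through a merge", {
  m1 <- mk_set("monusac", c("a1", "a2"), c(0, 100), c(0, 0),
               c("lymphocyte", "macrophage"), c(0.8, 0.9))
  m2 <- mk_set("pannuke", c("b1", "b2"), c(1, 101), c(0, 0),
               c("connective", "connective"), c(0.8, 0.5))
  r <- merge_predictions(m1, m2, schema)
  # pair 1: tie 0.8/0.8 -> M2 wins, equivocal; pair 2: M1 wins, not equivocal
  expect_equal(sort(r$nuclei$provenance),
               c("conflict_m1", "conflict_m2", "unmatched_m1"))
  expect_equal(nrow(r$equivocal), 1L)
  expect_equal(r$equivocal$winner_model, "m2")
  expect_equal(r$equivocal$label_m1, "lymphocyte")
  expect_equal(r$equivocal$label_m2, "connective")
  conf2 <- r$nuclei[r$nuclei$provenance == "conflict_m2", ]
  expect_true(conf2$equivocal)
  # the losing M1 of pair 1 is retained later as unmatched_m1
  expect_equal(r$nuclei$source_m1[r$nuclei$provenance == "unmatched_m1"], "a1")
})

test_that("indexed merge equals the brute-force oracle on random instances", {
  set.seed(303)
  for (rep in 1:25) {
    n1 <- sample(0:120, 1)
    n2 <- sample(0:120, 1)
    m1 <- random_prediction_set("monusac", n1, field = 150)
    m2 <- random_prediction_set("pannuke", n2, field = 150)
    for (strategy in c("literal", "one_to_one")) {
      cfg <- merge_config(matching_strategy = strategy)
      expect_same_merge(merge_predictions(m1, m2, schema, cfg),
                        brute_force_merge(m1, m2, schema, cfg))
    }
  }
})

test_that("size bound and conservation identities hold on random instances", {
  set.seed(404)
  for (rep in 1:20) {
    m1 <- random_prediction_set("monusac", sample(0:150, 1), field = 120)
    m2 <- random_prediction_set("pannuke", sample(0:150, 1), field = 120)
    r <- merge_predictions(m1, m2, schema)
    prov <- table(factor(r$nuclei$provenance,
                         levels = c("merged", "conflict_m1", "conflict_m2",
                                    "unmatched_m1", "unmatched_m2")))
    expect_lte(nrow(r$nuclei), r$n_m1 + r$n_m2)
    expect_equal(prov[["merged"]] + prov[["conflict_m1"]] +
                 prov[["conflict_m2"]] + prov[["unmatched_m2"]], r$n_m2)
    expect_equal(prov[["unmatched_m1"]], r$n_m1 - sum(r$match_m1))
    expect_false(any(duplicated(na.omit(r$nuclei$source_m1))))
    expect_false(any(duplicated(na.omit(r$nuclei$source_m2))))
  }
})

test_that("exact-backend merges are reproducible run to run", {
  set.seed(505)
  m1 <- random_prediction_set("monusac", 80, field = 100)
  m2 <- random_prediction_set("pannuke", 80, field = 100)
  r1 <- merge_predictions(m1, m2, schema)
  r2 <- merge_predictions(m1, m2, schema)
  expect_identical(r1$nuclei, r2$nuclei)
})

test_that("merged pairs grow monotonically with D when neighbors are uncontended", {
  # widely separated truth nuclei give each detection a unique plausible
  # partner, so raising D can only add pairs; under heavy contention the
  # greedy consumption order can swap partners, hence the spacing here
  cfg_syn <- synthetic_config(field_size = 2500,
                              counts = c("non-neoplastic epithelial" = 120L,
                                         connective = 100L, lymphocyte = 30L),
                              min_separation = 40)
  pair <- generate_pair(cfg_syn, seed = 77)
  pair_keys <- function(D) {
    cfg <- merge_config(distance_threshold = D,
                        matching_strategy = "one_to_one")
    r <- merge_predictions(pair$m1, pair$m2, schema, cfg)
    merged <- r$nuclei[r$nuclei$provenance == "merged", ]
    paste(merged$source_m1, merged$source_m2)
  }
  small <- pair_keys(1)
  big <- pair_keys(10)
  expect_gt(length(small), 0L)
  expect_gt(length(big), length(small))
  expect_true(all(small %in% big))
})

test_that("coincident centroids within one set are legal", {
  m1 <- mk_set("monusac", c("a1", "a2"), c(0, 0), c(0, 0),
               c("epithelial", "epithelial"), c(0.5, 0.7))
  m2 <- mk_set("pannuke", "b1", 0, 0, "non-neoplastic epithelial", 0.9)
  r <- merge_predictions(m1, m2, schema)
  expect_equal(sort(r$nuclei$provenance), c("merged", "unmatched_m1"))
  expect_equal(r$nuclei$source_m1[r$nuclei$provenance == "merged"], "a1")
})

test_that("a non-positive distance threshold is a config error", {
  expect_error(merge_config(distance_threshold = 0), "positive")
  expect_error(merge_config(distance_threshold = -3), "positive")
  expect_error(merge_config(equivocal_prob_threshold = 1), "0, 1")
})
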