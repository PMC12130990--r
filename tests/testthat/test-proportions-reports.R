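schema <- default_type_schema()

test_that("proportions follow count(t)/total and include zero categories", {
  types <- c(rep("epithelial", 50), rep("connective", 43),
             rep("inflammatory", 7))
  tab <- compute_proportions(data.frame(type = types), schema)
  expect_equal(attr(tab, "total"), 100L)
  expect_equal(tab$proportion[tab$category == "epithelial"], 0.50)
  expect_equal(tab$proportion[tab$category == "connective"], 0.43)
  expect_equal(tab$proportion[tab$category == "inflammatory"], 0.07)
  expect_equal(tab$proportion[tab$category == "dead"], 0)
  expect_true(all(schema_categories(schema) %in% tab$category))

  single <- compute_proportions(data.frame(type = "lymphocyte"), schema)
  expect_equal(single$proportion[single$category == "lymphocyte"], 1.0)
})

test_that("empty results give total 0 with flagged-undefined proportions", {
  r <- merge_predictions(empty_set("monusac", monusac_labels),
                         empty_set("pannuke", pannuke_labels), schema)
  tab <- compute_proportions(r, schema)
  expect_equal(attr(tab, "total"), 0L)
  expect_true(attr(tab, "undefined"))
  expect_true(all(is.na(tab$proportion)))
})

test_that("proportions sum to 1 and match independent recounts", {
  set.seed(71)
  for (rep in 1:10) {
    m1 <- random_prediction_set("monusac", sample(10:150, 1), field = 120)
    m2 <- random_prediction_set("pannuke", sample(10:150, 1), field = 120)
    r <- merge_predictions(m1, m2, schema)
    tab <- compute_proportions(r, schema)
    expect_equal(sum(tab$proportion), 1, tolerance = 1e-9)
    recount <- table(r$nuclei$type)
    for (cat in names(recount)) {
      expect_equal(tab$count[tab$category == cat], unname(recount[cat]))
      expect_equal(tab$proportion[tab$category == cat],
                   unname(recount[cat]) / nrow(r$nuclei))
    }
  }
})

test_that("merge report details and summary agree with the result", {
  set.seed(72)
  m1 <- random_prediction_set("monusac", 60, field = 80)
  m2 <- random_prediction_set("pannuke", 60, field = 80)
  r <- merge_predictions(m1, m2, schema)
  path <- withr::local_tempfile(fileext = ".csv")
  man <- write_merge_report(r, path)
  detail <- read.csv(path, stringsAsFactors = FALSE)
  expect_equal(nrow(detail), nrow(r$nuclei))
  smry <- read.csv(man$summary, stringsAsFactors = FALSE)
  # summary counts equal recounts from detail rows
  for (i in seq_len(nrow(smry))) {
    sub <- detail[detail$category == smry$category[i], ]
    expect_equal(smry$merged[i], sum(sub$provenance == "merged"))
    expect_equal(smry$unmatched_m1[i], sum(sub$provenance == "unmatched_m1"))
    expect_equal(smry$unmatched_m2[i], sum(sub$provenance == "unmatched_m2"))
    expect_equal(smry$total[i], nrow(sub))
  }

  # empty result -> header-only detail
  er <- merge_predictions(empty_set("monusac", monusac_labels),
                          empty_set("pannuke", pannuke_labels), schema)
  epath <- withr::local_tempfile(fileext = ".csv")
  write_merge_report(er, epath)
  expect_equal(nrow(read.csv(epath)), 0L)

  # 1 merged + 1 unmatched_m1 bookkeeping
  sm1 <- mk_set("monusac", c("a1", "a2"), c(0, 50), c(0, 0),
                c("epithelial", "epithelial"), c(0.6, 0.7))
  sm2 <- mk_set("pannuke", "b1", 1, 0, "non-neoplastic epithelial", 0.9)
  rr <- merge_predictions(sm1, sm2, schema)
  ppath <- withr::local_tempfile(fileext = ".csv")
  mman <- write_merge_report(rr, ppath)
  det <- read.csv(ppath, stringsAsFactors = FALSE)
  expect_equal(nrow(det), 2L)
  sm <- read.csv(mman$summary, stringsAsFactors = FALSE)
  expect_equal(sm$merged[sm$category == "non-neoplastic epithelial"], 1L)
})

test_that("equivocal report rows are exactly the strict-threshold conflicts", {
  m1 <- mk_set("monusac", c("a1", "a2"), c(0, 50), c(0, 0),
               c("lymphocyte", "lymphocyte"), c(0.8, 0.8))
  m2 <- mk_set("pannuke", c("b1", "b2"), c(1, 51), c(0, 0),
               c("connective", "connective"), c(0.9, 0.7))
  r <- merge_predictions(m1, m2, schema)
  path <- withr::local_tempfile(fileext = ".csv")
  man <- write_equivocal_report(r, path)
  rows <- read.csv(path, stringsAsFactors = FALSE)
  expect_equal(nrow(rows), 1L)  # (0.8, 0.9) yes; (0.8, 0.7) no
  expect_equal(rows$prob_m1, 0.8)
  expect_equal(rows$prob_m2, 0.9)
  expect_equal(rows$label_m1, "lymphocyte")
  expect_equal(rows$label_m2, "connective")

  # no equivocal records -> header-only file
  r2 <- merge_predictions(mk_set("monusac", "a1", 0, 0, "epithelial", 0.9),
                          mk_set("pannuke", "b1", 1, 0,
                                 "non-neoplastic epithelial", 0.9), schema)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_equivocal_report(r2, p2)
  expect_equal(nrow(read.csv(p2)), 0L)
})

test_that("equivocal rows always have both probabilities strictly above 0.75", {
  set.seed(73)
  for (rep in 1:5) {
    m1 <- random_prediction_set("monusac", 100, field = 60)
    m2 <- random_prediction_set("pannuke", 100, field = 60)
    r <- merge_predictions(m1, m2, schema)
    if (nrow(r$equivocal)) {
      expect_true(all(r$equivocal$prob_m1 > 0.75))
      expect_true(all(r$equivocal$prob_m2 > 0.75))
    }
    # and every recorded conflict with both probs > 0.75 is in the report
    conf <- r$nuclei$provenance %in% c("conflict_m1", "conflict_m2")
    expect_equal(sum(r$nuclei$equivocal[conf]), nrow(r$equivocal))
  }
})

test_that("proportions CSV round-trips, supports percent, handles empty", {
  types <- c(rep("epithelial", 1), rep("connective", 1))
  tab <- compute_proportions(data.frame(type = types), schema)
  path <- withr::local_tempfile(fileext = ".csv")
  write_proportions_csv(tab, path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  expect_equal(raw$proportion[raw$category == "epithelial"], 0.5)
  back <- read_proportions_csv(path)
  expect_equal(back$count, tab$count)
  expect_equal(back$proportion, tab$proportion, tolerance = 1e-8)
  expect_equal(attr(back, "total"), attr(tab, "total"))

  ppath <- withr::local_tempfile(fileext = ".csv")
  write_proportions_csv(tab, ppath, percent = TRUE)
  praw <- read.csv(ppath, stringsAsFactors = FALSE)
  expect_equal(praw$proportion[praw$category == "connective"], 50)

  etab <- compute_proportions(data.frame(type = character(0)), schema)
  epath <- withr::local_tempfile(fileext = ".csv")
  write_proportions_csv(etab, epath)
  eraw <- read.csv(epath, stringsAsFactors = FALSE)
  expect_equal(eraw$count[eraw$category == "TOTAL"], 0L)
})

test_that("aggregation to match level and TV distance behave", {
  tab <- compute_proportions(
    data.frame(type = c(rep("lymphocyte", 2), rep("neutrophil", 1),
                        rep("non-neoplastic epithelial", 5),
                        rep("connective", 2))), schema)
  agg <- aggregate_proportions(tab, schema)
  expect_equal(agg$count[agg$category == "inflammatory"], 3L)
  expect_equal(agg$count[agg$category == "epithelial"], 5L)
  expect_equal(sum(agg$proportion), 1)
  expect_equal(tv_distance(agg, agg), 0)
  other <- agg
  expect_gte(tv_distance(agg, aggregate_proportions(
    compute_proportions(data.frame(type = rep("dead", 4)), schema), schema)),
    0.5)
})
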