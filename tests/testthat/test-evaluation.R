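test_that("stratified 7:3 split of balanced data gives 7/7/7 and 3/3/3", {
  ds <- generate_dataset(synthetic_config(
    profiles = default_profiles("balanced"), seed = 1))
  sp <- split_calibration_validation(ds, 0.7, seed = 5)
  expect_equal(as.integer(table(sp$calibration$labels)), rep(7L, 3))
  expect_equal(as.integer(table(sp$validation$labels)), rep(3L, 3))
})

test_that("splits are disjoint, exhaustive, stratified and seed-deterministic", {
  ds <- generate_dataset(synthetic_config(seed = 2))   # 14/5/11
  sp1 <- split_calibration_validation(ds, 0.7, seed = 9)
  sp2 <- split_calibration_validation(ds, 0.7, seed = 9)
  sp3 <- split_calibration_validation(ds, 0.7, seed = 10)
  expect_identical(sp1$membership, sp2$membership)
  expect_false(identical(sp1$membership, sp3$membership))
  ids <- c(sp1$calibration$sample_ids, sp1$validation$sample_ids)
  expect_setequal(ids, ds$sample_ids)
  expect_length(intersect(sp1$calibration$sample_ids,
                          sp1$validation$sample_ids), 0)
  expect_equal(n_samples(sp1$calibration), 21)  # round-half-up(0.7 * 30)
  # largest-remainder allocation for 14/5/11 at 0.7 -> 10/3/8
  expect_equal(as.integer(table(sp1$calibration$labels)), c(10L, 3L, 8L))
  expect_error(split_calibration_validation(ds, 0.7, seed = NULL),
               "seed is mandatory")
  expect_error(split_calibration_validation(ds, 1.2, seed = 1),
               "calibration_fraction")
  tiny <- subset_samples(ds, c(1, 2, 15, 20, 21))   # one mild sample only
  expect_error(split_calibration_validation(tiny, 0.7, seed = 1),
               "too small to stratify")
})

test_that("confusion matrices use predicted rows and actual columns", {
  cm <- confusion_matrix(class_levels(), class_levels())
  expect_equal(unname(diag(cm)), rep(1L, 3))
  expect_equal(sum(cm), 3)

  cm2 <- confusion_matrix(actual = rep("severe", 3), predicted = rep("mild", 3))
  expect_equal(cm2["mild", "severe"], 3L, ignore_attr = TRUE)
  expect_equal(sum(cm2), 3)

  # the study's univariate description: 9 normals correct, 6 severe as mild
  actual <- c(rep("normal", 9), rep("severe", 6))
  predicted <- c(rep("normal", 9), rep("mild", 6))
  cm3 <- confusion_matrix(actual, predicted)
  expect_equal(cm3["normal", "normal"], 9L, ignore_attr = TRUE)
  expect_equal(cm3["mild", "severe"], 6L, ignore_attr = TRUE)

  expect_error(confusion_matrix("normal", c("mild", "severe")),
               "differ in length")
})

test_that("one-vs-rest truth table matches hand-computed counts and conserves totals", {
  cal_none <- rbind(c(7, 1, 0), c(0, 2, 1), c(0, 4, 6))
  tt <- truth_table(cal_none)
  normal <- tt[tt$class == "normal", ]
  expect_equal(unlist(normal[c("TP", "FP", "FN", "TN")], use.names = FALSE),
               c(7L, 1L, 0L, 13L))
  expect_true(all(tt$TP + tt$FP + tt$TN + tt$FN == sum(cal_none)))

  ident <- truth_table(diag(c(3, 3, 3)))
  expect_equal(ident$TP, rep(3L, 3))
  expect_equal(ident$FP, rep(0L, 3))
  expect_equal(ident$FN, rep(0L, 3))
  expect_equal(ident$TN, rep(6L, 3))
})

test_that("truth table and metrics agree with per-sample brute force", {
  set.seed(6)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    actual <- sample(class_levels(), n, replace = TRUE)
    predicted <- sample(class_levels(), n, replace = TRUE)
    tt <- truth_table(confusion_matrix(actual, predicted))
    bf <- brute_force_truth_table(actual, predicted)
    expect_equal(tt$TP, bf$TP); expect_equal(tt$FP, bf$FP)
    expect_equal(tt$TN, bf$TN); expect_equal(tt$FN, bf$FN)
    m <- class_metrics(tt)
    expect_equal(m$micro_accuracy, mean(actual == predicted))
    with(bf, {
      expect_equal(m$per_class$accuracy, (TP + TN) / n)
      ok <- TP + FN > 0
      expect_equal(m$per_class$sensitivity[ok], (TP / (TP + FN))[ok])
    })
  }
})

test_that("degenerate ratios follow the stated conventions and are flagged", {
  # a class never predicted and absent: precision 0/0 -> 1.0
  cm <- rbind(c(3, 0, 3), c(0, 3, 0), c(0, 0, 0))  # snv validation table
  m <- class_metrics(truth_table(cm))
  expect_equal(m$per_class$precision[3], 1.0)
  expect_match(paste(m$flags, collapse = " "), "precision 0/0.*severe")
  # sensitivity 0/0 (no actual samples of a class) -> NA, flagged
  cm2 <- rbind(c(2, 0, 0), c(1, 0, 0), c(0, 0, 1))
  m2 <- class_metrics(truth_table(cm2))
  expect_true(is.na(m2$per_class$sensitivity[2]))
  expect_match(paste(m2$flags, collapse = " "), "sensitivity 0/0.*mild")
  # perfect table: everything 1
  mp <- class_metrics(truth_table(diag(c(4, 4, 4))))
  expect_equal(unlist(mp$per_class[-1], use.names = FALSE), rep(1, 12))
  expect_equal(mp$macro_accuracy, 1)
  expect_equal(mp$micro_accuracy, 1)
})

test_that("macro accuracy is the mean of per-class accuracies", {
  set.seed(13)
  actual <- sample(class_levels(), 30, replace = TRUE)
  predicted <- sample(class_levels(), 30, replace = TRUE)
  m <- class_metrics(confusion_matrix(actual, predicted))
  expect_equal(m$macro_accuracy, mean(m$per_class$accuracy))
})

test_that("reports round half-to-even and keep both tables", {
  res <- list(
    univariate = list(calibration = evaluate_predictions(
      c("normal", "mild", "mild", "severe"),
      c("normal", "mild", "severe", "severe"))))
  rep_ <- render_report(res)
  expect_named(rep_, c("confusions", "metrics"))
  expect_equal(nrow(rep_$confusions), 9)
  expect_equal(nrow(rep_$metrics), 3)
  expect_equal(round(0.7142857, 2), 0.71)
  expect_equal(round(0.625, 2), 0.62)   # half to even
  # written artifacts
  dir <- withr::local_tempdir()
  render_report(res, dir = dir)
  expect_setequal(list.files(dir),
                  c("confusions.csv", "metrics.csv", "report.json"))
  raw <- jsonlite::read_json(file.path(dir, "report.json"), simplifyVector = TRUE)
  expect_equal(raw$univariate$calibration$macro_accuracy,
               res$univariate$calibration$metrics$macro_accuracy)
})

test_that("truth_table_from_counts validates conservation", {
  tt <- truth_table_from_counts(c(9, 10, 4), c(1, 6, 0), c(20, 13, 20),
                                c(0, 1, 6))
  expect_s3_class(tt, "truth_table")
  expect_error(truth_table_from_counts(c(9, 10, 4), c(1, 6, 0), c(20, 13, 20),
                                       c(0, 1, 7)), "equal across classes")
})
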