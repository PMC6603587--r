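# Confusion-cell fixtures of the published evaluation: c(tp, fp, fn,
# tn, positive_total, negative_total) for {our method, YOLO1-3} x
# {training, testing}.
all_fixtures <- list(
  c(94, 2, 1, 108, 95, 110), c(84, 5, 2, 115, 86, 120),
  c(90, 6, 5, 104, 95, 110), c(80, 8, 6, 112, 86, 120),
  c(91, 7, 4, 103, 95, 110), c(80, 8, 6, 112, 86, 120),
  c(89, 9, 6, 101, 95, 110), c(79, 10, 7, 110, 86, 120))

rc_of <- function(v) rate_confusion(v[1], v[2], v[3], v[4], v[5], v[6])

test_that("rate_confusion validates count bounds", {
  rc <- rc_of(all_fixtures[[1]])
  expect_equal(unname(rc$tp_rate), c(94, 95))
  expect_equal(unname(rc$fp_rate), c(1, 55))       # 2/110 reduced
  expect_error(rate_confusion(96, 0, 0, 0, 95, 110),
               class = "csvd_count_error")
  expect_error(rate_confusion(1, 0, 0, 0, 0, 1), class = "csvd_count_error")
  expect_error(rate_confusion(-1, 0, 0, 0, 5, 5), class = "csvd_count_error")
  z <- rate_confusion(0, 0, 0, 0, 1, 1)
  expect_equal(z$tp_rate[["num"]], 0)
  perfect <- rate_confusion(95, 0, 0, 110, 95, 110)
  expect_equal(as.numeric(standard_recall(perfect)), 1)
  expect_equal(as.numeric(paper_precision(perfect)), 1)
})

test_that("rate-based precision reproduces the printed values", {
  expect_equal(as.numeric(paper_precision(rc_of(all_fixtures[[1]]))),
               0.981956315)
  expect_equal(as.numeric(paper_precision(rc_of(all_fixtures[[7]]))),
               0.919680601)
  no_fp <- rate_confusion(5, 0, 1, 10, 6, 10)
  expect_equal(as.numeric(paper_precision(no_fp)), 1)
  expect_error(paper_precision(rate_confusion(0, 0, 3, 1, 5, 5)),
               class = "csvd_undefined_metric_error")
  # count-based variant is the textbook value, distinct from the
  # rate-based one on these tables
  expect_equal(as.numeric(count_precision(rc_of(all_fixtures[[1]]))),
               round(94 / 96, 9), tolerance = 1e-9)
})

test_that("as-printed recall is the miss rate; standard recall its complement", {
  expect_equal(as.numeric(paper_recall(rc_of(all_fixtures[[1]]))),
               0.010526316)
  expect_equal(as.numeric(paper_recall(rc_of(all_fixtures[[8]]))),
               0.081395349)
  expect_equal(as.numeric(standard_recall(rc_of(all_fixtures[[1]]))),
               0.989473684)
  no_fn <- rate_confusion(5, 1, 0, 9, 5, 10)
  expect_equal(as.numeric(paper_recall(no_fn)), 0)
  expect_equal(as.numeric(standard_recall(no_fn)), 1)
  # complement identity holds on every fixture (tp + fn = P there)
  for (v in all_fixtures) {
    rc <- rc_of(v)
    pr <- attr(paper_recall(rc), "fraction")
    sr <- attr(standard_recall(rc), "fraction")
    expect_equal(pr[["num"]] / pr[["den"]] + sr[["num"]] / sr[["den"]], 1)
  }
})

test_that("F1 is the harmonic mean with its classical bounds", {
  p <- paper_precision(rc_of(all_fixtures[[1]]))
  r <- paper_recall(rc_of(all_fixtures[[1]]))
  expect_equal(as.numeric(f1_score(p, r)), 0.020829346)
  p8 <- paper_precision(rc_of(all_fixtures[[8]]))
  r8 <- paper_recall(rc_of(all_fixtures[[8]]))
  expect_equal(as.numeric(f1_score(p8, r8)), 0.149516707)
  expect_error(f1_score(0, 0.5), class = "csvd_undefined_metric_error")
  set.seed(30)
  for (i in 1:50) {
    x <- runif(1, 0.01, 1)
    expect_equal(as.numeric(f1_score(x, x)), round(x, 9), tolerance = 1e-9)
    p <- runif(1, 0.01, 1); r <- runif(1, 0.01, 1)
    f <- as.numeric(f1_score(p, r))
    expect_gte(f + 1e-9, min(p, r))
    expect_lte(f, 2 * min(p, r) + 1e-9)
  }
})

test_that("accuracy follows direct count arithmetic", {
  expect_equal(as.numeric(accuracy_counts(94, 2, 1, 108)), 0.985365854)
  expect_equal(as.numeric(accuracy_counts(0, 0, 0, 10)), 1)
  expect_equal(as.numeric(accuracy_counts(1, 1, 1, 1)), 0.5)
  expect_error(accuracy_counts(0, 0, 0, 0),
               class = "csvd_undefined_metric_error")
})

test_that("half-even rendering at 9 decimals is exact", {
  # 0.0000000005 rounds to even (0); 0.0000000015 rounds up to 2e-9
  expect_equal(csvdseg:::rat_round(csvdseg:::rat(1, 2e9)), 0)
  expect_equal(csvdseg:::rat_round(csvdseg:::rat(3, 2e9)), 2e-9)
  expect_equal(csvdseg:::rat_round(csvdseg:::rat(1, 3)), 0.333333333)
  expect_equal(csvdseg:::rat_round(csvdseg:::rat(2, 3)), 0.666666667)
})

test_that("map-based confusion counting matches an exhaustive oracle", {
  # pred == truth with 5 lesion patches of 100
  g <- patch_grid(70, 70, 7)
  cls <- rep(1L, 100); cls[c(3, 20, 41, 77, 99)] <- 3L
  m <- reassemble(cls, g)
  rc <- confusion_from_maps(m, m, unit = "patch", grid = g)
  expect_equal(c(rc$tp, rc$fp, rc$fn, rc$tn), c(5, 0, 0, 95))
  # all-zero prediction: tp = 0, fn = positives
  zero <- label_map(matrix(0L, 70, 70))
  rc <- confusion_from_maps(zero, m, unit = "patch", grid = g)
  expect_equal(c(rc$tp, rc$fn), c(0, 5))
  expect_error(confusion_from_maps(zero, m, unit = "patch"),
               class = "csvd_config_error")
  expect_error(confusion_from_maps(zero, label_map(matrix(0L, 3, 3))),
               class = "csvd_shape_error")
  # random pairs vs brute-force per-unit comparison
  set.seed(31)
  for (i in 1:20) {
    h <- sample(6:20, 1); w <- sample(6:20, 1)
    pred <- random_labelmap(h, w); truth <- random_labelmap(h, w)
    rc <- confusion_from_maps(pred, truth, unit = "pixel")
    tp <- fp <- fn <- tn <- 0L
    for (r in 1:h) for (c in 1:w) {
      t3 <- truth$classes[r, c] == 3L; p3 <- pred$classes[r, c] == 3L
      if (t3 && p3) tp <- tp + 1L else if (!t3 && p3) fp <- fp + 1L
      else if (t3 && !p3) fn <- fn + 1L else tn <- tn + 1L
    }
    expect_equal(c(rc$tp, rc$fp, rc$fn, rc$tn), c(tp, fp, fn, tn))
    gg <- patch_grid(h, w, 3)
    rc2 <- confusion_from_maps(pred, truth, unit = "patch", grid = gg)
    tp <- fp <- fn <- tn <- 0L
    for (gr in seq_len(gg$grid_rows)) for (gc in seq_len(gg$grid_cols)) {
      rows <- ((gr - 1) * 3 + 1):min(gr * 3, h)
      cols <- ((gc - 1) * 3 + 1):min(gc * 3, w)
      t3 <- any(truth$classes[rows, cols] == 3L)
      p3 <- any(pred$classes[rows, cols] == 3L)
      if (t3 && p3) tp <- tp + 1L else if (!t3 && p3) fp <- fp + 1L
      else if (t3 && !p3) fn <- fn + 1L else tn <- tn + 1L
    }
    expect_equal(c(rc2$tp, rc2$fp, rc2$fn, rc2$tn), c(tp, fp, fn, tn))
  }
})

test_that("the published summary tables reproduce cell-exactly", {
  rep <- reproduce_report_tables()
  expect_true(rep$all_match)
  expect_true(all(rep$training$match))
  expect_true(all(rep$testing$match))
  our_test <- rep$testing[rep$testing$method == "our", ]
  expect_equal(our_test$f1, 0.045410519)
  expect_equal(our_test$precision, 0.959086584)
  expect_equal(our_test$recall, 0.023255814)
  # YOLO1's own confusion cells do NOT give the printed column
  expect_false(rep$yolo1_discrepancy$precision[1] ==
                 rep$training$printed_precision[2])
})

test_that("k-fold assignment is stratified and balanced", {
  strata <- rep(c(0, 1), c(80, 20))
  f <- kfold_split(100, 10, strata, seed = 3)
  expect_equal(sort(unique(f)), 1:10)
  expect_true(all(table(f) == 10))
  expect_true(all(table(f[strata == 1]) == 2))
  expect_identical(f, kfold_split(100, 10, strata, seed = 3))
  expect_error(kfold_split(5, 10), class = "csvd_config_error")
})
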