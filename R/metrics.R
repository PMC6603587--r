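# Rate-valued confusion tables and the published evaluation formulas.
#
# The published tables store each confusion cell as a fraction of the
# positive/negative instance totals (94/95 style). The printed
# precision/recall/F1 values are reproduced only when the formulas are
# applied to those RATE-valued entries (count-based precision for the
# training table would give 94/96 ~ 0.979167, not the printed
# 0.981956315), and when "recall" is computed exactly as printed:
# FN/(TP+FN), i.e. the miss rate, not sensitivity. Both the as-printed
# and the textbook forms are provided under distinct names.
#
# All metric arithmetic is exact: fractions are integer
# numerator/denominator pairs (held in doubles, reduced by gcd after
# every operation so magnitudes stay far below 2^53), and rendering to
# 9 decimals uses half-even rounding done in integer arithmetic.

gcd2 <- function(a, b) {
  while (b != 0) { t <- a %% b; a <- b; b <- t }
  a
}

rat <- function(num, den) {
  if (den == 0) abort_undefined_metric("zero denominator")
  g <- gcd2(num, den)
  if (g > 0) { num <- num / g; den <- den / g }
  c(num = num, den = den)
}

rat_add <- function(a, b) rat(a[1] * b[2] + b[1] * a[2], a[2] * b[2])
rat_mul <- function(a, b) rat(a[1] * b[1], a[2] * b[2])

# Half-even rounding of num/den (>= 0) to `digits` decimals, exact.
rat_round <- function(r, digits = 9L) {
  num <- r[[1]]; den <- r[[2]]
  q0 <- num %/% den
  rem <- num %% den
  digs <- numeric(digits)
  for (i in seq_len(digits)) {
    rem <- rem * 10
    digs[i] <- rem %/% den
    rem <- rem %% den
  }
  frac <- sum(digs * 10^(digits - seq_len(digits)))
  if (2 * rem > den || (2 * rem == den && frac %% 2 == 1))
    frac <- frac + 1
  unname(q0 + frac / 10^digits)
}

with_fraction <- function(value, r) {
  attr(value, "fraction") <- c(num = unname(r[[1]]), den = unname(r[[2]]))
  value
}

fraction_of <- function(x) {
  f <- attr(x, "fraction")
  if (!is.null(f)) return(rat(f[[1]], f[[2]]))
  # fall back to a dyadic representation of the double
  rat(round(x * 1e12), 1e12)
}

#' Rate-valued confusion table
#'
#' Stores a binary (lesion vs non-lesion) confusion table whose
#' entries are exact fractions of the positive and negative instance
#' totals: `tp_rate = tp / positive_total`,
#' `fp_rate = fp / negative_total`, etc.
#'
#' @param tp,fp,fn,tn non-negative counts with
#'   `tp + fn <= positive_total` and `fp + tn <= negative_total`.
#' @param positive_total,negative_total instance totals (>= 1).
#' @return object of class `rate_confusion` carrying the counts,
#'   totals and exact rates.
#' @export
rate_confusion <- function(tp, fp, fn, tn, positive_total, negative_total) {
  v <- c(tp, fp, fn, tn)
  if (any(v < 0) || any(v != round(v)))
    abort_count("counts must be non-negative integers")
  if (positive_total < 1 || negative_total < 1)
    abort_count("instance totals must be >= 1")
  if (tp + fn > positive_total)
    abort_count("tp + fn exceeds positive_total")
  if (fp + tn > negative_total)
    abort_count("fp + tn exceeds negative_total")
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 positive_total = positive_total,
                 negative_total = negative_total,
                 tp_rate = rat(tp, positive_total),
                 fp_rate = rat(fp, negative_total),
                 fn_rate = rat(fn, positive_total),
                 tn_rate = rat(tn, negative_total)),
            class = "rate_confusion")
}

#' @export
print.rate_confusion <- function(x, ...) {
  cat(sprintf("<rate_confusion TP %d/%d  FP %d/%d  FN %d/%d  TN %d/%d>\n",
              x$tp, x$positive_total, x$fp, x$negative_total,
              x$fn, x$positive_total, x$tn, x$negative_total))
  invisible(x)
}

#' Confusion counts from predicted and true label maps
#'
#' Reduces both maps to binary lesion / non-lesion at the chosen unit.
#' A pixel unit is positive when its true class is the positive class;
#' a patch unit is positive when any pixel of its footprint is.
#'
#' @param pred,truth [label_map()]s of equal dimensions.
#' @param positive_class class id treated as positive (default 3,
#'   lesion).
#' @param unit `"pixel"` or `"patch"`.
#' @param grid a [patch_grid()], required for `unit = "patch"`.
#' @return a [rate_confusion()] whose totals are the positive and
#'   negative unit counts.
#' @export
confusion_from_maps <- function(pred, truth, positive_class = 3L,
                                unit = c("pixel", "patch"), grid = NULL) {
  unit <- match.arg(unit)
  stopifnot(inherits(pred, "label_map"), inherits(truth, "label_map"))
  if (pred$height != truth$height || pred$width != truth$width)
    abort_shape("label map dimensions differ")
  if (unit == "pixel") {
    tpos <- as.vector(truth$classes == positive_class)
    ppos <- as.vector(pred$classes == positive_class)
  } else {
    if (is.null(grid)) abort_config("unit = 'patch' requires a grid")
    tpos <- rowSums(extract_patches(truth, grid)$patches ==
                      positive_class) > 0
    ppos <- rowSums(extract_patches(pred, grid)$patches ==
                      positive_class) > 0
  }
  rate_confusion(tp = sum(tpos & ppos), fp = sum(!tpos & ppos),
                 fn = sum(tpos & !ppos), tn = sum(!tpos & !ppos),
                 positive_total = max(sum(tpos), 1L),
                 negative_total = max(sum(!tpos), 1L))
}

#' Evaluation formulas on rate-valued confusion entries
#'
#' `paper_precision()` is `tp_rate / (tp_rate + fp_rate)`;
#' `paper_recall()` is the as-printed form `fn_rate / (tp_rate +
#' fn_rate)` — the miss rate; `standard_recall()` is textbook
#' sensitivity `tp_rate / (tp_rate + fn_rate)`. `count_precision()`
#' and `count_recall()` are the plain count-based variants. All return
#' the exact value rounded half-even to `digits` decimals, with the
#' exact fraction in attribute `"fraction"`.
#'
#' @param rc a [rate_confusion()].
#' @param digits decimals for the rendered value (default 9, matching
#'   the published tables).
#' @return a numeric scalar with attribute `"fraction"`.
#' @export
paper_precision <- function(rc, digits = 9L) {
  stopifnot(inherits(rc, "rate_confusion"))
  den <- rc$tp * rc$negative_total + rc$fp * rc$positive_total
  if (den == 0) abort_undefined_metric("tp_rate + fp_rate is zero")
  r <- rat(rc$tp * rc$negative_total, den)
  with_fraction(rat_round(r, digits), r)
}

#' @rdname paper_precision
#' @export
paper_recall <- function(rc, digits = 9L) {
  stopifnot(inherits(rc, "rate_confusion"))
  if (rc$tp + rc$fn == 0) abort_undefined_metric("tp_rate + fn_rate is zero")
  r <- rat(rc$fn, rc$tp + rc$fn)   # the shared positive_total cancels
  with_fraction(rat_round(r, digits), r)
}

#' @rdname paper_precision
#' @export
standard_recall <- function(rc, digits = 9L) {
  stopifnot(inherits(rc, "rate_confusion"))
  if (rc$tp + rc$fn == 0) abort_undefined_metric("tp_rate + fn_rate is zero")
  r <- rat(rc$tp, rc$tp + rc$fn)
  with_fraction(rat_round(r, digits), r)
}

#' @rdname paper_precision
#' @export
count_precision <- function(rc, digits = 9L) {
  stopifnot(inherits(rc, "rate_confusion"))
  if (rc$tp + rc$fp == 0) abort_undefined_metric("tp + fp is zero")
  r <- rat(rc$tp, rc$tp + rc$fp)
  with_fraction(rat_round(r, digits), r)
}

#' @rdname paper_precision
#' @export
count_recall <- function(rc, digits = 9L) standard_recall(rc, digits)

#' F1 score (harmonic mean)
#'
#' `2 / (1/recall + 1/precision)`. When both inputs carry exact
#' fractions (as the metric functions here produce) the harmonic mean
#' is computed in exact rational arithmetic before rounding.
#'
#' @param precision,recall values in (0, 1], e.g. from
#'   [paper_precision()] and [paper_recall()].
#' @param digits rendered decimals.
#' @return numeric scalar with attribute `"fraction"`.
#' @export
f1_score <- function(precision, recall, digits = 9L) {
  if (precision <= 0 || recall <= 0)
    abort_undefined_metric("F1 needs positive precision and recall")
  p <- fraction_of(precision); r <- fraction_of(recall)
  # 2pr / (p + r)
  num <- rat_mul(rat(2, 1), rat_mul(p, r))
  den <- rat_add(p, r)
  f <- rat(num[[1]] * den[[2]], num[[2]] * den[[1]])
  with_fraction(rat_round(f, digits), f)
}

#' Overall accuracy from counts
#'
#' @param tp,fp,fn,tn non-negative counts, total > 0.
#' @param digits rendered decimals.
#' @return numeric scalar with attribute `"fraction"`.
#' @export
accuracy_counts <- function(tp, fp, fn, tn, digits = 9L) {
  total <- tp + fp + fn + tn
  if (total == 0) abort_undefined_metric("empty confusion table")
  r <- rat(tp + tn, total)
  with_fraction(rat_round(r, digits), r)
}

## ---- published-table reproduction --------------------------------------

# Confusion-cell fixtures as printed: c(tp, fp, fn, tn, P, N).
report_fixtures <- function() {
  list(
    our   = list(train = c(94, 2, 1, 108, 95, 110),
                 test  = c(84, 5, 2, 115, 86, 120)),
    yolo1 = list(train = c(90, 6, 5, 104, 95, 110),
                 test  = c(80, 8, 6, 112, 86, 120)),
    yolo2 = list(train = c(91, 7, 4, 103, 95, 110),
                 test  = c(80, 8, 6, 112, 86, 120)),
    yolo3 = list(train = c(89, 9, 6, 101, 95, 110),
                 test  = c(79, 10, 7, 110, 86, 120)))
}

printed_report_tables <- function() {
  list(
    training = data.frame(
      method = c("our", "yolo1", "yolo2", "yolo3"),
      f1 = c(0.020829346, 0.080591758, 0.080591758, 0.118198648),
      precision = c(0.981956315, 0.937704918, 0.937704918, 0.919680601),
      recall = c(0.010526316, 0.042105263, 0.042105263, 0.063157895)),
    testing = data.frame(
      method = c("our", "yolo1", "yolo2", "yolo3"),
      f1 = c(0.045410519, 0.129827978, 0.129827978, 0.149516707),
      precision = c(0.959086584, 0.933125972, 0.933125972, 0.916827853),
      recall = c(0.023255814, 0.069767442, 0.069767442, 0.081395349)))
}

metrics_row <- function(counts) {
  rc <- rate_confusion(counts[1], counts[2], counts[3], counts[4],
                       counts[5], counts[6])
  p <- paper_precision(rc)
  r <- paper_recall(rc)
  c(f1 = as.numeric(f1_score(p, r)), precision = as.numeric(p),
    recall = as.numeric(r))
}

#' Reproduce the published evaluation tables
#'
#' Recomputes every F1 / precision / recall cell of the published
#' training and testing summary tables from the confusion-cell
#' fixtures, in exact rational arithmetic rounded half-even to 9
#' decimals, and compares against the printed values.
#'
#' Note: the printed summary tables show identical YOLO1 and YOLO2
#' columns, both consistent with YOLO2's confusion tables and not
#' YOLO1's. The reproduction therefore maps the printed YOLO1 column
#' to the YOLO2 confusion fixtures and reports the discrepancy
#' (`yolo1_discrepancy`) — computed from YOLO1's own confusion cells —
#' rather than silently "fixing" the source.
#'
#' @return list with `training` and `testing` data frames (computed
#'   values plus printed values and a `match` flag per cell), and
#'   `yolo1_discrepancy`: the values YOLO1's own confusion tables
#'   would give.
#' @export
reproduce_report_tables <- function() {
  fx <- report_fixtures()
  printed <- printed_report_tables()
  # printed YOLO1 column is consistent with the YOLO2 fixtures
  col_source <- c(our = "our", yolo1 = "yolo2", yolo2 = "yolo2",
                  yolo3 = "yolo3")
  out <- list()
  for (split in c("training", "testing")) {
    key <- if (split == "training") "train" else "test"
    rows <- lapply(names(col_source), function(m)
      metrics_row(fx[[col_source[[m]]]][[key]]))
    comp <- do.call(rbind, rows)
    df <- data.frame(method = names(col_source), comp,
                     printed_f1 = printed[[split]]$f1,
                     printed_precision = printed[[split]]$precision,
                     printed_recall = printed[[split]]$recall)
    df$match <- df$f1 == df$printed_f1 &
      df$precision == df$printed_precision &
      df$recall == df$printed_recall
    out[[split]] <- df
  }
  out$yolo1_discrepancy <- data.frame(
    split = c("training", "testing"),
    rbind(metrics_row(fx$yolo1$train), metrics_row(fx$yolo1$test)))
  out$all_match <- all(out$training$match) && all(out$testing$match)
  out
}

#' Stratified k-fold assignment
#'
#' Seeded fold assignment for cross-validation, stratified so each
#' fold gets a proportional share of every stratum (e.g. lesion
#' presence).
#'
#' @param n number of instances.
#' @param k folds (default 10).
#' @param strata optional vector of length `n`.
#' @param seed RNG seed.
#' @return integer vector of fold ids 1..k.
#' @export
kfold_split <- function(n, k = 10L, strata = NULL, seed = 1L) {
  if (k < 2L || k > n) abort_config("need 2 <= k <= n")
  if (is.null(strata)) strata <- rep(1L, n)
  set.seed(seed)
  folds <- integer(n)
  for (s in unique(strata)) {
    idx <- sample(which(strata == s))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}
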