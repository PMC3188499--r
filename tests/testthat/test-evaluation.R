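# Labeled sets, ROC/AUC, operating points, calibration.

test_that("labeled tables validate sequences, labels and duplicates", {
  d <- data.frame(sequence = c("CVIM", "CVLS", "CKDD"),
                  label = c("MTO", "MTO", "NON"))
  suppressMessages(set <- readLabeledSet(d))
  expect_identical(nrow(records(set)), 3L)
  expect_error(suppressMessages(readLabeledSet(
    data.frame(sequence = c("CVIM", "CVIM"), label = c("MTO", "NON")))),
    "duplicate")
  expect_error(suppressMessages(readLabeledSet(
    data.frame(sequence = "CVIM", label = "FOO"))), "unknown label")
  # TSV round trip with a score column
  tsv <- tempfile(fileext = ".tsv")
  d$score <- c(-2, -1, 1)
  utils::write.table(d, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  suppressMessages(set2 <- readLabeledSet(tsv))
  expect_equal(records(set2)$score, d$score)
})

test_that("ROC endpoints, orientation and hand-computed AUC on a 2x2 case", {
  # positives {-3, -1}, negatives {-2, 0}: 3 of 4 pairs concordant
  roc <- rocCurve(c(-3, -1, -2, 0), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(auc(roc), 0.75)
  pts <- rocPoints(roc)
  expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1); expect_equal(pts$tpr[nrow(pts)], 1)
  expect_false(is.unsorted(pts$fpr)); expect_false(is.unsorted(pts$tpr))
  # perfect separation (lower = positive) and the ties convention
  expect_equal(auc(rocCurve(c(-5, -4, 1, 2), c(TRUE, TRUE, FALSE, FALSE))),
               1)
  expect_equal(auc(rocCurve(rep(0.3, 6), rep(c(TRUE, FALSE), 3))), 0.5)
  expect_error(rocCurve(1:3, c(TRUE, TRUE, TRUE)), "positive and one")
})

test_that("trapezoid AUC equals the concordant-pair count on random inputs", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    scores <- round(stats::rnorm(n), sample(0:2, 1))  # force ties sometimes
    labels <- stats::runif(n) < 0.5
    if (!any(labels) || all(labels)) next
    roc <- rocCurve(scores, labels)  # internal cross-check runs here
    cmp <- outer(scores[labels], scores[!labels],
                 function(a, b) (a < b) + 0.5 * (a == b))
    expect_equal(auc(roc), mean(cmp), tolerance = 1e-12)
  }
})

test_that("AUC agrees with pROC as an independent reference", {
  skip_if_not_installed("pROC")
  set.seed(7)
  scores <- stats::rnorm(60)
  labels <- stats::runif(60) < 0.4
  ours <- auc(rocCurve(scores, labels))
  ref <- suppressMessages(pROC::auc(pROC::roc(
    response = labels, predictor = scores, direction = ">")))
  expect_equal(ours, as.numeric(ref), tolerance = 1e-12)
})

test_that("rates at a threshold count at-or-below calls and are monotone", {
  sp <- c(-3, -1); sn <- c(-2, 0)
  scores <- c(sp, sn); labels <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(unname(ratesAtThreshold(scores, labels, -1.5)), c(0.5, 0.5))
  expect_equal(unname(ratesAtThreshold(scores, labels, -10)), c(0, 0))
  expect_equal(unname(ratesAtThreshold(scores, labels, 10)), c(1, 1))
  prev <- c(-1, -1)
  for (t in seq(-4, 1, by = 0.25)) {
    r <- ratesAtThreshold(scores, labels, t)
    expect_gte(r["tpr"], prev[1]); expect_gte(r["fpr"], prev[2])
    prev <- r
  }
})

test_that("negating scores and swapping orientation preserves the curve", {
  set.seed(11)
  scores <- stats::rnorm(30)
  labels <- stats::runif(30) < 0.5
  if (any(labels) && !all(labels)) {
    a1 <- auc(rocCurve(scores, labels))
    # negated scores with inverted labels give the mirrored problem
    a2 <- auc(rocCurve(-scores, !labels))
    expect_equal(a1, a2, tolerance = 1e-12)
  }
})

test_that("threshold calibration matches an exhaustive sweep and handles edge cases", {
  # perfectly separated: midpoint of the gap
  cfg <- calibrateThresholds(c(-5, -4, 2, 3), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(cfg@loose, -1)
  expect_lte(cfg@stringent, cfg@loose)
  # known optimum against a brute-force Youden sweep
  set.seed(3)
  scores <- stats::rnorm(40)
  labels <- c(stats::rnorm(20, -1), stats::rnorm(20, 1)) < 0
  scores <- c(stats::rnorm(20, -1), stats::rnorm(20, 1))
  labels <- rep(c(TRUE, FALSE), each = 20)
  cfg2 <- calibrateThresholds(scores, labels)
  sweep <- vapply(sort(unique(scores)), function(t) {
    r <- ratesAtThreshold(scores, labels, t)
    r["tpr"] - r["fpr"]
  }, numeric(1))
  got <- ratesAtThreshold(scores, labels, cfg2@loose)
  expect_equal(unname(got["tpr"] - got["fpr"]), max(sweep),
               tolerance = 1e-12)
  # requested fpr 0 on overlapping data: threshold below all negatives
  cfg3 <- calibrateThresholds(scores, labels, looseFpr = 0,
                              stringentFpr = 0)
  expect_equal(unname(ratesAtThreshold(scores, labels, cfg3@loose)["fpr"]),
               0)
  # fpr-bound mode respects the bound
  cfg4 <- calibrateThresholds(scores, labels, looseFpr = 0.1)
  expect_lte(unname(ratesAtThreshold(scores, labels, cfg4@loose)["fpr"]),
             0.1)
})
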