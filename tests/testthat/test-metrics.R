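test_that("matching reproduces the simple hand cases", {
  t1 <- matrix(c(10, 10, 30, 30), 1)
  d_same <- detection_set(t1, 0.9)
  mr <- match_detections(t1, d_same, 0.9)
  expect_equal(c(mr$TP, mr$FP, mr$FN), c(1, 0, 0))

  # two detections on one truth: single-match rule
  d2 <- detection_set(rbind(t1, t1 + 0.5), c(0.9, 0.8))
  mr2 <- match_detections(t1, d2, 0.5)
  expect_equal(c(mr2$TP, mr2$FP, mr2$FN), c(1, 1, 0))

  expect_error(match_detections(matrix(c(5, 5, 5, 9), 1), d_same, 0.5),
               "invalid ground-truth")
  expect_error(match_detections(t1, d_same, 1.5), "iou_threshold")
})

test_that("matching agrees with the brute-force oracle on seeded scenes", {
  set.seed(61)
  for (trial in 1:10) {
    nt <- sample(5:20, 1); nd <- sample(5:20, 1)
    tx <- runif(nt, 0, 200); ty <- runif(nt, 0, 200)
    truth <- cbind(tx, ty, tx + runif(nt, 10, 40), ty + runif(nt, 10, 40))
    base <- truth[sample(nt, nd, replace = TRUE), , drop = FALSE]
    db <- base + matrix(rnorm(nd * 4, sd = 4), nd)
    bad <- db[, 3] <= db[, 1]; db[bad, 3] <- db[bad, 1] + 1
    bad <- db[, 4] <= db[, 2]; db[bad, 4] <- db[bad, 2] + 1
    scores <- runif(nd)
    dets <- detection_set(db, scores)
    for (thr in c(0.3, 0.5, 0.75)) {
      got <- match_detections(truth, dets, thr)
      want <- oracle_match(truth, db, scores, thr)
      expect_equal(got$TP, want$TP)
      expect_equal(got$FP, want$FP)
      expect_equal(got$FN, want$FN)
      # bookkeeping invariants
      expect_equal(got$TP + got$FN, nt)
      expect_equal(got$TP + got$FP, nd)
    }
  }
})

test_that("recall and precision follow TP/(TP+FN) and TP/(TP+FP)", {
  # 10 truths; 7 hit by exact detections, 3 extra false positives
  n <- 10
  truth <- cbind(seq(0, 900, by = 100), 0, seq(0, 900, by = 100) + 20, 20)
  hits <- truth[1:7, , drop = FALSE]
  fps <- cbind(seq(0, 200, 100), 500, seq(0, 200, 100) + 20, 520)
  dets <- detection_set(rbind(hits, fps), c(rep(0.9, 7), rep(0.8, 3)))
  pr <- pr_and_ap(truth, dets, 0.5)
  expect_equal(pr$recall, 0.7)
  expect_equal(pr$precision, 0.7)
})

test_that("AP fixtures: perfect single detection, and the (hit, miss, hit) ranking", {
  t1 <- matrix(c(0, 0, 20, 20), 1)
  expect_equal(pr_and_ap(t1, detection_set(t1, 1.0), 0.5)$ap, 1)

  # two truths, ranked list (correct, fp, correct):
  # after rank 1: r=0.5, p=1; after rank 3: r=1, p=2/3
  truth <- rbind(c(0, 0, 20, 20), c(100, 100, 120, 120))
  dets <- detection_set(rbind(c(0, 0, 20, 20), c(300, 300, 320, 320),
                              c(100, 100, 120, 120)),
                        c(0.9, 0.8, 0.7))
  got <- pr_and_ap(truth, dets, 0.5)$ap
  # independent enumeration of the 101-point interpolated sum
  grid <- seq(0, 1, by = 0.01)
  want <- mean(ifelse(grid <= 0.5, 1, 2 / 3))
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("zero ground truths flag a warning and report AP 0", {
  d <- detection_set(matrix(c(0, 0, 5, 5), 1), 0.9)
  expect_warning(res <- pr_and_ap(matrix(numeric(0), 0, 4), d, 0.5),
                 "no ground-truth")
  expect_equal(res$ap, 0)
})

test_that("ap_range is the mean of exactly ten values and is permutation-safe", {
  expect_equal(ap_range(rep(0.6, 10)), 0.6)
  expect_equal(ap_range(seq(0.1, 1, by = 0.1)), 0.55)
  expect_equal(ap_range(rev(seq(0.1, 1, by = 0.1))), 0.55)
  expect_error(ap_range(rep(0.5, 9)), "exactly 10")
})

test_that("AP is within [0,1] and non-increasing along the IoU sweep", {
  set.seed(62)
  for (trial in 1:5) {
    nt <- 15
    tx <- runif(nt, 0, 300); ty <- runif(nt, 0, 300)
    truth <- cbind(tx, ty, tx + runif(nt, 8, 30), ty + runif(nt, 8, 30))
    dets <- make_noisy_detections(truth, seed = trial)
    sw <- ap_sweep(truth, dets)
    aps <- sw$by_threshold
    expect_true(all(aps >= 0 & aps <= 1))
    expect_true(all(diff(aps) <= 1e-12))
    expect_equal(sw$ap50_95, mean(aps))
  }
})

test_that("size classification uses the 1024 / 9216 px^2 boundaries", {
  boxes <- rbind(c(0, 0, 32, 32),    # area 1024 -> small (inclusive)
                 c(0, 0, 33, 33),    # 1089 -> medium
                 c(0, 0, 96, 96),    # 9216 -> medium (inclusive)
                 c(0, 0, 97, 97))    # 9409 -> large
  expect_equal(as.character(size_class(boxes)),
               c("small", "medium", "medium", "large"))
  expect_error(size_class(c(100, 0)), "positive")
})

test_that("size-stratified AP: all-small perfect detections; subset equivalence", {
  truth <- rbind(c(0, 0, 20, 20), c(50, 50, 80, 80))   # both small
  dets <- detection_set(truth, c(0.9, 0.8))
  res <- ap_by_size(truth, dets)
  expect_equal(res$AP_S, 1)
  expect_true(is.na(res$AP_M))

  # mixed scene: per-class AP equals pr_and_ap on the class-filtered subset
  set.seed(63)
  small_t <- cbind(seq(0, 450, 50), 0, seq(0, 450, 50) + 20, 25)
  med_t <- cbind(seq(0, 300, 150), 200, seq(0, 300, 150) + 50, 250)
  truth <- rbind(small_t, med_t)
  dets <- make_noisy_detections(truth, drop = 0.3, fp = 4, seed = 9)
  full <- ap_by_size(truth, dets, 0.5)
  cls <- size_class(truth)
  # remove detections that match out-of-class truths, then evaluate subset
  subset_ap <- function(kls) {
    mr <- match_detections(truth, dets, 0.5)
    in_class <- cls == kls
    ignored <- !is.na(mr$matched_truth) & !in_class[mr$matched_truth]
    keep <- which(!ignored)
    sub <- detection_set(dets$boxes[keep, , drop = FALSE], dets$scores[keep])
    pr_and_ap(truth[in_class, , drop = FALSE], sub, 0.5)$ap
  }
  expect_equal(full$AP_S, subset_ap("small"))
  expect_equal(full$AP_M, subset_ap("medium"))
})

test_that("count metrics reproduce the hand-arithmetic fixtures to 1e-12", {
  m <- c(10, 20); p <- c(9, 22)
  cm <- count_metrics(m, p)
  expect_equal(cm$MAE, 1.5, tolerance = 1e-12)
  expect_equal(cm$RMSE, sqrt(5 / 2), tolerance = 1e-12)
  expect_equal(cm$MAPE, 10.0, tolerance = 1e-12)
  expect_equal(cm$R2, 0.9, tolerance = 1e-12)

  perfect <- count_metrics(c(3, 7, 11), c(3, 7, 11))
  expect_equal(perfect$R2, 1)
  expect_equal(perfect$RMSE, 0)
  expect_equal(perfect$MAE, 0)
  expect_equal(perfect$MAPE, 0)

  # predicting the mean for every image gives R^2 = 0 by definition
  m2 <- c(4, 8, 12)
  cm2 <- count_metrics(m2, rep(mean(m2), 3))
  expect_equal(cm2$R2, 0, tolerance = 1e-12)
})

test_that("degenerate counting series are reported as undefined, not skipped", {
  expect_warning(cm <- count_metrics(c(5, 5, 5), c(4, 5, 6)), "undefined")
  expect_true(is.na(cm$R2))
  expect_warning(cm2 <- count_metrics(c(0, 10), c(1, 9)), "MAPE")
  expect_true(is.na(cm2$MAPE))
  expect_false(is.na(cm2$RMSE))
  expect_error(count_metrics(c(1, 2), c(1)), "equal-length")
})
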