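test_that("confusion matrix tallies exactly", {
  cm <- confusion(c("A", "B", "B"), c("A", "B", "A"), c("A", "B"))
  expect_equal(unclass(cm), matrix(c(1L, 1L, 0L, 1L), 2, 2),
               ignore_attr = TRUE)
  expect_equal(sum(cm), 3)

  y <- rep(lesion_classes(), each = 4)
  perfect <- compute_metrics(confusion(y, y, lesion_classes()))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$kappa, 1)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$macro_f1, 1)

  expect_error(confusion(c("A"), c("Z"), c("A", "B")), "outside")
  expect_error(confusion(c("A", "B"), c("A"), NULL), "equal length")
})

test_that("binary toy reproduces hand-derived accuracy and kappa", {
  # cm [[40,10],[5,45]]: acc 0.85, p_e 0.5, kappa 0.7
  y_true <- c(rep("A", 50), rep("B", 50))
  y_pred <- c(rep("A", 40), rep("B", 10), rep("A", 5), rep("B", 45))
  m <- compute_metrics(confusion(y_true, y_pred, c("A", "B")))
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$kappa, 0.7, tolerance = 1e-12)
  # binary Gorodkin MCC equals the classic binary formula
  tp <- 40; tn <- 45; fp <- 5; fn <- 10
  mcc_binary <- (tp * tn - fp * fn) /
    sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  expect_equal(m$mcc, mcc_binary, tolerance = 1e-12)
  expect_lte(m$kappa, m$accuracy)
})

test_that("per-class recalls reproduce published confusion arithmetic", {
  # row with 457 correct of 500 -> 91.4% recall, and the near-perfect rows
  correct <- c(ACK = 457L, SCC = 497L, SEK = 496L)
  for (cls in names(correct)) {
    y_true <- rep(cls, 500)
    other <- setdiff(lesion_classes(), cls)[1]
    y_pred <- c(rep(cls, correct[[cls]]), rep(other, 500L - correct[[cls]]))
    m <- suppressWarnings(
      compute_metrics(confusion(y_true, y_pred, lesion_classes()))
    )
    got <- m$per_class$recall[m$per_class$class == cls]
    expect_equal(round(100 * got, 1),
                 c(ACK = 91.4, SCC = 99.4, SEK = 99.2)[[cls]])
  }
})

test_that("macro metrics are unweighted class means and AUC needs probs", {
  set.seed(8)
  y_true <- sample(c("A", "B", "C"), 90, replace = TRUE)
  y_pred <- ifelse(runif(90) < 0.7, y_true,
                   sample(c("A", "B", "C"), 90, replace = TRUE))
  cm <- confusion(y_true, y_pred, c("A", "B", "C"))
  m <- compute_metrics(cm)
  expect_equal(m$macro_recall, mean(m$per_class$recall))
  expect_equal(m$macro_precision, mean(m$per_class$precision))
  expect_true(is.na(m$macro_auc))

  # probabilities that always rank the true class first give AUC 1
  probs <- matrix(0.05, 90, 3, dimnames = list(NULL, c("A", "B", "C")))
  probs[cbind(1:90, match(y_true, c("A", "B", "C")))] <- 0.9
  m2 <- compute_metrics(cm, probs = probs, y_true = y_true)
  expect_equal(m2$macro_auc, 1)

  g <- glance(m)
  expect_identical(names(g)[1:2], c("n", "accuracy"))
  expect_identical(tidy(m), m$per_class)
})

test_that("never-predicted classes yield zero precision with a warning", {
  y_true <- c("A", "A", "B", "B")
  y_pred <- c("A", "A", "A", "A")
  expect_warning(m <- compute_metrics(confusion(y_true, y_pred, c("A", "B"))),
                 "never predicted")
  expect_equal(m$per_class$precision[2], 0)
})

test_that("bootstrap intervals are seeded, degenerate-safe and shrink with n", {
  y <- rep(lesion_classes(), each = 10)
  ci_perfect <- bootstrap_ci(y, y, metric = "accuracy", B = 200, seed = 3)
  expect_equal(ci_perfect$lower, 1)
  expect_equal(ci_perfect$upper, 1)

  sim <- function(n, seed) {
    set.seed(seed)
    y_true <- rep("A", n)
    y_pred <- ifelse(runif(n) < 0.9, "A", "B")
    list(t = y_true, p = y_pred)
  }
  d <- sim(1000, 1)
  ci1 <- bootstrap_ci(d$t, d$p, metric = "accuracy", B = 400, seed = 5,
                      label_order = c("A", "B"))
  ci2 <- bootstrap_ci(d$t, d$p, metric = "accuracy", B = 400, seed = 5,
                      label_order = c("A", "B"))
  expect_identical(ci1, ci2)
  expect_true(ci1$lower <= 0.9 && ci1$upper >= 0.9)
  # width within 30% of the binomial normal approximation
  want <- 2 * 1.96 * sqrt(0.9 * 0.1 / 1000)
  expect_lt(abs((ci1$upper - ci1$lower) - want) / want, 0.3)

  small <- sim(100, 2)
  ci_small <- bootstrap_ci(small$t, small$p, metric = "accuracy", B = 400,
                           seed = 5, label_order = c("A", "B"))
  expect_gt(ci_small$upper - ci_small$lower, ci1$upper - ci1$lower)

  expect_error(bootstrap_ci(d$t, d$p, B = 50), "at least 100")
})

test_that("plot methods return ggplot objects", {
  y <- rep(lesion_classes(), each = 5)
  set.seed(2)
  p <- sample(y)
  cm <- confusion(y, p, lesion_classes())
  expect_s3_class(autoplot(cm), "ggplot")
  expect_s3_class(autoplot(suppressWarnings(compute_metrics(cm))), "ggplot")
})
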