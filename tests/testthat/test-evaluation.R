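test_that("the decision rule is strict on the normal side", {
  # P(normal) = 0.51 -> normal; P(normal) = 0.50 exactly -> aspiration
  expect_identical(classifyProb(0.49), "normal")
  expect_identical(classifyProb(0.50), "aspiration")
  expect_identical(classifyProb(0.51), "aspiration")
  # threshold 0: everything normal unless P(normal) == 0
  expect_identical(classifyProb(c(0.999, 1), threshold = 1e-12),
                   c("normal", "aspiration"))
  expect_error(classifyProb(1.2))
})

test_that("confusion metrics reproduce hand arithmetic", {
  m <- confusionMetrics(list(tp = 9, fn = 1, tn = 8, fp = 2))
  expect_equal(m$sensitivity, 90)
  expect_equal(m$specificity, 80)
  expect_equal(m$ppv, 81.8182, tolerance = 1e-4)
  expect_equal(m$npv, 88.8889, tolerance = 1e-4)
  expect_equal(m$accuracy, 85)
  expect_equal(m$f1, 0.8571, tolerance = 1e-4)
  # perfect classifier
  p <- confusionMetrics(list(tp = 5, fn = 0, tn = 5, fp = 0))
  expect_true(all(unlist(p[c("accuracy", "sensitivity", "specificity",
                             "ppv", "npv")]) == 100))
  expect_equal(p$f1, 1)
  # swapping tp and fn complements sensitivity
  a <- confusionMetrics(list(tp = 3, fn = 7, tn = 4, fp = 6))
  b <- confusionMetrics(list(tp = 7, fn = 3, tn = 4, fp = 6))
  expect_equal(a$sensitivity + b$sensitivity, 100)
  # zero denominator -> undefined, not zero
  z <- confusionMetrics(list(tp = 0, fn = 0, tn = 10, fp = 0))
  expect_true(is.na(z$sensitivity))
  expect_true(is.na(z$ppv))
  expect_false(is.na(z$specificity))
})

test_that("accuracy decomposes into prevalence-weighted sens/spec", {
  set.seed(31)
  for (i in 1:10) {
    cts <- as.list(setNames(sample(1:30, 4, replace = TRUE),
                            c("tp", "fp", "tn", "fn")))
    m <- confusionMetrics(cts)
    P <- cts$tp + cts$fn; N <- cts$tn + cts$fp
    expect_equal(m$accuracy,
                 (m$sensitivity * P + m$specificity * N) / (P + N))
  }
})

test_that("AUC equals brute-force pair counting and its identities", {
  expect_equal(rocAuc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)), 0.75)
  expect_equal(rocAuc(c(0, 1), c(0, 1)), 1)
  expect_equal(rocAuc(c(0, 1, 0, 1), rep(0.3, 4)), 0.5)
  expect_error(rocAuc(c(1, 1), c(0.2, 0.3)), "both classes")
  brute <- function(labels, scores) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    s <- 0
    for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
    s / (length(pos) * length(neg))
  }
  set.seed(13)
  for (i in 1:25) {
    n <- sample(4:50, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    expect_equal(rocAuc(labels, scores), brute(labels, scores))
    # complement identity (tie-free scores)
    sc2 <- rnorm(n)
    expect_equal(rocAuc(labels, sc2) + rocAuc(labels, -sc2), 1)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  set.seed(14)
  labels <- sample(0:1, 40, replace = TRUE, prob = c(0.6, 0.4))
  labels[1:2] <- 0:1
  scores <- rnorm(40) + labels
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(rocAuc(labels, scores), ref)
})

test_that("BCE-with-logits is stable and correct", {
  z <- c(0, 2, -2, 500, -500)
  y <- c(1, 1, 0, 1, 0)
  l <- bceWithLogits(z, y, reduce = FALSE)
  expect_true(all(is.finite(l)))
  expect_equal(l[1], log(2))
  expect_equal(l[2], log(1 + exp(-2)))
  expect_equal(l[4], 0, tolerance = 1e-10)
  expect_equal(bceWithLogits(z, y), mean(l))
})

test_that("fold summaries give t-based confidence intervals and the max", {
  r <- data.frame(auc = c(0.7, 0.8, 0.9))
  s <- summarizeFolds(r)
  expect_equal(s$mean, 0.8)
  expect_equal(s$ci_low, 0.8 - qt(0.975, 2) * 0.1 / sqrt(3), tolerance = 1e-6)
  expect_equal(s$ci_low, 0.5516, tolerance = 1e-4)
  expect_equal(s$ci_high, 1.0484, tolerance = 1e-4)
  expect_equal(s$max, 0.9)
  # identical reports collapse the interval onto the mean
  same <- data.frame(auc = rep(0.75, 10))
  ss <- summarizeFolds(same)
  expect_equal(ss$ci_low, 0.75)
  expect_equal(ss$ci_high, 0.75)
  # symmetric values give an interval centered on the mean
  sym <- summarizeFolds(data.frame(acc = rep(c(0, 1), 5)))
  expect_equal(sym$mean - sym$ci_low, sym$ci_high - sym$mean)
  expect_error(summarizeFolds(data.frame(auc = 0.5)), "two fold")
  # intervals are not clipped to the metric's natural range
  wide <- summarizeFolds(data.frame(acc = c(99, 100, 100, 98, 100)))
  expect_gt(wide$ci_high, 100)
})

test_that("metricsReport assembles the full row", {
  set.seed(15)
  labels <- rep(0:1, each = 10)
  probs <- pmin(pmax(labels * 0.6 + runif(20, 0, 0.4), 0), 1)
  r <- metricsReport(labels, probs, loss = 0.4, train_accuracy = 99,
                     train_loss = 0.1)
  expect_true(all(c("auc", "accuracy", "sensitivity", "specificity", "f1",
                    "ppv", "npv", "loss", "train_accuracy", "train_loss")
                  %in% names(r)))
  expect_true(r$auc >= 0 && r$auc <= 1)
  expect_equal(r$loss, 0.4)
})
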