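test_that("channel arithmetic of the built graph matches its contract", {
  det <- buildDetector(modelConfig(width_multiplier = 0.25), seed = 1)
  tr <- channelTrace(det)
  # decoder input is twice the encoder output (branch concatenation)
  cc <- tr[tr$stage == "concat", ]
  expect_equal(cc$cout, 2 * cc$cin)
  expect_equal(cc$cin, det$encoder_out_channels)
  # decoder expands x6 then x2: a total x12 over its input budget
  d1 <- tr[tr$stage == "decoder.expand1", ]
  d2 <- tr[tr$stage == "decoder.expand2", ]
  expect_equal(d1$cout / d1$cin, 6)
  expect_equal(d2$cout / d2$cin, 2)
  expect_equal(d2$cout / d1$cin, 12)
  # head emits one logit from the expanded features
  hd <- tr[tr$stage == "head", ]
  expect_equal(hd$cin, d2$cout)
  expect_equal(hd$cout, 1)
  # wiring is consistent stage to stage inside the encoder blocks
  enc <- tr[grepl("^encoder", tr$stage), ]
  expect_true(all(enc$cin[-1] == enc$cout[-nrow(enc)] |
                    grepl("depthwise", enc$stage[-1]) |
                    grepl("expand|project", enc$stage[-1])))
})

test_that("builds are seeded and parameter count grows with width", {
  checksum <- function(det)
    sum(vapply(vowelscreen:::.detector_units(det),
               function(u) sum(u$W) + sum(u$b), numeric(1)))
  d1 <- buildDetector(modelConfig(0.25), seed = 11)
  d2 <- buildDetector(modelConfig(0.25), seed = 11)
  d3 <- buildDetector(modelConfig(0.25), seed = 12)
  expect_identical(checksum(d1), checksum(d2))
  expect_false(identical(checksum(d1), checksum(d3)))
  counts <- vapply(c(0.25, 0.5, 1.0), function(w)
    countParameters(buildDetector(modelConfig(w), seed = 1)), numeric(1))
  expect_true(all(diff(counts) > 0))
  expect_error(modelConfig(width_multiplier = 0), "positive")
})

test_that("forward pass meets its shape and sensitivity contracts", {
  det <- buildDetector(modelConfig(0.25), seed = 3)
  set.seed(4)
  xp <- array(rnorm(128 * 201 * 4), c(128, 201, 1, 4))
  xq <- array(rnorm(128 * 201 * 4), c(128, 201, 1, 4))
  z <- forwardDetector(det, xp, xq)
  expect_length(z, 4)
  expect_true(all(is.finite(z)))
  # swapping pre and post changes the logit (no accidental symmetry)
  z_swap <- forwardDetector(det, xq, xp)
  expect_false(isTRUE(all.equal(z, z_swap)))
  # identical branches still give finite output
  z_same <- forwardDetector(det, xp, xp)
  expect_true(all(is.finite(z_same)))
  # mismatched branch shapes rejected
  expect_error(forwardDetector(det, xp, xq[, 1:100, , , drop = FALSE]),
               "identical shapes")
  # deterministic in evaluation mode
  expect_identical(z, forwardDetector(det, xp, xq))
})

test_that("all parameters receive gradient through the dual-branch wiring", {
  det <- buildDetector(modelConfig(0.25), seed = 5)
  set.seed(6)
  xp <- array(rnorm(128 * 201 * 8), c(128, 201, 1, 8))
  xq <- array(rnorm(128 * 201 * 8), c(128, 201, 1, 8))
  units <- vowelscreen:::.detector_units(det)
  for (u in units) vowelscreen:::.unit_zero_grads(u)
  fw <- vowelscreen:::.detector_fwd(det, xp, xq, train = TRUE)
  y <- rep(c(0, 1), 4)
  p <- predictProba(fw$logits)
  vowelscreen:::.detector_bwd(det, fw, (p - y) / 8)
  for (u in units) {
    for (pn in c("W", "gamma", "beta")) {
      if (is.null(u[[pn]])) next
      expect_gt(max(abs(u[[paste0("g_", pn)]])), 0)
    }
  }
})

test_that("analytic gradients match finite differences", {
  cfg <- modelConfig(width_multiplier = 0.25, stem_channels = 8L,
                     block_out = c(8L, 8L), block_stride = c(2L, 1L),
                     block_expand = c(1, 3))
  det <- buildDetector(cfg, seed = 7)
  set.seed(8)
  xp <- array(rnorm(32 * 33 * 2), c(32, 33, 1, 2))
  xq <- array(rnorm(32 * 33 * 2), c(32, 33, 1, 2))
  y <- c(0, 1)
  units <- vowelscreen:::.detector_units(det)
  for (u in units) vowelscreen:::.unit_zero_grads(u)
  fw <- vowelscreen:::.detector_fwd(det, xp, xq, train = TRUE)
  vowelscreen:::.detector_bwd(det, fw, (predictProba(fw$logits) - y) / 2)
  loss_at <- function() {
    z <- vowelscreen:::.detector_fwd(det, xp, xq, train = TRUE)$logits
    bceWithLogits(z, y)
  }
  set.seed(9)
  for (ui in sample(seq_along(units), 4)) {
    u <- units[[ui]]
    for (pn in c("W", "gamma", "beta")) {
      if (is.null(u[[pn]])) next
      idx <- sample(length(u[[pn]]), 1)
      eps <- 1e-5
      orig <- u[[pn]][idx]
      u[[pn]][idx] <- orig + eps; l1 <- loss_at()
      u[[pn]][idx] <- orig - eps; l2 <- loss_at()
      u[[pn]][idx] <- orig
      num <- (l1 - l2) / (2 * eps)
      ana <- u[[paste0("g_", pn)]][idx]
      expect_equal(ana, num, tolerance = 1e-3)
    }
  }
})

test_that("probabilities follow the logistic contract", {
  expect_equal(predictProba(0), 0.5)
  expect_equal(predictProba(50), 1, tolerance = 1e-10)
  expect_equal(predictProba(-50), 0, tolerance = 1e-10)
  z <- seq(-5, 5, by = 0.5)
  expect_true(all(diff(predictProba(z)) > 0))
})

test_that("checkpoints are self-describing and restore the forward pass", {
  det <- buildDetector(modelConfig(0.25), seed = 21)
  set.seed(22)
  xp <- array(rnorm(128 * 201 * 2), c(128, 201, 1, 2))
  xq <- array(rnorm(128 * 201 * 2), c(128, 201, 1, 2))
  z <- forwardDetector(det, xp, xq)
  path <- tempfile(fileext = ".rds")
  saveCheckpoint(det, path, MelConfig(), extra = list(note = "test"))
  det2 <- loadCheckpoint(path)
  expect_equal(forwardDetector(det2, xp, xq), z)
  expect_s4_class(attr(det2, "mel_config"), "MelConfig")
  expect_equal(attr(det2, "extra")$note, "test")
  unlink(path)
})
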