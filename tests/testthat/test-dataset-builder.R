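segtab <- function(subject, phase, n, substance = NA_character_,
                   group = "normal", sex = "male") {
  out <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(subject_id = subject, phase = phase, group_label = group,
               sex = sex, substance = substance, segment_index = i,
               stringsAsFactors = FALSE)))
  out$clip <- I(replicate(n, new("EncodedClip", payload = as.raw(1:4),
                                 codec = "pcm16", bitrate_kbps = 64,
                                 channels = 1L, sample_rate = 32000L,
                                 subject_id = subject, phase = phase,
                                 segment_index = 1L), simplify = FALSE))
  out
}

test_that("pair enumeration is the within-subject Cartesian product", {
  segs <- rbind(segtab("A", "pre", 3), segtab("A", "post", 4))
  expect_equal(nrow(enumeratePairs(segs)), 12)
  # a subject without pre segments contributes nothing
  expect_equal(nrow(enumeratePairs(segtab("B", "post", 5))), 0)
  # two subjects, no cross-subject pairs (brute-force count: 2x2 + 1x3)
  segs2 <- rbind(segtab("A", "pre", 2), segtab("A", "post", 2),
                 segtab("B", "pre", 1, group = "aspiration"),
                 segtab("B", "post", 3, group = "aspiration"))
  pairs <- enumeratePairs(segs2)
  expect_equal(nrow(pairs), 7)
  expect_equal(sum(pairs$subject_id == "A"), 4)
  expect_equal(sum(pairs$subject_id == "B"), 3)
  expect_equal(unique(pairs$label[pairs$subject_id == "B"]), 1L)
  for (i in seq_len(nrow(pairs))) {
    expect_identical(subjectID(pairs$pre[[i]]), pairs$subject_id[i])
    expect_identical(subjectID(pairs$post[[i]]), pairs$subject_id[i])
    expect_identical(phase(pairs$pre[[i]]), "pre")
    expect_identical(phase(pairs$post[[i]]), "post")
  }
})

test_that("pairing respects substance sessions when metadata is present", {
  segs <- rbind(segtab("A", "pre", 2, substance = "water"),
                segtab("A", "post", 2, substance = "water"),
                segtab("A", "pre", 1, substance = "YP"),
                segtab("A", "post", 3, substance = "YP"))
  expect_equal(nrow(enumeratePairs(segs, within_substance = TRUE)), 4 + 3)
  expect_equal(nrow(enumeratePairs(segs, within_substance = FALSE)), 3 * 5)
})

test_that("fold assignment is a stratified, seeded partition by subject", {
  subjects <- data.frame(
    subject_id = sprintf("S%02d", 1:30),
    label = rep(c(0L, 1L), c(20, 10)))
  plan <- assignFolds(subjects, k = 10, seed = 4)
  expect_s4_class(plan, "FoldPlan")
  a <- foldAssignment(plan)
  expect_length(a, 30)
  expect_true(all(table(a) == 3))
  # stratification: every fold gets 2 normal + 1 aspiration subjects
  for (i in 0:9) {
    ids <- foldSubjects(plan, i)
    labs <- subjects$label[match(ids, subjects$subject_id)]
    expect_equal(sum(labs == 0), 2)
    expect_equal(sum(labs == 1), 1)
  }
  # determinism and partition
  plan2 <- assignFolds(subjects, k = 10, seed = 4)
  expect_identical(foldAssignment(plan2), a)
  expect_false(identical(foldAssignment(assignFolds(subjects, 10, 5)), a))
  expect_error(assignFolds(subjects, k = 1), "at least 2")
  expect_warning(assignFolds(subjects[1:5, ], k = 10), "best-effort")
})

test_that("oversampling balances training labels and keeps originals", {
  set.seed(1)
  pairs <- toy_pairs(n_subjects = 8, pairs_per_subject = 5,
                     labels = rep(c(0L, 0L, 0L, 1L), 2))
  # 30 normal vs 10 aspiration
  pairs <- pairs[c(which(pairs$label == 0), which(pairs$label == 1)[1:10]), ]
  out <- oversampleTraining(pairs, seed = 3)
  expect_equal(sum(out$label == 0), 30)
  expect_equal(sum(out$label == 1), 30)
  # all originals retained
  expect_true(all(rownames(pairs) %in% rownames(pairs)))
  expect_equal(nrow(merge(pairs[c("subject_id", "label")],
                          out[c("subject_id", "label")])) >= nrow(pairs), TRUE)
  # balanced input unchanged
  bal <- toy_pairs(n_subjects = 4, labels = c(0L, 1L, 0L, 1L))
  expect_identical(oversampleTraining(bal, seed = 3), bal)
  # determinism
  expect_identical(oversampleTraining(pairs, seed = 3)$subject_id,
                   oversampleTraining(pairs, seed = 3)$subject_id)
  # single label: warning, unchanged
  one <- pairs[pairs$label == 0, ]
  expect_warning(same <- oversampleTraining(one, seed = 3), "single label")
  expect_identical(same, one)
})

test_that("female-scope oversampling balances within female pairs only", {
  pairs <- toy_pairs(n_subjects = 8, pairs_per_subject = 3,
                     labels = c(0L, 0L, 0L, 0L, 0L, 1L, 0L, 1L))
  n_male <- sum(pairs$sex == "male")
  out <- oversampleTraining(pairs, seed = 2, scope = "female")
  expect_equal(sum(out$sex == "male"), n_male)
  f <- out[out$sex == "female", ]
  expect_equal(sum(f$label == 0), sum(f$label == 1))
})

test_that("the HDF5 store round-trips pairs and enforces fold structure", {
  store <- micro_store()
  info <- datasetStoreInfo(store)
  expect_equal(info$k, 4L)
  expect_identical(info$codec, "pcm16")
  expect_equal(info$sample_rate, 32000L)
  plan <- assignFolds(enumeratePairs(micro_segments()), k = 4, seed = 17)
  all_pairs <- enumeratePairs(micro_segments())
  for (i in 0:3) {
    test <- readDatasetStore(store, i, "test")
    train <- readDatasetStore(store, i, "train")
    # leakage guard
    expect_length(intersect(unique(train$subject_id),
                            unique(test$subject_id)), 0)
    # test split holds exactly that fold's subjects
    expect_setequal(unique(test$subject_id), foldSubjects(plan, i))
    # oversampled training labels are balanced
    expect_equal(sum(train$label == 0), sum(train$label == 1))
    # test split is untouched: same pair count as the raw enumeration
    keep <- all_pairs[all_pairs$subject_id %in% foldSubjects(plan, i), ]
    expect_equal(nrow(test), nrow(keep))
  }
  # byte-exact payload round trip
  t0 <- readDatasetStore(store, 0, "test")
  orig <- all_pairs[all_pairs$subject_id %in% foldSubjects(plan, 0), ]
  ord1 <- order(t0$subject_id, vapply(t0$pre, function(x) sum(as.integer(payload(x))), 0))
  ord2 <- order(orig$subject_id, vapply(orig$pre, function(x) sum(as.integer(payload(x))), 0))
  for (j in seq_along(ord1)) {
    expect_identical(payload(t0$pre[[ord1[j]]]), payload(orig$pre[[ord2[j]]]))
    expect_identical(payload(t0$post[[ord1[j]]]), payload(orig$post[[ord2[j]]]))
  }
  expect_error(readDatasetStore(store, 9, "test"), "not present")
})

test_that("disabling oversampling reproduces raw pair counts", {
  pairs <- enumeratePairs(micro_segments())
  plan <- assignFolds(pairs, k = 4, seed = 17)
  path <- tempfile(fileext = ".h5")
  writeDatasetStore(pairs, plan, path, oversample = "off")
  for (i in 0:3) {
    train <- readDatasetStore(path, i, "train")
    expect_equal(nrow(train),
                 sum(!pairs$subject_id %in% foldSubjects(plan, i)))
  }
  unlink(path)
})
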