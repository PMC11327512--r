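#' Pair pre- and post-swallow segments within subjects
#'
#' Builds the model's input atoms: for every subject, the Cartesian product
#' of that subject's pre-phase clips with its post-phase clips. When
#' substance metadata is present and `within_substance = TRUE`, only
#' segments from the same substance session are paired. Subjects lacking
#' either phase contribute no pairs; no pair ever crosses subjects.
#'
#' @param segments a segment table as returned by [standardizeManifest()]:
#'   data.frame with columns `subject_id`, `phase`, `group_label`, `sex`,
#'   `substance` and a `clip` list column of [EncodedClip-class] objects.
#' @param within_substance restrict pairing to matching substance sessions
#'   (default `TRUE`; ignored when substance is absent).
#' @return a pair table: data.frame with columns `subject_id`, `label`
#'   (0 = normal, 1 = aspiration), `sex`, and list columns `pre`, `post` of
#'   [EncodedClip-class] objects.
#' @export
enumeratePairs <- function(segments, within_substance = TRUE) {
  stopifnot(all(c("subject_id", "phase", "group_label", "clip") %in%
                  names(segments)))
  sub_key <- if (within_substance && !all(is.na(segments$substance)))
    paste(segments$subject_id, segments$substance, sep = "\r")
  else segments$subject_id
  out <- list()
  for (key in unique(sub_key)) {
    grp <- segments[sub_key == key, ]
    pre_i <- which(grp$phase == "pre")
    post_i <- which(grp$phase == "post")
    if (!length(pre_i) || !length(post_i)) next
    combos <- expand.grid(pre = pre_i, post = post_i)
    lab <- match(grp$group_label[1L], .GROUPS) - 1L
    blk <- data.frame(subject_id = grp$subject_id[1L], label = lab,
                      sex = grp$sex[1L], stringsAsFactors = FALSE)
    blk <- blk[rep(1L, nrow(combos)), , drop = FALSE]
    blk$pre <- I(grp$clip[combos$pre])
    blk$post <- I(grp$clip[combos$post])
    out[[length(out) + 1L]] <- blk
  }
  if (!length(out))
    return(data.frame(subject_id = character(), label = integer(),
                      sex = character(), pre = I(list()), post = I(list())))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Subject-grouped, label-stratified fold assignment
#'
#' Assigns every subject to exactly one of `k` folds. Within each class
#' label the shuffled subjects are dealt round-robin into folds, so class
#' balance per fold is as even as the subject counts allow, and no subject
#' ever spans folds. Deterministic given `seed`.
#'
#' @param subjects data.frame with columns `subject_id` and `label`
#'   (one row per subject), or a pair table from [enumeratePairs()].
#' @param k number of folds (default 10).
#' @param seed RNG seed.
#' @return a [FoldPlan-class].
#' @export
assignFolds <- function(subjects, k = 10L, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  subjects <- unique(subjects[, c("subject_id", "label")])
  if (anyDuplicated(subjects$subject_id))
    stop("a subject_id appears with more than one label")
  per_label <- table(subjects$label)
  if (any(per_label < k))
    warning("fewer than k subjects in some label; stratification is ",
            "best-effort")
  assignment <- integer(0)
  withr_seed <- .with_seed(seed, {
    for (lab in sort(unique(subjects$label))) {
      ids <- subjects$subject_id[subjects$label == lab]
      ids <- sample(ids)
      folds <- (seq_along(ids) - 1L) %% k
      assignment[ids] <- folds
    }
    assignment
  })
  new("FoldPlan", k = k, assignment = withr_seed, seed = as.integer(seed))
}

# evaluate expr under a temporary RNG seed, restoring prior state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  expr
}

#' Random oversampling of minority-class training pairs
#'
#' Duplicates minority-label pairs uniformly at random with replacement
#' until label counts are equal (or reach `ratio` times the majority
#' count). All original pairs are retained. Test splits must never pass
#' through this operation; [writeDatasetStore()] enforces that. With
#' `scope = "female"` only female pairs are balanced (the combined-model
#' convention), leaving male pairs untouched.
#'
#' @param pairs a pair table (training split).
#' @param seed optional RNG seed; `NULL` uses the current RNG state.
#' @param ratio target minority/majority count ratio (default 1 = equality).
#' @param scope `"all"` or `"female"`.
#' @return the oversampled pair table.
#' @export
oversampleTraining <- function(pairs, seed = NULL, ratio = 1,
                               scope = c("all", "female")) {
  scope <- match.arg(scope)
  stopifnot(ratio > 0, ratio <= 1)
  body <- function() {
    idx_pool <- if (scope == "female") which(pairs$sex == "female")
                else seq_len(nrow(pairs))
    counts <- table(factor(pairs$label[idx_pool], levels = 0:1))
    if (any(counts == 0L)) {
      warning("training split contains a single label within scope; ",
              "returned unchanged")
      return(pairs)
    }
    minority <- as.integer(names(which.min(counts)))
    need <- floor(ratio * max(counts)) - min(counts)
    if (need <= 0L) return(pairs)
    min_idx <- idx_pool[pairs$label[idx_pool] == minority]
    extra <- sample(min_idx, need, replace = TRUE)
    out <- rbind(pairs, pairs[extra, , drop = FALSE])
    rownames(out) <- NULL
    out
  }
  if (is.null(seed)) body() else .with_seed(seed, body())
}

.bytes_to_mat <- function(payloads) {
  lens <- vapply(payloads, length, integer(1))
  m <- matrix(as.raw(0L), nrow = max(lens), ncol = length(payloads))
  for (i in seq_along(payloads)) m[seq_len(lens[i]), i] <- payloads[[i]]
  list(mat = m, lens = lens)
}

.write_split <- function(file, group, pairs) {
  suppressMessages({
    rhdf5::h5createGroup(file, group)
    rhdf5::h5write(pairs$subject_id, file, paste0(group, "/ids"))
    rhdf5::h5write(as.integer(pairs$label), file, paste0(group, "/labels"))
    rhdf5::h5write(as.character(pairs$sex), file, paste0(group, "/sex"))
    for (side in c("pre", "post")) {
      pk <- .bytes_to_mat(lapply(pairs[[side]], payload))
      nm <- paste0(group, "/", side, "_audio")
      # uncompressed: PCM payloads barely deflate and write speed matters
      rhdf5::h5createDataset(file, nm, dims = dim(pk$mat),
                             storage.mode = "raw", level = 0L)
      rhdf5::h5write(pk$mat, file, nm)
      rhdf5::h5write(pk$lens, file, paste0(group, "/", side, "_len"))
    }
  })
}

#' Write the fold-structured HDF5 dataset store
#'
#' Persists the paired dataset in hierarchical HDF5 layout: one group per
#' fold, `/fold{i}/train` and `/fold{i}/test`, each holding parallel arrays
#' `ids`, `labels`, `sex` and the variable-length byte payloads
#' `pre_audio` / `post_audio` (zero-padded byte columns plus `pre_len` /
#' `post_len`). Root attributes record the seed, segment length, sampling
#' rate, codec and bitrate. Fold `i`'s test split holds exactly the pairs
#' of that fold's subjects; its train split holds all other subjects'
#' pairs, oversampled when requested. Oversampling never touches test
#' splits.
#'
#' @param pairs a pair table from [enumeratePairs()].
#' @param plan a [FoldPlan-class] covering every subject in `pairs`.
#' @param path output .h5 path (overwritten).
#' @param oversample `"auto"` (balance training labels to equality),
#'   `"off"`, or a numeric minority/majority ratio.
#' @param oversample_scope `"all"` or `"female"` (see
#'   [oversampleTraining()]).
#' @param seed RNG seed for the oversampling draws.
#' @return `path`, invisibly.
#' @export
writeDatasetStore <- function(pairs, plan, path, oversample = "auto",
                              oversample_scope = "all", seed = 1L) {
  stopifnot(is(plan, "FoldPlan"), nrow(pairs) > 0L)
  missing <- setdiff(unique(pairs$subject_id), names(plan@assignment))
  if (length(missing))
    stop("subjects absent from the fold plan: ",
         paste(missing, collapse = ", "))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  clip1 <- pairs$pre[[1L]]
  for (i in seq_len(plan@k) - 1L) {
    test_subj <- foldSubjects(plan, i)
    is_test <- pairs$subject_id %in% test_subj
    train <- pairs[!is_test, , drop = FALSE]
    if (!identical(oversample, "off"))
      train <- oversampleTraining(
        train, seed = as.integer(seed) + i,
        ratio = if (identical(oversample, "auto")) 1 else as.numeric(oversample),
        scope = oversample_scope)
    grp <- sprintf("fold%d", i)
    rhdf5::h5createGroup(path, grp)
    .write_split(path, paste0(grp, "/train"), train)
    .write_split(path, paste0(grp, "/test"), pairs[is_test, , drop = FALSE])
  }
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(as.integer(plan@seed), fid, "fold_seed")
  rhdf5::h5writeAttribute(as.integer(seed), fid, "seed")
  rhdf5::h5writeAttribute(plan@k, fid, "k")
  rhdf5::h5writeAttribute(clip1@sample_rate, fid, "sample_rate")
  rhdf5::h5writeAttribute(length(clip1@payload) /
                            (2 * clip1@sample_rate), fid, "seg_len_s")
  rhdf5::h5writeAttribute(clip1@codec, fid, "codec")
  rhdf5::h5writeAttribute(clip1@bitrate_kbps, fid, "bitrate_kbps")
  rhdf5::H5Fclose(fid)
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read one split of the dataset store
#'
#' @param path the store written by [writeDatasetStore()].
#' @param fold fold index in `0:(k-1)`.
#' @param split `"train"` or `"test"`.
#' @return a pair table (as in [enumeratePairs()]).
#' @export
readDatasetStore <- function(path, fold, split = c("train", "test")) {
  split <- match.arg(split)
  info <- datasetStoreInfo(path)
  if (!(fold %in% (seq_len(info$k) - 1L)))
    stop("fold ", fold, " not present in store (k = ", info$k, ")")
  grp <- sprintf("fold%d/%s", as.integer(fold), split)
  ids <- as.character(rhdf5::h5read(path, paste0(grp, "/ids")))
  labels <- as.integer(rhdf5::h5read(path, paste0(grp, "/labels")))
  sex <- as.character(rhdf5::h5read(path, paste0(grp, "/sex")))
  side_clips <- function(side) {
    mat <- rhdf5::h5read(path, paste0(grp, "/", side, "_audio"))
    lens <- as.integer(rhdf5::h5read(path, paste0(grp, "/", side, "_len")))
    lapply(seq_along(lens), function(j) {
      new("EncodedClip", payload = as.raw(mat[seq_len(lens[j]), j]),
          codec = info$codec, bitrate_kbps = info$bitrate_kbps,
          channels = 1L, sample_rate = as.integer(info$sample_rate),
          subject_id = ids[j], phase = side, segment_index = NA_integer_)
    })
  }
  out <- data.frame(subject_id = ids, label = labels, sex = sex,
                    stringsAsFactors = FALSE)
  out$pre <- I(side_clips("pre"))
  out$post <- I(side_clips("post"))
  rhdf5::h5closeAll()
  out
}

#' Summary of a dataset store
#'
#' @param path the store path.
#' @return list with `k`, root attributes, and per-fold train/test sizes.
#' @export
datasetStoreInfo <- function(path) {
  at <- rhdf5::h5readAttributes(path, "/")
  ls <- rhdf5::h5ls(path)
  folds <- grep("^fold[0-9]+$", unique(ls$name[ls$group == "/"]), value = TRUE)
  sizes <- lapply(sort(as.integer(sub("fold", "", folds))), function(i) {
    c(train = length(rhdf5::h5read(path, sprintf("fold%d/train/labels", i))),
      test = length(rhdf5::h5read(path, sprintf("fold%d/test/labels", i))))
  })
  rhdf5::h5closeAll()
  list(k = as.integer(at$k), seed = as.integer(at$seed),
       fold_seed = as.integer(at$fold_seed),
       sample_rate = as.integer(at$sample_rate),
       seg_len_s = as.numeric(at$seg_len_s), codec = as.character(at$codec),
       bitrate_kbps = as.numeric(at$bitrate_kbps),
       sizes = do.call(rbind, sizes))
}
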