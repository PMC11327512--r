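#' Model configuration for the paired change detector
#'
#' A width-scalable inverted-residual convolutional encoder is applied to
#' the pre- and post-swallow spectrograms separately (weights shared across
#' the two branches by default — a Siamese layout), the branch features are
#' concatenated along channels, and a channel-expanding decoder (x6 then
#' x2, a total x12 expansion of its input channel budget) feeds a fully
#' convolutional head: global mean pooling followed by a 1x1 convolution
#' emitting one logit. Batch normalization follows every convolution.
#'
#' `width_multiplier` scales every channel count; the reference
#' configuration uses 2.0, while 0.25 is a practical desk-scale default.
#'
#' @param width_multiplier positive channel scaling factor.
#' @param shared_encoder share encoder weights across the pre and post
#'   branches (default `TRUE`).
#' @param stem_channels base channel count of the stem convolution.
#' @param block_out base output channels of the inverted-residual blocks.
#' @param block_stride per-block stride (1 or 2).
#' @param block_expand expansion factor inside each inverted-residual block.
#' @param decoder_expansions ordered channel-expansion factors of the
#'   decoder (default `c(6, 2)`).
#' @param bn_momentum,bn_eps batch-normalization constants.
#' @return list of class `ModelConfig`.
#' @export
modelConfig <- function(width_multiplier = 0.25, shared_encoder = TRUE,
                        stem_channels = 16L,
                        block_out = c(24L, 32L, 48L, 48L, 48L),
                        block_stride = c(2L, 2L, 2L, 2L, 1L),
                        block_expand = c(1, 3, 3, 3, 3),
                        decoder_expansions = c(6, 2), bn_momentum = 0.1,
                        bn_eps = 1e-5) {
  if (width_multiplier <= 0) stop("width_multiplier must be positive")
  stopifnot(length(block_out) == length(block_stride),
            all(block_stride %in% c(1L, 2L)), length(decoder_expansions) >= 1)
  block_expand <- rep_len(block_expand, length(block_out))
  structure(list(width_multiplier = width_multiplier,
                 shared_encoder = shared_encoder,
                 stem_channels = stem_channels, block_out = block_out,
                 block_stride = block_stride, block_expand = block_expand,
                 decoder_expansions = decoder_expansions,
                 bn_momentum = bn_momentum, bn_eps = bn_eps),
            class = "ModelConfig")
}

.scale_ch <- function(base, w) max(1L, as.integer(round(base * w)))

.build_encoder <- function(cfg) {
  w <- cfg$width_multiplier
  c_stem <- .scale_ch(cfg$stem_channels, w)
  stem <- .nn_unit(1L, c_stem, k = 3L, stride = 2L, pad = 1L,
                   bn_momentum = cfg$bn_momentum, bn_eps = cfg$bn_eps)
  blocks <- list()
  cin <- c_stem
  for (j in seq_along(cfg$block_out)) {
    cout <- .scale_ch(cfg$block_out[j], w)
    cexp <- max(1L, as.integer(round(cin * cfg$block_expand[j])))
    s <- cfg$block_stride[j]
    blocks[[j]] <- list(
      # the expansion stage is omitted when the factor is 1 (first block)
      expand = if (cexp != cin)
        .nn_unit(cin, cexp, k = 1L, bn_momentum = cfg$bn_momentum,
                 bn_eps = cfg$bn_eps),
      dw = .nn_unit(cexp, cexp, k = 3L, stride = s, pad = 1L, groups = cexp,
                    bn_momentum = cfg$bn_momentum, bn_eps = cfg$bn_eps),
      project = .nn_unit(cexp, cout, k = 1L, act = FALSE,
                         bn_momentum = cfg$bn_momentum, bn_eps = cfg$bn_eps),
      residual = (s == 1L && cin == cout))
    cin <- cout
  }
  list(stem = stem, blocks = blocks, out_channels = cin)
}

#' Build the paired pre/post change detector
#'
#' Constructs the network described by a [modelConfig()], with seeded
#' (He-normal) initialization. See [forwardDetector()] for the forward
#' contract and [channelTrace()] for the channel arithmetic of the built
#' graph.
#'
#' @param cfg a [modelConfig()].
#' @param seed RNG seed for weight initialization.
#' @return a detector object (list of class `Detector`).
#' @export
buildDetector <- function(cfg = modelConfig(), seed = 1L) {
  stopifnot(inherits(cfg, "ModelConfig"))
  .with_seed(seed, {
    enc <- .build_encoder(cfg)
    enc2 <- if (cfg$shared_encoder) NULL else .build_encoder(cfg)
    C <- enc$out_channels
    dec_in <- 2L * C
    dec <- list()
    cin <- dec_in
    for (e in cfg$decoder_expansions) {
      cout <- as.integer(cin * e)
      dec[[length(dec) + 1L]] <- .nn_unit(cin, cout, k = 1L,
                                          bn_momentum = cfg$bn_momentum,
                                          bn_eps = cfg$bn_eps)
      cin <- cout
    }
    head <- new.env(parent = emptyenv())
    head$W <- matrix(rnorm(cin, sd = sqrt(1 / cin)), 1L, cin)
    head$b <- 0
    structure(list(cfg = cfg, enc = enc, enc2 = enc2, dec = dec,
                   head = head, encoder_out_channels = C,
                   decoder_in_channels = dec_in,
                   head_in_channels = cin, seed = as.integer(seed)),
              class = "Detector")
  })
}

.detector_units <- function(det) {
  grab <- function(enc) {
    us <- list(enc$stem)
    for (b in enc$blocks) {
      if (!is.null(b$expand)) us <- c(us, list(b$expand))
      us <- c(us, list(b$dw, b$project))
    }
    us
  }
  us <- grab(det$enc)
  if (!is.null(det$enc2)) us <- c(us, grab(det$enc2))
  c(us, det$dec, list(det$head))
}

#' Number of trainable parameters
#'
#' @param det a detector from [buildDetector()].
#' @return integer parameter count.
#' @export
countParameters <- function(det) {
  sum(vapply(.detector_units(det), function(u) {
    sum(vapply(.PARAM_NAMES, function(p)
      if (is.null(u[[p]])) 0L else length(u[[p]]), integer(1)))
  }, integer(1)))
}

#' Channel arithmetic of the built graph
#'
#' Walks the network and reports every stage's input and output channel
#' counts, so the wiring (decoder input = 2 x encoder output; decoder
#' expansions in configured order) can be asserted on the constructed
#' object rather than on the configuration.
#'
#' @param det a detector from [buildDetector()].
#' @return data.frame with columns `stage`, `cin`, `cout`.
#' @export
channelTrace <- function(det) {
  rows <- list()
  add <- function(stage, cin, cout)
    rows[[length(rows) + 1L]] <<- data.frame(stage = stage, cin = cin,
                                             cout = cout)
  add("encoder.stem", det$enc$stem$cin, det$enc$stem$cout)
  for (j in seq_along(det$enc$blocks)) {
    b <- det$enc$blocks[[j]]
    if (!is.null(b$expand))
      add(sprintf("encoder.block%d.expand", j), b$expand$cin, b$expand$cout)
    add(sprintf("encoder.block%d.depthwise", j), b$dw$cin, b$dw$cout)
    add(sprintf("encoder.block%d.project", j), b$project$cin, b$project$cout)
  }
  add("concat", det$encoder_out_channels, det$decoder_in_channels)
  for (j in seq_along(det$dec))
    add(sprintf("decoder.expand%d", j), det$dec[[j]]$cin, det$dec[[j]]$cout)
  add("head", det$head_in_channels, 1L)
  do.call(rbind, rows)
}

.enc_fwd <- function(enc, x, train) {
  caches <- list()
  r <- .unit_fwd(enc$stem, x, train)
  caches$stem <- r$cache
  y <- r$y
  for (j in seq_along(enc$blocks)) {
    b <- enc$blocks[[j]]
    x_in <- y
    r1 <- if (!is.null(b$expand)) .unit_fwd(b$expand, y, train)
          else list(y = y, cache = NULL)
    r2 <- .unit_fwd(b$dw, r1$y, train)
    r3 <- .unit_fwd(b$project, r2$y, train)
    y <- if (b$residual) r3$y + x_in else r3$y
    caches[[paste0("block", j)]] <- list(c1 = r1$cache, c2 = r2$cache,
                                         c3 = r3$cache)
  }
  list(y = y, caches = caches)
}

.enc_bwd <- function(enc, dy, caches) {
  for (j in rev(seq_along(enc$blocks))) {
    b <- enc$blocks[[j]]
    cc <- caches[[paste0("block", j)]]
    d3 <- .unit_bwd(b$project, dy, cc$c3)
    d2 <- .unit_bwd(b$dw, d3, cc$c2)
    d1 <- if (!is.null(b$expand)) .unit_bwd(b$expand, d2, cc$c1) else d2
    dy <- if (b$residual) d1 + dy else d1
  }
  .unit_bwd(enc$stem, dy, caches$stem, need_dx = FALSE)
}

.detector_fwd <- function(det, xpre, xpost, train = FALSE) {
  if (!identical(dim(xpre), dim(xpost)))
    stop("pre and post branches must have identical shapes")
  enc2 <- if (is.null(det$enc2)) det$enc else det$enc2
  rp <- .enc_fwd(det$enc, xpre, train)
  rq <- .enc_fwd(enc2, xpost, train)
  xcat <- .concat_channels(rp$y, rq$y)
  dec_caches <- list()
  y <- xcat
  for (j in seq_along(det$dec)) {
    r <- .unit_fwd(det$dec[[j]], y, train)
    dec_caches[[j]] <- r$cache
    y <- r$y
  }
  feat <- .global_mean_pool(y)
  logits <- as.numeric(det$head$W %*% feat + det$head$b)
  list(logits = logits,
       caches = list(pre = rp$caches, post = rq$caches, dec = dec_caches,
                     feat = feat, pool_dim = dim(y),
                     split = dim(rp$y)[3]))
}

.detector_bwd <- function(det, fw, dlogits) {
  head <- det$head
  dlog <- matrix(dlogits, 1L)
  head$g_W <- head$g_W + dlog %*% t(fw$caches$feat)
  head$g_b <- head$g_b + sum(dlogits)
  dfeat <- t(head$W) %*% dlog
  dy <- .global_mean_pool_bwd(dfeat, fw$caches$pool_dim)
  for (j in rev(seq_along(det$dec)))
    dy <- .unit_bwd(det$dec[[j]], dy, fw$caches$dec[[j]])
  Cs <- fw$caches$split
  dpre <- dy[, , seq_len(Cs), , drop = FALSE]
  dpost <- dy[, , Cs + seq_len(Cs), , drop = FALSE]
  enc2 <- if (is.null(det$enc2)) det$enc else det$enc2
  .enc_bwd(det$enc, dpre, fw$caches$pre)
  .enc_bwd(enc2, dpost, fw$caches$post)
  invisible(NULL)
}

#' Forward pass of the paired change detector
#'
#' @param det a detector from [buildDetector()].
#' @param xpre,xpost numeric arrays of standardized Mel spectrograms with
#'   dim (n_mels, n_frames, 1, batch); both branches must share one shape.
#' @param train use batch statistics (training mode) instead of running
#'   statistics.
#' @return numeric vector of one logit per batch element (positive
#'   direction = aspiration).
#' @export
forwardDetector <- function(det, xpre, xpost, train = FALSE) {
  stopifnot(inherits(det, "Detector"))
  .detector_fwd(det, xpre, xpost, train)$logits
}

#' Logit to class probability
#'
#' @param logit finite numeric logits.
#' @return `P(aspiration)` = `sigmoid(logit)`; `P(normal)` is its
#'   complement.
#' @export
predictProba <- function(logit) 1 / (1 + exp(-logit))

#' Stack spectrogram matrices into a network input batch
#'
#' @param specs list of (n_mels x n_frames) matrices.
#' @return array with dim (n_mels, n_frames, 1, length(specs)).
#' @export
stackSpectrograms <- function(specs) {
  d <- dim(specs[[1L]])
  out <- array(0, c(d[1L], d[2L], 1L, length(specs)))
  for (i in seq_along(specs)) out[, , 1L, i] <- specs[[i]]
  out
}

#' Save / load a self-describing checkpoint
#'
#' The checkpoint carries the trained weights together with the model and
#' mel-front-end configurations, so inference needs nothing but the file.
#'
#' @param det a detector.
#' @param path checkpoint path (.rds).
#' @param mel_config the [MelConfig-class] the detector was trained with.
#' @param extra optional named list stored alongside.
#' @return `path` (save) or the restored detector with attribute
#'   `mel_config` (load).
#' @export
saveCheckpoint <- function(det, path, mel_config = MelConfig(),
                           extra = list()) {
  units <- .detector_units(det)
  state <- lapply(units, function(u)
    mget(c(.PARAM_NAMES, "rmean", "rvar"), envir = as.environment(u),
         ifnotfound = list(NULL)))
  saveRDS(list(cfg = det$cfg, seed = det$seed, state = state,
               mel = list(n_mels = mel_config@n_mels,
                          sample_rate = mel_config@sample_rate,
                          win_length = mel_config@win_length,
                          hop_length = mel_config@hop_length,
                          n_fft = mel_config@n_fft,
                          preemphasis = mel_config@preemphasis,
                          htk = mel_config@htk,
                          log_eps = mel_config@log_eps),
               extra = extra), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  det <- buildDetector(ck$cfg, seed = ck$seed)
  units <- .detector_units(det)
  stopifnot(length(units) == length(ck$state))
  for (i in seq_along(units)) {
    for (nm in names(ck$state[[i]])) {
      if (!is.null(ck$state[[i]][[nm]])) units[[i]][[nm]] <- ck$state[[i]][[nm]]
    }
  }
  attr(det, "mel_config") <- do.call(MelConfig, ck$mel)
  attr(det, "extra") <- ck$extra
  det
}
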