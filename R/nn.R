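# Internal neural-network primitives.
#
# Activations are numeric arrays with dim (H, W, C, N); convolution
# weights are (Cout x K) matrices with K = (Cin/groups)*kh*kw (layout
# matched to the C++ kernels). Each "unit" is a conv(+BN)(+ReLU) stage
# held in an environment so parameters, gradients, Adam state and batch
# norm running statistics can be updated in place; a shared (Siamese)
# encoder is then just the same environments visited twice, with
# gradients accumulating naturally.

.nn_unit <- function(cin, cout, k = 1L, stride = 1L, pad = 0L, groups = 1L,
                     act = TRUE, use_bn = TRUE, bn_momentum = 0.1,
                     bn_eps = 1e-5) {
  u <- new.env(parent = emptyenv())
  K <- (cin %/% groups) * k * k
  u$W <- matrix(rnorm(cout * K, sd = sqrt(2 / K)), cout, K)
  u$b <- numeric(cout)
  u$kh <- as.integer(k); u$kw <- as.integer(k)
  u$stride <- as.integer(stride); u$pad <- as.integer(pad)
  u$groups <- as.integer(groups)
  u$cin <- as.integer(cin); u$cout <- as.integer(cout)
  u$act <- act; u$use_bn <- use_bn
  if (use_bn) {
    u$gamma <- rep(1, cout); u$beta <- numeric(cout)
    u$rmean <- numeric(cout); u$rvar <- rep(1, cout)
    u$bn_momentum <- bn_momentum; u$bn_eps <- bn_eps
  }
  u
}

# ReLU (when the unit has one) is fused into the BN kernels: the forward
# caches the post-activation output and the backward masks dy where it is
# zero.
.unit_fwd <- function(u, x, train) {
  y <- nn_conv_fwd(x, u$W, u$b, u$kh, u$kw, u$stride, u$pad, u$groups)
  cache <- list(x = x)
  if (u$use_bn) {
    r <- nn_bn_fwd(y, u$gamma, u$beta, u$rmean, u$rvar, u$bn_momentum,
                   u$bn_eps, train, u$act)
    if (train) {
      u$rmean <- as.numeric(r$rmean)
      u$rvar <- as.numeric(r$rvar)
    }
    y <- r$y
    cache$bn <- list(xhat = r$xhat, inv = as.numeric(r$inv), y = y)
  } else if (u$act) {
    cache$mask <- y > 0
    y <- y * cache$mask
  }
  list(y = y, cache = cache)
}

.unit_bwd <- function(u, dy, cache, need_dx = TRUE) {
  if (u$use_bn) {
    r <- nn_bn_bwd(cache$bn$xhat, cache$bn$inv, u$gamma, dy, cache$bn$y,
                   u$act)
    u$g_gamma <- u$g_gamma + as.numeric(r$dgamma)
    u$g_beta <- u$g_beta + as.numeric(r$dbeta)
    dy <- r$dx
  } else if (u$act) {
    dy <- dy * cache$mask
  }
  r <- nn_conv_bwd(cache$x, u$W, dy, u$kh, u$kw, u$stride, u$pad, u$groups,
                   need_dx)
  u$g_W <- u$g_W + r$dW
  u$g_b <- u$g_b + as.numeric(r$db)
  if (need_dx) r$dx else NULL
}

.PARAM_NAMES <- c("W", "b", "gamma", "beta")

.unit_zero_grads <- function(u) {
  for (p in .PARAM_NAMES) {
    if (!is.null(u[[p]])) u[[paste0("g_", p)]] <- u[[p]] * 0
  }
  invisible(u)
}

.unit_adam_step <- function(u, lr, t, beta1 = 0.9, beta2 = 0.999,
                            eps = 1e-8) {
  for (p in .PARAM_NAMES) {
    if (is.null(u[[p]])) next
    g <- u[[paste0("g_", p)]]
    mkey <- paste0("adam_m_", p); vkey <- paste0("adam_v_", p)
    if (is.null(u[[mkey]])) { u[[mkey]] <- g * 0; u[[vkey]] <- g * 0 }
    u[[mkey]] <- beta1 * u[[mkey]] + (1 - beta1) * g
    u[[vkey]] <- beta2 * u[[vkey]] + (1 - beta2) * g * g
    mhat <- u[[mkey]] / (1 - beta1^t)
    vhat <- u[[vkey]] / (1 - beta2^t)
    u[[p]] <- u[[p]] - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(u)
}

.concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(all(da[c(1, 2, 4)] == db[c(1, 2, 4)]))
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

.global_mean_pool <- function(x) {
  d <- dim(x)
  m <- x
  dim(m) <- c(d[1] * d[2], d[3] * d[4])
  matrix(colMeans(m), d[3], d[4])
}

.global_mean_pool_bwd <- function(dfeat, d) {
  array(rep(as.vector(dfeat), each = d[1] * d[2]) / (d[1] * d[2]), dim = d)
}
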