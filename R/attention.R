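# Cross-sequence attention: each sequence's feature vector queries keys and
# values derived from all three sequences.  Multi-head with H = 2 by
# default; heads are evaluated sequentially and, when cascading is on, the
# d_h-slot of the running feature is incremented by the head output before
# the next head's projections are read.  The attended vectors stay in R^d.

#' Attention specification
#'
#' @param d Feature dimension (default 512); must be divisible by `H`.
#' @param H Number of attention heads (default 2).
#' @param residual_policy `"ADD"` (attended = input + concatenated head
#'   outputs, default) or `"REPLACE"`.
#' @param cascade Add each head's output back into the running feature
#'   before the next head reads its projections (default `TRUE`); `FALSE`
#'   gives the plain parallel-head variant.
#' @param share_projections Share one set of Q/K/V projection matrices
#'   across the three sequence slots (default `FALSE`: per-slot
#'   projections).
#' @return An `attention_spec`; `$dh` is `d / H`.
#' @export
attention_spec <- function(d = 512L, H = 2L,
                           residual_policy = c("ADD", "REPLACE"),
                           cascade = TRUE, share_projections = FALSE) {
  residual_policy <- match.arg(residual_policy)
  if (d %% H != 0) stopf("feature dim d=%d is not divisible by H=%d heads", d, H)
  structure(list(d = as.integer(d), H = as.integer(H),
                 dh = as.integer(d / H), residual_policy = residual_policy,
                 cascade = cascade, share_projections = share_projections),
            class = "attention_spec")
}

#' Initialise attention projections
#'
#' One learnable d x d matrix per projection (query/key/value) per sequence
#' slot (or one shared set when `share_projections`).
#'
#' @param spec An [attention_spec()].
#' @return Parameter list `Wq`, `Wk`, `Wv`, each a list of three d x d
#'   matrices (aliased when shared).
#' @export
attention_init <- function(spec) {
  d <- spec$d
  mk <- function() matrix(rnorm(d * d, sd = 1 / sqrt(d)), d, d)
  if (spec$share_projections) {
    q <- mk(); k <- mk(); v <- mk()
    list(Wq = list(q, q, q), Wk = list(k, k, k), Wv = list(v, v, v))
  } else {
    list(Wq = list(mk(), mk(), mk()), Wk = list(mk(), mk(), mk()),
         Wv = list(mk(), mk(), mk()))
  }
}

slot_cols <- function(h, dh) ((h - 1L) * dh + 1L):(h * dh)

#' Cross-sequence attention forward pass (batched)
#'
#' @param params Output of [attention_init()].
#' @param spec An [attention_spec()].
#' @param hs List of three N x d matrices (one per sequence).
#' @return list with `hhat` (three attended N x d matrices), `probs`
#'   (attention probabilities, `probs[[h]][[i]]` an N x 3 row-stochastic
#'   matrix), and `cache` for [attention_backward()].
#' @export
attention_forward <- function(params, spec, hs) {
  for (m in hs) assert_finite(m, "attention inputs")
  d <- spec$d; H <- spec$H; dh <- spec$dh
  if (any(vapply(hs, ncol, 1L) != d)) stopf("inputs must have %d columns", d)
  r <- hs
  head_out <- vector("list", H)
  probs <- vector("list", H)
  head_cache <- vector("list", H)
  for (h in seq_len(H)) {
    cols <- slot_cols(h, dh)
    Q <- K <- V <- vector("list", 3)
    for (i in 1:3) {
      Q[[i]] <- r[[i]] %*% params$Wq[[i]][, cols, drop = FALSE]
      K[[i]] <- r[[i]] %*% params$Wk[[i]][, cols, drop = FALSE]
      V[[i]] <- r[[i]] %*% params$Wv[[i]][, cols, drop = FALSE]
    }
    ho <- vector("list", 3); pr <- vector("list", 3); sc <- vector("list", 3)
    for (i in 1:3) {
      score <- sapply(1:3, function(j) rowSums(Q[[i]] * K[[j]])) / sqrt(dh)
      score <- matrix(score, ncol = 3)
      p <- exp(score - apply(score, 1, max))
      p <- p / rowSums(p)
      out <- matrix(0, nrow(p), dh)
      for (j in 1:3) out <- out + p[, j] * V[[j]]
      ho[[i]] <- out; pr[[i]] <- p; sc[[i]] <- score
    }
    head_cache[[h]] <- list(r = r, Q = Q, K = K, V = V, prob = pr)
    head_out[[h]] <- ho
    probs[[h]] <- pr
    if (spec$cascade)
      for (i in 1:3) r[[i]][, cols] <- r[[i]][, cols] + ho[[i]]
  }
  hhat <- vector("list", 3)
  for (i in 1:3) {
    concat <- do.call(cbind, lapply(seq_len(H), function(h) head_out[[h]][[i]]))
    hhat[[i]] <- if (spec$residual_policy == "ADD") hs[[i]] + concat else concat
  }
  list(hhat = hhat, probs = probs,
       cache = list(hs = hs, head_cache = head_cache, spec = spec,
                    params = params))
}

#' Cross-sequence attention backward pass
#'
#' @param cache `cache` from [attention_forward()].
#' @param dhhat List of three N x d gradients w.r.t. the attended vectors.
#' @return list with `dh` (gradients w.r.t. the three inputs) and `grads`
#'   (`Wq`, `Wk`, `Wv` gradient lists; shared-projection gradients are
#'   summed across slots by the optimiser via aliasing-aware updates).
#' @export
attention_backward <- function(cache, dhhat) {
  spec <- cache$spec; params <- cache$params
  d <- spec$d; H <- spec$H; dh <- spec$dh
  N <- nrow(cache$hs[[1]])
  zero_d <- function() matrix(0, N, d)
  dWq <- lapply(1:3, function(i) matrix(0, d, d))
  dWk <- lapply(1:3, function(i) matrix(0, d, d))
  dWv <- lapply(1:3, function(i) matrix(0, d, d))
  dr <- lapply(1:3, function(i) zero_d())       # grad w.r.t. r after last head
  for (h in rev(seq_len(H))) {
    cols <- slot_cols(h, dh)
    hc <- cache$head_cache[[h]]
    dQ <- lapply(1:3, function(i) matrix(0, N, dh))
    dK <- lapply(1:3, function(i) matrix(0, N, dh))
    dV <- lapply(1:3, function(i) matrix(0, N, dh))
    for (i in 1:3) {
      dho <- dhhat[[i]][, cols, drop = FALSE]
      if (spec$cascade) dho <- dho + dr[[i]][, cols, drop = FALSE]
      p <- hc$prob[[i]]
      dp <- sapply(1:3, function(j) rowSums(dho * hc$V[[j]]))
      dp <- matrix(dp, ncol = 3)
      for (j in 1:3) dV[[j]] <- dV[[j]] + p[, j] * dho
      dscore <- p * (dp - rowSums(p * dp))       # softmax backward, per row
      for (j in 1:3) {
        dQ[[i]] <- dQ[[i]] + dscore[, j] * hc$K[[j]] / sqrt(dh)
        dK[[j]] <- dK[[j]] + dscore[, j] * hc$Q[[i]] / sqrt(dh)
      }
    }
    for (i in 1:3) {
      dWq[[i]][, cols] <- dWq[[i]][, cols] + t(hc$r[[i]]) %*% dQ[[i]]
      dWk[[i]][, cols] <- dWk[[i]][, cols] + t(hc$r[[i]]) %*% dK[[i]]
      dWv[[i]][, cols] <- dWv[[i]][, cols] + t(hc$r[[i]]) %*% dV[[i]]
      dr[[i]] <- dr[[i]] +
        dQ[[i]] %*% t(params$Wq[[i]][, cols, drop = FALSE]) +
        dK[[i]] %*% t(params$Wk[[i]][, cols, drop = FALSE]) +
        dV[[i]] %*% t(params$Wv[[i]][, cols, drop = FALSE])
    }
  }
  dhs <- vector("list", 3)
  for (i in 1:3) {
    g <- dr[[i]]
    if (spec$residual_policy == "ADD") g <- g + dhhat[[i]]
    dhs[[i]] <- g
  }
  if (spec$share_projections) {
    sq <- Reduce(`+`, dWq); sk <- Reduce(`+`, dWk); sv <- Reduce(`+`, dWv)
    dWq <- list(sq, sq, sq); dWk <- list(sk, sk, sk); dWv <- list(sv, sv, sv)
  }
  list(dh = dhs, grads = list(Wq = dWq, Wk = dWk, Wv = dWv))
}

#' Cross-sequence attention on single feature vectors
#'
#' Convenience wrapper around [attention_forward()] for three d-dim
#' vectors, returning the three attended vectors and the per-head
#' attention probabilities.
#'
#' @param h1,h2,h3 Numeric d-dim vectors.
#' @param params Output of [attention_init()].
#' @param spec An [attention_spec()].
#' @return list with `hhat` (list of three d-dim vectors) and `probs`.
#' @export
cross_sequence_attention <- function(h1, h2, h3, params, spec) {
  hs <- lapply(list(h1, h2, h3), function(v) matrix(v, nrow = 1))
  out <- attention_forward(params, spec, hs)
  list(hhat = lapply(out$hhat, as.numeric), probs = out$probs)
}
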