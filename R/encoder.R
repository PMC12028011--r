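# VGG-style 3D convolutional encoder.  Each stage applies
# [conv 3x3x3 -> batch norm -> ReLU] x blocks, then dropout, then a
# stride-2 max pool between stages; the terminal GlobalMaxAvgPool yields a
# feature vector whose length equals the last stage width regardless of
# input spatial size (adaptive-pooling contract).

#' Encoder architecture specification
#'
#' Defaults follow the full-scale model: stage widths
#' `c(64, 128, 256, 512)`, blocks per stage `c(1, 2, 3, 4)`, dropout 0.5,
#' giving a 512-dimensional feature vector.  All fields are configurable so
#' the identical code runs a desk-scale variant in tests.
#'
#' @param stage_widths Feature maps per stage.
#' @param blocks_per_stage Number of conv blocks per stage; same length as
#'   `stage_widths`.
#' @param dropout Dropout rate applied once per stage, after its blocks.
#' @param in_channels 1 (per-sequence encoders) or 3 (stacked channels).
#' @return An `encoder_spec`; `$feature_dim` equals the last stage width.
#' @export
encoder_spec <- function(stage_widths = c(64L, 128L, 256L, 512L),
                         blocks_per_stage = c(1L, 2L, 3L, 4L),
                         dropout = 0.5, in_channels = 1L) {
  if (length(stage_widths) != length(blocks_per_stage))
    stopf("stage_widths and blocks_per_stage must have equal length")
  if (!in_channels %in% c(1L, 3L)) stopf("in_channels must be 1 or 3")
  structure(list(stage_widths = as.integer(stage_widths),
                 blocks_per_stage = as.integer(blocks_per_stage),
                 dropout = dropout, in_channels = as.integer(in_channels),
                 feature_dim = as.integer(stage_widths[length(stage_widths)])),
            class = "encoder_spec")
}

#' Initialise encoder parameters
#'
#' Kaiming initialisation for convolutions, unit gamma / zero beta for
#' batch norm.  Call inside [with_seed()] (or after `set.seed`) for
#' reproducibility.
#'
#' @param spec An [encoder_spec()].
#' @return A parameter list (`$params`) plus batch-norm running state
#'   (`$state`).
#' @export
encoder_init <- function(spec) {
  params <- list(); state <- list()
  c_in <- spec$in_channels
  for (s in seq_along(spec$stage_widths)) {
    width <- spec$stage_widths[s]
    for (b in seq_len(spec$blocks_per_stage[s])) {
      key <- sprintf("s%db%d", s, b)
      params[[key]] <- list(conv = conv3d_init(c_in, width),
                            bn = bn_init(width))
      state[[key]] <- list()
      c_in <- width
    }
  }
  list(spec = spec, params = params, state = state)
}

min_input_size <- function(spec) 2^(length(spec$stage_widths) - 1L)

#' Encoder forward pass
#'
#' @param enc An initialised encoder (see [encoder_init()]).
#' @param x Batch tensor dim `c(Z, Y, X, in_channels, N)`.
#' @param train Training mode (batch-norm batch statistics + dropout).
#' @return list with `feat` (N x feature_dim matrix), updated `state`, and
#'   `cache` for the backward pass.
#' @export
encoder_forward <- function(enc, x, train = FALSE) {
  spec <- enc$spec
  d <- dim(x)
  if (d[4] != spec$in_channels)
    stopf("input has %d channels, spec expects %d", d[4], spec$in_channels)
  mis <- min_input_size(spec)
  if (any(d[1:3] < mis))
    stopf("input spatial dims (%s) too small for the downsampling ladder; every axis must be >= %d",
          paste(d[1:3], collapse = "x"), mis)
  caches <- list()
  n_stage <- length(spec$stage_widths)
  for (s in seq_len(n_stage)) {
    for (b in seq_len(spec$blocks_per_stage[s])) {
      key <- sprintf("s%db%d", s, b)
      p <- enc$params[[key]]
      cv <- conv3d_fwd(p$conv, x)
      bn <- bn_fwd(p$bn, enc$state[[key]], cv$out, train)
      enc$state[[key]] <- bn$state
      rl <- relu_fwd(bn$out)
      caches[[key]] <- list(conv = cv$cache, bn = bn$cache, relu = rl$cache)
      x <- rl$out
    }
    dp <- dropout_fwd(x, spec$dropout, train)
    caches[[sprintf("drop%d", s)]] <- dp$cache
    x <- dp$out
    if (s < n_stage) {
      mp <- maxpool_fwd(x)
      caches[[sprintf("pool%d", s)]] <- mp$cache
      x <- mp$out
    }
  }
  gp <- gmap_fwd(x)
  caches$gmap <- gp$cache
  list(feat = gp$out, state = enc$state, cache = caches)
}

#' Encoder backward pass
#'
#' @param enc The encoder used in the forward pass.
#' @param cache `cache` from [encoder_forward()].
#' @param dfeat Gradient w.r.t. the feature matrix (N x feature_dim).
#' @return list with `dx` (gradient w.r.t. the input tensor) and `grads`
#'   mirroring `enc$params`.
#' @export
encoder_backward <- function(enc, cache, dfeat) {
  spec <- enc$spec
  grads <- list()
  dx <- gmap_bwd(cache$gmap, dfeat)
  n_stage <- length(spec$stage_widths)
  for (s in rev(seq_len(n_stage))) {
    if (s < n_stage) dx <- maxpool_bwd(cache[[sprintf("pool%d", s)]], dx)
    dx <- dropout_bwd(cache[[sprintf("drop%d", s)]], dx)
    for (b in rev(seq_len(spec$blocks_per_stage[s]))) {
      key <- sprintf("s%db%d", s, b)
      cc <- cache[[key]]
      dx <- relu_bwd(cc$relu, dx)
      bn <- bn_bwd(cc$bn, dx)
      cv <- conv3d_bwd(cc$conv, bn$dx)
      grads[[key]] <- list(conv = cv$grads, bn = bn$grads)
      dx <- cv$dx
    }
  }
  list(dx = dx, grads = grads)
}
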