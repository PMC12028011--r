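# The three classification architectures.
#
#   3CH : one encoder, three stacked input channels       -> d features
#   ME  : three per-sequence encoders, concatenated       -> 3d features
#   MECA: three encoders + cross-sequence attention       -> 3d features
#
# Clinical scalars (age, PSA, PSA density, each scaled to [-1,1]) are
# concatenated after the imaging features, never fed to the attention; the
# fused vector goes through a single linear layer to one logit.  At the
# full-scale defaults (d = 512, 3 clinical scalars) the ME/MECA fused
# representation has length 3*512 + 3 = 1539.

#' Fusion model specification
#'
#' @param family `"3CH"`, `"ME"` or `"MECA"`.
#' @param encoder An [encoder_spec()]; for `3CH` its `in_channels` is
#'   forced to 3, otherwise to 1.
#' @param use_clinical Concatenate clinical scalars before the classifier.
#' @param n_clinical Number of clinical scalars (default 3: age, PSA, PSAD).
#' @param attention An [attention_spec()] (MECA only); its `d` is aligned
#'   to the encoder feature dim.
#' @param share_encoders Use one shared encoder for the three sequences
#'   (ME/MECA ablation; default `FALSE`, per-sequence encoders).
#' @return A `fusion_model_spec`; `$fused_dim` is the classifier input
#'   length.
#' @export
fusion_model_spec <- function(family = c("MECA", "ME", "3CH"),
                              encoder = encoder_spec(),
                              use_clinical = TRUE, n_clinical = 3L,
                              attention = NULL, share_encoders = FALSE) {
  family <- match.arg(family)
  encoder$in_channels <- if (family == "3CH") 3L else 1L
  d <- encoder$feature_dim
  n_clin <- if (use_clinical) as.integer(n_clinical) else 0L
  fused <- if (family == "3CH") d + n_clin else 3L * d + n_clin
  if (family == "MECA") {
    attention <- attention %||% attention_spec(d = d)
    if (attention$d != d)
      attention <- attention_spec(d = d, H = attention$H,
                                  residual_policy = attention$residual_policy,
                                  cascade = attention$cascade,
                                  share_projections = attention$share_projections)
  } else attention <- NULL
  structure(list(family = family, encoder = encoder,
                 use_clinical = use_clinical, n_clinical = n_clin,
                 attention = attention, share_encoders = share_encoders,
                 fused_dim = fused),
            class = "fusion_model_spec")
}

#' Initialise a fusion model
#'
#' @param spec A [fusion_model_spec()].
#' @param seed Integer seed controlling weight initialisation.
#' @return A `fusion_model` with encoders, optional attention projections,
#'   and the linear classifier head.
#' @export
fusion_init <- function(spec, seed = 0L) {
  with_seed(seed, {
    model <- list(spec = spec)
    if (spec$family == "3CH") {
      model$encoders <- list(encoder_init(spec$encoder))
    } else if (spec$share_encoders) {
      enc <- encoder_init(spec$encoder)
      model$encoders <- list(enc)
    } else {
      model$encoders <- list(encoder_init(spec$encoder),
                             encoder_init(spec$encoder),
                             encoder_init(spec$encoder))
    }
    if (spec$family == "MECA") model$attention <- attention_init(spec$attention)
    model$classifier <- linear_init(spec$fused_dim, 1L)
    model
  })
}

# Assemble the clinical matrix (N x n_clinical) from preprocessed cases.
clinical_matrix <- function(cases, n_clinical) {
  t(vapply(cases, function(cs) {
    v <- c(cs$clinical$age_norm, cs$clinical$psa_norm, cs$clinical$psad_norm)
    v <- v[seq_len(n_clinical)]
    v[is.na(v)] <- 0
    v
  }, numeric(n_clinical)))
}

# Stack case volumes into input tensors for a model family.
#   3CH -> one tensor (Z,Y,X,3,N); ME/MECA -> list of three (Z,Y,X,1,N).
case_tensors <- function(cases, family) {
  d <- dim(cases[[1]]$volumes$T2W$voxels)
  N <- length(cases)
  if (family == "3CH") {
    x <- array(0, dim = c(d, 3L, N))
    for (n in seq_len(N))
      for (k in seq_along(SEQUENCE_KINDS))
        x[, , , k, n] <- cases[[n]]$volumes[[SEQUENCE_KINDS[k]]]$voxels
    x
  } else {
    lapply(SEQUENCE_KINDS, function(kind) {
      x <- array(0, dim = c(d, 1L, N))
      for (n in seq_len(N)) x[, , , 1L, n] <- cases[[n]]$volumes[[kind]]$voxels
      x
    })
  }
}

#' Fusion model forward pass
#'
#' @param model A [fusion_init()] model.
#' @param inputs Output of `case_tensors` for the model family (a tensor
#'   for `3CH`, a list of three tensors otherwise), or a list of
#'   preprocessed [bpmri_case()]s.
#' @param clinical Optional N x n_clinical matrix (required when the spec
#'   uses clinical variables and `inputs` is not a case list).
#' @param train Training mode.
#' @return list with `prob` (per-case probabilities in (0,1)), `logit`,
#'   `model` (updated batch-norm state) and `cache`.
#' @export
fusion_forward <- function(model, inputs, clinical = NULL, train = FALSE) {
  spec <- model$spec
  if (is.list(inputs) && length(inputs) && inherits(inputs[[1]], "bpmri_case")) {
    if (spec$use_clinical && is.null(clinical))
      clinical <- clinical_matrix(inputs, spec$n_clinical)
    inputs <- case_tensors(inputs, spec$family)
  }
  cache <- list()
  if (spec$family == "3CH") {
    ef <- encoder_forward(model$encoders[[1]], inputs, train)
    model$encoders[[1]]$state <- ef$state
    feats <- ef$feat
    cache$enc <- list(ef$cache)
  } else {
    hs <- vector("list", 3); cache$enc <- vector("list", 3)
    for (i in 1:3) {
      enc_i <- if (spec$share_encoders) model$encoders[[1]] else model$encoders[[i]]
      ef <- encoder_forward(enc_i, inputs[[i]], train)
      if (spec$share_encoders) model$encoders[[1]]$state <- ef$state
      else model$encoders[[i]]$state <- ef$state
      hs[[i]] <- ef$feat
      cache$enc[[i]] <- ef$cache
    }
    if (spec$family == "MECA") {
      at <- attention_forward(model$attention, spec$attention, hs)
      cache$att <- at$cache
      hs <- at$hhat
    }
    feats <- do.call(cbind, hs)
  }
  if (spec$use_clinical) {
    if (is.null(clinical)) stopf("clinical matrix required (use_clinical = TRUE)")
    feats <- cbind(feats, clinical)
  }
  lin <- linear_fwd(model$classifier, feats)
  cache$lin <- lin$cache
  cache$inputs <- inputs
  logit <- as.numeric(lin$out)
  list(prob = sigmoid(logit), logit = logit, model = model, cache = cache)
}

#' Fusion model backward pass
#'
#' @param model The model used in the forward pass.
#' @param cache `cache` from [fusion_forward()].
#' @param dlogit Gradient of the loss w.r.t. the logits (length N).
#' @return Gradient list mirroring the model parameter structure
#'   (`encoders`, optional `attention`, `classifier`).
#' @export
fusion_backward <- function(model, cache, dlogit) {
  spec <- model$spec
  lb <- linear_bwd(cache$lin, matrix(dlogit, ncol = 1))
  grads <- list(classifier = lb$grads)
  dfeat <- lb$dx
  if (spec$use_clinical && spec$n_clinical > 0)
    dfeat <- dfeat[, seq_len(ncol(dfeat) - spec$n_clinical), drop = FALSE]
  if (spec$family == "3CH") {
    eb <- encoder_backward(model$encoders[[1]], cache$enc[[1]], dfeat)
    grads$encoders <- list(eb$grads)
  } else {
    d <- spec$encoder$feature_dim
    dhs <- lapply(1:3, function(i)
      dfeat[, ((i - 1) * d + 1):(i * d), drop = FALSE])
    if (spec$family == "MECA") {
      ab <- attention_backward(cache$att, dhs)
      grads$attention <- ab$grads
      dhs <- ab$dh
    }
    if (spec$share_encoders) {
      acc <- NULL
      for (i in 1:3) {
        eb <- encoder_backward(model$encoders[[1]], cache$enc[[i]], dhs[[i]])
        acc <- if (is.null(acc)) eb$grads else add_grads(acc, eb$grads)
      }
      grads$encoders <- list(acc)
    } else {
      grads$encoders <- lapply(1:3, function(i)
        encoder_backward(model$encoders[[i]], cache$enc[[i]], dhs[[i]])$grads)
    }
  }
  grads
}

# Recursively add two parameter-shaped gradient lists.
add_grads <- function(a, b) {
  if (is.numeric(a)) return(a + b)
  for (k in names(a)) a[[k]] <- add_grads(a[[k]], b[[k]])
  a
}

#' Predict probabilities for preprocessed cases
#'
#' Evaluation-mode forward pass.
#'
#' @param model A trained [fusion_init()] model.
#' @param cases List of preprocessed [bpmri_case()]s.
#' @return Numeric vector of P(PCa) per case.
#' @export
predict_cases <- function(model, cases) {
  fusion_forward(model, cases, train = FALSE)$prob
}
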