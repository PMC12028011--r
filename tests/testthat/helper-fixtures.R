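# Shared fixtures: tiny volumes, desk-scale specs, numerical gradient
# helper.  Everything is generated in code; nothing is read from disk
# except files the tests themselves write to tempdir().

tiny_volume <- function(dim = c(4L, 6L, 6L), spacing = c(3, 1, 1),
                        kind = "T2W", case_id = "case1", seed = 1) {
  with_seed(seed, sequence_volume(array(rnorm(prod(dim)), dim), spacing,
                                  kind, case_id))
}

tiny_case <- function(case_id = "case1", label = 1L, dim = c(4L, 6L, 6L),
                      seed = 1, with_mask = TRUE) {
  vols <- list(
    T2W = tiny_volume(dim, kind = "T2W", case_id = case_id, seed = seed),
    DWI_HIGH_B = tiny_volume(dim, kind = "DWI_HIGH_B", case_id = case_id,
                             seed = seed + 1),
    ADC = tiny_volume(dim, kind = "ADC", case_id = case_id, seed = seed + 2))
  mask <- NULL
  if (with_mask) {
    mask <- array(0, dim)
    mask[2:3, 2:5, 2:5] <- 1
  }
  clin <- clinical_record(age = 60 + (seed %% 20), psa = 5 + seed %% 7,
                          site = "SiteA", field_strength = 3.0,
                          manufacturer = "VendorX")
  bpmri_case(case_id, vols, clin, label, gland_mask = mask)
}

desk_encoder <- function(widths = c(4L, 8L), blocks = c(1L, 1L), dropout = 0)
  encoder_spec(stage_widths = widths, blocks_per_stage = blocks,
               dropout = dropout)

# Brute-force pair-counting AUC: the independent oracle for auc_score.
auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

# central-difference gradient of scalar f at x (vectorised over components)
numeric_gradient <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# Brute-force cross-sequence attention oracle: scalar loops, written
# directly from the score/softmax/weighted-sum equations, independent of
# the vectorised implementation.  Single sample (vectors), cascade + ADD.
attention_oracle <- function(h1, h2, h3, params, d, H,
                             residual = c("ADD", "REPLACE"), cascade = TRUE) {
  residual <- match.arg(residual)
  dh <- d / H
  hs <- list(h1, h2, h3)
  r <- hs
  head_outputs <- lapply(1:3, function(i) matrix(NA_real_, H, dh))
  probs <- array(NA_real_, c(H, 3, 3))
  for (h in seq_len(H)) {
    slot <- ((h - 1) * dh + 1):(h * dh)
    Q <- K <- V <- list()
    for (i in 1:3) {
      Qf <- rep(0, d); Kf <- rep(0, d); Vf <- rep(0, d)
      for (col in 1:d) for (row in 1:d) {
        Qf[col] <- Qf[col] + r[[i]][row] * params$Wq[[i]][row, col]
        Kf[col] <- Kf[col] + r[[i]][row] * params$Wk[[i]][row, col]
        Vf[col] <- Vf[col] + r[[i]][row] * params$Wv[[i]][row, col]
      }
      Q[[i]] <- Qf[slot]; K[[i]] <- Kf[slot]; V[[i]] <- Vf[slot]
    }
    new_r <- r
    for (i in 1:3) {
      alpha <- rep(0, 3)
      for (j in 1:3) {
        s <- 0
        for (t in seq_len(dh)) s <- s + Q[[i]][t] * K[[j]][t]
        alpha[j] <- s / sqrt(dh)
      }
      e <- exp(alpha)
      p <- e / sum(e)
      probs[h, i, ] <- p
      ho <- rep(0, dh)
      for (j in 1:3) for (t in seq_len(dh)) ho[t] <- ho[t] + p[j] * V[[j]][t]
      head_outputs[[i]][h, ] <- ho
      if (cascade) new_r[[i]][slot] <- new_r[[i]][slot] + ho
    }
    r <- new_r
  }
  hhat <- lapply(1:3, function(i) {
    concat <- as.vector(t(head_outputs[[i]]))
    if (residual == "ADD") hs[[i]] + concat else concat
  })
  list(hhat = hhat, probs = probs)
}
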