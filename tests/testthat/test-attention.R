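test_that("identical inputs with shared projections give uniform attention", {
  spec <- attention_spec(d = 8, H = 2, share_projections = TRUE)
  params <- with_seed(1, attention_init(spec))
  h <- with_seed(2, rnorm(8))
  out <- cross_sequence_attention(h, h, h, params, spec)
  for (hd in seq_len(spec$H))
    for (i in 1:3)
      expect_equal(unname(out$probs[[hd]][[i]][1, ]), rep(1 / 3, 3),
                   tolerance = 1e-12)
})

test_that("attention probabilities are a distribution for any input", {
  for (seed in 1:20) {
    d <- sample(c(4L, 8L), 1)
    spec <- attention_spec(d = d, H = sample(c(1L, 2L), 1))
    params <- with_seed(seed, attention_init(spec))
    hs <- with_seed(seed + 100, lapply(1:3, function(i) matrix(rnorm(2 * d), 2, d)))
    out <- attention_forward(params, spec, hs)
    for (hd in seq_len(spec$H)) for (i in 1:3) {
      p <- out$probs[[hd]][[i]]
      expect_true(all(p >= 0))
      expect_equal(unname(rowSums(p)), rep(1, nrow(p)), tolerance = 1e-12)
    }
    for (i in 1:3) expect_equal(dim(out$hhat[[i]]), c(2L, d))
  }
})

test_that("vectorized attention equals the brute-force oracle (>=100 cases)", {
  n_checked <- 0L
  for (d in c(2L, 4L, 8L)) for (H in c(1L, 2L)) {
    if (d %% H != 0) next
    for (rep_i in 1:12) for (casc in c(TRUE, FALSE)) {
      seed <- d * 1000 + H * 100 + rep_i * 2 + casc
      spec <- attention_spec(d = d, H = H, cascade = casc)
      params <- with_seed(seed, attention_init(spec))
      hs <- with_seed(seed + 1, lapply(1:3, function(i) rnorm(d)))
      fast <- cross_sequence_attention(hs[[1]], hs[[2]], hs[[3]], params, spec)
      slow <- attention_oracle(hs[[1]], hs[[2]], hs[[3]], params, d, H,
                               cascade = casc)
      for (i in 1:3)
        expect_lt(max(abs(fast$hhat[[i]] - slow$hhat[[i]])), 1e-6)
      for (hd in seq_len(H)) for (i in 1:3)
        expect_lt(max(abs(fast$probs[[hd]][[i]][1, ] - slow$probs[hd, i, ])),
                  1e-9)
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 100L)
})

test_that("small integer-weight case matches the oracle exactly", {
  d <- 4L; H <- 2L
  spec <- attention_spec(d = d, H = H)
  params <- list(Wq = list(), Wk = list(), Wv = list())
  vals <- c(1, -1, 2, 0)
  for (i in 1:3) {
    params$Wq[[i]] <- matrix(vals[(seq_len(d * d) + i) %% 4 + 1], d, d) / 2
    params$Wk[[i]] <- matrix(vals[(seq_len(d * d) + 2 * i) %% 4 + 1], d, d) / 2
    params$Wv[[i]] <- matrix(vals[(seq_len(d * d) + 3 * i) %% 4 + 1], d, d) / 2
  }
  hs <- list(c(1, 0, -1, 2), c(0, 1, 1, -1), c(2, -2, 0, 1))
  fast <- cross_sequence_attention(hs[[1]], hs[[2]], hs[[3]], params, spec)
  slow <- attention_oracle(hs[[1]], hs[[2]], hs[[3]], params, d, H)
  for (i in 1:3) expect_lt(max(abs(fast$hhat[[i]] - slow$hhat[[i]])), 1e-6)
})

test_that("scale sanity: keys scaled by c scale pre-softmax scores by c", {
  d <- 4L
  spec <- attention_spec(d = d, H = 1L, cascade = FALSE)
  params <- with_seed(3, attention_init(spec))
  hs <- with_seed(4, lapply(1:3, function(i) matrix(rnorm(d), 1, d)))
  score_of <- function(par) {
    Q <- hs[[1]] %*% par$Wq[[1]]
    sapply(1:3, function(j) sum(Q * (hs[[j]] %*% par$Wk[[j]]))) / sqrt(d)
  }
  s1 <- score_of(params)
  p2 <- params; for (j in 1:3) p2$Wk[[j]] <- 3 * p2$Wk[[j]]
  expect_equal(score_of(p2), 3 * s1, tolerance = 1e-12)
  # d_h = 1: the scaled score reduces to a plain dot product
  spec1 <- attention_spec(d = 1L, H = 1L)
  par1 <- list(Wq = list(matrix(1), matrix(1), matrix(1)),
               Wk = list(matrix(1), matrix(1), matrix(1)),
               Wv = list(matrix(1), matrix(1), matrix(1)))
  out <- cross_sequence_attention(2, 3, 5, par1, spec1)
  sc <- c(2 * 2, 2 * 3, 2 * 5)  # query 2 against keys 2,3,5
  expect_equal(unname(out$probs[[1]][[1]][1, ]), exp(sc) / sum(exp(sc)),
               tolerance = 1e-12)
})

test_that("attention errors on invalid dims and non-finite input", {
  expect_error(attention_spec(d = 6, H = 4), "divisible")
  spec <- attention_spec(d = 4, H = 2)
  params <- with_seed(5, attention_init(spec))
  bad <- matrix(c(1, NA, 0, 1), 1, 4)
  expect_error(attention_forward(params, spec, list(bad, bad, bad)),
               "non-finite")
})

test_that("attention backward matches numerical gradients", {
  for (casc in c(TRUE, FALSE)) {
    spec <- attention_spec(d = 4, H = 2, cascade = casc)
    params <- with_seed(6, attention_init(spec))
    hs <- with_seed(7, lapply(1:3, function(i) matrix(rnorm(2 * 4), 2, 4)))
    dh <- with_seed(8, lapply(1:3, function(i) matrix(rnorm(2 * 4), 2, 4)))
    fw <- attention_forward(params, spec, hs)
    bk <- attention_backward(fw$cache, dh)
    loss_h <- function(v, i) {
      h2 <- hs; h2[[i]] <- matrix(v, 2, 4)
      o <- attention_forward(params, spec, h2)
      sum(mapply(function(a, b) sum(a * b), o$hhat, dh))
    }
    for (i in 1:3) {
      ng <- numeric_gradient(function(v) loss_h(v, i), as.vector(hs[[i]]))
      expect_lt(max(abs(bk$dh[[i]] - matrix(ng, 2, 4))), 1e-6)
    }
    loss_w <- function(v, which, i) {
      p2 <- params; p2[[which]][[i]] <- matrix(v, 4, 4)
      o <- attention_forward(p2, spec, hs)
      sum(mapply(function(a, b) sum(a * b), o$hhat, dh))
    }
    for (w in c("Wq", "Wk", "Wv")) for (i in 1:3) {
      ng <- numeric_gradient(function(v) loss_w(v, w, i),
                             as.vector(params[[w]][[i]]))
      expect_lt(max(abs(bk$grads[[w]][[i]] - matrix(ng, 4, 4))), 1e-6)
    }
  }
})
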