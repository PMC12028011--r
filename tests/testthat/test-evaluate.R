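test_that("auc_score equals exhaustive pair counting, with ties", {
  expect_equal(auc_score(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc_pairs(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  for (seed in 1:25) {
    n <- with_seed(seed, sample(6:20, 1))
    scores <- with_seed(seed + 50, round(runif(n), 1))  # force ties
    labels <- with_seed(seed + 99, rbinom(n, 1, 0.5))
    if (length(unique(labels)) < 2) next
    expect_equal(auc_score(scores, labels), auc_pairs(scores, labels),
                 tolerance = 1e-12)
  }
  # perfect separation and random scores
  expect_equal(auc_score(c(1, 2, 3, 11, 12), c(0, 0, 0, 1, 1)), 1)
  big <- with_seed(1, list(s = runif(4000), l = rbinom(4000, 1, 0.5)))
  expect_lt(abs(auc_score(big$s, big$l) - 0.5), 0.03)
  expect_error(auc_score(1:3, c(1, 1, 1)), "both classes")
})

test_that("auc_score is invariant under strictly monotone transforms", {
  scores <- with_seed(2, runif(50))
  labels <- with_seed(3, rbinom(50, 1, 0.4))
  a <- auc_score(scores, labels)
  expect_equal(auc_score(qlogis(scores), labels), a)
  expect_equal(auc_score(scores^3 + 2, labels), a)
})

test_that("ppv_npv evaluates the prevalence equations with guards", {
  expect_equal(ppv_npv(0.9, 1, 0.3)$ppv, 1)       # no false positives
  expect_equal(ppv_npv(0.7, 0.7, 0.5)$ppv, 0.7)   # sens=spec at prev .5
  expect_equal(ppv_npv(0.7, 0.7, 0.5)$npv, 0.7)
  r <- ppv_npv(0.83, 0.71, 0.6133513)             # radiologists' row
  expect_equal(100 * r$npv, 72.47, tolerance = 0.02)
  expect_error(ppv_npv(1.2, 0.5, 0.5), "\\[0, 1\\]")
  expect_error(ppv_npv(0, 1, 1), "PPV undefined")
})

test_that("solve_prevalence inverts the PPV equation", {
  p <- solve_prevalence(0.83, 0.71, 0.8195)
  expect_equal(p, 0.613, tolerance = 1e-3)
  expect_equal(ppv_npv(0.83, 0.71, p)$ppv, 0.8195, tolerance = 1e-9)
  p2 <- solve_prevalence(0.87, 0.65, 0.7315)
  expect_equal(p2, 0.523, tolerance = 1e-3)
  expect_equal(ppv_npv(0.87, 0.65, p2)$ppv, 0.7315, tolerance = 1e-9)
  # identity case: sens = spec = ppv = s implies prevalence one half
  expect_equal(solve_prevalence(0.8, 0.8, 0.8), 0.5, tolerance = 1e-12)
  # property: round trip over random operating points
  for (seed in 1:30) {
    v <- with_seed(seed, runif(3, 0.05, 0.95))
    ppv0 <- ppv_npv(v[1], v[2], v[3])$ppv
    expect_equal(solve_prevalence(v[1], v[2], ppv0), v[3], tolerance = 1e-9)
  }
  # spec = 1 makes PPV = 1 for every prevalence: no unique inverse exists
  expect_error(solve_prevalence(0.9, 1, 1.0), "no prevalence")
})

test_that("bootstrap CI: determinism, degenerate case, coverage-ish", {
  scores <- with_seed(4, runif(60))
  labels <- with_seed(5, rbinom(60, 1, 0.5))
  ci1 <- bootstrap_auc_ci(scores, labels, n_boot = 300, seed = 11)
  ci2 <- bootstrap_auc_ci(scores, labels, n_boot = 300, seed = 11)
  expect_identical(as.numeric(ci1), as.numeric(ci2))
  # perfectly separated scores: interval collapses at 1
  ps <- c(rep(0.1, 10), rep(0.9, 10)); pl <- rep(c(0, 1), each = 10)
  expect_equal(as.numeric(bootstrap_auc_ci(ps, pl, n_boot = 100, seed = 1)),
               c(1, 1))
  # the interval contains the point AUC in the vast majority of datasets
  hits <- 0L; total <- 0L
  for (seed in 1:40) {
    s <- with_seed(seed + 200, runif(40))
    l <- with_seed(seed + 300, rbinom(40, 1, 0.5))
    if (length(unique(l)) < 2) next
    a <- auc_score(s, l)
    ci <- bootstrap_auc_ci(s, l, n_boot = 200, seed = seed)
    total <- total + 1L
    if (a >= ci[1] && a <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits / total, 0.9)
})

test_that("delong_test: identity, symmetry, consistency with auc_score", {
  scores <- with_seed(6, runif(80))
  labels <- with_seed(7, rbinom(80, 1, 0.5))
  same <- delong_test(scores, scores, labels)
  expect_equal(same$p_value, 1)
  other <- with_seed(8, runif(80))
  ab <- delong_test(scores, other, labels)
  ba <- delong_test(other, scores, labels)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
  expect_equal(ab$auc_a, auc_score(scores, labels), tolerance = 1e-12)
  expect_equal(ab$delta, auc_score(scores, labels) - auc_score(other, labels),
               tolerance = 1e-12)
  expect_error(delong_test(scores[1:10], other, labels), "paired")
})

test_that("delong p agrees with a paired permutation oracle", {
  # permutation oracle: swap the two models' scores per case at random;
  # the null distribution of the AUC difference is symmetric under swaps
  with_seed(9, {
    n <- 60
    labels <- rbinom(n, 1, 0.5)
    base <- runif(n)
    scores_a <- base + 0.5 * labels + rnorm(n, sd = 0.3)
    scores_b <- base + 0.25 * labels + rnorm(n, sd = 0.3)
  })
  dl <- delong_test(scores_a, scores_b, labels)
  obs <- abs(auc_score(scores_a, labels) - auc_score(scores_b, labels))
  n_perm <- 10000L
  cnt <- with_seed(10, {
    sum(vapply(seq_len(n_perm), function(b) {
      sw <- runif(length(labels)) < 0.5
      aa <- ifelse(sw, scores_b, scores_a)
      bb <- ifelse(sw, scores_a, scores_b)
      abs(auc_score(aa, labels) - auc_score(bb, labels)) >= obs - 1e-12
    }, logical(1)))
  })
  p_perm <- (cnt + 1) / (n_perm + 1)
  # Monte-Carlo + asymptotic tolerance
  expect_lt(abs(dl$p_value - p_perm),
            0.03 + 3 * sqrt(p_perm * (1 - p_perm) / n_perm))
})

test_that("eval_report is internally consistent with its confusion matrix", {
  for (seed in 1:5) {
    scores <- with_seed(seed + 400, runif(70))
    labels <- with_seed(seed + 500, rbinom(70, 1, 0.45))
    if (length(unique(labels)) < 2) next
    r <- eval_report(scores, labels, n_boot = 100, seed = seed)
    cm <- r$confusion
    expect_equal(unname(cm["TP"] + cm["FN"]), sum(labels == 1))
    expect_equal(unname(cm["TN"] + cm["FP"]), sum(labels == 0))
    # Eq-based PPV/NPV at empirical prevalence equal the empirical ratios
    expect_equal(r$ppv, unname(cm["TP"] / (cm["TP"] + cm["FP"])),
                 tolerance = 1e-9)
    expect_equal(r$npv, unname(cm["TN"] / (cm["TN"] + cm["FN"])),
                 tolerance = 1e-9)
    expect_true(all(c(r$sensitivity, r$specificity, r$ppv, r$npv) >= 0 &
                    c(r$sensitivity, r$specificity, r$ppv, r$npv) <= 1))
  }
  # transported prevalence changes predictive values but not discrimination
  scores <- with_seed(20, runif(80)); labels <- with_seed(21, rbinom(80, 1, 0.5))
  r1 <- eval_report(scores, labels, n_boot = 50, seed = 1)
  r2 <- eval_report(scores, labels, prevalence = 0.1, n_boot = 50, seed = 1)
  expect_equal(r1$auc, r2$auc)
  expect_false(isTRUE(all.equal(r1$ppv, r2$ppv)))
})
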