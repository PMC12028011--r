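fair_case <- function(id, label, psa = NA, age = NA, site = NA,
                      field = NA, vendor = NA) {
  cs <- tiny_case(id, label = label, dim = c(3L, 4L, 4L), seed = 1,
                  with_mask = FALSE)
  cs$clinical <- clinical_record(age = if (is.na(age)) 60 else age, psa = psa,
                                 site = site, field_strength = field,
                                 manufacturer = vendor)
  if (is.na(age)) cs$clinical$age <- NA_real_
  cs
}

test_that("PSA and age boundary handling is exactly as printed", {
  sc <- builtin_schemes()
  case_psa <- function(p) fair_case("x", 1L, psa = p)
  expect_equal(assign_stratum(case_psa(9.9), sc$psa_damico3), "[0-10)")
  expect_equal(assign_stratum(case_psa(10.0), sc$psa_damico3), "[10-20]")
  expect_equal(assign_stratum(case_psa(20.0), sc$psa_damico3), "[10-20]")
  expect_equal(assign_stratum(case_psa(20.01), sc$psa_damico3), ">20")
  expect_equal(assign_stratum(case_psa(3.9), sc$psa_damico4), "<4")
  expect_equal(assign_stratum(case_psa(4), sc$psa_damico4), "[4-10)")

  case_age <- function(a) fair_case("x", 1L, psa = 5, age = a)
  expect_equal(assign_stratum(case_age(75), sc$age_surgery), "<=75")
  expect_equal(assign_stratum(case_age(76), sc$age_surgery), ">75")
  expect_equal(assign_stratum(case_age(55), sc$age_screening), "55-65")
  expect_equal(assign_stratum(case_age(54.5), sc$age_screening), "<55")
  # cumulative scheme: 75-year-old is in >45,>55,>65 but not >75
  expect_setequal(assign_stratum(case_age(75), sc$age_cumulative),
                  c(">45", ">55", ">65"))
  expect_setequal(assign_stratum(case_age(78), sc$age_cumulative),
                  c(">45", ">55", ">65", ">75"))
  # distinct scheme: closed/open bounds as printed
  expect_equal(assign_stratum(case_age(55), sc$age_distinct), "[55-65]")
  expect_equal(assign_stratum(case_age(65), sc$age_distinct), "[55-65]")
  expect_equal(assign_stratum(case_age(65.5), sc$age_distinct), "(65-75]")
  expect_true(is.na(assign_stratum(case_age(80), sc$age_distinct)))
  # missing variable excludes the case
  expect_true(is.na(assign_stratum(fair_case("x", 1L, psa = NA),
                                   sc$psa_damico3)))
})

make_fair_cohort <- function(n_per_site = 120, seed = 1) {
  with_seed(seed, {
    cases <- list(); labels <- integer(); scores_a <- c(); scores_b <- c()
    i <- 0L
    for (site in c("SiteA", "SiteB")) {
      for (k in seq_len(n_per_site)) {
        i <- i + 1L
        lab <- rbinom(1, 1, 0.5)
        cases[[i]] <- fair_case(sprintf("f%03d", i), lab,
                                psa = exp(rnorm(1, 1.8, 0.7)),
                                age = round(runif(1, 46, 84)), site = site,
                                field = sample(c(1.5, 3), 1),
                                vendor = sample(c("VX", "VY"), 1))
        labels[i] <- lab
        scores_a[i] <- plogis(2.2 * lab + rnorm(1))
        scores_b[i] <- plogis(1.1 * lab + rnorm(1))
      }
    }
    list(cases = cases, labels = labels,
         scores = list(meca = scores_a, me = scores_b))
  })
}

test_that("per-stratum report has the expected shape and pairwise tests", {
  ch <- make_fair_cohort()
  schemes <- builtin_schemes()["provider"]
  rep <- per_stratum_report(ch$scores, ch$labels, ch$cases, schemes,
                            n_boot = 50, seed = 1)
  expect_equal(sort(unique(rep$table$stratum)), c("SiteA", "SiteB"))
  expect_equal(nrow(rep$table), 4L)            # 2 strata x 2 models
  expect_equal(nrow(rep$pairwise), 2L)         # one model pair per stratum
  expect_true(all(rep$table$lo <= rep$table$auc &
                  rep$table$auc <= rep$table$hi))
  expect_true(all(rep$pairwise$p_value >= 0 & rep$pairwise$p_value <= 1))
  expect_true(all(rep$pairwise$tier %in% c("", "*", "**", "***", "****")))
})

test_that("undersized and single-class strata are suppressed with reasons", {
  ch <- make_fair_cohort(30, seed = 2)
  # a tiny third site below the threshold
  extra <- fair_case("tiny1", 1L, psa = 5, site = "SiteC")
  cases <- c(ch$cases, list(extra))
  scores <- lapply(ch$scores, function(s) c(s, 0.9))
  labels <- c(ch$labels, 1L)
  rep <- per_stratum_report(scores, labels, cases,
                            builtin_schemes(min_stratum_n = 20)["provider"],
                            n_boot = 30, seed = 1)
  expect_true("SiteC" %in% rep$suppressed$stratum)
  expect_match(rep$suppressed$reason[rep$suppressed$stratum == "SiteC"],
               "below min_stratum_n")
  expect_false("SiteC" %in% rep$table$stratum)
})

test_that("partitioning schemes cover evaluable cases; counts pool", {
  ch <- make_fair_cohort(80, seed = 3)
  rep <- per_stratum_report(ch$scores, ch$labels, ch$cases,
                            builtin_schemes(min_stratum_n = 1)["psa_damico3"],
                            n_boot = 20, seed = 1)
  per_model <- rep$table[rep$table$model == "meca", ]
  n_suppressed <- if (is.null(rep$suppressed)) 0 else sum(rep$suppressed$n)
  expect_equal(sum(per_model$n) + n_suppressed,
               length(ch$cases) - rep$missing[["psa_damico3"]])
  # pooling invariance of confusion counts at a fixed threshold
  thr <- 0.5
  sc <- builtin_schemes(min_stratum_n = 1)$psa_damico3
  strata <- vapply(ch$cases, assign_stratum, "", scheme = sc)
  tp_pool <- sum(ch$scores$meca >= thr & ch$labels == 1)
  tp_sum <- sum(vapply(unique(strata), function(st) {
    idx <- strata == st
    sum(ch$scores$meca[idx] >= thr & ch$labels[idx] == 1)
  }, numeric(1)))
  expect_equal(tp_sum, tp_pool)
})

test_that("a site-specific score corruption lowers only that stratum's AUC", {
  ch <- make_fair_cohort(100, seed = 4)
  sites <- vapply(ch$cases, function(cs) cs$clinical$site, "")
  corrupted <- ch$scores
  idx_b <- sites == "SiteB"
  corrupted$meca[idx_b] <- with_seed(5, runif(sum(idx_b)))  # destroy signal
  clean <- per_stratum_report(ch$scores, ch$labels, ch$cases,
                              builtin_schemes()["provider"], n_boot = 20,
                              seed = 1)
  dirty <- per_stratum_report(corrupted, ch$labels, ch$cases,
                              builtin_schemes()["provider"], n_boot = 20,
                              seed = 1)
  g <- function(rep, st) rep$table$auc[rep$table$model == "meca" &
                                       rep$table$stratum == st]
  expect_lt(g(dirty, "SiteB"), g(clean, "SiteB") - 0.15)
  expect_equal(g(dirty, "SiteA"), g(clean, "SiteA"), tolerance = 1e-12)
})
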