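# Sub-cohort stratification and per-stratum evaluation.  Boundary handling
# follows the printed conventions exactly: PSA 3-class [0,10), [10,20],
# (20,inf); PSA 4-class adds <4; age {<=75, >75}, {<55, 55-65, >65},
# cumulative {>45, >55, >65, >75} (overlapping, non-partitioning) and
# distinct {[45-55), [55-65], (65-75]}.

#' Stratification scheme
#'
#' @param name Scheme identifier.
#' @param variable One of `PSA`, `AGE`, `PROVIDER`, `FIELD`, `MANUFACTURER`.
#' @param assign A function mapping one case to a character vector of
#'   stratum labels (length > 1 only for cumulative schemes), or `NA` when
#'   the variable is missing.
#' @param strata Ordered stratum labels.
#' @param partitioning Whether strata are disjoint and cover all evaluable
#'   cases (cumulative age strata are not).
#' @param min_stratum_n Minimum cases (with both classes) for a stratum to
#'   be reported rather than suppressed; default 20.
#' @return A `stratification_scheme`.
#' @export
stratification_scheme <- function(name, variable, assign, strata,
                                  partitioning = TRUE, min_stratum_n = 20L) {
  variable <- match.arg(variable, c("PSA", "AGE", "PROVIDER", "FIELD",
                                    "MANUFACTURER"))
  structure(list(name = name, variable = variable, assign = assign,
                 strata = strata, partitioning = partitioning,
                 min_stratum_n = as.integer(min_stratum_n)),
            class = "stratification_scheme")
}

#' Built-in stratification schemes
#'
#' The analysis grid: PSA by D'Amico bands (3- and 4-class), four age
#' schemes, provider, field strength and manufacturer.
#'
#' @param min_stratum_n Suppression threshold shared by all schemes.
#' @return Named list of [stratification_scheme()]s.
#' @export
builtin_schemes <- function(min_stratum_n = 20L) {
  num_or_na <- function(x) if (is.null(x) || is.na(x)) NA_real_ else as.numeric(x)
  lab_or_na <- function(x) if (is.null(x) || is.na(x) || !nzchar(x)) NA_character_ else as.character(x)
  mk <- function(...) stratification_scheme(..., min_stratum_n = min_stratum_n)
  list(
    psa_damico3 = mk("psa_damico3", "PSA", function(case) {
      p <- num_or_na(case$clinical$psa)
      if (is.na(p)) return(NA_character_)
      if (p < 10) "[0-10)" else if (p <= 20) "[10-20]" else ">20"
    }, c("[0-10)", "[10-20]", ">20")),
    psa_damico4 = mk("psa_damico4", "PSA", function(case) {
      p <- num_or_na(case$clinical$psa)
      if (is.na(p)) return(NA_character_)
      if (p < 4) "<4" else if (p < 10) "[4-10)" else if (p <= 20) "[10-20]" else ">20"
    }, c("<4", "[4-10)", "[10-20]", ">20")),
    age_surgery = mk("age_surgery", "AGE", function(case) {
      a <- num_or_na(case$clinical$age)
      if (is.na(a)) return(NA_character_)
      if (a <= 75) "<=75" else ">75"
    }, c("<=75", ">75")),
    age_screening = mk("age_screening", "AGE", function(case) {
      a <- num_or_na(case$clinical$age)
      if (is.na(a)) return(NA_character_)
      if (a < 55) "<55" else if (a <= 65) "55-65" else ">65"
    }, c("<55", "55-65", ">65")),
    age_cumulative = mk("age_cumulative", "AGE", function(case) {
      a <- num_or_na(case$clinical$age)
      if (is.na(a)) return(NA_character_)
      out <- c(">45", ">55", ">65", ">75")[c(a > 45, a > 55, a > 65, a > 75)]
      if (length(out)) out else NA_character_
    }, c(">45", ">55", ">65", ">75"), partitioning = FALSE),
    age_distinct = mk("age_distinct", "AGE", function(case) {
      a <- num_or_na(case$clinical$age)
      if (is.na(a)) return(NA_character_)
      if (a >= 45 && a < 55) "[45-55)"
      else if (a >= 55 && a <= 65) "[55-65]"
      else if (a > 65 && a <= 75) "(65-75]"
      else NA_character_
    }, c("[45-55)", "[55-65]", "(65-75]"), partitioning = FALSE),
    provider = mk("provider", "PROVIDER", function(case)
      lab_or_na(case$clinical$site), character()),
    field = mk("field", "FIELD", function(case) {
      f <- num_or_na(case$clinical$field_strength)
      if (is.na(f)) NA_character_ else sprintf("%gT", f)
    }, character()),
    manufacturer = mk("manufacturer", "MANUFACTURER", function(case)
      lab_or_na(case$clinical$manufacturer), character())
  )
}

#' Assign a case to its stratum (strata) under a scheme
#'
#' @param case A [bpmri_case()].
#' @param scheme A [stratification_scheme()].
#' @return Character vector of stratum labels; `NA` when the stratifying
#'   variable is missing (the case is then excluded from the scheme and
#'   counted in the suppression log).
#' @export
assign_stratum <- function(case, scheme) scheme$assign(case)

significance_tier <- function(p) {
  if (is.na(p)) return("")
  if (p <= 1e-4) "****" else if (p <= 1e-3) "***"
  else if (p <= 1e-2) "**" else if (p <= 0.05) "*" else ""
}

#' Per-stratum fairness report
#'
#' For every scheme and stratum with at least `min_stratum_n` cases and
#' both classes present: per-model AUC with bootstrap CI plus pairwise
#' DeLong p-values (raw, with significance tier markers; an optional Holm
#' adjustment can be applied downstream).  Undersized or single-class
#' strata are flagged as suppressed with a reason rather than scored.
#'
#' @param scores Named list: one numeric score vector per model, all paired
#'   on `cases`.
#' @param labels 0/1 ground truth, paired with `cases`.
#' @param cases List of [bpmri_case()]s carrying the stratifying variables.
#' @param schemes List of [stratification_scheme()]s
#'   (default [builtin_schemes()]).
#' @param n_boot,seed Bootstrap settings.
#' @return A `fairness_report`: `table` (long data frame
#'   `scheme,stratum,model,n,n_pos,auc,lo,hi`), `pairwise` (DeLong rows
#'   with tiers), `suppressed`, `missing` (per-scheme count of cases with
#'   the variable absent).
#' @export
per_stratum_report <- function(scores, labels, cases,
                               schemes = builtin_schemes(),
                               n_boot = 500L, seed = 0L) {
  stopifnot(is.list(scores), length(names(scores)) == length(scores))
  labels <- as.integer(labels)
  n <- length(labels)
  for (s in scores) if (length(s) != n) stopf("all score vectors must be paired")
  rows <- list(); pw <- list(); supp <- list(); missing_log <- list()
  for (scheme in schemes) {
    assigned <- lapply(cases, assign_stratum, scheme = scheme)
    is_missing <- vapply(assigned, function(a) all(is.na(a)), logical(1))
    missing_log[[scheme$name]] <- sum(is_missing)
    strata <- scheme$strata
    if (!length(strata))
      strata <- sort(unique(unlist(assigned[!is_missing])))
    for (st in strata) {
      idx <- which(vapply(assigned, function(a) st %in% a, logical(1)))
      reason <- NULL
      if (length(idx) < scheme$min_stratum_n)
        reason <- sprintf("n=%d below min_stratum_n=%d", length(idx),
                          scheme$min_stratum_n)
      else if (length(unique(labels[idx])) < 2L)
        reason <- "single class present"
      if (!is.null(reason)) {
        supp[[length(supp) + 1L]] <- data.frame(scheme = scheme$name,
                                                stratum = st, n = length(idx),
                                                reason = reason)
        next
      }
      for (mod in names(scores)) {
        sc <- scores[[mod]][idx]
        ci <- bootstrap_auc_ci(sc, labels[idx], n_boot = n_boot,
                               seed = derive_seed(seed, length(rows)))
        rows[[length(rows) + 1L]] <- data.frame(
          scheme = scheme$name, stratum = st, model = mod, n = length(idx),
          n_pos = sum(labels[idx]), auc = auc_score(sc, labels[idx]),
          lo = ci[1], hi = ci[2])
      }
      mods <- names(scores)
      if (length(mods) >= 2)
        for (i in seq_len(length(mods) - 1L))
          for (j in (i + 1L):length(mods)) {
            dl <- delong_test(scores[[mods[i]]][idx], scores[[mods[j]]][idx],
                              labels[idx])
            pw[[length(pw) + 1L]] <- data.frame(
              scheme = scheme$name, stratum = st, model_a = mods[i],
              model_b = mods[j], auc_a = dl$auc_a, auc_b = dl$auc_b,
              p_value = dl$p_value, tier = significance_tier(dl$p_value))
          }
    }
  }
  bindr <- function(x) if (length(x)) do.call(rbind, x) else NULL
  structure(list(table = bindr(rows), pairwise = bindr(pw),
                 suppressed = bindr(supp),
                 missing = unlist(missing_log)),
            class = "fairness_report")
}

#' @export
print.fairness_report <- function(x, ...) {
  cat("<fairness_report>\n")
  if (!is.null(x$table)) {
    cat(sprintf("  %d stratum x model rows over %d schemes\n",
                nrow(x$table), length(unique(x$table$scheme))))
  }
  if (!is.null(x$suppressed))
    cat(sprintf("  %d suppressed strata\n", nrow(x$suppressed)))
  invisible(x)
}
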