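# Published patient-level operating points (sensitivity, specificity, PPV,
# NPV per model and cohort) shipped as a plain-text fixture.  They anchor
# the predictive-value consistency checks: PPV and NPV printed for one
# operating point must be mutually consistent through the prevalence
# equations, since both were computed on the same cohort.

#' Reference operating points
#'
#' @return Data frame of the published per-model operating points
#'   (percent-valued `ppv`/`npv` columns).
#' @export
reference_operating_points <- function() {
  path <- system.file("extdata", "reference_operating_points.csv",
                      package = "bpfusion")
  read.csv(path, stringsAsFactors = FALSE)
}

#' Back-solve a cohort's prevalence from one reference row
#'
#' @param cohort `"retrospective"` or `"prospective"`.
#' @param model Row to invert (default `"radiologists"`, the conventional
#'   anchor since human readers and models scored the same cohort).
#' @return Prevalence in (0, 1).
#' @export
reference_prevalence <- function(cohort = c("retrospective", "prospective"),
                                 model = "radiologists") {
  cohort <- match.arg(cohort)
  tab <- reference_operating_points()
  row <- tab[tab$cohort == cohort & tab$model == model, ]
  if (nrow(row) != 1) stopf("no reference row for %s / %s", cohort, model)
  solve_prevalence(row$sensitivity, row$specificity, row$ppv / 100)
}

#' Predictive-value consistency checks on the reference tables
#'
#' For every row: back-solve the prevalence implied by that row's
#' sensitivity/specificity/PPV, evaluate the NPV equation there, and
#' compare with the printed NPV; additionally recompute every row's PPV at
#' the cohort prevalence implied by the radiologists row.  Differences
#' beyond `tol` percentage points (default 0.5, the propagation allowance
#' for inputs printed to two decimals) are flagged.
#'
#' @param tol Tolerance in percentage points.
#' @return Data frame with computed values, printed values and pass flags.
#' @export
check_reference_tables <- function(tol = 0.5) {
  tab <- reference_operating_points()
  out <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    p_row <- solve_prevalence(row$sensitivity, row$specificity, row$ppv / 100)
    npv_hat <- 100 * ppv_npv(row$sensitivity, row$specificity, p_row)$npv
    p_cohort <- reference_prevalence(row$cohort)
    ppv_hat <- 100 * ppv_npv(row$sensitivity, row$specificity, p_cohort)$ppv
    data.frame(cohort = row$cohort, model = row$model,
               prevalence_row = p_row, prevalence_cohort = p_cohort,
               npv_computed = round(npv_hat, 2), npv_printed = row$npv,
               npv_ok = abs(npv_hat - row$npv) <= tol,
               ppv_computed = round(ppv_hat, 2), ppv_printed = row$ppv,
               ppv_ok = abs(ppv_hat - row$ppv) <= tol,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
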