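# Stratified cohort splitting with largest-remainder rounding, so cohort
# sizes always sum exactly to the number of cases and the class ratio is
# preserved per cohort.

largest_remainder <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    order_idx <- order(raw - base, decreasing = TRUE)
    base[order_idx[seq_len(left)]] <- base[order_idx[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Stratified train/validation/test split
#'
#' Cases are shuffled deterministically (given `seed`) within each class and
#' allocated to cohorts by largest-remainder rounding per class, so cohorts
#' are disjoint, exhaustive, and preserve the class ratio.
#'
#' @param cases Either a list of [bpmri_case()] objects or a data frame with
#'   columns `case_id` and `label`.
#' @param fractions Numeric vector summing to 1; default `c(0.70, 0.15, 0.15)`.
#' @param seed Integer seed; identical inputs and seed give identical splits.
#' @param cohort_names Labels for the cohorts, by default
#'   `c("TRAIN", "VAL", "TEST_RETRO")`.
#' @param tolerance Maximum allowed absolute deviation between a cohort's
#'   positive fraction and the global one (default 0.02).
#' @return A `cohort_split` object: per-cohort case-id vectors, per-cohort
#'   positive/negative counts, and the fractions used.
#' @export
stratified_split <- function(cases, fractions = c(0.70, 0.15, 0.15),
                             seed = 0L,
                             cohort_names = c("TRAIN", "VAL", "TEST_RETRO"),
                             tolerance = 0.02) {
  if (abs(sum(fractions) - 1) > 1e-8) stopf("fractions must sum to 1")
  if (length(fractions) != length(cohort_names))
    stopf("need one cohort name per fraction")
  if (is.data.frame(cases)) {
    ids <- as.character(cases$case_id); labels <- as.integer(cases$label)
  } else {
    ids <- vapply(cases, function(cs) as.character(cs$case_id), character(1))
    labels <- vapply(cases, function(cs) as.integer(cs$label), integer(1))
  }
  if (anyDuplicated(ids)) stopf("duplicate case ids in input")
  if (length(unique(labels)) < 2L)
    stopf("both classes must be present to stratify; found only class %s",
          unique(labels))
  members <- stats::setNames(vector("list", length(cohort_names)), cohort_names)
  counts <- matrix(0L, nrow = length(cohort_names), ncol = 2,
                   dimnames = list(cohort_names, c("neg", "pos")))
  with_seed(seed, {
    for (cls in c(0L, 1L)) {
      cls_ids <- ids[labels == cls]
      cls_ids <- cls_ids[sample.int(length(cls_ids))]
      sizes <- largest_remainder(length(cls_ids), fractions)
      ends <- cumsum(sizes); starts <- c(1L, head(ends, -1) + 1L)
      for (k in seq_along(cohort_names)) {
        take <- if (sizes[k] > 0) cls_ids[starts[k]:ends[k]] else character()
        members[[k]] <- c(members[[k]], take)
        counts[k, cls + 1L] <- sizes[k]
      }
    }
  })
  global_pos <- mean(labels)
  for (k in seq_along(cohort_names)) {
    n_k <- sum(counts[k, ])
    if (n_k > 0 && abs(counts[k, "pos"] / n_k - global_pos) > tolerance)
      warnf("cohort %s positive fraction deviates from global by > %.3f",
            cohort_names[k], tolerance)
  }
  structure(list(fractions = fractions, members = members, counts = counts,
                 seed = seed, tolerance = tolerance),
            class = "cohort_split")
}

#' @export
print.cohort_split <- function(x, ...) {
  cat("<cohort_split>\n")
  for (k in names(x$members))
    cat(sprintf("  %-10s n=%5d (pos %d / neg %d)\n", k,
                sum(x$counts[k, ]), x$counts[k, "pos"], x$counts[k, "neg"]))
  invisible(x)
}

#' Write / read a split manifest (`case_id,cohort` CSV)
#'
#' @param split A `cohort_split`.
#' @param path CSV path.
#' @return `path` (write) or a data frame (read).
#' @export
write_split_manifest <- function(split, path) {
  rows <- do.call(rbind, lapply(names(split$members), function(k) {
    if (!length(split$members[[k]])) return(NULL)
    data.frame(case_id = split$members[[k]], cohort = k,
               stringsAsFactors = FALSE)
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_split_manifest
#' @export
read_split_manifest <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("case_id", "cohort") %in% names(df)))
    stopf("split manifest %s must have columns case_id,cohort", path)
  df$case_id <- as.character(df$case_id)
  df
}
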