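# Case-level containers: a single MR sequence volume, a clinical record,
# and a full bi-parametric case (three aligned sequences + optional gland
# mask + clinical data + biopsy-proven label).

#' Construct a sequence volume
#'
#' @param voxels 3-D numeric array in (slice, row, col) order.
#' @param spacing Voxel spacing in mm as (dz, dy, dx), all > 0.
#' @param kind One of `"T2W"`, `"DWI_HIGH_B"`, `"ADC"`.
#' @param case_id Case identifier.
#' @return A `sequence_volume` object.
#' @export
sequence_volume <- function(voxels, spacing, kind, case_id = NA_character_) {
  kind <- match.arg(kind, SEQUENCE_KINDS)
  if (length(dim(voxels)) != 3L)
    stopf("voxels for %s must have rank 3, got rank %d", kind,
          length(dim(voxels)) %||% 1L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("spacing must be 3 strictly positive mm values")
  assert_finite(voxels, sprintf("voxel intensities (%s, case %s)", kind, case_id))
  structure(list(voxels = voxels, spacing = spacing, kind = kind,
                 case_id = case_id),
            class = "sequence_volume")
}

#' @export
print.sequence_volume <- function(x, ...) {
  cat(sprintf("<sequence_volume %s case=%s dim=%s spacing=%s mm>\n",
              x$kind, x$case_id, paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "/")))
  invisible(x)
}

#' Construct a clinical record
#'
#' Raw values are in clinical units (age in years, PSA in ng/mL, PSA density
#' in ng/mL per mL); `*_norm` fields, when set by [scale_clinical()], lie in
#' \[-1, 1\].
#'
#' @param age Age in years (> 0).
#' @param psa PSA in ng/mL (>= 0).
#' @param psa_density Optional PSA density; computable via [psa_density()].
#' @param site,field_strength,manufacturer Optional cohort metadata.
#' @param age_norm,psa_norm,psad_norm Optional normalised values in \[-1, 1\].
#' @return A `clinical_record` object.
#' @export
clinical_record <- function(age, psa, psa_density = NA_real_,
                            site = NA_character_, field_strength = NA_real_,
                            manufacturer = NA_character_,
                            age_norm = NA_real_, psa_norm = NA_real_,
                            psad_norm = NA_real_) {
  if (!is.na(age) && age <= 0) stopf("age must be > 0, got %s", age)
  if (!is.na(psa) && psa < 0) stopf("psa must be >= 0, got %s", psa)
  for (v in c(age_norm, psa_norm, psad_norm))
    if (!is.na(v) && (v < -1 || v > 1))
      stopf("normalised clinical values must lie in [-1, 1]")
  structure(list(age = age, psa = psa, psa_density = psa_density,
                 site = site, field_strength = field_strength,
                 manufacturer = manufacturer, age_norm = age_norm,
                 psa_norm = psa_norm, psad_norm = psad_norm),
            class = "clinical_record")
}

#' Construct a bi-parametric MRI case
#'
#' @param case_id Identifier.
#' @param volumes Named list with exactly one [sequence_volume()] per kind
#'   (`T2W`, `DWI_HIGH_B`, `ADC`).
#' @param clinical A [clinical_record()].
#' @param label Biopsy-proven ground truth: 0 (no PCa) or 1 (PCa).
#' @param gland_mask Optional binary 3-D array aligned to the T2W volume.
#' @param cohort Optional cohort tag (`TRAIN`, `VAL`, `TEST_RETRO`,
#'   `TEST_PROSP`).
#' @return A `bpmri_case` object.
#' @export
bpmri_case <- function(case_id, volumes, clinical, label, gland_mask = NULL,
                       cohort = NA_character_) {
  if (!label %in% c(0, 1)) stopf("label must be 0 or 1, got %s", label)
  missing_kind <- setdiff(SEQUENCE_KINDS, names(volumes))
  if (length(missing_kind))
    stopf("case %s is missing sequence kind(s): %s", case_id,
          paste(missing_kind, collapse = ", "))
  for (k in SEQUENCE_KINDS) {
    v <- volumes[[k]]
    if (!inherits(v, "sequence_volume"))
      stopf("volumes[['%s']] is not a sequence_volume", k)
    if (v$kind != k) stopf("volume stored under '%s' has kind '%s'", k, v$kind)
  }
  if (!is.null(gland_mask)) {
    t2dim <- dim(volumes$T2W$voxels)
    if (!identical(dim(gland_mask), t2dim))
      stopf("gland mask shape (%s) does not match T2W shape (%s) for case %s",
            paste(dim(gland_mask), collapse = "x"),
            paste(t2dim, collapse = "x"), case_id)
    if (!all(gland_mask %in% c(0, 1)))
      stopf("gland mask must be binary for case %s", case_id)
  }
  if (!is.na(cohort)) cohort <- match.arg(cohort, COHORTS)
  structure(list(case_id = case_id, volumes = volumes[SEQUENCE_KINDS],
                 gland_mask = gland_mask, clinical = clinical,
                 label = as.integer(label), cohort = cohort),
            class = "bpmri_case")
}

#' @export
print.bpmri_case <- function(x, ...) {
  cat(sprintf("<bpmri_case %s label=%d cohort=%s mask=%s>\n", x$case_id,
              x$label, x$cohort, if (is.null(x$gland_mask)) "no" else "yes"))
  invisible(x)
}

#' Load one case from NIfTI volumes plus a clinical row
#'
#' Assembles a validated [bpmri_case()] from per-sequence NIfTI files, a row
#' of the clinical table, and an optional gland-mask NIfTI.  Sequences are
#' assumed co-registered.  DICOM series directories are not supported by
#' this implementation; convert to NIfTI first.
#'
#' @param volume_paths Named character vector/list with elements `T2W`,
#'   `DWI_HIGH_B`, `ADC` pointing at NIfTI files.
#' @param clinical_row A one-row data frame with columns
#'   `case_id, age, psa, label` and optionally
#'   `site, field_strength, manufacturer`.
#' @param mask_path Optional path to a binary NIfTI gland mask.
#' @return A validated [bpmri_case()]; voxel spacing is read from headers.
#' @export
load_case <- function(volume_paths, clinical_row, mask_path = NULL) {
  missing_kind <- setdiff(SEQUENCE_KINDS, names(volume_paths))
  if (length(missing_kind))
    stopf("no path supplied for sequence kind(s): %s",
          paste(missing_kind, collapse = ", "))
  case_id <- as.character(clinical_row$case_id)
  vols <- list()
  for (k in SEQUENCE_KINDS) {
    p <- volume_paths[[k]]
    if (dir.exists(p))
      stopf("%s is a directory; DICOM series are not supported, supply NIfTI", p)
    img <- read_nifti(p)
    vols[[k]] <- sequence_volume(img$voxels, img$spacing, k, case_id)
  }
  mask <- NULL
  if (!is.null(mask_path)) {
    m <- read_nifti(mask_path)$voxels
    m[] <- as.numeric(m > 0.5)
    mask <- m
  }
  clin <- clinical_record(
    age = as.numeric(clinical_row$age), psa = as.numeric(clinical_row$psa),
    site = as.character(clinical_row$site %||% NA),
    field_strength = as.numeric(clinical_row$field_strength %||% NA),
    manufacturer = as.character(clinical_row$manufacturer %||% NA))
  bpmri_case(case_id, vols, clin, as.integer(clinical_row$label),
             gland_mask = mask)
}

#' Read a clinical table
#'
#' Expected CSV header: `case_id,age,psa,label` with optional
#' `site,field_strength,manufacturer`.
#'
#' @param path CSV path.
#' @return A data frame with `case_id` as character.
#' @export
read_clinical_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "age", "psa", "label")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("clinical table %s lacks column(s): %s", path,
                          paste(miss, collapse = ", "))
  df$case_id <- as.character(df$case_id)
  df
}
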