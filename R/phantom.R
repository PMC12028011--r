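# Synthetic bpMRI phantom cohorts.
#
# Each case is an ellipsoidal gland in a noisy background, imaged by three
# "sequences" with distinct arbitrary dynamic ranges.  A true lesion
# (label 1) imprints the three signed contrasts that motivate cross-modal
# fusion: darker than the gland on T2w, brighter on high-b DWI, darker on
# ADC.  Distractor nodules (BPH-like) imprint the lesion-sign contrast in
# exactly ONE randomly chosen modality, independent of the label, so any
# single-modality classifier is systematically misled while a fused reader
# is not.  Clinical variables follow a simple generative model in which
# PSA rises with gland volume (a BPH effect) and with the cancer label.

#' Phantom cohort configuration
#'
#' Defaults are the desk-scale stated world: 16 x 64 x 64 volumes at
#' (4.0, 1.5, 1.5) mm, prevalence 0.6 (the empirical pre-test probability
#' of the archive this emulates), distractor rate 0.3, noise 0.08 in
#' normalised-intensity units.
#'
#' @param n_cases Number of cases.
#' @param prevalence P(label = 1), in (0, 1).
#' @param volume_shape (slices, rows, cols); default `c(16, 64, 64)`.
#' @param spacing (dz, dy, dx) mm; default `c(4.0, 1.5, 1.5)`.
#' @param gland_semiaxes Mean ellipsoid semi-axes (z, y, x) in mm.
#' @param gland_jitter Relative jitter on semi-axes (uniform +-).
#' @param lesion_radius_mm Range of lesion radius in mm.
#' @param contrast Named lesion contrasts in normalised units; signs are
#'   enforced: `t2w < 0`, `dwi > 0`, `adc < 0`.
#' @param distractor_rate Probability a case carries a one-modality
#'   distractor nodule.
#' @param noise_sd Gaussian noise sd in normalised units.
#' @param psa_label_shift Additive PSA shift (ng/mL) for positive cases.
#' @param sites Site labels; each gets a deterministic intensity offset.
#' @param seed Cohort seed.
#' @return A `phantom_config`.
#' @export
phantom_config <- function(n_cases = 200L, prevalence = 0.6,
                           volume_shape = c(16L, 64L, 64L),
                           spacing = c(4.0, 1.5, 1.5),
                           gland_semiaxes = c(15, 22, 20),
                           gland_jitter = 0.15,
                           lesion_radius_mm = c(5, 9),
                           contrast = c(t2w = -0.35, dwi = 0.45, adc = -0.40),
                           distractor_rate = 0.3, noise_sd = 0.08,
                           psa_label_shift = 3.5,
                           sites = c("SiteA", "SiteB", "SiteC"),
                           seed = 0L) {
  if (prevalence <= 0 || prevalence >= 1) stopf("prevalence must be in (0,1)")
  if (contrast["t2w"] >= 0 || contrast["dwi"] <= 0 || contrast["adc"] >= 0)
    stopf("lesion contrasts must carry the physiological signs: t2w<0, dwi>0, adc<0")
  structure(list(n_cases = as.integer(n_cases), prevalence = prevalence,
                 volume_shape = as.integer(volume_shape),
                 spacing = as.numeric(spacing),
                 gland_semiaxes = gland_semiaxes, gland_jitter = gland_jitter,
                 lesion_radius_mm = lesion_radius_mm, contrast = contrast,
                 distractor_rate = distractor_rate, noise_sd = noise_sd,
                 psa_label_shift = psa_label_shift, sites = sites,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# mm coordinate grids centred on the volume centre.
axis_mm <- function(n, sp) (seq_len(n) - (n + 1) / 2) * sp

ellipsoid_mask <- function(shape, spacing, center_mm, semiaxes) {
  z <- axis_mm(shape[1], spacing[1]) - center_mm[1]
  y <- axis_mm(shape[2], spacing[2]) - center_mm[2]
  x <- axis_mm(shape[3], spacing[3]) - center_mm[3]
  q <- outer(outer((z / semiaxes[1])^2, (y / semiaxes[2])^2, "+"),
             (x / semiaxes[3])^2, "+")
  array(as.numeric(q <= 1), dim = shape)
}

# Sequence dynamic ranges (arbitrary per sequence, pre-normalisation):
# value = offset + scale * normalised_intensity.
SEQ_SCALES <- list(T2W = c(offset = 100, scale = 600),
                   DWI_HIGH_B = c(offset = 50, scale = 900),
                   ADC = c(offset = 200, scale = 2000))
# normalised base intensities: background, gland
SEQ_BASE <- list(T2W = c(bg = 0.35, gland = 0.75),
                 DWI_HIGH_B = c(bg = 0.20, gland = 0.35),
                 ADC = c(bg = 0.50, gland = 0.75))

generate_case <- function(config, case_id, label, site_idx, case_seed) {
  with_seed(case_seed, {
    shape <- config$volume_shape; sp <- config$spacing
    semi <- config$gland_semiaxes *
      (1 + runif(3, -config$gland_jitter, config$gland_jitter))
    gland <- ellipsoid_mask(shape, sp, c(0, 0, 0), semi)
    lesion <- NULL; distractor <- NULL; distractor_seq <- NA_character_
    if (label == 1) {
      r <- runif(1, config$lesion_radius_mm[1], config$lesion_radius_mm[2])
      if (r >= min(semi))
        stopf("impossible geometry: lesion radius %.1f mm exceeds gland semi-axis %.1f mm",
              r, min(semi))
      ctr <- runif(3, -0.4, 0.4) * (semi - r)
      lesion <- ellipsoid_mask(shape, sp, ctr, rep(r, 3)) * gland
    }
    if (runif(1) < config$distractor_rate) {
      r <- runif(1, config$lesion_radius_mm[1], config$lesion_radius_mm[2])
      r <- min(r, min(semi) * 0.9)
      ctr <- runif(3, -0.4, 0.4) * (semi - r)
      distractor <- ellipsoid_mask(shape, sp, ctr, rep(r, 3)) * gland
      distractor_seq <- sample(SEQUENCE_KINDS, 1)
    }
    site_off <- c(0, 0.03, -0.03)[((site_idx - 1) %% 3) + 1]
    contrasts <- c(T2W = unname(config$contrast["t2w"]),
                   DWI_HIGH_B = unname(config$contrast["dwi"]),
                   ADC = unname(config$contrast["adc"]))
    vols <- list()
    for (k in SEQUENCE_KINDS) {
      base <- SEQ_BASE[[k]]
      v <- array(base["bg"], dim = shape) + gland * (base["gland"] - base["bg"])
      if (!is.null(lesion)) v <- v + lesion * contrasts[k]
      if (!is.null(distractor) && distractor_seq == k)
        v <- v + distractor * contrasts[k]
      v <- v + site_off
      if (config$noise_sd > 0)
        v <- v + array(rnorm(length(v), sd = config$noise_sd), dim = shape)
      sc <- SEQ_SCALES[[k]]
      v <- sc["offset"] + sc["scale"] * v
      vols[[k]] <- sequence_volume(v, sp, k, case_id)
    }
    gland_ml <- prostate_volume(gland, sp)
    psa <- max(0.3, 1.0 + 0.10 * gland_ml + config$psa_label_shift * label +
                 rnorm(1, sd = 1.5))
    age <- round(min(90, max(45, rnorm(1, 66 + 2 * label, 7))))
    clin <- clinical_record(
      age = age, psa = psa, psa_density = psa_density(psa, gland_ml),
      site = config$sites[site_idx],
      field_strength = if (runif(1) < 0.4) 1.5 else 3.0,
      manufacturer = sample(c("VendorX", "VendorY", "VendorZ"), 1))
    case <- bpmri_case(case_id, vols, clin, label, gland_mask = gland)
    attr(case, "distractor_seq") <- distractor_seq
    case
  })
}

#' Generate a phantom cohort
#'
#' Deterministic given `config$seed`: every case derives its own RNG stream
#' from the cohort seed and its index.
#'
#' @param config A [phantom_config()].
#' @return list with `cases` (list of [bpmri_case()]) and `truth` (data
#'   frame: case_id, label, psa, age, gland volume, site, field,
#'   manufacturer, distractor modality).
#' @export
generate_cohort <- function(config = phantom_config()) {
  n <- config$n_cases
  labels <- with_seed(derive_seed(config$seed, 0), {
    n_pos <- round(n * config$prevalence)
    sample(c(rep(1L, n_pos), rep(0L, n - n_pos)))
  })
  site_idx <- with_seed(derive_seed(config$seed, 1),
                        sample.int(length(config$sites), n, replace = TRUE))
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    cases[[i]] <- generate_case(config, sprintf("phantom%04d", i), labels[i],
                                site_idx[i], derive_seed(config$seed, 100 + i))
  }
  truth <- do.call(rbind, lapply(cases, function(cs) data.frame(
    case_id = cs$case_id, label = cs$label, psa = cs$clinical$psa,
    age = cs$clinical$age, gland_ml = sum(cs$gland_mask) * prod(config$spacing) / 1000,
    site = cs$clinical$site, field_strength = cs$clinical$field_strength,
    manufacturer = cs$clinical$manufacturer,
    distractor_seq = attr(cs, "distractor_seq") %||% NA_character_,
    stringsAsFactors = FALSE)))
  list(cases = cases, truth = truth, config = config)
}

#' Write a cohort to disk as NIfTI + CSV
#'
#' Produces `<id>_t2w/_dwi/_adc.nii.gz` (float64, so the round trip through
#' [load_case()] is bit-exact), `<id>_mask.nii.gz`, one `clinical.csv`, and
#' an optional split manifest.
#'
#' @param cohort Output of [generate_cohort()].
#' @param out_dir Output directory (created if needed).
#' @param split Optional `cohort_split` to write as `split.csv`.
#' @return `out_dir`, invisibly.
#' @export
emit_cohort <- function(cohort, out_dir, split = NULL) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok) stopf("cannot create output directory %s", out_dir)
  suffix <- c(T2W = "t2w", DWI_HIGH_B = "dwi", ADC = "adc")
  for (cs in cohort$cases) {
    for (k in SEQUENCE_KINDS) {
      v <- cs$volumes[[k]]
      write_nifti(v$voxels, file.path(out_dir,
                  sprintf("%s_%s.nii.gz", cs$case_id, suffix[k])),
                  v$spacing, datatype = "float64")
    }
    write_nifti(cs$gland_mask,
                file.path(out_dir, sprintf("%s_mask.nii.gz", cs$case_id)),
                cs$volumes$T2W$spacing, datatype = "uint8")
  }
  write.csv(cohort$truth[, c("case_id", "age", "psa", "label", "site",
                             "field_strength", "manufacturer")],
            file.path(out_dir, "clinical.csv"), row.names = FALSE,
            quote = FALSE)
  if (!is.null(split)) write_split_manifest(split, file.path(out_dir, "split.csv"))
  invisible(out_dir)
}

#' Load an emitted cohort back into cases
#'
#' @param dir Directory produced by [emit_cohort()].
#' @return List of [bpmri_case()]s in clinical-table order.
#' @export
load_cohort <- function(dir) {
  clin <- read_clinical_csv(file.path(dir, "clinical.csv"))
  lapply(seq_len(nrow(clin)), function(i) {
    id <- clin$case_id[i]
    paths <- list(T2W = file.path(dir, sprintf("%s_t2w.nii.gz", id)),
                  DWI_HIGH_B = file.path(dir, sprintf("%s_dwi.nii.gz", id)),
                  ADC = file.path(dir, sprintf("%s_adc.nii.gz", id)))
    load_case(paths, clin[i, ], mask_path = file.path(dir, sprintf("%s_mask.nii.gz", id)))
  })
}

# 3x3x3 box smoothing via the conv kernel.
box_smooth <- function(vol) {
  x <- array(vol, dim = c(dim(vol), 1L, 1L))
  w <- matrix(1 / 27, nrow = 1, ncol = 27)
  array(cpp_conv3d_fwd(x, w, 0), dim = dim(vol))
}

#' Oracle classifiers thresholding the known effect directions
#'
#' Non-learned reference scores used to bound what any classifier could
#' achieve: per modality, the most lesion-like smoothed intensity deviation
#' inside the gland (signed per the known contrast direction); `"FUSED"`
#' sums the three aligned voxel-wise deviations, so a one-modality
#' distractor contributes only a third of the evidence of a true lesion.
#'
#' @param cases List of [bpmri_case()]s with gland masks.
#' @param modality `"T2W"`, `"DWI_HIGH_B"`, `"ADC"`, or `"FUSED"`.
#' @return Numeric score per case (higher = more lesion-like).
#' @export
oracle_scores <- function(cases, modality = c("FUSED", SEQUENCE_KINDS)) {
  modality <- match.arg(modality)
  sgn <- c(T2W = -1, DWI_HIGH_B = 1, ADC = -1)
  vapply(cases, function(cs) {
    if (is.null(cs$gland_mask)) stopf("oracle scores need gland masks")
    # restrict to interior voxels whose whole 3x3x3 neighbourhood is gland,
    # so the smoothed deviation never mixes in background intensity
    interior <- box_smooth(cs$gland_mask) > 1 - 1e-9
    if (!any(interior)) interior <- cs$gland_mask > 0
    dev <- lapply(SEQUENCE_KINDS, function(k) {
      v <- minmax_normalize(cs$volumes[[k]]$voxels)
      s <- box_smooth(v)
      sgn[k] * (s - median(s[interior]))
    })
    names(dev) <- SEQUENCE_KINDS
    if (modality == "FUSED") {
      total <- dev$T2W + dev$DWI_HIGH_B + dev$ADC
      max(total[interior])
    } else {
      max(dev[[modality]][interior])
    }
  }, numeric(1))
}
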