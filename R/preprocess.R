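# Preprocessing chain: resample to a target spacing, central crop (with
# zero padding when undersized), per-image min-max normalisation, prostate
# volume from the gland mask, PSA density, and [-1, 1] clinical scaling
# fitted on the training cohort only.

#' Preprocessing configuration
#'
#' @param target_spacing Target (dz, dy, dx) spacing in mm; default
#'   `c(3.0, 0.5, 0.5)`.
#' @param crop_shape Output (slices, rows, cols) shape; default
#'   `c(32, 224, 224)`.
#' @param crop_center_policy `"IMAGE_CENTER"` (default) or `"MASK_CENTROID"`.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(target_spacing = c(3.0, 0.5, 0.5),
                              crop_shape = c(32L, 224L, 224L),
                              crop_center_policy = c("IMAGE_CENTER",
                                                     "MASK_CENTROID")) {
  crop_center_policy <- match.arg(crop_center_policy)
  if (any(target_spacing <= 0)) stopf("target_spacing must be positive")
  if (any(crop_shape <= 0)) stopf("crop_shape must be positive")
  structure(list(target_spacing = as.numeric(target_spacing),
                 crop_shape = as.integer(crop_shape),
                 crop_center_policy = crop_center_policy),
            class = "preprocess_config")
}

# Trilinear (or nearest) sampling of a 3-D array at fractional 1-based
# indices given as three equally-long vectors per axis grid.
sample_grid <- function(vol, gz, gy, gx, nearest = FALSE) {
  d <- dim(vol)
  if (nearest) {
    iz <- pmin(pmax(round(gz), 1), d[1])
    iy <- pmin(pmax(round(gy), 1), d[2])
    ix <- pmin(pmax(round(gx), 1), d[3])
    g <- expand.grid(z = iz, y = iy, x = ix)
    return(array(vol[cbind(g$z, g$y, g$x)], dim = c(length(gz), length(gy), length(gx))))
  }
  cl <- function(v, n) pmin(pmax(v, 1), n)
  z0 <- cl(floor(gz), d[1]); z1 <- cl(z0 + 1, d[1]); fz <- cl(gz, d[1]) - z0
  y0 <- cl(floor(gy), d[2]); y1 <- cl(y0 + 1, d[2]); fy <- cl(gy, d[2]) - y0
  x0 <- cl(floor(gx), d[3]); x1 <- cl(x0 + 1, d[3]); fx <- cl(gx, d[3]) - x0
  nz <- length(gz); ny <- length(gy); nx <- length(gx)
  FZ <- array(fz, dim = c(nz, ny, nx))
  FY <- array(rep(fy, each = nz), dim = c(nz, ny, nx))
  FX <- array(rep(fx, each = nz * ny), dim = c(nz, ny, nx))
  take <- function(zi, yi, xi) {
    g <- expand.grid(z = zi, y = yi, x = xi)
    array(vol[cbind(g$z, g$y, g$x)], dim = c(nz, ny, nx))
  }
  c000 <- take(z0, y0, x0); c100 <- take(z1, y0, x0)
  c010 <- take(z0, y1, x0); c110 <- take(z1, y1, x0)
  c001 <- take(z0, y0, x1); c101 <- take(z1, y0, x1)
  c011 <- take(z0, y1, x1); c111 <- take(z1, y1, x1)
  (c000 * (1 - FZ) + c100 * FZ) * (1 - FY) * (1 - FX) +
  (c010 * (1 - FZ) + c110 * FZ) * FY * (1 - FX) +
  (c001 * (1 - FZ) + c101 * FZ) * (1 - FY) * FX +
  (c011 * (1 - FZ) + c111 * FZ) * FY * FX
}

#' Resample a volume to a target voxel spacing
#'
#' Output shape is `round(input_shape * input_spacing / target_spacing)`;
#' intensities are interpolated trilinearly (masks should use
#' `nearest = TRUE`).  Voxel centres are aligned at the first voxel.
#'
#' @param volume A [sequence_volume()] or a plain 3-D array (then `spacing`
#'   must be given).
#' @param target_spacing (dz, dy, dx) in mm, all > 0.
#' @param spacing Required when `volume` is a bare array.
#' @param nearest Use nearest-neighbour interpolation (for masks).
#' @return Same type as the input, at the new spacing.
#' @export
resample_volume <- function(volume, target_spacing, spacing = NULL,
                            nearest = FALSE) {
  if (any(target_spacing <= 0)) stopf("target_spacing must be positive")
  is_sv <- inherits(volume, "sequence_volume")
  vol <- if (is_sv) volume$voxels else volume
  sp <- if (is_sv) volume$spacing else spacing
  if (is.null(sp)) stopf("spacing must be supplied for a bare array")
  d_in <- dim(vol)
  d_out <- pmax(1L, as.integer(round(d_in * sp / target_spacing)))
  if (identical(d_out, d_in) && all(abs(sp - target_spacing) < 1e-9)) {
    out <- vol
  } else {
    # output voxel i (0-based) sits at physical i*target; input index space
    # 1-based: 1 + i*target/sp
    gz <- 1 + (seq_len(d_out[1]) - 1) * target_spacing[1] / sp[1]
    gy <- 1 + (seq_len(d_out[2]) - 1) * target_spacing[2] / sp[2]
    gx <- 1 + (seq_len(d_out[3]) - 1) * target_spacing[3] / sp[3]
    out <- sample_grid(vol, gz, gy, gx, nearest = nearest)
  }
  if (is_sv)
    sequence_volume(out, target_spacing, volume$kind, volume$case_id)
  else out
}

#' Central crop (or zero-pad) to a fixed shape
#'
#' @param volume A [sequence_volume()] or 3-D array.
#' @param shape Target (slices, rows, cols); default `c(32, 224, 224)`.
#' @param center Optional (z, y, x) crop centre in voxel coordinates; by
#'   default the image centre.  Use [mask_centroid()] for the
#'   `MASK_CENTROID` policy.
#' @return Cropped/padded object of exactly `shape`.
#' @export
central_crop <- function(volume, shape = c(32L, 224L, 224L), center = NULL) {
  is_sv <- inherits(volume, "sequence_volume")
  vol <- if (is_sv) volume$voxels else volume
  d <- dim(vol)
  shape <- as.integer(shape)
  ctr <- if (is.null(center)) (d + 1) / 2 else as.numeric(center)
  out <- array(0, dim = shape)
  # window in input coordinates, clamped to the array; remainder is padding
  lo_in <- integer(3); hi_in <- integer(3); lo_out <- integer(3)
  for (a in 1:3) {
    start <- round(ctr[a] - (shape[a] + 1) / 2)  # 0-based window start;
    # symmetric: equal padding/trim on both sides for centred windows
    lo <- max(0L, as.integer(start))
    hi <- min(d[a], as.integer(start) + shape[a])
    lo_in[a] <- lo + 1L; hi_in[a] <- hi
    lo_out[a] <- lo - as.integer(start) + 1L
    if (hi < lo) { lo_in[a] <- 1L; hi_in[a] <- 0L }
  }
  if (all(hi_in >= lo_in)) {
    block <- vol[lo_in[1]:hi_in[1], lo_in[2]:hi_in[2], lo_in[3]:hi_in[3],
                 drop = FALSE]
    out[lo_out[1]:(lo_out[1] + dim(block)[1] - 1L),
        lo_out[2]:(lo_out[2] + dim(block)[2] - 1L),
        lo_out[3]:(lo_out[3] + dim(block)[3] - 1L)] <- block
  }
  if (is_sv) sequence_volume(out, volume$spacing, volume$kind, volume$case_id)
  else out
}

#' Centroid of a binary mask in voxel coordinates
#'
#' @param mask Binary 3-D array.
#' @return Numeric (z, y, x) centroid (1-based voxel indices).
#' @export
mask_centroid <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stopf("mask is empty; no centroid")
  colMeans(idx)
}

#' Per-image min-max normalisation to \[0, 1\]
#'
#' Subtracts the image minimum and divides by the intensity range, per
#' sequence and per patient.  A constant image (zero range) maps to all
#' zeros with a warning.
#'
#' @param volume A [sequence_volume()] or 3-D array.
#' @return Normalised object with intensities in \[0, 1\].
#' @export
minmax_normalize <- function(volume) {
  is_sv <- inherits(volume, "sequence_volume")
  vol <- if (is_sv) volume$voxels else volume
  rng <- range(vol)
  if (rng[2] - rng[1] <= 0) {
    warnf("constant image: min-max range is zero, returning all zeros")
    out <- array(0, dim = dim(vol))
  } else {
    out <- (vol - rng[1]) / (rng[2] - rng[1])
  }
  if (is_sv) sequence_volume(out, volume$spacing, volume$kind, volume$case_id)
  else out
}

#' Prostate volume from a gland mask
#'
#' `N_voxels * dz*dy*dx / 1000`: voxel count times single-voxel volume in
#' mm^3, converted to mL (1000 mm^3 per mL, made explicit to avoid silent
#' unit bugs).
#'
#' @param mask Binary 3-D array.
#' @param spacing (dz, dy, dx) in mm.
#' @return Gland volume in mL.
#' @export
prostate_volume <- function(mask, spacing) {
  if (!all(mask %in% c(0, 1))) stopf("mask must be binary")
  n_vox <- sum(mask)
  if (n_vox == 0) stopf("empty gland mask: volume would be zero and PSA density undefined")
  n_vox * prod(spacing) / 1000
}

#' PSA density
#'
#' @param psa PSA in ng/mL (>= 0).
#' @param gland_volume Gland volume in mL (> 0).
#' @return PSA density in ng/mL per mL.
#' @export
psa_density <- function(psa, gland_volume) {
  if (gland_volume <= 0) stopf("gland volume must be > 0, got %s", gland_volume)
  if (psa < 0) stopf("psa must be >= 0")
  psa / gland_volume
}

#' Fit \[-1, 1\] clinical scaling bounds on the training cohort
#'
#' @param records List of [clinical_record()] (training cohort only, to
#'   avoid leakage).
#' @return A named list of `(min, max)` per variable (`age`, `psa`, `psad`).
#' @export
fit_clinical_bounds <- function(records) {
  grab <- function(f) {
    v <- vapply(records, function(r) as.numeric(r[[f]]), numeric(1))
    v[is.finite(v)]
  }
  mk <- function(v) if (length(v)) c(min = min(v), max = max(v)) else c(min = NA_real_, max = NA_real_)
  list(age = mk(grab("age")), psa = mk(grab("psa")),
       psad = mk(grab("psa_density")))
}

scale_one <- function(x, b, what) {
  if (is.na(x)) return(NA_real_)
  if (any(is.na(b))) return(NA_real_)
  if (b["max"] == b["min"]) {
    warnf("degenerate bounds for %s (min == max): mapping to 0", what)
    return(0)
  }
  min(1, max(-1, 2 * (x - b["min"]) / (b["max"] - b["min"]) - 1))
}

#' Scale a clinical record to \[-1, 1\]
#'
#' `x -> 2 (x - min) / (max - min) - 1` with bounds fitted on the training
#' cohort; out-of-range values (e.g. test cases beyond the training range)
#' are clipped to \[-1, 1\].
#'
#' @param record A [clinical_record()].
#' @param bounds Output of [fit_clinical_bounds()].
#' @return The record with `age_norm`, `psa_norm`, `psad_norm` filled in.
#' @export
scale_clinical <- function(record, bounds) {
  record$age_norm <- unname(scale_one(record$age, bounds$age, "age"))
  record$psa_norm <- unname(scale_one(record$psa, bounds$psa, "psa"))
  record$psad_norm <- unname(scale_one(record$psa_density, bounds$psad, "psad"))
  record
}

#' Preprocess one case end-to-end
#'
#' Resample all sequences (and mask) to the target spacing, crop to the
#' configured shape (centred on the image or on the gland centroid),
#' min-max normalise each sequence, and fill PSA density when a mask is
#' present.  Normalisation is applied after cropping, so the \[0, 1\] span
#' refers to the cropped image.
#'
#' @param case A [bpmri_case()].
#' @param config A [preprocess_config()].
#' @param clinical_bounds Optional [fit_clinical_bounds()] output; when
#'   given, normalised clinical fields are filled in.
#' @return The preprocessed [bpmri_case()].
#' @export
preprocess_case <- function(case, config = preprocess_config(),
                            clinical_bounds = NULL) {
  mask_r <- NULL
  if (!is.null(case$gland_mask)) {
    gv <- prostate_volume(case$gland_mask, case$volumes$T2W$spacing)
    case$clinical$psa_density <- psa_density(case$clinical$psa, gv)
    mask_r <- resample_volume(case$gland_mask, config$target_spacing,
                              spacing = case$volumes$T2W$spacing,
                              nearest = TRUE)
  }
  center <- NULL
  if (config$crop_center_policy == "MASK_CENTROID") {
    if (is.null(mask_r))
      stopf("MASK_CENTROID crop policy requires a gland mask (case %s)",
            case$case_id)
    center <- mask_centroid(mask_r)
  }
  for (k in SEQUENCE_KINDS) {
    v <- resample_volume(case$volumes[[k]], config$target_spacing)
    v <- central_crop(v, config$crop_shape, center = center)
    case$volumes[[k]] <- minmax_normalize(v)
  }
  if (!is.null(mask_r))
    case$gland_mask <- central_crop(mask_r, config$crop_shape, center = center)
  if (!is.null(clinical_bounds))
    case$clinical <- scale_clinical(case$clinical, clinical_bounds)
  case
}
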