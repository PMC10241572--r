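#' Phantom generation parameters
#'
#' Describes the synthetic CT-like volumes used in place of clinical data:
#' a noisy soft-tissue background with one bright elliptical lesion visible
#' on a run of consecutive slices. The two classes share the *same*
#' middle-slice appearance distribution by construction; class identity
#' lives only in how the lesion moves across slices ("tubular" drifts
#' consistently along one direction, like a tubular organ crossing slices;
#' "focal" jitters in an independent direction per slice). A single middle
#' slice therefore carries no class signal, which is what makes the 2.5D
#' advantage testable.
#'
#' @param n_slices,height,width volume shape (slices, rows, columns).
#' @param lesion_radius_px_range semi-axis range in pixels; both ellipse
#'   semi-axes are drawn uniformly from it (per patient).
#' @param drift_px per-slice lesion displacement in pixels.
#' @param lesion_contrast_hu lesion brightness over the background, HU.
#' @param background_hu mean background attenuation, HU.
#' @param noise_sd_hu Gaussian noise standard deviation, HU.
#' @param n_lesion_slices number of consecutive slices showing the lesion
#'   (odd, so a middle slice exists).
#' @param box_margin_px margin added around the lesion extent when the
#'   per-slice annotation box is drawn.
#' @param pixel_spacing,slice_thickness geometry metadata (mm).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_slices = 24L, height = 96L, width = 96L,
                         lesion_radius_px_range = c(4, 7), drift_px = 3,
                         lesion_contrast_hu = 60, background_hu = 30,
                         noise_sd_hu = 8, n_lesion_slices = 5L,
                         box_margin_px = 6L, pixel_spacing = c(0.7, 0.7),
                         slice_thickness = 4) {
  stopifnot(drift_px >= 0, n_lesion_slices %% 2 == 1, n_lesion_slices >= 3)
  if (n_slices < n_lesion_slices + 2)
    stop("volume too short to hold the lesion run with neighbours")
  structure(list(n_slices = as.integer(n_slices), height = as.integer(height),
                 width = as.integer(width),
                 lesion_radius_px_range = lesion_radius_px_range,
                 drift_px = drift_px, lesion_contrast_hu = lesion_contrast_hu,
                 background_hu = background_hu, noise_sd_hu = noise_sd_hu,
                 n_lesion_slices = as.integer(n_lesion_slices),
                 box_margin_px = as.integer(box_margin_px),
                 pixel_spacing = pixel_spacing,
                 slice_thickness = slice_thickness),
            class = "phantom_spec")
}

#' Generate one phantom volume with per-slice lesion annotations
#'
#' The lesion appears on `n_lesion_slices` consecutive slices. The middle
#' lesion slice is drawn from a sampler shared by both classes (identical
#' marginal distribution). Class `"tubular"` moves the lesion centre by
#' `drift_px` per slice along one direction drawn once per patient; class
#' `"focal"` displaces it from the middle position by `drift_px` in an
#' independently resampled direction on every other slice. Stored values
#' encode HU with slope 1 and intercept -1024. Lesion placement is drawn
#' from the region where every slice's lesion and box stay inside the
#' volume (bounded retries, then error).
#'
#' @param class_label `"tubular"` or `"focal"`.
#' @param spec a [phantom_spec()].
#' @param seed integer seed; the same seed and class reproduce the volume
#'   bit for bit.
#' @param patient_id identifier stamped on the volume and annotations.
#' @return list with `volume` (a [ct_volume()]) and `annotations` (list of
#'   [box_annotation()], one per lesion slice, 0-based slice indices).
#' @export
generate_phantom_volume <- function(class_label = c("tubular", "focal"),
                                    spec = phantom_spec(), seed = 1L,
                                    patient_id = "phantom") {
  class_label <- match.arg(class_label)
  set.seed(seed)
  H <- spec$height; W <- spec$width
  nl <- spec$n_lesion_slices
  half <- (nl - 1L) %/% 2L
  a <- stats::runif(1, spec$lesion_radius_px_range[1], spec$lesion_radius_px_range[2])
  b <- stats::runif(1, spec$lesion_radius_px_range[1], spec$lesion_radius_px_range[2])
  k_start <- sample(2:(spec$n_slices - nl), 1)
  # identical safe region for both classes keeps the middle-slice sampler shared
  off_max <- half * spec$drift_px
  bound <- ceiling(max(a, b)) + spec$box_margin_px + off_max + 2
  if (2 * bound + 2 >= min(H, W))
    stop("lesion cannot fit inside the volume for this spec")
  cy <- stats::runif(1, bound + 1, H - bound)
  cx <- stats::runif(1, bound + 1, W - bound)
  phi <- stats::runif(1, 0, 2 * pi)
  u <- c(cos(phi), sin(phi))                     # (row, col) direction
  centres <- matrix(NA_real_, nl, 2)
  for (j in seq_len(nl)) {
    k_rel <- j - 1L - half                       # -half .. +half
    if (class_label == "tubular") {
      off <- k_rel * spec$drift_px * u
    } else if (k_rel == 0L) {
      off <- c(0, 0)
    } else {
      phi_k <- stats::runif(1, 0, 2 * pi)
      off <- spec$drift_px * c(cos(phi_k), sin(phi_k))
    }
    centres[j, ] <- c(cy, cx) + off
  }
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  slices <- vector("list", spec$n_slices)
  for (k in seq_len(spec$n_slices)) {
    hu <- spec$background_hu + stats::rnorm(H * W, 0, spec$noise_sd_hu)
    dim(hu) <- c(H, W)
    j <- k - k_start + 1L
    if (j >= 1 && j <= nl) {
      inside <- ((rows - centres[j, 1]) / b)^2 +
                ((cols - centres[j, 2]) / a)^2 <= 1
      hu[inside] <- hu[inside] + spec$lesion_contrast_hu
    }
    slices[[k]] <- round_half_away(hu) + 1024   # stored, slope 1, intercept -1024
  }
  volume <- ct_volume(patient_id, slices,
                      rescale_slope = 1, rescale_intercept = -1024,
                      pixel_spacing = spec$pixel_spacing,
                      slice_positions = seq_len(spec$n_slices) * spec$slice_thickness,
                      slice_thickness = spec$slice_thickness)
  annotations <- lapply(seq_len(nl), function(j) {
    k <- k_start + j - 1L
    rmin <- floor(centres[j, 1] - b) - spec$box_margin_px
    rmax <- ceiling(centres[j, 1] + b) + spec$box_margin_px
    cmin <- floor(centres[j, 2] - a) - spec$box_margin_px
    cmax <- ceiling(centres[j, 2] + a) + spec$box_margin_px
    box_annotation(patient_id, k - 1L,
                   c(cmin - 1, rmin - 1, cmax - cmin + 1, rmax - rmin + 1),
                   class_label)
  })
  for (ann in annotations) validate_annotation(ann, volume)
  list(volume = volume, annotations = annotations,
       lesion_centres = centres, drift_direction = u)
}

#' Generate a phantom cohort
#'
#' One volume per synthetic patient, `n_per_class` patients for each of the
#' two classes, with unique patient ids and per-patient seeds derived from
#' `seed`. With `out_dir` set, writes a DICOM series per patient plus
#' `annotations.csv` and `manifest.csv` in the formats the readers of this
#' package consume; with `out_dir = NULL` everything stays in memory.
#'
#' @param n_per_class patients per class (>= 1).
#' @param spec a [phantom_spec()].
#' @param seed integer base seed.
#' @param out_dir output directory or `NULL`.
#' @return list with `volumes` (named by patient id), `annotations` (flat
#'   list) and `manifest` (one row per annotated slice).
#' @export
generate_cohort <- function(n_per_class, spec = phantom_spec(), seed = 1L,
                            out_dir = NULL) {
  stopifnot(n_per_class >= 1)
  volumes <- list()
  annotations <- list()
  rows <- list()
  idx <- 0L
  for (cls in c("tubular", "focal")) {
    for (i in seq_len(n_per_class)) {
      idx <- idx + 1L
      pid <- sprintf("%s%04d", toupper(substr(cls, 1, 3)), i)
      g <- generate_phantom_volume(cls, spec, seed = (seed + 7919L * idx) %% 2147483647L,
                                   patient_id = pid)
      volumes[[pid]] <- g$volume
      annotations <- c(annotations, g$annotations)
      for (ann in g$annotations) {
        rows[[length(rows) + 1L]] <-
          data.frame(id = sprintf("%s_s%02d", pid, ann$slice_index),
                     patient_id = pid, label = cls,
                     fold = NA_integer_, fake = FALSE,
                     stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (pid in names(volumes))
      write_dicom_series(volumes[[pid]], file.path(out_dir, pid))
    write_annotation_table(annotations, file.path(out_dir, "annotations.csv"))
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(volumes = volumes, annotations = annotations, manifest = manifest)
}
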