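#' Configuration for the synthetic paired-modality cohort generator
#'
#' Describes a cohort of subjects, each with a co-registered sMRI-like and
#' PET-like 3D volume and a binary diagnosis (AD or CN). The generator plants
#' a focal multiplicative intensity reduction (an atrophy/hypometabolism
#' analogue) inside a sphere in the AD class of both modalities.
#'
#' @param n_ad,n_cn subject counts per class. Defaults mirror a typical
#'   clinical AD/CN cohort of 88 patients and 122 controls.
#' @param grid edge length of the cubic volume in voxels (default 64).
#' @param lesion_center voxel coordinate (1-based) of the lesion sphere
#'   center; default sits in a deep off-center location inside the
#'   ellipsoidal brain support, scaled with `grid`.
#' @param lesion_radius lesion sphere radius in voxels (default `grid / 8`).
#' @param effect_size fractional intensity reduction inside the lesion for AD
#'   subjects, in `[0, 1]`.
#' @param noise_sd standard deviation of additive voxel noise (independent
#'   per modality).
#' @param subject_sd standard deviation of the per-subject global intensity
#'   scale jitter.
#' @param seed integer RNG seed; a fixed seed yields a byte-identical cohort.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_ad = 88L, n_cn = 122L, grid = 64L,
                             lesion_center = NULL, lesion_radius = NULL,
                             effect_size = 0.3, noise_sd = 0.05,
                             subject_sd = 0.1, seed = 1L) {
  grid <- as.integer(grid)
  if (is.null(lesion_radius)) lesion_radius <- max(2, round(grid / 8))
  if (is.null(lesion_center))
    lesion_center <- round((grid + 1) / 2 + (grid / 2) * c(-0.30, 0.25, -0.20))
  cfg <- list(n_ad = as.integer(n_ad), n_cn = as.integer(n_cn), grid = grid,
              lesion_center = as.numeric(lesion_center),
              lesion_radius = as.numeric(lesion_radius),
              effect_size = as.numeric(effect_size),
              noise_sd = as.numeric(noise_sd),
              subject_sd = as.numeric(subject_sd), seed = as.integer(seed))
  if (cfg$effect_size < 0 || cfg$effect_size > 1)
    stop("synthetic_config: effect_size must lie in [0, 1]")
  if (cfg$n_ad < 0 || cfg$n_cn < 0 || cfg$n_ad + cfg$n_cn < 1)
    stop("synthetic_config: need at least one subject")
  if (any(cfg$lesion_center - cfg$lesion_radius < 1) ||
      any(cfg$lesion_center + cfg$lesion_radius > grid))
    stop("synthetic_config: lesion sphere extends outside the grid")
  class(cfg) <- "synthetic_config"
  cfg
}

#' Construct a subject
#'
#' @param subject_id opaque identifier string.
#' @param smri,pet co-registered [volume()] objects of identical shape.
#' @param label diagnostic class, `"AD"` or `"CN"`.
#' @return A `subject` list.
#' @export
subject <- function(subject_id, smri, pet, label) {
  smri <- as_volume(smri); pet <- as_volume(pet)
  if (!identical(dim(smri$data), dim(pet$data)))
    stop("subject: sMRI and PET volumes must share a shape (co-registered)")
  label <- match.arg(label, c("AD", "CN"))
  structure(list(subject_id = as.character(subject_id), smri = smri,
                 pet = pet, label = label), class = "adfuse_subject")
}

# Smooth ellipsoidal "brain" support with a soft edge plus a mild radial
# intensity profile, on a grid of edge g. Returns an array in [0, ~1].
brain_phantom <- function(g) {
  u <- (seq_len(g) - (g + 1) / 2) / (g / 2)
  ux <- array(rep(u, times = g * g), c(g, g, g))
  uy <- aperm(ux, c(2, 1, 3))
  uz <- aperm(ux, c(3, 2, 1))
  re2 <- (ux / 0.85)^2 + (uy / 0.72)^2 + (uz / 0.80)^2
  edge <- 1 / (1 + exp((sqrt(re2) - 1) / 0.06))
  edge * (0.75 + 0.25 * exp(-re2))
}

# Lesion field: 1 inside the sphere, Gaussian falloff of 1 voxel outside.
lesion_field <- function(g, center, radius) {
  ax <- seq_len(g)
  dx2 <- outer(outer((ax - center[1])^2, (ax - center[2])^2, `+`),
               (ax - center[3])^2, `+`)
  d <- sqrt(dx2)
  ifelse(d <= radius, 1, exp(-(d - radius)^2 / 2))
}

#' Generate a synthetic paired-modality cohort
#'
#' Each subject's two volumes share a smooth ellipsoidal brain support and a
#' per-subject global intensity scale; modality-specific additive noise is
#' drawn independently. AD subjects additionally have intensities inside the
#' lesion sphere multiplied by `1 - effect_size` (with a 1-voxel Gaussian
#' falloff at the boundary) in both modalities. Every volume is min-max
#' normalized to `[0, 1]`, per modality. Generation is a pure function of
#' `cfg$seed`.
#'
#' @param cfg a [synthetic_config()].
#' @return List of [subject()] objects (AD subjects first).
#' @examples
#' coh <- generate_cohort(synthetic_config(n_ad = 2, n_cn = 2, grid = 16,
#'                                         seed = 7))
#' sapply(coh, `[[`, "label")
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  g <- cfg$grid
  base <- brain_phantom(g)
  les <- 1 - cfg$effect_size * lesion_field(g, cfg$lesion_center, cfg$lesion_radius)
  labels <- c(rep("AD", cfg$n_ad), rep("CN", cfg$n_cn))
  with_local_seed(cfg$seed, {
    lapply(seq_along(labels), function(i) {
      lab <- labels[i]
      scale <- exp(rnorm(1, 0, cfg$subject_sd))
      sig <- base * scale
      if (lab == "AD") sig <- sig * les
      mk <- function() {
        v <- sig + array(rnorm(g^3, 0, cfg$noise_sd), c(g, g, g))
        normalize_minmax(volume(v))
      }
      subject(sprintf("S%03d_%s", i, lab), mk(), mk(), lab)
    })
  })
}

cohort_labels <- function(cohort) vapply(cohort, `[[`, character(1), "label")

#' Write a cohort to disk as NIfTI volumes plus a CSV manifest
#'
#' @param cohort list of [subject()]s.
#' @param dir output directory (created if missing).
#' @return Path of the manifest CSV (columns `subject_id`, `smri_path`,
#'   `pet_path`, `label`), invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(s) {
    sp <- file.path(dir, paste0(s$subject_id, "_smri.nii.gz"))
    pp <- file.path(dir, paste0(s$subject_id, "_pet.nii.gz"))
    write_volume(s$smri, sp)
    write_volume(s$pet, pp)
    data.frame(subject_id = s$subject_id, smri_path = sp, pet_path = pp,
               label = s$label, stringsAsFactors = FALSE)
  })
  manifest <- file.path(dir, "manifest.csv")
  write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort from a manifest CSV
#'
#' @param manifest path to a CSV with columns `subject_id`, `smri_path`,
#'   `pet_path`, `label` (paths relative to the manifest's directory or
#'   absolute).
#' @return List of [subject()]s.
#' @export
read_cohort <- function(manifest) {
  df <- read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("subject_id", "smri_path", "pet_path", "label")
  if (!all(need %in% names(df)))
    stop(sprintf("read_cohort: manifest must have columns %s",
                 paste(need, collapse = ", ")))
  root <- dirname(manifest)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(root, p))
  lapply(seq_len(nrow(df)), function(i) {
    subject(df$subject_id[i], read_volume(resolve(df$smri_path[i])),
            read_volume(resolve(df$pet_path[i])), df$label[i])
  })
}
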