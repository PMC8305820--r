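#' Specification of a synthetic renal-ultrasound cohort
#'
#' Describes a two-class cohort of speckle-textured grayscale slices with
#' annular parenchyma masks. The two classes are labelled `"MN"`
#' (membranous nephropathy, class A, the positive class downstream) and
#' `"IgA"` (IgA nephropathy, class B). Class difference enters the speckle
#' model in two ways, both scaled by `texture_effect`: MN slices get a
#' longer speckle correlation length (`base_sigma * (1 + texture_effect)`
#' versus `base_sigma`) and a mean echogenicity offset
#' (`mean_shift * texture_effect` gray levels). With `texture_effect = 0`
#' the two classes are drawn from the identical distribution.
#'
#' The default geometry reproduces the bookkeeping of a 68-patient renal
#' ultrasound cohort: 46 MN + 22 IgA patients, at least 9 slices each,
#' 623 slices in total, split at the patient level into 51 training cases
#' (470 slices) and 17 validation cases (9 MN + 8 IgA, 153 slices). The
#' eleven extra tenth slices are assigned to training patients so those
#' totals hold exactly.
#'
#' @param n_patients_class_A number of MN patients (default 46).
#' @param n_patients_class_B number of IgA patients (default 22).
#' @param slices_per_patient minimum slices per patient (default 9; at
#'   least 9 to honour the at-least-nine-slices design).
#' @param n_extra_slice_patients training patients receiving one extra
#'   slice (default 11).
#' @param n_val_A,n_val_B validation patients per class (defaults 9 and 8).
#' @param image_size integer vector `c(rows, cols)` (default 256 x 256).
#' @param texture_effect non-negative class-separation scale (default 1).
#' @param noise_sd additive Gaussian noise, 8-bit gray levels (default 4).
#' @param base_sigma base speckle correlation length in pixels (default 2).
#' @param speckle_scale log-amplitude of the exponentiated speckle field.
#' @param envelope_gain gray-level gain applied to the speckle envelope.
#' @param mean_shift gray levels of class-A mean offset per unit effect.
#' @param seed master seed for the cohort's named random sub-streams.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients_class_A = 46, n_patients_class_B = 22,
                        slices_per_patient = 9, n_extra_slice_patients = 11,
                        n_val_A = 9, n_val_B = 8,
                        image_size = c(256L, 256L),
                        texture_effect = 1, noise_sd = 4,
                        base_sigma = 2, speckle_scale = 0.5,
                        envelope_gain = 60, mean_shift = 12,
                        seed = 7L) {
  stopifnot(n_patients_class_A >= 1, n_patients_class_B >= 1,
            slices_per_patient >= 9, n_extra_slice_patients >= 0,
            length(image_size) == 2, all(image_size >= 1),
            texture_effect >= 0, noise_sd >= 0, base_sigma > 0)
  if (n_val_A > n_patients_class_A || n_val_B > n_patients_class_B)
    stop("more validation patients requested than exist in a class")
  n_train <- (n_patients_class_A - n_val_A) + (n_patients_class_B - n_val_B)
  if (n_extra_slice_patients > n_train)
    stop("n_extra_slice_patients exceeds the number of training patients")
  structure(list(
    n_patients_class_A = as.integer(n_patients_class_A),
    n_patients_class_B = as.integer(n_patients_class_B),
    slices_per_patient = as.integer(slices_per_patient),
    n_extra_slice_patients = as.integer(n_extra_slice_patients),
    n_val_A = as.integer(n_val_A), n_val_B = as.integer(n_val_B),
    image_size = as.integer(image_size),
    texture_effect = texture_effect, noise_sd = noise_sd,
    base_sigma = base_sigma, speckle_scale = speckle_scale,
    envelope_gain = envelope_gain, mean_shift = mean_shift,
    seed = as.integer(seed)), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Synthetic ultrasound cohort spec: %d MN + %d IgA patients\n",
              x$n_patients_class_A, x$n_patients_class_B))
  cat(sprintf("  slices/patient >= %d (+1 for %d training patients), image %dx%d\n",
              x$slices_per_patient, x$n_extra_slice_patients,
              x$image_size[1], x$image_size[2]))
  cat(sprintf("  texture_effect %.3g, noise_sd %.3g, seed %d\n",
              x$texture_effect, x$noise_sd, x$seed))
  invisible(x)
}

# periodic Gaussian smoothing by FFT; returns a field standardized to
# zero mean, unit variance
smooth_field <- function(noise, sigma) {
  d <- dim(noise)
  r <- c(0:(d[1] %/% 2), -((d[1] - d[1] %/% 2 - 1):1)) # wrapped coordinates
  c_ <- c(0:(d[2] %/% 2), -((d[2] - d[2] %/% 2 - 1):1))
  k <- exp(-outer(r^2, c_^2, "+") / (2 * sigma^2))
  k <- k / sum(k)
  f <- Re(fft(fft(noise) * fft(k), inverse = TRUE)) / length(noise)
  (f - mean(f)) / sd(as.vector(f))
}

annulus_mask <- function(nr, nc, center, axes, inner_scale, theta) {
  rc <- outer(seq_len(nr), rep(1, nc)) - center[1]
  cc <- outer(rep(1, nr), seq_len(nc)) - center[2]
  u <- rc * cos(theta) + cc * sin(theta)
  v <- -rc * sin(theta) + cc * cos(theta)
  outer_d <- (u / axes[1])^2 + (v / axes[2])^2
  inner_d <- (u / (axes[1] * inner_scale))^2 + (v / (axes[2] * inner_scale))^2
  m <- matrix(0L, nr, nc)
  m[outer_d <= 1 & inner_d > 1] <- 1L
  m
}

render_slice_image <- function(spec, is_class_A, kernels) {
  sigma_key <- if (is_class_A) "A" else "B"
  field <- smooth_field(matrix(rnorm(prod(spec$image_size)),
                               spec$image_size[1], spec$image_size[2]),
                        kernels[[sigma_key]])
  env <- exp(spec$speckle_scale * field)
  img <- spec$envelope_gain * env +
    if (is_class_A) spec$mean_shift * spec$texture_effect else 0
  if (spec$noise_sd > 0)
    img <- img + matrix(rnorm(length(img), sd = spec$noise_sd),
                        nrow = nrow(img))
  matrix(as.integer(round(clamp(img, 0, 255))), nrow = nrow(img))
}

#' Generate a synthetic masked-slice cohort
#'
#' Draws every slice of the cohort described by a [cohort_spec()]: a
#' log-normal speckle texture (unit-variance Gaussian field smoothed with a
#' class-dependent kernel, exponentiated, scaled, mean-shifted for MN,
#' plus sensor noise, quantized to 8-bit) under an annulus-shaped
#' parenchyma mask with randomized center, axes and rotation. Randomness
#' flows from `spec$seed` through named sub-streams (`"cohort"` for the
#' textures, `"masks"` for mask geometry, `"split"` for the patient-level
#' split), so the same spec always yields byte-identical output.
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `us_cohort`: a list with `manifest` (a
#'   `cohort_manifest` data frame with one row per slice: `patient_id`,
#'   `class_label`, `slice_index`, `split`) and `slices` (a list of
#'   `masked_slice` objects: `image`, `mask`, `patient_id`, `slice_index`,
#'   `class_label`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_pat <- spec$n_patients_class_A + spec$n_patients_class_B
  patient_id <- sprintf("P%03d", seq_len(n_pat))
  class_label <- rep(c("MN", "IgA"),
                     c(spec$n_patients_class_A, spec$n_patients_class_B))

  val_ids <- pick_validation(patient_id, class_label, spec$n_val_A,
                             spec$n_val_B, sub_seed(spec$seed, "split"))
  split <- ifelse(patient_id %in% val_ids, "validation", "training")
  # extra slices go to the first training patients in id order so the
  # training/validation slice totals are fixed by the spec counts alone
  train_ids <- patient_id[split == "training"]
  extra_ids <- head(train_ids, spec$n_extra_slice_patients)
  n_slices <- spec$slices_per_patient + as.integer(patient_id %in% extra_ids)

  manifest <- data.frame(
    patient_id = rep(patient_id, n_slices),
    class_label = rep(class_label, n_slices),
    slice_index = unlist(lapply(n_slices, seq_len), use.names = FALSE),
    split = rep(split, n_slices),
    stringsAsFactors = FALSE)
  class(manifest) <- c("cohort_manifest", "data.frame")
  attr(manifest, "seed") <- spec$seed
  attr(manifest, "split_seed") <- sub_seed(spec$seed, "split")

  total <- nrow(manifest)
  set.seed(sub_seed(spec$seed, "masks"))
  minhw <- min(spec$image_size)
  mask_par <- data.frame(
    cr = spec$image_size[1] / 2 + runif(total, -0.05, 0.05) * spec$image_size[1],
    cc = spec$image_size[2] / 2 + runif(total, -0.05, 0.05) * spec$image_size[2],
    a = runif(total, 0.30, 0.38) * minhw,
    b = runif(total, 0.22, 0.30) * minhw,
    inner = runif(total, 0.45, 0.55),
    theta = runif(total, 0, pi))

  kernels <- list(A = spec$base_sigma * (1 + spec$texture_effect),
                  B = spec$base_sigma)
  set.seed(sub_seed(spec$seed, "cohort"))
  slices <- vector("list", total)
  for (s in seq_len(total)) {
    mask <- annulus_mask(spec$image_size[1], spec$image_size[2],
                         c(mask_par$cr[s], mask_par$cc[s]),
                         c(mask_par$a[s], mask_par$b[s]),
                         mask_par$inner[s], mask_par$theta[s])
    if (sum(mask) < 64)
      stop_stage("synthetic_cohort",
                 "image_size %dx%d too small to contain an annulus with >= 64 pixels",
                 spec$image_size[1], spec$image_size[2])
    img <- render_slice_image(spec, manifest$class_label[s] == "MN", kernels)
    slices[[s]] <- structure(list(
      patient_id = manifest$patient_id[s],
      slice_index = manifest$slice_index[s],
      class_label = manifest$class_label[s],
      image = img, mask = mask), class = "masked_slice")
  }
  structure(list(manifest = manifest, slices = slices, spec = spec),
            class = "us_cohort")
}

pick_validation <- function(patient_id, class_label, n_val_A, n_val_B, seed) {
  a <- patient_id[class_label == "MN"]
  b <- patient_id[class_label == "IgA"]
  if (n_val_A > length(a) || n_val_B > length(b))
    stop_stage("synthetic_cohort",
               "requested more validation patients than exist (MN %d/%d, IgA %d/%d)",
               n_val_A, length(a), n_val_B, length(b))
  set.seed(seed)
  c(if (n_val_A > 0) sample(a, n_val_A) else character(0),
    if (n_val_B > 0) sample(b, n_val_B) else character(0))
}

#' Assign a patient-level training/validation split
#'
#' Randomly selects `n_val_A` MN and `n_val_B` IgA patients as the
#' validation set; every slice of a patient follows its patient, so the
#' two sets never share a patient. With the manifest's own stored split
#' seed (the default) this reproduces the split the generator embedded.
#'
#' @param manifest a `cohort_manifest` data frame.
#' @param n_val_A,n_val_B validation patients per class (defaults 9 MN,
#'   8 IgA).
#' @param seed integer; defaults to the manifest's `"split_seed"`
#'   attribute.
#' @return the manifest with its `split` column reassigned.
#' @export
split_by_patient <- function(manifest, n_val_A = 9, n_val_B = 8, seed = NULL) {
  stopifnot(is.data.frame(manifest),
            all(c("patient_id", "class_label") %in% names(manifest)))
  seed <- seed %||% attr(manifest, "split_seed") %||% 1L
  pat <- unique(manifest[, c("patient_id", "class_label")])
  val_ids <- pick_validation(pat$patient_id, pat$class_label,
                             n_val_A, n_val_B, seed)
  manifest$split <- ifelse(manifest$patient_id %in% val_ids,
                           "validation", "training")
  manifest
}

#' @export
print.us_cohort <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("Synthetic ultrasound cohort: %d patients, %d slices (%dx%d)\n",
              length(unique(m$patient_id)), nrow(m),
              nrow(x$slices[[1]]$image), ncol(x$slices[[1]]$image)))
  print(table(class_label = m$class_label, split = m$split))
  invisible(x)
}

#' @export
print.masked_slice <- function(x, ...) {
  cat(sprintf("masked_slice %s #%d (%s): image %dx%d, %d ROI pixels\n",
              x$patient_id, x$slice_index, x$class_label,
              nrow(x$image), ncol(x$image), sum(x$mask)))
  invisible(x)
}
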