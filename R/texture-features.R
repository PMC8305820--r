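gl_feature_names <- c("energy", "entropy", "kurtosis", "maximum", "mean",
                      "mad", "median", "minimum", "range", "rms",
                      "skewness", "sd", "uniformity", "variance")

glcm_feature_names <- c("energy", "contrast", "entropy", "homogeneity",
                        "correlation", "variance", "sum_average",
                        "dissimilarity", "autocorrelation")

glrlm_feature_names <- c("sre", "lre", "gln", "rln", "rp", "lgre", "hgre",
                         "srlge", "srhge", "lrlge", "lrhge", "glv", "rlv")

radiomics_bands <- c("original", "wavelet-AA", "wavelet-AD",
                     "wavelet-DA", "wavelet-DD")

# the 4 standard distance-1 offsets (0 deg, 45 deg, 90 deg, 135 deg),
# shared by GLCM pairs and GLRLM run directions
texture_offsets <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))

#' Canonical names of the 180 radiomics features
#'
#' For each of the five bands (the original image and the four
#' non-decimated wavelet sub-bands AA/AD/DA/DD) there are 14 first-order
#' (`gl`), 9 co-occurrence (`glcm`) and 13 run-length (`glrlm`) features,
#' named `{band}_{family}_{feature}`. Order is fixed: bands in the order
#' above, families gl, glcm, glrlm within each band.
#'
#' @return character vector of length 180.
#' @export
radiomics_feature_names <- function() {
  unlist(lapply(radiomics_bands, function(b)
    c(paste(b, "gl", gl_feature_names, sep = "_"),
      paste(b, "glcm", glcm_feature_names, sep = "_"),
      paste(b, "glrlm", glrlm_feature_names, sep = "_"))),
    use.names = FALSE)
}

#' Quantize ROI intensities to Ng gray levels
#'
#' Min-max uniform binning of the in-mask intensities:
#' `level(v) = min(Ng, floor((v - min) / (max - min) * Ng) + 1)`.
#' A constant ROI maps to level 1 everywhere. Pixels outside the mask get
#' level 0 and are never touched by the matrix builders.
#'
#' @param image_in_box numeric matrix (any real values, e.g. a wavelet
#'   sub-band).
#' @param mask_in_box 0/1 matrix of the same shape.
#' @param ng number of gray levels (default 32, must be >= 2).
#' @return list of class `quantized_roi`: `levels_in_box` (integer
#'   matrix), `ng`, `mask_in_box`.
#' @export
quantize_roi <- function(image_in_box, mask_in_box, ng = 32) {
  stopifnot(is.matrix(image_in_box), identical(dim(image_in_box),
                                               dim(mask_in_box)), ng >= 2)
  inm <- mask_in_box != 0
  if (!any(inm)) stop_stage("texture_features", "empty ROI: cannot quantize")
  v <- image_in_box[inm]
  lo <- min(v); hi <- max(v)
  lev <- matrix(0L, nrow(image_in_box), ncol(image_in_box))
  if (hi > lo) {
    lev[inm] <- pmin(ng, floor((image_in_box[inm] - lo) / (hi - lo) * ng) + 1L)
  } else {
    lev[inm] <- 1L
  }
  structure(list(levels_in_box = lev, ng = as.integer(ng),
                 mask_in_box = matrix(as.integer(inm), nrow = nrow(inm))),
            class = "quantized_roi")
}

#' First-order (histogram) features of an ROI
#'
#' Fourteen statistics of the raw in-mask intensities. Moments are
#' population moments (1/N); kurtosis is non-excess (normal -> 3);
#' skewness and kurtosis of a constant ROI are 0 by convention. Entropy
#' (bits) and uniformity are computed on an `n_bins` min-max histogram of
#' the values, with 0 log 0 = 0; a constant ROI has entropy 0 and
#' uniformity 1.
#'
#' @param values numeric vector of in-mask intensities, or a `roi_view`.
#' @param n_bins histogram bins for entropy/uniformity (default 32).
#' @return named numeric vector of length 14.
#' @export
first_order_features <- function(values, n_bins = 32) {
  if (inherits(values, "roi_view")) values <- values$pixel_values
  if (length(values) == 0)
    stop_stage("texture_features", "empty ROI: no first-order features")
  n <- length(values)
  mu <- mean(values)
  m2 <- mean((values - mu)^2)
  sdv <- sqrt(m2)
  skew <- if (sdv > 0) mean((values - mu)^3) / sdv^3 else 0
  kurt <- if (sdv > 0) mean((values - mu)^4) / m2^2 else 0
  lo <- min(values); hi <- max(values)
  if (hi > lo) {
    bin <- pmin(n_bins, floor((values - lo) / (hi - lo) * n_bins) + 1L)
    p <- tabulate(bin, n_bins) / n
  } else {
    p <- c(1, numeric(n_bins - 1))
  }
  c(energy = sum(values^2),
    entropy = -sum(xlog2x(p)),
    kurtosis = kurt,
    maximum = hi,
    mean = mu,
    mad = mean(abs(values - mu)),
    median = median(values),
    minimum = lo,
    range = hi - lo,
    rms = sqrt(mean(values^2)),
    skewness = skew,
    sd = sdv,
    uniformity = sum(p^2),
    variance = m2)
}

#' Gray-level co-occurrence matrix for one offset
#'
#' Counts in-mask pixel pairs `(p, p + offset)`, symmetrizes (each pair in
#' both orders) and normalizes to sum 1. Pairs with either endpoint
#' outside the mask are ignored.
#'
#' @param q a `quantized_roi`.
#' @param offset integer `c(dr, dc)` displacement.
#' @return list of class `glcm_matrix` with `P` (Ng x Ng, sums to 1),
#'   `offset`, `n_pairs` (directed pair count before symmetrization), or
#'   `NULL` when the offset admits no valid pair (callers skip it).
#' @export
compute_glcm <- function(q, offset = c(0L, 1L)) {
  stopifnot(inherits(q, "quantized_roi"))
  counts <- glcm_counts_cpp(q$levels_in_box, q$mask_in_box,
                            as.integer(offset[1]), as.integer(offset[2]), q$ng)
  n_pairs <- sum(counts)
  if (n_pairs == 0) return(NULL)
  sym <- counts + t(counts)
  structure(list(P = sym / sum(sym), offset = as.integer(offset),
                 n_pairs = n_pairs), class = "glcm_matrix")
}

#' Haralick-style features of a co-occurrence matrix
#'
#' Nine statistics of a normalized GLCM `P` over levels `i, j = 1..Ng`:
#' energy, contrast, entropy (bits), homogeneity, correlation, variance,
#' sum average, dissimilarity, autocorrelation. For a degenerate matrix
#' with zero marginal spread the correlation is 1 by convention (all mass
#' at one level).
#'
#' @param g a `glcm_matrix` (or a plain normalized matrix).
#' @return named numeric vector of length 9.
#' @export
glcm_features <- function(g) {
  P <- if (inherits(g, "glcm_matrix")) g$P else g
  if (abs(sum(P) - 1) > 1e-8)
    stop_stage("texture_features", "GLCM not normalized: sum is %.6g", sum(P))
  ng <- nrow(P)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(P)
  mu_x <- sum(seq_len(ng) * px)
  sig_x <- sqrt(sum((seq_len(ng) - mu_x)^2 * px))
  # symmetric P => identical y marginal
  corr <- if (sig_x > 0)
    sum((i - mu_x) * (j - mu_x) * P) / sig_x^2 else 1
  # p_{x+y}(k), k = 2..2Ng
  k <- 2:(2 * ng)
  pxy <- vapply(k, function(kk) sum(P[i + j == kk]), numeric(1))
  c(energy = sum(P^2),
    contrast = sum((i - j)^2 * P),
    entropy = -sum(xlog2x(P)),
    homogeneity = sum(P / (1 + abs(i - j))),
    correlation = corr,
    variance = sum((i - mu_x)^2 * P),
    sum_average = sum(k * pxy),
    dissimilarity = sum(abs(i - j) * P),
    autocorrelation = sum(i * j * P))
}

#' Gray-level run-length matrix along one direction
#'
#' A run is a maximal chain of consecutive in-mask pixels with the same
#' quantized level along the direction; leaving the mask or the grid
#' terminates a run (runs never jump mask gaps). `R[i, r]` counts runs of
#' level `i` and length `r`.
#'
#' @param q a `quantized_roi`.
#' @param direction integer `c(dr, dc)` step.
#' @return list of class `glrlm_matrix` with `R` (Ng x Lmax run counts),
#'   `Nr` (total runs), `Np` (in-mask pixel count), `direction`.
#' @export
compute_glrlm <- function(q, direction = c(0L, 1L)) {
  stopifnot(inherits(q, "quantized_roi"))
  if (!any(q$mask_in_box != 0))
    stop_stage("texture_features", "empty ROI: no runs")
  R <- glrlm_counts_cpp(q$levels_in_box, q$mask_in_box,
                        as.integer(direction[1]), as.integer(direction[2]),
                        q$ng)
  structure(list(R = R, Nr = sum(R), Np = sum(q$mask_in_box != 0),
                 direction = as.integer(direction)), class = "glrlm_matrix")
}

#' Run-length features of a GLRLM
#'
#' The 13 classical run-length statistics (1-based level index `i`, run
#' length `r`, `Nr` total runs, `Np` in-mask pixels): short/long run
#' emphasis, gray-level and run-length non-uniformity, run percentage,
#' low/high gray-level run emphasis, the four combined short/long x
#' low/high emphases, and gray-level / run-length variance about the
#' run-weighted means.
#'
#' @param g a `glrlm_matrix`.
#' @return named numeric vector of length 13.
#' @export
glrlm_features <- function(g) {
  stopifnot(inherits(g, "glrlm_matrix"))
  R <- g$R
  Nr <- g$Nr
  if (Nr < 1) stop_stage("texture_features", "GLRLM has no runs")
  i <- matrix(seq_len(nrow(R)), nrow(R), ncol(R))
  r <- t(matrix(seq_len(ncol(R)), ncol(R), nrow(R)))
  mu_i <- sum(i * R) / Nr
  mu_r <- sum(r * R) / Nr
  c(sre = sum(R / r^2) / Nr,
    lre = sum(R * r^2) / Nr,
    gln = sum(rowSums(R)^2) / Nr,
    rln = sum(colSums(R)^2) / Nr,
    rp = Nr / g$Np,
    lgre = sum(R / i^2) / Nr,
    hgre = sum(R * i^2) / Nr,
    srlge = sum(R / (i^2 * r^2)) / Nr,
    srhge = sum(R * i^2 / r^2) / Nr,
    lrlge = sum(R * r^2 / i^2) / Nr,
    lrhge = sum(R * i^2 * r^2) / Nr,
    glv = sum((i - mu_i)^2 * R) / Nr,
    rlv = sum((r - mu_r)^2 * R) / Nr)
}

wavelet_filters <- function(family) {
  switch(family,
    haar = list(lo = c(1, 1) / sqrt(2), hi = c(1, -1) / sqrt(2)),
    db2 = {
      lo <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
      list(lo = lo, hi = rev(lo) * c(1, -1, 1, -1))
    },
    stop_stage("texture_features", "unknown wavelet family '%s'", family))
}

# periodic filtering along rows (dim = 1: across columns within each row)
# or along columns (dim = 2)
filter_periodic <- function(x, f, dim) {
  out <- matrix(0, nrow(x), ncol(x))
  n <- if (dim == 1) ncol(x) else nrow(x)
  for (k in seq_along(f)) {
    idx <- ((seq_len(n) - 1 + (k - 1)) %% n) + 1
    out <- out + f[k] * (if (dim == 1) x[, idx, drop = FALSE]
                         else x[idx, , drop = FALSE])
  }
  out
}

#' One level of the non-decimated 2-D wavelet transform
#'
#' Separable periodic filtering without downsampling, so every sub-band
#' keeps the input shape and the original ROI mask applies unchanged.
#' Sub-band names put the row filter first: `XY` applies filter `X` along
#' each row (across columns) and `Y` along each column, with `A` the
#' low-pass and `D` the high-pass. A purely horizontal ramp (intensity a
#' function of column index only) therefore loads the `DA` band.
#'
#' @param image_in_box numeric matrix (bounding-box crop).
#' @param family `"haar"` (default) or `"db2"`.
#' @return list of class `wavelet_subbands` with same-shape matrices
#'   `AA`, `AD`, `DA`, `DD` and the `family` name.
#' @export
wavelet_subbands <- function(image_in_box, family = "haar") {
  stopifnot(is.matrix(image_in_box))
  f <- wavelet_filters(family)
  support <- length(f$lo)
  if (nrow(image_in_box) < support || ncol(image_in_box) < support)
    stop_stage("texture_features",
               "bounding box %dx%d smaller than the %s filter support (%dx%d minimum)",
               nrow(image_in_box), ncol(image_in_box), family, support, support)
  rowA <- filter_periodic(image_in_box, f$lo, 1)
  rowD <- filter_periodic(image_in_box, f$hi, 1)
  structure(list(AA = filter_periodic(rowA, f$lo, 2),
                 AD = filter_periodic(rowA, f$hi, 2),
                 DA = filter_periodic(rowD, f$lo, 2),
                 DD = filter_periodic(rowD, f$hi, 2),
                 family = family), class = "wavelet_subbands")
}

band_features <- function(image_in_box, mask_in_box, band, ng, n_bins) {
  inm <- mask_in_box != 0
  fo <- first_order_features(image_in_box[inm], n_bins = n_bins)
  q <- quantize_roi(image_in_box, mask_in_box, ng)
  glcm_acc <- NULL
  n_ok <- 0
  for (off in texture_offsets) {
    g <- compute_glcm(q, off)
    if (is.null(g)) next
    v <- glcm_features(g)
    glcm_acc <- if (is.null(glcm_acc)) v else glcm_acc + v
    n_ok <- n_ok + 1
  }
  if (n_ok == 0)
    stop_stage("texture_features",
               "no valid co-occurrence pairs in any direction (band %s)", band)
  glcm_avg <- glcm_acc / n_ok
  glrlm_avg <- Reduce(`+`, lapply(texture_offsets, function(d)
    glrlm_features(compute_glrlm(q, d)))) / length(texture_offsets)
  out <- c(fo, glcm_avg, glrlm_avg)
  names(out) <- c(paste(band, "gl", gl_feature_names, sep = "_"),
                  paste(band, "glcm", glcm_feature_names, sep = "_"),
                  paste(band, "glrlm", glrlm_feature_names, sep = "_"))
  out
}

#' Extract the 180-feature radiomics vector of one masked slice
#'
#' Computes 14 first-order + 9 GLCM + 13 GLRLM features on the original
#' ROI and on each of the four non-decimated wavelet sub-bands (AA, AD,
#' DA, DD), 180 features in all. GLCM and GLRLM statistics are computed
#' per direction over the four standard distance-1 offsets and averaged
#' feature-wise. Sub-bands are re-quantized independently inside the mask
#' (their values are signed). ROIs smaller than 16 pixels are rejected:
#' their texture matrices are degenerate.
#'
#' @param slice a `masked_slice`, or a numeric image matrix (then `mask`
#'   must be given).
#' @param mask optional 0/1 matrix when `slice` is a plain matrix.
#' @param ng gray levels for quantization (default 32).
#' @param wavelet wavelet family (default `"haar"`).
#' @param n_bins histogram bins for first-order entropy/uniformity.
#' @return named numeric vector of length 180, all finite.
#' @export
extract_features <- function(slice, mask = NULL, ng = 32, wavelet = "haar",
                             n_bins = 32) {
  rv <- roi_view(slice, mask)
  if (rv$n_pixels < 16)
    stop_stage("texture_features",
               "ROI too small: %d pixels (< 16); texture statistics degenerate",
               rv$n_pixels)
  out <- band_features(rv$image_in_box, rv$mask_in_box, "original", ng, n_bins)
  sb <- wavelet_subbands(rv$image_in_box, wavelet)
  for (b in c("AA", "AD", "DA", "DD")) {
    out <- c(out, band_features(sb[[b]], rv$mask_in_box,
                                paste0("wavelet-", b), ng, n_bins))
  }
  bad <- names(out)[!is.finite(out)]
  if (length(bad) > 0)
    stop_stage("texture_features", "non-finite feature(s): %s",
               paste(bad, collapse = ", "))
  out[radiomics_feature_names()]
}

#' Extract the feature table of a whole cohort
#'
#' @param cohort a `us_cohort` (or a list of `masked_slice` objects plus a
#'   manifest).
#' @param manifest optional manifest when `cohort` is a plain slice list.
#' @inheritParams extract_features
#' @return data frame: `patient_id`, `slice_index`, `class_label`,
#'   `split`, then the 180 canonical feature columns.
#' @export
extract_feature_table <- function(cohort, manifest = NULL, ng = 32,
                                  wavelet = "haar", n_bins = 32) {
  if (inherits(cohort, "us_cohort")) {
    manifest <- cohort$manifest
    slices <- cohort$slices
  } else {
    slices <- cohort
  }
  stopifnot(length(slices) == nrow(manifest))
  feats <- t(vapply(slices, extract_features, numeric(180),
                    ng = ng, wavelet = wavelet, n_bins = n_bins))
  out <- cbind(manifest[, c("patient_id", "slice_index", "class_label",
                            "split")],
               as.data.frame(feats, check.names = FALSE))
  rownames(out) <- NULL
  out
}
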