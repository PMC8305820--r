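#' Write a synthetic cohort to disk as PNG slices plus a CSV manifest
#'
#' Slices and masks are written as 8-bit grayscale PNG; the manifest CSV
#' gains `slice_path` and `mask_path` columns (relative to `dir`).
#'
#' @param cohort a `us_cohort` from [generate_cohort()].
#' @param dir output directory (created if absent).
#' @return invisibly, the path of the written manifest CSV.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "us_cohort"))
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  m <- cohort$manifest
  m$slice_path <- sprintf("images/%s_s%02d.png", m$patient_id, m$slice_index)
  m$mask_path <- sprintf("masks/%s_s%02d.png", m$patient_id, m$slice_index)
  for (i in seq_along(cohort$slices)) {
    sl <- cohort$slices[[i]]
    png::writePNG(sl$image / 255, file.path(dir, m$slice_path[i]))
    png::writePNG(sl$mask + 0, file.path(dir, m$mask_path[i]))
  }
  path <- file.path(dir, "manifest.csv")
  write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}

read_gray <- function(path) {
  if (!file.exists(path))
    stop_stage("imaging_io", "unreadable file: '%s' does not exist", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop_stage("imaging_io", "unsupported image format '%s' (PNG/TIFF)", ext))
  if (length(dim(arr)) == 3) arr <- arr[, , 1]  # gray channel of RGB(A)
  arr * 255  # [0,1] file scale -> 8-bit gray-level convention
}

#' Load one masked slice from image and mask files
#'
#' Reads a grayscale PNG or TIFF image and a same-shaped binary mask
#' (values must be 0/maximum). Pixel intensities are returned on the
#' 0-255 gray-level scale regardless of file bit depth.
#'
#' @param image_path,mask_path file paths.
#' @param patient_id,slice_index,class_label optional manifest linkage.
#' @return a `masked_slice` object.
#' @export
load_slice <- function(image_path, mask_path, patient_id = NA_character_,
                       slice_index = NA_integer_, class_label = NA_character_) {
  img <- read_gray(image_path)
  msk <- read_gray(mask_path)
  if (!identical(dim(img), dim(msk)))
    stop_stage("imaging_io", "shape mismatch: image %s vs mask %s",
               paste(dim(img), collapse = "x"),
               paste(dim(msk), collapse = "x"))
  u <- sort(unique(as.vector(msk)))
  if (!all(u %in% c(0, max(u))))
    stop_stage("imaging_io", "mask not binary: values other than {0, max} found")
  if (max(u) == 0)
    stop_stage("imaging_io", "empty mask: no foreground pixels in '%s'", mask_path)
  structure(list(patient_id = patient_id, slice_index = slice_index,
                 class_label = class_label, image = img,
                 mask = matrix(as.integer(msk > 0), nrow = nrow(msk))),
            class = "masked_slice")
}

#' Load a cohort previously written by [write_cohort()]
#'
#' @param manifest_path path to the manifest CSV.
#' @return a `us_cohort` object.
#' @export
load_cohort <- function(manifest_path) {
  m <- read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("patient_id", "class_label", "slice_index", "split",
            "slice_path", "mask_path")
  if (!all(need %in% names(m)))
    stop_stage("imaging_io", "manifest missing columns: %s",
               paste(setdiff(need, names(m)), collapse = ", "))
  base <- dirname(manifest_path)
  slices <- lapply(seq_len(nrow(m)), function(i)
    load_slice(file.path(base, m$slice_path[i]), file.path(base, m$mask_path[i]),
               m$patient_id[i], m$slice_index[i], m$class_label[i]))
  man <- m[, c("patient_id", "class_label", "slice_index", "split")]
  class(man) <- c("cohort_manifest", "data.frame")
  structure(list(manifest = man, slices = slices), class = "us_cohort")
}

#' Extract the region-of-interest view of a masked slice
#'
#' Crops image and mask to the tight bounding box of the mask foreground
#' and lists the in-mask pixel values in row-major order. The bounding box
#' is reported 0-based and half-open, `c(row0, col0, row1, col1)`.
#'
#' @param image numeric matrix, or a `masked_slice` (then `mask` is taken
#'   from it).
#' @param mask 0/1 integer matrix of the same shape.
#' @return a list of class `roi_view` with `pixel_values`, `bounding_box`,
#'   `image_in_box`, `mask_in_box`, `n_pixels`.
#' @export
roi_view <- function(image, mask = NULL) {
  if (inherits(image, "masked_slice")) {
    mask <- image$mask
    image <- image$image
  }
  stopifnot(is.matrix(image), is.matrix(mask),
            identical(dim(image), dim(mask)))
  fg <- which(mask != 0, arr.ind = TRUE)
  if (nrow(fg) == 0) stop_stage("imaging_io", "empty mask: ROI has no pixels")
  r0 <- min(fg[, 1]); r1 <- max(fg[, 1])
  c0 <- min(fg[, 2]); c1 <- max(fg[, 2])
  ib <- image[r0:r1, c0:c1, drop = FALSE]
  mb <- mask[r0:r1, c0:c1, drop = FALSE]
  # row-major listing of in-mask pixels
  pv <- t(ib)[t(mb) != 0]
  structure(list(pixel_values = as.numeric(pv),
                 bounding_box = c(r0 - 1L, c0 - 1L, r1, c1),
                 image_in_box = ib,
                 mask_in_box = matrix(as.integer(mb != 0), nrow = nrow(mb)),
                 n_pixels = length(pv)),
            class = "roi_view")
}

#' Write / read a per-slice feature table as CSV
#'
#' The table holds the key columns `patient_id`, `slice_index`,
#' `class_label`, `split` followed by the 180 canonical feature columns in
#' canonical order. Values round-trip losslessly to 15 significant
#' digits.
#'
#' @param table a feature table data frame.
#' @param path CSV path.
#' @return `write_feature_table` invisibly returns `path`;
#'   `read_feature_table` returns the table.
#' @export
write_feature_table <- function(table, path) {
  fn <- radiomics_feature_names()
  missing <- setdiff(fn, names(table))
  if (length(missing) > 0)
    stop_stage("imaging_io", "feature table missing column(s): %s",
               paste(missing, collapse = ", "))
  keys <- intersect(c("patient_id", "slice_index", "class_label", "split"),
                    names(table))
  out <- table[, c(keys, fn), drop = FALSE]
  for (j in fn) out[[j]] <- sprintf("%.15g", out[[j]])
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  fn <- radiomics_feature_names()
  missing <- setdiff(fn, names(tab))
  if (length(missing) > 0)
    stop_stage("imaging_io", "feature table missing column(s): %s",
               paste(missing, collapse = ", "))
  extra <- setdiff(names(tab),
                   c("patient_id", "slice_index", "class_label", "split", fn))
  if (length(extra) > 0)
    stop_stage("imaging_io", "unexpected column(s) in feature table: %s",
               paste(extra, collapse = ", "))
  for (j in fn) tab[[j]] <- as.numeric(tab[[j]])
  keys <- intersect(c("patient_id", "slice_index", "class_label", "split"),
                    names(tab))
  tab[, c(keys, fn), drop = FALSE]
}
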