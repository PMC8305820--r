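full <- function(nr, nc) matrix(1L, nr, nc)

test_that("quantization maps endpoints, constants and two-point sets correctly", {
  q <- quantize_roi(matrix(c(0, 100, 200, 255), 2, 2), full(2, 2), ng = 32)
  expect_equal(q$levels_in_box[1, 1], 1L)   # minimum -> level 1
  expect_equal(q$levels_in_box[2, 2], 32L)  # maximum -> level Ng
  qc <- quantize_roi(matrix(7, 3, 3), full(3, 3), ng = 32)
  expect_true(all(qc$levels_in_box == 1L))
  q2 <- quantize_roi(matrix(c(10, 20), 1, 2), full(1, 2), ng = 2)
  expect_equal(as.vector(q2$levels_in_box), c(1L, 2L))
  expect_error(quantize_roi(matrix(1, 2, 2), matrix(0L, 2, 2)), "empty ROI")
})

test_that("first-order features match hand arithmetic", {
  f <- first_order_features(c(2, 4, 6, 8))
  expect_equal(unname(f["mean"]), 5)
  expect_equal(unname(f["range"]), 6)
  expect_equal(unname(f["variance"]), 5)
  expect_equal(unname(f["rms"]), sqrt(30))
  expect_equal(unname(f["energy"]), 4 + 16 + 36 + 64)
  expect_equal(unname(f["median"]), 5)
  expect_equal(unname(f["mad"]), 2)

  fc <- first_order_features(rep(3, 10))
  expect_equal(unname(fc[c("entropy", "uniformity", "variance",
                           "skewness", "kurtosis")]), c(0, 1, 0, 0, 0))

  f2 <- first_order_features(c(0, 0, 1, 1), n_bins = 2)
  expect_equal(unname(f2["entropy"]), 1)     # two equal bins -> 1 bit
  expect_equal(unname(f2["uniformity"]), 0.5)
  expect_error(first_order_features(numeric(0)), "empty ROI")
})

test_that("GLCM of simple patterns matches enumeration", {
  # two rows of constant levels: both horizontal pairs are concordant
  q <- quantize_roi(matrix(c(1, 2, 1, 2), 2, 2), full(2, 2), ng = 2)
  g <- compute_glcm(q, c(0L, 1L))
  expect_equal(g$P, matrix(c(0.5, 0, 0, 0.5), 2, 2))
  f <- glcm_features(g)
  expect_equal(unname(f[c("energy", "contrast", "homogeneity",
                          "dissimilarity", "autocorrelation")]),
               c(0.5, 0, 1, 0, 2.5))
  expect_equal(unname(f["sum_average"]), 3)  # p_{x+y}(2) = p_{x+y}(4) = 0.5

  # checkerboard: every horizontal pair is discordant
  cb <- (outer(1:4, 1:4, "+") %% 2L) * 100L
  qcb <- quantize_roi(cb, full(4, 4), ng = 2)
  fcb <- glcm_features(compute_glcm(qcb, c(0L, 1L)))
  expect_equal(unname(fcb["contrast"]), 1)
  expect_equal(unname(fcb["energy"]), 0.5)

  # all mass at one cell
  single <- glcm_features(matrix(c(1, 0, 0, 0), 2, 2))
  expect_equal(unname(single[c("energy", "entropy", "contrast",
                               "correlation")]), c(1, 0, 0, 1))

  # independent uniform P has correlation 0
  unif <- glcm_features(matrix(0.25, 2, 2))
  expect_equal(unname(unif["correlation"]), 0)

  expect_error(glcm_features(matrix(0.4, 2, 2)), "not normalized")
})

test_that("GLRLM of simple rows matches run enumeration", {
  q <- quantize_roi(matrix(c(10, 10, 20), 1, 3), full(1, 3), ng = 2)
  g <- compute_glrlm(q, c(0L, 1L))
  expect_equal(g$Nr, 2)
  expect_equal(g$R[1, 2], 1L)  # run of level 1, length 2
  expect_equal(g$R[2, 1], 1L)
  f <- glrlm_features(g)
  expect_equal(unname(f[c("sre", "lre", "rp", "hgre")]),
               c(0.625, 2.5, 2 / 3, 2.5))

  # constant row: one run of length n
  qc <- quantize_roi(matrix(5, 1, 6), full(1, 6), ng = 4)
  gc <- compute_glrlm(qc, c(0L, 1L))
  expect_equal(gc$Nr, 1)
  expect_equal(gc$R[1, 6], 1L)
  fc <- glrlm_features(gc)
  expect_equal(unname(fc[c("gln", "rln", "glv", "rlv")]), c(1, 1, 0, 0))

  # checkerboard: all runs length 1
  cb <- (outer(1:4, 1:4, "+") %% 2L) * 100L
  fcb <- glrlm_features(compute_glrlm(quantize_roi(cb, full(4, 4), 2),
                                      c(0L, 1L)))
  expect_equal(unname(fcb[c("sre", "lre", "rp")]), c(1, 1, 1))
})

test_that("compiled GLCM/GLRLM agree with brute-force enumeration", {
  set.seed(31)
  dirs <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
  for (rep in 1:60) {
    nr <- sample(8:16, 1); nc <- sample(8:16, 1)
    f <- random_masked_image(nr, nc)
    ng <- sample(c(4L, 8L, 16L), 1)
    q <- quantize_roi(f$image, f$mask, ng)
    for (d in dirs) {
      ours <- sonoradiomics:::glcm_counts_cpp(q$levels_in_box, q$mask_in_box,
                                              d[1], d[2], ng)
      expect_identical(ours, brute_glcm_counts(q$levels_in_box, q$mask_in_box,
                                               d[1], d[2], ng))
      r_ours <- sonoradiomics:::glrlm_counts_cpp(q$levels_in_box,
                                                 q$mask_in_box, d[1], d[2], ng)
      expect_identical(r_ours, brute_glrlm_counts(q$levels_in_box,
                                                  q$mask_in_box, d[1], d[2], ng))
      # conservation: run-length mass equals in-mask pixel count
      expect_equal(sum(r_ours %*% seq_len(ncol(r_ours))), sum(q$mask_in_box))
      g <- compute_glcm(q, d)
      if (!is.null(g)) expect_equal(sum(g$P), 1)
    }
  }
})

test_that("wavelet sub-bands have the non-decimated shape and filter roles", {
  const <- matrix(4, 6, 7)
  sb <- wavelet_subbands(const, "haar")
  expect_equal(dim(sb$AA), c(6L, 7L))
  expect_true(all(abs(sb$AD) < 1e-12))
  expect_true(all(abs(sb$DA) < 1e-12))
  expect_true(all(abs(sb$DD) < 1e-12))
  expect_true(all(abs(sb$AA - 8) < 1e-12))  # 4 * sqrt(2)^2

  # horizontal ramp (varies across columns): row high-pass catches it
  ramp <- matrix(rep(1:8, each = 8), 8, 8)
  sbr <- wavelet_subbands(ramp, "haar")
  # periodic wrap-around contributes one column of edge energy; interior:
  interior <- 1:6
  expect_true(all(abs(sbr$DD[, interior]) < 1e-12))
  expect_true(sum(sbr$DA[, interior]^2) > 1)
  expect_true(all(abs(sbr$AD[, interior]) < 1e-12))

  expect_error(wavelet_subbands(matrix(1, 1, 5), "haar"), "filter support")
  expect_error(wavelet_subbands(matrix(1, 3, 3), "db2"), "filter support")
  sb2 <- wavelet_subbands(matrix(rnorm(64), 8, 8), "db2")
  expect_equal(dim(sb2$DD), c(8L, 8L))
})

test_that("extractor emits 180 finite canonically named features", {
  set.seed(12)
  f <- random_masked_image(24, 20)
  f$mask[] <- 1L  # plenty of pixels
  v <- extract_features(f$image, f$mask)
  expect_length(v, 180)
  expect_true(all(is.finite(v)))
  expect_identical(names(v), radiomics_feature_names())
  # family census within the canonical names
  nm <- radiomics_feature_names()
  expect_equal(sum(grepl("_gl_", nm)), 70)
  expect_equal(sum(grepl("_glcm_", nm)), 45)
  expect_equal(sum(grepl("_glrlm_", nm)), 65)
  expect_equal(sum(grepl("^wavelet-", nm)), 144)
  expect_error(extract_features(f$image[1:3, 1:3], f$mask[1:3, 1:3]),
               "ROI too small")
})

test_that("features are translation-invariant and shift-covariant", {
  set.seed(13)
  f <- random_masked_image(14, 14)
  f$mask[c(1, 14), ] <- 0L; f$mask[, c(1, 14)] <- 0L
  if (sum(f$mask) < 16) f$mask[4:10, 4:10] <- 1L
  big_img <- matrix(0, 22, 22); big_msk <- matrix(0L, 22, 22)
  big_img[5:18, 6:19] <- f$image; big_msk[5:18, 6:19] <- f$mask
  expect_equal(extract_features(f$image, f$mask),
               extract_features(big_img, big_msk))

  # +c on all in-mask pixels: GLCM/GLRLM invariant, first-order mean shifts
  shifted <- f$image + 40
  a <- extract_features(f$image, f$mask)
  b <- extract_features(shifted, f$mask)
  tex <- grepl("^original_(glcm|glrlm)_", names(a))
  expect_equal(b[tex], a[tex])
  expect_equal(unname(b["original_gl_mean"] - a["original_gl_mean"]), 40)
})

test_that("longer speckle correlation raises run length and lowers contrast", {
  sp <- cohort_spec(n_patients_class_A = 7, n_patients_class_B = 7,
                    n_extra_slice_patients = 0, n_val_A = 2, n_val_B = 2,
                    image_size = c(64L, 64L), texture_effect = 1.5,
                    mean_shift = 0, seed = 41)
  co <- generate_cohort(sp)  # 126 slices, MN smoother than IgA
  ft <- extract_feature_table(co)
  mn <- ft$class_label == "MN"
  expect_gt(mean(ft[["original_glrlm_lre"]][mn]),
            mean(ft[["original_glrlm_lre"]][!mn]))
  expect_lt(mean(ft[["original_glcm_contrast"]][mn]),
            mean(ft[["original_glcm_contrast"]][!mn]))
})
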