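# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (explicit loops, no shared code with the package
# internals) so they can certify the vectorized/compiled implementations.

# directed co-occurrence counts by explicit pair enumeration
brute_glcm_counts <- function(levels, mask, dr, dc, ng) {
  counts <- matrix(0L, ng, ng)
  for (r in seq_len(nrow(levels))) {
    for (c in seq_len(ncol(levels))) {
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nrow(levels) || c2 < 1 || c2 > ncol(levels)) next
      if (mask[r, c] == 0 || mask[r2, c2] == 0) next
      counts[levels[r, c], levels[r2, c2]] <- counts[levels[r, c], levels[r2, c2]] + 1L
    }
  }
  counts
}

# run-length counts by walking every line of the image in the direction
brute_glrlm_counts <- function(levels, mask, dr, dc, ng) {
  nr <- nrow(levels); nc <- ncol(levels)
  R <- matrix(0L, ng, max(nr, nc))
  seen <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (seen[r, c] || mask[r, c] == 0) next
      # walk backwards to the start of this run
      sr <- r; sc <- c
      repeat {
        pr <- sr - dr; pc <- sc - dc
        if (pr < 1 || pr > nr || pc < 1 || pc > nc || mask[pr, pc] == 0 ||
            levels[pr, pc] != levels[r, c]) break
        sr <- pr; sc <- pc
      }
      # walk forwards counting the run
      len <- 0; cr <- sr; cc <- sc
      repeat {
        seen[cr, cc] <- TRUE
        len <- len + 1
        nr2 <- cr + dr; nc2 <- cc + dc
        if (nr2 < 1 || nr2 > nr || nc2 < 1 || nc2 > nc || mask[nr2, nc2] == 0 ||
            levels[nr2, nc2] != levels[r, c]) break
        cr <- nr2; cc <- nc2
      }
      R[levels[sr, sc], len] <- R[levels[sr, sc], len] + 1L
    }
  }
  # 'seen' marks only pixels reachable forward from starts found by scan
  # order; the scan visits every pixel so every run is counted exactly once
  R
}

# pairwise Mann-Whitney AUC: concordant pairs + half ties over n1*n0
brute_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# small random masked image: values 0..255, mask with a guaranteed pixel
random_masked_image <- function(nr, nc) {
  img <- matrix(sample(0:255, nr * nc, replace = TRUE), nr, nc)
  mask <- matrix(rbinom(nr * nc, 1, 0.6), nr, nc)
  if (sum(mask) == 0) mask[sample(nr, 1), sample(nc, 1)] <- 1L
  list(image = img, mask = mask)
}

# a compact synthetic cohort for pipeline-level tests
small_cohort_spec <- function(effect = 1, seed = 11, n_a = 16, n_b = 12,
                              n_val_a = 8, n_val_b = 8, img = 96L) {
  cohort_spec(n_patients_class_A = n_a, n_patients_class_B = n_b,
              n_extra_slice_patients = 0, n_val_A = n_val_a,
              n_val_B = n_val_b, image_size = c(img, img),
              texture_effect = effect, seed = seed)
}

# synthetic slice-level feature table: per-patient latent class signal plus
# independent per-slice noise, the structure the aggregation argument assumes
latent_feature_table <- function(n_pat_a = 10, n_pat_b = 10, slices = 6,
                                 effect = 1, noise = 2, p_extra = 3,
                                 seed = 1) {
  set.seed(seed)
  pats <- data.frame(
    patient_id = sprintf("P%02d", seq_len(n_pat_a + n_pat_b)),
    class_label = rep(c("MN", "IgA"), c(n_pat_a, n_pat_b)),
    latent = c(rnorm(n_pat_a, effect), rnorm(n_pat_b, 0)),
    stringsAsFactors = FALSE)
  n <- nrow(pats) * slices
  tab <- data.frame(
    patient_id = rep(pats$patient_id, each = slices),
    class_label = rep(pats$class_label, each = slices),
    stringsAsFactors = FALSE)
  tab$f1 <- rep(pats$latent, each = slices) + rnorm(n, sd = noise)
  for (j in seq_len(p_extra)) tab[[paste0("g", j)]] <- rnorm(n)
  tab
}
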