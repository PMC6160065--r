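# Shared fixtures, built in code at test time.

# Uniform-color image.
uniform_image <- function(h, w, rgb) {
  arr <- array(0, dim = c(h, w, 3))
  for (c in 1:3) arr[, , c] <- rgb[c]
  rgb_image(arr)
}

# Smooth two-axis gradient image (deterministic, no RNG).
gradient_image <- function(h, w) {
  arr <- array(0, dim = c(h, w, 3))
  rows <- matrix(seq_len(h) / h, h, w)
  cols <- matrix(seq_len(w) / w, h, w, byrow = TRUE)
  arr[, , 1] <- 0.2 + 0.6 * rows
  arr[, , 2] <- 0.2 + 0.5 * cols
  arr[, , 3] <- 0.1 + 0.4 * rows * cols
  rgb_image(arr)
}

# Rectangular mask.
rect_mask <- function(h, w, rows, cols) {
  m <- matrix(FALSE, h, w)
  m[rows, cols] <- TRUE
  m
}

# Brute-force exact two-sided Mann-Whitney p over all label assignments
# (no-ties samples only): doubled smaller tail including the observed point.
brute_force_mw <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  combos <- utils::combn(length(pooled), nx)
  u_of <- function(xs, ys) sum(outer(xs, ys, ">")) # no ties by construction
  u_all <- apply(combos, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  u_obs <- u_of(x, y)
  p_less <- mean(u_all <= u_obs)
  p_greater <- mean(u_all >= u_obs)
  list(U = u_obs, p = min(1, 2 * min(p_less, p_greater)))
}

# Channel-means table for a two-hospital cohort with per-class separation,
# built without images (direct channel sampling).
synthetic_channels <- function(n = 60, seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    hosp <- rep(c("a", "b"), length.out = n)
    data.frame(hospital = hosp,
               r = stats::runif(n, 0.5, 0.9),
               g = stats::runif(n, 0.4, 0.7),
               b = stats::runif(n, 0.2, 0.5))
  })
}

# Feature table straight from a fast-path synthetic cohort (no rendering),
# normalizer fit on the training split; returns dataset + split indices.
cohort_features <- function(cfg, seed) {
  coh <- sample_cohort(cfg, seed = seed, render = FALSE)
  md <- coh$metadata
  ch <- md[, c("hospital", "r", "g", "b")]
  ds0 <- labeled_dataset(matrix(0, nrow(ch), 1), md$outcome)
  sp <- stratified_split(ds0, seed = seed)
  ref <- fit_normalizer(ch[sp$train$ids, ])
  f <- extract_features(cbind(ch, md[c("wound_area_cm2", "days_post_injury",
                                       "age", "outcome")]), ref)
  ds <- as_labeled_dataset(f)
  list(ds = ds, train_idx = sp$train$ids, valid_idx = sp$validation$ids,
       metadata = md, ref = ref, features = f)
}

train_valid <- function(cf) {
  list(train = wound3ccd:::subset_dataset(cf$ds, cf$train_idx),
       valid = wound3ccd:::subset_dataset(cf$ds, cf$valid_idx))
}
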