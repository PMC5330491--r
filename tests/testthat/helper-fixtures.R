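# Shared fixtures and independent oracles, all built in code at test time.

# Noiseless sphere phantom: background 20, sphere intensity 100.
make_sphere_image <- function(dims = c(32, 32, 32), radius = 8,
                              center = (dims + 1) / 2, voxel = c(1, 1, 1),
                              bg = 20, fg = 100) {
  idx <- as.matrix(expand.grid(seq_len(dims[1]), seq_len(dims[2]),
                               seq_len(dims[3])))
  d2 <- (idx[, 1] - center[1])^2 + (idx[, 2] - center[2])^2 +
    (idx[, 3] - center[3])^2
  inside <- d2 <= radius^2
  img <- array(ifelse(inside, fg, bg), dims)
  list(image = image_volume(img, voxel),
       mask = binary_mask(array(inside, dims), voxel),
       n_inside = sum(inside))
}

random_mask <- function(dims = c(16, 16, 16), p = 0.3, voxel = c(1, 1, 1)) {
  binary_mask(array(stats::runif(prod(dims)) < p, dims), voxel)
}

# Naive queue-based breadth-first region growth: the reference oracle for
# the vectorised flood fill (6-connectivity, inclusive band).
bfs_region_grow <- function(data, seeds, lo, hi) {
  dims <- dim(data)
  inband <- data >= lo & data <= hi
  visited <- array(FALSE, dims)
  queue <- which(seeds & inband)
  visited[queue] <- TRUE
  nxy <- dims[1] * dims[2]
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    i3 <- (v - 1) %/% nxy + 1
    r <- (v - 1) %% nxy
    i2 <- r %/% dims[1] + 1
    i1 <- r %% dims[1] + 1
    for (d in list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
                   c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))) {
      j <- c(i1, i2, i3) + d
      if (any(j < 1) || any(j > dims)) next
      w <- (j[3] - 1) * nxy + (j[2] - 1) * dims[1] + j[1]
      if (!visited[w] && inband[w]) {
        visited[w] <- TRUE
        queue <- c(queue, w)
      }
    }
  }
  visited
}

# Brute-force AUC: count concordant positive/negative pairs, ties half.
auc_bruteforce <- function(labels, scores) {
  x <- scores[labels == 1]; y <- scores[labels == 0]
  cmp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Stratified bootstrap of the AUC difference between two score vectors.
bootstrap_auc_diff_var <- function(labels, pa, pb, B = 10000L) {
  i1 <- which(labels == 1); i0 <- which(labels == 0)
  d <- numeric(B)
  for (b in seq_len(B)) {
    s <- c(sample(i1, length(i1), TRUE), sample(i0, length(i0), TRUE))
    l <- labels[s]
    d[b] <- auc_bruteforce(l, pa[s]) - auc_bruteforce(l, pb[s])
  }
  stats::var(d)
}

# Direct GLMM data simulator with known coefficients (independent of the
# phantom generator): standard-normal predictors, logistic outcome with a
# patient random intercept.
simulate_glmm_data <- function(n_patients = 200, n_pairs = 5,
                               beta = c(dcv = 0.4, dfv = 0, scv = 0, sfv = 0),
                               intercept = -0.5, sd_patient = 0.5) {
  n <- n_patients * n_pairs
  X <- matrix(stats::rnorm(4 * n), ncol = 4,
              dimnames = list(NULL, c("dcv", "dfv", "scv", "sfv")))
  id <- rep(seq_len(n_patients), each = n_pairs)
  b <- stats::rnorm(n_patients, 0, sd_patient)
  eta <- intercept + X %*% beta + b[id]
  y <- stats::rbinom(n, 1, stats::plogis(eta))
  data.frame(patient_id = id, progression = y, X)
}

# Small low-volume phantom spec for image-mode unit tests (fits a 48-cube).
small_image_spec <- function(seed = 1, ...) {
  phantom_spec(n_patients = 1, grid_shape = c(48L, 48L, 48L),
               cv_baseline_meanlog = log(2.5),
               fv_cv_ratio_meanlog = log(4), fv_cv_ratio_sdlog = 0.2,
               seed = seed, ...)
}
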