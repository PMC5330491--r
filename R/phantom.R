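#' Specification of a synthetic longitudinal cohort
#'
#' Parameters of the phantom generator, whose defaults emulate the study
#' conditions the package is built around: a 30-patient glioblastoma cohort
#' with 3-12 high-resolution MRI follow-ups per patient, a small
#' contrast-enhancing compartment (median CV around 2.8 ml) inside a much
#' larger FLAIR-hyperintense compartment (median FV around 50 ml), an
#' initial-diagnosis scan followed by a postoperative volume collapse, and
#' follow-ups that progress (multiplicative CV growth) or remain
#' stable/regress. Progression labels are coupled primarily to CV change.
#'
#' @param n_patients number of patients.
#' @param scans_per_patient integer range (min, max); min >= 3 mirrors the
#'   cohort inclusion criterion of at least three follow-ups.
#' @param grid_shape voxels per axis for rendered phantoms (<= 256 each).
#' @param voxel_size mm per axis (default isotropic 1 mm).
#' @param cv_baseline_meanlog,cv_baseline_sdlog log-normal parameters of
#'   the pre-operative CV volume (ml).
#' @param fv_cv_ratio_meanlog,fv_cv_ratio_sdlog log-normal parameters of
#'   the FV/CV volume ratio (floored at 1.2 so FV strictly contains CV).
#' @param progression_prob probability that a follow-up scan progresses.
#' @param growth_effect multiplicative CV change under progression (> 1;
#'   1 switches the progression signal off, the null generator).
#' @param stable_sdlog log-scale volume noise of non-progressing follow-ups.
#' @param fv_coupling exponent coupling FV change to CV change (0-1).
#' @param fv_noise_sdlog extra log-scale noise on FV changes.
#' @param rating_noise per-rater probability of confusing a follow-up
#'   rating with an adjacent category.
#' @param histo_prob,board_prob availability rates of histopathology and
#'   tumor-board labels in the MC hierarchy (matching the reported 16.4%
#'   and 42%).
#' @param noise_sd additive intensity noise of rendered images (tumor /
#'   background contrast is 80 intensity units).
#' @param misregistration_sd SD of the per-scan rigid offset (mm for
#'   translations, degrees for rotations); also drives the simulated
#'   registration error of table-mode regional subtractions.
#' @param seg_jitter_cv,seg_jitter_fv relative scale of the simulated
#'   segmentation non-overlap error entering table-mode sCV / sFV.
#' @param cavity_prob probability that a patient carries a resection
#'   cavity / cyst structure adjacent to (but outside) the tumor masks.
#' @param seed RNG seed; identical spec + seed gives identical cohorts.
#' @return list of class \code{phantom_spec}.
#' @export
phantom_spec <- function(n_patients = 30L,
                         scans_per_patient = c(3L, 12L),
                         grid_shape = c(88L, 88L, 88L),
                         voxel_size = c(1, 1, 1),
                         cv_baseline_meanlog = log(6.6),
                         cv_baseline_sdlog = 0.9,
                         fv_cv_ratio_meanlog = log(7.9),
                         fv_cv_ratio_sdlog = 0.45,
                         progression_prob = 0.75,
                         growth_effect = 2.0,
                         stable_sdlog = 0.22,
                         fv_coupling = 0.5,
                         fv_noise_sdlog = 0.25,
                         rating_noise = 0.13,
                         histo_prob = 0.164,
                         board_prob = 0.42,
                         noise_sd = 12,
                         misregistration_sd = 1.5,
                         seg_jitter_cv = 0.30,
                         seg_jitter_fv = 0.70,
                         cavity_prob = 0.2,
                         seed = 1L) {
  stopifnot(n_patients >= 1,
            length(scans_per_patient) == 2,
            scans_per_patient[1] >= 3,
            scans_per_patient[2] >= scans_per_patient[1],
            all(grid_shape >= 8), all(grid_shape <= 256),
            all(voxel_size > 0),
            cv_baseline_sdlog > 0, fv_cv_ratio_sdlog > 0,
            progression_prob >= 0, progression_prob <= 1,
            growth_effect > 0, stable_sdlog > 0,
            fv_coupling >= 0, fv_coupling <= 1, fv_noise_sdlog > 0,
            rating_noise >= 0, rating_noise < 1,
            histo_prob >= 0, histo_prob <= 1,
            board_prob >= 0, board_prob <= 1,
            noise_sd >= 0, misregistration_sd >= 0,
            seg_jitter_cv > 0, seg_jitter_fv > 0)
  spec <- as.list(environment())
  spec$n_patients <- as.integer(n_patients)
  spec$scans_per_patient <- as.integer(scans_per_patient)
  spec$grid_shape <- as.integer(grid_shape)
  spec$seed <- as.integer(seed)
  structure(spec, class = "phantom_spec")
}

# Scan-count distribution shaped like the study cohort (many short series,
# a few long ones), truncated to the spec's range.
.draw_n_scans <- function(spec, n) {
  lo <- spec$scans_per_patient[1]; hi <- spec$scans_per_patient[2]
  k <- lo:hi
  w <- exp(-0.35 * (k - lo))
  sample(k, n, replace = TRUE, prob = w)
}

# Map a pair's true relative CV change + progression status to a 2-5 rating.
.true_category <- function(progressed, rel_change, uncertain_prob = 0.08) {
  n <- length(progressed)
  out <- integer(n)
  u <- stats::runif(n)
  for (i in seq_len(n)) {
    if (progressed[i]) {
      out[i] <- if (u[i] < 0.85) 5L else 4L
    } else if (rel_change[i] < -0.25) {
      out[i] <- 2L
    } else {
      out[i] <- if (u[i] < uncertain_prob) 4L else 3L
    }
  }
  out
}

.confuse_rating <- function(true_cat, p) {
  out <- true_cat
  flip <- stats::runif(length(out)) < p & true_cat >= 2L
  for (i in which(flip)) {
    nb <- intersect(true_cat[i] + c(-1L, 1L), 2:5)
    out[i] <- if (length(nb) == 1) nb else sample(nb, 1)
  }
  out
}

.rand_small_rigid <- function(sd) {
  rigid_transform(rotation = stats::rnorm(3, sd = sd),
                  translation = stats::rnorm(3, sd = sd))
}

#' Simulate a longitudinal cohort volume table with ground truth
#'
#' Generates the tabular form of a phantom cohort: per-scan CV and FV
#' volumes (ml), simulated regional-subtraction volumes (sCV, sFV, carrying
#' the registration and segmentation non-overlap error that makes regional
#' subtractions noisier than absolute deltas), two raters' 0-5 ratings, MC
#' label sources, and the ground-truth progression label (1 exactly when
#' the generating process applied the growth effect). Scan 1 is the initial
#' diagnosis (rating 0), scan 2 the immediate postoperative MRI (rating 1,
#' large volume drop); later scans are follow-ups.
#'
#' Geometric shape parameters (lobulated multi-ellipsoid tumors) and
#' per-scan rigid poses are drawn here too, so
#' \code{\link{render_phantom_images}} can realise the same cohort as 3D
#' image volumes.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return list of class \code{phantom_cohort}: \code{scans} (data.frame:
#'   patient_id, scan_index, cv_ml, fv_ml, scv_ml, sfv_ml, rating,
#'   progression), \code{ratings} (long table, raters "a"/"b"),
#'   \code{mc_sources} (histo/board/rc per scan), \code{truth} (per-patient
#'   shapes and per-scan poses), and \code{spec}.
#' @export
simulate_cohort_table <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  scans <- list(); ratings <- list(); mc <- list(); truth <- list()
  n_scans_all <- .draw_n_scans(spec, spec$n_patients)
  for (p in seq_len(spec$n_patients)) {
    pid <- sprintf("P%02d", p)
    ns <- n_scans_all[p]
    cv <- numeric(ns); fv <- numeric(ns)
    progressed <- rep(NA, ns)   # per-scan label; NA for scans 1-2
    cv[1] <- exp(stats::rnorm(1, spec$cv_baseline_meanlog,
                              spec$cv_baseline_sdlog))
    ratio <- max(1.2, exp(stats::rnorm(1, spec$fv_cv_ratio_meanlog,
                                       spec$fv_cv_ratio_sdlog)))
    fv[1] <- cv[1] * ratio
    # postoperative collapse
    cv[2] <- cv[1] * stats::runif(1, 0.03, 0.25)
    fv[2] <- fv[1] * stats::runif(1, 0.35, 0.7)
    progressed[2] <- FALSE
    if (ns >= 3) for (t in 3:ns) {
      pr <- stats::runif(1) < spec$progression_prob
      g_cv <- if (pr) spec$growth_effect *
                exp(stats::rnorm(1, 0, spec$stable_sdlog))
              else exp(stats::rnorm(1, log(0.93), spec$stable_sdlog))
      cv[t] <- cv[t - 1] * g_cv
      g_fv <- g_cv^spec$fv_coupling *
        exp(stats::rnorm(1, 0, spec$fv_noise_sdlog))
      fv[t] <- fv[t - 1] * g_fv
      progressed[t] <- pr
    }
    # physiologic caps (intracranial space bounds tumor size) and
    # containment: FV strictly larger than CV
    cv <- pmin(cv, 45)
    fv <- pmin(pmax(fv, 1.2 * cv), 150)
    # simulated regional subtractions: true new volume plus non-overlap
    # error from misregistration (surface x offset) and independent
    # re-segmentation jitter of both scans
    scv <- rep(NA_real_, ns); sfv <- rep(NA_real_, ns)
    for (t in 2:ns) {
      off <- sqrt(sum(stats::rnorm(3, sd = spec$misregistration_sd)^2))
      r_cv <- (3 * cv[t] * 1000 / (4 * pi))^(1 / 3)   # mm, sphere-equiv.
      r_fv <- (3 * fv[t] * 1000 / (4 * pi))^(1 / 3)
      reg_cv <- pi * r_cv^2 * off / 1000 * stats::runif(1, 0.2, 1)
      reg_fv <- pi * r_fv^2 * off / 1000 * stats::runif(1, 0.2, 1)
      # re-segmentation error is a boundary-shell phenomenon: scale with
      # surface area (volume^(2/3)), not volume
      jit_cv <- cv[t]^(2 / 3) * spec$seg_jitter_cv * stats::rgamma(1, 2, 2)
      jit_fv <- fv[t]^(2 / 3) * spec$seg_jitter_fv * stats::rgamma(1, 2, 2)
      scv[t] <- max(cv[t] - cv[t - 1], 0) + reg_cv + jit_cv
      sfv[t] <- max(fv[t] - fv[t - 1], 0) + reg_fv + jit_fv
    }
    rel <- c(NA, diff(cv) / pmax(utils::head(cv, -1), 0.001))
    true_cat <- integer(ns)
    true_cat[1] <- 0L
    true_cat[2] <- 1L
    if (ns >= 3)
      true_cat[3:ns] <- .true_category(progressed[3:ns], rel[3:ns])
    ra <- .confuse_rating(true_cat, spec$rating_noise)
    rb <- .confuse_rating(true_cat, spec$rating_noise)
    # discrepant ratings resolved in a consensus session: the session
    # settles on one reading (it has no oracle access to the truth)
    pick_a <- stats::runif(ns) < 0.5
    rc <- ifelse(ra == rb, ra, ifelse(pick_a, ra, rb))
    histo <- ifelse(stats::runif(ns) < spec$histo_prob, true_cat, NA_integer_)
    board <- ifelse(is.na(histo) & stats::runif(ns) < spec$board_prob,
                    true_cat, NA_integer_)
    # postoperative / initial scans keep their structural rating everywhere
    fixed <- true_cat <= 1L
    ra[fixed] <- true_cat[fixed]; rb[fixed] <- true_cat[fixed]
    rc[fixed] <- true_cat[fixed]
    scans[[p]] <- data.frame(patient_id = pid, scan_index = seq_len(ns),
                             cv_ml = cv, fv_ml = fv,
                             scv_ml = scv, sfv_ml = sfv,
                             rating = rc,
                             progression = as.integer(progressed),
                             stringsAsFactors = FALSE)
    ratings[[p]] <- data.frame(patient_id = pid,
                               scan_index = rep(seq_len(ns), 2),
                               rater = rep(c("a", "b"), each = ns),
                               category = c(ra, rb),
                               stringsAsFactors = FALSE)
    mc[[p]] <- data.frame(patient_id = pid, scan_index = seq_len(ns),
                          histo = histo, board = board, rc = rc,
                          stringsAsFactors = FALSE)
    # geometry: lobulated multi-ellipsoid shapes + cumulative rigid poses
    n_lobes_cv <- sample(2:5, 1)
    shape_cv <- .draw_shape(n_lobes_cv)
    shape_fv <- .draw_shape(sample(2:5, 1), spread = 0.45)
    poses <- vector("list", ns)
    poses[[1]] <- diag(4)
    if (ns >= 2) for (t in 2:ns)
      poses[[t]] <- compose_transforms(
        .rand_small_rigid(spec$misregistration_sd), poses[[t - 1]])
    cavity <- stats::runif(1) < spec$cavity_prob
    truth[[pid]] <- list(shape_cv = shape_cv, shape_fv = shape_fv,
                         poses = poses, cavity = cavity,
                         n_scans = ns)
  }
  structure(list(scans = do.call(rbind, scans),
                 ratings = do.call(rbind, ratings),
                 mc_sources = do.call(rbind, mc),
                 truth = truth,
                 spec = spec),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat("<phantom_cohort> ", x$spec$n_patients, " patients, ",
      nrow(x$scans), " scans; median CV ",
      format(stats::median(x$scans$cv_ml), digits = 3), " ml, median FV ",
      format(stats::median(x$scans$fv_ml), digits = 3), " ml\n", sep = "")
  invisible(x)
}

# Random lobulated shape: unit-scale union of ellipsoid lobes with a
# low-frequency sinusoidal boundary perturbation.
.draw_shape <- function(n_lobes, spread = 0.35) {
  centers <- matrix(stats::rnorm(3 * n_lobes, sd = spread), ncol = 3)
  centers[1, ] <- 0  # anchor one lobe at the origin so scaling is well-posed
  list(centers = centers,
       semiaxes = matrix(stats::runif(3 * n_lobes, 0.55, 1.0), ncol = 3),
       wobble_freq = stats::runif(3, 1.5, 3.5),
       wobble_phase = stats::runif(3, 0, 2 * pi),
       wobble_amp = 0.15)
}

# Inclusion test of a shape at scale s, evaluated at shape-frame mm coords.
.shape_inside <- function(shape, pts, s) {
  q <- rep(Inf, nrow(pts))
  ps <- pts / s
  for (l in seq_len(nrow(shape$centers))) {
    d <- sweep(ps, 2, shape$centers[l, ], "-")
    d <- sweep(d, 2, shape$semiaxes[l, ], "/")
    q <- pmin(q, rowSums(d * d))
  }
  thr <- 1 + shape$wobble_amp *
    sin(ps %*% shape$wobble_freq + sum(shape$wobble_phase))
  q <= as.numeric(thr)
}

# Voxelise a shape at the scale matching a target volume (bisection on the
# linear scale; volumes are exact voxel counts).
.voxelize_shape <- function(shape, target_ml, grid_pts, voxel_vol_mm3,
                            tol = 0.02, max_iter = 40L) {
  target_vox <- target_ml * 1000 / voxel_vol_mm3
  # restrict evaluation to a conservative bounding sphere around the shape
  # centre: unit shape extent is |lobe centre| + semiaxis, inflated by the
  # wobble amplitude; the scale is at most ~(target / unit ball) ^ (1/3)
  ext <- max(sqrt(rowSums(shape$centers^2)) + apply(shape$semiaxes, 1, max))
  r_target <- (3 * target_vox * voxel_vol_mm3 / (4 * pi))^(1 / 3)
  # the union is at least as big as its largest lobe, bounding the scale
  r_unit <- max(apply(shape$semiaxes, 1, prod)^(1 / 3))
  s_max <- r_target / r_unit
  R <- 1.25 * ext * (1 + shape$wobble_amp) * s_max
  inside_box <- rowSums(grid_pts^2) <= R^2
  pts <- grid_pts[inside_box, , drop = FALSE]
  f <- function(s) sum(.shape_inside(shape, pts, s))
  if (f(s_max) < target_vox)
    stop("tumor larger than the phantom grid; enlarge grid_shape")
  # voxel count scales as s^3 up to the boundary wobble, so a cubic-scaling
  # fixed point converges in a handful of evaluations
  s <- s_max * 0.8
  best_s <- s_max; best_gap <- Inf
  for (i in seq_len(max_iter)) {
    n <- f(s)
    gap <- abs(n - target_vox)
    if (n > 0 && gap < best_gap) { best_gap <- gap; best_s <- s }
    if (gap <= max(1, tol * target_vox)) break
    s <- if (n == 0) s * 1.5 else min(s * (target_vox / n)^(1 / 3), s_max)
    if (i > 8 && abs(s - best_s) / best_s < 1e-4) break
  }
  out <- rep(FALSE, nrow(grid_pts))
  out[inside_box] <- .shape_inside(shape, pts, best_s)
  out
}

#' Render a patient's phantom scans as 3D image volumes
#'
#' Realises the geometric ground truth of one simulated patient as per-scan
#' MPRage-like and FLAIR-like image volumes plus true CV and FV masks, each
#' in the scan's native grid (consecutive scans differ by the stored rigid
#' pose). The contrast-enhancing compartment is hyperintense on the
#' MPRage-like channel, the FLAIR compartment on the FLAIR-like channel;
#' intensities are piecewise constant (background 20, non-enhancing FLAIR
#' compartment 30 on MPRage, tumor 100) plus additive Gaussian noise, so at
#' zero noise thresholding at the tumor/background midpoint recovers the
#' truth mask exactly. An optional dark fluid cavity is placed adjacent to
#' the tumor, outside both truth masks, emulating resection cavities and
#' cysts that segmentation must not include.
#'
#' True volumes in the returned table are recomputed from the voxelised
#' masks (voxel count times voxel volume), so they match the stored masks
#' exactly; they track the tabular trajectory volumes up to discretisation.
#'
#' @param cohort a \code{\link{phantom_cohort}}.
#' @param patient_id patient to render (e.g. \code{"P01"}).
#' @param scan_indices which scans to render (default all).
#' @return list of class \code{phantom_scans}: per scan a list with
#'   \code{mprage}, \code{flair} (\code{image_volume}), \code{cv_mask},
#'   \code{fv_mask} (\code{binary_mask}), \code{cv_true_ml},
#'   \code{fv_true_ml}, and \code{transform_from_prev} (4x4 matrix mapping
#'   this scan's world coords to the previous scan's, NULL for the first
#'   rendered scan).
#' @export
render_phantom_images <- function(cohort, patient_id,
                                  scan_indices = NULL) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  tr <- cohort$truth[[patient_id]]
  if (is.null(tr)) stop("unknown patient_id: ", patient_id)
  spec <- cohort$spec
  rows <- cohort$scans[cohort$scans$patient_id == patient_id, ]
  if (is.null(scan_indices)) scan_indices <- rows$scan_index
  set.seed(spec$seed + 7919L * match(patient_id, names(cohort$truth)))
  dims <- spec$grid_shape
  vs <- spec$voxel_size
  vox_vol <- prod(vs)
  idx <- as.matrix(expand.grid(seq_len(dims[1]), seq_len(dims[2]),
                               seq_len(dims[3])))
  center_mm <- (dims - 1) * vs / 2
  world <- sweep(sweep(idx - 1, 2, vs, "*"), 2, -center_mm, "+")
  # patient-specific low-frequency background texture, fixed in the
  # reference frame so it moves rigidly with the pose: a stand-in for the
  # brain structure that anchors image registration (rotations especially,
  # which a single central lesion cannot pin down)
  kmat <- qr.Q(qr(matrix(stats::rnorm(9), 3)))  # three orthogonal wave axes
  kmat <- sweep(kmat, 2, 2 * pi / c(45, 30, 36), "*")
  ph <- stats::runif(3, 0, 2 * pi)
  texture <- function(ref) {
    w <- sweep(ref %*% kmat, 2, ph, "+")
    3 * (sin(w[, 1]) + cos(w[, 2]) + sin(w[, 3]))
  }
  cavity_center <- NULL
  out <- vector("list", length(scan_indices))
  names(out) <- paste0("scan", scan_indices)
  prev_t <- NULL
  for (k in seq_along(scan_indices)) {
    t <- scan_indices[k]
    row <- rows[rows$scan_index == t, ]
    pose <- tr$poses[[t]]
    # evaluate shapes at reference coords: pull scan-grid world coords
    # through the scan's pose
    ref <- transform_points(pose, world)
    cv_in <- .voxelize_shape(tr$shape_cv, row$cv_ml, ref, vox_vol)
    fv_in <- .voxelize_shape(tr$shape_fv, row$fv_ml, ref, vox_vol) | cv_in
    # texture paints the normal-appearing background only: tumor
    # compartments are homogeneous up to noise, as the segmentation's
    # intensity-band model assumes
    tex <- as.numeric(texture(ref))
    mpr <- ifelse(cv_in, 100, ifelse(fv_in, 30, 20 + tex))
    fla <- ifelse(fv_in, 100, 20 + tex)
    if (tr$cavity) {
      if (is.null(cavity_center)) {
        fv_r <- (3 * row$fv_ml * 1000 / (4 * pi))^(1 / 3)
        dirn <- stats::rnorm(3); dirn <- dirn / sqrt(sum(dirn^2))
        cavity_center <- dirn * (fv_r * 1.15)
        cavity_r <- max(4, fv_r * 0.35)
      }
      dcav <- sweep(ref, 2, cavity_center, "-")
      cav <- rowSums(dcav * dcav) <= cavity_r^2 & !fv_in
      mpr[cav] <- 5; fla[cav] <- 5
    }
    if (spec$noise_sd > 0) {
      mpr <- mpr + stats::rnorm(length(mpr), sd = spec$noise_sd)
      fla <- fla + stats::rnorm(length(fla), sd = spec$noise_sd)
    }
    tf_prev <- if (is.null(prev_t)) NULL else
      compose_transforms(invert_transform(tr$poses[[prev_t]]), pose)
    out[[k]] <- list(
      mprage = image_volume(array(mpr, dims), vs, -center_mm),
      flair = image_volume(array(fla, dims), vs, -center_mm),
      cv_mask = binary_mask(array(cv_in, dims), vs, "CV", -center_mm),
      fv_mask = binary_mask(array(fv_in, dims), vs, "FV", -center_mm),
      cv_true_ml = sum(cv_in) * vox_vol / 1000,
      fv_true_ml = sum(fv_in) * vox_vol / 1000,
      transform_from_prev = tf_prev)
    prev_t <- t
  }
  structure(out, class = "phantom_scans")
}

#' Write a cohort table (and ground truth) to CSV
#'
#' @param cohort a \code{\link{phantom_cohort}}.
#' @param dir output directory (created if missing).
#' @return invisibly, the written file paths.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(scans = file.path(dir, "cohort_scans.csv"),
             ratings = file.path(dir, "cohort_ratings.csv"),
             mc_sources = file.path(dir, "cohort_mc_sources.csv"))
  utils::write.csv(cohort$scans, paths["scans"], row.names = FALSE)
  utils::write.csv(cohort$ratings, paths["ratings"], row.names = FALSE)
  utils::write.csv(cohort$mc_sources, paths["mc_sources"], row.names = FALSE)
  invisible(paths)
}
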