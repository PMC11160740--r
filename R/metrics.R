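# Evaluation metrics: Fourier shell correlation, per-image FSC, rotation
# alignment and error decomposition, optimal 3D shift for translations,
# quaternion loss.

#' Fourier shell correlation between two maps
#'
#' Per-shell normalized cross-correlation of Fourier coefficients, shells
#' of one Fourier-pixel width (DC included). Resolution crossings at the
#' 0.5 and 0.143 thresholds are reported by linear interpolation.
#'
#' @param map_a,map_b D^3 real arrays of identical shape.
#' @return object of class `fsc_curve`: data frame with `shell` (radius in
#'   grid units), `freq` (cycles/image length), `fsc`; attributes
#'   `crossing_0.5` and `crossing_0.143` (grid units, NA if never crossed).
#' @export
fsc <- function(map_a, map_b) {
  if (!all(dim(map_a) == dim(map_b)))
    stop("fsc: maps must have identical dimensions")
  D <- dim(map_a)[1]
  Fa <- cfft(map_a); Fb <- cfft(map_b)
  mi <- freq_index(D)
  r <- sqrt(outer(mi^2, outer(mi^2, mi^2, `+`), `+`))
  shell <- as.integer(round(r))
  keep <- shell <= D %/% 2L
  sh <- shell[keep]
  num <- Re(Fa * Conj(Fb))[keep]
  pa <- abs(Fa)[keep]^2
  pb <- abs(Fb)[keep]^2
  ns <- rowsum(num, sh); as <- rowsum(pa, sh); bs <- rowsum(pb, sh)
  corr <- as.numeric(ns / sqrt(pmax(as * bs, 1e-300)))
  shells <- sort(unique(sh))
  out <- data.frame(shell = shells, freq = shells / D, fsc = corr)
  crossing <- function(thr) {
    below <- which(out$fsc < thr)
    below <- below[below > 1]
    if (length(below) == 0) return(NA_real_)
    i <- below[1]
    x0 <- out$shell[i - 1]; x1 <- out$shell[i]
    y0 <- out$fsc[i - 1]; y1 <- out$fsc[i]
    x0 + (thr - y0) * (x1 - x0) / (y1 - y0)
  }
  attr(out, "crossing_0.5") <- crossing(0.5)
  attr(out, "crossing_0.143") <- crossing(0.143)
  class(out) <- c("fsc_curve", "data.frame")
  out
}

#' Per-image FSC of a heterogeneous reconstruction
#'
#' For each selected image, renders the map decoded from that image's
#' latent embedding and computes its FSC against the image's ground-truth
#' map; curves are averaged shell-wise across images.
#'
#' @param field trained `volume_field`.
#' @param latents N x d latent matrix.
#' @param gt_maps list of ground-truth D^3 maps.
#' @param map_of integer vector: ground-truth map index per image.
#' @param D render size.
#' @param subset image indices to evaluate (default: all, capped at
#'   `max_images` deterministically).
#' @param max_images cap on evaluated images.
#' @param gain model intensity scale (irrelevant to FSC, kept for
#'   interface symmetry).
#' @return `fsc_curve` with the shell-wise mean correlation.
#' @export
per_image_fsc <- function(field, latents, gt_maps, map_of, D,
                          subset = NULL, max_images = 100L, gain = 1) {
  N <- nrow(latents)
  if (is.null(subset)) subset <- seq_len(N)
  if (length(subset) > max_images)
    subset <- subset[seq(1, length(subset), length.out = max_images)]
  acc <- NULL
  for (i in subset) {
    m <- render_map(field, latents[i, ], D, gain = gain)
    cu <- fsc(m, gt_maps[[map_of[i]]])
    acc <- if (is.null(acc)) cu$fsc else acc + cu$fsc
  }
  out <- fsc(gt_maps[[map_of[subset[1]]]], gt_maps[[map_of[subset[1]]]])
  out$fsc <- acc / length(subset)
  attr(out, "crossing_0.5") <- NA_real_
  attr(out, "crossing_0.143") <- NA_real_
  out
}

#' Align estimated rotations to a reference set
#'
#' Candidate global rotations are `r_i^-1 R_i` for the first
#' `min(N, 100)` particles; the candidate minimizing the mean Frobenius
#' distance `||R_i - r_i R||` is kept and per-particle geodesic errors are
#' reported after alignment.
#'
#' @param est list of estimated rotations `r_i`.
#' @param ref list of reference rotations `R_i`.
#' @param n_candidates candidates tried (default 100).
#' @return list with `R_align` (3 x 3), `errors` (radians, per particle),
#'   `aligned` (list `r_i R_align`).
#' @export
align_rotations <- function(est, ref, n_candidates = 100L) {
  N <- length(est)
  stopifnot(N == length(ref), N >= 1)
  ncand <- min(N, n_candidates)
  best <- NULL; best_cost <- Inf
  for (i in seq_len(ncand)) {
    cand <- crossprod(est[[i]], ref[[i]])   # r_i^-1 R_i
    cost <- 0
    for (j in seq_len(N)) cost <- cost +
        sqrt(sum((ref[[j]] - est[[j]] %*% cand)^2))
    if (cost < best_cost) { best_cost <- cost; best <- cand }
  }
  aligned <- lapply(est, function(r) r %*% best)
  errors <- vapply(seq_len(N), function(j) rot_geodesic(aligned[[j]],
                                                        ref[[j]]),
                   numeric(1))
  list(R_align = best, errors = errors, aligned = aligned)
}

#' Decompose rotation errors into out-of-plane and in-plane parts
#'
#' The viewing direction of a rotation is `R %*% c(0,0,1)` (invariant
#' under in-plane spin with the `k -> R k` slicing convention); the
#' out-of-plane error is the angle between estimated and reference viewing
#' directions, the in-plane error the wrapped difference of the ZYZ
#' in-plane Euler angle. Near the gimbal degeneracy the in-plane angle is
#' taken from the quaternion-free fallback of [euler_zyz()].
#'
#' @param est list of (aligned) estimated rotations.
#' @param ref list of reference rotations.
#' @return list with `out_of_plane` and `in_plane`, degrees per particle.
#' @export
decompose_errors <- function(est, ref) {
  N <- length(est)
  oop <- numeric(N); ip <- numeric(N)
  for (j in seq_len(N)) {
    va <- est[[j]][, 3]; vb <- ref[[j]][, 3]
    oop[j] <- acos(pmin(1, pmax(-1, sum(va * vb)))) * 180 / pi
    ea <- euler_zyz(est[[j]]); eb <- euler_zyz(ref[[j]])
    ip[j] <- abs(wrap_angle(ea["gamma"] - eb["gamma"])) * 180 / pi
  }
  list(out_of_plane = oop, in_plane = ip)
}

#' Optimal 3D shift between translation sets
#'
#' The 2D translation error between estimate and reference is explained up
#' to an unknown 3D origin shift `u`: the minimizer of
#' `sum_i ||T_i - t_i - P r_i u||^2` with `P` the 2 x 3 projector onto the
#' image plane. Solved as a linear least-squares problem; corrected
#' translations are `t_i + P r_i u*`.
#'
#' @param est_t N x 2 estimated translations.
#' @param ref_T N x 2 reference translations.
#' @param est_R list of N estimated rotations.
#' @return list with `u` (length 3), `corrected` (N x 2), `mse_before`,
#'   `mse_after`, and `rank_deficient` flag.
#' @export
optimal_shift <- function(est_t, ref_T, est_R) {
  N <- nrow(est_t)
  stopifnot(N >= 2, nrow(ref_T) == N, length(est_R) == N)
  P <- rbind(c(1, 0, 0), c(0, 1, 0))
  A <- matrix(0, 2 * N, 3)
  b <- numeric(2 * N)
  for (i in seq_len(N)) {
    rows <- (2 * i - 1):(2 * i)
    A[rows, ] <- P %*% est_R[[i]]
    b[rows] <- ref_T[i, ] - est_t[i, ]
  }
  sv <- svd(A)
  pos <- sv$d > max(sv$d) * 1e-10
  rank_deficient <- any(!pos)
  if (rank_deficient)
    warning("optimal_shift: rank-deficient system; minimum-norm solution")
  u <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], b)) / sv$d[pos])
  u <- as.numeric(u)
  corr <- est_t + t(vapply(seq_len(N), function(i) {
    as.numeric(P %*% est_R[[i]] %*% u)
  }, numeric(2)))
  list(u = u, corrected = corr,
       mse_before = mean(rowSums((ref_T - est_t)^2)),
       mse_after = mean(rowSums((ref_T - corr)^2)),
       rank_deficient = rank_deficient)
}

#' Quaternion pose loss
#'
#' `L(q, q') = 1 - (q . q')^2`, invariant under the quaternion double
#' cover (`q` and `-q` give 0) and equal to 1 for orthogonal quaternions.
#'
#' @param q,qp unit quaternions (length 4); non-unit inputs are normalized
#'   with a warning.
#' @return scalar in `[0, 1]`.
#' @export
quaternion_loss <- function(q, qp) {
  nq <- sqrt(sum(q^2)); nqp <- sqrt(sum(qp^2))
  if (abs(nq - 1) > 1e-6 || abs(nqp - 1) > 1e-6) {
    warning("quaternion_loss: non-unit input normalized")
    q <- q / nq; qp <- qp / nqp
  }
  1 - sum(q * qp)^2
}

#' Summarize pose accuracy of a training run
#'
#' Convenience wrapper: aligns estimated to reference rotations, decomposes
#' errors, and corrects translations by the optimal 3D shift.
#'
#' @param est_poses list with `R` (list) and `t` (N x 2).
#' @param ref_poses same structure, ground truth.
#' @return list of class `pose_error_report`.
#' @export
pose_error_report <- function(est_poses, ref_poses) {
  al <- align_rotations(est_poses$R, ref_poses$R)
  dec <- decompose_errors(al$aligned, ref_poses$R)
  sh <- optimal_shift(est_poses$t, ref_poses$t, al$aligned)
  structure(list(R_align = al$R_align,
                 geodesic = al$errors * 180 / pi,
                 out_of_plane = dec$out_of_plane,
                 in_plane = dec$in_plane,
                 shift_u = sh$u,
                 trans_mse_before = sh$mse_before,
                 trans_mse_after = sh$mse_after),
            class = "pose_error_report")
}
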