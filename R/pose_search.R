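# Hierarchical pose search over SO(3) x R^2.
#
# The base grid is the Hopf-fibration product of a HEALPix sphere grid
# (viewing directions) and a regular circle grid (in-plane angles), crossed
# with a 7 x 7 translation grid. Search: exhaustive evaluation of the
# band-limited reprojection error on the base grid, keep the top 8
# rotations, then 5 refinement rounds, each replacing every kept rotation
# by its 8 children at half the angular spacing (4 nested HEALPix
# sub-pixels x 2 in-plane half-step offsets) and halving the translation
# extent (re-centered on the current best translation, still 7 x 7).

#' Base SO(3) x R^2 search grid
#'
#' Defaults reproduce the standard configuration: HEALPix nside 4
#' (192 directions) x 24 in-plane angles at 15 degree spacing = 4,608
#' rotations, and 49 translations on a 7 x 7 grid over +/- 10 pixels.
#'
#' @param nside HEALPix resolution of the direction grid.
#' @param n_psi number of in-plane angles (spacing `360 / n_psi` degrees).
#' @param t_extent translation half-extent in pixels.
#' @param n_t translations per axis (grid is `n_t x n_t`).
#' @return object of class `search_grid` with fields `nodes` (data frame of
#'   pixel id, psi id, psi radians, theta, phi), `rotations` (list of 3 x 3
#'   matrices), `trans` (n_t^2 x 2 matrix), and the grid parameters.
#' @export
base_grid <- function(nside = 4L, n_psi = 24L, t_extent = 10, n_t = 7L) {
  key <- paste(nside, n_psi, t_extent, n_t, sep = "_")
  hit <- .grid_memo[[key]]
  if (!is.null(hit)) return(hit)
  ang <- healpix_pix2ang(nside)
  npix <- nrow(ang)
  psi_step <- 2 * pi / n_psi
  nodes <- expand.grid(psi_id = seq_len(n_psi) - 1L,
                       pix = seq_len(npix) - 1L)
  nodes <- nodes[, c("pix", "psi_id")]
  nodes$psi <- nodes$psi_id * psi_step
  nodes$theta <- ang[nodes$pix + 1L, 1L]
  nodes$phi <- ang[nodes$pix + 1L, 2L]
  rotations <- lapply(seq_len(nrow(nodes)), function(i) {
    hopf_rotation(nodes$theta[i], nodes$phi[i], nodes$psi[i])
  })
  trans <- as.matrix(expand.grid(
    tx = seq(-t_extent, t_extent, length.out = n_t),
    ty = seq(-t_extent, t_extent, length.out = n_t)))
  out <- structure(list(nodes = nodes, rotations = rotations, trans = trans,
                        nside = as.integer(nside), n_psi = as.integer(n_psi),
                        t_extent = t_extent, n_t = as.integer(n_t)),
                   class = "search_grid")
  .grid_memo[[key]] <- out
  out
}

# memo for constructed base grids (they are deterministic in their
# parameters and moderately expensive to build)
.grid_memo <- new.env(parent = emptyenv())

#' Children of a rotation node at the next refinement level
#'
#' Eight children: the four nested HEALPix sub-pixels of the node's
#' direction pixel crossed with two in-plane offsets of a quarter of the
#' node's angular spacing on either side.
#'
#' @param node list/row with `pix`, `psi`, `psi_id`.
#' @param level current refinement level of the node (0 = base grid).
#' @param grid the [base_grid()] the hierarchy started from.
#' @return data frame of 8 child nodes (`pix`, `psi_id`, `psi`, `theta`,
#'   `phi`) at level `level + 1`.
#' @export
refine_candidates <- function(node, level, grid) {
  nside_child <- grid$nside * 2L^(level + 1L)
  pix_child <- healpix_children(node$pix)
  ang <- healpix_pix2ang(nside_child, pix_child)
  psi_step <- 2 * pi / grid$n_psi / 2^level
  psi_child <- node$psi + c(-1, 1) * psi_step / 4
  psi_id_child <- 2L * node$psi_id + 0:1
  out <- expand.grid(ci = 1:4, pi_ = 1:2)
  data.frame(pix = pix_child[out$ci],
             psi_id = psi_id_child[out$pi_],
             psi = psi_child[out$pi_],
             theta = ang[out$ci, 1L],
             phi = ang[out$ci, 2L])
}

#' Band-limit cutoff schedule
#'
#' The pose-search band limit rises linearly with the number of images
#' processed, from `k_min` to `k_max` (grid units, cycles per image
#' length) over `T` images: `round(k_min + (k_max - k_min) min(1, t/T))`.
#'
#' @param images_processed non-negative counter.
#' @param schedule list with `k_min` (default 6), `k_max` (default 16),
#'   `T` (phase length in images).
#' @return integer cutoff.
#' @export
cutoff_at <- function(images_processed,
                      schedule = list(k_min = 6, k_max = 16, T = 1)) {
  if (images_processed < 0) stop("images_processed must be >= 0")
  frac <- min(1, images_processed / schedule$T)
  as.integer(round(schedule$k_min + (schedule$k_max - schedule$k_min) * frac))
}

# Resolve the sliceable representation + scale for pose search. Returns
# list(vext, D_big, scale) compatible with sample_hartley_volume.
.search_cache <- function(vol, z, D, cutoff, gain = 1) {
  if (inherits(vol, "volume_field")) {
    vext <- field_grid_cache(vol, z, D, cutoff)
    list(vext = vext, D_big = D, scale = sqrt(D) * gain)
  } else if (inherits(vol, "hartley_slicer")) {
    list(vext = vol$vext, D_big = vol$D_big, scale = vol$scale * gain)
  } else {
    list(vext = ht_extend(vol), D_big = D, scale = sqrt(D) * gain)
  }
}

# Evaluate CTF-weighted slices for a list of rotations at the in-band
# lattice points. Returns R x n_k matrices A (at k) and B (at -k).
# The rotated coordinates for all candidates are produced by one matrix
# product: K3 %*% [t(R_1) | ... | t(R_R)].
.slice_candidates <- function(cache, rotations, lat, weights) {
  nR <- length(rotations)
  nk <- length(lat$m)
  k3 <- cbind(lat$k, 0)
  Tall <- matrix(unlist(lapply(rotations, t), use.names = FALSE), 3, 3 * nR)
  big <- k3 %*% Tall                                  # nk x 3R
  M <- matrix(aperm(array(big, c(nk, 3L, nR)), c(1, 3, 2)), nk * nR, 3)
  vals <- sample_hartley_volume(cache$vext, M, cache$D_big) * cache$scale
  S <- t(matrix(vals, nrow = nk))                     # nR x nk
  A <- sweep(S, 2, weights, `*`)
  B <- sweep(S[, lat$neg, drop = FALSE], 2, weights, `*`)
  list(A = A, B = B)
}

# cos/sin translation phase tables for a translation grid (n_k x n_t).
.phase_tables <- function(lat, trans) {
  ph <- 2 * pi * (outer(lat$k[, 1], trans[, 1]) +
                  outer(lat$k[, 2], trans[, 2]))
  list(C = cos(ph), S = sin(ph))
}

#' Band-limited reprojection error of one pose
#'
#' Squared L2 distance, over the Hartley coefficients with `|k| <= cutoff`
#' (grid units), between the observed image and the CTF-modulated,
#' translated central slice of the model at the given pose. Computed by
#' direct evaluation of the model (no search cache).
#'
#' @param image D x D real image.
#' @param vol `volume_field`, D^3 Hartley volume, or [prep_slicer()] object.
#' @param z latent embedding (fields).
#' @param pose list with `R` and `t`.
#' @param ctf [ctf_params()], a numeric vector of per-coefficient weights
#'   aligned with `inband_lattice(D, cutoff)`, or `NULL` for identity.
#' @param cutoff band radius in grid units (`NULL` = full band).
#' @param pixel_size Angstrom per pixel (CTF evaluation).
#' @param gain global intensity scale applied to the model.
#' @return non-negative scalar.
#' @export
reprojection_error <- function(image, vol, z = NULL, pose, ctf = NULL,
                               cutoff = NULL, pixel_size = 1, gain = 1) {
  D <- nrow(image)
  lat <- inband_lattice(D, cutoff)
  Ihat <- dht(image)[lat$idx]
  w <- .resolve_weights(ctf, lat, D, pixel_size)
  k3 <- cbind(lat$k, 0) %*% t(pose$R)
  Fv <- if (inherits(vol, "volume_field")) {
    eval_field(vol, z, k3) * sqrt(D) * gain
  } else {
    cache <- .search_cache(vol, z, D, lat$cutoff, gain)
    sample_hartley_volume(cache$vext, k3, cache$D_big) * cache$scale
  }
  ph <- 2 * pi * (lat$k[, 1] * pose$t[1] + lat$k[, 2] * pose$t[2])
  model <- w * (cos(ph) * Fv + sin(ph) * Fv[lat$neg])
  sum((Ihat - model)^2)
}

.resolve_weights <- function(ctf, lat, D, pixel_size) {
  if (is.null(ctf)) rep(1, length(lat$m))
  else if (is.numeric(ctf)) {
    stopifnot(length(ctf) == length(lat$m))
    ctf
  } else eval_ctf(ctf, cbind(lat$m, lat$n), D = D, pixel_size = pixel_size)
}

#' Hierarchical pose search for one image
#'
#' The base grid is ranked at the `cutoff` band limit; each refinement
#' round then raises the band limit linearly towards `cutoff_final`
#' (frequency marching within the search), so coarse basins are ranked on
#' the smooth low-frequency landscape while the final sub-degree rotations
#' are discriminated with the full scheduled band.
#'
#' @param image D x D real image.
#' @param vol `volume_field`, D^3 Hartley volume, or [prep_slicer()].
#' @param z latent embedding (fields).
#' @param ctf [ctf_params()], a D x D matrix of per-coefficient weights on
#'   the full centered lattice, or `NULL`.
#' @param cutoff band radius (grid units) for the base-grid search.
#' @param cutoff_final band radius for the last refinement round (defaults
#'   to `cutoff`; the trainer passes the scheduled cutoff here).
#' @param pixel_size Angstrom per pixel.
#' @param grid a [base_grid()].
#' @param n_refine number of refinement rounds after the base search
#'   (default 5; final angular spacing `360/n_psi/2^n_refine` degrees).
#' @param topk rotations kept per round (default 8; ties broken by node id).
#' @param gain global model intensity scale.
#' @return list `R`, `t`, `err`, `node` (pix/psi of the winner). `err` is
#'   the reprojection error at the final-round band limit.
#' @export
hps <- function(image, vol, z = NULL, ctf = NULL, cutoff = 6,
                cutoff_final = cutoff, pixel_size = 1, grid = base_grid(),
                n_refine = 5L, topk = 8L, gain = 1, exact_final = FALSE) {
  D <- nrow(image)
  H <- dht(image)
  W <- .weight_matrix(ctf, D, pixel_size)
  cache <- .search_cache(vol, z, D, max(cutoff, cutoff_final), gain)
  exact <- if (exact_final && inherits(vol, "volume_field")) {
    .exact_field_slicer(vol, z, D, gain)
  } else NULL
  .hps_core(list(H), list(W), list(diag(3)), D, cutoff, cutoff_final,
            cache, grid, n_refine, topk, exact_slicer = exact)
}

# direct (interpolation-free) candidate slicer through the neural field,
# used for the last refinement level when sub-degree accuracy matters
.exact_field_slicer <- function(field, z, D, gain) {
  function(rotations, lat, weights) {
    nR <- length(rotations)
    nk <- length(lat$m)
    k3 <- cbind(lat$k, 0)
    Tall <- matrix(unlist(lapply(rotations, t), use.names = FALSE),
                   3, 3 * nR)
    big <- k3 %*% Tall
    M <- matrix(aperm(array(big, c(nk, 3L, nR)), c(1, 3, 2)), nk * nR, 3)
    vals <- eval_field(field, z, M) * sqrt(D) * gain
    S <- t(matrix(vals, nrow = nk))
    list(A = sweep(S, 2, weights, `*`),
         B = sweep(S[, lat$neg, drop = FALSE], 2, weights, `*`))
  }
}

# Full-lattice weight matrix from a ctf_params, matrix, or NULL.
.weight_matrix <- function(ctf, D, pixel_size, tilt = NULL) {
  if (is.null(ctf)) return(matrix(1, D, D))
  if (is.matrix(ctf)) {
    stopifnot(all(dim(ctf) == D))
    return(ctf)
  }
  mi <- freq_index(D)
  kk <- as.matrix(expand.grid(kx = mi, ky = mi))
  w <- if (is.null(tilt)) eval_ctf(ctf, kk, D = D, pixel_size = pixel_size)
       else tilt_weights(ctf, tilt, kk, D = D, pixel_size = pixel_size)
  matrix(w, D, D)
}

# Shared search core. Hs/Ws: lists (one per subtilt; SPA is J = 1) of D x D
# Hartley images and weight matrices; tilt_rots[[j]] composes left of the
# candidate rotation. Band limit marches from `cutoff` (base grid) to
# `cutoff_final` (last refinement round).
.hps_core <- function(Hs, Ws, tilt_rots, D, cutoff, cutoff_final,
                      cache, grid, n_refine, topk, exact_slicer = NULL) {
  J <- length(Hs)
  eval_set <- function(rot_list, trans, lat, exact = FALSE) {
    pt <- .phase_tables(lat, trans)
    E <- 0
    for (j in seq_len(J)) {
      rots_j <- if (J == 1L) rot_list
                else lapply(rot_list, function(R) tilt_rots[[j]] %*% R)
      sl <- if (exact) exact_slicer(rots_j, lat, Ws[[j]][lat$idx])
            else .slice_candidates(cache, rots_j, lat, Ws[[j]][lat$idx])
      E <- E + .pose_errors_cpp(sl$A, sl$B, Hs[[j]][lat$idx], pt$C, pt$S)
    }
    E
  }
  lat <- inband_lattice(D, cutoff)
  nodes <- grid$nodes
  rot_list <- grid$rotations
  E <- eval_set(rot_list, grid$trans, lat)
  node_id <- nodes$pix * grid$n_psi + nodes$psi_id
  rot_best <- apply(E, 1, min)
  ord <- order(rot_best, node_id)[seq_len(min(topk, nrow(nodes)))]
  kept <- nodes[ord, , drop = FALSE]
  gbest <- which(E == min(E), arr.ind = TRUE)[1, ]
  best <- list(err = min(E),
               R = rot_list[[gbest[1]]],
               t = grid$trans[gbest[2], ],
               node = nodes[gbest[1], c("pix", "psi_id")])
  if (n_refine < 1L) return(best)
  for (level in 0:(n_refine - 1L)) {
    c_l <- as.integer(round(cutoff + (cutoff_final - cutoff) *
                              (level + 1) / n_refine))
    lat_l <- inband_lattice(D, c_l)
    children <- do.call(rbind, lapply(seq_len(nrow(kept)), function(i) {
      refine_candidates(kept[i, ], level, grid)
    }))
    rot_list <- lapply(seq_len(nrow(children)), function(i) {
      hopf_rotation(children$theta[i], children$phi[i], children$psi[i])
    })
    ext <- grid$t_extent / 2^(level + 1L)
    tr <- as.matrix(expand.grid(
      tx = best$t[1] + seq(-ext, ext, length.out = grid$n_t),
      ty = best$t[2] + seq(-ext, ext, length.out = grid$n_t)))
    E <- eval_set(rot_list, tr, lat_l,
                  exact = !is.null(exact_slicer) && level == n_refine - 1L)
    node_id <- children$pix * (grid$n_psi * 2L^(level + 1L)) + children$psi_id
    rot_best <- apply(E, 1, min)
    ord <- order(rot_best, node_id)[seq_len(min(topk, nrow(children)))]
    kept <- children[ord, , drop = FALSE]
    gi <- which(E == min(E), arr.ind = TRUE)[1, ]
    # at a fixed band limit errors are comparable across levels and the
    # global minimizer seen is returned; under frequency marching each
    # level re-ranks at its own band, so the last level decides
    if (cutoff_final != cutoff || E[gi[1], gi[2]] <= best$err) {
      best <- list(err = E[gi[1], gi[2]],
                   R = rot_list[[gi[1]]],
                   t = tr[gi[2], ],
                   node = children[gi[1], c("pix", "psi_id")])
    }
  }
  best
}

#' Tilt-constrained hierarchical pose search for one particle
#'
#' A single pose is searched per particle: candidate subtilt rotations are
#' composed as `R_ij = Ry(tilt_j) R`, the reprojection error is summed over
#' the J subtilts with their individual CTF/dose/tilt weights, and the
#' minimizer is returned. With J = 1 and zero tilt this reduces exactly
#' to [hps()].
#'
#' @param images list (or D x D x J array) of subtilt images of one
#'   particle, in tilt-scheme order.
#' @param vol,z,pixel_size,grid,n_refine,topk,gain as in [hps()].
#' @param weights list with one entry per subtilt: a [ctf_params()]
#'   (combined with `tilts[[j]]` when given) or a D x D weight matrix.
#' @param tilt_angles_deg tilt angle of each subtilt, degrees.
#' @param tilts optional list of [tilt_meta()] used to fold dose/tilt
#'   attenuation into the weights.
#' @param cutoff,cutoff_final band radii in grid units, as in [hps()].
#' @return list `R`, `t`, `err` for the particle.
#' @export
hps_tilt <- function(images, vol, z = NULL, weights, tilt_angles_deg,
                     tilts = NULL, cutoff = 6, cutoff_final = cutoff,
                     pixel_size = 1, grid = base_grid(), n_refine = 5L,
                     topk = 8L, gain = 1) {
  if (is.array(images) && length(dim(images)) == 3L) {
    images <- lapply(seq_len(dim(images)[3]), function(j) images[, , j])
  }
  J <- length(images)
  if (length(tilt_angles_deg) != J)
    stop("tilt_angles_deg must have one entry per subtilt (J = ", J, ")")
  D <- nrow(images[[1]])
  Ws <- lapply(seq_len(J), function(j) {
    .weight_matrix(weights[[j]], D, pixel_size,
                   tilt = if (is.null(tilts)) NULL else tilts[[j]])
  })
  Hs <- lapply(images, dht)
  tilt_rots <- lapply(tilt_angles_deg, function(a) rot_y(a * pi / 180))
  cache <- .search_cache(vol, z, D, max(cutoff, cutoff_final), gain)
  .hps_core(Hs, Ws, tilt_rots, D, cutoff, cutoff_final, cache, grid,
            n_refine, topk)
}
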