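# Autodecoder training loop: three phases (pretrain -> hierarchical pose
# search -> stochastic gradient refinement) minimizing the Hartley-space
# reconstruction error jointly over network weights, per-particle latent
# embeddings and poses.

#' Training configuration
#'
#' Defaults are the reference settings: Adam with learning rates 1e-4
#' (network), 1e-2 (latents), 1e-3 (poses, single-particle) / 1e-5
#' (subtilt poses); batch sizes 32 (pretrain), 8 (pose search), 256
#' (single-particle SGD) / 32 (subtilt SGD); 10,000 pretrain image visits;
#' pose-search phase length `max(2N, 5e5)` image visits (single-particle)
#' or `max(2N, 1.5e5)` particle visits (subtilt); band-limit schedule 6 to
#' 16 cycles/image-length over the pose-search phase.
#'
#' @param N dataset size (images for SPA, particles for STA).
#' @param d latent dimension.
#' @param seed run seed (controls initialization, data order, pretrain
#'   poses).
#' @param width,n_freqs network architecture, see [init_field()].
#' @param pretrain_images,hps_images,sgd_images phase lengths in visits.
#' @param batch_pretrain,batch_hps,batch_sgd batch sizes per phase.
#' @param lr_field,lr_z,lr_pose Adam learning rates.
#' @param k_min,k_max band-limit schedule endpoints (grid units).
#' @param t_extent,n_t translation search grid (pixels; the reference
#'   extent of 10 px corresponds to a 128-pixel box - scale with D/128
#'   for smaller boxes).
#' @param nside,n_psi rotation search grid resolution (defaults are the
#'   reference 192 x 24 = 4,608-rotation grid; scaled-down studies may use
#'   the coarser 48 x 12 = 576-rotation tiny grid).
#' @param mode `"spa"` or `"sta"`.
#' @param n_tilts subtilts used per particle (STA; the reference keeps the
#'   first 11 of the dose-symmetric scheme).
#' @param resample_particles STA: latents are redrawn from N(0, 0.1^2)
#'   each epoch for the first this-many particle visits instead of being
#'   optimized.
#' @param latent_sd initialization scale of the latent table.
#' @param oversample slicing oversample for ground-truth volumes (unused in
#'   training itself).
#' @return list of class `train_config`.
#' @export
train_config <- function(N, d = 8L, seed = 0L, width = 256L, n_freqs = 64L,
                         pretrain_images = 10000L,
                         hps_images = NULL, sgd_images = N,
                         batch_pretrain = 32L, batch_hps = 8L,
                         batch_sgd = if (mode == "spa") 256L else 32L,
                         lr_field = 1e-4, lr_z = 1e-2,
                         lr_pose = if (mode == "spa") 1e-3 else 1e-5,
                         k_min = 6L, k_max = 16L,
                         t_extent = 10, n_t = 7L,
                         nside = 4L, n_psi = 24L,
                         mode = c("spa", "sta"), n_tilts = 11L,
                         resample_particles = 50000L, latent_sd = 0.1,
                         oversample = 2L) {
  mode <- match.arg(mode)
  if (is.null(hps_images)) {
    hps_images <- if (mode == "spa") max(2 * N, 5e5) else max(2 * N, 1.5e5)
  }
  cfg <- list(N = N, d = as.integer(d), seed = as.integer(seed),
              width = as.integer(width), n_freqs = as.integer(n_freqs),
              pretrain_images = pretrain_images, hps_images = hps_images,
              sgd_images = sgd_images, batch_pretrain = batch_pretrain,
              batch_hps = batch_hps, batch_sgd = batch_sgd,
              lr_field = lr_field, lr_z = lr_z, lr_pose = lr_pose,
              k_min = k_min, k_max = k_max, t_extent = t_extent,
              n_t = as.integer(n_t), nside = as.integer(nside),
              n_psi = as.integer(n_psi), mode = mode,
              n_tilts = as.integer(n_tilts),
              resample_particles = resample_particles,
              latent_sd = latent_sd, oversample = as.integer(oversample))
  stopifnot(all(vapply(cfg[c("pretrain_images", "hps_images", "batch_hps",
                             "lr_field", "lr_z", "lr_pose")],
                       function(x) x > 0, logical(1))))
  class(cfg) <- "train_config"
  cfg
}

# ---- internal batch gradient -----------------------------------------------

# Loss and gradients for a batch of images under the Hartley forward model
# model_i(k) = gain * W_i(k) * (cos(2 pi t_i.k) F_i(k) + sin(2 pi t_i.k)
# F_i(-k)), F_i = field(z_i, R_i k). Returns the summed squared residual
# and (optionally) gradients wrt the field weights, the batch latents and
# the batch poses.
.batch_grad <- function(field, gain, Rlist, tmat, Z, Hmat, Wmat, idx, lat,
                        want_pose = FALSE, want_grads = TRUE) {
  B <- length(idx)
  nk <- length(lat$m)
  k3 <- cbind(lat$k, 0)
  Tall <- matrix(unlist(lapply(Rlist, t), use.names = FALSE), 3, 3 * B)
  big <- k3 %*% Tall
  M <- matrix(aperm(array(big, c(nk, 3L, B)), c(1, 3, 2)), nk * B, 3)
  Zrep <- Z[rep(seq_len(B), each = nk), , drop = FALSE]
  fw <- .field_forward(field, Zrep, M)
  Fm <- matrix(fw$out, nk, B)
  Fneg <- Fm[lat$neg, , drop = FALSE]
  kx <- lat$k[, 1]; ky <- lat$k[, 2]
  PH <- 2 * pi * (outer(kx, tmat[, 1]) + outer(ky, tmat[, 2]))
  cosP <- cos(PH); sinP <- sin(PH)
  Wb <- matrix(0, nk, B); Ib <- matrix(0, nk, B)
  for (b in seq_len(B)) {
    Wb[, b] <- Wmat[, , idx[b]][lat$idx]
    Ib[, b] <- Hmat[, , idx[b]][lat$idx]
  }
  sD <- sqrt(lat$D)
  M0 <- sD * Wb * (cosP * Fm + sinP * Fneg)   # model before gain
  model <- gain * M0
  resid <- model - Ib
  out <- list(loss = sum(resid^2),
              gain_num = sum(Ib * M0), gain_den = sum(M0^2))
  if (!want_grads) return(out)
  dmodel <- 2 * gain * sD * Wb * resid
  tmp <- dmodel * sinP
  dF <- dmodel * cosP + tmp[lat$neg, , drop = FALSE]
  bk <- .field_backward(field, Zrep, M, fw$cache, as.numeric(dF))
  out$gtheta <- bk$grads
  grp <- rep(seq_len(B), each = nk)
  out$dZ <- rowsum(bk$dZ, grp)
  if (want_pose) {
    dRs <- vector("list", B)
    for (b in seq_len(B)) {
      rows <- ((b - 1) * nk + 1):(b * nk)
      dRs[[b]] <- t(bk$dK[rows, , drop = FALSE]) %*% k3
    }
    dph <- dmodel * (-sinP * Fm + cosP * Fneg)
    dT <- 2 * pi * t(lat$k) %*% dph             # 2 x B
    out$dR <- dRs
    out$dT <- t(dT)
  }
  out
}

#' Hartley-space reconstruction loss of a batch
#'
#' The full-band squared residual between the observed images and the
#' model (CTF times translated central slice of the conditioned field),
#' summed over the batch - the quantity the trainer minimizes.
#'
#' @param field a `volume_field`.
#' @param poses list with `R` (list of rotations) and `t` (N x 2 matrix).
#' @param latents N x d latent matrix.
#' @param data dataset (see [train_spa()]).
#' @param idx image indices forming the batch.
#' @param gain global model intensity scale.
#' @param cutoff band radius; `NULL` = full band.
#' @return scalar loss.
#' @export
train_loss <- function(field, poses, latents, data, idx, gain = 1,
                       cutoff = NULL) {
  D <- dim(data$images)[1]
  lat <- inband_lattice(D, cutoff)
  Hmat <- .all_dht(data$images[, , idx, drop = FALSE])
  Wmat <- .all_weights(data, idx)
  .batch_grad(field, gain, poses$R[idx],
              poses$t[idx, , drop = FALSE],
              latents[idx, , drop = FALSE], Hmat, Wmat,
              seq_along(idx), lat, want_grads = FALSE)$loss
}

# precompute Hartley transforms of an image stack -> D x D x N
.all_dht <- function(images) {
  d <- dim(images)
  out <- array(0, dim = d)
  for (i in seq_len(d[3])) out[, , i] <- dht(images[, , i])
  out
}

# precompute full-lattice weight matrices (CTF or CTF*tilt*dose) -> DxDxN
.all_weights <- function(data, idx = NULL) {
  D <- dim(data$images)[1]
  n <- dim(data$images)[3]
  if (is.null(idx)) idx <- seq_len(n)
  out <- array(0, dim = c(D, D, length(idx)))
  for (j in seq_along(idx)) {
    i <- idx[j]
    ctf_i <- if (is.null(data$ctf)) NULL else data$ctf[[i]]
    tilt_i <- if (is.null(data$tilts)) NULL else data$tilts[[i]]
    out[, , j] <- .weight_matrix(ctf_i, D, data$pixel_size, tilt = tilt_i)
  }
  out
}

# lazy (batch-row) Adam for table parameters (latents, pose params)
.table_adam_step <- function(tab, grad_rows, idx, st, lr) {
  st$t <- st$t + 1L
  bc1 <- 1 - st$beta1^st$t; bc2 <- 1 - st$beta2^st$t
  g <- grad_rows
  st$m[idx, ] <- st$beta1 * st$m[idx, , drop = FALSE] + (1 - st$beta1) * g
  st$v[idx, ] <- st$beta2 * st$v[idx, , drop = FALSE] + (1 - st$beta2) * g^2
  mh <- st$m[idx, , drop = FALSE] / bc1
  vh <- st$v[idx, , drop = FALSE] / bc2
  tab[idx, ] <- tab[idx, , drop = FALSE] - lr * mh / (sqrt(vh) + st$eps)
  list(tab = tab, st = st)
}

.table_adam_init <- function(n, p) {
  list(t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
       m = matrix(0, n, p), v = matrix(0, n, p))
}

#' Train on a single-particle dataset
#'
#' Runs the three-phase autodecoder optimization:
#' \enumerate{
#'   \item \emph{pretrain}: network weights only, against fixed random
#'     poses (uniform over SO(3), zero translations) and the initial
#'     latents;
#'   \item \emph{pose search}: per batch, each image's pose is re-estimated
#'     by [hps()] against the current field/latents, then the network and
#'     the batch latents take an Adam step at the scheduled band limit;
#'   \item \emph{SGD}: poses become free parameters (6D two-column rotation
#'     + pixel translations) optimized jointly with weights and latents at
#'     full band.
#' }
#'
#' @param data list with `images` (D x D x N), `ctf` (list of
#'   [ctf_params()] or NULL), `pixel_size`; a `simulated_dataset` works
#'   directly.
#' @param config a [train_config()].
#' @param log_every write a diagnostics record every this-many batches.
#' @param verbose print phase transitions.
#' @return `train_state`: list with `field`, `gain`, `latents`, `poses`
#'   (R list, t matrix), `images_processed`, `phase`, `log` (list of
#'   records), `config`.
#' @export
train_spa <- function(data, config, log_every = 25L, verbose = FALSE) {
  D <- dim(data$images)[1]
  N <- dim(data$images)[3]
  cfg <- config
  set.seed(cfg$seed)
  state <- list(
    field = init_field(cfg$d, seed = cfg$seed + 1L, width = cfg$width,
                       n_freqs = cfg$n_freqs),
    gain = 1,
    latents = matrix(stats::rnorm(N * cfg$d, sd = cfg$latent_sd), N, cfg$d),
    poses = list(R = random_rotations(N), t = matrix(0, N, 2)),
    images_processed = 0L, phase = "pretrain", log = list(), config = cfg)
  state$Hmat <- .all_dht(data$images)
  state$Wmat <- .all_weights(data)
  state$opt_field <- adam_init(state$field$params, cfg$lr_field)
  state$opt_z <- .table_adam_init(N, cfg$d)
  grid <- base_grid(nside = cfg$nside, n_psi = cfg$n_psi,
                    t_extent = cfg$t_extent, n_t = cfg$n_t)
  state <- .run_pretrain(state, data, cfg, log_every, verbose)
  state <- .run_hps_phase(state, data, cfg, grid, log_every, verbose)
  state <- .run_sgd_phase(state, data, cfg, log_every, verbose)
  state$Hmat <- NULL; state$Wmat <- NULL
  class(state) <- "train_state"
  state
}

.log_record <- function(state, cutoff, loss, batch_n) {
  rec <- list(phase = state$phase,
              images_processed = state$images_processed,
              cutoff = cutoff, loss = loss, batch = batch_n,
              time = as.numeric(Sys.time()))
  state$log[[length(state$log) + 1L]] <- rec
  state
}

#' Append training diagnostics to a JSONL file
#' @param state a `train_state`.
#' @param path output file; one JSON object per log record.
#' @return the path, invisibly.
#' @export
write_train_log <- function(state, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in state$log) {
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

.run_pretrain <- function(state, data, cfg, log_every, verbose) {
  if (verbose) message("phase: pretrain (", cfg$pretrain_images, " visits)")
  N <- nrow(state$latents)
  lat <- inband_lattice(dim(data$images)[1], cfg$k_min)
  # first pretrain_images in dataset order, cycling if the set is smaller
  order_all <- rep(seq_len(N), length.out = cfg$pretrain_images)
  nb <- 0L
  i <- 1L
  # the global intensity gain is fitted during pretraining only: the
  # closed-form least-squares numerator/denominator are accumulated over
  # the first half of the phase (training with the initial gain), the
  # fit is applied once at the midpoint, and the value is frozen. A
  # per-batch refit is unstable: near initialization the model is tiny
  # and the fitted scale arbitrary, and a moving gain keeps rescaling
  # the objective under the optimizer.
  g_num <- 0; g_den <- 0
  gain_set <- FALSE
  half <- ceiling(cfg$pretrain_images / 2)
  while (i <= length(order_all)) {
    idx <- order_all[i:min(i + cfg$batch_pretrain - 1L, length(order_all))]
    i <- i + length(idx)
    bg <- .batch_grad(state$field, state$gain, state$poses$R[idx],
                      state$poses$t[idx, , drop = FALSE],
                      state$latents[idx, , drop = FALSE],
                      state$Hmat, state$Wmat, idx, lat)
    if (!gain_set) {
      g_num <- g_num + bg$gain_num
      g_den <- g_den + bg$gain_den
      if (i > half && g_den > 0) {
        state$gain <- g_num / g_den
        gain_set <- TRUE
      }
    }
    up <- adam_step(state$field$params, bg$gtheta, state$opt_field)
    state$field$params <- up$params; state$opt_field <- up$st
    state$images_processed <- state$images_processed + length(idx)
    nb <- nb + 1L
    if (nb %% log_every == 0L)
      state <- .log_record(state, cfg$k_min, bg$loss, length(idx))
  }
  state
}

.run_hps_phase <- function(state, data, cfg, grid, log_every, verbose) {
  if (verbose) message("phase: hps (", cfg$hps_images, " visits)")
  D <- dim(data$images)[1]
  N <- nrow(state$latents)
  state$phase <- "hps"
  sched <- list(k_min = cfg$k_min, k_max = min(cfg$k_max, D %/% 2L - 1L),
                T = cfg$hps_images)
  done <- 0L
  nb <- 0L
  epoch_order <- integer(0)
  while (done < cfg$hps_images) {
    if (length(epoch_order) == 0L) epoch_order <- sample.int(N)
    take <- min(cfg$batch_hps, length(epoch_order), cfg$hps_images - done)
    idx <- epoch_order[seq_len(take)]
    epoch_order <- epoch_order[-seq_len(take)]
    co <- cutoff_at(done, sched)
    lat <- inband_lattice(D, co)
    for (b in seq_along(idx)) {
      i <- idx[b]
      p <- hps(data$images[, , i], state$field, z = state$latents[i, ],
               ctf = matrix(state$Wmat[, , i], D, D), cutoff = cfg$k_min,
               cutoff_final = co, grid = grid, gain = state$gain)
      state$poses$R[[i]] <- p$R
      state$poses$t[i, ] <- p$t
    }
    bg <- .batch_grad(state$field, state$gain, state$poses$R[idx],
                      state$poses$t[idx, , drop = FALSE],
                      state$latents[idx, , drop = FALSE],
                      state$Hmat, state$Wmat, idx, lat)
    up <- adam_step(state$field$params, bg$gtheta, state$opt_field)
    state$field$params <- up$params; state$opt_field <- up$st
    zu <- .table_adam_step(state$latents, bg$dZ, idx, state$opt_z, cfg$lr_z)
    state$latents <- zu$tab; state$opt_z <- zu$st
    done <- done + length(idx)
    state$images_processed <- state$images_processed + length(idx)
    nb <- nb + 1L
    if (nb %% log_every == 0L) state <- .log_record(state, co, bg$loss,
                                                    length(idx))
  }
  state
}

.run_sgd_phase <- function(state, data, cfg, log_every, verbose) {
  if (verbose) message("phase: sgd (", cfg$sgd_images, " visits)")
  D <- dim(data$images)[1]
  N <- nrow(state$latents)
  state$phase <- "sgd"
  lat <- inband_lattice(D, NULL)
  # poses become free parameters: 6D rotation + translation per image
  pose6 <- t(vapply(state$poses$R, matrix_to_rot6, numeric(6)))
  tpar <- state$poses$t
  opt_p6 <- .table_adam_init(N, 6L)
  opt_t <- .table_adam_init(N, 2L)
  done <- 0L
  nb <- 0L
  epoch_order <- integer(0)
  while (done < cfg$sgd_images) {
    if (length(epoch_order) == 0L) epoch_order <- sample.int(N)
    take <- min(cfg$batch_sgd, length(epoch_order), cfg$sgd_images - done)
    idx <- epoch_order[seq_len(take)]
    epoch_order <- epoch_order[-seq_len(take)]
    Rl <- lapply(idx, function(i) rot6_to_matrix(pose6[i, ]))
    bg <- .batch_grad(state$field, state$gain, Rl,
                      tpar[idx, , drop = FALSE],
                      state$latents[idx, , drop = FALSE],
                      state$Hmat, state$Wmat, idx, lat, want_pose = TRUE)
    up <- adam_step(state$field$params, bg$gtheta, state$opt_field)
    state$field$params <- up$params; state$opt_field <- up$st
    zu <- .table_adam_step(state$latents, bg$dZ, idx, state$opt_z, cfg$lr_z)
    state$latents <- zu$tab; state$opt_z <- zu$st
    g6 <- t(vapply(seq_along(idx), function(b) {
      rot6_backward(pose6[idx[b], ], bg$dR[[b]])
    }, numeric(6)))
    pu <- .table_adam_step(pose6, g6, idx, opt_p6, cfg$lr_pose)
    pose6 <- pu$tab; opt_p6 <- pu$st
    tu <- .table_adam_step(tpar, bg$dT, idx, opt_t, cfg$lr_pose)
    tpar <- tu$tab; opt_t <- tu$st
    done <- done + length(idx)
    state$images_processed <- state$images_processed + length(idx)
    nb <- nb + 1L
    if (nb %% log_every == 0L)
      state <- .log_record(state, lat$cutoff, bg$loss, length(idx))
  }
  state$poses$R <- lapply(seq_len(N), function(i) rot6_to_matrix(pose6[i, ]))
  state$poses$t <- tpar
  state$final_loss <- train_loss(state$field,
                                 state$poses, state$latents,
                                 data, seq_len(min(N, 64L)),
                                 gain = state$gain)
  state
}

#' Train on a subtilt (tilt-series) dataset
#'
#' The tilt-constrained variant: one pose per particle during the search
#' phase (subtilt poses composed through the known tilting scheme, errors
#' summed over the first `n_tilts` subtilts); for the first
#' `resample_particles` particle visits the latent embeddings are redrawn
#' from N(0, 0.1^2) at each epoch instead of optimized; at the switch to
#' SGD the constraint is relaxed and every subtilt carries an independent
#' pose.
#'
#' @param data a `simulated_dataset` from [simulate_tilt_series()] or a
#'   list with `images`, `ctf`, `tilts`, `particle_index`, `pixel_size`.
#' @param config a [train_config()] with `mode = "sta"`.
#' @param log_every,verbose as in [train_spa()].
#' @return `train_state`; `poses` hold per-subtilt entries, `particle_poses`
#'   the per-particle rotations estimated by the search phase.
#' @export
train_sta <- function(data, config, log_every = 25L, verbose = FALSE) {
  if (is.null(data$tilts) || is.null(data$particle_index))
    stop("train_sta requires tilt metadata and particle_index")
  cfg <- config
  D <- dim(data$images)[1]
  pidx <- data$particle_index
  parts <- sort(unique(pidx))
  P <- length(parts)
  sub_of <- lapply(parts, function(p) which(pidx == p))
  J <- unique(lengths(sub_of))
  if (length(J) != 1L) stop("all particles must share the same tilt count")
  J <- min(J, cfg$n_tilts)
  sub_of <- lapply(sub_of, function(s) s[seq_len(J)])
  tilt_deg <- vapply(sub_of[[1]], function(i) data$tilts[[i]]$tilt_angle,
                     numeric(1))
  set.seed(cfg$seed)
  state <- list(
    field = init_field(cfg$d, seed = cfg$seed + 1L, width = cfg$width,
                       n_freqs = cfg$n_freqs),
    gain = 1,
    latents = matrix(stats::rnorm(P * cfg$d, sd = cfg$latent_sd), P, cfg$d),
    particle_poses = random_rotations(P),
    images_processed = 0L, phase = "pretrain", log = list(), config = cfg)
  state$Hmat <- .all_dht(data$images)
  state$Wmat <- .all_weights(data)
  state$opt_field <- adam_init(state$field$params, cfg$lr_field)
  state$opt_z <- .table_adam_init(P, cfg$d)
  grid <- base_grid(nside = cfg$nside, n_psi = cfg$n_psi,
                    t_extent = cfg$t_extent, n_t = cfg$n_t)
  n_img <- dim(data$images)[3]

  # expand per-particle pose to per-subtilt rotations via the tilt scheme
  compose <- function(Rp, j) rot_y(tilt_deg[j] * pi / 180) %*% Rp
  subtilt_poses <- function() {
    R <- vector("list", n_img); tm <- matrix(0, n_img, 2)
    for (q in seq_len(P)) {
      for (j in seq_len(J)) R[[sub_of[[q]][j]]] <- compose(
        state$particle_poses[[q]], j)
    }
    list(R = R, t = tm)
  }

  # --- pretrain on subtilt images with fixed random particle poses
  lat0 <- inband_lattice(D, cfg$k_min)
  sp <- subtilt_poses()
  zrow <- function(q) state$latents[q, , drop = FALSE]
  img_particle <- rep(0L, n_img)
  for (q in seq_len(P)) img_particle[sub_of[[q]]] <- q
  all_sub <- unlist(sub_of)
  order_all <- rep(all_sub, length.out = cfg$pretrain_images)
  i <- 1L
  g_num <- 0; g_den <- 0; gain_set <- FALSE
  half <- ceiling(cfg$pretrain_images / 2)
  while (i <= length(order_all)) {
    idx <- order_all[i:min(i + cfg$batch_pretrain - 1L, length(order_all))]
    i <- i + length(idx)
    bg <- .batch_grad(state$field, state$gain, sp$R[idx],
                      sp$t[idx, , drop = FALSE],
                      state$latents[img_particle[idx], , drop = FALSE],
                      state$Hmat, state$Wmat, idx, lat0)
    if (!gain_set) {
      g_num <- g_num + bg$gain_num; g_den <- g_den + bg$gain_den
      if (i > half && g_den > 0) { state$gain <- g_num / g_den; gain_set <- TRUE }
    }
    up <- adam_step(state$field$params, bg$gtheta, state$opt_field)
    state$field$params <- up$params; state$opt_field <- up$st
    state$images_processed <- state$images_processed + length(idx)
  }

  # --- tilt-constrained pose search phase (counted in particles)
  state$phase <- "hps"
  sched <- list(k_min = cfg$k_min, k_max = min(cfg$k_max, D %/% 2L - 1L),
                T = cfg$hps_images)
  done <- 0L; nb <- 0L
  epoch_order <- integer(0)
  batch_p <- max(1L, cfg$batch_hps)
  while (done < cfg$hps_images) {
    if (length(epoch_order) == 0L) {
      epoch_order <- sample.int(P)
      if (done < cfg$resample_particles) {
        state$latents <- matrix(stats::rnorm(P * cfg$d, sd = cfg$latent_sd),
                                P, cfg$d)
      }
    }
    take <- min(batch_p, length(epoch_order), cfg$hps_images - done)
    qs <- epoch_order[seq_len(take)]
    epoch_order <- epoch_order[-seq_len(take)]
    co <- cutoff_at(done, sched)
    for (q in qs) {
      imgs <- lapply(sub_of[[q]], function(i) data$images[, , i])
      Ws <- lapply(sub_of[[q]], function(i) matrix(state$Wmat[, , i], D, D))
      p <- hps_tilt(imgs, state$field, z = state$latents[q, ],
                    weights = Ws, tilt_angles_deg = tilt_deg,
                    cutoff = cfg$k_min, cutoff_final = co, grid = grid,
                    gain = state$gain)
      state$particle_poses[[q]] <- p$R
    }
    sp <- subtilt_poses()
    idx <- unlist(sub_of[qs])
    bg <- .batch_grad(state$field, state$gain, sp$R[idx],
                      sp$t[idx, , drop = FALSE],
                      state$latents[img_particle[idx], , drop = FALSE],
                      state$Hmat, state$Wmat, idx,
                      inband_lattice(D, co))
    up <- adam_step(state$field$params, bg$gtheta, state$opt_field)
    state$field$params <- up$params; state$opt_field <- up$st
    if (done >= cfg$resample_particles) {
      dZq <- rowsum(bg$dZ, rep(qs, each = J))
      zu <- .table_adam_step(state$latents, dZq, qs, state$opt_z, cfg$lr_z)
      state$latents <- zu$tab; state$opt_z <- zu$st
    }
    done <- done + length(qs)
    state$images_processed <- state$images_processed + length(idx)
    nb <- nb + 1L
    if (nb %% log_every == 0L) state <- .log_record(state, co, bg$loss,
                                                    length(idx))
  }

  # --- SGD phase: relax to one independent pose per subtilt
  state$phase <- "sgd"
  sp <- subtilt_poses()
  state$poses <- sp
  state$poses_at_relaxation <- lapply(sp$R, identity)
  lat <- inband_lattice(D, NULL)
  pose6 <- t(vapply(sp$R[all_sub], matrix_to_rot6, numeric(6)))
  rownames(pose6) <- NULL
  sub_pos <- match(seq_len(n_img), all_sub)   # image -> row in pose6
  tpar <- sp$t[all_sub, , drop = FALSE]
  opt_p6 <- .table_adam_init(length(all_sub), 6L)
  opt_t <- .table_adam_init(length(all_sub), 2L)
  done <- 0L
  epoch_order <- integer(0)
  while (done < cfg$sgd_images) {
    if (length(epoch_order) == 0L) epoch_order <- sample(all_sub)
    take <- min(cfg$batch_sgd, length(epoch_order), cfg$sgd_images - done)
    idx <- epoch_order[seq_len(take)]
    epoch_order <- epoch_order[-seq_len(take)]
    rows <- sub_pos[idx]
    Rl <- lapply(rows, function(r) rot6_to_matrix(pose6[r, ]))
    bg <- .batch_grad(state$field, state$gain, Rl,
                      tpar[rows, , drop = FALSE],
                      state$latents[img_particle[idx], , drop = FALSE],
                      state$Hmat, state$Wmat, idx, lat, want_pose = TRUE)
    up <- adam_step(state$field$params, bg$gtheta, state$opt_field)
    state$field$params <- up$params; state$opt_field <- up$st
    dZq <- rowsum(bg$dZ, img_particle[idx])
    qs <- sort(unique(img_particle[idx]))
    zu <- .table_adam_step(state$latents, dZq, qs, state$opt_z, cfg$lr_z)
    state$latents <- zu$tab; state$opt_z <- zu$st
    g6 <- t(vapply(seq_along(rows), function(b) {
      rot6_backward(pose6[rows[b], ], bg$dR[[b]])
    }, numeric(6)))
    pu <- .table_adam_step(pose6, g6, rows, opt_p6, cfg$lr_pose)
    pose6 <- pu$tab; opt_p6 <- pu$st
    tu <- .table_adam_step(tpar, bg$dT, rows, opt_t, cfg$lr_pose)
    tpar <- tu$tab; opt_t <- tu$st
    done <- done + length(idx)
    state$images_processed <- state$images_processed + length(idx)
  }
  for (s in seq_along(all_sub)) {
    state$poses$R[[all_sub[s]]] <- rot6_to_matrix(pose6[s, ])
    state$poses$t[all_sub[s], ] <- tpar[s, ]
  }
  state$sub_of <- sub_of
  state$Hmat <- NULL; state$Wmat <- NULL
  class(state) <- "train_state"
  state
}
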