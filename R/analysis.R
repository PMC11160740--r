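# Latent-space analysis of a trained run: k-means sampling of the
# conformational landscape, PCA views, map sampling and traversals.

#' k-means clustering of latent embeddings
#'
#' @param Z N x d latent matrix.
#' @param k number of clusters (k <= N).
#' @param seed RNG seed (clustering is deterministic under it).
#' @param nstart restarts.
#' @return list with `labels` (length N) and `centroids` (k x d).
#' @export
kmeans_latents <- function(Z, k, seed = 0, nstart = 10L) {
  if (k > nrow(Z)) stop("k must not exceed the number of points")
  set.seed(seed)
  if (k == nrow(Z)) {
    return(list(labels = seq_len(nrow(Z)), centroids = Z))
  }
  km <- stats::kmeans(Z, centers = k, nstart = nstart, iter.max = 100L)
  list(labels = km$cluster, centroids = km$centers)
}

#' PCA of latent embeddings
#'
#' @param Z N x d latent matrix.
#' @param n_components components to keep.
#' @return list with `projections` (N x n_components), `rotation`
#'   (d x n_components, orthonormal columns), `explained` (variance
#'   fractions).
#' @export
pca_latents <- function(Z, n_components = 2L) {
  n_components <- min(n_components, ncol(Z))
  p <- stats::prcomp(Z, center = TRUE, scale. = FALSE)
  list(projections = p$x[, seq_len(n_components), drop = FALSE],
       rotation = p$rotation[, seq_len(n_components), drop = FALSE],
       explained = (p$sdev^2 / sum(p$sdev^2))[seq_len(n_components)])
}

#' Render and write maps at a list of latent embeddings
#'
#' @param field trained `volume_field`.
#' @param z_list list (or matrix rows) of latent vectors.
#' @param D map size.
#' @param outdir output directory; files are `map_000.mrc`, ...
#' @param pixel_size voxel size for the MRC headers.
#' @param gain model intensity scale.
#' @return character vector of file paths.
#' @export
sample_maps <- function(field, z_list, D, outdir, pixel_size = 1,
                        gain = 1) {
  if (is.matrix(z_list))
    z_list <- lapply(seq_len(nrow(z_list)), function(i) z_list[i, ])
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(z_list))
  for (i in seq_along(z_list)) {
    m <- render_map(field, z_list[[i]], D, gain = gain)
    paths[i] <- file.path(outdir, sprintf("map_%03d.mrc", i - 1L))
    write_mrc(m, pixel_size, paths[i])
  }
  paths
}

#' Latent-space traversal
#'
#' Renders maps at `n_steps` equally spaced convex combinations of two
#' latent embeddings, endpoints included (`n_steps = 1` gives the
#' midpoint).
#'
#' @param field trained `volume_field`.
#' @param z_a,z_b endpoint latents.
#' @param n_steps number of maps.
#' @param D map size.
#' @param gain model intensity scale.
#' @return list of D^3 arrays.
#' @export
traverse <- function(field, z_a, z_b, n_steps, D, gain = 1) {
  al <- if (n_steps == 1L) 0.5 else seq(0, 1, length.out = n_steps)
  lapply(al, function(a) render_map(field, (1 - a) * z_a + a * z_b, D,
                                    gain = gain))
}

#' Select particles by cluster and write the subset
#'
#' Non-interactive replacement for lasso selection: keep the images whose
#' k-means label falls in `keep`, write the subset stack and metadata for
#' retraining.
#'
#' @param stack a `particle_stack`.
#' @param labels per-image cluster labels.
#' @param keep cluster ids to keep.
#' @param mrcs_path,star_path output files (optional).
#' @return the subset `particle_stack` (invisibly if files are written).
#' @export
filter_by_cluster <- function(stack, labels, keep, mrcs_path = NULL,
                              star_path = NULL) {
  sel <- which(labels %in% keep)
  if (length(sel) == 0) stop("no particles in the selected clusters")
  sub <- particle_stack(stack$images[, , sel, drop = FALSE],
                        pixel_size = stack$pixel_size,
                        ctf = if (is.null(stack$ctf)) NULL else stack$ctf[sel],
                        tilt = if (is.null(stack$tilt)) NULL
                               else stack$tilt[sel],
                        particle_index = stack$particle_index[sel])
  if (!is.null(mrcs_path)) {
    write_particle_stack(sub, mrcs_path, star_path)
    return(invisible(sub))
  }
  sub
}

#' Full latent analysis of a trained state
#'
#' @param state a `train_state`.
#' @param k k-means cluster count.
#' @param D map size for sampled maps (NULL = skip rendering).
#' @param outdir where to write sampled maps (NULL = skip).
#' @param seed RNG seed.
#' @return list with `kmeans`, `pca`, and `map_paths` (if rendered).
#' @export
analyze_latents <- function(state, k = 4L, D = NULL, outdir = NULL,
                            seed = 0) {
  km <- kmeans_latents(state$latents, k, seed = seed)
  pc <- pca_latents(state$latents, n_components = min(2L,
                                                      ncol(state$latents)))
  out <- list(kmeans = km, pca = pc)
  if (!is.null(D) && !is.null(outdir)) {
    out$map_paths <- sample_maps(state$field, km$centroids, D, outdir,
                                 gain = state$gain)
  }
  out
}
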