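# STAR file reader/writer (RELION dialect). Accepts both the flat legacy
# layout (one data_ block with a loop_) and the 3.1 optics-group layout
# (data_optics + data_particles, joined on rlnOpticsGroup). All angles in
# metadata are degrees; conversion to radians happens at the boundary of
# the numerical code.

#' Read a STAR file
#'
#' @param path file path.
#' @return named list of data frames, one per `data_` block; block names
#'   keep the suffix after `data_` (the empty suffix becomes `"main"`).
#'   Numeric-looking columns are converted.
#' @export
read_star <- function(path) {
  if (!file.exists(path)) stop("STAR file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  blocks <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    ln <- lines[i]
    if (startsWith(ln, "data_")) {
      name <- substring(ln, 6L)
      if (name == "") name <- "main"
      i <- i + 1L
      while (i <= n && lines[i] != "loop_" && !startsWith(lines[i], "_"))
        i <- i + 1L
      if (i > n) break
      if (lines[i] == "loop_") {
        i <- i + 1L
        tags <- character(0)
        while (i <= n && startsWith(lines[i], "_")) {
          tags <- c(tags, sub("^_", "", strsplit(lines[i], "[ #]")[[1]][1]))
          i <- i + 1L
        }
        rows <- character(0)
        while (i <= n && lines[i] != "" && !startsWith(lines[i], "data_")) {
          if (!startsWith(lines[i], "#")) rows <- c(rows, lines[i])
          i <- i + 1L
        }
        if (length(rows) > 0) {
          mat <- do.call(rbind, strsplit(rows, "[ \t]+"))
          if (ncol(mat) != length(tags))
            stop("STAR block '", name, "': ", length(tags),
                 " tags but rows have ", ncol(mat), " fields")
          df <- as.data.frame(mat, stringsAsFactors = FALSE)
          names(df) <- tags
          for (cn in names(df)) {
            sup <- suppressWarnings(as.numeric(df[[cn]]))
            if (!anyNA(sup)) df[[cn]] <- sup
          }
          blocks[[name]] <- df
        }
      } else {
        # simple key-value block
        kv <- list()
        while (i <= n && startsWith(lines[i], "_")) {
          parts <- strsplit(lines[i], "[ \t]+")[[1]]
          kv[[sub("^_", "", parts[1])]] <- parts[2]
          i <- i + 1L
        }
        blocks[[name]] <- as.data.frame(kv, stringsAsFactors = FALSE)
      }
    } else i <- i + 1L
  }
  blocks
}

#' Write a STAR file
#'
#' @param blocks named list of data frames (block name -> loop table).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_star <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# written by cryofield", con)
  for (name in names(blocks)) {
    df <- blocks[[name]]
    writeLines(c("", paste0("data_", if (name == "main") "" else name), "",
                 "loop_"), con)
    writeLines(sprintf("_%s #%d", names(df), seq_along(df)), con)
    mat <- vapply(df, function(col) {
      if (is.numeric(col)) sprintf("%.6f", col) else as.character(col)
    }, character(nrow(df)))
    if (nrow(df) == 1L) mat <- matrix(mat, nrow = 1L)
    writeLines(apply(mat, 1, paste, collapse = "  "), con)
  }
  writeLines("", con)
  invisible(path)
}

# tag lookup helpers ---------------------------------------------------------

.star_first <- function(df, tags) {
  for (tg in tags) if (tg %in% names(df)) return(df[[tg]])
  NULL
}

#' Extract CTF parameters from a particles table
#' @param df data frame of particle rows (optics merged).
#' @return list of [ctf_params()], one per row.
#' @keywords internal
star_ctf <- function(df) {
  n <- nrow(df)
  du <- .star_first(df, "rlnDefocusU")
  dv <- .star_first(df, "rlnDefocusV")
  ang <- .star_first(df, "rlnDefocusAngle")
  kv <- .star_first(df, "rlnVoltage")
  cs <- .star_first(df, "rlnSphericalAberration")
  w <- .star_first(df, "rlnAmplitudeContrast")
  ps <- .star_first(df, "rlnPhaseShift")
  lapply(seq_len(n), function(i) {
    ctf_params(defocus_u = if (is.null(du)) 10000 else du[i],
               defocus_v = if (is.null(dv)) 10000 else dv[i],
               astigmatism_angle = if (is.null(ang)) 0 else ang[i],
               voltage = if (is.null(kv)) 300 else kv[i],
               cs = if (is.null(cs)) 2.7 else cs[i],
               amplitude_contrast = if (is.null(w)) 0.1 else w[i],
               phase_shift = if (is.null(ps)) 0 else ps[i])
  })
}

#' Merge a 3.1-style optics block into the particles table
#' @param blocks list from [read_star()].
#' @return single data frame of particle rows.
#' @keywords internal
star_particles <- function(blocks) {
  if (!is.null(blocks$particles)) {
    df <- blocks$particles
    if (!is.null(blocks$optics) && "rlnOpticsGroup" %in% names(df)) {
      op <- blocks$optics
      j <- match(df$rlnOpticsGroup, op$rlnOpticsGroup)
      for (cn in setdiff(names(op), names(df))) df[[cn]] <- op[[cn]][j]
    }
    df
  } else if (!is.null(blocks$main)) {
    blocks$main
  } else {
    blocks[[1]]
  }
}

#' Group subtilt rows of a tilt-series STAR table by particle
#'
#' Particles are identified by the first available of
#' `rlnTomoParticleId`, `rlnGroupNumber`, or the particle component of
#' `rlnImageName`; subtilts within a particle are ordered by tilt order
#' (or file order when absent). The cumulative dose per subtilt is taken
#' from the first available dose tag, or computed as
#' `tilt_order * dose_per_tilt`.
#'
#' @param df particles data frame.
#' @param dose_per_tilt fallback dose increment, e/A^2.
#' @return list with `groups` (list of row-index vectors), `n_particles`,
#'   `n_subtilts` (total row count), `tilt_angle` and `dose` vectors
#'   (per row; NA when unavailable).
#' @export
tilt_groups <- function(df, dose_per_tilt = NULL) {
  id <- .star_first(df, c("rlnTomoParticleId", "rlnGroupNumber"))
  if (is.null(id)) {
    img <- .star_first(df, "rlnImageName")
    if (!is.null(img)) id <- sub("^[0-9]+@", "", img)
  }
  if (is.null(id)) stop("no particle grouping tag found in STAR table")
  groups <- split(seq_len(nrow(df)), factor(id, levels = unique(id)))
  tilt <- .star_first(df, c("rlnTomoTiltAngle", "rlnAngleTilt",
                            "rlnTiltAngle"))
  order_tag <- .star_first(df, c("rlnTomoTiltOrder", "rlnTiltOrder"))
  dose <- .star_first(df, c("rlnCumulativeDose", "rlnTomoCumulativeDose",
                            "rlnCtfBfactorDose"))
  if (is.null(dose) && !is.null(dose_per_tilt)) {
    ord <- if (is.null(order_tag)) {
      unlist(lapply(groups, function(g) seq_along(g) - 1L))
    } else order_tag
    dose <- unname(ord * dose_per_tilt)
  }
  list(groups = groups, n_particles = length(groups),
       n_subtilts = nrow(df),
       tilt_angle = if (is.null(tilt)) rep(NA_real_, nrow(df)) else tilt,
       dose = if (is.null(dose)) rep(NA_real_, nrow(df)) else dose)
}
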