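#' Heterogeneity parameters for the particle population
#'
#' @param radius_mean Mean particle radius (nm).
#' @param radius_cv Coefficient of variation of the radius (lognormal).
#' @param encapsulation_sd Standard deviation (natural-log scale) of the
#'   per-dye multiplicative encapsulation noise.
#' @return A list of class `het_params`.
#' @export
het_params <- function(radius_mean = 50, radius_cv = 0.1,
                       encapsulation_sd = 0.25) {
  if (radius_mean <= 0) stop("radius_mean must be positive")
  if (radius_cv < 0) stop("radius_cv must be non-negative")
  if (encapsulation_sd < 0) stop("encapsulation_sd must be non-negative")
  structure(list(radius_mean = radius_mean, radius_cv = radius_cv,
                 encapsulation_sd = encapsulation_sd),
            class = "het_params")
}

#' Draw one particle's ground truth for a barcode
#'
#' The radius is lognormal with mean `radius_mean` and coefficient of
#' variation `radius_cv`. Dye loads scale with particle volume — a particle
#' twice the nominal radius carries 8x the dye — and carry independent
#' per-dye lognormal encapsulation noise `exp(eta)`, `eta ~ N(0,
#' encapsulation_sd^2)`. Dyes at level zero get exactly zero load. Uses the
#' current R random stream.
#'
#' @param concentrations Per-dye nominal concentrations (uM / load units),
#'   e.g. one row of [barcode_concentrations()].
#' @param het A [het_params()].
#' @param model An [optical_model()] used to derive emissive loads and
#'   expected channel signals.
#' @param barcode_id Optional id stored with the particle.
#' @param radius Optional fixed radius (nm) overriding the lognormal draw
#'   (useful for deterministic checks).
#' @return A list of class `particle_truth`: `barcode_id`, `radius` (nm),
#'   `loads`, `emissive_loads` (per dye), `expected_signal` (per channel).
#' @export
sample_particle <- function(concentrations, het = het_params(),
                            model = optical_model(), barcode_id = NA_integer_,
                            radius = NULL) {
  if (length(concentrations) != nrow(model$dyes)) {
    stop("one concentration per dye required")
  }
  if (is.null(radius)) {
    if (het$radius_cv > 0) {
      sdlog <- sqrt(log(1 + het$radius_cv^2))
      meanlog <- log(het$radius_mean) - sdlog^2 / 2
      radius <- stats::rlnorm(1L, meanlog, sdlog)
    } else {
      radius <- het$radius_mean
    }
  }
  eta <- if (het$encapsulation_sd > 0) {
    stats::rnorm(length(concentrations), 0, het$encapsulation_sd)
  } else rep(0, length(concentrations))
  loads <- concentrations * (radius / het$radius_mean)^3 * exp(eta)
  loads[concentrations == 0] <- 0
  m <- apply_quenching(loads, model$Q)
  structure(list(
    barcode_id = barcode_id, radius = radius, loads = loads,
    emissive_loads = m,
    expected_signal = expected_channel_signal(m, model)
  ), class = "particle_truth")
}

# integrated 2-D Gaussian rendered onto a pixel patch; total volume = N.
# Positions in pixel units, pixel centers at (i - 0.5) for 1-based indices.
render_spot <- function(img, x_px, y_px, sigma_px, N, half = NULL) {
  if (is.null(half)) half <- max(3L, ceiling(5 * sigma_px))
  nx <- ncol(img); ny <- nrow(img)
  cx <- ceiling(x_px); cy <- ceiling(y_px)
  x_lo <- max(1L, cx - half); x_hi <- min(nx, cx + half)
  y_lo <- max(1L, cy - half); y_hi <- min(ny, cy + half)
  if (x_lo > x_hi || y_lo > y_hi) return(img)
  xs <- x_lo:x_hi
  ys <- y_lo:y_hi
  fx <- stats::pnorm(xs, x_px, sigma_px) - stats::pnorm(xs - 1, x_px, sigma_px)
  fy <- stats::pnorm(ys, y_px, sigma_px) - stats::pnorm(ys - 1, y_px, sigma_px)
  img[ys, xs] <- img[ys, xs] + N * (fy %o% fx)
  img
}

#' Render one field of view in all channels
#'
#' Each particle appears in channel `c` as a symmetric 2-D Gaussian whose
#' total integral equals its expected channel signal and whose width follows
#' [psf_sigma()] at the channel's excitation wavelength and the particle's
#' diameter. The constant background rate is added everywhere; with noise
#' enabled each pixel is Poisson-drawn, Gaussian read noise and the camera
#' offset are added, and the result is clipped to the 16-bit range (a
#' warning reports saturated pixels).
#'
#' @param particles Data.frame with columns `x_nm`, `y_nm`, `radius_nm` and
#'   either an `expected_signal` matrix attribute or columns
#'   `sig_<channel>`; build it with [generate_dataset()] or manually.
#' @param model An [optical_model()].
#' @param noise Logical; draw shot/read noise or return the noiseless
#'   expectation (plus offset).
#' @param dim Image size in pixels (square).
#' @param pixel_size_nm Pixel pitch in nm.
#' @return An object of class `fov_image`: list with `pixels` (array
#'   dim x dim x channels), `pixel_size_nm`, `bit_depth`, `channels`.
#' @export
render_fov <- function(particles, model = optical_model(), noise = TRUE,
                       dim = 504L, pixel_size_nm = 92.45) {
  chn <- model$channels$name
  nch <- length(chn)
  sig_cols <- paste0("sig_", chn)
  if (nrow(particles) > 0 && !all(sig_cols %in% names(particles))) {
    stop("particles must carry sig_<channel> columns of expected signals")
  }
  pixels <- array(0, c(dim, dim, nch))
  for (c in seq_len(nch)) {
    img <- matrix(model$background_rate, dim, dim)
    lam <- model$channels$laser_nm[c]
    if (nrow(particles) > 0) {
      for (i in seq_len(nrow(particles))) {
        s_px <- psf_sigma(lam, model$numerical_aperture,
                          2 * particles$radius_nm[i]) / pixel_size_nm
        img <- render_spot(img,
                           particles$x_nm[i] / pixel_size_nm,
                           particles$y_nm[i] / pixel_size_nm,
                           s_px, particles[[sig_cols[c]]][i])
      }
    }
    if (noise) {
      img <- stats::rpois(length(img), img) +
        stats::rnorm(length(img), 0, model$read_noise_sd)
      img <- round(img) + model$offset
      n_sat <- sum(img > 65535)
      if (n_sat > 0) warning(sprintf("channel %s: %d pixel(s) saturated", chn[c], n_sat))
      img <- matrix(pmin(pmax(img, 0), 65535), dim, dim)
    } else {
      img <- img + model$offset
    }
    pixels[, , c] <- img
  }
  structure(list(pixels = pixels, pixel_size_nm = pixel_size_nm,
                 bit_depth = 16L, channels = chn),
            class = "fov_image")
}

# uniform placement with minimum pairwise separation (rejection sampling)
place_particles <- function(n, dim, pixel_size_nm, min_sep_nm = 1000,
                            margin_nm = 1000, max_tries = 200L) {
  lim <- dim * pixel_size_nm
  xs <- numeric(0); ys <- numeric(0)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      x <- stats::runif(1, margin_nm, lim - margin_nm)
      y <- stats::runif(1, margin_nm, lim - margin_nm)
      if (!length(xs) || min((xs - x)^2 + (ys - y)^2) >= min_sep_nm^2) {
        xs <- c(xs, x); ys <- c(ys, y); placed <- TRUE; break
      }
    }
    if (!placed) {
      stop(sprintf("could not place %d particles with %g nm separation", n, min_sep_nm))
    }
  }
  data.frame(x_nm = xs, y_nm = ys)
}

#' Generate a full synthetic dataset (images + ground truth)
#'
#' Draws `particles_per_class` particles for every barcode in `codes`,
#' distributes them round-robin over `fovs` fields of view at uniform random
#' positions with a minimum pairwise separation, and renders every FOV in
#' all channels. Deterministic given `seed`.
#'
#' @param codes A `barcode_table` (or subset of rows).
#' @param particles_per_class Particles drawn per barcode.
#' @param fovs Number of fields of view.
#' @param het A [het_params()].
#' @param model An [optical_model()].
#' @param seed Integer seed.
#' @param noise Render with noise?
#' @param dim,pixel_size_nm Image geometry.
#' @param min_sep_nm Minimum pairwise particle separation.
#' @return List with `images` (list of `fov_image`) and `truth` (data.frame:
#'   particle_id, fov, barcode_id, x_nm, y_nm, radius_nm, per-dye load_*/em_*
#'   and per-channel sig_* columns).
#' @export
generate_dataset <- function(codes, particles_per_class, fovs = 1L,
                             het = het_params(), model = optical_model(),
                             seed = 1L, noise = TRUE,
                             dim = 504L, pixel_size_nm = 92.45,
                             min_sep_nm = 1000) {
  set.seed(seed)
  conc <- barcode_concentrations(codes)
  dye_names <- colnames(conc)
  n_total <- nrow(codes) * particles_per_class
  ids <- rep(codes$id, each = particles_per_class)
  fov_of <- rep_len(seq_len(fovs), n_total)
  # shuffle class order so every FOV mixes classes
  ord <- sample.int(n_total)
  ids <- ids[ord]

  rows <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    p <- sample_particle(conc[match(ids[i], codes$id), ], het, model, ids[i])
    rows[[i]] <- c(barcode_id = p$barcode_id, radius_nm = p$radius,
                   stats::setNames(p$loads, paste0("load_", dye_names)),
                   stats::setNames(p$emissive_loads, paste0("em_", dye_names)),
                   stats::setNames(p$expected_signal,
                                   paste0("sig_", names(p$expected_signal))))
  }
  truth <- as.data.frame(do.call(rbind, rows))
  truth$particle_id <- seq_len(n_total)
  truth$fov <- fov_of

  images <- vector("list", fovs)
  pos <- vector("list", fovs)
  truth$x_nm <- NA_real_
  truth$y_nm <- NA_real_
  for (f in seq_len(fovs)) {
    idx <- which(truth$fov == f)
    pos[[f]] <- place_particles(length(idx), dim, pixel_size_nm, min_sep_nm)
    truth$x_nm[idx] <- pos[[f]]$x_nm
    truth$y_nm[idx] <- pos[[f]]$y_nm
    images[[f]] <- render_fov(truth[idx, , drop = FALSE], model, noise,
                              dim, pixel_size_nm)
  }
  front <- c("particle_id", "fov", "barcode_id", "x_nm", "y_nm", "radius_nm")
  truth <- truth[, c(front, setdiff(names(truth), front))]
  list(images = images, truth = truth)
}

#' Write / read a field of view as multi-page TIFF
#'
#' One 16-bit page per channel, channel order as in the model; an optional
#' YAML sidecar records pixel size and channel table.
#'
#' @param fov A `fov_image`.
#' @param path Output TIFF path.
#' @param sidecar Write `<path>.yaml` with geometry and channel metadata?
#' @return `path`, invisibly.
#' @export
write_fov_tiff <- function(fov, path, sidecar = TRUE) {
  planes <- lapply(seq_along(fov$channels), function(c) {
    fov$pixels[, , c] / 65535
  })
  tiff::writeTIFF(planes, path, bits.per.sample = 16L)
  if (sidecar) {
    yaml::write_yaml(list(
      pixel_size_nm = fov$pixel_size_nm, bit_depth = fov$bit_depth,
      channels = as.list(fov$channels)
    ), paste0(path, ".yaml"))
  }
  invisible(path)
}

#' @rdname write_fov_tiff
#' @param channels Channel names for a TIFF read without a sidecar.
#' @param pixel_size_nm Pixel size override when no sidecar exists.
#' @export
read_fov_tiff <- function(path, channels = NULL, pixel_size_nm = NULL) {
  planes <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  side <- paste0(path, ".yaml")
  meta <- if (file.exists(side)) yaml::read_yaml(side) else list()
  if (is.null(channels)) {
    channels <- if (!is.null(meta$channels)) unlist(meta$channels)
      else default_channels()$name
  }
  if (is.null(pixel_size_nm)) {
    pixel_size_nm <- if (!is.null(meta$pixel_size_nm)) meta$pixel_size_nm else 92.45
  }
  if (length(planes) != length(channels)) {
    stop(sprintf("TIFF has %d page(s), expected %d channels",
                 length(planes), length(channels)))
  }
  pixels <- array(0, c(nrow(planes[[1]]), ncol(planes[[1]]), length(planes)))
  for (c in seq_along(planes)) pixels[, , c] <- planes[[c]]
  structure(list(pixels = pixels, pixel_size_nm = pixel_size_nm,
                 bit_depth = 16L, channels = channels),
            class = "fov_image")
}

#' @export
print.fov_image <- function(x, ...) {
  cat(sprintf("FOV image: %d x %d px, %d channel(s) [%s], %.2f nm/px\n",
              dim(x$pixels)[1], dim(x$pixels)[2], length(x$channels),
              paste(x$channels, collapse = ","), x$pixel_size_nm))
  invisible(x)
}
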