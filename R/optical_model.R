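#' Optical forward model for dye-loaded nanoparticles
#'
#' Bundles every photophysical parameter needed to turn per-dye loads into
#' expected photon counts in the six acquisition channels:
#'
#' * `E` — excitation efficiency of each laser line for each dye (dyes x
#'   lasers, in \[0, 1\], diagonal-dominant at each dye's main line);
#' * `W` — fraction of each dye's emission falling inside each detection
#'   window (dyes x windows, rows need not sum to 1: light outside all
#'   windows is lost);
#' * `fret_pairs` — ordered spectrally-downhill donor/acceptor pairs with a
#'   half-saturation constant `K` in load units: the transferred fraction of
#'   a donor's excitations is `m_acceptor / (m_acceptor + K)`;
#' * `Q` — per-dye aggregation-caused-quenching constants (load units): a
#'   raw load `a` yields emissive load `a / (1 + a/Q)`, saturating at `Q`;
#' * `yield` — per-dye effective quantum yields;
#' * `gain` — expected detected photons per unit emissive load at unit
#'   yield, calibrated so a high-level single-dye particle reaches a
#'   main-channel peak signal-to-noise ratio near 20;
#' * `background_rate`, `read_noise_sd`, `offset` — camera model (photons
#'   per pixel, counts, counts).
#'
#' Load units are micromolar-equivalent: the default barcode scheme maps
#' level low/high to loads 1 and 10.
#'
#' @param dyes A [dye_panel()].
#' @param channels A `channel_table`, default [default_channels()].
#' @param E,W Excitation / emission-window matrices as above.
#' @param fret_pairs Data.frame with columns `donor`, `acceptor`, `K`.
#' @param Q Per-dye quench constants (load units).
#' @param yield Per-dye quantum yields.
#' @param gain Photons per unit emissive load.
#' @param background_rate Mean background photons per pixel.
#' @param read_noise_sd Gaussian read noise (counts).
#' @param offset Camera offset (counts).
#' @param numerical_aperture Objective NA used for the channel PSFs.
#' @return An object of class `optical_model`.
#' @export
optical_model <- function(dyes = dye_panel(),
                          channels = default_channels(),
                          E = NULL, W = NULL,
                          fret_pairs = NULL,
                          Q = rep(50, nrow(dyes)),
                          yield = rep(0.9, nrow(dyes)),
                          gain = 600,
                          background_rate = 5,
                          read_noise_sd = 2,
                          offset = 100,
                          numerical_aperture = 1.4) {
  m <- nrow(dyes)
  lasers <- sort(unique(channels$laser_nm))
  win <- unique(channels[, c("em_low_nm", "em_high_nm")])
  win <- win[order(win$em_low_nm), , drop = FALSE]
  rownames(win) <- NULL

  if (is.null(E)) {
    if (!identical(dyes$name, c("DiO", "DiI", "DiD"))) {
      stop("a default excitation matrix exists only for the DiO/DiI/DiD panel")
    }
    # lasers 488, 552, 638: direct excitation on the diagonal, cross-excitation
    # of the next-redder dye by a bluer line off-diagonal
    E <- rbind(
      DiO = c(1.00, 0.03, 0.00),
      DiI = c(0.15, 1.00, 0.02),
      DiD = c(0.03, 0.15, 1.00)
    )
    colnames(E) <- as.character(lasers)
  }
  if (is.null(W)) {
    if (!identical(dyes$name, c("DiO", "DiI", "DiD"))) {
      stop("a default emission matrix exists only for the DiO/DiI/DiD panel")
    }
    # windows 498-538, 563-620, 648-750: own window on the diagonal, red-tail
    # bleed-through off-diagonal
    W <- rbind(
      DiO = c(0.55, 0.25, 0.03),
      DiI = c(0.00, 0.50, 0.12),
      DiD = c(0.00, 0.01, 0.75)
    )
    colnames(W) <- paste0(win$em_low_nm, "-", win$em_high_nm)
  }
  if (is.null(fret_pairs)) {
    fret_pairs <- if (identical(dyes$name, c("DiO", "DiI", "DiD"))) {
      data.frame(donor = c("DiO", "DiO", "DiI"),
                 acceptor = c("DiI", "DiD", "DiD"),
                 K = c(10, 25, 10),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(donor = character(), acceptor = character(), K = numeric())
    }
  }

  stopifnot(all(E >= 0 & E <= 1), all(W >= 0 & W <= 1),
            all(Q > 0), all(yield >= 0 & yield <= 1), gain > 0,
            background_rate >= 0, read_noise_sd >= 0, offset >= 0,
            nrow(E) == m, nrow(W) == m,
            length(Q) == m, length(yield) == m)
  if (nrow(fret_pairs) > 0) {
    stopifnot(all(fret_pairs$K > 0),
              all(fret_pairs$donor %in% dyes$name),
              all(fret_pairs$acceptor %in% dyes$name))
  }

  # channel -> (laser index, window index) map
  ch_laser <- match(channels$laser_nm, lasers)
  ch_window <- match(paste(channels$em_low_nm, channels$em_high_nm),
                     paste(win$em_low_nm, win$em_high_nm))

  structure(list(
    dyes = dyes, channels = channels, lasers = lasers, windows = win,
    E = E, W = W, fret_pairs = fret_pairs, Q = Q, yield = yield,
    gain = gain, background_rate = background_rate,
    read_noise_sd = read_noise_sd, offset = offset,
    numerical_aperture = numerical_aperture,
    ch_laser = ch_laser, ch_window = ch_window
  ), class = "optical_model")
}

#' @export
print.optical_model <- function(x, ...) {
  cat(sprintf(
    "Optical model: %d dyes, %d channels, gain %.0f, Q = %s, %d FRET pair(s)\n",
    nrow(x$dyes), nrow(x$channels), x$gain,
    paste(x$Q, collapse = "/"), nrow(x$fret_pairs)))
  invisible(x)
}

#' Aggregation-caused quenching saturation
#'
#' Converts raw per-dye loads into emissive loads via the saturating form
#' `m = a / (1 + a/Q)`: linear at low load, approaching the plateau `Q` as
#' the local dye concentration grows and stacking quenches emission.
#'
#' @param loads Numeric vector/matrix of raw loads (>= 0).
#' @param Q Quench constant(s), recycled along loads' last dimension.
#' @return Emissive loads, same shape as `loads`.
#' @examples
#' apply_quenching(50, 50)  # 25: half the plateau at a = Q
#' @export
apply_quenching <- function(loads, Q) {
  if (any(loads < 0)) stop("loads must be non-negative")
  if (any(Q <= 0)) stop("quench constants must be positive")
  if (is.matrix(loads)) {
    sweep(loads, 2L, Q, function(a, q) a / (1 + a / q))
  } else {
    loads / (1 + loads / Q)
  }
}

# FRET cascade on one laser's excited loads. x: excitations per dye,
# m: emissive loads (drive acceptor saturation). Pairs applied in order;
# total excitation is conserved exactly.
fret_redistribute <- function(x, m, model) {
  fp <- model$fret_pairs
  if (nrow(fp) == 0L) return(x)
  nm <- model$dyes$name
  for (k in seq_len(nrow(fp))) {
    di <- match(fp$donor[k], nm)
    ai <- match(fp$acceptor[k], nm)
    f <- m[ai] / (m[ai] + fp$K[k])
    t <- x[di] * f
    x[di] <- x[di] - t
    x[ai] <- x[ai] + t
  }
  x
}

#' Expected photon counts per acquisition channel
#'
#' Deterministic forward model for one particle. For each laser line the
#' emissive loads are excited according to `E`; excitations then cascade
#' through the ordered FRET pairs (the transferred fraction saturates with
#' the acceptor's emissive load), conserving the per-laser excitation total;
#' finally each dye's post-transfer excitations emit into the detection
#' windows according to its quantum yield and `W`, scaled by the gain.
#'
#' @param m Emissive loads, one per dye (from [apply_quenching()]).
#' @param model An [optical_model()].
#' @return Named numeric vector of expected photons, one per channel.
#' @export
expected_channel_signal <- function(m, model) {
  if (length(m) != nrow(model$dyes)) stop("one emissive load per dye required")
  if (any(m < 0)) stop("emissive loads must be non-negative")
  n_las <- length(model$lasers)
  # post-FRET excitations per dye, one column per laser
  e <- vapply(seq_len(n_las), function(l) {
    fret_redistribute(model$E[, l] * m, m, model)
  }, numeric(length(m)))
  S <- vapply(seq_len(nrow(model$channels)), function(c) {
    model$gain * sum(model$yield * e[, model$ch_laser[c]] *
                       model$W[, model$ch_window[c]])
  }, numeric(1))
  names(S) <- model$channels$name
  S
}

#' Diffraction-limited PSF width for a finite-size emitter
#'
#' Lateral full width at half maximum of the image of a particle of diameter
#' `d`: the diffraction-limited width `0.51 * lambda / NA` combined in
#' quadrature with the physical size. At 552 nm excitation through a 1.4 NA
#' objective a point emitter gives ~201 nm; a 100 nm particle ~225 nm.
#'
#' @param lambda Excitation wavelength (nm).
#' @param na Numerical aperture.
#' @param d Particle diameter (nm), 0 for a point source.
#' @return FWHM in nm (`psf_fwhm`) or the Gaussian sigma FWHM/2.355
#'   (`psf_sigma`).
#' @export
psf_fwhm <- function(lambda, na = 1.4, d = 0) {
  sqrt((0.51 * lambda / na)^2 + d^2)
}

#' @rdname psf_fwhm
#' @export
psf_sigma <- function(lambda, na = 1.4, d = 0) {
  psf_fwhm(lambda, na, d) / 2.355
}
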