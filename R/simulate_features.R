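# Vectorized forward model: expected signals for a matrix of emissive loads
# (rows = particles, cols = dyes). Same math as expected_channel_signal().
expected_signal_matrix <- function(m, model) {
  n <- nrow(m)
  nm <- model$dyes$name
  n_las <- length(model$lasers)
  e <- vector("list", n_las)
  for (l in seq_len(n_las)) {
    x <- sweep(m, 2L, model$E[, l], `*`)
    fp <- model$fret_pairs
    if (nrow(fp) > 0L) {
      for (k in seq_len(nrow(fp))) {
        di <- match(fp$donor[k], nm); ai <- match(fp$acceptor[k], nm)
        f <- m[, ai] / (m[, ai] + fp$K[k])
        t <- x[, di] * f
        x[, di] <- x[, di] - t
        x[, ai] <- x[, ai] + t
      }
    }
    e[[l]] <- x
  }
  S <- matrix(0, n, nrow(model$channels),
              dimnames = list(NULL, model$channels$name))
  for (c in seq_len(nrow(model$channels))) {
    S[, c] <- model$gain *
      (e[[model$ch_laser[c]]] %*% (model$yield * model$W[, model$ch_window[c]]))
  }
  S
}

#' Simulate per-particle fingerprint tables directly
#'
#' A feature-level shortcut through the image pipeline: particles are drawn
#' from the same ground-truth model as [generate_dataset()], and the
#' detection/fit stage is emulated statistically instead of rendering and
#' re-fitting pixels. Per channel the measured integrated intensity is the
#' expected signal plus shot noise and fit noise from the local background
#' (variance `S + 4*pi*sigma_px^2*(bg + read^2)`); the fitted width gets the
#' corresponding relative error; and a spot is recorded only when its peak
#' amplitude clears `detect_k` times the background noise floor, otherwise
#' the channel carries the absent-spot sentinel (intensity 0, sigma 0) —
#' exactly how the image reader encodes unmatched channels. The merged
#' channel sums all six planes before the same treatment. Agreement with the
#' full render-and-fit pipeline is checked in the package tests.
#'
#' @param codes A `barcode_table` (or subset).
#' @param particles_per_class Particles per barcode.
#' @param het A [het_params()].
#' @param model An [optical_model()].
#' @param seed Integer seed.
#' @param detect_k Detection threshold in background-noise sigmas.
#' @param dim,pixel_size_nm FOV geometry used for coordinates.
#' @return A fingerprint data.frame in the standard schema: `particle_id`,
#'   `fov`, `x_nm`, `y_nm`, `label`, `I_alpha..I_zeta`, `I_merged`,
#'   `S_alpha..S_zeta`, `S_merged` (intensities in photons, sigmas in nm).
#' @export
simulate_fingerprints <- function(codes, particles_per_class,
                                  het = het_params(),
                                  model = optical_model(), seed = 1L,
                                  detect_k = 5, dim = 504L,
                                  pixel_size_nm = 92.45) {
  set.seed(seed)
  conc <- barcode_concentrations(codes)
  n <- nrow(codes) * particles_per_class
  label <- rep(codes$id, each = particles_per_class)
  cmat <- conc[match(label, codes$id), , drop = FALSE]

  # ground truth: radius, loads, emissive loads, expected signals
  if (het$radius_cv > 0) {
    sdlog <- sqrt(log(1 + het$radius_cv^2))
    radius <- stats::rlnorm(n, log(het$radius_mean) - sdlog^2 / 2, sdlog)
  } else radius <- rep(het$radius_mean, n)
  eta <- matrix(stats::rnorm(n * ncol(cmat), 0, het$encapsulation_sd),
                n, ncol(cmat))
  loads <- cmat * (radius / het$radius_mean)^3 * exp(eta)
  loads[cmat == 0] <- 0
  m <- apply_quenching(loads, model$Q)
  S <- expected_signal_matrix(m, model)

  chn <- model$channels$name
  nch <- length(chn)
  bgv <- model$background_rate + model$read_noise_sd^2  # per-px noise variance
  I <- matrix(0, n, nch); SG <- matrix(0, n, nch)
  sig_true <- matrix(0, n, nch)
  for (c in seq_len(nch)) {
    sig_nm <- psf_sigma(model$channels$laser_nm[c], model$numerical_aperture,
                        2 * radius)
    sig_true[, c] <- sig_nm
    s_px <- sig_nm / pixel_size_nm
    v_fit <- 4 * pi * s_px^2 * bgv
    I_meas <- S[, c] + stats::rnorm(n) * sqrt(pmax(S[, c], 0) + v_fit)
    amp <- I_meas / (2 * pi * s_px^2)
    det <- amp > detect_k * sqrt(bgv)
    rel <- pmin(0.5, sqrt((1 + v_fit / pmax(S[, c], 1)) / pmax(S[, c], 1)))
    s_meas <- sig_nm * (1 + stats::rnorm(n) * rel)
    I[det, c] <- I_meas[det]
    SG[det, c] <- s_meas[det]
  }
  # merged channel: sum of planes -> 6x background, width ~ signal-weighted
  S_m <- rowSums(S)
  sig_m <- rowSums(S * sig_true) / pmax(S_m, .Machine$double.eps)
  s_px_m <- sig_m / pixel_size_nm
  v_fit_m <- 4 * pi * s_px_m^2 * nch * bgv
  I_mg <- S_m + stats::rnorm(n) * sqrt(pmax(S_m, 0) + v_fit_m)
  S_mg <- sig_m * (1 + stats::rnorm(n) *
                     pmin(0.5, sqrt((1 + v_fit_m / pmax(S_m, 1)) / pmax(S_m, 1))))
  det_m <- I_mg / (2 * pi * s_px_m^2) > detect_k * sqrt(nch * bgv)

  out <- data.frame(
    particle_id = seq_len(n), fov = 1L,
    x_nm = stats::runif(n, 0, dim * pixel_size_nm),
    y_nm = stats::runif(n, 0, dim * pixel_size_nm),
    label = label
  )
  for (c in seq_len(nch)) out[[paste0("I_", chn[c])]] <- I[, c]
  out$I_merged <- I_mg
  for (c in seq_len(nch)) out[[paste0("S_", chn[c])]] <- SG[, c]
  out$S_merged <- S_mg
  out <- out[det_m, , drop = FALSE]  # the reference channel defines records
  out$particle_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Names of the 14 fingerprint features
#'
#' Integrated intensity and fitted sigma for the six channels and the merged
#' reference channel, in the canonical column order.
#'
#' @param channels Channel names, default the six-channel scheme.
#' @return Character vector of length 14.
#' @export
feature_columns <- function(channels = default_channels()$name) {
  c(paste0("I_", channels), "I_merged", paste0("S_", channels), "S_merged")
}
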