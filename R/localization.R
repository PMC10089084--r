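#' Merge all channels into the reference image
#'
#' Pixelwise sum of the channel planes in a wider accumulator (no 16-bit
#' clipping). Summation rather than maximum preserves linearity, so the
#' merged integrated intensity is itself a meaningful feature.
#'
#' @param fov A `fov_image`.
#' @return Numeric matrix.
#' @export
merge_channels <- function(fov) {
  if (length(dim(fov$pixels)) != 3L) stop("fov must carry a 3-D pixel array")
  rowSums(fov$pixels, dims = 2L)
}

# separable Gaussian blur with edge replication
gaussian_blur <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, 0, sigma)
  k <- k / sum(k)
  n <- nrow(img); m <- ncol(img)
  v <- stats::filter(img[c(rep(1L, r), seq_len(n), rep(n, r)), , drop = FALSE],
                     k, sides = 2)
  v <- v[(r + 1):(r + n), , drop = FALSE]
  h <- stats::filter(t(v)[c(rep(1L, r), seq_len(m), rep(m, r)), , drop = FALSE],
                     k, sides = 2)
  t(h[(r + 1):(r + m), , drop = FALSE])
}

#' Spot detection parameters
#' @param sigma_px Band-pass scale: difference of Gaussians at `sigma_px`
#'   and `2 * sigma_px`, matched to the PSF width in pixels.
#' @param threshold_k Keep maxima whose filtered value exceeds `threshold_k`
#'   times the robust noise level (1.4826 x MAD of the filtered image).
#' @param min_sep_px Maxima closer than this collapse to the brighter one.
#' @return List of class `detect_params`.
#' @export
detect_params <- function(sigma_px = 1.1, threshold_k = 5, min_sep_px = 3) {
  structure(list(sigma_px = sigma_px, threshold_k = threshold_k,
                 min_sep_px = min_sep_px), class = "detect_params")
}

#' Detect candidate spots in one image plane
#'
#' Difference-of-Gaussians band-pass, 3x3 local maxima, robust-noise
#' thresholding and brightness-ranked suppression of near-duplicates — the
#' standard single-molecule detection pipeline.
#'
#' @param image Numeric matrix.
#' @param params A [detect_params()].
#' @return Data.frame with integer pixel positions `x_px`, `y_px` (column,
#'   row; 1-based) and the filtered `value`, brightest first. May be empty.
#' @export
detect_spots <- function(image, params = detect_params()) {
  f <- gaussian_blur(image, params$sigma_px) -
    gaussian_blur(image, 2 * params$sigma_px)
  noise <- stats::mad(f)                      # 1.4826 * MAD
  thr <- params$threshold_k * noise
  n <- nrow(f); m <- ncol(f)
  if (n < 3L || m < 3L) return(data.frame(x_px = integer(), y_px = integer(), value = numeric()))
  ctr <- f[2:(n - 1), 2:(m - 1)]
  is_max <- ctr > thr
  for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0L && dy == 0L) next
    nb <- f[(2 + dy):(n - 1 + dy), (2 + dx):(m - 1 + dx)]
    # strict on the lexicographically earlier neighbour, >= on the rest,
    # so a flat-topped spot yields exactly one maximum
    is_max <- is_max & if (dy < 0L || (dy == 0L && dx < 0L)) ctr > nb else ctr >= nb
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(data.frame(x_px = integer(), y_px = integer(), value = numeric()))
  out <- data.frame(x_px = idx[, 2] + 1L, y_px = idx[, 1] + 1L,
                    value = ctr[is_max])
  out <- out[order(-out$value), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    if (i < nrow(out)) {
      later <- (i + 1):nrow(out)
      d2 <- (out$x_px[later] - out$x_px[i])^2 + (out$y_px[later] - out$y_px[i])^2
      keep[later][d2 < params$min_sep_px^2] <- FALSE
    }
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit a 2-D Gaussian to one candidate spot
#'
#' Unweighted least squares of the integrated symmetric 2-D Gaussian
#' `N * [F(x + 1/2) - F(x - 1/2)] * [F(y + 1/2) - F(y - 1/2)] + b` (with `F`
#' the Gaussian CDF centered at `(x0, y0)` with width `sigma`), i.e. the
#' Gaussian volume integrated over each pixel — the integrated-Gaussian
#' least-squares estimator standard in single-molecule localization, which
#' is free of pixelation bias. The window is square around the candidate,
#' in pixel units; results are converted to nm using the pixel-center
#' convention (pixel `(i, j)` is centered at `(i - 0.5) * pixel_size`). `fit_ok` is FALSE when the solver
#' fails, the width leaves `(0.3, 3)` times the nominal PSF sigma, or the
#' center leaves the window.
#'
#' @param image Numeric matrix.
#' @param x_px,y_px Candidate pixel (column, row; 1-based).
#' @param half Half-width of the fit window in px (window is
#'   `2 * half + 1` squared; default 3 gives 7x7).
#' @param pixel_size_nm Pixel pitch.
#' @param sigma0_px Nominal PSF sigma (start value and sanity band).
#' @return One-row data.frame: `x_nm`, `y_nm`, `intensity` (background-
#'   subtracted Gaussian volume, counts), `sigma_nm`, `background`, `fit_ok`.
#' @export
fit_gaussian <- function(image, x_px, y_px, half = 3L,
                         pixel_size_nm = 92.45, sigma0_px = 1.1) {
  n <- nrow(image); m <- ncol(image)
  if (x_px - half < 1L || x_px + half > m || y_px - half < 1L || y_px + half > n) {
    stop("fit window extends outside the image")
  }
  xs <- (x_px - half):(x_px + half)
  ys <- (y_px - half):(y_px + half)
  z <- image[ys, xs]
  d <- data.frame(
    x = rep(xs - 0.5, each = length(ys)),
    y = rep(ys - 0.5, times = length(xs)),
    z = as.vector(z)
  )
  b0 <- min(d$z)
  N0 <- max(sum(d$z - b0), 1)
  start <- list(N = N0, x0 = x_px - 0.5, y0 = y_px - 0.5,
                sigma = sigma0_px, b = b0)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ N * (pnorm(x + 0.5, x0, sigma) - pnorm(x - 0.5, x0, sigma)) *
        (pnorm(y + 0.5, y0, sigma) - pnorm(y - 0.5, y0, sigma)) + b,
      data = d, start = start,
      lower = c(N = 0, x0 = min(d$x) - 1, y0 = min(d$y) - 1,
                sigma = 0.05, b = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  bad <- function() data.frame(
    x_nm = (x_px - 0.5) * pixel_size_nm, y_nm = (y_px - 0.5) * pixel_size_nm,
    intensity = 0, sigma_nm = 0, background = b0, fit_ok = FALSE)
  if (is.null(fit)) return(bad())
  p <- as.list(stats::coef(fit))
  ok <- p$sigma > 0.3 * sigma0_px && p$sigma < 3 * sigma0_px &&
    p$x0 >= min(d$x) && p$x0 <= max(d$x) &&
    p$y0 >= min(d$y) && p$y0 <= max(d$y) && p$N >= 0
  if (!ok) return(bad())
  data.frame(
    x_nm = p$x0 * pixel_size_nm, y_nm = p$y0 * pixel_size_nm,
    intensity = p$N, sigma_nm = p$sigma * pixel_size_nm,
    background = p$b, fit_ok = TRUE)
}

# detect + fit one plane; returns only fit_ok localizations
localize_plane <- function(image, params = detect_params(),
                           pixel_size_nm = 92.45, half = 3L) {
  cand <- detect_spots(image, params)
  rows <- list()
  for (i in seq_len(nrow(cand))) {
    if (cand$x_px[i] - half < 1L || cand$x_px[i] + half > ncol(image) ||
        cand$y_px[i] - half < 1L || cand$y_px[i] + half > nrow(image)) next
    loc <- fit_gaussian(image, cand$x_px[i], cand$y_px[i], half,
                        pixel_size_nm, params$sigma_px)
    if (loc$fit_ok) rows[[length(rows) + 1L]] <- loc
  }
  if (!length(rows)) {
    return(data.frame(x_nm = numeric(), y_nm = numeric(),
                      intensity = numeric(), sigma_nm = numeric(),
                      background = numeric(), fit_ok = logical()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Match channel localizations to the merged-channel reference
#'
#' Each reference (merged-channel) localization becomes one particle record.
#' Per channel, the nearest unused channel localization within `radius_nm`
#' is assigned, greedily in reference order (ties broken by lower
#' localization index). Channels with no match carry the absent-spot
#' sentinel: intensity 0, sigma 0. Merged intensity/sigma always come from
#' the reference fit.
#'
#' @param reference Data.frame of merged-channel localizations
#'   (`x_nm`, `y_nm`, `intensity`, `sigma_nm`).
#' @param per_channel Named list of per-channel localization data.frames.
#' @param radius_nm Matching radius, default 120 nm.
#' @return Fingerprint data.frame: `particle_id`, `x_nm`, `y_nm`,
#'   `I_<channel>`, `I_merged`, `S_<channel>`, `S_merged`.
#' @export
match_localizations <- function(reference, per_channel, radius_nm = 120) {
  if (radius_nm <= 0) stop("radius_nm must be positive")
  chn <- names(per_channel)
  n <- nrow(reference)
  I <- matrix(0, n, length(chn)); SG <- matrix(0, n, length(chn))
  for (c in seq_along(chn)) {
    locs <- per_channel[[c]]
    used <- rep(FALSE, nrow(locs))
    for (i in seq_len(n)) {
      if (nrow(locs) == 0L) break
      d2 <- (locs$x_nm - reference$x_nm[i])^2 +
        (locs$y_nm - reference$y_nm[i])^2
      d2[used] <- Inf
      j <- which.min(d2)                      # ties -> lowest index
      if (length(j) && d2[j] <= radius_nm^2) {
        I[i, c] <- locs$intensity[j]
        SG[i, c] <- locs$sigma_nm[j]
        used[j] <- TRUE
      }
    }
  }
  out <- data.frame(particle_id = seq_len(n),
                    x_nm = reference$x_nm, y_nm = reference$y_nm)
  for (c in seq_along(chn)) out[[paste0("I_", chn[c])]] <- I[, c]
  out$I_merged <- reference$intensity
  for (c in seq_along(chn)) out[[paste0("S_", chn[c])]] <- SG[, c]
  out$S_merged <- reference$sigma_nm
  out
}

#' Build the fingerprint table from fields of view
#'
#' Runs the full reading pipeline per FOV: merge the channels, detect and
#' fit on the merged reference, detect and fit per channel, match by
#' proximity, and concatenate across FOVs with globally unique particle
#' ids. When a ground-truth table is supplied (simulator output), a `label`
#' column is attached by nearest truth particle within the matching radius.
#'
#' @param fovs List of `fov_image` objects (or a single one).
#' @param params A [detect_params()].
#' @param truth Optional truth data.frame with `fov`, `x_nm`, `y_nm`,
#'   `barcode_id`.
#' @param radius_nm Matching radius (channels and truth), default 120 nm.
#' @param half Fit window half-width (px).
#' @return Fingerprint data.frame in the standard schema (see
#'   [simulate_fingerprints()]); `label` is NA where no truth matches.
#' @export
build_feature_table <- function(fovs, params = detect_params(), truth = NULL,
                                radius_nm = 120, half = 3L) {
  if (inherits(fovs, "fov_image")) fovs <- list(fovs)
  chn_all <- if (length(fovs)) fovs[[1]]$channels else default_channels()$name
  empty <- data.frame(particle_id = integer(), fov = integer(),
                      x_nm = numeric(), y_nm = numeric(),
                      label = integer())
  for (cn in feature_columns(chn_all)) empty[[cn]] <- numeric()
  if (!length(fovs)) return(empty)
  tabs <- list()
  for (f in seq_along(fovs)) {
    fov <- fovs[[f]]
    px <- fov$pixel_size_nm
    merged <- merge_channels(fov)
    ref <- localize_plane(merged, params, px, half)
    if (nrow(ref) == 0L) next
    per_channel <- lapply(seq_along(fov$channels), function(c) {
      localize_plane(fov$pixels[, , c], params, px, half)
    })
    names(per_channel) <- fov$channels
    tab <- match_localizations(ref, per_channel, radius_nm)
    tab$fov <- f
    if (!is.null(truth)) {
      tr <- truth[truth$fov == f, , drop = FALSE]
      tab$label <- vapply(seq_len(nrow(tab)), function(i) {
        if (!nrow(tr)) return(NA_integer_)
        d2 <- (tr$x_nm - tab$x_nm[i])^2 + (tr$y_nm - tab$y_nm[i])^2
        j <- which.min(d2)
        if (d2[j] <= radius_nm^2) as.integer(tr$barcode_id[j]) else NA_integer_
      }, integer(1))
    } else {
      tab$label <- NA_integer_
    }
    tabs[[length(tabs) + 1L]] <- tab
  }
  if (!length(tabs)) return(empty)
  out <- do.call(rbind, tabs)
  out$particle_id <- seq_len(nrow(out))
  cols <- c("particle_id", "fov", "x_nm", "y_nm", "label",
            feature_columns(chn_all))
  out[, cols]
}

#' Write / read a fingerprint table as CSV
#' @param table Fingerprint data.frame.
#' @param path File path.
#' @return `path` (write) or the table (read).
#' @export
write_fingerprints <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(path) {
  utils::read.csv(path)
}
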