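test_that("particle sampling follows the r^3 load law and zero levels", {
  model <- optical_model()
  het0 <- het_params(50, 0, 0)
  p <- sample_particle(c(0, 0, 10), het0, model)
  expect_equal(unname(p$loads), c(0, 0, 10))
  # doubling the radius at zero heterogeneity scales nonzero loads by 8
  p1 <- sample_particle(c(5, 0, 10), het0, model)
  p2 <- sample_particle(c(5, 0, 10), het0, model, radius = 100)
  expect_equal(unname(p2$loads[c(1, 3)] / p1$loads[c(1, 3)]), c(8, 8))
  expect_equal(p2$loads[[2]], 0)
  # radius is exactly the mean when cv = 0
  expect_equal(p1$radius, 50)
  expect_error(het_params(-1, 0, 0), "radius_mean")
})

test_that("population load spread matches an independent Monte-Carlo oracle", {
  # oracle: compose the radius lognormal (cv 0.1 -> volume factor) with the
  # encapsulation lognormal directly, without the package's sampler
  set.seed(101)
  n <- 10000
  cv_r <- 0.1; enc_sd <- 0.25
  sdlog <- sqrt(log(1 + cv_r^2))
  r <- rlnorm(n, log(50) - sdlog^2 / 2, sdlog)
  a_oracle <- 10 * (r / 50)^3 * exp(rnorm(n, 0, enc_sd))
  cv_oracle <- sd(a_oracle) / mean(a_oracle)

  model <- optical_model()
  het <- het_params(50, cv_r, enc_sd)
  set.seed(202)
  a_pkg <- replicate(n, sample_particle(c(0, 0, 10), het, model)$loads[3])
  cv_pkg <- sd(a_pkg) / mean(a_pkg)
  expect_lt(abs(cv_pkg - cv_oracle) / cv_oracle, 0.08)
  # closed form for the composed lognormal as a second, analytic oracle
  cv_closed <- sqrt(exp(9 * sdlog^2 + enc_sd^2) - 1)
  expect_lt(abs(cv_pkg - cv_closed) / cv_closed, 0.08)
})

test_that("quenching saturates toward Q and is monotone", {
  expect_equal(apply_quenching(0, 50), 0)
  expect_equal(apply_quenching(50, 50), 25)
  expect_lt(abs(apply_quenching(1e6 * 50, 50) - 50) / 50, 1e-5)
  a <- seq(0, 200, by = 0.5)
  m <- apply_quenching(a, 50)
  expect_true(all(diff(m) > 0))
  expect_true(all(m <= 50))
  expect_error(apply_quenching(-1, 50), "non-negative")
})

test_that("bulk-like quench curve rises then flattens over 0.1-100 uM", {
  model <- optical_model()
  conc <- c(0.1, 1, 5, 10, 25, 50, 100)
  main <- vapply(conc, function(cc) {
    m <- apply_quenching(c(cc, 0, 0), model$Q)
    expected_channel_signal(m, model)[["delta"]]
  }, numeric(1))
  expect_true(all(diff(main) > 0))
  # relative growth per decade collapses at the top of the range
  expect_lt((main[7] - main[6]) / main[6], 0.5 * (main[2] - main[1]) / main[1])
})

test_that("channel signals behave like the optical scheme", {
  model <- optical_model()
  expect_equal(unname(expected_channel_signal(c(0, 0, 0), model)), rep(0, 6))
  # diagonal optics: DiD-only emits only in alpha
  diag_model <- model
  diag_model$E <- diag(3); diag_model$W <- diag(3)
  diag_model$fret_pairs <- diag_model$fret_pairs[0, ]
  diag_model$yield <- rep(1, 3)
  S <- expected_channel_signal(c(0, 0, 10), diag_model)
  expect_gt(S[["alpha"]], 0)
  expect_equal(unname(S[c("beta", "gamma", "delta", "epsilon", "zeta")]),
               rep(0, 5))
  expect_error(expected_channel_signal(c(1, 2), model), "per dye")
})

test_that("FRET conserves per-laser excitation and boosts epsilon for DiO+DiI", {
  model <- optical_model()
  set.seed(99)
  for (i in 1:1000) {
    m <- runif(3, 0, 20)
    K <- runif(3, 1, 100)
    fuzz <- model
    fuzz$fret_pairs$K <- K
    for (l in seq_along(fuzz$lasers)) {
      x <- fuzz$E[, l] * m
      e <- nanobarcoder:::fret_redistribute(x, m, fuzz)
      expect_equal(sum(e), sum(x), tolerance = 1e-12)
      expect_true(all(e >= -1e-12))
    }
  }
  # DiO + DiI: FRET routes 488-excited DiO excitations into the DiI window
  m_oi <- apply_quenching(c(10, 10, 0), model$Q)
  no_fret <- model
  no_fret$fret_pairs <- no_fret$fret_pairs[0, ]
  S_fret <- expected_channel_signal(m_oi, model)
  S_plain <- expected_channel_signal(m_oi, no_fret)
  expect_gt(S_fret[["epsilon"]], S_plain[["epsilon"]])
})

test_that("signals without FRET are monotone in every emissive load", {
  model <- optical_model()
  model$fret_pairs <- model$fret_pairs[0, ]
  set.seed(7)
  for (i in 1:50) {
    m0 <- runif(3, 0, 10)
    S0 <- expected_channel_signal(m0, model)
    for (d in 1:3) {
      m1 <- m0; m1[d] <- m1[d] + runif(1, 0.1, 5)
      expect_true(all(expected_channel_signal(m1, model) >= S0 - 1e-9))
    }
  }
})

test_that("PSF width combines diffraction and particle size", {
  expect_equal(psf_fwhm(552, 1.4, 0), 0.51 * 552 / 1.4)
  expect_equal(round(psf_fwhm(552, 1.4, 0)), 201)
  expect_equal(round(psf_fwhm(552, 1.4, 100)), 225)
  expect_equal(psf_sigma(552, 1.4, 100), psf_fwhm(552, 1.4, 100) / 2.355)
})

test_that("noiseless rendering integrates to the expected channel signal", {
  model <- optical_model()
  p <- data.frame(x_nm = 5000, y_nm = 5500, radius_nm = 50)
  sig <- c(2000, 1500, 800, 3000, 400, 120)
  for (i in seq_along(model$channels$name)) {
    p[[paste0("sig_", model$channels$name[i])]] <- sig[i]
  }
  fov <- render_fov(p, model, noise = FALSE, dim = 120)
  for (c in 1:6) {
    img <- fov$pixels[, , c]
    cx <- round(5000 / 92.45); cy <- round(5500 / 92.45)
    patch <- img[(cy - 7):(cy + 7), (cx - 7):(cx + 7)]
    got <- sum(patch) - 225 * (model$background_rate + model$offset)
    expect_lt(abs(got - sig[c]) / sig[c], 0.005)
  }
})

test_that("empty noiseless FOV is flat at offset + background", {
  model <- optical_model()
  p <- data.frame(x_nm = numeric(), y_nm = numeric(), radius_nm = numeric())
  fov <- render_fov(p, model, noise = FALSE, dim = 32)
  expect_true(all(fov$pixels == model$offset + model$background_rate))
})

test_that("dataset generation is deterministic and respects counts", {
  codes <- enumerate_barcodes()[1:3, ]
  ds1 <- generate_dataset(codes, 4, fovs = 2, seed = 5, noise = TRUE,
                          dim = 128, min_sep_nm = 800)
  ds2 <- generate_dataset(codes, 4, fovs = 2, seed = 5, noise = TRUE,
                          dim = 128, min_sep_nm = 800)
  expect_identical(ds1$truth, ds2$truth)
  expect_identical(ds1$images[[1]]$pixels, ds2$images[[1]]$pixels)
  expect_equal(nrow(ds1$truth), 12L)
  expect_equal(unname(table(ds1$truth$barcode_id)), rep(4L, 3), ignore_attr = TRUE)
  # pairwise separation honored within each FOV
  for (f in 1:2) {
    tr <- ds1$truth[ds1$truth$fov == f, ]
    dmat <- as.matrix(dist(tr[, c("x_nm", "y_nm")]))
    expect_true(all(dmat[upper.tri(dmat)] >= 800))
  }
  # unsatisfiable density errors out
  expect_error(
    generate_dataset(codes, 40, fovs = 1, seed = 5, dim = 48,
                     min_sep_nm = 4000),
    "could not place")
})

test_that("FOV TIFF round-trips pixels and metadata", {
  codes <- enumerate_barcodes()[2, , drop = FALSE]
  ds <- generate_dataset(codes, 2, fovs = 1, seed = 3, noise = TRUE,
                         dim = 64, min_sep_nm = 500)
  path <- withr::local_tempfile(fileext = ".tif")
  write_fov_tiff(ds$images[[1]], path)
  back <- read_fov_tiff(path)
  expect_equal(back$pixels, ds$images[[1]]$pixels)
  expect_equal(back$channels, ds$images[[1]]$channels)
  expect_equal(back$pixel_size_nm, 92.45)
})
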