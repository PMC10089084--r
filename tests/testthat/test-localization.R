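test_that("channel merging is a pixelwise sum", {
  tf <- make_test_fov(n_particles = 2, dim = 96, noise = FALSE)
  merged <- merge_channels(tf$fov)
  expect_equal(merged, apply(tf$fov$pixels, c(1, 2), sum))
  expect_equal(sum(merged), sum(tf$fov$pixels))
  zero <- tf$fov
  zero$pixels[] <- 0
  expect_true(all(merge_channels(zero) == 0))
})

test_that("spot detection finds isolated PSFs and nothing on flat images", {
  flat <- matrix(100, 64, 64)
  expect_equal(nrow(detect_spots(flat)), 0L)

  model <- optical_model()
  p <- data.frame(x_nm = c(2000, 2000 + 10 * 92.45), y_nm = c(2000, 2000),
                  radius_nm = 50)
  for (ch in model$channels$name) p[[paste0("sig_", ch)]] <- 2500
  set.seed(31)
  fov <- render_fov(p, model, noise = TRUE, dim = 64)
  cand <- detect_spots(fov$pixels[, , 4])
  expect_equal(nrow(cand), 2L)
  # both within 1 px of the truth
  for (i in 1:2) {
    d <- sqrt((cand$x_px - p$x_nm[i] / 92.45)^2 +
                (cand$y_px - p$y_nm[i] / 92.45)^2)
    expect_lt(min(d), 1.5)
  }
})

test_that("detection recall is >= 99% with <= 1 false positive per FOV", {
  model <- optical_model()
  codes <- enumerate_barcodes()[c(2, 4, 6), ]   # high-level singles, SNR ~ 20
  set.seed(77)
  ds <- generate_dataset(codes, 10, fovs = 1, het = het_params(50, 0, 0),
                         model = model, seed = 77, noise = TRUE, dim = 256,
                         min_sep_nm = 1500)
  merged <- merge_channels(ds$images[[1]])
  cand <- detect_spots(merged)
  truth <- ds$truth
  d2 <- outer(cand$x_px * 92.45, truth$x_nm, `-`)^2 +
    outer(cand$y_px * 92.45, truth$y_nm, `-`)^2
  hit <- sqrt(apply(d2, 2, min)) < 2 * 92.45          # truth with a candidate
  fp <- sqrt(apply(d2, 1, min)) > 2 * 92.45           # candidate with no truth
  expect_gte(mean(hit), 0.99)
  expect_lte(sum(fp), 1)
})

test_that("noiseless Gaussian fits recover truth almost exactly", {
  model <- optical_model()
  # off-center subpixel position, arbitrary signal
  p <- data.frame(x_nm = 3000.3, y_nm = 3210.7, radius_nm = 50)
  for (ch in model$channels$name) p[[paste0("sig_", ch)]] <- 10000
  fov <- render_fov(p, model, noise = FALSE, dim = 72)
  img <- fov$pixels[, , 2]                            # beta, lambda 552
  cand <- detect_spots(img)
  expect_equal(nrow(cand), 1L)
  loc <- fit_gaussian(img, cand$x_px[1], cand$y_px[1])
  expect_true(loc$fit_ok)
  sigma_true <- psf_sigma(552, 1.4, 100)
  expect_lt(abs(loc$intensity - 10000) / 10000, 0.01)
  expect_lt(abs(loc$sigma_nm - sigma_true) / sigma_true, 0.02)
  expect_lt(abs(loc$x_nm - 3000.3) / 92.45, 0.05)
  expect_lt(abs(loc$y_nm - 3210.7) / 92.45, 0.05)
  # a PSF rendered at an exact pixel center is recovered at that center
  pc <- data.frame(x_nm = 30.5 * 92.45, y_nm = 40.5 * 92.45, radius_nm = 50)
  for (ch in model$channels$name) pc[[paste0("sig_", ch)]] <- 10000
  fovc <- render_fov(pc, model, noise = FALSE, dim = 72)
  locc <- fit_gaussian(fovc$pixels[, , 2], 31L, 41L)
  expect_equal(locc$x_nm / 92.45, 30.5, tolerance = 1e-6)
  expect_equal(locc$y_nm / 92.45, 40.5, tolerance = 1e-6)
})

test_that("degenerate fits are flagged rather than returned", {
  flat <- matrix(100, 32, 32)
  loc <- fit_gaussian(flat, 16L, 16L)
  expect_false(loc$fit_ok)
  expect_equal(loc$intensity, 0)
  expect_equal(loc$sigma_nm, 0)
  expect_error(fit_gaussian(flat, 2L, 2L), "outside")
})

test_that("greedy matching equals the brute-force oracle on random instances", {
  set.seed(404)
  for (rep in 1:200) {
    n_ref <- sample(1:30, 1)
    n_ch <- sample(0:30, 1)
    span <- 3000
    ref <- data.frame(x_nm = runif(n_ref, 0, span),
                      y_nm = runif(n_ref, 0, span),
                      intensity = runif(n_ref, 100, 1000),
                      sigma_nm = runif(n_ref, 50, 150))
    ch <- data.frame(x_nm = runif(n_ch, 0, span),
                     y_nm = runif(n_ch, 0, span),
                     intensity = runif(n_ch, 100, 1000),
                     sigma_nm = runif(n_ch, 50, 150),
                     background = rep(0, n_ch),
                     fit_ok = rep(TRUE, n_ch))
    radius <- runif(1, 50, 600)
    rec <- match_localizations(ref, list(alpha = ch), radius)
    oracle <- brute_force_match(ref, ch, radius)
    got_I <- rec$I_alpha
    want_I <- ifelse(is.na(oracle), 0, ch$intensity[oracle])
    expect_equal(got_I, unname(want_I))
  }
})

test_that("matching is radius-monotone and keeps the nearest candidate", {
  ref <- data.frame(x_nm = 1000, y_nm = 1000, intensity = 500, sigma_nm = 90)
  ch <- data.frame(x_nm = c(1050, 1100), y_nm = 1000,
                   intensity = c(11, 22), sigma_nm = c(80, 85))
  rec <- match_localizations(ref, list(alpha = ch), 120)
  expect_equal(rec$I_alpha, 11)                 # 50 nm beats 100 nm
  # empty channel lists -> sentinels
  rec0 <- match_localizations(ref, list(alpha = ch[0, ]), 120)
  expect_equal(rec0$I_alpha, 0)
  expect_equal(rec0$S_alpha, 0)
  expect_equal(rec0$I_merged, 500)
  # enlarging the radius never decreases matched slots
  set.seed(11)
  ref2 <- data.frame(x_nm = runif(15, 0, 2000), y_nm = runif(15, 0, 2000),
                     intensity = 1, sigma_nm = 1)
  ch2 <- data.frame(x_nm = runif(15, 0, 2000), y_nm = runif(15, 0, 2000),
                    intensity = 1, sigma_nm = 1)
  matched <- vapply(c(50, 100, 200, 400, 800), function(r) {
    sum(match_localizations(ref2, list(a = ch2), r)$I_a > 0)
  }, numeric(1))
  expect_true(all(diff(matched) >= 0))
})

test_that("feature table round-trips simulated FOVs with correct labels", {
  model <- optical_model()
  codes <- enumerate_barcodes()[c(2, 4, 6, 26), ]
  ds <- generate_dataset(codes, 6, fovs = 1, het = het_params(50, 0.05, 0.1),
                         model = model, seed = 15, noise = TRUE, dim = 256,
                         min_sep_nm = 1500)
  tab <- build_feature_table(ds$images, truth = ds$truth)
  expect_equal(names(tab),
               c("particle_id", "fov", "x_nm", "y_nm", "label",
                 feature_columns()))
  # nearly all particles found and labeled correctly
  expect_gte(nrow(tab), 0.95 * nrow(ds$truth))
  expect_gte(mean(!is.na(tab$label)), 0.95)
  # labels agree with the nearest truth particle
  for (i in seq_len(nrow(tab))) {
    d2 <- (ds$truth$x_nm - tab$x_nm[i])^2 + (ds$truth$y_nm - tab$y_nm[i])^2
    expect_equal(tab$label[i], ds$truth$barcode_id[which.min(d2)])
  }
  # no table from no FOVs, but schema preserved
  empty <- build_feature_table(list())
  expect_equal(nrow(empty), 0L)
  expect_true(all(feature_columns() %in% names(empty)))
})

test_that("fitted intensities track expected signals with slope ~1", {
  model <- optical_model()
  codes <- enumerate_barcodes()[c(2, 4, 6, 12, 26), ]
  ds <- generate_dataset(codes, 5, fovs = 1, het = het_params(50, 0.08, 0.2),
                         model = model, seed = 21, noise = FALSE, dim = 256,
                         min_sep_nm = 1800)
  tab <- build_feature_table(ds$images, truth = ds$truth)
  # align fitted per-channel intensity with the truth expectation
  got <- c(); want <- c()
  for (i in seq_len(nrow(tab))) {
    j <- which.min((ds$truth$x_nm - tab$x_nm[i])^2 +
                     (ds$truth$y_nm - tab$y_nm[i])^2)
    for (ch in model$channels$name) {
      I <- tab[[paste0("I_", ch)]][i]
      S <- ds$truth[[paste0("sig_", ch)]][j]
      if (I > 0 && S > 50) { got <- c(got, I); want <- c(want, S) }
    }
  }
  fit <- lm(got ~ want)
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.02)
  expect_gt(summary(fit)$r.squared, 0.999)
})
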