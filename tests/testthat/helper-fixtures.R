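# shared fixtures, all built in code

# well-separated Gaussian blobs in a small feature space, in the fingerprint
# table layout (label + named feature columns)
make_blobs <- function(n_per_class, k = 3L, p = 4L, sep = 8, sd = 1,
                       seed = 42L) {
  stopifnot(p >= k)
  set.seed(seed)
  # orthogonal centers: class c sits at sep * e_c, pairwise distance sep*sqrt(2)
  X <- do.call(rbind, lapply(seq_len(k), function(c) {
    M <- matrix(stats::rnorm(n_per_class * p, sd = sd), n_per_class, p)
    M[, c] <- M[, c] + sep
    M
  }))
  colnames(X) <- paste0("f", seq_len(p))
  df <- as.data.frame(X)
  df$label <- rep(seq_len(k), each = n_per_class)
  df
}

blob_features <- function(p = 4L) paste0("f", seq_len(p))

# a small noiseless FOV with known particles; returns the fov plus truth
make_test_fov <- function(n_particles = 5L, dim = 160L, seed = 7L,
                          noise = FALSE, class_ids = 26L,
                          het = het_params(50, 0, 0)) {
  codes <- enumerate_barcodes()
  codes <- codes[codes$id %in% class_ids, , drop = FALSE]
  model <- optical_model()
  ds <- generate_dataset(codes, ceiling(n_particles / nrow(codes)),
                         fovs = 1L, het = het, model = model, seed = seed,
                         noise = noise, dim = dim, min_sep_nm = 1500)
  list(fov = ds$images[[1]], truth = ds$truth, model = model)
}

# brute-force re-implementation of greedy nearest-within-radius matching,
# written as plain loops for use as an oracle
brute_force_match <- function(reference, channel, radius_nm) {
  n_ref <- nrow(reference)
  assigned <- rep(NA_integer_, n_ref)
  used <- rep(FALSE, nrow(channel))
  for (i in seq_len(n_ref)) {
    best <- NA_integer_; best_d <- Inf
    for (j in seq_len(nrow(channel))) {
      if (used[j]) next
      d <- sqrt((channel$x_nm[j] - reference$x_nm[i])^2 +
                  (channel$y_nm[j] - reference$y_nm[i])^2)
      if (d < best_d || (d == best_d && (is.na(best) || j < best))) {
        best_d <- d; best <- j
      }
    }
    if (!is.na(best) && best_d <= radius_nm) {
      assigned[i] <- best
      used[best] <- TRUE
    }
  }
  assigned
}
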