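#' Dye panel definition
#'
#' A dye panel is an ordered set of fluorophores with nominal excitation and
#' emission peaks. The default is the lipophilic carbocyanine trio DiO, DiI,
#' DiD, ordered blue-to-red so that every downstream convention ("first dye",
#' "spectrally downhill") is unambiguous.
#'
#' @param names Character vector of unique dye identifiers.
#' @param excitation_peak Numeric vector, nominal excitation maxima (nm).
#' @param emission_peak Numeric vector, nominal emission maxima (nm).
#' @return An object of class `dye_panel`: a data.frame with one row per dye.
#' @examples
#' dye_panel()
#' @export
dye_panel <- function(names = c("DiO", "DiI", "DiD"),
                      excitation_peak = c(484, 549, 644),
                      emission_peak = c(501, 565, 665)) {
  if (length(names) < 1L) stop("dye panel must contain at least one dye")
  if (anyDuplicated(names)) stop("dye names must be unique")
  if (length(excitation_peak) != length(names) ||
      length(emission_peak) != length(names)) {
    stop("peak vectors must match the number of dyes")
  }
  out <- data.frame(
    name = as.character(names),
    excitation_peak = as.numeric(excitation_peak),
    emission_peak = as.numeric(emission_peak),
    stringsAsFactors = FALSE
  )
  class(out) <- c("dye_panel", "data.frame")
  out
}

#' Enumerate all barcodes for a level/dye scheme
#'
#' With `m` dyes and `n` intensity levels (level 0 meaning "dye absent") there
#' are `n^m - 1` usable barcodes, the all-zero combination being excluded.
#' Ids are assigned canonically: codes with fewer active dyes come first
#' (singles, then duals, then triples, ...), and within each group codes are
#' ordered lexicographically by the flattened (dye index, level) sequence of
#' their active dyes. For the default 3-dye/3-level panel this puts the six
#' single-colour codes at ids 1-6 (DiO low, DiO high, DiI low, DiI high,
#' DiD low, DiD high), the twelve duals at 7-18 and the eight triples at
#' 19-26; e.g. id 8 is 1 uM DiO + 10 uM DiI and id 11 is 10 uM DiO + 1 uM DiI.
#'
#' @param n_levels Number of intensity levels including zero (>= 2).
#' @param dyes A [dye_panel()].
#' @param concentrations Micromolar concentration assigned to each nonzero
#'   level, length `n_levels - 1`. Defaults to the decade series 1, 10, 100...
#'   so that the 3-level scheme uses 0 / 1 uM / 10 uM.
#' @return A `barcode_table` data.frame with columns `id`, one `<dye>_level`
#'   and one `<dye>_uM` column per dye.
#' @examples
#' nrow(enumerate_barcodes())        # 26
#' nrow(enumerate_barcodes(2, dye_panel(c("A", "B"), c(1, 2), c(3, 4))))  # 3
#' @export
enumerate_barcodes <- function(n_levels = 3L, dyes = dye_panel(),
                               concentrations = 10^(seq_len(n_levels - 1L) - 1L)) {
  if (!is.numeric(n_levels) || length(n_levels) != 1L || n_levels < 2L) {
    stop("n_levels must be a single integer >= 2")
  }
  if (!inherits(dyes, "dye_panel")) dyes <- dye_panel(dyes)
  m <- nrow(dyes)
  n_levels <- as.integer(n_levels)
  if (length(concentrations) != n_levels - 1L) {
    stop("concentrations must have length n_levels - 1")
  }
  grid <- as.matrix(expand.grid(rep(list(0:(n_levels - 1L)), m)))
  colnames(grid) <- dyes$name
  grid <- grid[rowSums(grid) > 0L, , drop = FALSE]

  # canonical order: fewer active dyes first, then lexicographic over the
  # flattened (dye index, level) pairs of the active dyes
  key <- apply(grid, 1L, function(lv) {
    act <- which(lv > 0L)
    paste(sprintf("%03d", c(length(act), rbind(act, lv[act]))), collapse = "")
  })
  grid <- grid[order(key), , drop = FALSE]

  out <- data.frame(id = seq_len(nrow(grid)))
  for (d in seq_len(m)) {
    out[[paste0(dyes$name[d], "_level")]] <- as.integer(grid[, d])
  }
  conc <- c(0, concentrations)
  for (d in seq_len(m)) {
    out[[paste0(dyes$name[d], "_uM")]] <- conc[grid[, d] + 1L]
  }
  attr(out, "dyes") <- dyes
  attr(out, "n_levels") <- n_levels
  class(out) <- c("barcode_table", "data.frame")
  out
}

#' Decode a barcode id back to its level vector
#'
#' @param id Integer vector of barcode ids.
#' @param codes A `barcode_table` from [enumerate_barcodes()].
#' @return Integer matrix, one row per id, one column per dye.
#' @export
decode_barcode <- function(id, codes = enumerate_barcodes()) {
  if (any(!id %in% codes$id)) stop("unknown barcode id")
  lv <- as.matrix(codes[match(id, codes$id),
                        grep("_level$", names(codes)), drop = FALSE])
  rownames(lv) <- NULL
  colnames(lv) <- sub("_level$", "", colnames(lv))
  lv
}

#' Level vectors of a barcode table as a matrix
#' @param codes A `barcode_table`.
#' @return Integer matrix codes x dyes.
#' @export
barcode_levels <- function(codes) {
  decode_barcode(codes$id, codes)
}

#' Per-dye concentrations of a barcode table as a matrix (uM)
#' @param codes A `barcode_table`.
#' @return Numeric matrix codes x dyes.
#' @export
barcode_concentrations <- function(codes) {
  cc <- as.matrix(codes[, grep("_uM$", names(codes)), drop = FALSE])
  rownames(cc) <- NULL
  colnames(cc) <- sub("_uM$", "", colnames(cc))
  cc
}

#' The six-channel confocal acquisition scheme
#'
#' Returns the detection channels used throughout: three "main" channels
#' pairing each dye's optimal laser line with its own emission window
#' (alpha = DiD 638/648-750, beta = DiI 552/563-620, delta = DiO 488/498-538)
#' and three "additional" channels (gamma, epsilon, zeta) that pair a shorter
#' laser line with a redder window to capture cross-excitation, emission
#' bleed-through and FRET.
#'
#' @return A `channel_table` data.frame with columns `name`, `laser_nm`,
#'   `em_low_nm`, `em_high_nm`, `role` and `dye` (main-channel dye or NA).
#' @examples
#' default_channels()
#' @export
default_channels <- function() {
  out <- data.frame(
    name = c("alpha", "beta", "gamma", "delta", "epsilon", "zeta"),
    laser_nm = c(638, 552, 552, 488, 488, 488),
    em_low_nm = c(648, 563, 648, 498, 563, 648),
    em_high_nm = c(750, 620, 750, 538, 620, 750),
    role = c("main", "main", "additional", "main", "additional", "additional"),
    dye = c("DiD", "DiI", NA, "DiO", NA, NA),
    stringsAsFactors = FALSE
  )
  class(out) <- c("channel_table", "data.frame")
  out
}

#' All valid laser/emission-window pairings
#'
#' A pairing is valid when the emission window lies entirely above the laser
#' line (`em_low > laser`), i.e. detected light is Stokes-shifted relative to
#' the excitation.
#'
#' @param lasers Numeric vector of laser lines (nm).
#' @param windows List of length-2 numeric vectors `c(low, high)` (nm), or a
#'   2-column matrix.
#' @return Data.frame with columns `laser_nm`, `em_low_nm`, `em_high_nm`,
#'   one row per valid pair, ordered by laser then window.
#' @examples
#' nrow(valid_channel_pairs(c(488, 552, 638),
#'      list(c(498, 538), c(563, 620), c(648, 750))))  # 6
#' @export
valid_channel_pairs <- function(lasers, windows) {
  if (length(lasers) < 1L) stop("need at least one laser line")
  if (is.matrix(windows)) windows <- asplit(windows, 1L)
  if (length(windows) < 1L) stop("need at least one emission window")
  win <- do.call(rbind, lapply(windows, function(w) {
    if (length(w) != 2L || w[1] >= w[2]) stop("each window must be c(low, high) with low < high")
    as.numeric(w)
  }))
  grid <- expand.grid(l = seq_along(lasers), w = seq_len(nrow(win)))
  keep <- win[grid$w, 1L] > lasers[grid$l]
  grid <- grid[keep, , drop = FALSE]
  out <- data.frame(
    laser_nm = lasers[grid$l],
    em_low_nm = win[grid$w, 1L],
    em_high_nm = win[grid$w, 2L]
  )
  out <- out[order(out$laser_nm, out$em_low_nm), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a barcode table to CSV
#' @param codes A `barcode_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_barcode_table <- function(codes, path) {
  utils::write.csv(as.data.frame(codes), path, row.names = FALSE)
  invisible(path)
}

#' Write the channel table to CSV
#' @param channels A `channel_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_channel_table <- function(channels, path) {
  utils::write.csv(
    as.data.frame(channels)[, c("name", "laser_nm", "em_low_nm", "em_high_nm")],
    path, row.names = FALSE
  )
  invisible(path)
}

#' @export
print.barcode_table <- function(x, ...) {
  cat(sprintf("Barcode table: %d codes, %d dyes, %d levels\n",
              nrow(x), nrow(attr(x, "dyes")), attr(x, "n_levels")))
  print.data.frame(x, ...)
  invisible(x)
}
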