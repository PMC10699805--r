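#' Generate a synthetic single-band spectrum
#'
#' Gaussian band in wavelength; stands in for a measured donor emission
#' band or a low-extinction transition-metal absorbance band. Gaussian
#' shape keeps an analytic overlap integral available for cross-checks.
#'
#' @param peak_nm Band maximum position (nm).
#' @param width_nm Gaussian SD of the band (nm), > 0.
#' @param kind `"emission"`, `"absorbance"` or `"extinction"`.
#' @param scale Peak height (arbitrary units, dimensionless absorbance,
#'   or M^-1 cm^-1).
#' @param grid Wavelength grid (nm), strictly increasing.
#' @param pH_tag Optional condition label.
#' @return A [spectrum()] object.
#' @export
gen_spectrum <- function(peak_nm, width_nm,
                         kind = c("emission", "absorbance", "extinction"),
                         scale = 1, grid = seq(350, 650, by = 1),
                         pH_tag = NA_character_) {
  kind <- match.arg(kind)
  if (!is.numeric(width_nm) || width_nm <= 0)
    stop("width_nm must be positive", call. = FALSE)
  if (any(diff(grid) <= 0))
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  v <- scale * exp(-(grid - peak_nm)^2 / (2 * width_nm^2))
  spectrum(grid, v, kind = kind, pH_tag = pH_tag)
}

#' Generate a synthetic three-stage imaging bundle
#'
#' Emulates the unroofed-cell tmFRET imaging protocol: per cell, three
#' images (pre-metal, +metal, post-reversal) with ROI-mean expectations
#' \deqn{F_1 = S + B,\quad F_2 = S b (1 - q) + B,\quad F_3 = S b^2 r + B}
#' where S is the donor signal per pixel, B the background level, b the
#' per-stage photobleaching factor, q the metal quench fraction (the true
#' FRET efficiency) and r the reversal fraction (1 = full DTT/EDTA
#' reversal). Poisson noise is applied per pixel after the background is
#' added. Mock (no-metal) bundles are simply `quench = 0`.
#'
#' @param n_cells Number of cells, >= 1.
#' @param quench True quench fraction q in [0, 1]; scalar or per-cell
#'   vector.
#' @param bleach Per-stage bleach factor b in (0, 1] (default 0.9).
#' @param reversal Reversal fraction r in (0, 1] (default 1, full
#'   reversal).
#' @param signal Expected donor counts per ROI pixel S (Poisson scale).
#' @param background Background level B in counts.
#' @param dims Image dimensions `c(rows, cols)`.
#' @param noise Apply Poisson noise? `FALSE` gives exact expectations.
#' @param seed Integer seed; one seed governs the whole bundle, per-cell
#'   substreams are derived from it deterministically.
#' @return List with `stacks` (named list of three-matrix stacks),
#'   `rois` (ROI data.frame in the standard dialect) and `truth`
#'   (data.frame `cell_id,quench,bleach,reversal`).
#' @export
gen_imaging_bundle <- function(n_cells, quench, bleach = 0.9, reversal = 1,
                               signal = 1e4, background = 50,
                               dims = c(40L, 40L), noise = TRUE, seed = 1L) {
  stopifnot(n_cells >= 1, bleach > 0, bleach <= 1,
            reversal > 0, reversal <= 1, signal > 0, background >= 0)
  if (any(quench < 0) || any(quench > 1))
    stop("quench fraction must lie in [0, 1]", call. = FALSE)
  q <- rep_len(quench, n_cells)
  set.seed(as.integer(seed))
  cell_seeds <- sample.int(.Machine$integer.max - 1L, n_cells)
  # fixed geometry: cell occupies an inner square, background ROI is a
  # cell-free corner patch
  x0 <- 4L; y0 <- 4L; x1 <- as.integer(dims[2L] * 0.7)
  y1 <- as.integer(dims[1L] * 0.7)
  bx0 <- as.integer(dims[2L] * 0.75); by0 <- as.integer(dims[1L] * 0.75)
  bx1 <- dims[2L]; by1 <- dims[1L]
  ids <- sprintf("cell_%03d", seq_len(n_cells))
  stacks <- vector("list", n_cells); names(stacks) <- ids
  for (i in seq_len(n_cells)) {
    set.seed(cell_seeds[i])
    expect <- c(signal,
                signal * bleach * (1 - q[i]),
                signal * bleach^2 * reversal)
    stacks[[i]] <- lapply(expect, function(s) {
      img <- matrix(background, dims[1L], dims[2L])
      img[(y0 + 1L):y1, (x0 + 1L):x1] <- s + background
      if (noise) img[] <- stats::rpois(length(img), img)
      img
    })
  }
  rois <- data.frame(cell_id = ids, x0 = x0, y0 = y0, x1 = x1, y1 = y1,
                     bg_x0 = bx0, bg_y0 = by0, bg_x1 = bx1, bg_y1 = by1)
  truth <- data.frame(cell_id = ids, quench = q, bleach = bleach,
                      reversal = reversal)
  list(stacks = stacks, rois = rois, truth = truth)
}

#' Write an imaging bundle to disk
#'
#' One plain-text stack file per cell (`<cell_id>.txt`), plus `rois.csv`
#' and `truth.csv` in the standard dialects.
#'
#' @param bundle As returned by [gen_imaging_bundle()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_imaging_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(bundle$stacks))
    write_image_stack(bundle$stacks[[id]], file.path(dir, paste0(id, ".txt")))
  utils::write.csv(bundle$rois, file.path(dir, "rois.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(bundle$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read all image stacks of a bundle directory
#'
#' @param dir Directory written by [write_imaging_bundle()].
#' @return Named list of stacks.
#' @export
read_imaging_bundle <- function(dir) {
  files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  if (!length(files)) stop("no stack files found in ", dir, call. = FALSE)
  stacks <- lapply(files, read_image_stack)
  names(stacks) <- sub("\\.txt$", "", basename(files))
  stacks
}

#' Tabulate the planar-model efficiency over a distance grid
#'
#' Ground-truth table of the theoretical dependence of FRET efficiency on
#' the closest-approach distance for a donor above a membrane loaded with
#' metal-chelating lipid.
#'
#' @param R0 Forster radius (Angstrom).
#' @param sigma Acceptor surface density (molecules/Angstrom^2).
#' @param d_grid Distances (Angstrom), all > 0.
#' @return data.frame with columns `d` and `E`, E strictly decreasing in
#'   d (for sigma > 0).
#' @export
gen_planar_truth <- function(R0, sigma, d_grid = seq(2, 40, by = 1)) {
  if (any(d_grid <= 0)) stop("all distances must be positive", call. = FALSE)
  data.frame(d = d_grid, E = planar_efficiency(d_grid, R0, sigma))
}

#' Generate synthetic pH dose-response families
#'
#' Per-cell normalized currents on a Hill curve with additive Gaussian
#' measurement noise (applied to the normalized response, clipped at 0).
#' Defaults emulate an acid-sensing channel activated between pH 7 and
#' pH 5.5 with a steep midpoint near pH 6.5.
#'
#' @param n_cells Number of cells.
#' @param pH05 True half-activation pH.
#' @param n_hill True Hill slope (negative for acid activation).
#' @param noise_sd Per-point Gaussian noise SD (fraction of max current).
#' @param test_pH Test pH values; must include the maximally activating
#'   (lowest) pH.
#' @param seed Integer seed.
#' @return data.frame `cell_id, pH, I_norm`.
#' @export
gen_dose_response <- function(n_cells, pH05 = 6.5, n_hill = -4,
                              noise_sd = 0.03,
                              test_pH = c(8, 7.5, 7, 6.8, 6.5, 6, 5.5),
                              seed = 1L) {
  if (!length(test_pH)) stop("test pH list must be non-empty", call. = FALSE)
  stopifnot(n_cells >= 1, noise_sd >= 0)
  set.seed(as.integer(seed))
  ideal <- hill_current(test_pH, pH05, n_hill)
  rows <- lapply(seq_len(n_cells), function(i) {
    I <- pmax(ideal + stats::rnorm(length(test_pH), 0, noise_sd), 0)
    data.frame(cell_id = sprintf("cell_%03d", i), pH = test_pH, I_norm = I)
  })
  do.call(rbind, rows)
}
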