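#' Write a three-stage image stack as plain text
#'
#' Stacks are stored as text so they survive source-only distribution:
#' one file per cell, three whitespace-separated matrices (stages
#' pre-metal, +metal, reversal) each preceded by a `# stage <k>` line.
#'
#' @param stack List of three numeric matrices of equal dimension.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(is.list(stack), length(stack) == 3L)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(stack)) {
    writeLines(sprintf("# stage %d", k), con)
    utils::write.table(stack[[k]], con, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a three-stage image stack written by [write_image_stack()]
#'
#' @param path Path to the stack file.
#' @return List of three numeric matrices.
#' @export
read_image_stack <- function(path) {
  lines <- readLines(path)
  starts <- grep("^# stage", lines)
  if (length(starts) != 3L)
    stop("expected 3 stages in image stack file: ", path, call. = FALSE)
  ends <- c(starts[-1L] - 1L, length(lines))
  lapply(seq_len(3L), function(k) {
    block <- lines[(starts[k] + 1L):ends[k]]
    do.call(rbind, lapply(strsplit(trimws(block), "\\s+"), as.numeric))
  })
}

#' Mean gray value of a rectangular ROI
#'
#' Coordinates are 0-based and half-open (`x0 <= x < x1`), as in the ROI
#' CSV dialect; x indexes columns, y rows.
#'
#' @param img Numeric matrix.
#' @param x0,y0,x1,y1 ROI bounds.
#' @return List with `mean` and `sd` of the ROI pixels.
#' @export
roi_stats <- function(img, x0, y0, x1, y1) {
  stopifnot(x1 > x0, y1 > y0, x1 <= ncol(img), y1 <= nrow(img))
  px <- img[(y0 + 1L):y1, (x0 + 1L):x1]
  list(mean = mean(px), sd = stats::sd(as.numeric(px)))
}

#' Subtract background from an ROI mean
#'
#' The mean gray value of a nearby cell-free background ROI is subtracted
#' from the cell ROI mean. Negative results are permitted (empty or
#' control ROIs) and preserved.
#'
#' @param roi_mean,bg_mean Mean gray values in counts.
#' @return Background-subtracted counts.
#' @export
subtract_background <- function(roi_mean, bg_mean) {
  stopifnot(all(is.finite(roi_mean)), all(is.finite(bg_mean)))
  roi_mean - bg_mean
}

#' Measure all cells of an imaging bundle
#'
#' Applies the cell and background ROIs to each three-stage stack and
#' returns per-cell, per-stage ROI means with background subtracted.
#' Cells whose pre-metal signal does not exceed `min_snr` times the
#' background SD are excluded (non-unroofed / low-signal cells) and
#' reported in the `excluded` attribute.
#'
#' @param stacks Named list of stacks (one per cell) as returned by
#'   [read_image_stack()] or generated in memory.
#' @param rois data.frame with columns `cell_id,x0,y0,x1,y1,bg_x0,bg_y0,
#'   bg_x1,bg_y1` (0-based, half-open pixel coordinates).
#' @param min_snr Exclusion threshold: minimum F_pre / bg SD (default 3).
#' @return data.frame of cell measurements: `cell_id`, background-
#'   subtracted `F_pre`, `F_metal`, `F_rev`, raw background means
#'   `B_pre`, `B_metal`, `B_rev`, and `bg_sd` (stage-1 background SD).
#'   Excluded cells are recorded in `attr(, "excluded")` with reasons.
#' @export
measure_cells <- function(stacks, rois, min_snr = 3) {
  need <- c("cell_id", "x0", "y0", "x1", "y1",
            "bg_x0", "bg_y0", "bg_x1", "bg_y1")
  if (!all(need %in% names(rois)))
    stop("ROI table missing columns: ",
         paste(setdiff(need, names(rois)), collapse = ", "), call. = FALSE)
  rows <- list(); excluded <- list()
  for (i in seq_len(nrow(rois))) {
    r <- rois[i, ]
    id <- as.character(r$cell_id)
    stk <- stacks[[id]]
    if (is.null(stk)) stop("no image stack for cell ", id, call. = FALSE)
    cell <- lapply(stk, roi_stats, r$x0, r$y0, r$x1, r$y1)
    bg <- lapply(stk, roi_stats, r$bg_x0, r$bg_y0, r$bg_x1, r$bg_y1)
    f <- subtract_background(vapply(cell, `[[`, 0, "mean"),
                             vapply(bg, `[[`, 0, "mean"))
    if (f[1L] <= min_snr * bg[[1L]]$sd) {
      excluded[[id]] <- sprintf(
        "F_pre = %.3g <= %g x background SD (%.3g)", f[1L], min_snr,
        bg[[1L]]$sd)
      next
    }
    rows[[id]] <- data.frame(
      cell_id = id, F_pre = f[1L], F_metal = f[2L], F_rev = f[3L],
      B_pre = bg[[1L]]$mean, B_metal = bg[[2L]]$mean, B_rev = bg[[3L]]$mean,
      bg_sd = bg[[1L]]$sd)
  }
  out <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
         else data.frame()
  attr(out, "excluded") <- unlist(excluded)
  out
}

#' Normalize a cell's stage fluorescence to the pre-metal image
#'
#' @param F_pre,F_metal,F_rev Background-subtracted stage fluorescences;
#'   `F_pre` must be positive.
#' @return Numeric vector `c(1, F_metal/F_pre, F_rev/F_pre)`.
#' @export
roi_series_to_normalized <- function(F_pre, F_metal, F_rev) {
  if (!is.finite(F_pre) || F_pre <= 0)
    stop("F_pre must be positive after background subtraction",
         call. = FALSE)
  c(1, F_metal / F_pre, F_rev / F_pre)
}

#' Estimate the photobleaching factor from mock experiments
#'
#' Mock experiments repeat the full imaging protocol (washes, timing)
#' without adding metal, so any drop in the second image is pure
#' photobleaching. F_bleach is the mean over mock cells of the
#' second-image fluorescence normalized to the first; it is estimated
#' per pH condition, pooled across donor positions.
#'
#' @param mock data.frame of metal-free mock cell measurements with
#'   columns `F_pre`, `F_metal` (background-subtracted).
#' @param pH_tag Condition label the factor applies to.
#' @return A `bleach_model`: list with `F_bleach`, `n_mock`, `pH_tag`.
#' @export
estimate_bleach_factor <- function(mock, pH_tag = NA_character_) {
  if (is.null(mock) || nrow(mock) == 0L)
    stop("bleach estimation requires at least one metal-free mock cell",
         call. = FALSE)
  ratios <- mock$F_metal / mock$F_pre
  structure(list(F_bleach = mean(ratios), n_mock = nrow(mock),
                 pH_tag = pH_tag),
            class = "bleach_model")
}

#' Bleach-corrected FRET efficiency for one cell
#'
#' \deqn{E = 1 - F_{FRET} / F_{bleach}}
#' where F_FRET is the cell's second-image (with metal) fluorescence
#' normalized to its first image, and F_bleach the mock-experiment
#' bleaching factor for the same pH. Negative efficiencies (controls)
#' are preserved, never clipped or adjusted.
#'
#' @param F_pre,F_metal Background-subtracted stage-1/stage-2
#'   fluorescence of the cell.
#' @param bleach A `bleach_model` from [estimate_bleach_factor()].
#' @return Efficiency (dimensionless, <= 1).
#' @export
fret_efficiency <- function(F_pre, F_metal, bleach) {
  if (!inherits(bleach, "bleach_model"))
    stop("a bleach model estimated from mock experiments is required",
         call. = FALSE)
  f_fret <- roi_series_to_normalized(F_pre, F_metal, F_metal)[2L]
  1 - f_fret / bleach$F_bleach
}

#' Summarize per-cell efficiencies for one condition
#'
#' @param E Numeric vector of per-cell efficiencies.
#' @param condition Condition label.
#' @param is_control Logical: Zn2+-style no-quench control group.
#'   Controls are summarized and flagged but never used to adjust the
#'   metal groups.
#' @return One-row data.frame `condition, mean_E, SEM, N, is_control`.
#'   SEM uses the n-1 sample SD; with N = 1 it is reported as 0.
#' @export
summarize_group <- function(E, condition = NA_character_,
                            is_control = FALSE) {
  stopifnot(length(E) >= 1L, all(is.finite(E)))
  n <- length(E)
  sem <- if (n > 1L) stats::sd(E) / sqrt(n) else 0
  data.frame(condition = condition, mean_E = mean(E), SEM = sem, N = n,
             is_control = is_control)
}
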