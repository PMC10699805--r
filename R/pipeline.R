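#' Run the full tmFRET analysis pipeline from a config
#'
#' Config-driven orchestration of the analysis stages. The config (YAML
#' file or equivalent list) may contain:
#'
#' * `input`: `image_dir` (per-cell stack files), `roi_csv`,
#'   `metadata_csv` with columns
#'   `cell_id,donor_site,acceptor,pH,is_control,is_mock`
#'   (`is_mock` marks metal-free bleach-calibration cells;
#'   `acceptor == "membrane"` selects the planar geometry).
#' * `constants`: `Q`, `kappa2`, `eta`, `C`, `sigma`, `d_floor`,
#'   `model` (`average`/`rate_sum`), and per-pH Forster radii
#'   `r0` (named list, e.g. `r0: {pH8: 17.6, pH6: 17.2}` for the
#'   point geometry and `r0_planar: {pH8: 12.4, pH6: 12.6}`).
#' * `spectra` (optional): `donor_csv`, `acceptor_csv`,
#'   `concentration` (M), `pathlength` (cm) — computes J and R0 and
#'   writes a calibration YAML instead of requiring `r0`.
#' * `ephys` (optional): `csv` with `cell_id,pH,I_norm`.
#' * `out_dir`, `seed`.
#'
#' Outputs written to `out_dir`: `cells.csv` (per-cell efficiencies),
#' `groups.csv`, `distances.csv`, `summary.csv` (Table-style layout),
#' optional `calibration.yaml` and `ephys_fits.csv`, and `run.log` with
#' per-stage messages and cell exclusion reasons. Deterministic given
#' inputs and seed; reruns are byte-identical.
#'
#' @param config Path to a YAML config or a list.
#' @return Invisibly, a list with the per-cell table, group summaries,
#'   distances and (if run) calibration and ephys fits.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  out_dir <- config$out_dir %||% stop("config needs out_dir", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  log <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  cst <- config$constants %||% list()
  result <- list()

  if (!is.null(config$spectra)) {
    sp <- config$spectra
    donor <- read_spectrum(sp$donor_csv, kind = "emission")
    acc_abs <- read_spectrum(sp$acceptor_csv, kind = "absorbance")
    eps <- extinction_from_absorbance(acc_abs, sp$concentration,
                                      sp$pathlength %||% 1)
    J <- overlap_integral(donor, eps)
    cal <- fret_calibration(J, Q = cst$Q %||% 0.22,
                            kappa2 = cst$kappa2 %||% 2 / 3,
                            eta = cst$eta %||% 1.33,
                            C = cst$C %||% 0.2108)
    cal <- forster_radius(cal)
    write_calibration(cal, file.path(out_dir, "calibration.yaml"))
    log(sprintf("spectra: J = %.6g, R0 = %.3f A", cal$J, cal$R0))
    result$calibration <- cal
  }

  if (!is.null(config$input)) {
    inp <- config$input
    stacks <- read_imaging_bundle(inp$image_dir)
    rois <- utils::read.csv(inp$roi_csv)
    meta <- utils::read.csv(inp$metadata_csv)
    need <- c("cell_id", "donor_site", "acceptor", "pH", "is_control",
              "is_mock")
    if (!all(need %in% names(meta)))
      stop("metadata missing columns: ",
           paste(setdiff(need, names(meta)), collapse = ", "),
           call. = FALSE)
    cm <- measure_cells(stacks, rois, min_snr = cst$min_snr %||% 3)
    for (ex in attr(cm, "excluded"))
      log("excluded cell: ", ex)
    cm <- merge(cm, meta, by = "cell_id")
    # metadata flags may arrive as logical or 0/1
    cm$is_mock <- as_flag(cm$is_mock)
    cm$is_control <- as_flag(cm$is_control)

    # one bleach factor per pH, pooled across donor positions, from
    # metal-free mocks only
    bleach_by_pH <- lapply(split(cm[cm$is_mock, ], cm$pH[cm$is_mock]),
                           function(m) estimate_bleach_factor(m, m$pH[1L]))
    for (tag in names(bleach_by_pH))
      log(sprintf("bleach %s: F_bleach = %.4f (n = %d mocks)", tag,
                  bleach_by_pH[[tag]]$F_bleach, bleach_by_pH[[tag]]$n_mock))

    exp_cells <- cm[!cm$is_mock, ]
    exp_cells$E <- vapply(seq_len(nrow(exp_cells)), function(i) {
      bm <- bleach_by_pH[[as.character(exp_cells$pH[i])]]
      if (is.null(bm))
        stop("no bleach model for pH condition ", exp_cells$pH[i],
             call. = FALSE)
      fret_efficiency(exp_cells$F_pre[i], exp_cells$F_metal[i], bm)
    }, numeric(1L))
    exp_cells$condition <- interaction(exp_cells$donor_site,
                                       exp_cells$acceptor, exp_cells$pH,
                                       drop = TRUE, sep = "|")
    groups <- do.call(rbind, lapply(split(exp_cells, exp_cells$condition),
      function(g) {
        s <- summarize_group(g$E, as.character(g$condition[1L]),
                             is_control = any(g$is_control))
        s$acceptor <- g$acceptor[1L]
        s$pH <- g$pH[1L]
        s
      }))
    rownames(groups) <- NULL
    utils::write.csv(
      exp_cells[, c("cell_id", "condition", "E")],
      file.path(out_dir, "cells.csv"), row.names = FALSE, quote = FALSE)
    utils::write.csv(groups[, c("condition", "mean_E", "SEM", "N",
                                "is_control")],
                     file.path(out_dir, "groups.csv"),
                     row.names = FALSE, quote = FALSE)
    log(sprintf("imaging: %d cells in %d groups", nrow(exp_cells),
                nrow(groups)))

    distances <- lapply(seq_len(nrow(groups)), function(i) {
      g <- groups[i, ]
      if (g$is_control) {
        return(new_distance_estimate(NA_real_, mode = "point",
                                     E = g$mean_E, R0 = NA_real_,
                                     reason = "control group"))
      }
      tag <- paste0("pH", g$pH)
      if (identical(g$acceptor, "membrane")) {
        r0 <- (cst[["r0_planar"]] %||% list())[[tag]]
        if (is.null(r0)) stop("constants$r0_planar missing entry ", tag,
                              call. = FALSE)
        if (is.null(cst$sigma))
          stop("planar data present but constants$sigma missing",
               call. = FALSE)
        if (g$mean_E <= 0)
          return(new_distance_estimate(NA_real_, mode = "planar",
                                       E = g$mean_E, R0 = r0,
                                       reason = "non-positive efficiency"))
        invert_planar_efficiency(g$mean_E, r0, cst$sigma,
                                 d_floor = cst$d_floor %||% 5,
                                 model = cst$model %||% "average")
      } else {
        r0 <- (cst[["r0"]] %||% list())[[tag]]
        if (is.null(r0)) stop("constants$r0 missing entry ", tag,
                              call. = FALSE)
        distance_from_efficiency_point(g$mean_E, r0)
      }
    })
    dist_df <- data.frame(
      condition = groups$condition,
      E = groups$mean_E,
      mode = vapply(distances, `[[`, "", "mode"),
      r_A = vapply(distances, `[[`, 0, "r"),
      reported = vapply(distances, format_distance, ""),
      beyond_range = vapply(distances, `[[`, FALSE, "beyond_range"))
    utils::write.csv(dist_df, file.path(out_dir, "distances.csv"),
                     row.names = FALSE, quote = FALSE)
    write_summary_table(groups, distances,
                        file.path(out_dir, "summary.csv"))
    result$cells <- exp_cells
    result$groups <- groups
    result$distances <- distances
  }

  if (!is.null(config$ephys)) {
    dr <- utils::read.csv(config$ephys$csv)
    fits <- fit_ph_activation(dr, exclude_pH = config$ephys$exclude_pH)
    utils::write.csv(fits$per_cell, file.path(out_dir, "ephys_fits.csv"),
                     row.names = FALSE, quote = FALSE)
    log(sprintf("ephys: mean pH0.5 = %.3f +/- %.3f (N = %d)",
                fits$summary$mean_pH05, fits$summary$SEM, fits$summary$N))
    result$ephys <- fits
  }

  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(result)
}

#' Write a Table-style condition summary
#'
#' One row per condition with mean efficiency, SEM, N and the reported
#' distance; beyond-range entries print as `<=floor` and control groups
#' as `N/A`.
#'
#' @param groups data.frame with `condition, mean_E, SEM, N, is_control`.
#' @param distances List of `distance_estimate`s, same order/keys.
#' @param path Output CSV path.
#' @return The summary data.frame, invisibly.
#' @export
write_summary_table <- function(groups, distances, path) {
  if (nrow(groups) != length(distances))
    stop("groups and distances differ in length; orphan conditions: ",
         nrow(groups), " groups vs ", length(distances), " distances",
         call. = FALSE)
  out <- data.frame(
    condition = groups$condition,
    mean_E = round(groups$mean_E, 4),
    SEM = round(groups$SEM, 4),
    N = groups$N,
    distance_A = vapply(distances, format_distance, ""))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_flag <- function(x) if (is.logical(x)) x else as.integer(x) == 1L
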