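#' Hill-type pH activation curve
#'
#' \deqn{I = \frac{1}{1 + 10^{(pH_{0.5} - pH)\,n}}}
#' I equals 0.5 at `pH05` for any slope. With this sign convention an
#' acid-activated response (current rising as pH falls) corresponds to a
#' negative fitted Hill slope n.
#'
#' @param pH Test pH value(s).
#' @param pH05 Half-maximally activating pH.
#' @param n Hill slope (negative for acid activation).
#' @return Normalized current in (0, 1).
#' @export
hill_current <- function(pH, pH05, n) {
  1 / (1 + 10^((pH05 - pH) * n))
}

#' Normalize raw currents to the maximally activating condition
#'
#' Each cell's test-pH currents are divided by its current at the
#' maximally activating pH (pH 5.5 in the standard protocol).
#'
#' @param raw Raw current amplitudes (e.g. pA).
#' @param test_pH Test pH of each current, same length.
#' @param max_pH The maximally activating pH; must be present in
#'   `test_pH`.
#' @return Normalized currents; the `max_pH` entry is exactly 1.
#' @export
normalize_currents <- function(raw, test_pH, max_pH) {
  stopifnot(length(raw) == length(test_pH))
  i <- which(test_pH == max_pH)
  if (!length(i))
    stop("max_pH not among the test pH values", call. = FALSE)
  ref <- raw[i[1L]]
  if (!is.finite(ref) || ref == 0)
    stop("zero current at the maximally activating pH; cell excluded",
         call. = FALSE)
  raw / ref
}

# single-cell least-squares Hill fit; analytic RSS gradient so BFGS
# converges to machine precision on noiseless data
fit_hill_one <- function(pH, I, n0 = -3, exclude_pH = NULL) {
  if (!is.null(exclude_pH)) {
    keep <- !(pH %in% exclude_pH)
    pH <- pH[keep]; I <- I[keep]
  }
  if (length(unique(pH)) < 4L)
    stop("need at least 4 distinct test pH values", call. = FALSE)
  # initial midpoint: linear interpolation of the half-max crossing
  ord <- order(pH)
  p0 <- tryCatch(stats::approx(I[ord], pH[ord], xout = 0.5, ties = mean)$y,
                 error = function(e) NA_real_)
  if (!is.finite(p0)) p0 <- stats::median(pH)
  rss <- function(par) sum((I - hill_current(pH, par[1L], par[2L]))^2)
  grad <- function(par) {
    x <- (par[1L] - pH) * par[2L]
    tenx <- 10^x
    f <- 1 / (1 + tenx)
    core <- tenx * f^2 * log(10)       # -dI/dx
    resid <- I - f
    c(sum(resid * 2 * core * par[2L]),
      sum(resid * 2 * core * (par[1L] - pH)))
  }
  # the sign of the slope is not known a priori (a non-activating or
  # inverted response fits with n > 0): start from both slopes and keep
  # the better optimum, then polish once from it
  fits <- lapply(c(n0, -n0), function(s)
    stats::optim(c(p0, s), rss, gr = grad, method = "BFGS",
                 control = list(reltol = 1e-15, maxit = 1000)))
  fit <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
  fit <- stats::optim(fit$par, rss, gr = grad, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 1000))
  list(pH05 = fit$par[1L], n = fit$par[2L], rss = fit$value,
       converged = fit$convergence == 0L)
}

#' Fit pH-dependence of activation per cell and aggregate
#'
#' Fits the Hill-type activation curve [hill_current()] to each cell's
#' normalized currents by unconstrained least squares, then summarizes
#' the per-cell midpoints as mean +/- SEM. Cells that fail to converge
#' are flagged and excluded from the group statistics; cells whose
#' fitted slope is positive (response increasing with pH, i.e. not
#' acid-activated) are kept but flagged with a warning.
#'
#' @param dr data.frame with columns `cell_id`, `pH`, `I_norm`.
#' @param n0 Initial Hill slope (default -3).
#' @param exclude_pH Optional pH value(s) to drop from every fit (e.g.
#'   the saturating pH 5.5 point).
#' @return List with `per_cell` (data.frame
#'   `cell_id, pH05, n, rss, converged`) and `summary` (data.frame
#'   `mean_pH05, SEM, N`).
#' @export
fit_ph_activation <- function(dr, n0 = -3, exclude_pH = NULL) {
  stopifnot(all(c("cell_id", "pH", "I_norm") %in% names(dr)))
  cells <- split(dr, dr$cell_id)
  per <- lapply(names(cells), function(id) {
    d <- cells[[id]]
    f <- tryCatch(fit_hill_one(d$pH, d$I_norm, n0 = n0,
                               exclude_pH = exclude_pH),
                  error = function(e) {
                    warning("cell ", id, " excluded: ", conditionMessage(e),
                            call. = FALSE)
                    NULL
                  })
    if (is.null(f))
      return(data.frame(cell_id = id, pH05 = NA_real_, n = NA_real_,
                        rss = NA_real_, converged = FALSE))
    data.frame(cell_id = id, pH05 = f$pH05, n = f$n, rss = f$rss,
               converged = f$converged)
  })
  per <- do.call(rbind, per)
  if (any(per$n > 0, na.rm = TRUE))
    warning("positive fitted Hill slope for ",
            paste(per$cell_id[which(per$n > 0)], collapse = ", "),
            ": response is not acid-activated", call. = FALSE)
  ok <- per$converged & is.finite(per$pH05)
  n_ok <- sum(ok)
  summ <- data.frame(
    mean_pH05 = if (n_ok) mean(per$pH05[ok]) else NA_real_,
    SEM = if (n_ok > 1L) stats::sd(per$pH05[ok]) / sqrt(n_ok) else 0,
    N = n_ok)
  list(per_cell = per, summary = summ)
}
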