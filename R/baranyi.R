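#' Baranyi-Roberts intrinsic growth adjustment
#'
#' The lag-phase adjustment `alpha_i(t) = r0 * c_i / (c_i + exp(-m t))`, which
#' modulates the onset of exponential growth. `r0` is the plate-global maximum
#' growth rate, `m` the global rate at which cells change their internal
#' physiological state, and `c_i` the colony-specific initial physiological
#' state. `alpha` increases monotonically in `t` (and in `c`) and saturates at
#' `r0`. Rates are expressed per sampling step (20-minute units by default).
#'
#' @param t Time in sampling steps (vector allowed).
#' @param r0 Global maximum growth rate (> 0), per step.
#' @param m Global physiological-state change rate (> 0), per step.
#' @param c Physiological state (> 0); scalar or vector.
#' @return Growth adjustment value(s) in `(0, r0)`.
#' @examples
#' baranyi_alpha(5, r0 = 0.119, m = 0.417, c = 1) # ~0.1058
#' @export
baranyi_alpha <- function(t, r0, m, c) {
  if (any(r0 <= 0) || any(m <= 0) || any(c <= 0))
    stop("r0, m and c must all be positive")
  r0 * c / (c + exp(-m * t))
}

#' Evaluate the growth adjustment across a plate
#'
#' @param params An `alpha_params` object (see [fit_alpha_two_stage()]), or a
#'   list with `r0`, `m` and matrix `c`.
#' @param times Time steps at which to evaluate.
#' @return Array `[n_rows x n_cols x length(times)]`; `NA` where `c` is `NA`
#'   (unoccupied or unfit colonies).
#' @export
alpha_field <- function(params, times) {
  cmat <- params$c
  d <- dim(cmat)
  et <- exp(-params$m * times)
  out <- array(NA_real_, dim = c(d[1], d[2], length(times)))
  for (k in seq_along(times))
    out[, , k] <- params$r0 * cmat / (cmat + et[k])
  out
}

# Fit (r0, m, c) of the adjustment function to one colony's early rates by
# bounded Levenberg-Marquardt. Returns NULL on failure.
.fit_alpha_local <- function(tt, y, r0_init, m_init, c_init) {
  resid_fun <- function(p) y - p[1] * p[3] / (p[3] + exp(-p[2] * tt))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(r0_init, m_init, c_init), fn = resid_fun,
                       lower = rep(1e-8, 3), upper = c(10, 10, 1e12),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !(fit$info %in% 1:4)) return(NULL)
  stats::setNames(fit$par, c("r0", "m", "c"))
}

# Refit c alone (r0, m fixed) by golden-section search on log(c).
.refit_c <- function(tt, y, r0, m, c_init) {
  sse <- function(lc) {
    cc <- exp(lc)
    sum((y - r0 * cc / (cc + exp(-m * tt)))^2)
  }
  opt <- stats::optimize(sse, interval = c(log(1e-12), log(1e12)), tol = 1e-10)
  exp(opt$minimum)
}

#' Two-stage fit of the growth adjustment function
#'
#' Fits the Baranyi-Roberts adjustment to the early part of each colony's
#' relative growth-rate curve (all samples up to and including the time of its
#' maximum, where the local environment is still effectively homogeneous), in
#' three stages: (1) per-colony bounded nonlinear least squares giving local
#' `(r0_i, m_i, c_i)`; (2) global `r0` and `m` as the medians of the converged
#' local estimates; (3) per-colony refit of `c_i` with the global `r0`, `m`
#' held fixed. Colonies whose local fit fails are flagged and excluded from the
#' global medians but still receive a stage-3 `c_i`.
#'
#' @param rates A `rate_series` from [compute_rates()].
#' @param background Optional array (same shape as `rates$rho`) of known
#'   multiplicative growth modifiers (e.g. `f(s)` or `eps_k * s` from a
#'   resource model); the adjustment is fitted to `rho / background`. Used for
#'   the adjustment-recomputation step of the iterative model fits.
#' @param m_init,c_init Stage-1 initial values (defaults 0.3, 0.05); `r0`
#'   starts at each colony's maximum observed rate.
#' @param min_points Minimum finite samples in the fit window (default 5).
#' @return An object of class `alpha_params`: list with global `r0`, `m`,
#'   matrix `c` (`NA` where unavailable), per-colony table `local`
#'   (`row, col, r0_i, m_i, c_i, converged`), and matrix `window_end` of fit
#'   window end times.
#' @export
fit_alpha_two_stage <- function(rates, background = NULL,
                                m_init = 0.3, c_init = 0.05, min_points = 5L) {
  stopifnot(inherits(rates, "rate_series"))
  d <- dim(rates$rho)
  tt_all <- rates$times
  y_all <- rates$rho
  if (!is.null(background)) {
    stopifnot(all(dim(background) == d))
    y_all <- y_all / background
  }
  nr <- d[1]; nc <- d[2]
  cmat <- matrix(NA_real_, nr, nc)
  wend <- matrix(NA_real_, nr, nc)
  loc <- vector("list", nr * nc)
  k <- 0L
  windows <- vector("list", nr * nc)
  for (cc in seq_len(nc)) for (rr in seq_len(nr)) {
    k <- k + 1L
    y <- y_all[rr, cc, ]
    ok <- is.finite(y)
    if (sum(ok) < min_points) { loc[[k]] <- NULL; next }
    # window: start of series up to the (earliest) maximum, inclusive
    imax <- which.max(replace(y, !ok, -Inf))
    sel <- which(ok & seq_along(y) <= imax)
    if (length(sel) < min_points) { loc[[k]] <- NULL; next }
    windows[[k]] <- sel
    wend[rr, cc] <- tt_all[imax]
    p <- .fit_alpha_local(tt_all[sel], y[sel],
                          r0_init = max(y[sel]), m_init = m_init, c_init = c_init)
    loc[[k]] <- if (is.null(p)) {
      data.frame(row = rr, col = cc, r0_i = NA_real_, m_i = NA_real_,
                 c_i = NA_real_, converged = FALSE)
    } else {
      data.frame(row = rr, col = cc, r0_i = p[["r0"]], m_i = p[["m"]],
                 c_i = p[["c"]], converged = TRUE)
    }
  }
  local_tab <- do.call(rbind, loc[!vapply(loc, is.null, TRUE)])
  if (is.null(local_tab) || !any(local_tab$converged))
    stop("no colony-level adjustment fit converged")
  conv <- local_tab[local_tab$converged, ]
  r0 <- stats::median(conv$r0_i)
  m <- stats::median(conv$m_i)
  # stage 3: refit c per colony with global r0, m fixed
  k <- 0L
  for (cc in seq_len(nc)) for (rr in seq_len(nr)) {
    k <- k + 1L
    sel <- windows[[k]]
    if (is.null(sel)) next
    y <- y_all[rr, cc, sel]
    cmat[rr, cc] <- .refit_c(tt_all[sel], y, r0, m,
                             c_init = c_init)
  }
  structure(list(r0 = r0, m = m, c = cmat, local = local_tab,
                 window_end = wend),
            class = "alpha_params")
}

#' @export
print.alpha_params <- function(x, ...) {
  cat(sprintf("alpha_params: r0 = %.4g, m = %.4g per step; c fitted for %d colonies (median %.3g)\n",
              x$r0, x$m, sum(is.finite(x$c)), stats::median(x$c, na.rm = TRUE)))
  invisible(x)
}

#' Export fitted adjustment parameters
#'
#' Writes the per-colony physiological states together with the global rates
#' as a CSV (`row, col, c_i` plus columns `r0`, `m`).
#' @param params An `alpha_params` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_alpha_params <- function(params, path) {
  w <- which(is.finite(params$c), arr.ind = TRUE)
  dt <- data.table::data.table(row = w[, 1], col = w[, 2],
                               c_i = params$c[w], r0 = params$r0, m = params$m)
  data.table::setorderv(dt, c("row", "col"))
  data.table::fwrite(dt, path)
  invisible(path)
}
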