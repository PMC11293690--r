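#' Decompose model error into spatial and temporal views
#'
#' Computes the sum of squared errors between observed and predicted relative
#' growth rates, viewed per colony (summed over time), per time point (summed
#' over colonies), and in total. Cells where either array is non-finite are
#' excluded consistently from every view, so the two marginal views always sum
#' to the same total.
#'
#' @param rho Observed rates, array `[rows x cols x T]`.
#' @param rho_hat Predicted rates, same shape.
#' @return An object of class `fit_report`: list with `sse_spatial`
#'   (`[rows x cols]`), `sse_temporal` (length `T`), `sse_total`, `n_obs`,
#'   and placeholders `aic`, `n_params` (filled by the model fitters).
#' @export
sse_decompose <- function(rho, rho_hat) {
  if (!all(dim(rho) == dim(rho_hat)))
    stop("rho and rho_hat must have identical dimensions")
  resid2 <- (rho - rho_hat)^2
  resid2[!is.finite(resid2)] <- NA_real_
  spatial <- apply(resid2, c(1, 2), sum, na.rm = TRUE)
  temporal <- apply(resid2, 3L, sum, na.rm = TRUE)
  structure(list(sse_spatial = spatial, sse_temporal = temporal,
                 sse_total = sum(resid2, na.rm = TRUE),
                 n_obs = sum(is.finite(resid2)),
                 aic = NA_real_, n_params = NA_integer_),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("fit_report: SSE = %.6g over %d observations", x$sse_total, x$n_obs))
  if (is.finite(x$aic)) cat(sprintf(", AIC = %.6g (%d parameters)", x$aic, x$n_params))
  cat("\n")
  invisible(x)
}

#' Akaike information criterion for least-squares fits
#'
#' Gaussian-error convention: `AIC = n * log(SSE / n) + 2 * p`. Parameter
#' counts used for the model hierarchy (with `T` fitted time points, `n_c`
#' colonies and `L` layers): null `T`; adjustment + global multiplier
#' `T + 2 + n_c`; layered multiplier `L*T + 2 + n_c`; density-dependent one
#' more (`nu`); diffusion `7 + n_c`.
#'
#' @param sse_total Total sum of squared errors.
#' @param n_obs Number of observations (must exceed `n_params`).
#' @param n_params Number of fitted parameters.
#' @param sse_floor Lower guard on the SSE (default 1e-300) so a perfect fit
#'   yields a finite score.
#' @return The AIC value (lower is better).
#' @export
aic <- function(sse_total, n_obs, n_params, sse_floor = 1e-300) {
  if (n_obs <= n_params)
    warning("fewer observations than parameters; AIC is not meaningful")
  n_obs * log(max(sse_total, sse_floor) / n_obs) + 2 * n_params
}

#' Impact of resource diffusion by plate layer
#'
#' Summarises the diffusion term `D * (sbar - s)` at occupied cells: colonies
#' in each border-distance layer are averaged at each time point, then the
#' mean and variance across time are reported per layer. On plates fitted or
#' simulated with positive diffusivity the outermost layers show the largest
#' positive means (surplus resource flowing in from the colony-free border).
#'
#' @param s_field A `resource_field`.
#' @param D Diffusivity (lattice units^2 per step).
#' @return Data frame with columns `layer`, `mean`, `var`.
#' @export
diffusion_impact_by_layer <- function(s_field, D) {
  geometry <- s_field$geometry
  lay <- layer_matrix(geometry)
  occ_in <- .inner_slice(s_field$occupancy * 1, geometry) > 0
  nt <- dim(s_field$s)[3]
  nl <- n_layers(geometry)
  series <- matrix(NA_real_, nl, nt)
  for (k in seq_len(nt)) {
    sl <- s_field$s[, , k]
    term <- D * (mean_field_neighbors(sl) - sl)
    term_in <- .inner_slice(term, geometry)
    for (l in seq_len(nl)) {
      sel <- lay == l & occ_in
      if (any(sel)) series[l, k] <- mean(term_in[sel])
    }
  }
  data.frame(layer = seq_len(nl),
             mean = rowMeans(series, na.rm = TRUE),
             var = apply(series, 1L, stats::var, na.rm = TRUE))
}

#' Cumulative resource use for growth versus maintenance
#'
#' Using the fitted consumption rates and the measured population dynamics,
#' splits cumulative plate-wide resource use into the growth-coupled part
#' `G(t) = nu1 * (sum_i N_i(t) - sum_i N_i(0))` (a telescoping sum of
#' `nu1 * dN`) and the maintenance part
#' `M(t) = nu2 * sum_i sum_{t' <= t} N_i(t') dt'`.
#'
#' @param rates A `rate_series`.
#' @param nu1,nu2 Fitted consumption rates.
#' @return Data frame with columns `time`, `growth`, `maintenance`.
#' @export
resource_usage_split <- function(rates, nu1, nu2) {
  nt <- length(rates$times)
  Ntot <- apply(rates$N, 3L, sum, na.rm = TRUE)
  dt <- c(diff(rates$times)[1], diff(rates$times))
  growth <- nu1 * (Ntot - Ntot[1])
  maintenance <- nu2 * cumsum(Ntot * dt)
  data.frame(time = rates$times, growth = growth, maintenance = maintenance)
}

#' Pairwise percent changes of growth parameters across conditions
#'
#' Computes, for the global rates `r0` and `m`, all ordered condition pairs'
#' percentage ratio (`100 * to/from`) and percentage reduction
#' (`100 * (1 - to/from)`), rounded to integer percent. Reproduces statements
#' such as "salt reduces the glucose growth rate by ~56%" directly from a
#' fitted parameter table.
#'
#' @param param_table Data frame with a `condition` column and columns `r0`
#'   and `m` (one row per condition), as returned by [growth_param_table()].
#' @param params Which parameters to compare (default `c("r0", "m")`).
#' @return Data frame with columns `param`, `from`, `to`, `ratio_pct`,
#'   `reduction_pct` (both rounded to integers).
#' @export
condition_ratios <- function(param_table, params = c("r0", "m")) {
  if (!"condition" %in% names(param_table))
    stop("param_table needs a 'condition' column")
  missing_p <- setdiff(params, names(param_table))
  if (length(missing_p))
    stop("param_table lacks columns: ", paste(missing_p, collapse = ", "))
  conds <- param_table$condition
  if (length(conds) < 2L) stop("need at least two conditions")
  out <- list()
  for (p in params) {
    v <- stats::setNames(param_table[[p]], conds)
    for (a in conds) for (b in conds) {
      if (a == b) next
      out[[length(out) + 1L]] <- data.frame(
        param = p, from = a, to = b,
        ratio_pct = round(100 * v[[b]] / v[[a]]),
        reduction_pct = round(100 * (1 - v[[b]] / v[[a]])))
    }
  }
  do.call(rbind, out)
}

#' Master model-comparison table
#'
#' Collects per-model error reports into a single table (model, SSE, AIC,
#' parameter count), the layout used to compare the model hierarchy across
#' conditions.
#'
#' @param reports Named list of `fit_report` objects.
#' @param condition Optional condition label column.
#' @return Data frame with one row per model.
#' @export
model_comparison_table <- function(reports, condition = NA_character_) {
  do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(condition = condition, model = nm, sse = r$sse_total,
               aic = r$aic, n_params = r$n_params, n_obs = r$n_obs)
  }))
}
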