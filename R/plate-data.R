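#' Plate grid geometry
#'
#' Describes the colony grid of a solid-medium plate: grid dimensions, sampling
#' interval, centre-to-centre colony spacing and the number of empty padding
#' layers used when the grid is embedded in a larger lattice for resource
#' diffusion (a 32 x 48 grid with 3 padding layers yields a 38 x 54 lattice).
#'
#' @param n_rows,n_cols Number of grid rows / columns (default 32 x 48).
#' @param dt_minutes Sampling interval in minutes (default 20).
#' @param pitch_mm Centre-to-centre colony spacing in mm (default 2.25,
#'   i.e. 105.75 mm of grid width divided by 47 inter-colony intervals).
#' @param pad_layers Number of colony-free lattice layers added on every side
#'   for the diffusion model (default 3).
#' @return An object of class `plate_geometry`.
#' @examples
#' geom <- plate_geometry()
#' padded_dims(geom) # 38 54
#' @export
plate_geometry <- function(n_rows = 32L, n_cols = 48L, dt_minutes = 20,
                           pitch_mm = 2.25, pad_layers = 3L) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  pad_layers <- as.integer(pad_layers)
  if (n_rows < 1L || n_cols < 1L) stop("n_rows and n_cols must be >= 1")
  if (pad_layers < 1L) stop("pad_layers must be >= 1")
  if (dt_minutes <= 0) stop("dt_minutes must be > 0")
  if (pitch_mm <= 0) stop("pitch_mm must be > 0")
  structure(list(n_rows = n_rows, n_cols = n_cols, dt_minutes = dt_minutes,
                 pitch_mm = pitch_mm, pad_layers = pad_layers),
            class = "plate_geometry")
}

#' @rdname plate_geometry
#' @param geometry A `plate_geometry` object.
#' @export
padded_dims <- function(geometry) {
  c(geometry$n_rows + 2L * geometry$pad_layers,
    geometry$n_cols + 2L * geometry$pad_layers)
}

#' @export
print.plate_geometry <- function(x, ...) {
  cat(sprintf("plate_geometry: %d x %d grid, dt = %g min, pitch = %g mm, %d padding layers (%d x %d padded)\n",
              x$n_rows, x$n_cols, x$dt_minutes, x$pitch_mm, x$pad_layers,
              padded_dims(x)[1], padded_dims(x)[2]))
  invisible(x)
}

#' Plate growth time series
#'
#' Container for a grid of colony population-size time series. Population sizes
#' are background-subtracted, calibrated estimates in arbitrary units; time is
#' measured in sampling steps (one step = `geometry$dt_minutes`).
#'
#' @param N Numeric array `[n_rows x n_cols x T]` of population-size estimates
#'   (all values must be >= 0; unoccupied positions are 0).
#' @param geometry A [plate_geometry()].
#' @param condition Label of the growth condition (e.g. `"Glc"`).
#' @param times Numeric vector of time-step indices (length `T`); defaults to
#'   `0:(T-1)` so that `t = 0` is the first image.
#' @return An object of class `plate_series`.
#' @export
plate_series <- function(N, geometry, condition = "unknown", times = NULL) {
  if (!is.array(N) || length(dim(N)) != 3L)
    stop("N must be a 3-d array [rows x cols x time]")
  d <- dim(N)
  if (d[1] != geometry$n_rows || d[2] != geometry$n_cols)
    stop(sprintf("N has grid %d x %d but geometry says %d x %d",
                 d[1], d[2], geometry$n_rows, geometry$n_cols))
  if (d[3] < 2L) stop("need at least 2 time points")
  if (any(N < 0, na.rm = TRUE)) stop("population sizes must be non-negative")
  if (is.null(times)) times <- seq_len(d[3]) - 1
  if (length(times) != d[3]) stop("times length must match dim(N)[3]")
  structure(list(N = N, geometry = geometry, condition = condition,
                 times = as.numeric(times)),
            class = "plate_series")
}

#' @export
print.plate_series <- function(x, ...) {
  cat(sprintf("plate_series [%s]: %d x %d colonies, %d time points (t = %g..%g steps)\n",
              x$condition, dim(x$N)[1], dim(x$N)[2], dim(x$N)[3],
              min(x$times), max(x$times)))
  invisible(x)
}

# Moving average along the time axis of a (colonies x T) matrix.
# trailing: value at t averages samples t-window+1 .. t (window-end aligned);
# centered: symmetric window (window forward-heavy when even).
.moving_average <- function(mat, window, align) {
  Tn <- ncol(mat)
  kern <- rep(1 / window, window)
  sides <- if (align == "trailing") 1L else 2L
  sm <- t(apply(mat, 1L, function(x) as.numeric(stats::filter(x, kern, sides = sides))))
  if (align == "trailing") {
    keep <- window:Tn
  } else {
    half_l <- (window - 1L) %/% 2L        # stats::filter centres even windows forward
    half_r <- window %/% 2L
    keep <- (1L + half_l):(Tn - half_r)
  }
  list(values = sm[, keep, drop = FALSE], keep = keep)
}

#' Smooth colony growth curves
#'
#' Replaces each colony's population-size curve by its moving average (window
#' of 10 samples by default) and discards the last `drop_tail` points, the
#' standard preprocessing applied before any derivative is computed. The
#' default alignment is a trailing window (output aligned to the window end);
#' a centered window is available via `align`.
#'
#' @param plate A [plate_series()].
#' @param window Moving-average window length in samples (default 10).
#' @param drop_tail Number of trailing samples discarded after smoothing
#'   (default 10).
#' @param align `"trailing"` (default) or `"centered"` window alignment.
#' @return A smoothed [plate_series()] with updated `times`. With trailing
#'   alignment and `T` input samples the output has `T - window + 1 - drop_tail`
#'   samples covering times `window-1 .. T-1-drop_tail`.
#' @export
smooth_series <- function(plate, window = 10L, drop_tail = 10L,
                          align = c("trailing", "centered")) {
  align <- match.arg(align)
  stopifnot(inherits(plate, "plate_series"))
  window <- as.integer(window); drop_tail <- as.integer(drop_tail)
  Tn <- dim(plate$N)[3]
  if (Tn <= window + drop_tail)
    stop(sprintf("series too short: %d samples but window %d + drop_tail %d requires > %d",
                 Tn, window, drop_tail, window + drop_tail))
  d <- dim(plate$N)
  mat <- matrix(plate$N, nrow = d[1] * d[2], ncol = d[3])
  ma <- .moving_average(mat, window, align)
  vals <- ma$values
  keep_t <- plate$times[ma$keep]
  if (drop_tail > 0L) {
    ncol_out <- ncol(vals) - drop_tail
    vals <- vals[, seq_len(ncol_out), drop = FALSE]
    keep_t <- keep_t[seq_len(ncol_out)]
  }
  out <- array(vals, dim = c(d[1], d[2], ncol(vals)))
  plate_series(out, plate$geometry, plate$condition, times = keep_t)
}

#' Absolute and relative growth rates
#'
#' Computes per-colony absolute growth rates `dN(t) = (N(t) - N(t-1)) / dt`
#' (backward difference, `dt` in sampling-step units) and relative (per-capita)
#' growth rates `rho(t) = dN(t) / N(t)` from a (smoothed) plate series. Points
#' with non-positive population size are masked (`NA`), not zero-filled, so
#' they are excluded from all downstream fits.
#'
#' @param plate A smoothed [plate_series()].
#' @return An object of class `rate_series` with components `dN`, `rho`, `N`
#'   (population sizes aligned with the rates), `times` (the `T-1` retained
#'   time steps), `geometry`, `condition` and attribute `n_masked`.
#' @export
compute_rates <- function(plate) {
  stopifnot(inherits(plate, "plate_series"))
  N <- plate$N
  d <- dim(N)
  dt <- diff(plate$times)
  if (any(abs(dt - dt[1]) > 1e-9)) stop("times must be evenly spaced")
  dt <- dt[1]
  cur <- N[, , -1L, drop = FALSE]
  prev <- N[, , -d[3], drop = FALSE]
  dN <- (cur - prev) / dt
  rho <- dN / cur
  bad <- !(cur > 0 & is.finite(rho))
  n_masked <- sum(bad)
  rho[bad] <- NA_real_
  structure(list(dN = dN, rho = rho, N = cur, times = plate$times[-1L],
                 geometry = plate$geometry, condition = plate$condition),
            class = "rate_series", n_masked = n_masked)
}

#' @export
print.rate_series <- function(x, ...) {
  cat(sprintf("rate_series [%s]: %d x %d colonies, %d time points, %d masked values\n",
              x$condition, dim(x$rho)[1], dim(x$rho)[2], dim(x$rho)[3],
              attr(x, "n_masked")))
  invisible(x)
}

#' Border-distance layer of a grid position
#'
#' Colonies are grouped into layers of equal distance (in grid units) to the
#' nearest grid border: layer 1 is the border ring, layer 2 the next ring
#' inwards, and so on. A 32 x 48 grid has 16 distinct layers. Row/column
#' indices are 1-based.
#'
#' @param row,col Integer vectors of 1-based grid coordinates.
#' @param geometry A [plate_geometry()].
#' @return Integer vector of 1-based layer indices.
#' @export
layer_index <- function(row, col, geometry) {
  if (any(row < 1L | row > geometry$n_rows | col < 1L | col > geometry$n_cols))
    stop(sprintf("indices out of range for %d x %d grid",
                 geometry$n_rows, geometry$n_cols))
  as.integer(pmin(row - 1L, col - 1L,
                  geometry$n_rows - row, geometry$n_cols - col) + 1L)
}

#' @rdname layer_index
#' @export
layer_matrix <- function(geometry) {
  outer(seq_len(geometry$n_rows), seq_len(geometry$n_cols),
        function(r, c) layer_index(r, c, geometry))
}

#' @rdname layer_index
#' @export
n_layers <- function(geometry) {
  as.integer((min(geometry$n_rows, geometry$n_cols) - 1L) %/% 2L + 1L)
}

#' Deterministic spatial train/test split
#'
#' Divides the colony grid into contiguous non-overlapping 2 x 2 blocks and
#' assigns the bottom-right position of each block to the test set; the other
#' three positions form the training set. For a 32 x 48 grid this yields 1152
#' training and 384 test colonies (a fixed 75/25 split that is spatially
#' balanced).
#'
#' @param geometry A [plate_geometry()] with even `n_rows` and `n_cols`.
#' @return A list with logical matrix `test_mask` (`TRUE` for test positions)
#'   and data frames `train` and `test` of 1-based `(row, col)` coordinates.
#' @export
split_train_test <- function(geometry) {
  if (geometry$n_rows %% 2L != 0L || geometry$n_cols %% 2L != 0L)
    stop("train/test split requires even grid dimensions")
  test_mask <- outer(seq_len(geometry$n_rows) %% 2L == 0L,
                     seq_len(geometry$n_cols) %% 2L == 0L, `&`)
  idx <- function(mask) {
    w <- which(mask, arr.ind = TRUE)
    data.frame(row = as.integer(w[, 1]), col = as.integer(w[, 2]))
  }
  list(test_mask = test_mask, train = idx(!test_mask), test = idx(test_mask))
}

#' Default plate ordering of the four growth conditions
#'
#' The canonical plate-array stacking order of the four growth environments:
#' galactose + NaCl, glucose, glucose + NaCl, galactose.
#' @return Character vector of four condition labels.
#' @export
default_conditions <- function() c("Gal+NaCl", "Glc", "Glc+NaCl", "Gal")

#' Read and write plate arrays
#'
#' The on-disk container is a long-format CSV with columns
#' `plate, condition, row, col, t, N`, holding a rank-4 numeric array
#' (plates x rows x cols x time). Values round-trip exactly.
#'
#' @param x Numeric 4-d array `[n_plates x n_rows x n_cols x T]`.
#' @param path Path of the CSV file.
#' @param conditions Character vector of per-plate condition labels
#'   (default [default_conditions()] for 4 plates).
#' @return `write_plate_array` returns `path` invisibly.
#' @export
write_plate_array <- function(x, path, conditions = NULL) {
  if (!is.array(x) || length(dim(x)) != 4L)
    stop(sprintf("expected a rank-4 array (plates x rows x cols x time), got rank %d",
                 length(dim(x))))
  d <- dim(x)
  if (is.null(conditions)) {
    conditions <- if (d[1] == 4L) default_conditions() else paste0("plate", seq_len(d[1]))
  }
  if (length(conditions) != d[1]) stop("need one condition label per plate")
  grid <- expand.grid(plate = seq_len(d[1]), row = seq_len(d[2]),
                      col = seq_len(d[3]), t = seq_len(d[4]) - 1L,
                      KEEP.OUT.ATTRS = FALSE)
  dt <- data.table::data.table(plate = grid$plate,
                               condition = conditions[grid$plate],
                               row = grid$row, col = grid$col, t = grid$t,
                               N = sprintf("%.17g", as.vector(x)))  # lossless
  data.table::setorderv(dt, c("plate", "row", "col", "t"))
  data.table::fwrite(dt, path, quote = FALSE)
  invisible(path)
}

#' @rdname write_plate_array
#' @param plate_index 1-based index of the plate to extract.
#' @param geometry Optional [plate_geometry()]; defaults to the dimensions
#'   found in the file (with default padding).
#' @return `load_plate_array` returns a [plate_series()] for the selected
#'   plate, labelled with its stored condition.
#' @export
load_plate_array <- function(path, plate_index, geometry = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path)
  need <- c("plate", "condition", "row", "col", "t", "N")
  if (!all(need %in% names(dt)))
    stop("not a plate-array container: expected columns ", paste(need, collapse = ", "))
  n_plates <- max(dt$plate); n_rows <- max(dt$row); n_cols <- max(dt$col)
  n_t <- length(unique(dt$t))
  if (nrow(dt) != n_plates * n_rows * n_cols * n_t)
    stop(sprintf("malformed container: expected %d x %d x %d x %d = %d rows, found %d",
                 n_plates, n_rows, n_cols, n_t,
                 n_plates * n_rows * n_cols * n_t, nrow(dt)))
  if (plate_index < 1L || plate_index > n_plates)
    stop(sprintf("plate_index %d out of range: file holds %d plates (%d x %d x %d each)",
                 plate_index, n_plates, n_rows, n_cols, n_t))
  sub <- dt[dt$plate == plate_index, ]
  data.table::setorderv(sub, c("t", "col", "row"))  # array fill order
  arr <- array(sub$N, dim = c(n_rows, n_cols, n_t))
  if (is.null(geometry)) geometry <- plate_geometry(n_rows, n_cols)
  plate_series(arr, geometry, condition = sub$condition[1],
               times = sort(unique(sub$t)))
}
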