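#' Random-forest regression with impurity importances
#'
#' Thin wrapper around [randomForest::randomForest()] configured to mirror the
#' reference regressor used for the growth analyses: `ntree = 100`, all
#' features tried at every split, fixed seed. Reports train/test R^2 and
#' mean-decrease-in-impurity feature importances normalised to sum to one.
#'
#' @param features Data frame of predictor columns.
#' @param target Numeric response vector (same length).
#' @param train_idx,test_idx Integer (or logical) row indices of the spatial
#'   train/test split.
#' @param seed RNG seed (default 0); results are reproducible bit-for-bit.
#' @param ntree Number of trees (default 100).
#' @param mtry Features tried per split (default all).
#' @return List with `model`, `r2_train`, `r2_test`, `importance` (named,
#'   sums to 1). A constant target yields `NaN` R^2 with a warning.
#' @export
rf_regress <- function(features, target, train_idx, test_idx, seed = 0L,
                       ntree = 100L, mtry = ncol(features)) {
  stopifnot(nrow(features) == length(target))
  ok <- stats::complete.cases(features) & is.finite(target)
  keep <- function(idx) {
    if (is.logical(idx)) idx <- which(idx)
    idx[idx %in% which(ok)]
  }
  tr <- keep(train_idx); te <- keep(test_idx)
  if (length(tr) < 2L) stop("too few usable training rows")
  if (stats::var(target[tr]) == 0)
    warning("constant target: R^2 is undefined (reported as NaN)")
  set.seed(seed)
  model <- randomForest::randomForest(features[tr, , drop = FALSE], target[tr],
                                      ntree = ntree, mtry = mtry)
  r2 <- function(idx) {
    if (!length(idx)) return(NA_real_)
    pred <- stats::predict(model, features[idx, , drop = FALSE])
    sst <- sum((target[idx] - mean(target[idx]))^2)
    1 - sum((target[idx] - pred)^2) / sst
  }
  imp <- model$importance[, "IncNodePurity"]
  tot <- sum(imp)
  if (tot > 0) imp <- imp / tot
  list(model = model, r2_train = r2(tr), r2_test = r2(te), importance = imp)
}

#' Time-resolved feature importance for growth-rate prediction
#'
#' Runs one random-forest regression per time point, predicting the relative
#' growth rate from the colony position `(row, col)` and instantaneous
#' population size `N(t)`, and reports the R^2 trajectories together with
#' importances scaled by test R^2. Position importance is the sum of the row
#' and column importances. On plates with spatially structured physiological
#' states, position dominates early (lag phase), is replaced by population
#' size during the exponential phase, and returns during deceleration.
#'
#' @param rates A `rate_series`.
#' @param split A [split_train_test()] result.
#' @param times Subset of time indices to analyse (default: all).
#' @param seed,ntree Passed to [rf_regress()].
#' @return An object of class `importance_trace`: list with `times`,
#'   `r2_train`, `r2_test`, `importance` (raw, rows `row`, `col`, `N`),
#'   `scaled` (importance x test R^2) and `position` / `position_scaled`
#'   (row + col combined).
#' @export
timewise_importance <- function(rates, split, times = NULL, seed = 0L,
                                ntree = 100L) {
  d <- dim(rates$rho)
  if (is.null(times)) times <- seq_len(d[3])
  grid <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]),
                      KEEP.OUT.ATTRS = FALSE)
  test_vec <- split$test_mask[cbind(grid$row, grid$col)]
  r2_train <- r2_test <- rep(NA_real_, length(times))
  imp <- matrix(NA_real_, 3L, length(times),
                dimnames = list(c("row", "col", "N"), NULL))
  for (j in seq_along(times)) {
    k <- times[j]
    y <- as.vector(rates$rho[, , k])
    feat <- data.frame(row = grid$row, col = grid$col,
                       N = as.vector(rates$N[, , k]))
    ok <- is.finite(y)
    if (sum(ok & !test_vec) < 5L || stats::var(y[ok & !test_vec]) == 0) next
    fit <- rf_regress(feat, y, which(!test_vec & ok), which(test_vec & ok),
                      seed = seed, ntree = ntree)
    r2_train[j] <- fit$r2_train
    r2_test[j] <- fit$r2_test
    imp[, j] <- fit$importance[c("row", "col", "N")]
  }
  scaled <- sweep(imp, 2L, r2_test, `*`)
  structure(list(times = rates$times[times], r2_train = r2_train,
                 r2_test = r2_test, importance = imp, scaled = scaled,
                 position = imp["row", ] + imp["col", ],
                 position_scaled = scaled["row", ] + scaled["col", ]),
            class = "importance_trace")
}

#' Per-colony growth summary statistics
#'
#' Computes the key summary values of each growth curve: final population
#' size (yield), maximum relative growth rate and its timing, plus the
#' initial population size and initial absolute growth rate used as
#' predictors.
#'
#' @param rates A `rate_series`.
#' @return List of matrices `yield`, `rho_max`, `t_rho_max`, `N0`, `dN0`.
#' @export
summary_stats <- function(rates) {
  d <- dim(rates$rho)
  nt <- d[3]
  yield <- rates$N[, , nt]
  rho_max <- apply(rates$rho, c(1, 2), function(x)
    if (all(!is.finite(x))) NA_real_ else max(x, na.rm = TRUE))
  t_idx <- apply(rates$rho, c(1, 2), function(x)
    if (all(!is.finite(x))) NA_integer_ else which.max(replace(x, !is.finite(x), -Inf)))
  t_rho_max <- matrix(rates$times[t_idx], d[1], d[2])
  list(yield = yield, rho_max = rho_max, t_rho_max = t_rho_max,
       N0 = rates$N[, , 1], dN0 = rates$dN[, , 1])
}

#' Regressions of growth summary values on initial conditions
#'
#' Trains three random-forest regressions predicting yield, maximum relative
#' growth rate and its timing from colony position, initial population size
#' and initial growth increment. Reports per-target train/test R^2 and
#' importances (scaled by test R^2).
#'
#' @param rates A `rate_series`.
#' @param split A [split_train_test()] result.
#' @param seed,ntree Passed to [rf_regress()].
#' @return Named list (`yield`, `rho_max`, `t_rho_max`), each with
#'   `r2_train`, `r2_test`, `importance`, `scaled`.
#' @export
summary_regressions <- function(rates, split, seed = 0L, ntree = 100L) {
  st <- summary_stats(rates)
  d <- dim(rates$rho)
  grid <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]),
                      KEEP.OUT.ATTRS = FALSE)
  feat <- data.frame(row = grid$row, col = grid$col,
                     N0 = as.vector(st$N0), dN0 = as.vector(st$dN0))
  test_vec <- split$test_mask[cbind(grid$row, grid$col)]
  run <- function(target) {
    y <- as.vector(target)
    ok <- is.finite(y)
    fit <- rf_regress(feat, y, which(!test_vec & ok), which(test_vec & ok),
                      seed = seed, ntree = ntree)
    list(r2_train = fit$r2_train, r2_test = fit$r2_test,
         importance = fit$importance,
         scaled = fit$importance * fit$r2_test)
  }
  list(yield = run(st$yield), rho_max = run(st$rho_max),
       t_rho_max = run(st$t_rho_max))
}

#' Drivers of the physiological-state parameter
#'
#' Three random-forest regressions probing what explains the per-colony
#' physiological states: position to state (`x -> c`), initial size to state
#' (`N0 -> c`) and position to initial size (`x -> N0`). Returns the
#' train/test R^2 table; negative test R^2 is reported as-is.
#'
#' @param c_field Matrix of fitted (or true) physiological states.
#' @param N0_field Matrix of initial population sizes.
#' @param geometry A [plate_geometry()].
#' @param split A [split_train_test()] result.
#' @param seed,ntree Passed to [rf_regress()].
#' @return Data frame with columns `model`, `r2_train`, `r2_test`.
#' @export
c_driver_regressions <- function(c_field, N0_field, geometry, split,
                                 seed = 0L, ntree = 100L) {
  grid <- expand.grid(row = seq_len(geometry$n_rows),
                      col = seq_len(geometry$n_cols), KEEP.OUT.ATTRS = FALSE)
  test_vec <- split$test_mask[cbind(grid$row, grid$col)]
  cvec <- as.vector(c_field); n0 <- as.vector(N0_field)
  run <- function(feat, y) {
    ok <- stats::complete.cases(feat) & is.finite(y)
    rf_regress(feat, y, which(!test_vec & ok), which(test_vec & ok),
               seed = seed, ntree = ntree)
  }
  m1 <- run(data.frame(row = grid$row, col = grid$col), cvec)
  m2 <- run(data.frame(N0 = n0), cvec)
  m3 <- run(data.frame(row = grid$row, col = grid$col), n0)
  data.frame(model = c("x -> c", "N0 -> c", "x -> N0"),
             r2_train = c(m1$r2_train, m2$r2_train, m3$r2_train),
             r2_test = c(m1$r2_test, m2$r2_test, m3$r2_test))
}
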