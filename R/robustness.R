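#' Enumerate the setup/range uncertainty scenarios
#'
#' The Cartesian product of 3 range errors (0, +3%, -3%) and 7 setup shifts
#' (zero shift, then +/-3 mm along each principal axis) — 21 scenarios with a
#' unique nominal member, ordered range-major with the zero shift first, then
#' axis, then sign.
#'
#' @param range_levels range-error fractions.
#' @param shift_mm setup shift magnitude, mm.
#' @return A data.frame of class `scenario_set` with columns `range_scale`,
#'   `shift_x`, `shift_y`, `shift_z`, `nominal`.
#' @export
enumerate_scenarios <- function(range_levels = c(0, 0.03, -0.03),
                                shift_mm = 3) {
  shifts <- rbind(c(0, 0, 0),
                  c(+shift_mm, 0, 0), c(-shift_mm, 0, 0),
                  c(0, +shift_mm, 0), c(0, -shift_mm, 0),
                  c(0, 0, +shift_mm), c(0, 0, -shift_mm))
  out <- do.call(rbind, lapply(range_levels, function(r)
    data.frame(range_scale = r, shift_x = shifts[, 1], shift_y = shifts[, 2],
               shift_z = shifts[, 3])))
  out$nominal <- out$range_scale == 0 & out$shift_x == 0 & out$shift_y == 0 &
    out$shift_z == 0
  class(out) <- c("scenario_set", "data.frame")
  out
}

# trilinear resampling of a 3-D field at positions displaced by `disp_vox`
# (in voxel units per axis), with edge-value padding
.translate_trilinear <- function(values, disp_vox) {
  d <- dim(values)
  out <- values
  ax <- lapply(1:3, function(a) seq_len(d[a]) - disp_vox[a])
  lo <- lapply(1:3, function(a) pmin(pmax(floor(ax[[a]]), 1L), d[a]))
  hi <- lapply(1:3, function(a) pmin(lo[[a]] + 1L, d[a]))
  fr <- lapply(1:3, function(a) pmin(pmax(ax[[a]] - floor(ax[[a]]), 0), 1))
  g <- function(ix, iy, iz) values[ix, iy, iz, drop = FALSE]
  fx <- array(rep(fr[[1]], times = d[2] * d[3]), d)
  fy <- array(rep(rep(fr[[2]], each = d[1]), times = d[3]), d)
  fz <- array(rep(fr[[3]], each = d[1] * d[2]), d)
  c000 <- g(lo[[1]], lo[[2]], lo[[3]]); c100 <- g(hi[[1]], lo[[2]], lo[[3]])
  c010 <- g(lo[[1]], hi[[2]], lo[[3]]); c110 <- g(hi[[1]], hi[[2]], lo[[3]])
  c001 <- g(lo[[1]], lo[[2]], hi[[3]]); c101 <- g(hi[[1]], lo[[2]], hi[[3]])
  c011 <- g(lo[[1]], hi[[2]], hi[[3]]); c111 <- g(hi[[1]], hi[[2]], hi[[3]])
  (1 - fz) * ((1 - fy) * ((1 - fx) * c000 + fx * c100) +
                fy * ((1 - fx) * c010 + fx * c110)) +
    fz * ((1 - fy) * ((1 - fx) * c001 + fx * c101) +
            fy * ((1 - fx) * c011 + fx * c111))
}

#' Apply an uncertainty scenario to a dose distribution
#'
#' A surrogate for scenario dose recomputation: the setup error translates
#' the dose field by the negated shift (trilinear resampling, edge-value
#' padding), and the range error translates it along the beam axis by
#' `range_scale * nominal_range_mm`. The nominal scenario returns the input
#' unchanged.
#'
#' @param dose a [scalar_volume()] of dose.
#' @param scenario one row of [enumerate_scenarios()] (or a list with
#'   `range_scale`, `shift_x`, `shift_y`, `shift_z`).
#' @param beam_axis axis (1, 2 or 3) along which range errors act.
#' @param nominal_range_mm nominal beam range, mm; the range error shifts the
#'   field by `range_scale` times this length.
#' @return A dose [scalar_volume()] on the same grid.
#' @export
apply_scenario <- function(dose, scenario, beam_axis = 1,
                           nominal_range_mm = 150) {
  stopifnot(inherits(dose, "scalar_volume"))
  shift_mm <- c(scenario$shift_x, scenario$shift_y, scenario$shift_z)
  if (any(abs(shift_mm) >= dose$grid$shape * dose$grid$spacing))
    stop("setup shift exceeds the grid extent")
  disp_mm <- -shift_mm
  disp_mm[beam_axis] <- disp_mm[beam_axis] +
    scenario$range_scale * nominal_range_mm
  if (all(disp_mm == 0)) return(dose)
  vals <- .translate_trilinear(dose$values, disp_mm / dose$grid$spacing)
  scalar_volume(vals, dose$grid, dose$quantity)
}

#' Cell-count uncertainty model
#'
#' Gaussian curves mapping the voxel ADC-fit RMSE to multiplicative
#' cell-count weights: at zero RMSE the weight is 1 (nominal); as RMSE grows
#' the best-case weight falls toward 0.5 and the worst-case weight rises
#' toward 1.5. `sigma` is the standard deviation of the pooled RMSE
#' distribution of the fitting cohort.
#'
#' @param sigma RMSE scale (> 0).
#' @param low_bound,high_bound weight asymptotes (fixed at 0.5 and 1.5 in the
#'   protocol).
#' @return An object of class `uncertainty_model`.
#' @export
uncertainty_model <- function(sigma, low_bound = 0.5, high_bound = 1.5) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive")
  structure(list(sigma = sigma, low_bound = low_bound,
                 high_bound = high_bound), class = "uncertainty_model")
}

#' Pooled RMSE standard deviation of a cohort
#'
#' Convenience for building the default [uncertainty_model()]: the standard
#' deviation of all in-GTV RMSE values pooled over the fitting cohort.
#'
#' @param cohort list of records from [make_cohort()].
#' @return Scalar standard deviation.
#' @export
pooled_rmse_sd <- function(cohort) {
  stats::sd(unlist(lapply(cohort, function(r)
    r$rmse_map$values[r$structures$masks$GTV])))
}

#' RMSE-to-weight mapping
#'
#' `best:  w(r) = 0.5 + 0.5 * exp(-r^2 / (2 sigma^2))` and
#' `worst: w(r) = 1.5 - 0.5 * exp(-r^2 / (2 sigma^2))`:
#' both equal 1 at `r = 0`, are monotone in `r`, and are bounded by
#' `(0.5, 1.5)`; best + worst = 2 at every RMSE.
#'
#' @param rmse non-negative RMSE value(s).
#' @param model an [uncertainty_model()].
#' @param mode `"best"` or `"worst"`.
#' @return Weight(s) in `[0.5, 1.5]`, shaped like `rmse`.
#' @export
uncertainty_weight <- function(rmse, model, mode = c("best", "worst")) {
  stopifnot(inherits(model, "uncertainty_model"))
  mode <- match.arg(mode)
  if (any(rmse < 0)) stop("rmse must be non-negative")
  gauss <- exp(-rmse^2 / (2 * model$sigma^2))
  half <- (model$high_bound - model$low_bound) / 2
  if (mode == "best") model$low_bound + half * gauss
  else model$high_bound - half * gauss
}

#' Best- and worst-case cell-count maps
#'
#' Scales the nominal clonogen map voxel-wise by the best-case and worst-case
#' RMSE weights, giving `best <= nominal <= worst` everywhere.
#'
#' @param cell_map nominal clonogen-count [scalar_volume()].
#' @param rmse_map RMSE [scalar_volume()] on the same grid.
#' @param model an [uncertainty_model()].
#' @return List with `best` and `worst` [scalar_volume()]s.
#' @export
scaled_cell_maps <- function(cell_map, rmse_map, model) {
  stopifnot(inherits(cell_map, "scalar_volume"),
            inherits(rmse_map, "scalar_volume"))
  stop_if_grid_mismatch(cell_map$grid, rmse_map$grid, "cell and RMSE maps")
  w_best <- uncertainty_weight(rmse_map$values, model, "best")
  w_worst <- uncertainty_weight(rmse_map$values, model, "worst")
  list(best = scalar_volume(cell_map$values * w_best, cell_map$grid,
                            "cells_per_voxel"),
       worst = scalar_volume(cell_map$values * w_worst, cell_map$grid,
                             "cells_per_voxel"))
}

#' TCP uncertainty range under cell-count scaling
#'
#' Evaluates the ROI TCP of a fixed (nominally optimized) dose distribution
#' under the best-case, nominal, and worst-case clonogen maps. More clonogens
#' mean lower TCP, so `best >= nominal >= worst`.
#'
#' @param plan a `plan` (or dose [scalar_volume()]) optimized on the nominal
#'   map.
#' @param cell_map nominal clonogen map.
#' @param rmse_map RMSE map.
#' @param model an [uncertainty_model()].
#' @param params a [tcp_params()].
#' @param scheme a [fractionation_scheme()].
#' @param mask logical ROI mask (e.g. GTV).
#' @return Named numeric vector `c(best, nominal, worst)` of ROI TCPs in
#'   percent.
#' @export
tcp_uncertainty_range <- function(plan, cell_map, rmse_map, model, params,
                                  scheme, mask) {
  maps <- scaled_cell_maps(cell_map, rmse_map, model)
  c(best = plan_tcp(plan, maps$best, mask, params, scheme)$roi_tcp,
    nominal = plan_tcp(plan, cell_map, mask, params, scheme)$roi_tcp,
    worst = plan_tcp(plan, maps$worst, mask, params, scheme)$roi_tcp)
}
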