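#' Protocol specification
#'
#' The institutional prescription and painting constraints: prescription dose
#' `Dp` (default 73.6 Gy(RBE) in the 16-fraction carbon-ion protocol),
#' per-voxel painting bounds as fractions of `Dp` (95% to 110%), the target
#' GTV mean dose as a fraction of `Dp` (1.03 for dose escalation, 1.00 for
#' dose redistribution and uniform plans), and the evaluation-only minimum
#' LET objective.
#'
#' @param Dp prescription dose, Gy(RBE).
#' @param bound_low_frac,bound_high_frac painting box as fractions of `Dp`.
#' @param mean_frac target GTV mean dose as a fraction of `Dp`.
#' @param let_objective minimum GTV LET_d objective, keV/um (audited, not
#'   optimized).
#' @param penumbra_mm Gaussian fall-off sigma outside the CTV_LD, mm
#'   (ideal-painting surrogate for the lateral/distal dose gradient).
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(Dp = 73.6, bound_low_frac = 0.95,
                          bound_high_frac = 1.10, mean_frac = 1.00,
                          let_objective = 43, penumbra_mm = 6) {
  if (Dp <= 0) stop("Dp must be positive")
  if (!(bound_low_frac > 0 && bound_low_frac <= mean_frac &&
        mean_frac <= bound_high_frac))
    stop("need 0 < bound_low_frac <= mean_frac <= bound_high_frac")
  structure(list(Dp = Dp, bound_low_frac = bound_low_frac,
                 bound_high_frac = bound_high_frac, mean_frac = mean_frac,
                 let_objective = let_objective, penumbra_mm = penumbra_mm),
            class = "protocol_spec")
}

new_plan <- function(dose, mode, achieved, letd = NULL) {
  structure(list(dose = dose, letd = letd, mode = mode, achieved = achieved),
            class = "plan")
}

#' @export
print.plan <- function(x, ...) {
  cat(sprintf("plan [%s]: dose range [%.2f, %.2f] Gy(RBE)\n", x$mode,
              min(x$dose$values), max(x$dose$values)))
  if (!is.null(x$achieved$mean_gtv_dose))
    cat(sprintf("  mean GTV dose %.4f Gy(RBE), objective %.6g\n",
                x$achieved$mean_gtv_dose,
                if (is.null(x$achieved$objective)) NA else x$achieved$objective))
  invisible(x)
}

# 6-neighbour binary dilation by one voxel
.dilate6 <- function(mask) {
  out <- mask
  d <- dim(mask)
  out[-1, , ] <- out[-1, , ] | mask[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | mask[-1, , ]
  out[, -1, ] <- out[, -1, ] | mask[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | mask[, -1, ]
  out[, , -1] <- out[, , -1] | mask[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | mask[, , -1]
  out
}

# Gaussian penumbra outside a mask: Dp inside, Dp*exp(-r^2/(2w^2)) outside,
# with r approximated by ring-distance from iterated one-voxel dilations.
.penumbra_dose <- function(mask, grid, Dp, penumbra_mm) {
  dose <- array(0, dim = grid$shape)
  dose[mask] <- Dp
  if (penumbra_mm <= 0) return(dose)
  step_mm <- min(grid$spacing)
  n_rings <- ceiling(3 * penumbra_mm / step_mm)
  cur <- mask
  for (k in seq_len(n_rings)) {
    nxt <- .dilate6(cur)
    ring <- nxt & !cur
    if (!any(ring)) break
    dose[ring] <- Dp * exp(-(k * step_mm)^2 / (2 * penumbra_mm^2))
    cur <- nxt
  }
  dose
}

#' Uniform reference plan
#'
#' The standard-of-care plan in ideal-painting mode: the prescription dose on
#' every CTV_LD voxel with a Gaussian fall-off outside (surrogate penumbra).
#'
#' @param structures a [structure_set()] containing `CTV_LD`.
#' @param protocol a [protocol_spec()].
#' @return A `plan` with mode `"uniform"`.
#' @export
uniform_plan <- function(structures, protocol = protocol_spec()) {
  stopifnot(inherits(structures, "structure_set"))
  if (is.null(structures$masks$CTV_LD)) stop("CTV_LD structure required")
  grid <- structures$grid
  dose <- .penumbra_dose(structures$masks$CTV_LD, grid, protocol$Dp,
                         protocol$penumbra_mm)
  gtv <- structures$masks$GTV
  achieved <- list(
    mean_gtv_dose = if (!is.null(gtv)) mean(dose[gtv]) else NA_real_,
    mean_residual = 0, objective = NULL)
  new_plan(scalar_volume(dose, grid, "dose_Gy_RBE"), "uniform", achieved)
}

#' Solve a separable convex objective under box and mean constraints
#'
#' Minimizes `sum(w_i * F_i(d_i))` subject to `lo <= d_i <= hi` and weighted
#' mean `sum(w_i d_i)/sum(w_i) = mean_target`, for per-voxel objectives that
#' are smooth, strictly decreasing and convex on the box (the voxel survival
#' curves are). The KKT system reduces to one scalar multiplier: for each
#' `lambda`, the voxel dose solves `F_i'(d) = -lambda` clipped to the box;
#' the multiplier is found by bisection on the mean constraint. Falls back to
#' projected gradient descent if bisection fails to bracket.
#'
#' @param deriv vectorized derivative spec: `deriv(d)` returns `F_i'(d_i)`
#'   for the current dose vector `d` (one value per voxel, all negative and
#'   increasing in `d`).
#' @param lo,hi box bounds, Gy(RBE).
#' @param mean_target required weighted mean dose, Gy(RBE); must lie inside
#'   `[lo, hi]`.
#' @param weights per-voxel volume weights (default equal).
#' @param n_voxels number of voxels (needed when `weights` is default).
#' @param tol_mean tolerance on the achieved mean, Gy.
#' @param tol_lambda relative bisection tolerance on the multiplier.
#' @param objective optional vectorized `F(d)` used only for the fallback and
#'   the reported objective value.
#' @return List with `dose`, `lambda`, `mean_residual`, `iterations`,
#'   `method`.
#' @export
solve_box_mean <- function(deriv, lo, hi, mean_target, weights = NULL,
                           n_voxels = NULL, tol_mean = 0.01,
                           tol_lambda = 1e-8, objective = NULL) {
  if (is.null(n_voxels)) n_voxels <- length(weights)
  if (is.null(n_voxels) || n_voxels < 1) stop("n_voxels required")
  if (is.null(weights)) weights <- rep(1, n_voxels)
  weights <- weights / sum(weights)
  if (mean_target < lo - 1e-12 || mean_target > hi + 1e-12)
    stop(sprintf("infeasible: mean target %.4g outside box [%.4g, %.4g]",
                 mean_target, lo, hi))

  # voxel dose at a given multiplier: solve F'(d) = -lambda on [lo, hi]
  dose_at <- function(lambda) {
    dlo <- rep(lo, n_voxels); dhi <- rep(hi, n_voxels)
    g_lo <- deriv(dlo); g_hi <- deriv(dhi)
    at_lo <- g_lo >= -lambda   # derivative already too shallow: clip low
    at_hi <- g_hi <= -lambda   # still steep at hi: clip high
    d <- rep(NA_real_, n_voxels)
    d[at_lo] <- lo; d[at_hi] <- hi
    free <- !(at_lo | at_hi)
    if (any(free)) {
      a <- rep(lo, sum(free)); b <- rep(hi, sum(free))
      dl_free <- function(dfull, sub) { x <- rep(lo, n_voxels); x[free] <- sub
        deriv(x)[free] }
      for (it in 1:60) {
        m <- (a + b) / 2
        gm <- dl_free(NULL, m)
        below <- gm < -lambda
        a[below] <- m[below]; b[!below] <- m[!below]
      }
      d[free] <- (a + b) / 2
    }
    d
  }
  wmean <- function(d) sum(weights * d)

  lam_lo <- 0                       # lambda = 0: every voxel at hi
  lam_hi <- max(-deriv(rep(lo, n_voxels)))  # all voxels clipped to lo
  if (lam_hi <= 0 || wmean(dose_at(lam_hi)) > mean_target + tol_mean ||
      wmean(dose_at(lam_lo)) < mean_target - tol_mean) {
    # non-bracketing: projected gradient fallback
    if (is.null(objective))
      stop("bisection failed to bracket and no objective given for fallback")
    d <- rep(mean_target, n_voxels)
    step <- (hi - lo) / 10
    for (it in 1:2000) {
      g <- deriv(d)
      d_new <- d - step * g
      # project onto {box, mean}: alternate clipping and mean recentring
      for (j in 1:50) {
        d_new <- pmin(pmax(d_new, lo), hi)
        d_new <- d_new + (mean_target - wmean(d_new))
      }
      d_new <- pmin(pmax(d_new, lo), hi)
      if (max(abs(d_new - d)) < 1e-10) { d <- d_new; break }
      d <- d_new
    }
    return(list(dose = d, lambda = NA_real_,
                mean_residual = wmean(d) - mean_target, iterations = it,
                method = "projected_gradient"))
  }

  it <- 0L
  repeat {
    it <- it + 1L
    lam <- (lam_lo + lam_hi) / 2
    d <- dose_at(lam)
    m <- wmean(d)
    if (m > mean_target) lam_lo <- lam else lam_hi <- lam
    if ((lam_hi - lam_lo) <= tol_lambda * max(lam_hi, 1) || it >= 200) break
  }
  d <- dose_at((lam_lo + lam_hi) / 2)
  list(dose = d, lambda = (lam_lo + lam_hi) / 2,
       mean_residual = wmean(d) - mean_target, iterations = it,
       method = "kkt_bisection")
}

# shared painting driver for DE and DR
.paint_plan <- function(cell_map, structures, protocol, scheme, params,
                        mode) {
  stopifnot(inherits(cell_map, "scalar_volume"),
            inherits(structures, "structure_set"),
            inherits(protocol, "protocol_spec"))
  stop_if_grid_mismatch(cell_map$grid, structures$grid,
                        "cell map and structures")
  gtv <- structures$masks$GTV
  if (is.null(gtv)) stop("GTV structure required")
  lo <- protocol$bound_low_frac * protocol$Dp
  hi <- protocol$bound_high_frac * protocol$Dp
  m_target <- protocol$mean_frac * protocol$Dp
  if (m_target < lo || m_target > hi)
    stop("infeasible protocol: mean target outside the painting box")

  counts <- cell_map$values[gtv]
  pos <- counts > 0
  if (!any(pos)) stop("no GTV voxel carries a positive clonogen count")
  n_gtv <- length(counts)
  doses <- rep(lo, n_gtv)       # zero-clonogen voxels: no TCP benefit, floor
  n0 <- sum(!pos)
  m_sub <- (m_target * n_gtv - lo * n0) / (n_gtv - n0)
  if (m_sub > hi)
    stop("infeasible: too many zero-count voxels for the mean target")

  d50 <- d50_of_count(counts[pos], params)
  k <- .k_gamma(params$gamma)
  eg <- exp(params$gamma)
  surv <- function(d) {
    e <- eqd(d, scheme)
    exp(eg - (e / d50) * k)
  }
  dsurv <- function(d) {
    e <- eqd(d, scheme)
    de <- (2 * d / scheme$n_fractions + scheme$alpha_beta) /
      (scheme$d_ref + scheme$alpha_beta)
    -(k / d50) * de * exp(eg - (e / d50) * k)
  }
  sol <- solve_box_mean(dsurv, lo, hi, m_sub, n_voxels = sum(pos),
                        objective = surv)
  doses[pos] <- sol$dose

  # assemble: painted GTV on top of the uniform base plan
  base <- uniform_plan(structures, protocol_spec(
    Dp = protocol$Dp, bound_low_frac = protocol$bound_low_frac,
    bound_high_frac = protocol$bound_high_frac, mean_frac = 1,
    let_objective = protocol$let_objective,
    penumbra_mm = protocol$penumbra_mm))
  dose_arr <- base$dose$values
  dose_arr[gtv] <- doses
  objective <- mean(c(surv(doses[pos]), numeric(0))) * (sum(pos) / n_gtv)
  achieved <- list(
    mean_gtv_dose = mean(doses),
    mean_residual = mean(doses) - m_target,
    box = c(lo = lo, hi = hi),
    box_violation = max(0, lo - min(doses), max(doses) - hi),
    objective = objective,
    lambda = sol$lambda, iterations = sol$iterations, method = sol$method,
    n_zero_count = n0)
  new_plan(scalar_volume(dose_arr, structures$grid, "dose_Gy_RBE"), mode,
           achieved)
}

#' Dose-escalation (DE) plan
#'
#' Minimizes the volume-weighted GTV survival `sum(S_i v_i / V_GTV)` over
#' per-voxel doses, subject to the painting box (95-110% of `Dp`) and a GTV
#' mean dose of 103% of `Dp`. Voxels outside the GTV keep the uniform plan's
#' dose. Voxels with higher clonogen count never receive less dose than
#' voxels with lower count.
#'
#' @param cell_map clonogen-count [scalar_volume()].
#' @param structures a [structure_set()] with `GTV` and `CTV_LD`.
#' @param protocol a [protocol_spec()]; its `mean_frac` is overridden to 1.03.
#' @param scheme a [fractionation_scheme()].
#' @param params a [tcp_params()].
#' @return A `plan` with mode `"DE"`.
#' @export
optimize_de <- function(cell_map, structures, protocol = protocol_spec(),
                        scheme = fractionation_scheme(),
                        params = tcp_params()) {
  protocol <- protocol_spec(Dp = protocol$Dp,
                            bound_low_frac = protocol$bound_low_frac,
                            bound_high_frac = protocol$bound_high_frac,
                            mean_frac = 1.03,
                            let_objective = protocol$let_objective,
                            penumbra_mm = protocol$penumbra_mm)
  .paint_plan(cell_map, structures, protocol, scheme, params, "DE")
}

#' Dose-redistribution (DR) plan
#'
#' As [optimize_de()] but holding the GTV mean dose at the prescription
#' (100% of `Dp`): dose is moved from low-count to high-count voxels at
#' constant mean.
#'
#' @inheritParams optimize_de
#' @return A `plan` with mode `"DR"`.
#' @export
optimize_dr <- function(cell_map, structures, protocol = protocol_spec(),
                        scheme = fractionation_scheme(),
                        params = tcp_params()) {
  protocol <- protocol_spec(Dp = protocol$Dp,
                            bound_low_frac = protocol$bound_low_frac,
                            bound_high_frac = protocol$bound_high_frac,
                            mean_frac = 1.00,
                            let_objective = protocol$let_objective,
                            penumbra_mm = protocol$penumbra_mm)
  .paint_plan(cell_map, structures, protocol, scheme, params, "DR")
}
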