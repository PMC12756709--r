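#' Fractionation scheme
#'
#' Describes how the RBE-weighted total dose is delivered: number of
#' fractions, the reference fraction dose used for equieffective-dose
#' conversion, and the linear-quadratic alpha/beta ratio. The defaults are
#' the institutional sacral-chordoma carbon-ion protocol: 16 fractions of
#' 4.6 Gy(RBE) with alpha/beta = 2 Gy.
#'
#' @param n_fractions number of fractions (>= 1).
#' @param d_ref reference fraction dose, Gy(RBE).
#' @param alpha_beta LQ alpha/beta ratio, Gy.
#' @return An object of class `fractionation_scheme`.
#' @export
fractionation_scheme <- function(n_fractions = 16, d_ref = 4.6,
                                 alpha_beta = 2) {
  if (n_fractions < 1 || n_fractions != round(n_fractions))
    stop("n_fractions must be a positive integer")
  if (d_ref <= 0) stop("d_ref must be positive")
  if (alpha_beta <= 0) stop("alpha_beta must be positive")
  structure(list(n_fractions = as.integer(n_fractions), d_ref = d_ref,
                 alpha_beta = alpha_beta), class = "fractionation_scheme")
}

#' TCP model parameters
#'
#' Parameters of the cell-count-dependent Poisson TCP model: `gamma` sets the
#' steepness of the voxel dose-response, `delta` (Gy(RBE)) and `phi` set the
#' voxel D50 through `D50 = delta * (1 + phi * log(c))` where `c` is the
#' clonogen count of the voxel, and `clonogenic_fraction` converts total cell
#' counts to clonogen counts (1% by default).
#'
#' The default `(gamma, delta, phi)` are calibrated so that a uniform plan at
#' the 73.6 Gy(RBE) prescription on the default synthetic phantom yields a
#' GTV TCP of about 75%, the operating point of a uniform-dose plan in this
#' protocol; they are fully overridable.
#'
#' @param gamma dimensionless slope parameter (> 0).
#' @param delta Gy(RBE), D50 at one clonogen (> 0).
#' @param phi dimensionless log-count coefficient.
#' @param clonogenic_fraction fraction of cells that are clonogenic, in (0, 1].
#' @return An object of class `tcp_params`.
#' @export
tcp_params <- function(gamma = 2.0, delta = 37.62, phi = 0.06,
                       clonogenic_fraction = 0.01) {
  if (gamma <= 0) stop("gamma must be positive")
  if (delta <= 0) stop("delta must be positive")
  if (clonogenic_fraction <= 0 || clonogenic_fraction > 1)
    stop("clonogenic_fraction must lie in (0, 1]")
  structure(list(gamma = gamma, delta = delta, phi = phi,
                 clonogenic_fraction = clonogenic_fraction),
            class = "tcp_params")
}

#' Equieffective dose at the reference fraction dose
#'
#' Converts an RBE-weighted total dose delivered in `scheme$n_fractions`
#' fractions into the equieffective total dose at the reference fraction dose
#' via the linear-quadratic model:
#' `EQD = D * (D/n + alpha/beta) / (d_ref + alpha/beta)`.
#' The conversion is the identity when the plan's fraction dose equals
#' `d_ref` (e.g. 73.6 Gy(RBE) in 16 fractions at d_ref = 4.6).
#'
#' @param total_dose non-negative total dose, Gy(RBE); scalar, vector or array.
#' @param scheme a [fractionation_scheme()].
#' @return Equieffective dose with the shape of `total_dose`, Gy(RBE).
#' @export
eqd <- function(total_dose, scheme = fractionation_scheme()) {
  stopifnot(inherits(scheme, "fractionation_scheme"))
  if (any(total_dose < 0)) stop("total_dose must be non-negative")
  total_dose * (total_dose / scheme$n_fractions + scheme$alpha_beta) /
    (scheme$d_ref + scheme$alpha_beta)
}

#' Voxel D50 as a function of clonogen count
#'
#' `D50(c) = delta * (1 + phi * log(c))`: voxels holding more clonogens need
#' more dose for 50% control. Strictly increasing in `c` for `phi > 0`.
#'
#' @param c clonogens per voxel (> 0); vector or array.
#' @param params a [tcp_params()].
#' @return D50 in Gy(RBE), same shape as `c`.
#' @export
d50_of_count <- function(c, params = tcp_params()) {
  stopifnot(inherits(params, "tcp_params"))
  if (any(c <= 0))
    stop("clonogen count must be positive; exclude zero-count voxels upstream")
  d50 <- params$delta * (1 + params$phi * log(c))
  if (any(d50 <= 0))
    stop("phi/delta combination gives non-positive D50 over this count range")
  d50
}

# exponent constant e^gamma - ln ln 2 (> 0 for all gamma)
.k_gamma <- function(gamma) exp(gamma) - log(log(2))

#' Voxel survival and TCP
#'
#' The voxel-wise Poisson dose-response:
#' `S_i = exp(e^gamma - (EQD_i / D50_i) * (e^gamma - ln ln 2))` and
#' `TCP_i = 100 * exp(-S_i)`. At `EQD = D50` the exponent collapses to
#' `ln ln 2`, so `S = ln 2` and `TCP = 50` exactly. TCP increases with dose
#' and, for `phi > 0`, decreases with clonogen count.
#'
#' @param eqd_i equieffective dose per voxel, Gy(RBE) (>= 0).
#' @param c_i clonogens per voxel (> 0), same shape as `eqd_i` (or scalar).
#' @param params a [tcp_params()].
#' @return List with `survival` (S_i) and `tcp` (TCP_i, percent), shaped like
#'   the inputs.
#' @export
voxel_tcp <- function(eqd_i, c_i, params = tcp_params()) {
  if (any(eqd_i < 0)) stop("eqd must be non-negative")
  d50 <- d50_of_count(c_i, params)
  s <- exp(exp(params$gamma) - (eqd_i / d50) * .k_gamma(params$gamma))
  if (any(!is.finite(s))) {
    bad <- which(!is.finite(s))
    stop(sprintf("non-finite survival at voxel index %d (eqd=%g, c=%g)",
                 bad[1], eqd_i[bad[1]],
                 if (length(c_i) > 1) c_i[bad[1]] else c_i))
  }
  list(survival = s, tcp = 100 * exp(-s))
}

#' ROI-level TCP from a survival map
#'
#' Aggregates voxel survivals over a region as the volume-weighted mean
#' `S_ROI = sum(S_i * v_i) / V_ROI`, which on the TCP scale equals the
#' volume-weighted product `prod(TCP_i^(v_i/V_ROI))`; the ROI TCP is
#' `100 * exp(-S_ROI)`. Voxels flagged in `exclude` (e.g. zero clonogens,
#' where the D50 relation is undefined) are dropped together with their
#' volume.
#'
#' @param survival_map a [scalar_volume()] of voxel survivals (or a bare
#'   numeric array on `grid`).
#' @param mask logical array selecting the ROI; must be non-empty.
#' @param grid a [grid3d()]; taken from `survival_map` when it is a
#'   `scalar_volume`.
#' @param exclude optional logical array of voxels to drop from the ROI.
#' @return List of class `tcp_result` with `roi_survival`, `roi_tcp`
#'   (percent), `tcp_map` and `survival_map` (`scalar_volume`s, zero outside
#'   the mask), and `n_excluded`.
#' @export
roi_tcp <- function(survival_map, mask, grid = NULL, exclude = NULL) {
  if (inherits(survival_map, "scalar_volume")) {
    grid <- survival_map$grid
    s <- survival_map$values
  } else {
    if (is.null(grid)) stop("grid required when survival_map is a bare array")
    s <- as.array(survival_map)
  }
  mask <- as.logical(mask)
  if (!any(mask)) stop("ROI mask is empty")
  keep <- mask
  n_excluded <- 0L
  if (!is.null(exclude)) {
    keep <- mask & !as.logical(exclude)
    n_excluded <- sum(mask) - sum(keep)
    if (!any(keep)) stop("all ROI voxels excluded")
  }
  s_roi <- mean(s[keep])  # uniform voxel volume: v_i/V_ROI = 1/N
  tcp_arr <- array(0, dim = grid$shape)
  surv_arr <- array(0, dim = grid$shape)
  surv_arr[keep] <- s[keep]
  tcp_arr[keep] <- 100 * exp(-s[keep])
  structure(list(
    roi_survival = s_roi,
    roi_tcp = 100 * exp(-s_roi),
    survival_map = scalar_volume(surv_arr, grid, "survival"),
    tcp_map = scalar_volume(tcp_arr, grid, "tcp_percent"),
    n_excluded = n_excluded
  ), class = "tcp_result")
}

#' @export
print.tcp_result <- function(x, ...) {
  cat(sprintf("tcp_result: ROI TCP %.2f%% (mean survival %.4f, %d excluded)\n",
              x$roi_tcp, x$roi_survival, x$n_excluded))
  invisible(x)
}

#' TCP of a dose distribution over a region
#'
#' Convenience wrapper running the full chain: equieffective-dose conversion,
#' count-dependent D50, voxel survival and TCP, and ROI aggregation. Voxels
#' with zero clonogen count inside the mask are excluded (with their volume)
#' from the aggregation.
#'
#' @param dose a [scalar_volume()] of RBE-weighted dose (or a `plan`).
#' @param cell_map a [scalar_volume()] of clonogens per voxel.
#' @param mask logical ROI array (e.g. the GTV mask).
#' @param params a [tcp_params()].
#' @param scheme a [fractionation_scheme()].
#' @return A `tcp_result` as from [roi_tcp()].
#' @export
plan_tcp <- function(dose, cell_map, mask, params = tcp_params(),
                     scheme = fractionation_scheme()) {
  if (inherits(dose, "plan")) dose <- dose$dose
  stopifnot(inherits(dose, "scalar_volume"),
            inherits(cell_map, "scalar_volume"))
  stop_if_grid_mismatch(dose$grid, cell_map$grid, "dose and cell map")
  mask <- as.logical(mask)
  if (!any(mask)) stop("ROI mask is empty")
  zero <- cell_map$values <= 0
  keep <- mask & !zero
  if (!any(keep)) stop("no ROI voxels with positive clonogen count")
  s <- array(0, dim = dose$grid$shape)
  vt <- voxel_tcp(eqd(dose$values[keep], scheme), cell_map$values[keep],
                  params)
  s[keep] <- vt$survival
  roi_tcp(s, mask, dose$grid, exclude = zero)
}

#' Fit TCP parameters to outcome-labelled cases by bounded least squares
#'
#' Estimates `(gamma, delta, phi)` by minimizing the squared difference
#' between each case's predicted GTV control probability (`TCP_ROI / 100`
#' under its planned dose and nominal cell map) and its binary outcome
#' (1 = local control, 0 = relapse), inside box bounds. The loss surface is
#' multi-modal, so a multi-start local optimizer (`L-BFGS-B`) is used with
#' deterministic Latin-hypercube-like starts derived from `seed`.
#'
#' @param cohort list of cohort records as produced by [make_cohort()]; each
#'   record needs `plan_dose`, `cell_map`, `structures$masks$GTV`, `outcome`.
#' @param scheme a [fractionation_scheme()].
#' @param bounds named list with `gamma`, `delta`, `phi`, each `c(lo, hi)`.
#' @param clonogenic_fraction passed through to the returned [tcp_params()].
#' @param n_starts number of local-optimizer starts.
#' @param seed integer seed controlling start placement.
#' @return A [tcp_params()] with attributes `loss` (achieved sum of squares),
#'   `converged` (any start converged) and `degenerate` (single-outcome
#'   cohort).
#' @export
fit_tcp_params <- function(cohort, scheme = fractionation_scheme(),
                           bounds = list(gamma = c(1.5, 2.5),
                                         delta = c(20, 60),
                                         phi = c(0, 0.15)),
                           clonogenic_fraction = 0.01,
                           n_starts = 8, seed = 1) {
  stopifnot(length(cohort) >= 2)
  for (nm in c("gamma", "delta", "phi")) {
    b <- bounds[[nm]]
    if (is.null(b) || length(b) != 2 || any(!is.finite(b)) || b[1] > b[2])
      stop(sprintf("bounds$%s must be finite c(lo, hi)", nm))
  }
  outcomes <- vapply(cohort, function(r) r$outcome, numeric(1))
  degenerate <- length(unique(outcomes)) < 2L
  if (degenerate)
    warning("all outcomes identical: fit is degenerate")

  # per-record sufficient statistics: EQD and log-count over in-GTV voxels
  recs <- lapply(cohort, function(r) {
    gtv <- r$structures$masks$GTV
    keep <- gtv & r$cell_map$values > 0
    list(eqd = eqd(r$plan_dose$values[keep], scheme),
         logc = log(r$cell_map$values[keep]))
  })

  loss_fn <- function(p) {
    g <- p[1]; dl <- p[2]; ph <- p[3]
    k <- .k_gamma(g); eg <- exp(g)
    pred <- vapply(recs, function(r) {
      d50 <- dl * (1 + ph * r$logc)
      if (any(d50 <= 0)) return(NA_real_)
      mean(exp(pmin(eg - (r$eqd / d50) * k, 700)))
    }, numeric(1))
    if (any(!is.finite(pred))) return(1e10)
    sum((exp(-pred) - outcomes)^2)
  }

  lo <- c(bounds$gamma[1], bounds$delta[1], bounds$phi[1])
  hi <- c(bounds$gamma[2], bounds$delta[2], bounds$phi[2])
  point_bounds <- all(hi - lo < 1e-12)
  if (point_bounds) {
    best <- list(par = lo, value = loss_fn(lo), convergence = 0L)
  } else {
    # deterministic stratified starts in the box
    set.seed(seed)
    starts <- lapply(seq_len(n_starts), function(i) {
      f <- (i - 0.5) / n_starts
      lo + (hi - lo) * ((f + c(0, 1, 2) / 3 + stats::runif(3, 0, 1 / n_starts))
                        %% 1)
    })
    fits <- lapply(starts, function(s) {
      tryCatch(
        stats::optim(pmin(pmax(s, lo), hi), loss_fn, method = "L-BFGS-B",
                     lower = lo, upper = hi,
                     control = list(maxit = 500, factr = 1e7)),
        error = function(e) list(par = s, value = Inf, convergence = 99L))
    })
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  }
  out <- tcp_params(gamma = best$par[1], delta = best$par[2],
                    phi = best$par[3],
                    clonogenic_fraction = clonogenic_fraction)
  attr(out, "loss") <- best$value
  attr(out, "converged") <- identical(best$convergence, 0L)
  attr(out, "degenerate") <- degenerate
  out
}
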