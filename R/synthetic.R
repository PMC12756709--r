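#' Phantom geometry configuration
#'
#' Parameters for the synthetic pelvic phantom: nested ellipsoidal targets
#' (GTV inside CTV_HD inside CTV_LD) centred in an ellipsoidal body, with one
#' bowel-like organ at risk abutting the CTV_LD surface. Radii are in mm.
#'
#' @param shape grid shape, voxels per axis (>= 8 each).
#' @param spacing grid spacing, mm.
#' @param gtv_radius,ctv_hd_radius,ctv_ld_radius target radii, mm; must be
#'   strictly increasing.
#' @param oar_radius radius of the OAR sphere, mm.
#' @param body_radius semi-axis of the body ellipsoid, mm (same in all axes).
#' @param centre_jitter_mm uniform jitter applied to the common target centre,
#'   mm per axis (gives per-seed anatomical variation across a cohort).
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(48, 48, 48), spacing = c(3, 3, 3),
                           gtv_radius = 24, ctv_hd_radius = 30,
                           ctv_ld_radius = 36, oar_radius = 12,
                           body_radius = 66, centre_jitter_mm = 3) {
  if (any(shape < 8)) stop("phantom grids need shape >= 8 voxels per axis")
  if (!(gtv_radius < ctv_hd_radius && ctv_hd_radius < ctv_ld_radius))
    stop("radii must satisfy GTV < CTV_HD < CTV_LD")
  half_extent <- min(shape * spacing) / 2
  if (ctv_ld_radius + oar_radius >= half_extent)
    stop("CTV_LD plus OAR does not fit inside the grid")
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 gtv_radius = gtv_radius, ctv_hd_radius = ctv_hd_radius,
                 ctv_ld_radius = ctv_ld_radius, oar_radius = oar_radius,
                 body_radius = body_radius,
                 centre_jitter_mm = centre_jitter_mm),
            class = "phantom_config")
}

# mm coordinates of voxel centres along each axis
.axis_mm <- function(grid) {
  lapply(1:3, function(a)
    (seq_len(grid$shape[a]) - (grid$shape[a] + 1) / 2) * grid$spacing[a])
}

# squared mm distance of every voxel from a centre (mm, grid coordinates)
.dist2_mm <- function(grid, centre) {
  ax <- .axis_mm(grid)
  dx2 <- (ax[[1]] - centre[1])^2
  dy2 <- (ax[[2]] - centre[2])^2
  dz2 <- (ax[[3]] - centre[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`)
}

#' Generate a synthetic phantom
#'
#' Builds the nested target masks and an abutting OAR on a fresh grid.
#' Deterministic given `(config, seed)`; the seed only moves the common
#' target centre by the configured jitter, so cohort members differ in
#' geometry while every invariant (nesting, OAR disjoint from GTV) holds by
#' construction.
#'
#' @param config a [phantom_config()].
#' @param seed integer seed.
#' @return List with `grid` ([grid3d()]) and `structures`
#'   ([structure_set()] with masks `BODY`, `GTV`, `CTV_HD`, `CTV_LD`,
#'   `bowel`).
#' @export
make_phantom <- function(config = phantom_config(), seed = 1) {
  stopifnot(inherits(config, "phantom_config"))
  grid <- grid3d(config$shape, config$spacing)
  set.seed(seed)
  centre <- stats::runif(3, -config$centre_jitter_mm, config$centre_jitter_mm)
  d2 <- .dist2_mm(grid, centre)
  gtv    <- d2 <= config$gtv_radius^2
  ctv_hd <- d2 <= config$ctv_hd_radius^2
  ctv_ld <- d2 <= config$ctv_ld_radius^2
  body   <- .dist2_mm(grid, c(0, 0, 0)) <= config$body_radius^2
  # OAR sphere abutting the CTV_LD surface along +x
  oar_centre <- centre + c(config$ctv_ld_radius + config$oar_radius, 0, 0)
  oar <- .dist2_mm(grid, oar_centre) <= config$oar_radius^2
  oar <- oar & !gtv  # guard against jitter-induced overlap at extreme radii
  body <- body | ctv_ld | oar
  list(grid = grid,
       structures = structure_set(
         list(BODY = body, GTV = gtv, CTV_HD = ctv_hd, CTV_LD = ctv_ld,
              bowel = oar), grid))
}

#' Cell-field parameters
#'
#' Statistical parameters of the synthetic microstructure maps. Per-voxel
#' total cell counts are log-normal; clonogen counts are
#' `clonogenic_fraction` times the total. The defaults place the marginal
#' 33rd/66th percentiles of clonogens per voxel at 2.1e5 and 3.8e5 (the
#' pooled population tertiles this protocol discretizes on), which on a
#' 0.027 cm^3 voxel corresponds to an average cell density of about
#' 1e7 cells/cm^3. Spatial correlation is imposed by Gaussian smoothing of
#' white noise before exponentiation; `correlation_mm` is the kernel sigma.
#'
#' @param log_mean mean of log total cells per voxel.
#' @param log_sd marginal sd of log total cells per voxel.
#' @param correlation_mm spatial correlation length (Gaussian kernel sigma), mm.
#' @param clonogenic_fraction fraction of cells that are clonogenic, (0, 1].
#' @param rmse_scale half-normal scale of the ADC-fit RMSE field.
#' @return An object of class `cell_field_params`.
#' @export
cell_field_params <- function(log_mean = 17.166, log_sd = 0.696,
                              correlation_mm = 9, clonogenic_fraction = 0.01,
                              rmse_scale = 0.1) {
  if (clonogenic_fraction <= 0 || clonogenic_fraction > 1)
    stop("clonogenic_fraction must lie in (0, 1]")
  if (log_sd < 0) stop("log_sd must be non-negative")
  if (rmse_scale < 0) stop("rmse_scale must be non-negative")
  structure(list(log_mean = log_mean, log_sd = log_sd,
                 correlation_mm = correlation_mm,
                 clonogenic_fraction = clonogenic_fraction,
                 rmse_scale = rmse_scale), class = "cell_field_params")
}

# separable Gaussian smoothing of a 3-D array, normalized so that smoothing
# unit white noise returns (approximately) unit marginal variance
.smooth_gaussian <- function(x, sigma_vox) {
  if (all(sigma_vox <= 0)) return(x)
  for (a in 1:3) {
    s <- sigma_vox[a]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    w <- stats::dnorm(seq(-half, half), sd = s)
    w <- w / sqrt(sum(w^2))  # unit-variance normalization for white noise
    n <- dim(x)[a]
    perm <- switch(a, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 2, 1))
    xp <- aperm(x, perm)
    dp <- dim(xp)
    m <- matrix(xp, nrow = dp[1])
    out <- matrix(0, nrow = dp[1], ncol = ncol(m))
    for (k in seq_along(w)) {
      off <- k - half - 1L
      idx <- pmin(pmax(seq_len(dp[1]) + off, 1L), dp[1])  # edge clamp
      out <- out + w[k] * m[idx, , drop = FALSE]
    }
    x <- aperm(array(out, dp), order(perm))
  }
  x
}

#' Generate clonogen-count and RMSE maps
#'
#' Draws a spatially correlated log-normal total-cell-count field, multiplies
#' by the clonogenic fraction, and zeroes it outside the GTV (cell estimates
#' are only available where diffusion imaging was fitted). The companion RMSE
#' map is a non-negative half-normal field emulating the voxel-wise ADC-fit
#' residual that drives the uncertainty model.
#'
#' @param grid a [grid3d()].
#' @param gtv logical GTV mask on `grid`.
#' @param params a [cell_field_params()].
#' @param seed integer seed.
#' @return List with `cell_map` and `rmse_map`, both [scalar_volume()]s.
#' @export
make_cell_map <- function(grid, gtv, params = cell_field_params(), seed = 1) {
  stopifnot(inherits(grid, "grid3d"))
  gtv <- as.logical(gtv)
  if (!any(gtv)) stop("GTV mask is empty")
  set.seed(seed)
  z <- array(stats::rnorm(prod(grid$shape)), dim = grid$shape)
  z <- .smooth_gaussian(z, params$correlation_mm / grid$spacing)
  # standardize the latent field over the GTV so the configured log-moments
  # are the realized in-mask moments (keeps cohort-pooled tertiles on the
  # calibrated 2.1e5/3.8e5 clonogens-per-voxel marks)
  s_gtv <- stats::sd(z[gtv])
  if (is.finite(s_gtv) && s_gtv > 0) z <- (z - mean(z[gtv])) / s_gtv
  total <- exp(params$log_mean + params$log_sd * z)
  cells <- params$clonogenic_fraction * total
  cells[!gtv] <- 0
  rmse <- array(abs(stats::rnorm(prod(grid$shape), sd = params$rmse_scale)),
                dim = grid$shape)
  list(cell_map = scalar_volume(cells, grid, "cells_per_voxel"),
       rmse_map = scalar_volume(rmse, grid, "rmse"))
}

#' LET-field parameters
#'
#' @param base in-GTV dose-averaged LET level, keV/um (>= 0).
#' @param gradient_per_voxel linear increase in keV/um per voxel of distance
#'   from the target centre (LET rises toward the target periphery where
#'   carbon ions stop).
#' @return An object of class `letd_params`.
#' @export
letd_params <- function(base = 44, gradient_per_voxel = 0.5) {
  if (base < 0) stop("base LET level must be non-negative")
  structure(list(base = base, gradient_per_voxel = gradient_per_voxel),
            class = "letd_params")
}

#' Generate a surrogate dose-averaged LET map
#'
#' A smooth radial ramp standing in for a transport-computed LET_d
#' distribution: `base + gradient * distance_from_centre_in_voxels`,
#' clipped at zero. Supports LET-volume-histogram evaluation only; it is not
#' a physical fragment-spectra model.
#'
#' @param grid a [grid3d()].
#' @param structures a [structure_set()] whose GTV centroid anchors the ramp.
#' @param params a [letd_params()].
#' @return A [scalar_volume()] with quantity `letd_keV_um`.
#' @export
make_letd_map <- function(grid, structures, params = letd_params()) {
  stopifnot(inherits(grid, "grid3d"), inherits(structures, "structure_set"))
  gtv <- structures$masks$GTV
  idx <- which(gtv, arr.ind = TRUE)
  centre_mm <- vapply(1:3, function(a) {
    ax <- .axis_mm(grid)[[a]]
    mean(ax[idx[, a]])
  }, numeric(1))
  dist_vox <- sqrt(.dist2_mm(grid, centre_mm)) / mean(grid$spacing)
  vals <- pmax(params$base + params$gradient_per_voxel * dist_vox, 0)
  scalar_volume(vals, grid, "letd_keV_um")
}

#' Generate an outcome-labelled synthetic cohort
#'
#' Each record gets its own phantom (seed `base seed + index`), clonogen and
#' RMSE maps, a uniform plan at the protocol prescription, and a binary
#' outcome drawn as `Bernoulli(TCP_ROI / 100)` under `true_params` — the
#' structure a TCP-model fitting set needs.
#'
#' @param n number of records (>= 2).
#' @param true_params the generating [tcp_params()].
#' @param scheme a [fractionation_scheme()].
#' @param seed integer base seed.
#' @param config a [phantom_config()].
#' @param field_params a [cell_field_params()].
#' @param protocol a [protocol_spec()] for the per-record uniform plan.
#' @return List of `n` records, each with `grid`, `structures`, `plan_dose`,
#'   `cell_map`, `rmse_map`, `outcome`, `true_tcp`, `seed`.
#' @export
make_cohort <- function(n, true_params = tcp_params(),
                        scheme = fractionation_scheme(), seed = 1,
                        config = phantom_config(),
                        field_params = cell_field_params(),
                        protocol = protocol_spec()) {
  if (n < 2) stop("a cohort needs at least 2 records")
  lapply(seq_len(n), function(i) {
    rec_seed <- seed + i
    ph <- make_phantom(config, seed = rec_seed)
    maps <- make_cell_map(ph$grid, ph$structures$masks$GTV, field_params,
                          seed = rec_seed)
    plan <- uniform_plan(ph$structures, protocol)
    res <- plan_tcp(plan, maps$cell_map, ph$structures$masks$GTV,
                    true_params, scheme)
    set.seed(rec_seed)
    outcome <- stats::rbinom(1, 1, res$roi_tcp / 100)
    list(grid = ph$grid, structures = ph$structures, plan_dose = plan$dose,
         cell_map = maps$cell_map, rmse_map = maps$rmse_map,
         outcome = outcome, true_tcp = res$roi_tcp, seed = rec_seed)
  })
}
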