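#' Voxel grid
#'
#' A regular 3-D voxel grid shared by all volumes of one case. Spacing is in
#' millimetres per axis; the default 3 mm isotropic grid matches a typical
#' particle-therapy dose grid.
#'
#' @param shape integer vector of length 3, voxel counts per axis (>= 8 each
#'   for phantom use).
#' @param spacing numeric vector of length 3, mm per voxel along each axis.
#' @param origin numeric vector of length 3, mm offset of the first voxel.
#' @return An object of class `grid3d`.
#' @export
grid3d <- function(shape, spacing = c(3, 3, 3), origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("shape must be three positive voxel counts")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive lengths in mm")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be three finite mm offsets")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "grid3d")
}

#' @export
print.grid3d <- function(x, ...) {
  cat(sprintf("grid3d: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Voxel volume of a grid in cm^3
#'
#' @param grid a [grid3d()].
#' @return Scalar voxel volume in cm^3 (`prod(spacing)/1000`).
#' @export
voxel_volume_cm3 <- function(grid) {
  stopifnot(inherits(grid, "grid3d"))
  prod(grid$spacing) / 1000
}

same_grid <- function(a, b, tol = 1e-9) {
  identical(a$shape, b$shape) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(sprintf(
      "grid mismatch between %s: [%s | %s mm] vs [%s | %s mm]", what,
      paste(a$shape, collapse = "x"), paste(signif(a$spacing, 4), collapse = "x"),
      paste(b$shape, collapse = "x"), paste(signif(b$spacing, 4), collapse = "x")))
  invisible(TRUE)
}

.quantities <- c("dose_Gy_RBE", "eqd_Gy_RBE", "cells_per_voxel", "rmse",
                 "letd_keV_um", "tcp_percent", "survival", "delta_tcp_pp")

#' Scalar volume on a grid
#'
#' A 3-D scalar field (dose, equieffective dose, clonogen count, ADC-fit RMSE,
#' dose-averaged LET, TCP or survival) defined on a [grid3d()].
#'
#' @param values numeric 3-D array matching `grid$shape`.
#' @param grid a [grid3d()].
#' @param quantity one of `"dose_Gy_RBE"`, `"eqd_Gy_RBE"`, `"cells_per_voxel"`,
#'   `"rmse"`, `"letd_keV_um"`, `"tcp_percent"`, `"survival"`, `"delta_tcp_pp"`.
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(values, grid, quantity = "dose_Gy_RBE") {
  stopifnot(inherits(grid, "grid3d"))
  quantity <- match.arg(quantity, .quantities)
  values <- as.array(values)
  if (!identical(dim(values), as.integer(grid$shape)))
    stop("values dimensions do not match grid shape")
  if (any(!is.finite(values)))
    stop("scalar volume contains non-finite values")
  if (quantity %in% c("cells_per_voxel", "rmse", "letd_keV_um") &&
      any(values < 0))
    stop(sprintf("%s values must be non-negative", quantity))
  if (quantity == "tcp_percent" && (any(values < 0) || any(values > 100)))
    stop("tcp_percent values must lie in [0, 100]")
  structure(list(values = values, grid = grid, quantity = quantity),
            class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("scalar_volume [%s]: %s voxels, range [%.4g, %.4g]\n",
              x$quantity, paste(x$grid$shape, collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Named structure masks on a shared grid
#'
#' Holds boolean masks for targets and organs at risk. When the canonical
#' target names are present the nesting GTV within CTV_HD within CTV_LD is
#' enforced, and every mask whose name is not a target is treated as an OAR
#' and must be disjoint from the GTV.
#'
#' @param masks named list of logical 3-D arrays, all matching `grid$shape`.
#' @param grid a [grid3d()].
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(masks, grid) {
  stopifnot(inherits(grid, "grid3d"), is.list(masks), length(masks) > 0)
  if (is.null(names(masks)) || any(!nzchar(names(masks))))
    stop("all masks must be named")
  masks <- lapply(masks, function(m) {
    m <- array(as.logical(m), dim = dim(as.array(m)))
    if (!identical(dim(m), as.integer(grid$shape)))
      stop("mask dimensions do not match grid shape")
    if (anyNA(m)) stop("mask contains NA")
    m
  })
  for (nm in names(masks))
    if (!any(masks[[nm]])) stop(sprintf("mask '%s' is empty", nm))
  targets <- c("GTV", "CTV_HD", "CTV_LD")
  if (all(targets %in% names(masks))) {
    if (any(masks$GTV & !masks$CTV_HD))
      stop("nesting violated: GTV not contained in CTV_HD")
    if (any(masks$CTV_HD & !masks$CTV_LD))
      stop("nesting violated: CTV_HD not contained in CTV_LD")
  }
  if ("GTV" %in% names(masks)) {
    oars <- setdiff(names(masks), c(targets, "BODY"))
    for (nm in oars)
      if (any(masks[[nm]] & masks$GTV))
        stop(sprintf("OAR mask '%s' overlaps the GTV", nm))
  }
  structure(list(masks = masks, grid = grid), class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  n <- vapply(x$masks, sum, numeric(1))
  cat("structure_set on", paste(x$grid$shape, collapse = "x"), "grid:\n")
  for (nm in names(n))
    cat(sprintf("  %-8s %6d voxels (%.1f cm^3)\n", nm, n[[nm]],
                n[[nm]] * voxel_volume_cm3(x$grid)))
  invisible(x)
}
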