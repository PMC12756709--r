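#' Nearest-rank percentile
#'
#' The value at rank `ceiling(p/100 * N)` of the ascending sort — the
#' deterministic, interpolation-free percentile convention used throughout
#' the package (DVH metrics, subregion thresholds).
#'
#' @param x numeric values.
#' @param p percentile in (0, 100].
#' @return The nearest-rank percentile of `x`.
#' @export
nearest_rank_percentile <- function(x, p) {
  if (length(x) == 0) stop("empty sample")
  if (p <= 0 || p > 100) stop("p must lie in (0, 100]")
  sort(x)[ceiling(p / 100 * length(x))]
}

#' Dose at volume (D_x%)
#'
#' The minimum dose received by the hottest `x`% of a structure: voxel doses
#' are sorted descending and the value at rank `ceiling(x/100 * N)` is taken
#' (nearest rank, no interpolation). `D_95% <= D_50% <= D_1%` always.
#'
#' @param dose a [scalar_volume()] of dose (or a bare numeric array).
#' @param mask logical ROI mask, non-empty.
#' @param x volume percentage in (0, 100].
#' @return Dose in Gy(RBE).
#' @export
dose_at_volume <- function(dose, mask, x) {
  vals <- if (inherits(dose, "scalar_volume")) dose$values else as.array(dose)
  mask <- as.logical(mask)
  if (!any(mask)) stop("ROI mask is empty")
  if (x <= 0 || x > 100) stop("x must lie in (0, 100]")
  v <- sort(vals[mask], decreasing = TRUE)
  v[ceiling(x / 100 * length(v))]
}

#' LET at volume (L_x%)
#'
#' Same nearest-rank contract as [dose_at_volume()], applied to a
#' dose-averaged LET field (keV/um): L_98%, L_50%, L_1%.
#'
#' @inheritParams dose_at_volume
#' @param letd a [scalar_volume()] of LET_d.
#' @return LET_d in keV/um.
#' @export
let_at_volume <- function(letd, mask, x) dose_at_volume(letd, mask, x)

#' Cumulative DVH (or LVH) curve
#'
#' Fraction of the ROI volume receiving at least each threshold; monotone
#' non-increasing from 1 toward 0.
#'
#' @param dose a [scalar_volume()] (dose or LET_d).
#' @param mask logical ROI mask.
#' @param thresholds ascending threshold values; defaults to an even grid
#'   spanning the in-ROI range.
#' @return A data.frame with `threshold` and `volume_fraction`.
#' @export
dvh_curve <- function(dose, mask, thresholds = NULL) {
  vals <- if (inherits(dose, "scalar_volume")) dose$values else as.array(dose)
  mask <- as.logical(mask)
  if (!any(mask)) stop("ROI mask is empty")
  v <- vals[mask]
  if (is.null(thresholds))
    thresholds <- seq(0, max(v), length.out = 201)
  if (is.unsorted(thresholds)) stop("thresholds must be ascending")
  frac <- vapply(thresholds, function(t) mean(v >= t), numeric(1))
  data.frame(threshold = thresholds, volume_fraction = frac)
}

#' Audit clinical goals of a plan
#'
#' Target coverage goals of the painting protocol: GTV `D_95% > 0.95 Dp`,
#' GTV `D_1% < 1.15 Dp`, and `D_1% < 1.05 Dp` in the non-escalated regions
#' (CTV_HD minus GTV and CTV_LD minus GTV), plus configurable near-maximum
#' (`D_1%`) limits for OARs. Missing structures produce explicit failure
#' entries rather than silent skips.
#'
#' @param plan a `plan` (or dose [scalar_volume()]).
#' @param structures a [structure_set()].
#' @param protocol a [protocol_spec()].
#' @param oar_limits named numeric vector of near-maximum dose limits in
#'   Gy(RBE) per OAR name; defaults to a placeholder bowel limit of
#'   `1.0 * Dp` (institutional OAR tables are configuration, not shipped
#'   constants).
#' @return A data.frame of class `goal_report` with columns `structure`,
#'   `metric`, `comparator`, `limit`, `achieved`, `pass`.
#' @export
check_goals <- function(plan, structures, protocol = protocol_spec(),
                        oar_limits = c(bowel = 73.6)) {
  dose <- if (inherits(plan, "plan")) plan$dose else plan
  stopifnot(inherits(dose, "scalar_volume"),
            inherits(structures, "structure_set"))
  Dp <- protocol$Dp
  masks <- structures$masks
  rows <- list()
  add <- function(structure, metric, comparator, limit, achieved) {
    pass <- if (is.na(achieved)) FALSE
            else if (comparator == ">") achieved > limit
            else achieved < limit
    rows[[length(rows) + 1]] <<- data.frame(
      structure = structure, metric = metric, comparator = comparator,
      limit = limit, achieved = achieved, pass = pass)
  }
  metric_or_na <- function(mask, x)
    if (is.null(mask) || !any(mask)) NA_real_
    else dose_at_volume(dose, mask, x)

  add("GTV", "D95%", ">", 0.95 * Dp, metric_or_na(masks$GTV, 95))
  add("GTV", "D1%", "<", 1.15 * Dp, metric_or_na(masks$GTV, 1))
  for (nm in c("CTV_HD", "CTV_LD")) {
    ring <- if (!is.null(masks[[nm]]) && !is.null(masks$GTV))
      masks[[nm]] & !masks$GTV else NULL
    add(paste0(nm, "-GTV"), "D1%", "<", 1.05 * Dp,
        if (is.null(ring) || !any(ring)) NA_real_
        else dose_at_volume(dose, ring, 1))
  }
  for (nm in names(oar_limits))
    add(nm, "D1%", "<", oar_limits[[nm]], metric_or_na(masks[[nm]], 1))
  out <- do.call(rbind, rows)
  class(out) <- c("goal_report", "data.frame")
  out
}

#' Voxel-wise TCP difference map
#'
#' `delta_TCP_i = TCP_painted_i - TCP_uniform_i`, in percentage points, on
#' the shared dose grid.
#'
#' @param tcp_a,tcp_b TCP [scalar_volume()]s (percent) on one grid; `tcp_a`
#'   is the painted plan, `tcp_b` the reference.
#' @return A [scalar_volume()] with quantity `delta_tcp_pp`.
#' @export
delta_tcp_map <- function(tcp_a, tcp_b) {
  stopifnot(inherits(tcp_a, "scalar_volume"),
            inherits(tcp_b, "scalar_volume"))
  stop_if_grid_mismatch(tcp_a$grid, tcp_b$grid, "TCP maps")
  scalar_volume(tcp_a$values - tcp_b$values, tcp_a$grid, "delta_tcp_pp")
}

#' Subregion summary of delta-TCP by clonogen-count tertile
#'
#' Discretizes the clonogen maps into low / medium / high ranges at the
#' pooled population 33rd/66th percentiles (nearest rank, computed over the
#' in-mask counts of the whole cohort, never per patient) and summarizes the
#' voxel-wise TCP difference per bin, per record and pooled. Bins a record
#' does not populate are reported as missing, not zero.
#'
#' @param delta_maps list of delta-TCP [scalar_volume()]s (one per record),
#'   or a single volume.
#' @param cell_maps matching list of clonogen-count volumes.
#' @param masks matching list of logical ROI masks (e.g. GTV).
#' @param percentiles two pooled percentiles defining the bin edges.
#' @param pooled_counts optional numeric vector of pooled counts to thresh
#'   on; defaults to the in-mask counts pooled over `cell_maps`.
#' @return List with `thresholds` and `summary`, a data.frame of per-record
#'   and pooled bin means/sds (`record = "pooled"` rows).
#' @export
subregion_summary <- function(delta_maps, cell_maps, masks,
                              percentiles = c(33, 66),
                              pooled_counts = NULL) {
  if (inherits(delta_maps, "scalar_volume")) delta_maps <- list(delta_maps)
  if (inherits(cell_maps, "scalar_volume")) cell_maps <- list(cell_maps)
  if (!is.list(masks)) masks <- list(masks)
  stopifnot(length(delta_maps) == length(cell_maps),
            length(cell_maps) == length(masks), length(percentiles) == 2)
  if (is.null(pooled_counts))
    pooled_counts <- unlist(lapply(seq_along(cell_maps), function(i)
      cell_maps[[i]]$values[as.logical(masks[[i]])]))
  thr <- c(nearest_rank_percentile(pooled_counts, percentiles[1]),
           nearest_rank_percentile(pooled_counts, percentiles[2]))
  bin_of <- function(c) cut(c, c(-Inf, thr[1], thr[2], Inf),
                            labels = c("low", "medium", "high"))
  rows <- list()
  pooled <- list(low = numeric(0), medium = numeric(0), high = numeric(0))
  for (i in seq_along(delta_maps)) {
    m <- as.logical(masks[[i]])
    dt <- delta_maps[[i]]$values[m]
    bins <- bin_of(cell_maps[[i]]$values[m])
    for (b in c("low", "medium", "high")) {
      sel <- bins == b
      rows[[length(rows) + 1]] <- data.frame(
        record = as.character(i), bin = b, n_voxels = sum(sel),
        mean_delta_tcp = if (any(sel)) mean(dt[sel]) else NA_real_,
        sd_delta_tcp = if (sum(sel) > 1) stats::sd(dt[sel]) else NA_real_)
      pooled[[b]] <- c(pooled[[b]], dt[sel])
    }
  }
  for (b in c("low", "medium", "high"))
    rows[[length(rows) + 1]] <- data.frame(
      record = "pooled", bin = b, n_voxels = length(pooled[[b]]),
      mean_delta_tcp = if (length(pooled[[b]])) mean(pooled[[b]]) else NA_real_,
      sd_delta_tcp = if (length(pooled[[b]]) > 1) stats::sd(pooled[[b]])
                     else NA_real_)
  list(thresholds = thr, summary = do.call(rbind, rows))
}

#' Compare a plan metric between two strategies across a cohort
#'
#' Shapiro normality check on each sample (alpha as given), then a two-sided
#' Mann-Whitney U test of the difference. Constant samples skip the normality
#' test with a note (Shapiro is undefined there).
#'
#' @param metric_a,metric_b numeric vectors (>= 3 values each).
#' @param alpha significance level.
#' @return List of class `cohort_test` with the Shapiro p-values, the
#'   Mann-Whitney `statistic` and `p_value`, `significant`, and `notes`.
#' @export
cohort_compare <- function(metric_a, metric_b, alpha = 0.05) {
  if (length(metric_a) < 3 || length(metric_b) < 3)
    stop("each sample needs at least 3 values")
  notes <- character(0)
  shapiro_p <- function(x, label) {
    if (length(unique(x)) == 1L) {
      notes <<- c(notes, sprintf("sample %s constant: normality test skipped",
                                 label))
      return(NA_real_)
    }
    stats::shapiro.test(x)$p.value
  }
  pa <- shapiro_p(metric_a, "a")
  pb <- shapiro_p(metric_b, "b")
  wt <- suppressWarnings(stats::wilcox.test(metric_a, metric_b,
                                            alternative = "two.sided",
                                            exact = FALSE, correct = TRUE))
  structure(list(shapiro_p = c(a = pa, b = pb),
                 normal = c(a = !is.na(pa) && pa >= alpha,
                            b = !is.na(pb) && pb >= alpha),
                 statistic = unname(wt$statistic), p_value = wt$p.value,
                 alpha = alpha, significant = wt$p.value < alpha,
                 notes = notes), class = "cohort_test")
}

#' @export
print.cohort_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.4g, p = %.4g (%ssignificant at alpha %.2f)\n",
              x$statistic, x$p_value, if (x$significant) "" else "not ",
              x$alpha))
  for (n in x$notes) cat(" note:", n, "\n")
  invisible(x)
}
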