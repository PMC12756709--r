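#' Write a scalar volume or mask as NIfTI-1
#'
#' Volumes are written as float32 (bit-stable round trip), masks as uint8.
#' Grid spacing is stored in the NIfTI pixdim and the origin in the sform.
#'
#' @param vol a [scalar_volume()], or a logical mask array with `grid` given.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param grid required when `vol` is a bare mask array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, grid = NULL) {
  if (inherits(vol, "scalar_volume")) {
    values <- vol$values
    grid <- vol$grid
    datatype <- "float"
  } else {
    if (is.null(grid)) stop("grid required for a bare mask array")
    values <- array(as.integer(as.logical(vol)), dim = grid$shape)
    datatype <- "uint8"
  }
  im <- RNifti::asNifti(values)
  affine <- diag(c(grid$spacing, 1))
  affine[1:3, 4] <- grid$origin
  RNifti::sform(im) <- structure(affine, code = 2L)
  RNifti::pixdim(im) <- grid$spacing
  RNifti::writeNifti(im, path, datatype = datatype)
  invisible(path)
}

#' Read a NIfTI-1 file as a scalar volume or mask
#'
#' @param path NIfTI file path.
#' @param quantity quantity tag for the volume (see [scalar_volume()]), or
#'   `"mask"` to load a boolean mask (payload must be 0/1).
#' @return A [scalar_volume()], or for `quantity = "mask"` a list with
#'   `mask` (logical array) and `grid`.
#' @export
read_volume <- function(path, quantity = "dose_Gy_RBE") {
  im <- RNifti::readNifti(path)
  vals <- array(as.numeric(im), dim = dim(im))
  aff <- tryCatch(RNifti::xform(im), error = function(e) NULL)
  origin <- if (is.null(aff)) c(0, 0, 0) else as.numeric(aff[1:3, 4])
  grid <- grid3d(dim(im), RNifti::pixdim(im), origin = origin)
  if (identical(quantity, "mask")) {
    if (!all(vals %in% c(0, 1)))
      stop("mask volume carries values other than 0/1")
    return(list(mask = array(vals > 0, dim = dim(vals)), grid = grid))
  }
  scalar_volume(vals, grid, quantity)
}

#' Default pipeline configuration
#'
#' Every tunable of the end-to-end run, with the protocol's values as
#' defaults. Serializing this list to YAML and back reproduces it
#' field-for-field.
#'
#' @param seed base seed for every random stage.
#' @return A nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    protocol = list(Dp = 73.6, bound_low_frac = 0.95, bound_high_frac = 1.10,
                    let_objective = 43, penumbra_mm = 6),
    scheme = list(n_fractions = 16, d_ref = 4.6, alpha_beta = 2),
    tcp = list(gamma = 2.0, delta = 37.62, phi = 0.06,
               clonogenic_fraction = 0.01),
    generator = list(
      n_fit = 27, n_eval = 10,
      phantom = list(shape = c(48, 48, 48), spacing = c(3, 3, 3),
                     gtv_radius = 24, ctv_hd_radius = 30, ctv_ld_radius = 36,
                     oar_radius = 12, body_radius = 66, centre_jitter_mm = 3),
      field = list(log_mean = 17.166, log_sd = 0.696, correlation_mm = 9,
                   clonogenic_fraction = 0.01, rmse_scale = 0.1),
      letd = list(base = 44, gradient_per_voxel = 0.5)),
    robustness = list(beam_axis = 1, nominal_range_mm = 150),
    fit = list(enabled = FALSE, n_starts = 8,
               bounds = list(gamma = c(1.5, 2.5), delta = c(20, 60),
                             phi = c(0, 0.15))),
    write_volumes = FALSE)
}

#' Read a pipeline configuration from YAML
#'
#' Missing fields are filled from [default_config()]; unknown top-level
#' fields and type violations are rejected.
#'
#' @param path YAML file path.
#' @return A validated configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  validate_config(modify_list_deep(default_config(), user))
}

modify_list_deep <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(base[[nm]])))
      base[[nm]] <- modify_list_deep(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Validate a pipeline configuration
#'
#' Hand-rolled schema check: required blocks present, numeric fields numeric
#' and in range, no unknown top-level blocks.
#'
#' @param config configuration list.
#' @return The config, invisibly, or an error naming the offending field.
#' @export
validate_config <- function(config) {
  known <- names(default_config())
  extra <- setdiff(names(config), known)
  if (length(extra))
    stop("unknown config blocks: ", paste(extra, collapse = ", "))
  missing <- setdiff(known, names(config))
  if (length(missing))
    stop("missing config blocks: ", paste(missing, collapse = ", "))
  num <- function(x, nm, lo = -Inf) {
    if (!is.numeric(x) || any(!is.finite(x)) || any(x < lo))
      stop(sprintf("config field %s must be numeric >= %g", nm, lo))
  }
  num(config$seed, "seed")
  num(config$protocol$Dp, "protocol.Dp", lo = 1e-9)
  num(config$scheme$n_fractions, "scheme.n_fractions", lo = 1)
  num(config$tcp$gamma, "tcp.gamma", lo = 1e-9)
  num(config$tcp$delta, "tcp.delta", lo = 1e-9)
  num(config$generator$n_fit, "generator.n_fit", lo = 2)
  num(config$generator$n_eval, "generator.n_eval", lo = 1)
  invisible(config)
}

# small deterministic fingerprint of a config (no hashing package required)
config_fingerprint <- function(config) {
  s <- paste(deparse(config), collapse = "")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.cfg_objects <- function(config) {
  g <- config$generator
  list(
    protocol = protocol_spec(Dp = config$protocol$Dp,
                             bound_low_frac = config$protocol$bound_low_frac,
                             bound_high_frac = config$protocol$bound_high_frac,
                             let_objective = config$protocol$let_objective,
                             penumbra_mm = config$protocol$penumbra_mm),
    scheme = fractionation_scheme(config$scheme$n_fractions,
                                  config$scheme$d_ref,
                                  config$scheme$alpha_beta),
    params = tcp_params(config$tcp$gamma, config$tcp$delta, config$tcp$phi,
                        config$tcp$clonogenic_fraction),
    phantom = do.call(phantom_config, g$phantom),
    field = do.call(cell_field_params, g$field),
    letd = do.call(letd_params, g$letd))
}

#' Run the full dose-painting pipeline
#'
#' Generate (fitting + evaluation cohorts) -> optionally fit the TCP
#' parameters -> plan (uniform, DE, DR per evaluation record) -> robustness
#' (best/nominal/worst TCP under the RMSE uncertainty model) -> evaluate
#' (DVH/LVH metrics, clinical goals, delta-TCP subregion summaries, cohort
#' statistics) -> report. All artifacts are written under `out_dir` with a
#' manifest carrying the seed and a config fingerprint; any stage failure
#' halts with the stage name.
#'
#' @param config a configuration list from [default_config()] or
#'   [read_config()].
#' @param out_dir output directory (created if missing).
#' @return The report list, invisibly; artifacts on disk under `out_dir`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("dp_")) {
  validate_config(config)
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
    message("created output directory ", out_dir)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  obj <- .cfg_objects(config)
  params <- obj$params

  fit_cohort <- stage("generate", make_cohort(
    config$generator$n_fit, params, obj$scheme, seed = config$seed,
    config = obj$phantom, field_params = obj$field, protocol = obj$protocol))
  eval_cohort <- stage("generate", make_cohort(
    config$generator$n_eval, params, obj$scheme, seed = config$seed + 1000,
    config = obj$phantom, field_params = obj$field, protocol = obj$protocol))

  fitted <- NULL
  if (isTRUE(config$fit$enabled)) {
    fitted <- stage("fit", fit_tcp_params(
      fit_cohort, obj$scheme, bounds = config$fit$bounds,
      clonogenic_fraction = config$tcp$clonogenic_fraction,
      n_starts = config$fit$n_starts, seed = config$seed))
    params <- fitted
  }

  model <- stage("robustness", uncertainty_model(pooled_rmse_sd(fit_cohort)))
  scen <- enumerate_scenarios()

  records <- stage("plan", lapply(seq_along(eval_cohort), function(i) {
    rec <- eval_cohort[[i]]
    gtv <- rec$structures$masks$GTV
    uni <- uniform_plan(rec$structures, obj$protocol)
    de <- optimize_de(rec$cell_map, rec$structures, obj$protocol, obj$scheme,
                      params)
    dr <- optimize_dr(rec$cell_map, rec$structures, obj$protocol, obj$scheme,
                      params)
    letd <- make_letd_map(rec$grid, rec$structures, obj$letd)
    tcp_uni <- plan_tcp(uni, rec$cell_map, gtv, params, obj$scheme)
    tcp_de <- plan_tcp(de, rec$cell_map, gtv, params, obj$scheme)
    tcp_dr <- plan_tcp(dr, rec$cell_map, gtv, params, obj$scheme)
    rng <- tcp_uncertainty_range(de, rec$cell_map, rec$rmse_map, model,
                                 params, obj$scheme, gtv)
    list(i = i, rec = rec, uni = uni, de = de, dr = dr, letd = letd,
         tcp_uni = tcp_uni, tcp_de = tcp_de, tcp_dr = tcp_dr, range = rng)
  }))

  report <- stage("evaluate", {
    metrics <- do.call(rbind, lapply(records, function(r) {
      gtv <- r$rec$structures$masks$GTV
      row <- function(mode, plan) data.frame(
        record = r$i, mode = mode,
        D95 = dose_at_volume(plan$dose, gtv, 95),
        D50 = dose_at_volume(plan$dose, gtv, 50),
        D1 = dose_at_volume(plan$dose, gtv, 1),
        Dmean = mean(plan$dose$values[gtv]),
        L98 = let_at_volume(r$letd, gtv, 98),
        L50 = let_at_volume(r$letd, gtv, 50),
        L1 = let_at_volume(r$letd, gtv, 1),
        tcp = switch(mode, uniform = r$tcp_uni, DE = r$tcp_de,
                     DR = r$tcp_dr)$roi_tcp,
        tcp_best = if (mode == "DE") r$range[["best"]] else NA_real_,
        tcp_worst = if (mode == "DE") r$range[["worst"]] else NA_real_)
      rbind(row("uniform", r$uni), row("DE", r$de), row("DR", r$dr))
    }))
    goals <- lapply(records, function(r)
      list(record = r$i,
           uniform = check_goals(r$uni, r$rec$structures, obj$protocol),
           DE = check_goals(r$de, r$rec$structures, obj$protocol),
           DR = check_goals(r$dr, r$rec$structures, obj$protocol)))
    masks <- lapply(records, function(r) r$rec$structures$masks$GTV)
    cells <- lapply(records, function(r) r$rec$cell_map)
    sub_de <- subregion_summary(
      lapply(records, function(r) delta_tcp_map(r$tcp_de$tcp_map,
                                                r$tcp_uni$tcp_map)),
      cells, masks)
    sub_dr <- subregion_summary(
      lapply(records, function(r) delta_tcp_map(r$tcp_dr$tcp_map,
                                                r$tcp_uni$tcp_map)),
      cells, masks)
    tcp_tab <- metrics[, c("record", "mode", "tcp")]
    stat <- if (config$generator$n_eval >= 3)
      cohort_compare(tcp_tab$tcp[tcp_tab$mode == "uniform"],
                     tcp_tab$tcp[tcp_tab$mode == "DE"])
    else NULL  # Mann-Whitney needs at least 3 cases per arm
    list(metrics = metrics, goals = goals, subregions_de = sub_de,
         subregions_dr = sub_dr, uniform_vs_de = stat,
         scenario_count = nrow(scen), rmse_sigma = model$sigma,
         fitted = fitted)
  })

  stage("report", {
    utils::write.csv(report$metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(report$subregions_de$summary,
                     file.path(out_dir, "subregions_de.csv"),
                     row.names = FALSE)
    utils::write.csv(report$subregions_dr$summary,
                     file.path(out_dir, "subregions_dr.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      lapply(report$goals, function(g)
        list(record = g$record, uniform = g$uniform, DE = g$DE, DR = g$DR)),
      file.path(out_dir, "goals.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
    if (isTRUE(config$write_volumes)) {
      for (r in records) {
        write_volume(r$de$dose,
                     file.path(out_dir, sprintf("record%02d_de.nii.gz", r$i)))
        write_volume(r$rec$cell_map,
                     file.path(out_dir, sprintf("record%02d_cells.nii.gz",
                                                r$i)))
      }
    }
    yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
    manifest <- list(
      seed = config$seed, config_fingerprint = config_fingerprint(config),
      n_fit = length(fit_cohort), n_eval = length(eval_cohort),
      scenario_count = nrow(scen), rmse_sigma = model$sigma,
      artifacts = list.files(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  })
  invisible(report)
}
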