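test_that("uniform plan delivers the prescription across the target", {
  ph <- make_phantom(small_phantom_config(), seed = 1)
  up <- uniform_plan(ph$structures)
  gtv <- ph$structures$masks$GTV
  expect_true(all(up$dose$values[gtv] == 73.6))
  expect_true(all(up$dose$values[ph$structures$masks$CTV_LD] == 73.6))
  expect_equal(dose_at_volume(up$dose, gtv, 50), 73.6)
  expect_equal(mean(up$dose$values[gtv]), 73.6)
  # Gaussian penumbra: dose decays outside the CTV_LD
  expect_lt(max(up$dose$values[!ph$structures$masks$CTV_LD]), 73.6)
})

test_that("identical clonogen counts give a flat painted plan", {
  ph <- make_phantom(small_phantom_config(), seed = 2)
  const <- cell_field_params(log_mean = log(2.7e7), log_sd = 0)
  cm <- make_cell_map(ph$grid, ph$structures$masks$GTV, const, seed = 2)$cell_map
  gtv <- ph$structures$masks$GTV
  de <- optimize_de(cm, ph$structures)
  expect_equal(unique(round(de$dose$values[gtv], 6)), 75.808)
  dr <- optimize_dr(cm, ph$structures)
  up <- uniform_plan(ph$structures)
  expect_equal(dr$dose$values[gtv], up$dose$values[gtv], tolerance = 1e-6)
})

test_that("painted plans satisfy box and mean constraints", {
  cs <- small_case(seed = 5)
  gtv <- cs$structures$masks$GTV
  for (planner in list(optimize_de, optimize_dr)) {
    pl <- planner(cs$cell_map, cs$structures)
    d <- pl$dose$values[gtv]
    expect_true(all(d >= 0.95 * 73.6 - 1e-9))
    expect_true(all(d <= 1.10 * 73.6 + 1e-9))
    target <- if (pl$mode == "DE") 1.03 * 73.6 else 73.6
    expect_lt(abs(mean(d) - target), 0.01)
    expect_lt(abs(pl$achieved$mean_residual), 0.01)
    expect_equal(pl$achieved$box_violation, 0)
  }
})

test_that("higher clonogen counts never receive less dose", {
  cs <- small_case(seed = 6)
  gtv <- cs$structures$masks$GTV
  de <- optimize_de(cs$cell_map, cs$structures)
  o <- order(cs$cell_map$values[gtv])
  d_sorted <- de$dose$values[gtv][o]
  expect_true(all(diff(d_sorted) > -1e-6))
})

test_that("DE beats the flat escalated plan; DR beats uniform", {
  for (seed in 1:3) {
    cs <- small_case(seed = seed)
    gtv <- cs$structures$masks$GTV
    counts <- cs$cell_map$values[gtv]
    de <- optimize_de(cs$cell_map, cs$structures)
    flat <- mean(survival_of_dose(rep(1.03 * 73.6, sum(gtv)), counts))
    expect_lte(de$achieved$objective, flat + 1e-12)
    dr <- optimize_dr(cs$cell_map, cs$structures)
    up <- uniform_plan(cs$structures)
    expect_gte(plan_tcp(dr, cs$cell_map, gtv)$roi_tcp,
               plan_tcp(up, cs$cell_map, gtv)$roi_tcp)
  }
})

test_that("box-mean solver handles degenerate and symmetric instances", {
  counts1 <- 2.7e5
  deriv1 <- function(d) {
    eps <- 1e-5
    (survival_of_dose(d + eps, counts1) - survival_of_dose(d, counts1)) / eps
  }
  s1 <- solve_box_mean(deriv1, 69.92, 80.96, 75.808, n_voxels = 1)
  expect_equal(s1$dose, 75.808, tolerance = 1e-4)

  counts2 <- rep(2.7e5, 2)
  deriv2 <- function(d) {
    eps <- 1e-5
    (survival_of_dose(d + eps, counts2) - survival_of_dose(d, counts2)) / eps
  }
  s2 <- solve_box_mean(deriv2, 69.92, 80.96, 75.808, n_voxels = 2)
  expect_equal(s2$dose[1], s2$dose[2], tolerance = 1e-6)
  expect_equal(mean(s2$dose), 75.808, tolerance = 1e-4)

  expect_error(solve_box_mean(deriv1, 69.92, 80.96, 90, n_voxels = 1),
               "infeasible")
})

test_that("permuting voxel order permutes the solution identically", {
  set.seed(8)
  counts <- 10^runif(12, 4, 6.5)
  ph <- make_phantom(tiny_phantom_config(), seed = 8)
  gtv_idx <- which(ph$structures$masks$GTV)[1:12]
  build <- function(cc) {
    vals <- array(0, dim = ph$grid$shape)
    # restrict the GTV to 12 voxels carrying the given counts
    m <- array(FALSE, dim = ph$grid$shape); m[gtv_idx] <- TRUE
    masks <- ph$structures$masks
    masks$GTV <- m
    vals[gtv_idx] <- cc
    list(cm = scalar_volume(vals, ph$grid, "cells_per_voxel"),
         st = structure_set(masks, ph$grid))
  }
  a <- build(counts)
  de_a <- optimize_de(a$cm, a$st)
  perm <- sample(12)
  b <- build(counts[perm])
  de_b <- optimize_de(b$cm, b$st)
  expect_equal(de_b$dose$values[gtv_idx], de_a$dose$values[gtv_idx][perm],
               tolerance = 1e-8)
})

test_that("infeasible protocol mean targets are rejected before solving", {
  expect_error(protocol_spec(mean_frac = 1.2), "mean_frac")
  expect_error(protocol_spec(bound_low_frac = 0), "mean_frac")
  cs <- small_case(seed = 9)
  bad <- protocol_spec(bound_low_frac = 1.05, bound_high_frac = 1.10,
                       mean_frac = 1.05)
  # DR forces mean_frac = 1.00, outside [1.05, 1.10]
  expect_error(optimize_dr(cs$cell_map, cs$structures, bad), "mean_frac|infeasible")
})
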