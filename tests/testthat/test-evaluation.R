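test_that("nearest-rank percentiles and Dx% follow the sort definition", {
  expect_equal(nearest_rank_percentile(1:100, 33), 33)
  expect_equal(nearest_rank_percentile(1:100, 66), 66)
  expect_equal(nearest_rank_percentile(1:100, 100), 100)
  expect_error(nearest_rank_percentile(numeric(0), 50), "empty")
  expect_error(nearest_rank_percentile(1:10, 0), "\\(0, 100\\]")

  g <- grid3d(c(8, 8, 8))
  u <- scalar_volume(array(73.6, c(8, 8, 8)), g)
  mask <- array(TRUE, c(8, 8, 8))
  for (x in c(1, 50, 95, 100))
    expect_equal(dose_at_volume(u, mask, x), 73.6)

  v <- array(0, c(8, 8, 8)); m4 <- array(FALSE, c(8, 8, 8))
  v[1:4] <- c(70, 72, 74, 76); m4[1:4] <- TRUE
  d4 <- scalar_volume(v, g)
  expect_equal(dose_at_volume(d4, m4, 50), 74)
  expect_equal(dose_at_volume(d4, m4, 95), 70)
  expect_equal(dose_at_volume(d4, m4, 1), 76)
  expect_error(dose_at_volume(d4, array(FALSE, c(8, 8, 8)), 50), "empty")
})

test_that("Dx% agrees with a brute-force counting oracle on random fields", {
  set.seed(13)
  g <- grid3d(c(6, 6, 6))
  for (i in 1:40) {
    vals <- array(round(runif(216, 50, 90), 2), c(6, 6, 6))
    mask <- array(runif(216) < 0.5, c(6, 6, 6))
    if (!any(mask)) next
    dv <- scalar_volume(vals, g)
    for (x in c(1, 35, 50, 95, 98)) {
      # oracle: the largest in-ROI dose d with >= x% of voxels receiving >= d
      cand <- sort(unique(vals[mask]), decreasing = TRUE)
      frac <- vapply(cand, function(d) mean(vals[mask] >= d), numeric(1))
      oracle <- max(cand[frac >= x / 100])
      expect_equal(dose_at_volume(dv, mask, x), oracle)
    }
    d <- vapply(c(95, 50, 1), function(x) dose_at_volume(dv, mask, x),
                numeric(1))
    expect_true(d[1] <= d[2] && d[2] <= d[3])
  }
})

test_that("DVH curves are monotone non-increasing from 1", {
  cs <- small_case(seed = 2)
  de <- optimize_de(cs$cell_map, cs$structures)
  curve <- dvh_curve(de$dose, cs$structures$masks$GTV)
  expect_equal(curve$volume_fraction[1], 1)
  expect_true(all(diff(curve$volume_fraction) <= 0))
  lvh <- dvh_curve(make_letd_map(cs$grid, cs$structures),
                   cs$structures$masks$GTV)
  expect_true(all(diff(lvh$volume_fraction) <= 0))
})

test_that("clinical goal audit passes a uniform plan and flags violations", {
  ph <- make_phantom(small_phantom_config(), seed = 1)
  up <- uniform_plan(ph$structures)
  rep_ <- check_goals(up, ph$structures)
  targets <- rep_[rep_$structure %in% c("GTV", "CTV_HD-GTV", "CTV_LD-GTV"), ]
  expect_true(all(targets$pass))
  # hand thresholds: 73.6 > 69.92, 73.6 < 84.64, 73.6 < 77.28
  expect_equal(rep_$limit[rep_$structure == "GTV" & rep_$metric == "D95%"],
               69.92)
  expect_equal(rep_$limit[rep_$structure == "GTV" & rep_$metric == "D1%"],
               84.64)

  # a DE plan obeys the 110% box, hence the 115% GTV near-max goal
  cs <- small_case(seed = 3)
  de <- optimize_de(cs$cell_map, cs$structures)
  gd <- check_goals(de, cs$structures)
  expect_true(gd$pass[gd$structure == "GTV" & gd$metric == "D1%"])

  # small GTV with one voxel forced to 0.9 Dp fails D95%
  g <- grid3d(c(8, 8, 8))
  m <- array(FALSE, c(8, 8, 8)); m[1:8] <- TRUE
  vals <- array(73.6, c(8, 8, 8)); vals[1] <- 0.9 * 73.6
  st <- structure_set(list(GTV = m, CTV_HD = m, CTV_LD = m), g)
  bad <- check_goals(scalar_volume(vals, g), st)
  expect_false(bad$pass[bad$structure == "GTV" & bad$metric == "D95%"])

  # missing structure: explicit failing entry, not a silent skip
  st2 <- structure_set(list(GTV = m, CTV_HD = m, CTV_LD = m), g)
  rep2 <- check_goals(scalar_volume(vals, g), st2,
                      oar_limits = c(rectum = 70))
  expect_true("rectum" %in% rep2$structure)
  expect_false(rep2$pass[rep2$structure == "rectum"])
  expect_true(is.na(rep2$achieved[rep2$structure == "rectum"]))
})

test_that("delta-TCP maps subtract voxel-wise and are antisymmetric", {
  g <- grid3d(c(8, 8, 8))
  a <- scalar_volume(array(83.3, c(8, 8, 8)), g, "tcp_percent")
  b <- scalar_volume(array(75.5, c(8, 8, 8)), g, "tcp_percent")
  d <- delta_tcp_map(a, b)
  expect_equal(unique(as.numeric(d$values)), 7.8, tolerance = 1e-12)
  expect_equal(delta_tcp_map(b, a)$values, -d$values)
  expect_equal(max(abs(delta_tcp_map(a, a)$values)), 0)
  g2 <- grid3d(c(8, 8, 8), spacing = c(2, 2, 2))
  b2 <- scalar_volume(array(75.5, c(8, 8, 8)), g2, "tcp_percent")
  expect_error(delta_tcp_map(a, b2), "grid mismatch")
})

test_that("subregion thresholds come from the pooled population", {
  expect_equal(
    subregion_summary(
      scalar_volume(array(1, c(8, 8, 8)), grid3d(c(8, 8, 8)), "delta_tcp_pp"),
      scalar_volume(array(50, c(8, 8, 8)), grid3d(c(8, 8, 8)),
                    "cells_per_voxel"),
      array(TRUE, c(8, 8, 8)), pooled_counts = 1:100)$thresholds,
    c(33, 66))

  # constant cell map occupies one bin, the others are reported missing
  g <- grid3d(c(8, 8, 8))
  sub <- subregion_summary(
    scalar_volume(array(2, c(8, 8, 8)), g, "delta_tcp_pp"),
    scalar_volume(array(10, c(8, 8, 8)), g, "cells_per_voxel"),
    array(TRUE, c(8, 8, 8)), pooled_counts = 1:100)
  s <- sub$summary[sub$summary$record == "1", ]
  expect_equal(s$n_voxels[s$bin == "low"], 512)
  expect_true(is.na(s$mean_delta_tcp[s$bin == "medium"]))
  expect_true(is.na(s$mean_delta_tcp[s$bin == "high"]))

  # pooled thresholds are invariant under record order
  cs1 <- small_case(seed = 1); cs2 <- small_case(seed = 2)
  dmap <- function(cs) scalar_volume(array(0, dim = cs$grid$shape), cs$grid,
                                     "delta_tcp_pp")
  masks <- list(cs1$structures$masks$GTV, cs2$structures$masks$GTV)
  t12 <- subregion_summary(list(dmap(cs1), dmap(cs2)),
                           list(cs1$cell_map, cs2$cell_map), masks)$thresholds
  t21 <- subregion_summary(list(dmap(cs2), dmap(cs1)),
                           list(cs2$cell_map, cs1$cell_map),
                           rev(masks))$thresholds
  expect_identical(t12, t21)
})

test_that("cohort comparison runs Shapiro then Mann-Whitney", {
  same <- cohort_compare(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_false(same$significant)
  expect_gt(same$p_value, 0.9)

  a <- c(1, 2, 3); b <- c(10, 11, 12)
  res <- cohort_compare(a, b)
  # brute-force U for sample a: count of pairs with a_i > b_j (plus ties/2)
  u <- sum(outer(a, b, `>`)) + 0.5 * sum(outer(a, b, `==`))
  expect_equal(res$statistic, u)
  expect_equal(res$statistic, 0)
  swapped <- cohort_compare(b, a)
  expect_equal(res$p_value, swapped$p_value)

  const <- cohort_compare(c(5, 5, 5), c(1, 2, 3))
  expect_true(any(grepl("constant", const$notes)))
  expect_true(is.na(const$shapiro_p[["a"]]))
  expect_error(cohort_compare(c(1, 2), c(1, 2, 3)), "at least 3")
})
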