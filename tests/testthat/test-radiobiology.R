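test_that("equieffective dose follows the LQ conversion", {
  sch <- fractionation_scheme()
  expect_identical(eqd(0, sch), 0)
  expect_equal(eqd(73.6, sch), 73.6)              # identity at 4.6 Gy/fx
  expect_equal(eqd(80, sch), 80 * 7 / 6.6)        # hand evaluation
  expect_error(eqd(-1, sch), "non-negative")
  # convex increasing in D
  d <- seq(0, 90, by = 0.5)
  e <- eqd(d, sch)
  expect_true(all(diff(e) > 0))
  expect_true(all(diff(diff(e)) > -1e-12))
  # array in, array out
  arr <- array(c(0, 73.6, 80, 10), c(2, 2, 1))
  expect_equal(dim(eqd(arr, sch)), dim(arr))
})

test_that("D50 grows logarithmically with clonogen count", {
  expect_equal(d50_of_count(1, tcp_params(delta = 40, phi = 0.37)), 40)
  expect_equal(d50_of_count(12345, tcp_params(delta = 40, phi = 0)), 40)
  expect_equal(d50_of_count(exp(10), tcp_params(delta = 40, phi = 0.05)), 60)
  cc <- exp(seq(8, 16, by = 0.5))
  expect_true(all(diff(d50_of_count(cc, tcp_params(phi = 0.06))) > 0))
  expect_error(d50_of_count(0, tcp_params()), "positive")
  expect_error(d50_of_count(c(1e5, -2), tcp_params()), "positive")
})

test_that("voxel TCP is 50 at D50 and behaves monotonically", {
  set.seed(42)
  for (i in 1:25) {
    p <- tcp_params(gamma = runif(1, 0.5, 3), delta = runif(1, 20, 60),
                    phi = runif(1, 0, 0.1))
    c_i <- 10^runif(1, 3, 7)
    d50 <- d50_of_count(c_i, p)
    expect_equal(voxel_tcp(d50, c_i, p)$tcp, 50, tolerance = 1e-13)
  }
  # essentially zero control at zero dose
  expect_lt(voxel_tcp(0, 2.7e5, tcp_params(gamma = 2))$tcp, 1e-3)
  expect_equal(voxel_tcp(0, 2.7e5, tcp_params(gamma = 2))$survival,
               exp(exp(2)))
  # monotone: increasing in EQD, decreasing in count for phi > 0
  # (strictly, wherever TCP has not underflowed to 0 at very low dose)
  doses <- seq(0, 120, by = 1)
  tcp_d <- voxel_tcp(doses, 2.7e5, tcp_params())$tcp
  expect_true(all(diff(tcp_d) >= 0))
  expect_true(all(diff(tcp_d[tcp_d > 1e-8]) > 0))
  counts <- exp(seq(9, 15, by = 0.25))
  tcp_c <- voxel_tcp(rep(73.6, length(counts)), counts, tcp_params())$tcp
  expect_true(all(diff(tcp_c) < 0))
  expect_error(voxel_tcp(-1, 1e5), "non-negative")
})

test_that("ROI TCP is the volume-weighted aggregate of voxel survivals", {
  g <- grid3d(c(8, 8, 8))
  # constant voxel TCP t gives ROI TCP t
  t_target <- 73.2
  s_const <- -log(t_target / 100)
  mask <- array(TRUE, c(8, 8, 8))
  r <- roi_tcp(array(s_const, c(8, 8, 8)), mask, g)
  expect_equal(r$roi_tcp, t_target)
  expect_equal(r$roi_tcp, 100 * exp(-r$roi_survival))

  # two equal-volume voxels, hand value
  g2 <- grid3d(c(8, 8, 8))
  s2 <- array(0, c(8, 8, 8)); m2 <- array(FALSE, c(8, 8, 8))
  s2[1, 1, 1] <- 0.2; s2[2, 1, 1] <- 0.6
  m2[1:2, 1, 1] <- TRUE
  r2 <- roi_tcp(s2, m2, g2)
  expect_equal(r2$roi_survival, 0.4)
  expect_equal(r2$roi_tcp, 100 * exp(-0.4), tolerance = 1e-12)
  expect_equal(round(r2$roi_tcp, 2), 67.03)
  expect_error(roi_tcp(s2, array(FALSE, c(8, 8, 8)), g2), "empty")
})

test_that("ROI TCP equals the volume-weighted product of voxel TCPs", {
  set.seed(7)
  g <- grid3d(c(10, 10, 10))
  for (i in 1:20) {
    s <- array(runif(1000, 0.01, 3), c(10, 10, 10))
    mask <- array(runif(1000) < 0.4, c(10, 10, 10))
    if (!any(mask)) next
    r <- roi_tcp(s, mask, g)
    n <- sum(mask)
    prod_form <- 100 * exp(sum(log(exp(-s[mask]))) / n)  # prod TCP_i^(1/n)
    expect_equal(r$roi_tcp, prod_form, tolerance = 1e-10)
  }
})

test_that("plan_tcp excludes zero-count voxels with their volume", {
  cs <- small_case(seed = 4)
  gtv <- cs$structures$masks$GTV
  vals <- cs$cell_map$values
  idx <- which(gtv)[1:5]
  vals[idx] <- 0
  cm <- scalar_volume(vals, cs$grid, "cells_per_voxel")
  r <- plan_tcp(uniform_plan(cs$structures), cm, gtv)
  expect_identical(r$n_excluded, 5L)
  expect_true(all(r$tcp_map$values[idx] == 0))
  # aggregation over the remaining voxels only
  keep <- gtv & vals > 0
  s <- survival_of_dose(rep(73.6, sum(keep)), vals[keep])
  expect_equal(r$roi_survival, mean(s))
})

test_that("bounded least-squares fit honours collapsed bounds and ordering", {
  coh <- make_cohort(8, seed = 3, config = tiny_phantom_config())
  pt <- list(gamma = c(2, 2), delta = c(37.62, 37.62), phi = c(0.06, 0.06))
  fit <- fit_tcp_params(coh, bounds = pt)
  expect_equal(fit$gamma, 2)
  expect_equal(fit$delta, 37.62)
  expect_true(is.finite(attr(fit, "loss")))

  b <- list(gamma = c(1.8, 2.2), delta = c(30, 45), phi = c(0.02, 0.1))
  f1 <- fit_tcp_params(coh, bounds = b, n_starts = 4, seed = 9)
  f2 <- fit_tcp_params(rev(coh), bounds = b, n_starts = 4, seed = 9)
  expect_equal(unclass(f1)[c("gamma", "delta", "phi")],
               unclass(f2)[c("gamma", "delta", "phi")])

  sure <- make_cohort(4, tcp_params(delta = 1e-3), seed = 1,
                      config = tiny_phantom_config())
  expect_warning(fit_tcp_params(sure, bounds = pt), "degenerate")
})
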