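test_that("sensitivity matrix is single-point calibration of the standards", {
  std <- kf_spectrum(c(240, 250), c(0.5, 1.0), "drug")
  H <- build_sensitivity_matrix(align_to_grid(list(std)), c(drug = 5))
  expect_equal(unname(H$values[, 1]), c(0.1, 0.2))
  expect_equal(H$components, "drug")

  other <- kf_spectrum(c(241, 251), c(0.5, 1.0), "other")
  expect_error(build_sensitivity_matrix(list(std, other), c(5, 20)),
               "mismatch")
  expect_error(build_sensitivity_matrix(align_to_grid(list(std)),
                                        c(drug = 0)), "> 0")
  zero <- kf_spectrum(c(240, 250), c(0, 0), "dead")
  expect_error(build_sensitivity_matrix(align_to_grid(list(zero)),
                                        c(dead = 5)), "nobservable")

  # preset standard peaks where its band model says it should
  pre <- preset_fixture()
  expect_equal(pre$grid[which.max(pre$H$values[, "HCT"])], 272)
  expect_equal(pre$grid[which.max(pre$H$values[, "LSP"])], 235)
})

test_that("a single measurement update follows the scalar Kalman algebra", {
  # zero prior, zero measurement: nothing moves
  st <- kalman_step(c(0, 0), diag(2), c(1, 0), 0, 1e-6)
  expect_equal(st$estimate, c(0, 0))
  expect_equal(st$innovation, 0)

  # diffuse-prior limit: one update pulls the estimate to A
  st <- kalman_step(0, matrix(1e12), 1, 0.7, 1e-6)
  expect_equal(st$estimate, 0.7, tolerance = 1e-9)

  # two-state closed form evaluated independently of the implementation
  P0 <- 1e6; r <- 1e-6; h <- c(1, 0.5); A <- 2
  g <- P0 * h / (sum(h^2) * P0 + r)
  st <- kalman_step(c(0, 0), diag(P0, 2), h, A, r)
  expect_equal(st$estimate, g * A, tolerance = 1e-12)
  expect_equal(st$innovation, 2)
  # covariance update matches P - g (h P) evaluated by hand
  P_manual <- diag(P0, 2) - (g %o% h) * P0
  expect_equal(st$covariance, (P_manual + t(P_manual)) / 2,
               tolerance = 1e-6)

  expect_error(kalman_step(c(0, 0), diag(2), c(1, NA), 0, 1e-6), "finite")
  expect_error(kalman_step(c(0, 0), diag(2), c(1), 0, 1e-6), "dimension")
  expect_error(kalman_step(0, matrix(1), 1, 0, 0), "> 0")
})

test_that("the filter solves exact linear systems and flags bad input", {
  # single-component proportionality: sample is twice the standard
  pre <- preset_fixture()
  sample <- kf_spectrum(pre$grid, 2 * 5 * pre$H$values[, "HCT"], "2xHCT5")
  res <- run_filter(pre$H, sample)
  expect_equal(unname(res$estimate), c(10, 0), tolerance = 1e-6)
  expect_true(res$converged)

  # exactly solvable 3-wavelength, 2-component system
  sys <- tiny_system()
  res <- run_filter(sys$H, sys$sample)
  expect_equal(unname(res$estimate), sys$truth, tolerance = 1e-6)
  expect_equal(length(res$innovations),
               length(sys$H$grid) * res$passes_used)

  off <- kf_spectrum(c(241, 251, 261), sys$sample$absorbances, "off")
  expect_error(run_filter(sys$H, off), "grid")

  # negative estimates are reported with a warning, never clipped
  neg <- kf_spectrum(sys$H$grid, drop(sys$H$values %*% c(1, -0.5)), "neg")
  expect_warning(resn <- run_filter(sys$H, neg), "negative")
  expect_equal(unname(resn$estimate), c(1, -0.5), tolerance = 1e-6)
})

test_that("noisy two-drug mixtures are recovered within assay accuracy", {
  pre <- preset_fixture()
  mix <- mixture_spectrum(list(pre$hct, pre$lsp), c(5, 20), pre$grid,
                          sigma = 0.002, seed = 101, label_prefix = "M7")
  res <- run_filter(pre$H, mix$spectra[[1]])
  expect_lt(max(abs(relative_error(res$estimate, c(5, 20)))), 2)
})

test_that("the least-squares oracle agrees with hand-solved systems", {
  sys <- tiny_system()
  o <- cls_oracle(sys$H, sys$sample)
  expect_equal(unname(o$estimate), sys$truth, tolerance = 1e-12)

  # noiseless single component: pure scale recovery
  pre <- preset_fixture()
  s <- kf_spectrum(pre$grid, 3.7 * 5 * pre$H$values[, "HCT"], "s")
  Hh <- kf_sensitivity(pre$grid, "HCT", pre$H$values[, "HCT", drop = FALSE])
  expect_equal(unname(cls_oracle(Hh, s)$estimate), 3.7 * 5,
               tolerance = 1e-12)

  # collinear columns are named in the singularity error
  Hc <- kf_sensitivity(c(240, 250), c("p", "q"),
                       matrix(c(1, 2, 1, 2), ncol = 2))
  sc <- kf_spectrum(c(240, 250), c(1, 2), "s")
  expect_error(cls_oracle(Hc, sc), "q")
})

test_that("converged filter matches the oracle, is order-invariant and linear", {
  set.seed(2024)
  for (i in 1:25) {
    sys <- random_system(sample(2:4, 1), sample(10:81, 1))
    noisy <- kf_spectrum(sys$H$grid,
                         sys$sample$absorbances +
                           rnorm(length(sys$H$grid), 0, 0.002), "n")
    kf <- run_filter(sys$H, noisy)
    o <- cls_oracle(sys$H, noisy)
    expect_lt(max(abs(kf$estimate - o$estimate) / abs(o$estimate)), 1e-6)
    # descending sweep converges to the same answer
    kd <- run_filter(sys$H, noisy, order = "descending")
    expect_lt(max(abs(kd$estimate - kf$estimate) / abs(kf$estimate)), 1e-6)
  }

  # linearity: scaling the spectrum scales the estimates (noiseless)
  sys <- tiny_system()
  base <- run_filter(sys$H, sys$sample)$estimate
  for (k in c(0.25, 3, 10)) {
    scaled <- kf_spectrum(sys$H$grid, k * sys$sample$absorbances, "k")
    expect_equal(unname(run_filter(sys$H, scaled)$estimate),
                 unname(k * base), tolerance = 1e-9)
  }
})

test_that("posterior variances contract monotonically across updates", {
  pre <- preset_fixture()
  sample <- component_spectrum(pre$hct, 5, pre$grid)
  est <- c(0, 0); P <- diag(1e6, 2)
  for (i in seq_along(pre$grid)) {
    st <- kalman_step(est, P, pre$H$values[i, ], sample$absorbances[i], 1e-6)
    expect_true(all(diag(st$covariance) <= diag(P) * (1 + 1e-12)))
    est <- st$estimate; P <- st$covariance
  }
  # Joseph form keeps the same contraction
  P <- diag(1e6, 2); est <- c(0, 0)
  for (i in seq_along(pre$grid)) {
    st <- kalman_step(est, P, pre$H$values[i, ], sample$absorbances[i],
                      1e-6, joseph = TRUE)
    expect_true(all(diag(st$covariance) <= diag(P) * (1 + 1e-12)))
    est <- st$estimate; P <- st$covariance
  }
})

test_that("innovation diagnostics summarize filter health", {
  expect_error(innovation_diagnostics(numeric(0)), "empty")
  d <- innovation_diagnostics(c(0, 0, 0))
  expect_equal(d$mean, 0)
  expect_equal(d$variance, 0)
  expect_true(is.na(d$lag1_autocorrelation))
  d <- innovation_diagnostics(c(1, -1, 1, -1))
  expect_equal(d$mean, 0)
  expect_equal(d$lag1_autocorrelation, -1)
  # converged noiseless run: innovations of the final sweep are ~0
  sys <- tiny_system()
  res <- run_filter(sys$H, sys$sample)
  last_sweep <- tail(res$innovations, length(sys$H$grid))
  expect_lt(stats::var(last_sweep), 1e-12)
})
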