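test_that("Hessian of simple analytic fields is recovered", {
  # constant volume: all-zero Hessian
  h0 <- compute_hessian(scalar_volume(array(0.5, c(12, 12, 12))), 1)
  for (cmp in c("hxx", "hyy", "hzz", "hxy", "hxz", "hyz"))
    expect_equal(max(abs(h0[[cmp]])), 0, tolerance = 1e-12)

  # separable quadratic I = x^2: H_xx = 2 in the interior, others 0
  n <- 24
  q <- array(rep((seq_len(n) / n)^2, times = n * n), c(n, n, n))
  hq <- compute_hessian(scalar_volume(q, intensity_domain = c(0, 1)), 1)
  interior <- 6:(n - 6)
  expect_equal(mean(hq$hxx[interior, interior, interior]) * n^2, 2,
               tolerance = 1e-6)
  expect_lt(max(abs(hq$hyy[interior, interior, interior])), 1e-10)
  expect_lt(max(abs(hq$hxy[interior, interior, interior])), 1e-10)

  # isotropic Gaussian blob: H at the center is c * Identity with c < 0
  s <- make_sphere(c(21, 21, 21), c(11, 11, 11), radius = 3, peak = 0.9)
  hb <- compute_hessian(s$volume, 1)
  cc <- hb$hxx[11, 11, 11]
  expect_lt(cc, 0)
  expect_equal(hb$hyy[11, 11, 11], cc, tolerance = 1e-8)
  expect_equal(hb$hzz[11, 11, 11], cc, tolerance = 1e-8)
  expect_lt(abs(hb$hxy[11, 11, 11]), 1e-10)

  expect_error(compute_hessian(scalar_volume(array(0, c(3, 3, 3))), 2), "kernel")
})

test_that("eigendecomposition sorts by signed value and pairs e3 with lambda3", {
  mk <- function(hxx, hyy, hzz, hxy = 0, hxz = 0, hyz = 0)
    structure(list(hxx = array(hxx, c(1, 1, 1)), hyy = array(hyy, c(1, 1, 1)),
                   hzz = array(hzz, c(1, 1, 1)), hxy = array(hxy, c(1, 1, 1)),
                   hxz = array(hxz, c(1, 1, 1)), hyz = array(hyz, c(1, 1, 1)),
                   scale = 1), class = "hessian_field")
  eg <- eigen_decompose(mk(-4, -2, -1))
  expect_equal(as.vector(eg$values), c(-4, -2, -1))
  expect_equal(abs(as.vector(eg$e3)), c(0, 0, 1))

  z <- eigen_decompose(mk(0, 0, 0))
  expect_equal(as.vector(z$values), c(0, 0, 0))
  expect_equal(sum(as.vector(z$e3)^2), 1)  # unit eigenvector even when degenerate

  # random symmetric matrices agree with base eigen()
  set.seed(8)
  for (rep in 1:20) {
    v <- rnorm(6)
    eg <- eigen_decompose(mk(v[1], v[2], v[3], v[4], v[5], v[6]))
    M <- matrix(c(v[1], v[4], v[5], v[4], v[2], v[6], v[5], v[6], v[3]), 3, 3)
    ref <- eigen(M, symmetric = TRUE)
    expect_equal(as.vector(eg$values), rev(ref$values), tolerance = 1e-12)
    expect_equal(abs(sum(as.vector(eg$e3) * ref$vectors[, 1])), 1,
                 tolerance = 1e-10)
  }

  bad <- mk(NaN, 0, 0)
  expect_error(eigen_decompose(bad), "finite")
})

test_that("the tube-axis eigenvector aligns with an analytic cylinder axis", {
  u <- c(1, 2, 0.5); u <- u / sqrt(sum(u^2))
  tube <- make_tube(c(32, 32, 32), c(16, 16, 16), u, radius = 3, peak = 0.9)
  eg <- eigen_decompose(compute_hessian(tube$volume, 1))
  d2 <- tfshift:::line_dist2(c(32, 32, 32), c(16, 16, 16), u)
  on_axis <- which(d2 <= 0.25, arr.ind = TRUE)
  on_axis <- on_axis[apply(on_axis, 1, function(p) all(p > 5 & p < 28)), ]
  ev <- cbind(eg$values[cbind(on_axis, 1)], eg$values[cbind(on_axis, 2)],
              eg$values[cbind(on_axis, 3)])
  # two strongly negative transverse curvatures, near-zero axial
  expect_true(all(ev[, 1] < 0 & ev[, 2] < 0))
  expect_true(all(abs(ev[, 3]) < 0.2 * abs(ev[, 1])))
  dots <- abs(eg$e3[cbind(on_axis, 1)] * u[1] + eg$e3[cbind(on_axis, 2)] * u[2] +
              eg$e3[cbind(on_axis, 3)] * u[3])
  expect_gte(mean(dots), 0.95)
})

test_that("lambda_ratio evaluates each branch of the piecewise definition", {
  expect_equal(lambda_ratio(-4, -2, -1), 0.25)   # all non-positive
  expect_equal(lambda_ratio(-4, -2, 1), 0.5)     # lambda3 > 0
  expect_equal(lambda_ratio(1, 2, 3), 0)         # bright-structure guard
  expect_equal(lambda_ratio(0, 0, 0), 0)         # degenerate: quotient undefined
  expect_equal(lambda_ratio(-1, -1, 0), 1)       # ideal tube limit
  expect_error(lambda_ratio(1, -1, 0), "lambda1 <= lambda2")
})

test_that("lambda_ratio is scale-invariant and bounded in [0, 1]", {
  set.seed(13)
  for (rep in 1:200) {
    l <- sort(rnorm(3))
    v <- lambda_ratio(l[1], l[2], l[3])
    expect_gte(v, 0); expect_lte(v, 1)
    for (c_ in c(0.01, 3, 1e4))
      expect_equal(lambda_ratio(c_ * l[1], c_ * l[2], c_ * l[3]), v,
                   tolerance = 1e-12)
  }
})

test_that("corrected_e3 zeroes the axis where structure is not bright", {
  expect_equal(as.vector(corrected_e3(-4, -2, c(0, 0, 1))), c(0, 0, 1))
  expect_equal(as.vector(corrected_e3(-1, 2, c(0.6, 0.8, 0))), c(0, 0, 0))
  # vectorized over rows
  out <- corrected_e3(c(-1, 1), c(-0.5, 2), rbind(c(1, 0, 0), c(0, 1, 0)))
  expect_equal(out, rbind(c(1, 0, 0), c(0, 0, 0)))
})

test_that("feature volume computes metric context and suppresses background", {
  tube <- make_tube(c(32, 32, 32), c(16, 16, 16), c(1, 1, 0), radius = 2,
                    peak = 0.9)
  fv <- build_feature_volume(tube$volume)
  expect_true(all(fv$lambda_ratio >= 0 & fv$lambda_ratio <= 1))
  expect_gt(fv$sigma_lambda, 0)
  # axis measure strictly exceeds background measure
  d2 <- tfshift:::line_dist2(c(32, 32, 32), c(16, 16, 16), c(1, 1, 0) / sqrt(2))
  interior <- array(FALSE, c(32, 32, 32)); interior[6:27, 6:27, 6:27] <- TRUE
  expect_gt(min(fv$lambda_ratio[d2 <= 0.25 & interior]),
            max(fv$lambda_ratio[d2 > 36 & interior]))
  # e3 norms are 1 or exactly 0
  nrm <- sqrt(matrix(fv$e3, ncol = 3)^2 %*% c(1, 1, 1))
  expect_true(all(abs(nrm - 1) < 1e-10 | nrm == 0))
  # covariance is symmetric positive definite after regularization
  expect_equal(fv$covariance, t(fv$covariance))
  expect_true(all(eigen(fv$covariance, symmetric = TRUE)$values > 0))
})

test_that("constant volumes yield null features", {
  fv <- build_feature_volume(scalar_volume(array(0.5, c(12, 12, 12))))
  expect_true(all(fv$lambda_ratio == 0))
  expect_true(all(fv$e3 == 0))
  expect_equal(fv$sigma_lambda, 0)
})

test_that("duplicated channels are regularized to an invertible covariance", {
  vol <- wavy_volume(12)
  fv <- build_feature_volume(vol, channel_spec = c("intensity", "intensity"))
  raw <- cov(fv$channels)
  expect_lt(rcond(raw), 1e-14)              # singular before regularization
  expect_no_error(solve(fv$covariance))     # invertible after
  expect_error(build_feature_volume(vol, channel_spec = character(0)),
               "channel_spec")
})
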