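test_that("dissimilarity metrics evaluate to their closed-form values", {
  # Mahalanobis
  expect_equal(dissim_mahalanobis(c(1, 2), c(1, 2), diag(2)), 0)
  expect_equal(dissim_mahalanobis(c(3, 4), c(0, 0), diag(2)), 5)
  expect_equal(dissim_mahalanobis(c(2, 0), c(0, 0), diag(c(4, 1))), 1)
  expect_true(is.finite(dissim_mahalanobis(c(1, 1), c(0, 0), diag(2))))
  expect_error(dissim_mahalanobis(c(1, 1), c(0, 0), matrix(1, 2, 2)))
  # symmetry in the two vector arguments
  set.seed(2)
  V <- crossprod(matrix(rnorm(9), 3)) + diag(3)
  a <- rnorm(3); b <- rnorm(3)
  expect_equal(dissim_mahalanobis(a, b, V), dissim_mahalanobis(b, a, V))

  # inner product
  expect_equal(dissim_dot(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(dissim_dot(c(1, 0, 0), c(0, 1, 0)), 1)
  expect_equal(dissim_dot(c(1, 0, 0), c(-1, 0, 0)), 2)
  # unnormalized inputs are normalized before use
  expect_equal(dissim_dot(c(5, 0, 0), c(0.1, 0, 0)), 0)

  # orientation: sign-invariant, zero vectors maximally dissimilar
  expect_equal(dissim_orientation(c(0, 0, 1), c(0, 0, -1)), 0)
  expect_equal(dissim_orientation(c(1, 0, 0), c(0, 1, 0)), 1)
  th <- 60 * pi / 180
  expect_equal(dissim_orientation(c(cos(th), sin(th), 0), c(1, 0, 0)), 0.5)
  expect_equal(dissim_orientation(c(0, 0, 0), c(1, 0, 0)), 1)

  # standardized linear-structure distance
  expect_equal(dissim_lambda_ratio(0.4, 0.4, 0.2), 0)
  expect_equal(dissim_lambda_ratio(0.5, 0.2, 0.3), 1)
  expect_equal(dissim_lambda_ratio(0.8, 0.2, 0.3), 2)
  expect_error(dissim_lambda_ratio(0.5, 0.2, 0), "positive")
})

test_that("sensitivity and locality weights match their formulas", {
  expect_equal(feature_weight(0, 5), 1)
  expect_equal(feature_weight(0.7, 0), 1)
  expect_equal(feature_weight(0.1, 10), exp(-1))
  expect_equal(locality_weight(6, 6), 0.5)
  expect_equal(locality_weight(0, 6), 1 / (1 + exp(-6)))
  expect_lt(locality_weight(26, 6), 1e-8)
})

test_that("g = f_F * f_E stays in [0, 1] over random inputs", {
  set.seed(21)
  d_f <- rexp(500); d_e <- rexp(500) * 30
  alpha <- runif(500, 0, 100); beta <- runif(500, 0, 20)
  g <- feature_weight(d_f, alpha) * locality_weight(d_e, beta)
  expect_true(all(g >= 0 & g <= 1))
})

test_that("region distance takes the minimum over stroke centers with anisotropy", {
  expect_equal(roi_distance(c(4, 5, 6), rbind(c(4, 5, 6))), 0)
  expect_equal(roi_distance(c(3, 4, 0), rbind(c(0, 0, 0))), 5)
  # two centers: min rule
  expect_equal(roi_distance(c(0, 0, 0), rbind(c(7, 0, 0), c(0, 2, 0))), 2)
  # anisotropic spacing scales per axis relative to x
  expect_equal(roi_distance(c(0, 0, 1), rbind(c(0, 0, 0)), spacing = c(1, 1, 4)), 4)
  expect_error(roi_distance(c(0, 0, 0), matrix(0, 0, 3)), "non-empty")
})

test_that("the shift field matches a brute-force voxel-by-voxel evaluation", {
  vol <- wavy_volume(16)
  fv <- build_feature_volume(vol)
  for (metric in c("orientation", "lambda_ratio", "mahalanobis", "dot")) {
    ed <- edit_operation(x0 = c(8, 8, 8),
                         stroke_centers = rbind(c(8, 8, 8), c(11, 6, 9)),
                         alpha = 10, beta = 6, metric = metric)
    sf <- compute_shift_field(vol, fv, ed)
    ref <- array(0, c(16, 16, 16))
    for (i in 1:16) for (j in 1:16) for (k in 1:16)
      ref[i, j, k] <- brute_shift_at(vol, fv, ed, i, j, k)
    expect_equal(sf$delta, ref, tolerance = 1e-10)
  }
})

test_that("the identity condition holds exactly at the reference intensity", {
  vol <- wavy_volume(16)
  fv <- build_feature_volume(vol)
  ed <- edit_operation(c(8, 8, 8), c(8, 8, 8), alpha = 3, beta = 10,
                       metric = "lambda_ratio")
  sf <- compute_shift_field(vol, fv, ed)
  same <- vol$data == vol$data[8, 8, 8]
  expect_true(any(same))
  expect_true(all(sf$delta[same] == 0))
  expect_identical(sf$delta[8, 8, 8], 0)
})

test_that("shift magnitude is monotone in alpha and beta", {
  vol <- wavy_volume(16)
  fv <- build_feature_volume(vol)
  mk <- function(alpha, beta)
    abs(compute_shift_field(vol, fv, edit_operation(
      c(8, 8, 8), c(6, 10, 8), alpha, beta, "mahalanobis"))$delta)
  a1 <- mk(1, 6); a10 <- mk(10, 6); a100 <- mk(100, 6)
  expect_true(all(a10 <= a1 + 1e-15))      # increasing alpha never increases |Delta|
  expect_true(all(a100 <= a10 + 1e-15))
  b1 <- mk(5, 1); b10 <- mk(5, 10); b20 <- mk(5, 20)
  expect_true(all(b10 >= b1 - 1e-15))      # increasing beta never decreases |Delta|
  expect_true(all(b20 >= b10 - 1e-15))
})

test_that("a reference with no defined orientation warns and suppresses everything", {
  vol <- wavy_volume(16)
  fv <- build_feature_volume(vol)
  # find a voxel whose corrected axis vector is zero
  nrm <- sqrt(rowSums(matrix(fv$e3, ncol = 3)^2))
  z <- which(nrm == 0)[1]
  d <- c(16, 16, 16)
  x0 <- c((z - 1) %% 16 + 1, ((z - 1) %/% 16) %% 16 + 1, (z - 1) %/% 256 + 1)
  ed <- edit_operation(x0, x0, alpha = 1, beta = 50, metric = "orientation")
  expect_warning(sf <- compute_shift_field(vol, fv, ed), "orientation")
  # d_F = 1 everywhere: the shift is the alpha-damped intensity difference
  I0 <- vol$data[x0[1], x0[2], x0[3]]
  g_max <- exp(-1) * 1
  expect_true(all(abs(sf$delta) <= abs(I0 - vol$data) * g_max + 1e-12))
})

test_that("shift fields combine linearly and respect disjoint regions", {
  vol <- wavy_volume(16)
  fv <- build_feature_volume(vol)
  e1 <- edit_operation(c(3, 3, 3), c(2, 2, 2), 0, 2, "lambda_ratio")
  e2 <- edit_operation(c(14, 14, 14), c(15, 15, 15), 0, 2, "lambda_ratio")
  f1 <- compute_shift_field(vol, fv, e1)
  f2 <- compute_shift_field(vol, fv, e2)
  both <- combine_shift_fields(list(f1, f2))
  expect_equal(both$delta, f1$delta + f2$delta)
  expect_length(both$provenance, 2)
  # single field returns itself; negation cancels
  expect_equal(combine_shift_fields(list(f1))$delta, f1$delta)
  neg <- f1; neg$delta <- -neg$delta
  expect_true(all(combine_shift_fields(list(f1, neg))$delta == 0))
  # far-apart edits do not interact beyond the locality tail
  far <- tfshift:::roi_distance(tfshift:::voxel_grid(c(16, 16, 16)),
                                e1$stroke_centers) >= e1$beta + 20
  if (any(far)) expect_true(all(abs(f1$delta)[far] < 1e-8))
  bad <- f2; bad$delta <- array(0, c(8, 8, 8))
  expect_error(combine_shift_fields(list(f1, bad)), "grids")
})

test_that("the shifted lookup clamps and reduces to the preset at zero shift", {
  tf <- transfer_function(data.frame(intensity = c(0, 0.8, 1),
                                     r = c(0, 0, 1), g = 0, b = 0,
                                     a = c(0, 0, 1)))
  expect_equal(evaluate_shifted_tf(tf, 0.4, 0), tf_evaluate(tf, 0.4))
  # I + Delta above the domain clamps to the max endpoint
  expect_equal(unname(evaluate_shifted_tf(tf, 0.9, 0.5)[, "a"]), 1)
  # hand lookup: 0.3 + 0.6 = 0.9, halfway up the 0.8..1 opacity ramp
  expect_equal(unname(evaluate_shifted_tf(tf, 0.3, 0.6)[, "a"]), 0.5)
  expect_equal(unname(evaluate_shifted_tf(tf, 0.3, 0.6)[, "r"]), 0.5)
})

test_that("transfer-function presets validate and round-trip through JSON", {
  tf <- ramp_preset()
  path <- withr::local_tempfile(fileext = ".json")
  write_tf_preset(tf, path)
  back <- read_tf_preset(path)
  expect_equal(back$control_points, tf$control_points)
  expect_error(transfer_function(data.frame(intensity = c(0, 0), r = 0, g = 0,
                                            b = 0, a = 0)), "increasing")
  expect_error(transfer_function(data.frame(intensity = c(0, 1), r = 2, g = 0,
                                            b = 0, a = 0)), "\\[0, 1\\]")
  expect_error(transfer_function(data.frame(intensity = 0, r = 0, g = 0, b = 0,
                                            a = 0)), "2 control points")
  # clamped evaluation outside the domain
  expect_equal(unname(tf_evaluate(tf, c(-1, 2))[, "a"]),
               c(tf$control_points$a[1], tf$control_points$a[4]))
})

test_that("edit operations validate their parameters and bounds", {
  expect_error(edit_operation(c(1, 1), c(1, 1, 1), 1, 1), "3-vector")
  expect_error(edit_operation(c(1, 1, 1), c(1, 1, 1), -1, 1), "alpha")
  expect_error(edit_operation(c(1, 1, 1), c(1, 1, 1), 1, -2), "beta")
  expect_error(edit_operation(c(20, 1, 1), c(1, 1, 1), 1, 1,
                              bounds = c(16, 16, 16)), "bounds")
  ed <- edit_operation(c(2, 3, 4), rbind(c(1, 1, 1), c(2, 2, 2)), 0, 0)
  expect_s3_class(ed, "edit_operation")
  expect_equal(nrow(ed$stroke_centers), 2)
})
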