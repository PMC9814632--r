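test_that("radial spectrum locates pure modes on the lattice", {
  x <- (0:127) * 0.25
  f <- outer(x, x, function(xx, yy) cos(1.178 * xx))  # lattice mode near 1.2
  rps <- radial_power_spectrum(f, 0.25)
  expect_equal(dominant_k <- rps$k[which.max(rps$power[-1]) + 1], 1.2,
               tolerance = rps$bin_width / 1.2)
  # constant field: all power in the k = 0 bin
  rps0 <- radial_power_spectrum(matrix(3.7, 64, 64), 0.25)
  expect_equal(sum(rps0$power[-1]), 0)
})

test_that("fixtures classify to their construction labels", {
  bw <- 2 * pi / (128 * 0.25)
  fx_s <- make_fixture("spots-hex", k = 1.2, nx = 128, ny = 128, dx = 0.25)
  rep_s <- classify_pattern(fx_s, 0.25)
  expect_identical(rep_s$label, "spots")
  expect_equal(rep_s$dominant_k, 1.2, tolerance = bw / 1.2)
  fx_t <- make_fixture("stripes", k = 1.2, nx = 128, ny = 128, dx = 0.25)
  rep_t <- classify_pattern(fx_t, 0.25)
  expect_identical(rep_t$label, "stripes")
  expect_equal(rep_t$dominant_k, 1.2, tolerance = bw / 1.2)
  fx_h <- make_fixture("homogeneous", nx = 64, ny = 64, dx = 0.25)
  expect_identical(classify_pattern(fx_h, 0.25)$label, "homogeneous-steady")
  fx_o <- make_fixture("homogeneous-oscillatory", nx = 64, ny = 64,
                       dx = 0.25)
  expect_identical(classify_pattern(fx_o, 0.25)$label,
                   "homogeneous-oscillatory")
  expect_error(make_fixture("stripes", k = 20, dx = 0.25), "resolvable")
})

test_that("classification is invariant to translation and rotation", {
  for (kind in c("spots-hex", "stripes")) {
    fx <- make_fixture(kind, k = 1.2, nx = 128, ny = 128, dx = 0.25)
    ref <- classify_pattern(fx, 0.25)
    shift <- lapply(fx, function(s) {
      u <- s$u[c(40:128, 1:39), c(90:128, 1:89)]
      field_state(u, u, s$t)
    })
    rot <- lapply(fx, function(s) {
      u <- t(s$u)[rev(seq_len(ncol(s$u))), ]
      field_state(u, u, s$t)
    })
    for (variant in list(shift, rot)) {
      rep2 <- classify_pattern(variant, 0.25)
      expect_identical(rep2$label, ref$label)
      expect_equal(rep2$dominant_k, ref$dominant_k, tolerance = 1e-12)
    }
  }
})

test_that("labels are robust to 1% additive noise", {
  for (kind in c("spots-hex", "stripes")) {
    clean <- classify_pattern(
      make_fixture(kind, k = 1.2, nx = 128, ny = 128, dx = 0.25), 0.25)
    noisy <- classify_pattern(
      make_fixture(kind, k = 1.2, nx = 128, ny = 128, dx = 0.25,
                   noise_sd = 0.01, seed = 3), 0.25)
    expect_identical(noisy$label, clean$label)
    expect_equal(noisy$dominant_k, clean$dominant_k, tolerance = 1e-12)
  }
})

test_that("wavelength locking compares dominant wavenumbers in bins", {
  fx1 <- make_fixture("spots-hex", k = 1.2, nx = 128, ny = 128, dx = 0.25)
  r1 <- classify_pattern(fx1, 0.25)
  expect_true(wavelength_locked(r1, r1, r1))
  # a pattern three bins away is not locked at tolerance one
  k3 <- 1.2 + 3 * r1$bin_width
  fx2 <- make_fixture("spots-hex", k = k3, nx = 128, ny = 128, dx = 0.25)
  r2 <- classify_pattern(fx2, 0.25)
  expect_false(wavelength_locked(r1, r1, r2, tol_bins = 1))
  expect_true(wavelength_locked(r1, r1, r2, tol_bins = 4))
  # homogeneous reports make locking undefined
  rh <- classify_pattern(make_fixture("homogeneous", nx = 64, ny = 64,
                                      dx = 0.25), 0.25)
  expect_error(wavelength_locked(rh, r1, r1), "undefined")
  # a protocol starting homogeneous compares only during vs after
  expect_true(wavelength_locked(NULL, r1, r1))
})

test_that("classification demands a usable snapshot sequence", {
  fx <- make_fixture("stripes", k = 1.2, nx = 64, ny = 64, dx = 0.25)
  expect_error(classify_pattern(fx[1], 0.25), "at least 2")
  expect_error(classify_pattern(list(1, 2), 0.25), "field_state")
})
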