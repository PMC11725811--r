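test_that("reslicing maps frames to kymograph rows", {
  # static movie: all rows identical
  mv <- simulate_bundle_movie(movie_spec(n_frames = 20, photon_scale = Inf),
                              fix_jet(), list(), seed = 1)
  k <- reslice_kymograph(mv, 1)
  expect_equal(nrow(k$image), 20)
  expect_true(all(apply(k$image, 2, function(col) all(col == col[1]))))

  # one-frame movie: one-row kymograph
  mv1 <- simulate_bundle_movie(movie_spec(n_frames = 1, photon_scale = Inf),
                               fix_jet(), list(), seed = 1)
  expect_equal(nrow(reslice_kymograph(mv1, 1)$image), 1)

  # a step moves the edge at exactly its onset frame
  fr <- 5000
  onset_ms <- 10  # frame 51 is the first stimulated frame
  mv2 <- simulate_bundle_movie(
    movie_spec(n_frames = 120, photon_scale = Inf),
    fix_jet(c_drag = 0, tau_jet = 0),
    list(list(amplitude = 0.3, onset = onset_ms, duration = 10)), seed = 1)
  k2 <- reslice_kymograph(mv2, 1)
  expect_equal(k2$image[50, ], k2$image[1, ])
  expect_false(isTRUE(all.equal(k2$image[51, ], k2$image[1, ])))

  expect_error(reslice_kymograph(mv, 999), "outside")
})

test_that("profile normalization is an affine map onto [0, 1]", {
  p <- normalize_profile(c(2, 4, 6))
  expect_equal(p$values, c(0, 0.5, 1))
  # invariant to camera gain/offset
  raw <- gauss_profile(2400)$values
  a <- normalize_profile(raw)
  b <- normalize_profile(17 * raw + 3)
  expect_equal(a$values, b$values)
  expect_equal(which.max(a$values), which.max(raw))
  expect_error(normalize_profile(rep(1, 10)), "contrast")
})

test_that("the Gaussian fit recovers noise-free centres and is equivariant", {
  g <- gauss_profile(1234.5)
  f <- fit_gaussian_position(g$values, positions = g$positions)
  expect_true(f$fit_ok)
  expect_equal(f$center, 1234.5, tolerance = 0.5 / 1234.5)

  # shifting by exactly 3 pixels shifts the centre by 3 * pixel_size
  g3 <- gauss_profile(1234.5 + 3 * 50)
  f3 <- fit_gaussian_position(g3$values, positions = g3$positions)
  expect_equal(f3$center - f$center, 150, tolerance = 1e-6)
  expect_equal(f3$sigma, f$sigma, tolerance = 1e-6)
  expect_equal(f3$amplitude, f$amplitude, tolerance = 1e-6)
})

test_that("noise-free localization bias stays below 0.02 pixel", {
  px <- 50
  offs <- seq(0, px, length.out = 25)
  bias <- vapply(offs, function(o) {
    g <- gauss_profile(2400 + o)
    fit_gaussian_position(g$values, positions = g$positions)$center -
      (2400 + o)
  }, numeric(1))
  expect_lt(max(abs(bias)) / px, 0.02)
})

test_that("noisy localization precision is within 2x the grid-search MLE", {
  px <- 50; sigma <- 150; xc <- 2400 + 17
  g <- gauss_profile(xc, sigma_nm = sigma)
  ps <- 2000
  cgrid <- seq(xc - 2 * px, xc + 2 * px, by = 0.02 * px)
  G <- outer(cgrid, g$positions,
             function(c, x) 0.1 + exp(-(x - c)^2 / (2 * sigma^2)))
  set.seed(99)
  fitc <- numeric(200); mlec <- numeric(200)
  for (i in seq_len(200)) {
    v <- rpois(length(g$values), ps * g$values) / ps
    fitc[i] <- fit_gaussian_position(v, positions = g$positions)$center
    mlec[i] <- cgrid[which.min(colSums((t(G) - v)^2))]
  }
  expect_lt(sd(fitc), 2 * sd(mlec))
})

test_that("tracking a static kymograph gives zero displacement", {
  mv <- simulate_bundle_movie(movie_spec(n_frames = 30, photon_scale = Inf),
                              fix_jet(), list(), seed = 1)
  tr <- track_displacement(reslice_kymograph(mv, 1))
  expect_true(all(abs(tr$x_nm) < 1e-6))
  expect_true(attr(tr, "usable"))
})

test_that("noise-free tracking follows the ground truth within 1 nm", {
  mv <- fix_movie(photon_scale = Inf)
  tr <- track_displacement(reslice_kymograph(mv, 1))
  expect_lt(max(abs(tr$x_nm - mv$truth$displacement_nm)), 1)
})

test_that("tracking is equivariant under a whole-frame shift", {
  mv <- fix_movie(n_frames = 60, seed = 3)
  k <- reslice_kymograph(mv, 1)
  k2 <- k
  k2$image <- k$image[, c(4:ncol(k$image), 1:3)]  # shift left by 3 px
  c1 <- track_displacement(k)$center_nm
  c2 <- track_displacement(k2)$center_nm
  expect_equal(c2 - c1, rep(-150, length(c1)), tolerance = 0.01 * 50 / 150)
})

test_that("contrast-free frames are flagged while others track", {
  mv <- fix_movie(n_frames = 60, photon_scale = Inf)
  k <- reslice_kymograph(mv, 1)
  k$image[10:12, ] <- 0.5
  tr <- track_displacement(k)
  expect_false(any(tr$fit_ok[10:12]))
  expect_true(all(tr$fit_ok[-(10:12)]))
  expect_true(attr(tr, "usable"))
  k$image[1:40, ] <- 0.5
  expect_false(attr(track_displacement(k), "usable"))
})

test_that("reslice-then-track equals tracking per-frame profiles directly", {
  mv <- fix_movie(n_frames = 40, seed = 8)
  tr1 <- track_displacement(reslice_kymograph(mv, 2))
  pos <- (seq_len(dim(mv$frames)[3]) - 0.5) * mv$pixel_size
  centers <- vapply(seq_len(40), function(f)
    fit_gaussian_position(mv$frames[f, 2, ], positions = pos)$center,
    numeric(1))
  expect_equal(tr1$center_nm, centers, tolerance = 1e-8)
})

test_that("stiffness estimation recovers k = F/x and is linear in force", {
  mv <- simulate_bundle_movie(
    movie_spec(photon_scale = Inf), fix_jet(k_true = 3),
    list(list(amplitude = 0.3, onset = 40, duration = 120)), seed = 1)
  est <- bundle_stiffness_pipeline(mv)$stiffness
  expect_true(est$valid)
  expect_equal(est$k_mN_per_m, 3, tolerance = 0.02 / 3)

  mv2 <- simulate_bundle_movie(
    movie_spec(photon_scale = Inf), fix_jet(k_true = 3),
    list(list(amplitude = 0.6, onset = 40, duration = 120)), seed = 1)
  est2 <- bundle_stiffness_pipeline(mv2)$stiffness
  expect_equal(est2$x_steady_nm, 2 * est$x_steady_nm, tolerance = 0.01)
  expect_equal(est2$k_mN_per_m, est$k_mN_per_m, tolerance = 0.01)

  # zero force is an error
  tr <- track_displacement(reslice_kymograph(mv, 1))
  expect_error(estimate_stiffness(tr, rep(0, nrow(tr))), "zero-force")
})

test_that("stiffness recovery holds at default shot noise", {
  for (k_true in c(1, 5)) {
    ests <- vapply(1:4, function(s) {
      mv <- simulate_bundle_movie(
        movie_spec(n_frames = 300), fix_jet(k_true = k_true),
        list(list(amplitude = 0.3, onset = 10, duration = 40)), seed = s)
      bundle_stiffness_pipeline(mv)$stiffness$k_mN_per_m
    }, numeric(1))
    expect_lt(abs(median(ests) - k_true) / k_true, 0.1)
  }
})
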