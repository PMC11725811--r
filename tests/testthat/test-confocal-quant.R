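test_that("per-landmark kernel widths default to the published SDs", {
  expect_equal(landmark_default_sigmas("stereocilia_tips"),
               c(sigma_xy = 250, sigma_z = 500))
  expect_equal(landmark_default_sigmas("stereocilia_bases"),
               c(sigma_xy = 250, sigma_z = 500))
  expect_equal(landmark_default_sigmas("cuticular_plate"),
               c(sigma_xy = 1000, sigma_z = 500))
  expect_equal(landmark_default_sigmas("cytoplasm_apex"),
               c(sigma_xy = 1000, sigma_z = 1000))
  expect_equal(landmark_default_sigmas("cytoplasm_base"),
               c(sigma_xy = 1000, sigma_z = 1000))
})

test_that("Gaussian weights are normalized, symmetric, and local", {
  dims <- c(40, 40, 60); vs <- c(50, 50, 250)
  for (nm in landmark_names()) {
    lm <- landmark(nm, c(20 * 50, 20 * 50, 30 * 250))  # at a voxel boundary? no: centre below
    w <- gaussian_weights(dims, lm, vs)
    expect_lt(abs(sum(w) - 1), 1e-9)
  }
  # landmark at the centre of voxel (20, 20, 30): weights must be symmetric
  # under reflection through that voxel (compare the in-range pairs
  # i <-> 40 - i, k <-> 60 - k)
  lm <- landmark("cytoplasm_apex", c(19.5 * 50, 19.5 * 50, 29.5 * 250))
  w <- gaussian_weights(dims, lm, vs)
  sub <- w[1:39, 1:39, 1:59]
  flipped <- w[39:1, 39:1, 59:1]
  expect_lt(max(abs(sub - flipped)), 1e-9)
  expect_error(
    gaussian_weights(dims, landmark("cytoplasm_apex", c(-10, 0, 0)), vs),
    "outside")
})

test_that("truncated weights reproduce brute-force full-volume averages", {
  dims <- c(30, 30, 50); vs <- c(50, 50, 250)
  lm <- landmark("cuticular_plate", c(750, 750, 6250))
  w <- gaussian_weights(dims, lm, vs)
  # independent brute-force: direct Gaussian over every voxel, no
  # separability, no truncation
  cx <- (seq_len(dims[1]) - 0.5) * vs[1]
  cy <- (seq_len(dims[2]) - 0.5) * vs[2]
  cz <- (seq_len(dims[3]) - 0.5) * vs[3]
  wb <- array(0, dims)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3]))
      wb[i, j, k] <- exp(-((cx[i] - 750)^2 / (2 * 1000^2) +
                             (cy[j] - 750)^2 / (2 * 1000^2) +
                             (cz[k] - 6250)^2 / (2 * 500^2)))
  wb <- wb / sum(wb)
  field <- outer(outer(cx / 1000, sqrt(cy) / 10, `+`),
                 log1p(cz / 500), `+`)  # smooth test field
  expect_lt(abs(sum(w * field) - sum(wb * field)) / abs(sum(wb * field)),
            1e-6)
})

test_that("weighted average of a constant field is the constant", {
  dims <- c(24, 24, 44); vs <- c(50, 50, 250)
  const <- array(7.3, dims)
  for (nm in landmark_names()) {
    lm <- landmark(nm, c(600, 600, 5500))
    for (tr in c(2, 4, 8)) {
      w <- gaussian_weights(dims, lm, vs, truncate = tr)
      expect_lt(abs(sum(w * const) - 7.3), 1e-9)
    }
  }
})

test_that("local ratios are exact on constant fields and homogeneous", {
  dims <- c(24, 24, 44)
  stack <- structure(list(myo7a = array(3, dims), actin = array(12, dims),
                          voxel_size = c(50, 50, 250)),
                     class = "ConfocalStack")
  lm <- landmark("stereocilia_bases", c(600, 600, 5500))
  expect_equal(local_ratio(stack, lm)$ratio, 0.25, tolerance = 1e-12)
  # joint gain leaves the ratio unchanged; myo7a gain scales it
  both <- stack
  both$myo7a <- 5 * stack$myo7a; both$actin <- 5 * stack$actin
  expect_equal(local_ratio(both, lm)$ratio, 0.25, tolerance = 1e-12)
  only <- stack
  only$myo7a <- 4 * stack$myo7a
  expect_equal(local_ratio(only, lm)$ratio, 1, tolerance = 1e-12)
})

test_that("the measurement is local: far voxels do not move the ratio", {
  sp <- stack_spec(dims = c(32, 32, 88), true_ratio = 0.5, noise_sd = 0)
  st <- simulate_confocal_stack(sp, seed = 1)
  lm <- st$landmarks$stereocilia_tips  # sigma_z 500 nm, z = 2000 nm
  r0 <- local_ratio(st, lm)$ratio
  far <- st
  far$myo7a[, , 40:88] <- 1e4  # z >= 9875 nm, far beyond 5 sigma_z
  r1 <- local_ratio(far, lm)$ratio
  expect_lt(abs(r1 - r0) / r0, 1e-4)
})

test_that("noise-free uniform stacks recover true ratios exactly", {
  sp <- stack_spec(dims = c(32, 32, 88), true_ratio = 0.37,
                   actin_level = 100, noise_sd = 0)
  st <- simulate_confocal_stack(sp, seed = 1)
  for (lm in st$landmarks)
    expect_equal(local_ratio(st, lm)$ratio, 0.37, tolerance = 1e-12)
})

test_that("the tip ratio is recovered at default noise", {
  sp <- stack_spec(true_ratio = c(stereocilia_tips = 0.13,
                                  stereocilia_bases = 0.15,
                                  cuticular_plate = 0.2,
                                  cytoplasm_apex = 0.1,
                                  cytoplasm_base = 0.1))
  st <- simulate_confocal_stack(sp, seed = 5)
  r <- local_ratio(st, st$landmarks$stereocilia_tips)
  expect_equal(r$ratio, 0.13, tolerance = 0.01 / 0.13)
})

test_that("a noise-dominated actin denominator is flagged invalid", {
  dims <- c(24, 24, 44)
  stack <- structure(list(myo7a = array(1, dims),
                          actin = array(c(1e-6, 100), dims),
                          voxel_size = c(50, 50, 250)),
                     class = "ConfocalStack")
  stack$actin[] <- 1e-6; stack$actin[1, 1, 1] <- 100
  r <- local_ratio(stack, landmark("cytoplasm_base", c(600, 600, 8000)))
  expect_false(r$valid)
  expect_true(is.na(r$ratio))
})

test_that("percent reduction covers its anchors and flags bad controls", {
  expect_equal(percent_reduction(5, 5)$percent, 0)
  expect_equal(percent_reduction(0, 5)$percent, 100)
  expect_equal(percent_reduction(0.5, 5)$percent, 90)
  expect_false(percent_reduction(1, 0)$valid)
})

test_that("group profiling aggregates and is duplication-consistent", {
  m <- data.frame(cell_id = "c1", genotype = "control", age = "P20",
                  landmark = "stereocilia_tips", ratio = 0.8, valid = TRUE)
  s1 <- profile_cells(m)
  expect_equal(s1$mean, 0.8)
  expect_equal(s1$sd, 0)
  expect_equal(s1$n, 1)
  m2 <- rbind(m, transform(m, ratio = 0.6),
              transform(m, ratio = 0.8, genotype = "ko"),
              transform(m, ratio = 0.6, genotype = "ko"))
  s2 <- profile_cells(m2)
  dup <- profile_cells(rbind(m2, m2))
  expect_equal(dup$mean, s2$mean)
  expect_equal(dup$n, 2 * s2$n)
  # sample SD under exact duplication: sd' = sd * sqrt(2(n-1)/(2n-1))
  expect_equal(dup$sd, s2$sd * sqrt(2 * (s2$n - 1) / (2 * s2$n - 1)))
  # ko vs control reduction
  ko <- s2[s2$genotype == "ko", ]
  expect_equal(ko$percent_reduction, 0)
})

test_that("a simulated knockout shows the expected percent reduction", {
  base <- stack_spec(dims = c(48, 48, 88))
  red <- 0.9
  meas <- list()
  for (geno in c("control", "ko")) {
    sp <- if (geno == "ko")
      stack_spec(dims = c(48, 48, 88), true_ratio = base$true_ratio * (1 - red))
    else base
    for (cell in 1:2) {
      st <- simulate_confocal_stack(sp, seed = cell + 100 * (geno == "ko"))
      for (lm in st$landmarks) {
        r <- local_ratio(st, lm)
        meas[[length(meas) + 1]] <-
          data.frame(cell_id = paste0(geno, cell), genotype = geno,
                     age = "P20", landmark = r$landmark, ratio = r$ratio,
                     valid = r$valid)
      }
    }
  }
  summ <- profile_cells(do.call(rbind, meas), control = "control")
  ko <- summ[summ$genotype == "ko", ]
  expect_equal(nrow(ko), 5)
  expect_true(all(abs(ko$percent_reduction - 90) <= 3))
})
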