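test_that("zero placement jitter reproduces the baseline with zero dispersion", {
  m <- default_model()
  rep0 <- placement_repeatability(m, sigma_mm = 0, replicates = 3L, seed = 5L)
  expect_true(all(rep0$sd == 0))
  one <- placement_repeatability(m, sigma_mm = 0, replicates = 1L, seed = 5L)
  base <- as.data.frame(hip_sweep(m))
  run1 <- as.data.frame(attr(one, "runs")[[1L]])
  expect_identical(run1, base)
})

test_that("placement repeatability is bit-reproducible given the seed", {
  m <- default_model()
  a <- placement_repeatability(m, sigma_mm = 0.5, replicates = 5L, seed = 42L)
  b <- placement_repeatability(m, sigma_mm = 0.5, replicates = 5L, seed = 42L)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(lapply(attr(a, "runs"), as.data.frame),
                   lapply(attr(b, "runs"), as.data.frame))
  c2 <- placement_repeatability(m, sigma_mm = 0.5, replicates = 5L, seed = 43L)
  expect_false(identical(as.data.frame(a), as.data.frame(c2)))
})

test_that("small placement jitter disperses less than between-model differences", {
  cohort <- default_cohort()
  rep1 <- placement_repeatability(cohort[[1L]], sigma_mm = 0.5, replicates = 5L,
                                  seed = 9L)
  within <- rep1[rep1$quantity == "mma_normalized", ]
  curves <- lapply(cohort, hip_sweep)
  between <- sapply(seq_len(75L), function(i)
    stats::sd(sapply(curves, function(cu) cu$mma_normalized[i])))
  # replicate placement error stays below the comparative signal
  expect_lt(stats::median(within$sd), stats::median(between))
})

test_that("mass perturbation scales normalized values by the analytic factor", {
  m <- default_model()
  base <- as.data.frame(hip_sweep(m))
  base <- base[order(base$muscle, base$angle_deg), ]
  rep_ <- mass_perturbation(m)
  for (f in c(-0.2, -0.1, 0.1, 0.2)) {
    sub <- rep_[rep_$level == f & rep_$quantity == "mma_normalized", ]
    sub <- sub[order(sub$muscle, sub$angle_deg), ]
    expect_lt(max(abs(sub$mean / (base$mma_normalized * (1 + f)^-0.33) - 1)), 1e-12)
    # raw arms and lengths untouched
    for (q in c("mma_3d_mm", "length_mm")) {
      sq <- rep_[rep_$level == f & rep_$quantity == q, ]
      sq <- sq[order(sq$muscle, sq$angle_deg), ]
      expect_equal(sq$mean, base[[q]], tolerance = 1e-15)
    }
  }
  # power-law asymmetry: +20% and -20% do not cancel
  expect_false(isTRUE(all.equal((1.2 * 0.8)^-0.33, 1)))
  expect_error(mass_perturbation(m, fractions = c(-1, 0.1)))
})

test_that("a zero origin shift is the baseline and shifts act monotonically", {
  m <- default_model()
  rep_ <- origin_shift(m, fractions = c(-0.2, -0.1, 0, 0.1, 0.2))
  base <- as.data.frame(hip_sweep(m))
  sub0 <- rep_[rep_$level == 0, ]
  bf0 <- sub0[sub0$quantity == "mma_3d_mm" & sub0$muscle == "biceps_femoris", ]
  expect_equal(bf0$mean[order(bf0$angle_deg)],
               base$mma_3d_mm[base$muscle == "biceps_femoris"], tolerance = 1e-15)
  # only the shifted muscle changes
  other <- rep_[rep_$muscle != "biceps_femoris" & rep_$quantity == "mma_3d_mm", ]
  for (f in unique(other$level)) {
    sub <- other[other$level == f, ]
    sub <- sub[order(sub$muscle, sub$angle_deg), ]
    ref <- base[base$muscle != "biceps_femoris", ]
    ref <- ref[order(ref$muscle, ref$angle_deg), ]
    expect_equal(sub$mean, ref$mma_3d_mm, tolerance = 1e-15)
  }
  # shifting the origin away from the joint lengthens the reference-pose arm
  at90 <- rep_[rep_$quantity == "mma_3d_mm" & rep_$muscle == "biceps_femoris" &
               rep_$angle_deg == 90, ]
  expect_true(all(diff(at90$mean[order(at90$level)]) > 0))
})

test_that("origin shift on a flat pelvis matches the closed-form oracle", {
  # flat pelvis surface: a dense grid in the z = 0 plane, long axis +y;
  # shifts are multiples of the grid spacing, so snapping is exact
  grid <- as.matrix(expand.grid(x = seq(-1, 1, 0.5), y = seq(-20, 20, 0.5), z = 0))
  origin <- c(0, 5, 0); insertion <- c(0, 2, -10)
  bones <- list(msk_bone("pelvis", grid, "pelvis-fixed"),
                msk_bone("femur", rbind(insertion, c(0, 0, -12)), "femur-fixed"))
  mus <- list(msk_muscle("m1", attachment_site("pelvis", centroid = origin),
                         attachment_site("femur", centroid = insertion), FALSE))
  hip <- build_hip_joint(sphere = list(center = c(0, 0, 0), radius = 1))
  m <- msk_model(bones, mus, hip, body_mass = 1, pelvis_length = 10,
                 femur_length = 12)
  rep_ <- origin_shift(m, muscle = "m1", fractions = c(-0.2, 0.1, 0.2))
  for (f in c(-0.2, 0.1, 0.2)) {
    shifted <- origin + c(0, f * 10, 0)
    sub <- rep_[rep_$level == f & rep_$quantity == "mma_3d_mm", ]
    got <- sub$mean[order(sub$angle_deg)]
    expected <- vapply(SWEEP_ANGLES, function(th)
      oracle_planar_mma(shifted, insertion, c(0, 0, 0), th), 0)
    # default sweep clamps at segment ends; oracle is the infinite line, so
    # compare where the perpendicular foot is interior
    interior <- abs(got - expected) < 1e-9
    expect_gt(mean(interior), 0.5)
    sub_u <- hip_sweep({
      mm <- m
      mm$muscles$m1$origin <- attachment_site("pelvis", centroid = shifted)
      msk_model(mm$bones, mm$muscles, mm$hip, 1, pelvis_length = 10,
                femur_length = 12)
    }, clamp = FALSE)
    expect_lt(max(abs(sub_u$mma_3d_mm - expected)), 1e-9)
  }
})
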