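test_that("attachment centroids are unweighted patch means", {
  s <- attachment_site("pelvis", patch = rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(attachment_centroid(s), c(1, 0, 0))
  s <- attachment_site("pelvis", patch = rbind(c(3, -1, 2)))
  expect_equal(attachment_centroid(s), c(3, -1, 2))
  corners <- as.matrix(expand.grid(c(4, 6), c(4, 6), c(4, 6)))
  expect_equal(attachment_centroid(attachment_site("pelvis", patch = corners)),
               c(5, 5, 5))
  # explicit centroid overrides the patch mean
  s <- attachment_site("pelvis", patch = corners, centroid = c(9, 9, 9))
  expect_equal(attachment_centroid(s), c(9, 9, 9))
  expect_error(attachment_site("pelvis"), "patch|centroid")
})

test_that("hip joint construction fits the head sphere and is equivariant", {
  set.seed(71)
  u <- matrix(rnorm(300L), ncol = 3L); u <- u / sqrt(rowSums(u^2))
  pts <- 3 * u
  hip <- build_hip_joint(pts, fe_axis = c(1, 0, 0))
  expect_lt(sqrt(sum(hip$center^2)), 1e-9)
  expect_lt(abs(hip$radius - 3), 1e-9)
  hip2 <- build_hip_joint(sweep(pts, 2L, c(10, 0, 0), `+`), fe_axis = c(1, 0, 0))
  expect_lt(sqrt(sum((hip2$center - c(10, 0, 0))^2)), 1e-9)
  # explicit sphere bypasses the fit
  hip3 <- build_hip_joint(sphere = list(center = c(1, 2, 3), radius = 4))
  expect_equal(hip3$center, c(1, 2, 3))
  expect_equal(hip3$radius, 4)
})

test_that("model assembly validates bones, segments and the biarticular flag", {
  m <- default_model()
  expect_s3_class(m, "msk_model")
  expect_named(m$muscles, c(GLUTEALS[1L], GLUTEALS[2L], HAMSTRINGS),
               ignore.order = TRUE)
  expect_true(all(vapply(m$muscles, `[[`, 0, "resting_length") > 0))

  bad <- m$muscles
  bad[["gluteus_medius"]]$biarticular <- TRUE
  expect_error(msk_model(m$bones, bad, m$hip, m$body_mass),
               "biarticular flag inconsistent")
  bad <- m$muscles
  bad[["biceps_femoris"]]$origin$bone <- "femur"
  expect_error(msk_model(m$bones, bad, m$hip, m$body_mass),
               "pelvis-fixed")
})

test_that("posing is the identity at the reference pose and purely functional", {
  m <- default_model()
  ref <- pose_model(m, 90)
  for (nm in names(m$muscles)) {
    expect_identical(ref[[nm]]$origin, m$muscles[[nm]]$origin$centroid)
    expect_identical(ref[[nm]]$insertion, m$muscles[[nm]]$insertion$centroid)
  }
  up <- lapply(SWEEP_ANGLES, function(th) pose_model(m, th))
  down <- lapply(rev(SWEEP_ANGLES), function(th) pose_model(m, th))
  expect_identical(up, rev(down))
  expect_warning(pose_model(m, 10), "outside")
  expect_error(pose_model(m, 90, knee_deg = 45), "locked")
})

test_that("origins are pose-invariant and insertions trace circles about the axis", {
  m <- default_model()
  ctr <- m$hip$center; ax <- m$hip$fe_axis
  radial <- function(p) {
    v <- p - ctr
    sqrt(sum((v - sum(v * ax) * ax)^2))
  }
  r0 <- vapply(names(m$muscles), function(nm)
    radial(m$muscles[[nm]]$insertion$centroid), 0)
  for (th in c(20, 60, 130, 160)) {
    posed <- pose_model(m, th)
    for (nm in names(m$muscles)) {
      expect_identical(posed[[nm]]$origin, m$muscles[[nm]]$origin$centroid)
      expect_equal(radial(posed[[nm]]$insertion), r0[[nm]], tolerance = 1e-10)
      # axial coordinate also preserved: rotation is about the fe axis
      expect_equal(sum((posed[[nm]]$insertion - ctr) * ax),
                   sum((m$muscles[[nm]]$insertion$centroid - ctr) * ax),
                   tolerance = 1e-10)
    }
  }
})

test_that("the shank rotates rigidly with the femur (knee locked at 90)", {
  m <- default_model()
  # distance between a femur-fixed point (gluteal insertion) and a shank-fixed
  # point (hamstring insertion) must be pose-invariant
  d0 <- sqrt(sum((m$muscles$gluteus_medius$insertion$centroid -
                  m$muscles$semitendinosus$insertion$centroid)^2))
  for (th in SWEEP_ANGLES) {
    posed <- pose_model(m, th)
    expect_equal(sqrt(sum((posed$gluteus_medius$insertion -
                           posed$semitendinosus$insertion)^2)),
                 d0, tolerance = 1e-10)
  }
})
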