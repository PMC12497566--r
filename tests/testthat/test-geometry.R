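test_that("sphere fit recovers exact spheres and the 4-point circumsphere", {
  fit <- fit_sphere(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 2)))
  expect_equal(fit$center, c(1, 1, 1), tolerance = 1e-12)
  expect_equal(fit$radius, sqrt(3), tolerance = 1e-12)

  set.seed(11)
  u <- matrix(rnorm(600L), ncol = 3L)
  u <- u / sqrt(rowSums(u^2))
  pts <- sweep(5 * u, 2L, c(1, 2, 3), `+`)
  fit <- fit_sphere(pts)
  expect_lt(sqrt(sum((fit$center - c(1, 2, 3))^2)), 1e-9)
  expect_lt(abs(fit$radius - 5), 1e-9)
  expect_lt(fit$rmse, 1e-9)
  expect_equal(unname(coef(fit)), c(fit$center, fit$radius))
})

test_that("noisy sphere fit agrees with the geometric least-squares oracle", {
  set.seed(21)
  u <- matrix(rnorm(600L), ncol = 3L)
  u <- u / sqrt(rowSums(u^2))
  pts <- sweep(5 * u, 2L, c(1, 2, 3), `+`) + matrix(rnorm(600L, sd = 0.05), ncol = 3L)
  fit <- fit_sphere(pts)
  orc <- oracle_sphere(pts)
  expect_lt(sqrt(sum((fit$center - c(1, 2, 3))^2)), 0.02)
  expect_lt(sqrt(sum((fit$center - orc$center)^2)), 5e-3)
  expect_lt(abs(fit$radius - orc$radius), 5e-3)
})

test_that("sphere fit rejects degenerate configurations", {
  expect_error(fit_sphere(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))), "at least 4")
  g <- as.matrix(expand.grid(x = 0:3, y = 0:3))          # coplanar grid, z = 0
  expect_error(fit_sphere(cbind(g, 0)), "degenerate")
  expect_error(fit_sphere(matrix(1, 5L, 3L)), "degenerate")
})

test_that("sphere fit center is equivariant under rigid transforms", {
  set.seed(31)
  u <- matrix(rnorm(240L), ncol = 3L)
  u <- u / sqrt(rowSums(u^2))
  pts <- sweep(3 * u, 2L, c(-2, 1, 4), `+`)
  base <- fit_sphere(pts)
  for (i in 1:100) {
    R <- random_rotation(); tr <- rnorm(3L, sd = 20)
    fit <- fit_sphere(apply_rigid(pts, R, tr))
    expect_lt(sqrt(sum((fit$center - apply_rigid(base$center, R, tr))^2)), 1e-9)
    expect_lt(abs(fit$radius - base$radius), 1e-9)
  }
})

test_that("nearest point on segment matches hand geometry, clamps at endpoints", {
  r <- nearest_point_on_segment(c(1, -1, 0), c(1, 1, 0), c(0, 0, 0))
  expect_equal(r$point, c(1, 0, 0))
  expect_equal(r$distance, 1)

  r <- nearest_point_on_segment(c(1, 1, 0), c(1, 2, 0), c(0, 0, 0), clamp = TRUE)
  expect_equal(r$point, c(1, 1, 0))
  expect_equal(r$distance, sqrt(2))

  r <- nearest_point_on_segment(c(0, 5, 0), c(3, -4, 0), c(0, 0, 0), clamp = FALSE)
  expect_equal(r$distance, 5 / sqrt(10), tolerance = 1e-12)

  expect_error(nearest_point_on_segment(c(1, 1, 1), c(1, 1, 1), c(0, 0, 0)),
               "degenerate")
})

test_that("unclamped nearest-point distance equals the cross-product closed form", {
  set.seed(41)
  for (i in 1:50) {
    a <- rnorm(3L, sd = 5); b <- rnorm(3L, sd = 5); q <- rnorm(3L, sd = 5)
    d <- b - a
    expected <- sqrt(sum(c(
      (q - a)[2L] * d[3L] - (q - a)[3L] * d[2L],
      (q - a)[3L] * d[1L] - (q - a)[1L] * d[3L],
      (q - a)[1L] * d[2L] - (q - a)[2L] * d[1L])^2)) / sqrt(sum(d^2))
    got <- nearest_point_on_segment(a, b, q, clamp = FALSE)$distance
    expect_equal(got, expected, tolerance = 1e-10)
  }
})

test_that("rotation about an axis is a rigid motion with the expected action", {
  expect_equal(rotate_about_axis(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1), 90),
               c(0, 1, 0), tolerance = 1e-12)
  p <- c(0.3, -2, 5)
  expect_equal(rotate_about_axis(p, c(1, 1, 1), c(0, 1, 0), 0), p)
  expect_equal(rotate_about_axis(c(2, 0, 0), c(1, 0, 0), c(0, 0, 1), 180),
               c(0, 0, 0), tolerance = 1e-12)

  set.seed(51)
  for (i in 1:30) {
    p1 <- rnorm(3L, sd = 3); p2 <- rnorm(3L, sd = 3)
    ax <- rnorm(3L); ax <- ax / sqrt(sum(ax^2)); c0 <- rnorm(3L)
    ang <- runif(1L, -180, 180)
    q1 <- rotate_about_axis(p1, c0, ax, ang)
    q2 <- rotate_about_axis(p2, c0, ax, ang)
    expect_equal(sqrt(sum((q1 - q2)^2)), sqrt(sum((p1 - p2)^2)), tolerance = 1e-10)
    expect_equal(sqrt(sum((q1 - c0)^2)), sqrt(sum((p1 - c0)^2)), tolerance = 1e-10)
  }
})

test_that("plane projection removes the normal component and is idempotent", {
  r <- project_vector_onto_plane(c(3, 4, 0), c(1, 0, 0))
  expect_equal(r$vector, c(0, 4, 0))
  expect_equal(r$length, 4)
  expect_equal(project_vector_onto_plane(c(0, 0, 7), c(0, 0, 1))$length, 0)
  r <- project_vector_onto_plane(c(1, 1, 1), c(0, 0, 1))
  expect_equal(r$vector, c(1, 1, 0))
  expect_equal(r$length, sqrt(2))

  set.seed(61)
  for (i in 1:20) {
    v <- rnorm(3L, sd = 4); n <- rnorm(3L); n <- n / sqrt(sum(n^2))
    once <- project_vector_onto_plane(v, n)
    twice <- project_vector_onto_plane(once$vector, n)
    expect_equal(twice$vector, once$vector, tolerance = 1e-12)
    expect_lte(once$length, sqrt(sum(v^2)) + 1e-12)
  }
})
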