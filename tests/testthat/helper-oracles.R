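# Independent oracles and shared fixtures. The oracles deliberately avoid the
# package's own geometry routines: the sphere oracle is a nonlinear geometric
# least squares, the moment-arm oracle a closed-form cross-product distance
# with an explicit 2D rotation.

# geometric (nonlinear) sphere fit: minimize sum (|p - c| - r)^2
oracle_sphere <- function(pts) {
  c0 <- colMeans(pts)
  r0 <- mean(sqrt(rowSums(sweep(pts, 2L, c0)^2)))
  obj <- function(par) {
    d <- sqrt(rowSums(sweep(pts, 2L, par[1:3])^2))
    sum((d - par[4L])^2)
  }
  fit <- stats::optim(c(c0, r0), obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  list(center = fit$par[1:3], radius = fit$par[4L])
}

# closed-form planar moment arm: rotate the reference insertion about the
# x-axis through `center` by (theta - 90) with an explicit 2D rotation in the
# (y, z) plane, then take the point-line distance |(O-C) x (I-C)| / |I-O|
oracle_planar_mma <- function(origin, insertion_ref, center, theta_deg) {
  a <- (theta_deg - 90) * pi / 180
  v <- insertion_ref - center
  ins <- center + c(v[1L],
                    v[2L] * cos(a) - v[3L] * sin(a),
                    v[2L] * sin(a) + v[3L] * cos(a))
  oc <- origin - center
  ic <- ins - center
  cr <- c(oc[2L] * ic[3L] - oc[3L] * ic[2L],
          oc[3L] * ic[1L] - oc[1L] * ic[3L],
          oc[1L] * ic[2L] - oc[2L] * ic[1L])
  sqrt(sum(cr^2)) / sqrt(sum((ins - origin)^2))
}

# random proper rotation matrix (QR of a Gaussian matrix, det forced to +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9L), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

apply_rigid <- function(pts, R, t) {
  if (is.null(dim(pts))) as.vector(R %*% pts) + t
  else sweep(pts %*% t(R), 2L, t, `+`)
}

# rigidly transform a whole model (bones, patches, hip) and rebuild it
transform_model <- function(model, R, t) {
  bones <- lapply(model$bones, function(b)
    momarm::msk_bone(b$name, apply_rigid(b$vertices, R, t), b$segment))
  muscles <- lapply(model$muscles, function(m) {
    site <- function(s) momarm::attachment_site(
      s$bone,
      patch = if (!is.null(s$patch)) apply_rigid(s$patch, R, t),
      centroid = apply_rigid(s$centroid, R, t))
    momarm::msk_muscle(m$name, site(m$origin), site(m$insertion), m$biarticular)
  })
  hip <- momarm::build_hip_joint(
    fe_axis = as.vector(R %*% model$hip$fe_axis),
    reference_femur_axis = as.vector(R %*% model$hip$zero_pose_femur_axis),
    sphere = list(center = apply_rigid(model$hip$center, R, t),
                  radius = model$hip$radius))
  momarm::msk_model(bones, muscles, hip, model$body_mass,
                    pelvis_length = model$pelvis_length,
                    femur_length = model$femur_length,
                    model_id = model$model_id)
}

# small explicit-centroid model for hand-computed moment-arm cases: hip center
# at the origin, fe axis +x, one pelvis-fixed origin and one femur-fixed
# insertion given directly
toy_model <- function(origin, insertion, biarticular = FALSE, body_mass = 1) {
  bones <- list(
    momarm::msk_bone("pelvis", rbind(origin, origin + c(0, 1, 0)), "pelvis-fixed"),
    momarm::msk_bone("femur", rbind(insertion, insertion + c(0, 0, -1)),
                     if (biarticular) "femur-fixed" else "femur-fixed"),
    momarm::msk_bone("tibia", rbind(insertion + c(0, 0, -2)), "shank-fixed"))
  ins_bone <- if (biarticular) "tibia" else "femur"
  if (biarticular) bones[[3L]] <- momarm::msk_bone("tibia", rbind(insertion), "shank-fixed")
  muscles <- list(momarm::msk_muscle(
    "m1",
    momarm::attachment_site("pelvis", centroid = origin),
    momarm::attachment_site(ins_bone, centroid = insertion),
    biarticular))
  hip <- momarm::build_hip_joint(
    fe_axis = c(1, 0, 0), reference_femur_axis = c(0, 0, -1),
    sphere = list(center = c(0, 0, 0), radius = 1))
  momarm::msk_model(bones, muscles, hip, body_mass,
                    pelvis_length = 10, femur_length = 10, model_id = "toy")
}

# default synthetic fixture, generated once per test session
fixture_env <- new.env(parent = emptyenv())
default_model <- function() {
  if (is.null(fixture_env$model))
    fixture_env$model <- momarm::generate_model(momarm::synthetic_spec())
  fixture_env$model
}
default_cohort <- function() {
  if (is.null(fixture_env$cohort))
    fixture_env$cohort <- momarm::generate_cohort(4L)
  fixture_env$cohort
}

SWEEP_ANGLES <- seq(20, 160, by = 10)
GLUTEALS <- c("gluteus_medius", "gluteus_minimus")
HAMSTRINGS <- c("biceps_femoris", "semimembranosus", "semitendinosus")

muscle_col <- function(curves, muscle, col = "mma_3d_mm") {
  d <- as.data.frame(curves)
  d <- d[d$muscle == muscle, ]
  d[[col]][order(d$angle_deg)]
}
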