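# The static musculoskeletal data model: bones (point clouds in mm), muscle
# attachment sites, the hip hinge, and rigid posing of the femur + shank
# assembly with the knee locked at 90 degrees.

.SEGMENTS <- c("pelvis-fixed", "femur-fixed", "shank-fixed")

#' Define a bone
#'
#' @param name Bone name; conventionally one of `pelvis`, `femur`, `tibia`,
#'   `fibula`.
#' @param vertices n x 3 matrix of surface points (mm).
#' @param segment Rigid segment the bone belongs to: `"pelvis-fixed"`,
#'   `"femur-fixed"` or `"shank-fixed"`.
#' @return Object of class `msk_bone`.
#' @export
msk_bone <- function(name, vertices, segment) {
  segment <- match.arg(segment, .SEGMENTS)
  structure(list(name = name, vertices = .as_pointmat(vertices, "vertices"),
                 segment = segment),
            class = "msk_bone")
}

#' Define an attachment site
#'
#' An attachment site is a patch of surface points on a bone; its centroid (the
#' unweighted arithmetic mean of the patch) is the point used to build the
#' muscle's straight line of action. An explicit `centroid` may be supplied
#' instead of (or in addition to) a patch, in which case it overrides the patch
#' mean.
#'
#' @param bone Bone name the site lies on.
#' @param patch n x 3 matrix of patch points, or `NULL` if `centroid` is given.
#' @param centroid Optional explicit centroid (length-3 numeric, mm).
#' @return Object of class `attachment_site` with a `centroid` element.
#' @export
attachment_site <- function(bone, patch = NULL, centroid = NULL) {
  if (is.null(patch) && is.null(centroid))
    stop("attachment site needs a non-empty patch or an explicit centroid", call. = FALSE)
  if (!is.null(patch)) {
    patch <- .as_pointmat(patch, "patch")
    if (nrow(patch) < 1L) stop("attachment patch is empty", call. = FALSE)
  }
  cen <- if (!is.null(centroid)) .as_point3(centroid, "centroid") else colMeans(patch)
  structure(list(bone = bone, patch = patch, centroid = cen),
            class = "attachment_site")
}

#' Centroid of an attachment site
#'
#' @param site An [attachment_site()].
#' @return Length-3 numeric point (mm).
#' @export
attachment_centroid <- function(site) {
  stopifnot(inherits(site, "attachment_site"))
  site$centroid
}

#' Define a muscle
#'
#' @param name Muscle name (e.g. `"gluteus_medius"`).
#' @param origin Origin [attachment_site()] (on the pelvis).
#' @param insertion Insertion [attachment_site()] (femur or shank).
#' @param biarticular `TRUE` for the hamstrings (insertion on the shank, the
#'   muscle crossing hip and knee), `FALSE` for the uniarticular gluteals.
#' @return Object of class `msk_muscle`.
#' @export
msk_muscle <- function(name, origin, insertion, biarticular) {
  stopifnot(inherits(origin, "attachment_site"),
            inherits(insertion, "attachment_site"),
            is.logical(biarticular), length(biarticular) == 1L)
  structure(list(name = name, origin = origin, insertion = insertion,
                 biarticular = biarticular),
            class = "msk_muscle")
}

#' Build the hip joint model from femoral-head surface points
#'
#' Fits a sphere to the supplied femoral-head points; its center approximates
#' the hip joint center of rotation. The flexion-extension axis (the normal of
#' the parasagittal plane) is a model input, not estimated from anatomy.
#'
#' @param femoral_head_points n x 3 matrix (n >= 4, non-coplanar) of head
#'   surface samples, or `NULL` if `sphere` is given.
#' @param fe_axis Medio-lateral flexion-extension axis (normalized internally).
#' @param reference_femur_axis Femur long-axis direction at the reference pose.
#' @param sphere Optional explicit list with `center` and `radius`, bypassing
#'   the fit.
#' @return Object of class `hip_joint` with `center`, `radius`, `fe_axis`,
#'   `zero_pose_femur_axis` and the underlying `sphere_fit` (if fitted).
#' @export
build_hip_joint <- function(femoral_head_points = NULL, fe_axis = c(1, 0, 0),
                            reference_femur_axis = c(0, 0, -1), sphere = NULL) {
  if (is.null(sphere)) {
    if (is.null(femoral_head_points))
      stop("either femoral head points or an explicit sphere is required", call. = FALSE)
    fit <- fit_sphere(femoral_head_points)
    center <- fit$center; radius <- fit$radius
  } else {
    fit <- NULL
    center <- .as_point3(sphere$center, "sphere$center")
    radius <- sphere$radius
    stopifnot(is.finite(radius), radius > 0)
  }
  structure(list(center = center, radius = radius,
                 fe_axis = .unit3(fe_axis, "fe_axis"),
                 zero_pose_femur_axis = .unit3(reference_femur_axis,
                                               "reference_femur_axis"),
                 sphere_fit = fit),
            class = "hip_joint")
}

#' Assemble a musculoskeletal model
#'
#' Collects bones, muscles, the hip joint, and body mass into one model.
#' Effective pelvis and femur lengths default to the maximum pairwise vertex
#' distance of the bone cloud (a caliper length). Muscle resting lengths are
#' computed once here, at the reference pose (90 degrees hip and knee), and
#' cached immutably.
#'
#' @param bones List of [msk_bone()] objects.
#' @param muscles List of [msk_muscle()] objects.
#' @param hip A [build_hip_joint()] result.
#' @param body_mass Body mass in grams (> 0).
#' @param pelvis_length,femur_length Effective lengths in mm; computed from the
#'   bone clouds when `NULL`.
#' @param model_id Identifier used in output tables.
#' @return Object of class `msk_model`.
#' @export
msk_model <- function(bones, muscles, hip, body_mass,
                      pelvis_length = NULL, femur_length = NULL,
                      model_id = "model") {
  stopifnot(inherits(hip, "hip_joint"), is.finite(body_mass), body_mass > 0)
  if (inherits(bones, "msk_bone")) bones <- list(bones)
  if (inherits(muscles, "msk_muscle")) muscles <- list(muscles)
  names(bones) <- vapply(bones, `[[`, "", "name")
  if (anyDuplicated(names(bones)))
    stop("bone names must be unique within a model", call. = FALSE)
  names(muscles) <- vapply(muscles, `[[`, "", "name")
  for (m in muscles) {
    for (side in c("origin", "insertion")) {
      bn <- m[[side]]$bone
      if (!bn %in% names(bones))
        stop(sprintf("muscle '%s': %s references unknown bone '%s'",
                     m$name, side, bn), call. = FALSE)
    }
    if (.site_segment(bones, m$origin) != "pelvis-fixed")
      stop(sprintf("muscle '%s': origin must lie on a pelvis-fixed bone", m$name),
           call. = FALSE)
    ins_seg <- .site_segment(bones, m$insertion)
    if (m$biarticular != (ins_seg == "shank-fixed"))
      stop(sprintf("muscle '%s': biarticular flag inconsistent with insertion segment '%s'",
                   m$name, ins_seg), call. = FALSE)
  }
  if (is.null(pelvis_length) && "pelvis" %in% names(bones))
    pelvis_length <- .caliper(bones[["pelvis"]]$vertices)
  if (is.null(femur_length) && "femur" %in% names(bones))
    femur_length <- .caliper(bones[["femur"]]$vertices)
  stopifnot(is.null(pelvis_length) || pelvis_length > 0,
            is.null(femur_length) || femur_length > 0)
  model <- structure(
    list(bones = bones, muscles = muscles, hip = hip, body_mass = body_mass,
         pelvis_length = pelvis_length, femur_length = femur_length,
         model_id = model_id),
    class = "msk_model")
  for (nm in names(model$muscles)) {
    L0 <- .norm3(model$muscles[[nm]]$insertion$centroid -
                 model$muscles[[nm]]$origin$centroid)
    if (L0 < 1e-9)
      stop(sprintf("muscle '%s': origin and insertion centroids coincide", nm),
           call. = FALSE)
    model$muscles[[nm]]$resting_length <- L0
  }
  model
}

.site_segment <- function(bones, site) bones[[site$bone]]$segment

# maximum pairwise vertex distance; bones here are a few thousand points at most
.caliper <- function(x) {
  x <- .as_pointmat(x)
  if (nrow(x) < 2L) return(0)
  max(stats::dist(x))
}

#' @export
print.msk_model <- function(x, ...) {
  cat("Musculoskeletal model '", x$model_id, "'\n", sep = "")
  cat("  bones:   ", paste(names(x$bones), collapse = ", "), "\n", sep = "")
  cat("  muscles: ", paste(names(x$muscles), collapse = ", "), "\n", sep = "")
  cat(sprintf("  hip center (%.3f, %.3f, %.3f) mm, head radius %.3f mm\n",
              x$hip$center[1L], x$hip$center[2L], x$hip$center[3L], x$hip$radius))
  cat(sprintf("  body mass %.1f g; pelvis %.1f mm, femur %.1f mm (effective lengths)\n",
              x$body_mass, x$pelvis_length %||% NA_real_, x$femur_length %||% NA_real_))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pose the femur + shank assembly at a hip extension angle
#'
#' Pelvis-fixed points stay put; femur-fixed and shank-fixed points rotate
#' rigidly together about the hip center and flexion-extension axis by
#' `hip_extension_deg - 90` degrees from the reference configuration, so the
#' knee angle stays at 90 degrees by construction. The convention: 90 degrees
#' is the reference pose (femur perpendicular to the pelvis cranial axis),
#' small angles are crouched/flexed, large angles an extended limb.
#'
#' @param model A [msk_model()].
#' @param hip_extension_deg Hip extension angle in degrees. Values outside
#'   \[20, 160\] are permitted with a warning.
#' @param knee_deg Must be 90 (the locked neutral knee).
#' @return Named list, one entry per muscle, each with posed `origin` and
#'   `insertion` centroids.
#' @export
pose_model <- function(model, hip_extension_deg, knee_deg = 90) {
  stopifnot(inherits(model, "msk_model"),
            is.finite(hip_extension_deg), length(hip_extension_deg) == 1L)
  if (!isTRUE(all.equal(knee_deg, 90)))
    stop("the knee is locked at 90 degrees in this model", call. = FALSE)
  if (hip_extension_deg < 20 || hip_extension_deg > 160)
    warning(sprintf("hip extension angle %.1f outside the standard 20-160 degree sweep",
                    hip_extension_deg), call. = FALSE)
  out <- lapply(model$muscles, function(m) {
    list(origin = .pose_point(model, m$origin, hip_extension_deg),
         insertion = .pose_point(model, m$insertion, hip_extension_deg))
  })
  names(out) <- names(model$muscles)
  out
}

.pose_point <- function(model, site, angle) {
  p <- site$centroid
  if (.site_segment(model$bones, site) == "pelvis-fixed") return(p)
  if (angle == 90) return(p)
  rotate_about_axis(p, model$hip$center, model$hip$fe_axis, angle - 90)
}
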