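# Parametric hindlimb generator: stylized analytic bone clouds (ellipsoid
# pelvis, cylindrical femur/tibia/fibula shafts, spherical femoral head cap)
# with five hip-extensor attachment layouts and exact geometric ground truth.
# Bone surfaces are deterministic lattices; randomness (head noise) is drawn
# under the spec seed only.
#
# Local frame before the global offset: hip center at the origin, +x
# medio-lateral (the flexion-extension axis), +y caudal, +z dorsal; the femur
# long axis points ventrally (0,0,-1) at the 90/90 reference pose and the
# shank caudally (0,1,0).

#' Specification for a synthetic hindlimb model
#'
#' Bundles every generator parameter. The default attachment layout is tuned
#' so that the fixture mirrors the qualitative hip-extensor behavior of small
#' leaping primates: the two uniarticular gluteals (iliac origin, proximal
#' femoral insertion at near-equal distances from the joint center) have a
#' moment arm that rises monotonically with hip extension, while the three
#' biarticular hamstrings (ischial origin, tibial insertion) follow a
#' bell-shaped curve peaking near the reference pose. Morphotypes scale all
#' attachment positions radially about the hip center: `trunk_leaper` (x1.15)
#' emphasizes torque via longer moment arms, `horizontal_leaper` (x0.88)
#' rotational velocity via shorter ones.
#'
#' @param seed Integer seed controlling every random draw of the generator.
#' @param body_mass Body mass in grams (default 350, mid marmoset/tamarin
#'   range).
#' @param morphotype One of `"generic"`, `"trunk_leaper"`,
#'   `"horizontal_leaper"`.
#' @param femur_length,tibia_length Shaft lengths, mm.
#' @param pelvis_semi Ellipsoid semi-axes (x, y, z) of the pelvis cloud, mm.
#' @param head_radius Femoral head radius, mm.
#' @param head_sample_n Number of head surface samples (>= 4).
#' @param head_noise_sigma Isotropic Gaussian noise on head samples, mm.
#' @param patch_radius Attachment patch disk radius, mm.
#' @param patch_n Points per patch (a symmetric disk; the patch mean equals
#'   the nominal centroid exactly).
#' @param st_insertion_frac Semitendinosus insertion position along the tibial
#'   shaft, as a fraction of tibia length (default places it toward the
#'   mid-shaft).
#' @param planar If `TRUE`, all attachment centroids lie in the parasagittal
#'   plane through the hip center, making the closed-form planar moment arm an
#'   exact oracle for the pipeline.
#' @param offset Global translation applied to the whole model (the hip center
#'   ends up here), so nothing is special about the coordinate origin.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, body_mass = 350, morphotype = "generic",
                           femur_length = 31, tibia_length = 33,
                           pelvis_semi = c(3.5, 19, 6.5),
                           head_radius = 2.5, head_sample_n = 200L,
                           head_noise_sigma = 0, patch_radius = 1.2,
                           patch_n = 17L, st_insertion_frac = 0.42,
                           planar = FALSE, offset = c(12, 40, 25)) {
  morphotype <- match.arg(morphotype,
                          c("generic", "trunk_leaper", "horizontal_leaper"))
  stopifnot(body_mass > 0, femur_length > 0, tibia_length > 0,
            all(pelvis_semi > 0), head_radius > 0, head_sample_n >= 4L,
            head_noise_sigma >= 0, patch_radius > 0, patch_n >= 1L,
            st_insertion_frac > 0, st_insertion_frac < 1)
  if (patch_radius > min(pelvis_semi))
    stop("patch radius exceeds the smallest pelvis semi-axis", call. = FALSE)
  structure(list(seed = as.integer(seed), body_mass = body_mass,
                 morphotype = morphotype, femur_length = femur_length,
                 tibia_length = tibia_length, pelvis_semi = pelvis_semi,
                 head_radius = head_radius, head_sample_n = as.integer(head_sample_n),
                 head_noise_sigma = head_noise_sigma,
                 patch_radius = patch_radius, patch_n = as.integer(patch_n),
                 st_insertion_frac = st_insertion_frac,
                 planar = isTRUE(planar), offset = .as_point3(offset, "offset")),
            class = "synthetic_spec")
}

.morpho_scale <- function(morphotype) {
  switch(morphotype, generic = 1.0, trunk_leaper = 1.15, horizontal_leaper = 0.88)
}

# nominal attachment centroids in the local frame (before morphotype scaling
# and global offset); (x, y, z) in mm
.muscle_layout <- function(spec) {
  ang <- function(a_deg, r, x) c(x, r * cospi(a_deg / 180), r * sinpi(a_deg / 180))
  fl <- spec$femur_length
  st_y <- spec$st_insertion_frac * spec$tibia_length
  list(
    gluteus_medius = list(
      origin = ang(135, 4.0, 1.2), insertion = ang(35, 4.0, 0.9),
      origin_bone = "pelvis", insertion_bone = "femur", biarticular = FALSE),
    gluteus_minimus = list(
      origin = ang(142, 3.2, 0.8), insertion = ang(42, 3.1, 0.6),
      origin_bone = "pelvis", insertion_bone = "femur", biarticular = FALSE),
    biceps_femoris = list(
      origin = c(1.0, 6.5, 1.5), insertion = c(0.8, 4.0, -fl + 1.0),
      origin_bone = "pelvis", insertion_bone = "tibia", biarticular = TRUE),
    semimembranosus = list(
      origin = c(0.5, 6.0, 0.5), insertion = c(0.5, 3.0, -fl + 1.5),
      origin_bone = "pelvis", insertion_bone = "tibia", biarticular = TRUE),
    semitendinosus = list(
      origin = c(0.8, 5.5, 1.0), insertion = c(0.6, st_y, -fl + 0.5),
      origin_bone = "pelvis", insertion_bone = "tibia", biarticular = TRUE)
  )
}

# deterministic spherical Fibonacci lattice on a cap of the unit sphere
.fibonacci_cap <- function(n, cap_fraction = 0.8) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * cap_fraction * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

.ellipsoid_cloud <- function(center, semi, n = 600L) {
  s <- .fibonacci_cap(n, cap_fraction = 1)  # full sphere
  sweep(sweep(s, 2L, semi, `*`), 2L, center, `+`)
}

.cylinder_cloud <- function(p0, axis, length, radius, n_circ = 14L, n_len = 40L) {
  u <- .unit3(axis)
  ref <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- .unit3(.cross3(u, ref)); e2 <- .cross3(u, e1)
  th <- 2 * pi * (seq_len(n_circ) - 1L) / n_circ
  h <- seq(0, length, length.out = n_len)
  g <- expand.grid(th = th, h = h)
  pts <- outer(g$h, u) + radius * (outer(cos(g$th), e1) + outer(sin(g$th), e2))
  sweep(pts, 2L, p0, `+`)
}

# symmetric disk of patch points around `center` in the plane with normal `n`;
# ring sums cancel so the patch mean equals `center` exactly
.patch_disk <- function(center, normal, radius, n) {
  u <- .unit3(normal)
  ref <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- .unit3(.cross3(u, ref)); e2 <- .cross3(u, e1)
  pts <- matrix(center, 1L, 3L, byrow = TRUE)
  remaining <- n - 1L
  rings <- list(c(0.5, min(6L, remaining)),
                c(1.0, max(0L, remaining - 6L)))
  for (rg in rings) {
    m <- rg[2L]
    if (m < 1L) next
    th <- 2 * pi * (seq_len(m) - 1L) / m
    ring <- matrix(center, m, 3L, byrow = TRUE) +
      radius * rg[1L] * (outer(cos(th), e1) + outer(sin(th), e2))
    pts <- rbind(pts, ring)
  }
  pts
}

#' Generate a synthetic hindlimb model
#'
#' Builds the bone point clouds, femoral head samples, attachment patches and
#' the assembled [msk_model()] from a [synthetic_spec()], deterministically
#' given the spec's seed. Attachment patches are point-symmetric disks, so the
#' patch centroids equal the nominal layout exactly; the returned ground truth
#' (true hip center, head radius, reference attachment centroids) is therefore
#' exact for noise-free specs.
#'
#' @param spec A [synthetic_spec()].
#' @return The [msk_model()], with the ground truth attached as attribute
#'   `"ground_truth"` (retrievable via [ground_truth()]).
#' @export
generate_model <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(spec$seed)

  off <- spec$offset
  sc <- .morpho_scale(spec$morphotype)
  fl <- spec$femur_length
  layout <- .muscle_layout(spec)
  if (spec$planar)
    layout <- lapply(layout, function(m) {
      m$origin[1L] <- 0; m$insertion[1L] <- 0; m
    })
  layout <- lapply(layout, function(m) {
    m$origin <- sc * m$origin; m$insertion <- sc * m$insertion; m
  })

  pelvis_center <- c(0, -5, 2.5)
  # stylized ischial ridge through the biceps femoris origin: a dense line of
  # surface points along the pelvis long axis, so that origin-shift analyses
  # slide along an actual surface feature rather than jumping across the
  # ellipsoid
  bf_o <- layout$biceps_femoris$origin
  ridge <- cbind(bf_o[1L], seq(-2, 14.5, by = 0.3), bf_o[3L])
  shaft <- list(
    pelvis = rbind(.ellipsoid_cloud(pelvis_center, spec$pelvis_semi), ridge),
    femur = .cylinder_cloud(c(0, 0, -2), c(0, 0, -1), fl - 2, 1.6),
    tibia = .cylinder_cloud(c(0, 0, -fl), c(0, 1, 0), spec$tibia_length, 1.4),
    fibula = .cylinder_cloud(c(1.6, 1, -fl), c(0, 1, 0),
                             spec$tibia_length * 0.9, 0.5))

  head_pts <- spec$head_radius * .fibonacci_cap(spec$head_sample_n)
  if (spec$head_noise_sigma > 0)
    head_pts <- head_pts + matrix(stats::rnorm(length(head_pts),
                                               sd = spec$head_noise_sigma),
                                  ncol = 3L)

  patch_normal <- function(bone, p) {
    n <- switch(bone,
      pelvis = (p - pelvis_center) / spec$pelvis_semi^2,
      femur = c(p[1L], p[2L], 0),
      tibia = c(p[1L], 0, p[3L] + fl),
      fibula = c(p[1L] - 1.6, 0, p[3L] + fl))
    if (.norm3(n) < 1e-9) n <- c(0, 0, 1)
    n
  }

  patches <- lapply(layout, function(m) {
    list(origin = .patch_disk(m$origin, patch_normal(m$origin_bone, m$origin),
                              spec$patch_radius, spec$patch_n),
         insertion = .patch_disk(m$insertion,
                                 patch_normal(m$insertion_bone, m$insertion),
                                 spec$patch_radius, spec$patch_n))
  })

  # assemble per-bone vertex arrays: shaft lattice, then head samples (femur),
  # then the attachment patches that live on the bone; record index ranges
  verts <- shaft
  head_idx <- NULL
  verts$femur <- rbind(verts$femur, head_pts)
  head_idx <- nrow(shaft$femur) + seq_len(nrow(head_pts))
  site_idx <- list()
  for (nm in names(layout)) {
    for (side in c("origin", "insertion")) {
      bone <- layout[[nm]][[paste0(side, "_bone")]]
      pp <- patches[[nm]][[side]]
      start <- nrow(verts[[bone]])
      verts[[bone]] <- rbind(verts[[bone]], pp)
      site_idx[[nm]][[side]] <- start + seq_len(nrow(pp))
    }
  }
  verts <- lapply(verts, function(v) sweep(v, 2L, off, `+`))

  seg <- c(pelvis = "pelvis-fixed", femur = "femur-fixed",
           tibia = "shank-fixed", fibula = "shank-fixed")
  bones <- lapply(names(verts), function(b) msk_bone(b, verts[[b]], seg[[b]]))
  names(bones) <- names(verts)

  muscles <- lapply(names(layout), function(nm) {
    m <- layout[[nm]]
    msk_muscle(nm,
               origin = attachment_site(m$origin_bone,
                 patch = bones[[m$origin_bone]]$vertices[site_idx[[nm]]$origin, , drop = FALSE]),
               insertion = attachment_site(m$insertion_bone,
                 patch = bones[[m$insertion_bone]]$vertices[site_idx[[nm]]$insertion, , drop = FALSE]),
               biarticular = m$biarticular)
  })

  hip <- build_hip_joint(bones$femur$vertices[head_idx, , drop = FALSE],
                         fe_axis = c(1, 0, 0),
                         reference_femur_axis = c(0, 0, -1))
  model <- msk_model(bones, muscles, hip, body_mass = spec$body_mass,
                     model_id = sprintf("synthetic_%s_seed%d",
                                        spec$morphotype, spec$seed))
  gt <- structure(list(
    center = off, radius = spec$head_radius, fe_axis = c(1, 0, 0),
    centroids = lapply(layout, function(m)
      list(origin = m$origin + off, insertion = m$insertion + off)),
    head_vertex_indices = head_idx,
    site_vertex_indices = site_idx,
    planar = spec$planar, morphotype_scale = sc, spec = spec),
    class = "ground_truth")
  attr(model, "ground_truth") <- gt
  model
}

#' Ground truth of a generated model
#'
#' @param model A model produced by [generate_model()].
#' @return The `ground_truth` object (true hip center, head radius, exact
#'   reference-pose attachment centroids, generator spec).
#' @export
ground_truth <- function(model) {
  gt <- attr(model, "ground_truth")
  if (is.null(gt)) stop("model carries no ground truth (not synthetic?)", call. = FALSE)
  gt
}

#' Generate a cohort of synthetic models
#'
#' Produces `n` models differing in morphotype and body mass, emulating a
#' small comparative sample, so that the sweep and the comparative summaries
#' run end to end.
#'
#' @param n Number of models (>= 1).
#' @param base_spec Template [synthetic_spec()]; per-model seeds are
#'   `base_spec$seed + 0:(n-1)`.
#' @param morphotypes Character vector recycled to length `n`.
#' @param masses Body masses in grams, recycled to length `n`; defaults span
#'   the small-bodied 120-700 g range.
#' @return List of models (see [generate_model()]).
#' @export
generate_cohort <- function(n = 4L, base_spec = synthetic_spec(),
                            morphotypes = c("trunk_leaper", "horizontal_leaper",
                                            "generic", "horizontal_leaper"),
                            masses = NULL) {
  stopifnot(n >= 1L, inherits(base_spec, "synthetic_spec"))
  morphotypes <- rep_len(morphotypes, n)
  if (is.null(masses))
    masses <- round(seq(500, 180, length.out = n))
  masses <- rep_len(masses, n)
  lapply(seq_len(n), function(i) {
    sp <- base_spec
    sp$seed <- base_spec$seed + i - 1L
    sp$morphotype <- match.arg(morphotypes[i],
                               c("generic", "trunk_leaper", "horizontal_leaper"))
    sp$body_mass <- masses[i]
    generate_model(sp)
  })
}
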