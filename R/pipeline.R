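# The core computation: per-muscle, per-angle instantaneous moment arms
# (3D and projected onto the flexion-extension plane), muscle length, strain
# against the optimal length-tension band, and body-mass^0.33 normalization,
# swept over the hip extension range.

#' Optimal length-tension band
#'
#' Strain (instantaneous length as a percentage of resting length) is
#' classified as optimal inside the band, inclusive at both bounds.
#'
#' @param low_pct,high_pct Band bounds in percent; defaults 85 and 115.
#' @return Object of class `strain_band`.
#' @export
strain_band <- function(low_pct = 85, high_pct = 115) {
  stopifnot(is.finite(low_pct), is.finite(high_pct),
            low_pct > 0, low_pct < 100, high_pct > 100)
  structure(list(low_pct = low_pct, high_pct = high_pct), class = "strain_band")
}

#' Muscle line of action at a pose
#'
#' The straight segment joining the posed origin and insertion centroids.
#'
#' @param model A [msk_model()].
#' @param muscle Muscle name or index.
#' @param hip_extension_deg Hip extension angle (degrees).
#' @return List with endpoints `a` (origin) and `b` (insertion).
#' @export
line_of_action <- function(model, muscle, hip_extension_deg) {
  m <- .get_muscle(model, muscle)
  a <- .pose_point(model, m$origin, hip_extension_deg)
  b <- .pose_point(model, m$insertion, hip_extension_deg)
  if (.norm3(b - a) < 1e-9)
    stop(sprintf("muscle '%s': degenerate line of action (coincident centroids)",
                 m$name), call. = FALSE)
  list(a = a, b = b)
}

.get_muscle <- function(model, muscle) {
  stopifnot(inherits(model, "msk_model"))
  m <- model$muscles[[muscle]]
  if (is.null(m)) stop(sprintf("unknown muscle '%s'", muscle), call. = FALSE)
  m
}

#' Instantaneous muscle moment arm at a pose
#'
#' The 3D moment arm is the distance from the hip joint center to the nearest
#' point on the muscle's line of action. Because an obliquely oriented muscle
#' contributes to several rotation axes, the arm is additionally restricted to
#' the parasagittal flexion-extension plane; three projection readings are
#' available:
#' \describe{
#'   \item{`"vector"`}{(default) project the 3D moment-arm vector (center to
#'     nearest point) onto the plane and report its length;}
#'   \item{`"inplane"`}{project the whole line of action and the center into
#'     the plane first, then take the 2D perpendicular distance;}
#'   \item{`"axis"`}{the torque-about-axis scalar
#'     \eqn{|((p - c) \times \hat u) \cdot n|} with \eqn{p} a point on the
#'     line, \eqn{\hat u} its direction and \eqn{n} the axis.}
#' }
#' All three agree in planar configurations. The signed torque-about-axis
#' value is returned alongside so extensor (positive: tension drives
#' extension) versus flexor action can be flagged.
#'
#' @inheritParams line_of_action
#' @param clamp If `TRUE` (default) the nearest point is constrained to the
#'   attachment-to-attachment segment; if `FALSE` the infinite line is used
#'   (the physically conventional moment arm).
#' @param projection Projection method, see Details.
#' @return List with `mma_3d_mm`, `mma_projected_mm` and `signed_axis_mm`.
#' @export
instantaneous_mma <- function(model, muscle, hip_extension_deg, clamp = TRUE,
                              projection = c("vector", "inplane", "axis")) {
  projection <- match.arg(projection)
  loa <- line_of_action(model, muscle, hip_extension_deg)
  ctr <- model$hip$center
  ax <- model$hip$fe_axis
  np <- nearest_point_on_segment(loa$a, loa$b, ctr, clamp = clamp)
  arm <- np$point - ctr
  u <- (loa$b - loa$a) / .norm3(loa$b - loa$a)
  signed <- sum(.cross3(arm, u) * ax)
  proj <- switch(projection,
    vector = project_vector_onto_plane(arm, ax)$length,
    inplane = {
      pp <- function(p) p - sum((p - ctr) * ax) * ax
      a2 <- pp(loa$a); b2 <- pp(loa$b)
      if (.norm3(b2 - a2) < 1e-12) 0
      else nearest_point_on_segment(a2, b2, ctr, clamp = clamp)$distance
    },
    axis = abs(signed))
  list(mma_3d_mm = np$distance, mma_projected_mm = proj, signed_axis_mm = signed)
}

#' Straight-line muscle length at a pose
#'
#' Euclidean distance between the posed origin and insertion centroids (the
#' chord length; no via points or wrapping).
#'
#' @inheritParams line_of_action
#' @return Length in mm.
#' @export
muscle_length <- function(model, muscle, hip_extension_deg) {
  loa <- line_of_action(model, muscle, hip_extension_deg)
  .norm3(loa$b - loa$a)
}

#' Muscle strain and its length-tension classification
#'
#' Strain is the instantaneous length divided by the resting length, in
#' percent. Strains inside the band (inclusive) are `optimal`; shorter is
#' `suboptimal_short`, longer `suboptimal_long`.
#'
#' @param length_mm Instantaneous length(s), mm.
#' @param resting_length_mm Resting length (at the 90/90 reference pose), mm.
#' @param band A [strain_band()].
#' @return Data frame with `strain_pct` and `strain_class` (factor).
#' @export
muscle_strain <- function(length_mm, resting_length_mm, band = strain_band()) {
  stopifnot(inherits(band, "strain_band"),
            all(is.finite(length_mm)), all(length_mm > 0),
            is.finite(resting_length_mm), resting_length_mm > 0)
  pct <- 100 * length_mm / resting_length_mm
  cls <- ifelse(pct < band$low_pct, "suboptimal_short",
         ifelse(pct > band$high_pct, "suboptimal_long", "optimal"))
  data.frame(strain_pct = pct,
             strain_class = factor(cls, levels = c("suboptimal_short", "optimal",
                                                   "suboptimal_long")))
}

#' Normalize a length or moment arm by body mass
#'
#' Divides by `body_mass^exponent`; the default exponent 0.33 makes lengths of
#' differently sized animals comparable (an isometric cube-root scaling, kept
#' at the printed two-decimal value rather than 1/3).
#'
#' @param value Value(s) in mm.
#' @param body_mass Body mass (> 0); unit-consistent across compared models.
#' @param exponent Scaling exponent.
#' @return Normalized value(s), mm / mass^exponent.
#' @export
normalize_by_mass <- function(value, body_mass, exponent = 0.33) {
  stopifnot(is.finite(body_mass), body_mass > 0)
  value / body_mass^exponent
}

#' Sweep moment arms and strains over the hip extension range
#'
#' The central computation. For every muscle and every angle of the sweep
#' (default 20 to 160 degrees in 10-degree steps, the knee locked at 90
#' degrees), computes the 3D and projected instantaneous moment arm, the
#' muscle length, the strain with its length-tension class, and the
#' mass-normalized projected moment arm.
#'
#' @param model A [msk_model()].
#' @param angles Sweep angles in degrees (an increasing arithmetic sequence).
#' @param clamp,projection Passed to [instantaneous_mma()].
#' @param exponent Mass-normalization exponent, see [normalize_by_mass()].
#' @param band A [strain_band()].
#' @return Object of class `mma_curves` (a data frame with one row per
#'   muscle x angle and columns `model_id`, `muscle`, `angle_deg`,
#'   `mma_3d_mm`, `mma_projected_mm`, `mma_normalized`, `length_mm`,
#'   `strain_pct`, `strain_class`), carrying the sweep configuration as
#'   attributes. Has print, summary and plot methods.
#' @export
hip_sweep <- function(model, angles = seq(20, 160, by = 10), clamp = TRUE,
                      projection = c("vector", "inplane", "axis"),
                      exponent = 0.33, band = strain_band()) {
  projection <- match.arg(projection)
  stopifnot(inherits(model, "msk_model"), length(angles) >= 1L,
            all(is.finite(angles)))
  if (is.unsorted(angles, strictly = TRUE))
    stop("sweep angles must be strictly increasing", call. = FALSE)
  if (length(angles) > 2L &&
      max(abs(diff(diff(angles)))) > 1e-9)
    stop("sweep angles must form an arithmetic sequence", call. = FALSE)
  rows <- vector("list", length(model$muscles) * length(angles))
  k <- 0L
  for (nm in names(model$muscles)) {
    m <- model$muscles[[nm]]
    for (th in angles) {
      mm <- instantaneous_mma(model, nm, th, clamp = clamp, projection = projection)
      len <- muscle_length(model, nm, th)
      st <- muscle_strain(len, m$resting_length, band)
      k <- k + 1L
      rows[[k]] <- data.frame(
        model_id = model$model_id, muscle = nm, angle_deg = th,
        mma_3d_mm = mm$mma_3d_mm, mma_projected_mm = mm$mma_projected_mm,
        mma_normalized = normalize_by_mass(mm$mma_projected_mm, model$body_mass,
                                           exponent),
        length_mm = len, strain_pct = st$strain_pct,
        strain_class = as.character(st$strain_class),
        signed_axis_mm = mm$signed_axis_mm)
    }
  }
  out <- if (k == 0L)
    data.frame(model_id = character(0), muscle = character(0),
               angle_deg = numeric(0), mma_3d_mm = numeric(0),
               mma_projected_mm = numeric(0), mma_normalized = numeric(0),
               length_mm = numeric(0), strain_pct = numeric(0),
               strain_class = character(0), signed_axis_mm = numeric(0))
  else do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out,
            class = c("mma_curves", "data.frame"),
            sweep = c(start = angles[1L], stop = angles[length(angles)],
                      step = if (length(angles) > 1L) angles[2L] - angles[1L] else 0),
            clamp = clamp, projection = projection, exponent = exponent,
            band = c(band$low_pct, band$high_pct),
            body_mass = model$body_mass,
            sphere = c(model$hip$center, model$hip$radius))
}

#' @export
print.mma_curves <- function(x, ...) {
  sw <- attr(x, "sweep")
  cat(sprintf("Moment arm / strain curves: %d muscles x %d angles (%g to %g by %g deg)\n",
              length(unique(x$muscle)), length(unique(x$angle_deg)),
              sw["start"], sw["stop"], sw["step"]))
  cat(sprintf("  nearest point: %s; projection: %s; mass exponent: %g\n",
              if (attr(x, "clamp")) "segment-clamped" else "infinite line",
              attr(x, "projection"), attr(x, "exponent")))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("... (", nrow(x) - 10L, " more rows)\n", sep = "")
  invisible(x)
}

#' @export
summary.mma_curves <- function(object, ...) {
  df <- as.data.frame(object)
  agg <- do.call(rbind, lapply(split(df, df$muscle), function(d) {
    pk <- d$angle_deg[which.max(d$mma_projected_mm)]
    data.frame(muscle = d$muscle[1L],
               mma_min = min(d$mma_projected_mm), mma_max = max(d$mma_projected_mm),
               peak_angle_deg = pk,
               strain_min = min(d$strain_pct), strain_max = max(d$strain_pct),
               pct_optimal = 100 * mean(d$strain_class == "optimal"))
  }))
  rownames(agg) <- NULL
  agg
}

#' Plot moment-arm and strain curves
#'
#' Two base-graphics panels: projected (or normalized) moment arm versus hip
#' extension angle per muscle, and strain versus angle with the optimal
#' length-tension band shaded.
#'
#' @param x An `mma_curves` object.
#' @param normalized Plot the mass-normalized arm instead of mm.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.mma_curves <- function(x, normalized = FALSE, ...) {
  df <- as.data.frame(x)
  muscles <- unique(df$muscle)
  ang <- sort(unique(df$angle_deg))
  ycol <- if (normalized) "mma_normalized" else "mma_projected_mm"
  mat <- sapply(muscles, function(m) df[[ycol]][df$muscle == m][order(df$angle_deg[df$muscle == m])])
  smat <- sapply(muscles, function(m) df$strain_pct[df$muscle == m][order(df$angle_deg[df$muscle == m])])
  op <- graphics::par(mfrow = c(2L, 1L), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::matplot(ang, mat, type = "b", pch = 1:5, lty = 1, col = 1:5,
                    xlab = "hip extension angle (deg)",
                    ylab = if (normalized) "IMMA / mass^exp" else "projected IMMA (mm)",
                    ...)
  graphics::legend("topleft", legend = muscles, col = 1:5, pch = 1:5, lty = 1,
                   cex = 0.7, bty = "n")
  band <- attr(x, "band")
  graphics::matplot(ang, smat, type = "b", pch = 1:5, lty = 1, col = 1:5,
                    xlab = "hip extension angle (deg)", ylab = "strain (% resting length)")
  graphics::rect(min(ang), band[1L], max(ang), band[2L],
                 col = grDevices::adjustcolor("palegreen", 0.3), border = NA)
  invisible(x)
}

#' Size-normalized length summary
#'
#' Effective femur and pelvis lengths and per-muscle resting lengths divided by
#' `body_mass^exponent` -- the standard relative-length comparison across
#' specimens of different size.
#'
#' @param model A [msk_model()].
#' @param exponent Mass-normalization exponent.
#' @return Data frame with `element`, `kind`, `length_mm`, `relative_length`.
#' @export
relative_lengths <- function(model, exponent = 0.33) {
  stopifnot(inherits(model, "msk_model"))
  el <- c(if (!is.null(model$femur_length)) c(femur = model$femur_length),
          if (!is.null(model$pelvis_length)) c(pelvis = model$pelvis_length))
  if (length(el) == 0L && length(model$muscles) == 0L)
    stop("model has no length measurements to summarize", call. = FALSE)
  mu <- vapply(model$muscles, `[[`, 0, "resting_length")
  out <- data.frame(
    model_id = model$model_id,
    element = c(names(el), names(mu)),
    kind = c(rep("bone", length(el)), rep("muscle", length(mu))),
    length_mm = unname(c(el, mu)))
  out$relative_length <- normalize_by_mass(out$length_mm, model$body_mass, exponent)
  out
}
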