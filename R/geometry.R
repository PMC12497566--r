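# Low-level 3D vector geometry. Points are length-3 numeric vectors or n x 3
# matrices, in millimetres. Angles are degrees at every interface.

.as_pointmat <- function(x, arg = "points") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.numeric(x) && is.null(dim(x)) && length(x) == 3L) x <- matrix(x, 1L, 3L)
  if (!is.matrix(x) || ncol(x) != 3L || !is.numeric(x))
    stop(sprintf("'%s' must be a numeric vector of length 3 or an n x 3 matrix", arg),
         call. = FALSE)
  if (!all(is.finite(x)))
    stop(sprintf("'%s' contains non-finite coordinates", arg), call. = FALSE)
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

.as_point3 <- function(x, arg = "point") {
  p <- .as_pointmat(x, arg)
  if (nrow(p) != 1L)
    stop(sprintf("'%s' must be a single 3D point", arg), call. = FALSE)
  drop(p)
}

.norm3 <- function(v) sqrt(sum(v * v))

.unit3 <- function(v, arg = "vector") {
  v <- .as_point3(v, arg)
  n <- .norm3(v)
  if (n < 1e-12)
    stop(sprintf("'%s' has zero length and cannot be normalized", arg), call. = FALSE)
  v / n
}

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Fit a sphere to 3D points by linear least squares
#'
#' Estimates the sphere minimizing the algebraic residual
#' \eqn{\sum_i (|p_i - c|^2 - r^2)^2} via the standard linear reformulation:
#' with unknowns \eqn{(c, k)}, \eqn{k = r^2 - |c|^2}, each point contributes the
#' linear equation \eqn{2 p_i \cdot c + k = |p_i|^2}. For points lying exactly
#' on a sphere the fit recovers it to machine precision; it is deterministic and
#' needs no initialization. The usual application here is approximating the hip
#' joint center of rotation from points sampled on the femoral head.
#'
#' @param points Numeric n x 3 matrix (n >= 4) of point coordinates in mm.
#' @return An object of class `sphere_fit`: a list with elements `center`
#'   (length-3 numeric), `radius`, `residuals` (geometric distances
#'   \eqn{|p_i - c| - r}), `rmse`, and `n`.
#' @examples
#' pts <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))
#' fit_sphere(pts)  # circumsphere: center (1,1,1), radius sqrt(3)
#' @export
fit_sphere <- function(points) {
  p <- .as_pointmat(points)
  if (nrow(p) < 4L)
    stop("sphere fitting needs at least 4 points", call. = FALSE)
  A <- cbind(2 * p, 1)
  b <- rowSums(p^2)
  qa <- qr(A)
  if (qa$rank < 4L)
    stop("degenerate point configuration (coplanar or coincident): sphere fit is singular",
         call. = FALSE)
  sol <- qr.coef(qa, b)
  center <- sol[1:3]
  r2 <- sol[4L] + sum(center^2)
  if (!is.finite(r2) || r2 <= 0)
    stop("degenerate point configuration: non-positive fitted radius", call. = FALSE)
  radius <- sqrt(r2)
  res <- sqrt(rowSums(sweep(p, 2L, center)^2)) - radius
  structure(
    list(center = unname(center), radius = radius, residuals = res,
         rmse = sqrt(mean(res^2)), n = nrow(p)),
    class = "sphere_fit"
  )
}

#' @export
print.sphere_fit <- function(x, digits = 4L, ...) {
  cat("Least-squares sphere fit (", x$n, " points)\n", sep = "")
  cat("  center: (", paste(signif(x$center, digits), collapse = ", "), ") mm\n", sep = "")
  cat("  radius: ", signif(x$radius, digits), " mm\n", sep = "")
  cat("  radial rmse: ", signif(x$rmse, digits), " mm\n", sep = "")
  invisible(x)
}

#' @export
coef.sphere_fit <- function(object, ...) {
  c(cx = object$center[1L], cy = object$center[2L], cz = object$center[3L],
    r = object$radius)
}

#' @export
residuals.sphere_fit <- function(object, ...) object$residuals

#' @export
fitted.sphere_fit <- function(object, ...) object$radius + 0 * object$residuals

#' Nearest point on a segment or line, and its distance
#'
#' Returns the point on the segment `a`--`b` (default) or on the infinite line
#' through `a` and `b` (`clamp = FALSE`) closest to the query point `q`, with
#' the Euclidean distance. With `q` a joint center and `a`, `b` the attachment
#' centroids of a muscle, the distance is the 3D instantaneous muscle moment
#' arm.
#'
#' @param a,b Segment endpoints (length-3 numeric, mm). Must differ.
#' @param q Query point.
#' @param clamp If `TRUE` (default) the parameter is clamped to the segment;
#'   if `FALSE` the infinite line is used.
#' @return List with `point` (nearest point), `distance` (mm) and `t` (the
#'   unclamped line parameter, 0 at `a`, 1 at `b`).
#' @export
nearest_point_on_segment <- function(a, b, q, clamp = TRUE) {
  a <- .as_point3(a, "a"); b <- .as_point3(b, "b"); q <- .as_point3(q, "q")
  d <- b - a
  dd <- sum(d * d)
  if (dd < 1e-24)
    stop("degenerate segment: endpoints coincide", call. = FALSE)
  t <- sum((q - a) * d) / dd
  tc <- if (clamp) min(1, max(0, t)) else t
  p <- a + tc * d
  list(point = p, distance = .norm3(p - q), t = t)
}

#' Rotate points about an arbitrary axis (Rodrigues' formula)
#'
#' @param p Point(s) to rotate: length-3 vector or n x 3 matrix.
#' @param axis_point A point on the rotation axis.
#' @param axis_dir Axis direction (normalized internally).
#' @param angle_deg Rotation angle in degrees (right-handed about `axis_dir`).
#' @return Rotated point(s), same shape as `p`.
#' @export
rotate_about_axis <- function(p, axis_point, axis_dir, angle_deg) {
  vec_in <- is.null(dim(p))
  pm <- .as_pointmat(p, "p")
  c0 <- .as_point3(axis_point, "axis_point")
  u <- .unit3(axis_dir, "axis_dir")
  stopifnot(is.finite(angle_deg), length(angle_deg) == 1L)
  a <- angle_deg * pi / 180
  ca <- cos(a); sa <- sin(a)
  v <- sweep(pm, 2L, c0)
  # v ca + (u x v) sa + u (u.v)(1-ca)
  uxv <- cbind(u[2L] * v[, 3L] - u[3L] * v[, 2L],
               u[3L] * v[, 1L] - u[1L] * v[, 3L],
               u[1L] * v[, 2L] - u[2L] * v[, 1L])
  udv <- as.vector(v %*% u)
  out <- v * ca + uxv * sa + outer(udv * (1 - ca), u)
  out <- sweep(out, 2L, -c0)
  if (vec_in) drop(out) else out
}

#' Project a vector onto the plane with a given normal
#'
#' Removes the component of `v` along `normal` and reports the remaining
#' in-plane vector and its length. Used to restrict a 3D moment-arm vector to
#' the parasagittal flexion-extension plane, whose normal is the medio-lateral
#' axis.
#'
#' @param v Vector to project.
#' @param normal Plane normal (normalized internally).
#' @return List with `vector` (the projection) and `length`.
#' @export
project_vector_onto_plane <- function(v, normal) {
  v <- .as_point3(v, "v")
  n <- .unit3(normal, "normal")
  w <- v - sum(v * n) * n
  list(vector = w, length = .norm3(w))
}
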