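# The three robustness analyses: repeated attachment-centroid placement
# (Gaussian jitter + surface re-projection), body-mass perturbation, and
# shifting the biceps femoris origin along the pelvis long axis.

.SENS_QUANTITIES <- c("mma_3d_mm", "mma_projected_mm", "mma_normalized",
                      "length_mm", "strain_pct")

.rebuild_model <- function(model, muscles = model$muscles,
                           body_mass = model$body_mass) {
  msk_model(model$bones, muscles, model$hip, body_mass,
            pelvis_length = model$pelvis_length,
            femur_length = model$femur_length, model_id = model$model_id)
}

# long-format quantity table from one sweep
.curves_long <- function(curves, level, replicate) {
  df <- as.data.frame(curves)
  do.call(rbind, lapply(.SENS_QUANTITIES, function(q)
    data.frame(level = level, replicate = replicate, muscle = df$muscle,
               angle_deg = df$angle_deg, quantity = q, value = df[[q]])))
}

.sens_report <- function(kind, long, spec, runs) {
  key <- interaction(long$level, long$muscle, long$angle_deg, long$quantity,
                     drop = TRUE)
  agg <- do.call(rbind, lapply(split(long, key), function(d)
    data.frame(kind = kind, level = d$level[1L], muscle = d$muscle[1L],
               angle_deg = d$angle_deg[1L], quantity = d$quantity[1L],
               mean = mean(d$value), sd = stats::sd(d$value),
               min = min(d$value), max = max(d$value))))
  agg$sd[is.na(agg$sd)] <- 0
  agg <- agg[order(agg$level, agg$muscle, agg$angle_deg, agg$quantity), ]
  rownames(agg) <- NULL
  structure(agg, class = c("sensitivity_report", "data.frame"),
            kind = kind, spec = spec, runs = runs)
}

#' @export
print.sensitivity_report <- function(x, ...) {
  sp <- attr(x, "spec")
  cat("Sensitivity report: ", attr(x, "kind") %||% paste(unique(x$kind), collapse = ","),
      "\n", sep = "")
  cat("  levels: ", paste(unique(x$level), collapse = ", "),
      "; replicates: ", sp$replicates %||% 1L, "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("... (", nrow(x) - 10L, " more rows)\n", sep = "")
  invisible(x)
}

# snap a point to the nearest of a set of candidate surface points
.snap_to_points <- function(p, candidates) {
  d2 <- rowSums(sweep(candidates, 2L, p)^2)
  candidates[which.min(d2), ]
}

#' Repeated attachment placement analysis
#'
#' Emulates repeated manual placement of the attachment centroids: per
#' replicate, every centroid is displaced by an isotropic Gaussian offset
#' (standard deviation `sigma_mm` per coordinate) and re-projected to the
#' nearest point of its attachment patch (or of its bone's surface cloud if
#' the site has no patch); the full sweep is recomputed and per-(muscle,
#' angle) dispersion statistics of every output quantity are returned.
#' Deterministic given `seed`. With `sigma_mm = 0` no displacement is applied
#' and every replicate reproduces the baseline exactly.
#'
#' @param model A [msk_model()].
#' @param sigma_mm Placement jitter standard deviation, mm (default 0.5,
#'   small relative to bone size).
#' @param replicates Number of independent placements (default 5).
#' @param seed Integer seed.
#' @param ... Passed to [hip_sweep()].
#' @return A `sensitivity_report` data frame (columns `kind`, `level`,
#'   `muscle`, `angle_deg`, `quantity`, `mean`, `sd`, `min`, `max`), with the
#'   per-replicate sweeps in attribute `"runs"`.
#' @export
placement_repeatability <- function(model, sigma_mm = 0.5, replicates = 5L,
                                    seed = 1L, ...) {
  stopifnot(inherits(model, "msk_model"), sigma_mm >= 0, replicates >= 1L)
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)
  runs <- vector("list", replicates)
  long <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    muscles <- model$muscles
    if (sigma_mm > 0) {
      for (nm in names(muscles)) {
        for (side in c("origin", "insertion")) {
          site <- muscles[[nm]][[side]]
          jit <- site$centroid + stats::rnorm(3L, sd = sigma_mm)
          surf <- site$patch %||% model$bones[[site$bone]]$vertices
          muscles[[nm]][[side]] <- attachment_site(site$bone, patch = site$patch,
                                                   centroid = .snap_to_points(jit, surf))
        }
      }
    }
    cur <- hip_sweep(.rebuild_model(model, muscles = muscles), ...)
    runs[[r]] <- cur
    long[[r]] <- .curves_long(cur, level = sigma_mm, replicate = r)
  }
  .sens_report("placement_jitter", do.call(rbind, long),
               spec = list(kind = "placement_jitter", magnitude = sigma_mm,
                           replicates = replicates, seed = seed),
               runs = runs)
}

#' Body-mass perturbation analysis
#'
#' Recomputes the sweep with the body mass changed by each fraction
#' (`mass * (1 + f)`). Raw moment arms and lengths are unchanged; normalized
#' quantities scale by the analytic factor \eqn{(1+f)^{-exponent}}.
#'
#' @param model A [msk_model()].
#' @param fractions Mass change fractions (all > -1); defaults to the
#'   standard +/-10%, +/-20% levels.
#' @param ... Passed to [hip_sweep()].
#' @return A `sensitivity_report` (one level per fraction; `sd` is 0 since
#'   each level is deterministic).
#' @export
mass_perturbation <- function(model, fractions = c(-0.20, -0.10, 0.10, 0.20),
                              ...) {
  stopifnot(inherits(model, "msk_model"), all(fractions > -1))
  runs <- list(); long <- list()
  for (f in fractions) {
    cur <- hip_sweep(.rebuild_model(model, body_mass = model$body_mass * (1 + f)),
                     ...)
    runs[[as.character(f)]] <- cur
    long[[as.character(f)]] <- .curves_long(cur, level = f, replicate = 1L)
  }
  .sens_report("mass_fraction", do.call(rbind, long),
               spec = list(kind = "mass_fraction", magnitude = fractions,
                           replicates = 1L),
               runs = runs)
}

# first principal axis of the pelvis cloud, oriented away from the hip center
.pelvis_axis <- function(model, from) {
  v <- model$bones[["pelvis"]]$vertices
  ax <- stats::prcomp(v, center = TRUE, scale. = FALSE)$rotation[, 1L]
  if (sum(ax * (from - model$hip$center)) < 0) ax <- -ax
  .unit3(ax)
}

#' Origin-shift analysis
#'
#' Shifts one muscle's origin centroid along the pelvis long axis (the first
#' principal component of the pelvis vertex cloud, oriented away from the hip
#' joint) by each fraction of the effective pelvis length, snaps the shifted
#' point back to the nearest pelvis surface point, and recomputes the sweep.
#' The conventional target is the biceps femoris.
#'
#' @param model A [msk_model()].
#' @param muscle Muscle whose origin is shifted.
#' @param fractions Shift fractions of pelvis length; positive values move the
#'   origin away from the hip joint.
#' @param ... Passed to [hip_sweep()].
#' @return A `sensitivity_report` (one level per fraction).
#' @export
origin_shift <- function(model, muscle = "biceps_femoris",
                         fractions = c(-0.20, -0.10, 0.10, 0.20), ...) {
  m <- .get_muscle(model, muscle)
  if (is.null(model$pelvis_length) || model$pelvis_length <= 0)
    stop("origin shift needs a positive pelvis length", call. = FALSE)
  pel <- model$bones[["pelvis"]]$vertices
  ax <- .pelvis_axis(model, from = m$origin$centroid)
  runs <- list(); long <- list()
  for (f in fractions) {
    muscles <- model$muscles
    if (f != 0) {
      target <- m$origin$centroid + f * model$pelvis_length * ax
      lo <- apply(pel, 2L, min); hi <- apply(pel, 2L, max)
      if (any(target < lo - 1e-9 | target > hi + 1e-9))
        warning(sprintf("shift %+g moves the origin outside the pelvis bounding box; snapping to the surface", f),
                call. = FALSE)
      snapped <- .snap_to_points(target, pel)
      muscles[[m$name]]$origin <- attachment_site(m$origin$bone,
                                                  patch = m$origin$patch,
                                                  centroid = snapped)
    }
    cur <- hip_sweep(.rebuild_model(model, muscles = muscles), ...)
    runs[[as.character(f)]] <- cur
    long[[as.character(f)]] <- .curves_long(cur, level = f, replicate = 1L)
  }
  .sens_report("origin_shift", do.call(rbind, long),
               spec = list(kind = "origin_shift", muscle = m$name,
                           magnitude = fractions, replicates = 1L),
               runs = runs)
}
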