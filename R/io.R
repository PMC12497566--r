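# Readers and writers: vertex-only OBJ point clouds, the JSON model
# descriptor, and provenance-headed CSV tables. Vertex indices are 0-based in
# descriptors (converted to R's 1-based indexing on read); OBJ is written and
# read as 'v' lines only, since the pipeline consumes point sets.

#' Write a point cloud as a vertex-only OBJ file
#'
#' @param vertices n x 3 matrix, mm.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(vertices, path) {
  v <- .as_pointmat(vertices, "vertices")
  lines <- sprintf("v %.17g %.17g %.17g", v[, 1L], v[, 2L], v[, 3L])
  writeLines(c("# vertex-only OBJ point cloud", lines), path)
  invisible(path)
}

#' Read vertices from an OBJ file
#'
#' Parses `v` lines; faces and other records are ignored.
#'
#' @param path OBJ file path.
#' @return n x 3 numeric matrix.
#' @export
read_obj <- function(path) {
  if (!file.exists(path)) stop(sprintf("mesh file not found: '%s'", path), call. = FALSE)
  ln <- readLines(path, warn = FALSE)
  vl <- ln[startsWith(ln, "v ")]
  if (length(vl) == 0L) stop(sprintf("no vertices in OBJ file '%s'", path), call. = FALSE)
  parts <- strsplit(trimws(sub("^v ", "", vl)), "[[:space:]]+")
  m <- t(vapply(parts, function(p) as.numeric(p[1:3]), numeric(3L)))
  if (anyNA(m)) stop(sprintf("malformed vertex line in '%s'", path), call. = FALSE)
  m
}

.pkg_version <- function() as.character(utils::packageVersion("momarm"))

.config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

#' Write a generated model to a directory
#'
#' Emits one vertex-only OBJ per bone, a JSON model descriptor
#' (`descriptor.json`) and, for synthetic models, the exact ground truth
#' (`ground_truth.json`). Attachment patches and femoral-head samples are
#' referenced by 0-based vertex indices into the bone meshes when the index
#' bookkeeping is available (synthetic models); otherwise explicit centroids
#' and the fitted sphere are written.
#'
#' @param model A [msk_model()].
#' @param dir Output directory (created if needed).
#' @return The descriptor path, invisibly.
#' @export
write_model <- function(model, dir) {
  stopifnot(inherits(model, "msk_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gt <- attr(model, "ground_truth")
  for (b in model$bones)
    write_obj(b$vertices, file.path(dir, paste0(b$name, ".obj")))
  desc <- list(
    model_id = model$model_id,
    body_mass_g = model$body_mass,
    fe_axis = model$hip$fe_axis,
    reference_femur_axis = model$hip$zero_pose_femur_axis,
    pelvis_length_mm = model$pelvis_length,
    femur_length_mm = model$femur_length,
    bones = lapply(model$bones, function(b)
      list(name = b$name, segment = b$segment, mesh = paste0(b$name, ".obj"))),
    femoral_head = if (!is.null(gt))
      list(bone = "femur", vertex_indices = gt$head_vertex_indices - 1L)
    else list(sphere = list(center = model$hip$center, radius = model$hip$radius)),
    muscles = lapply(names(model$muscles), function(nm) {
      m <- model$muscles[[nm]]
      site <- function(side) {
        s <- m[[side]]
        if (!is.null(gt))
          list(bone = s$bone,
               vertex_indices = gt$site_vertex_indices[[nm]][[side]] - 1L)
        else list(bone = s$bone, centroid = s$centroid)
      }
      list(name = nm, biarticular = m$biarticular,
           origin = site("origin"), insertion = site("insertion"))
    })
  )
  desc$bones <- unname(desc$bones)
  dpath <- file.path(dir, "descriptor.json")
  jsonlite::write_json(desc, dpath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(gt)) {
    gtj <- list(center = gt$center, radius = gt$radius, fe_axis = gt$fe_axis,
                planar = gt$planar, morphotype_scale = gt$morphotype_scale,
                centroids = lapply(gt$centroids, function(cc)
                  list(origin = cc$origin, insertion = cc$insertion)))
    jsonlite::write_json(gtj, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dpath)
}

.need <- function(x, field, where) {
  if (is.null(x[[field]]))
    stop(sprintf("model descriptor: missing required field '%s' in %s",
                 field, where), call. = FALSE)
  x[[field]]
}

#' Read a model from a JSON descriptor
#'
#' Loads the descriptor, reads the referenced OBJ meshes, resolves attachment
#' patches (0-based vertex indices) or explicit centroids, fits the hip sphere
#' from the femoral-head vertices (or takes an explicit sphere), and assembles
#' the [msk_model()] with derived quantities (centroids, resting lengths,
#' effective bone lengths).
#'
#' @param descriptor_path Path to `descriptor.json` (meshes are resolved
#'   relative to its directory).
#' @return A [msk_model()].
#' @export
read_model <- function(descriptor_path) {
  if (!file.exists(descriptor_path))
    stop(sprintf("descriptor not found: '%s'", descriptor_path), call. = FALSE)
  d <- jsonlite::read_json(descriptor_path, simplifyVector = TRUE)
  base <- dirname(descriptor_path)
  bl <- .need(d, "bones", "descriptor")
  if (is.data.frame(bl)) bl <- split(bl, seq_len(nrow(bl)))
  bones <- lapply(bl, function(b) {
    b <- as.list(b)
    msk_bone(.need(b, "name", "bones[]"),
             read_obj(file.path(base, .need(b, "mesh", sprintf("bone '%s'", b$name)))),
             .need(b, "segment", sprintf("bone '%s'", b$name)))
  })
  names(bones) <- vapply(bones, `[[`, "", "name")

  make_site <- function(s, muscle, side) {
    where <- sprintf("muscle '%s' %s", muscle, side)
    bn <- .need(s, "bone", where)
    if (!bn %in% names(bones))
      stop(sprintf("model descriptor: %s references unknown bone '%s'", where, bn),
           call. = FALSE)
    if (!is.null(s$vertex_indices)) {
      idx <- as.integer(unlist(s$vertex_indices)) + 1L  # 0-based on disk
      if (length(idx) == 0L)
        stop(sprintf("model descriptor: empty attachment patch for %s", where),
             call. = FALSE)
      nv <- nrow(bones[[bn]]$vertices)
      if (any(idx < 1L | idx > nv))
        stop(sprintf("model descriptor: vertex index out of range for %s (bone '%s' has %d vertices)",
                     where, bn, nv), call. = FALSE)
      attachment_site(bn, patch = bones[[bn]]$vertices[idx, , drop = FALSE])
    } else if (!is.null(s$centroid)) {
      attachment_site(bn, centroid = as.numeric(unlist(s$centroid)))
    } else {
      stop(sprintf("model descriptor: %s needs 'vertex_indices' or 'centroid'", where),
           call. = FALSE)
    }
  }
  ml <- .need(d, "muscles", "descriptor")
  if (is.data.frame(ml)) ml <- split(ml, seq_len(nrow(ml)))
  muscles <- lapply(ml, function(m) {
    m <- as.list(m)
    nm <- .need(m, "name", "muscles[]")
    msk_muscle(nm,
               make_site(as.list(.need(m, "origin", sprintf("muscle '%s'", nm))), nm, "origin"),
               make_site(as.list(.need(m, "insertion", sprintf("muscle '%s'", nm))), nm, "insertion"),
               isTRUE(as.logical(.need(m, "biarticular", sprintf("muscle '%s'", nm)))))
  })

  fh <- .need(d, "femoral_head", "descriptor")
  fe <- as.numeric(unlist(.need(d, "fe_axis", "descriptor")))
  ref_ax <- as.numeric(unlist(d$reference_femur_axis %||% c(0, 0, -1)))
  hip <- if (!is.null(fh$sphere)) {
    build_hip_joint(fe_axis = fe, reference_femur_axis = ref_ax,
                    sphere = list(center = as.numeric(unlist(fh$sphere$center)),
                                  radius = fh$sphere$radius))
  } else {
    bn <- .need(fh, "bone", "femoral_head")
    idx <- as.integer(unlist(.need(fh, "vertex_indices", "femoral_head"))) + 1L
    build_hip_joint(bones[[bn]]$vertices[idx, , drop = FALSE],
                    fe_axis = fe, reference_femur_axis = ref_ax)
  }
  msk_model(bones, muscles, hip,
            body_mass = .need(d, "body_mass_g", "descriptor"),
            pelvis_length = d$pelvis_length_mm,
            femur_length = d$femur_length_mm,
            model_id = d$model_id %||% "model")
}

.fmt_num <- function(x) {
  if (is.numeric(x)) sprintf("%.17g", x) else as.character(x)
}

.write_table_csv <- function(df, path, header_kv) {
  hdr <- sprintf("#momarm %s=%s", names(header_kv), vapply(header_kv, paste,
                                                           "", collapse = ","))
  body <- df
  for (j in seq_along(body)) if (is.numeric(body[[j]])) body[[j]] <- .fmt_num(body[[j]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(body, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.read_table_csv <- function(path) {
  ln <- readLines(path)
  hd <- ln[startsWith(ln, "#momarm ")]
  kv <- list()
  for (h in sub("^#momarm ", "", hd)) {
    eq <- regexpr("=", h, fixed = TRUE)
    kv[[substr(h, 1L, eq - 1L)]] <- substr(h, eq + 1L, nchar(h))
  }
  body <- ln[!startsWith(ln, "#")]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  list(df = df, header = kv)
}

#' Write / read curve tables with a provenance header
#'
#' The CSV carries `#momarm` comment lines recording the package version, a
#' hash of the sweep configuration, the fitted sphere, and the sweep settings,
#' so that the producing run can be reconstructed; numeric values are written
#' at full precision (17 significant digits) so the table round-trips
#' losslessly. Output is byte-deterministic for equal inputs.
#'
#' @param curves An `mma_curves` object from [hip_sweep()].
#' @param path CSV path.
#' @return `write_curves()`: the path, invisibly. `read_curves()`: the
#'   `mma_curves` object (sweep attributes restored from the header).
#' @export
write_curves <- function(curves, path) {
  stopifnot(inherits(curves, "mma_curves"))
  cfg <- list(sweep = attr(curves, "sweep"), clamp = attr(curves, "clamp"),
              projection = attr(curves, "projection"),
              exponent = attr(curves, "exponent"), band = attr(curves, "band"))
  kv <- list(version = .pkg_version(),
             config_hash = .config_hash(cfg),
             sweep = .fmt_num(attr(curves, "sweep")),
             clamp = attr(curves, "clamp"),
             projection = attr(curves, "projection"),
             exponent = .fmt_num(attr(curves, "exponent")),
             band = .fmt_num(attr(curves, "band")),
             body_mass = .fmt_num(attr(curves, "body_mass")),
             sphere = .fmt_num(attr(curves, "sphere")))
  .write_table_csv(as.data.frame(curves), path, kv)
}

#' @rdname write_curves
#' @export
read_curves <- function(path) {
  r <- .read_table_csv(path)
  num <- function(k) as.numeric(strsplit(r$header[[k]], ",", fixed = TRUE)[[1L]])
  sw <- num("sweep"); names(sw) <- c("start", "stop", "step")
  structure(r$df, class = c("mma_curves", "data.frame"),
            sweep = sw,
            clamp = identical(r$header$clamp, "TRUE"),
            projection = r$header$projection,
            exponent = num("exponent"), band = num("band"),
            body_mass = num("body_mass"), sphere = num("sphere"))
}

#' Write a sensitivity report as CSV
#'
#' @param report A `sensitivity_report`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_sensitivity <- function(report, path) {
  stopifnot(inherits(report, "sensitivity_report"))
  sp <- attr(report, "spec")
  kv <- list(version = .pkg_version(), kind = attr(report, "kind"),
             config_hash = .config_hash(sp))
  if (!is.null(sp$seed)) kv$seed <- sp$seed
  .write_table_csv(as.data.frame(report), path, kv)
}

#' Read a run configuration file (YAML or JSON)
#'
#' Configuration files mirror the command-line flags of the `momarm` CLI.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return Named list of settings.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: '%s'", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("config file must be YAML or JSON", call. = FALSE)
}
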