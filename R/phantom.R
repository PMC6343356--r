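## Synthetic CT phantom generator.
##
## The phantom emulates the image classes the pipeline must tell apart:
## air background, a soft-tissue body ellipse, two low-attenuation lung
## ellipsoids, an optional trachea, straight tubular vessels at controlled
## tilt angles, and spherical nodules (solid, faint GGO, juxtapleural).
## Structures are painted with a one-voxel linear partial-volume falloff and
## i.i.d. Gaussian HU noise is added last. Geometry is specified in mm
## relative to the volume centre, (x, y, z) = (col, row, slice) directions.

#' Phantom specification
#'
#' @param shape `(slices, rows, cols)` of the volume.
#' @param spacing `c(dz, dy, dx)` mm; default `c(2.5, 0.7, 0.7)` mimics
#'   thick-slice CT.
#' @param body_hu,lung_hu,air_hu attenuation of soft-tissue body, aerated
#'   lung and air (HU).
#' @param noise_sd additive Gaussian noise standard deviation (HU, `>= 0`).
#' @param body_semiaxes in-plane `(x, y)` semi-axes of the body ellipse, mm.
#' @param lung_center_x distance of each lung centre from the midline, mm.
#' @param lung_semiaxes `(x, y, z)` semi-axes of each lung ellipsoid, mm.
#' @param trachea `NULL` or `list(radius_mm, x, y, z_range)` for a vertical
#'   air tube.
#' @param vessels data.frame with columns `radius_mm`, `tilt_deg` (angle
#'   from the axial normal; 0 = vertical), `azimuth_deg`, anchor `x, y, z`
#'   (mm) and `hu`. Vessels are straight cylinders clipped to the lungs.
#' @param nodules data.frame with columns `x, y, z` (mm), `diameter_mm`,
#'   `hu` and `kind` in `solid | ggo | juxtapleural`.
#' @param edge_mm partial-volume edge width (mm); default one mean voxel.
#' @param seed integer RNG seed; equal spec + seed gives bit-identical
#'   output.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 128L, 128L),
                         spacing = c(2.5, 0.7, 0.7),
                         body_hu = 40, lung_hu = -850, air_hu = -1000,
                         noise_sd = 20,
                         body_semiaxes = c(38, 32),
                         lung_center_x = 19,
                         lung_semiaxes = c(13.5, 24, 60),
                         trachea = list(radius_mm = 4, x = 0, y = -10,
                                        z_range = c(0, 55)),
                         vessels = empty_vessels(),
                         nodules = empty_nodules(),
                         edge_mm = mean(spacing),
                         seed = 1L) {
  spec <- structure(
    list(shape = as.integer(shape), spacing = as.numeric(spacing),
         body_hu = body_hu, lung_hu = lung_hu, air_hu = air_hu,
         noise_sd = noise_sd, body_semiaxes = body_semiaxes,
         lung_center_x = lung_center_x, lung_semiaxes = lung_semiaxes,
         trachea = trachea, vessels = vessels, nodules = nodules,
         edge_mm = edge_mm, seed = as.integer(seed)),
    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %d x %d x %d, %d nodule(s), %d vessel(s), noise_sd = %g HU, seed = %d\n",
              x$shape[1], x$shape[2], x$shape[3], nrow(x$nodules),
              nrow(x$vessels), x$noise_sd, x$seed))
  invisible(x)
}

empty_vessels <- function() {
  data.frame(radius_mm = numeric(0), tilt_deg = numeric(0),
             azimuth_deg = numeric(0), x = numeric(0), y = numeric(0),
             z = numeric(0), hu = numeric(0))
}

empty_nodules <- function() {
  data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
             diameter_mm = numeric(0), hu = numeric(0),
             kind = character(0), stringsAsFactors = FALSE)
}

# squared ellipsoid norm of nodule-centre offsets for one lung
lung_norm <- function(spec, x, y, z, side) {
  cx <- side * spec$lung_center_x
  a <- spec$lung_semiaxes
  ((x - cx) / a[1])^2 + (y / a[2])^2 + (z / a[3])^2
}

nearest_lung_side <- function(x) ifelse(x < 0, -1, 1)

#' Validate a phantom specification
#'
#' Checks the stated invariants: nodule centroids inside a lung ellipsoid,
#' GGO attenuation strictly between lung and body, no overlapping nodules,
#' non-juxtapleural nodules entirely inside their lung, non-negative noise.
#'
#' @param spec a [phantom_spec].
#' @return `spec`, invisibly; errors otherwise.
#' @export
validate_phantom_spec <- function(spec) {
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(spec$shape) != 3 || any(spec$shape < 3))
    stop("shape must be (slices, rows, cols) with at least 3 slices")
  nd <- spec$nodules
  if (nrow(nd)) {
    if (!all(nd$kind %in% c("solid", "ggo", "juxtapleural")))
      stop("nodule kind must be solid, ggo or juxtapleural")
    if (any(nd$diameter_mm <= 0)) stop("nodule diameters must be > 0")
    side <- nearest_lung_side(nd$x)
    n0 <- lung_norm(spec, nd$x, nd$y, nd$z, side)
    if (any(n0 > 1))
      stop("nodule centroid(s) outside the lung ellipsoids: rows ",
           paste(which(n0 > 1), collapse = ", "))
    ggo <- nd$kind == "ggo"
    if (any(ggo & !(nd$hu > spec$lung_hu & nd$hu < spec$body_hu)))
      stop("GGO nodule hu must lie strictly between lung_hu and body_hu")
    ## whole sphere inside the lung for non-juxtapleural kinds
    ## (upper bound on the ellipsoid norm over the sphere surface)
    a <- spec$lung_semiaxes
    g <- sqrt(((nd$x - side * spec$lung_center_x) / a[1]^2)^2 +
                (nd$y / a[2]^2)^2 + (nd$z / a[3]^2)^2)
    r <- nd$diameter_mm / 2
    nmax <- n0 + 2 * r * g + (r / min(a))^2
    inside <- spec$nodules$kind == "juxtapleural" | nmax <= 1
    if (any(!inside))
      stop("nodule(s) extend outside the lung (use kind = 'juxtapleural' ",
           "for wall-attached nodules): rows ",
           paste(which(!inside), collapse = ", "))
    if (nrow(nd) > 1) {
      d <- as.matrix(dist(nd[, c("x", "y", "z")]))
      rr <- outer(r, r, "+")
      diag(d) <- Inf
      if (any(d <= rr))
        stop("overlapping nodules in spec (ground truth would be ambiguous)")
    }
  }
  vs <- spec$vessels
  if (nrow(vs) && any(vs$radius_mm <= 0)) stop("vessel radii must be > 0")
  invisible(spec)
}

## physical coordinate grids (mm, relative to volume centre)
phantom_grids <- function(spec) {
  ns <- spec$shape[1]; nr <- spec$shape[2]; nc <- spec$shape[3]
  list(x = (seq_len(nc) - (nc + 1) / 2) * spec$spacing[3],
       y = (seq_len(nr) - (nr + 1) / 2) * spec$spacing[2],
       z = (seq_len(ns) - (ns + 1) / 2) * spec$spacing[1])
}

mm_to_voxel <- function(spec, x, y, z) {
  ns <- spec$shape[1]; nr <- spec$shape[2]; nc <- spec$shape[3]
  c(slice = round(z / spec$spacing[1] + (ns + 1) / 2),
    row = round(y / spec$spacing[2] + (nr + 1) / 2),
    col = round(x / spec$spacing[3] + (nc + 1) / 2))
}

## linear partial-volume weight: 1 inside, 0 outside, ramp of width edge_mm
edge_weight <- function(signed_dist_mm, edge_mm) {
  clamp(signed_dist_mm / edge_mm + 0.5, 0, 1)
}

#' Generate a synthetic CT phantom
#'
#' Renders the phantom described by `spec` and returns the volume, the
#' ground-truth annotations (one per nodule, in the format of
#' [nodule_annotations()], with extra `kind` and `hu` columns) and the
#' ground-truth lung mask (lung-interior voxels before any structure is
#' painted).
#'
#' @param spec a [phantom_spec].
#' @return `list(volume, annotations, lung_mask, spec)` of class
#'   `ct_phantom`.
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  g <- phantom_grids(spec)
  nr <- spec$shape[2]; nc <- spec$shape[3]; ns <- spec$shape[1]
  e <- spec$edge_mm
  X <- array(rep(g$x, each = nr), dim = c(nr, nc, ns))
  Y <- array(rep(g$y, times = nc * ns), dim = c(nr, nc, ns))
  Z <- array(rep(g$z, each = nr * nc), dim = c(nr, nc, ns))

  vol <- array(as.numeric(spec$air_hu), dim = c(nr, nc, ns))

  ## signed surface distance of an ellipse/ellipsoid in mm, first order:
  ## (1 - nhat) / |grad nhat|, exact at the surface in every direction
  ell_dist <- function(nhat2, grad2, min_ax) {
    nhat <- sqrt(nhat2)
    d <- (1 - nhat) * nhat / sqrt(pmax(grad2, 1e-12))
    d[nhat2 < 1e-9] <- min_ax          # centre voxel: deep interior
    d
  }

  ## body ellipse (same on every slice)
  b <- spec$body_semiaxes
  nb2 <- (X / b[1])^2 + (Y / b[2])^2
  gb2 <- (X / b[1]^2)^2 + (Y / b[2]^2)^2
  vol <- vol + edge_weight(ell_dist(nb2, gb2, min(b)), e) *
    (spec$body_hu - vol)

  ## lungs (side masks kept: vessels are clipped to their own lung)
  a <- spec$lung_semiaxes
  side_mask <- list()
  for (side in c(-1, 1)) {
    xl <- X - side * spec$lung_center_x
    nl2 <- (xl / a[1])^2 + (Y / a[2])^2 + (Z / a[3])^2
    gl2 <- (xl / a[1]^2)^2 + (Y / a[2]^2)^2 + (Z / a[3]^2)^2
    vol <- vol + edge_weight(ell_dist(nl2, gl2, min(a)), e) *
      (spec$lung_hu - vol)
    side_mask[[as.character(side)]] <- nl2 <= 1
  }
  lung_mask <- side_mask[["-1"]] | side_mask[["1"]]

  ## trachea: vertical air tube between the lungs
  tr <- spec$trachea
  if (!is.null(tr)) {
    d <- sqrt((X - tr$x)^2 + (Y - tr$y)^2)
    w <- edge_weight(tr$radius_mm - d, e) *
      (Z >= tr$z_range[1] & Z <= tr$z_range[2])
    vol <- vol + w * (spec$air_hu - vol)
  }

  ## vessels: straight cylinders clipped to the lung interior
  vs <- spec$vessels
  for (i in seq_len(nrow(vs))) {
    th <- vs$tilt_deg[i] * pi / 180
    ph <- vs$azimuth_deg[i] * pi / 180
    dvec <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th)) # (x, y, z)
    px <- X - vs$x[i]; py <- Y - vs$y[i]; pz <- Z - vs$z[i]
    t <- px * dvec[1] + py * dvec[2] + pz * dvec[3]
    d2 <- (px - t * dvec[1])^2 + (py - t * dvec[2])^2 + (pz - t * dvec[3])^2
    clip <- side_mask[[as.character(nearest_lung_side(vs$x[i]))]]
    w <- edge_weight(vs$radius_mm[i] - sqrt(d2), e) * clip
    vol <- vol + w * (vs$hu[i] - vol)
  }

  ## nodules: spheres (juxtapleural ones may protrude into the wall)
  nd <- spec$nodules
  for (i in seq_len(nrow(nd))) {
    d <- sqrt((X - nd$x[i])^2 + (Y - nd$y[i])^2 + (Z - nd$z[i])^2)
    w <- edge_weight(nd$diameter_mm[i] / 2 - d, e)
    vol <- vol + w * (nd$hu[i] - vol)
  }

  if (spec$noise_sd > 0)
    vol <- vol + with_seed(spec$seed,
                           array(rnorm(length(vol), 0, spec$noise_sd),
                                 dim = dim(vol)))
  vol <- array(as.integer(clamp(round(vol), -1024, 3071)), dim = dim(vol))

  volume <- ct_volume(vol, spacing = spec$spacing,
                      patient_id = sprintf("phantom-seed%d", spec$seed))

  ann <- phantom_annotations(spec)
  structure(list(volume = volume, annotations = ann, lung_mask = lung_mask,
                 spec = spec),
            class = "ct_phantom")
}

## ground-truth annotation table for the spec's nodules
phantom_annotations <- function(spec) {
  nd <- spec$nodules
  if (nrow(nd) == 0) {
    ann <- cbind(data.frame(nodule_id = character(0), reader_id = character(0),
                            slice = integer(0), row = integer(0),
                            col = integer(0), diameter_mm = numeric(0)),
                 as.data.frame(sapply(names(CHARACTERISTIC_RANGES),
                                      function(x) integer(0),
                                      simplify = FALSE)),
                 data.frame(has_characteristics = logical(0),
                            is_ggo = logical(0), kind = character(0),
                            hu = numeric(0)))
    return(ann)
  }
  vox <- t(mapply(function(x, y, z) mm_to_voxel(spec, x, y, z),
                  nd$x, nd$y, nd$z))
  is_ggo <- nd$kind == "ggo"
  ann <- data.frame(
    nodule_id = sprintf("phantom-nodule-%02d", seq_len(nrow(nd))),
    reader_id = "ground-truth",
    slice = as.integer(vox[, "slice"]), row = as.integer(vox[, "row"]),
    col = as.integer(vox[, "col"]),
    diameter_mm = nd$diameter_mm,
    subtlety = ifelse(is_ggo, 3L, 5L),
    internal_structure = 1L,
    calcification = 6L,
    sphericity = 5L,
    margin = ifelse(is_ggo, 3L, 5L),
    lobulation = 1L,
    spiculation = 1L,
    texture = ifelse(is_ggo, 1L, 5L),
    malignancy = 3L,
    has_characteristics = TRUE,
    is_ggo = is_ggo,
    kind = nd$kind,
    hu = nd$hu,
    stringsAsFactors = FALSE)
  nodule_annotations(ann)
}

#' Built-in phantom presets used by the test and acceptance suites
#'
#' Three fixed, documented specs on a 64 x 128 x 128 grid with the default
#' thick-slice spacing `(2.5, 0.7, 0.7)` mm:
#' \describe{
#'   \item{easy}{10 nodules (solid, GGO at -500 HU, one juxtapleural) with
#'     diameters spanning 4-20 mm, plus two oblique vessels (30 and 45
#'     degrees).}
#'   \item{ggo-heavy}{4 faint GGO nodules at 180 HU contrast above lung
#'     background (-670 HU) plus one solid nodule and the two vessels.}
#'   \item{vessel-heavy}{vessels at 0, 30, 45 and 60 degrees tilt
#'     (radius 2.5 mm) in the left lung and three solid nodules (8, 10,
#'     12 mm) in the right lung.}
#' }
#' Nodule centres are aligned to slice centres so that sphere cross-sections
#' sample symmetrically around the central slice.
#'
#' @param difficulty `"easy"`, `"ggo-heavy"` or `"vessel-heavy"`.
#' @param noise_sd noise level in HU (default 20).
#' @param seed RNG seed for the noise field.
#' @return a [phantom_spec].
#' @export
default_test_spec <- function(difficulty = c("easy", "ggo-heavy",
                                             "vessel-heavy"),
                              noise_sd = 20, seed = 20260911L) {
  if (!is.character(difficulty) ||
      !difficulty[1] %in% c("easy", "ggo-heavy", "vessel-heavy"))
    stop("unknown difficulty label: ", difficulty[1])
  difficulty <- match.arg(difficulty)
  vessel <- function(radius_mm, tilt_deg, azimuth_deg, x, y, z, hu = 30)
    data.frame(radius_mm = radius_mm, tilt_deg = tilt_deg,
               azimuth_deg = azimuth_deg, x = x, y = y, z = z, hu = hu)
  nodule <- function(x, y, z, diameter_mm, kind, hu)
    data.frame(x = x, y = y, z = z, diameter_mm = diameter_mm, hu = hu,
               kind = kind, stringsAsFactors = FALSE)
  easy_vessels <- rbind(
    vessel(2.0, 30, 0, -19, -14, 0),
    vessel(2.0, 45, 0,  19,  15, 0))
  cfg <- switch(difficulty,
    "easy" = list(
      vessels = easy_vessels,
      nodules = rbind(
        nodule(-19,  6, -43.75,  8, "solid", 30),
        nodule(-19, -6, -21.25,  6, "ggo",  -500),
        nodule(-19,  0,   1.25, 20, "solid", 30),
        nodule(-19,  6,  26.25, 10, "ggo",  -500),
        nodule(-19, -6,  43.75,  4, "solid", 30),
        nodule( 19, -4, -43.75,  6, "solid", 30),
        nodule( 19,  6, -21.25, 10, "solid", 30),
        nodule( 19,  0,   1.25, 16, "ggo",  -500),
        nodule( 19, -6,  26.25,  8, "ggo",  -500),
        nodule( 25.5, 0, 43.75,  8, "juxtapleural", 30))),
    "ggo-heavy" = list(
      vessels = easy_vessels,
      nodules = rbind(
        nodule(-19,  6, -43.75,  8, "ggo", -670),
        nodule(-19,  0,   1.25, 12, "ggo", -670),
        nodule(-19,  6,  26.25, 10, "ggo", -670),
        nodule( 19,  6, -21.25, 10, "solid", 30),
        nodule( 19,  0,   1.25, 12, "ggo", -670))),
    "vessel-heavy" = list(
      vessels = rbind(
        vessel(2.5,  0, 0, -19, -15, 1.25),
        vessel(2.5, 30, 0, -19,  -5, 1.25),
        vessel(2.5, 45, 0, -19,   5, 1.25),
        vessel(2.5, 60, 0, -19,  15, 1.25)),
      nodules = rbind(
        nodule(19, 0, -43.75,  8, "solid", 30),
        nodule(19, 0,   1.25, 12, "solid", 30),
        nodule(19, 0,  43.75, 10, "solid", 30))))
  phantom_spec(noise_sd = noise_sd, seed = seed,
               vessels = cfg$vessels, nodules = cfg$nodules)
}

#' Voxel centres of every structure in a phantom
#'
#' Returns one row per nodule and per vessel (at its anchor point) with the
#' 1-based voxel coordinates of a representative centre, used to cut
#' structure-centred ROIs for scoring experiments.
#'
#' @param spec a [phantom_spec].
#' @return data.frame with `type`, `index`, `tilt_deg` (NA for nodules),
#'   `diameter_mm` (NA for vessels), `slice`, `row`, `col`.
#' @export
phantom_structure_centers <- function(spec) {
  out <- list()
  nd <- spec$nodules
  for (i in seq_len(nrow(nd))) {
    v <- mm_to_voxel(spec, nd$x[i], nd$y[i], nd$z[i])
    out[[length(out) + 1L]] <- data.frame(
      type = "nodule", index = i, tilt_deg = NA_real_,
      diameter_mm = nd$diameter_mm[i], kind = nd$kind[i],
      slice = v["slice"], row = v["row"], col = v["col"])
  }
  vs <- spec$vessels
  for (i in seq_len(nrow(vs))) {
    v <- mm_to_voxel(spec, vs$x[i], vs$y[i], vs$z[i])
    out[[length(out) + 1L]] <- data.frame(
      type = "vessel", index = i, tilt_deg = vs$tilt_deg[i],
      diameter_mm = NA_real_, kind = "vessel",
      slice = v["slice"], row = v["row"], col = v["col"])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Serialize / read a phantom spec as JSON
#'
#' @param spec a [phantom_spec].
#' @param path file path.
#' @return `read_phantom_spec` returns a [phantom_spec]; the writer returns
#'   `path` invisibly.
#' @export
write_phantom_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "columns")
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$vessels <- if (length(raw$vessels$radius_mm))
    as.data.frame(raw$vessels) else empty_vessels()
  raw$nodules <- if (length(raw$nodules$x))
    as.data.frame(raw$nodules) else empty_nodules()
  do.call(phantom_spec, raw)
}
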