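## Tri-slice RGB pseudo-color superposition.
##
## The three consecutive slices of a candidate ROI are windowed to 8-bit and
## assigned to the red (upper, z-1), green (centre, z) and blue (lower,
## z+1) channels. A spherical nodule produces nearly coincident channel
## foregrounds; an oblique vessel's cross-section shifts between slices and
## the channels separate. The coincidence score quantifies that, and the
## baseline scorer (coincidence x compactness) is the deterministic
## stand-in at the scorer seam where a trained model would plug in.

#' Map an HU patch to 8-bit bytes through a lung window
#'
#' Linear map of `[center - width/2, center + width/2]` onto `[0, 255]`,
#' clamped outside, rounding half-up.
#'
#' @param patch numeric matrix/array of HU values.
#' @param center_hu,width_hu window centre and width (HU); defaults are the
#'   common lung window (-600, 1500).
#' @return same shape, values in `0..255`.
#' @export
window_to_bytes <- function(patch, center_hu = -600, width_hu = 1500) {
  if (width_hu <= 0) stop("width_hu must be > 0")
  lo <- center_hu - width_hu / 2
  v <- clamp((patch - lo) / width_hu, 0, 1) * 255
  out <- floor(v + 0.5)
  if (!is.null(dim(patch))) dim(out) <- dim(patch)
  out
}

#' Compose an RGB pseudo-color image from a tri-slice ROI
#'
#' @param roi a [extract_roi_stack()] candidate (or any list with a
#'   `64 x 64 x 3` `stack`).
#' @param center_hu,width_hu HU window, see [window_to_bytes()].
#' @return object of class `rgb_composite`: `channels` (`64 x 64 x 3`,
#'   bytes), `assignment` (slice -> channel record) and `window`.
#' @export
compose_rgb <- function(roi, center_hu = -600, width_hu = 1500) {
  stack <- roi$stack
  d <- dim(stack)
  if (length(d) != 3 || d[3] != 3) stop("roi$stack must be n x n x 3")
  channels <- array(0, dim = d)
  for (i in 1:3) channels[, , i] <- window_to_bytes(stack[, , i],
                                                    center_hu, width_hu)
  structure(list(channels = channels,
                 assignment = c(R = "slice z-1", G = "slice z",
                                B = "slice z+1"),
                 window = c(center_hu = center_hu, width_hu = width_hu),
                 center = roi$center),
            class = "rgb_composite")
}

#' Channel coincidence score
#'
#' Foreground per channel = pixels strictly brighter than
#' `fg_byte_threshold`; the score is the Jaccard overlap
#' `|R n G n B| / |R u G u B|` (0 when the union is empty). Symmetric under
#' any channel permutation.
#'
#' @param composite an [rgb_composite].
#' @param fg_byte_threshold byte threshold (default 96: solid and
#'   ground-glass structures are foreground under the default lung window,
#'   aerated lung background is not).
#' @return value in `[0, 1]`.
#' @export
coincidence_score <- function(composite, fg_byte_threshold = 96) {
  ch <- composite$channels
  fg <- ch > fg_byte_threshold
  inter <- fg[, , 1] & fg[, , 2] & fg[, , 3]
  uni <- fg[, , 1] | fg[, , 2] | fg[, , 3]
  if (!any(uni)) return(0)
  sum(inter) / sum(uni)
}

## compactness (4 pi area / perimeter^2) of the TRUE region of a logical
## matrix; perimeter counted as exposed 4-neighbour pixel edges.
region_compactness <- function(m) {
  area <- sum(m)
  if (area == 0) return(0)
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  per <- sum(core & !pad[1:nr, 2:(nc + 1)]) +
    sum(core & !pad[3:(nr + 2), 2:(nc + 1)]) +
    sum(core & !pad[2:(nr + 1), 1:nc]) +
    sum(core & !pad[2:(nr + 1), 3:(nc + 2)])
  clamp(4 * pi * area / per^2, 0, 1)
}

#' Baseline sphere-likeness score
#'
#' Deterministic reference scorer built from the superposition idea, but
#' measured on the candidate's own structure rather than on the whole
#' window: the candidate region is the `R u G u B` foreground component
#' containing the patch centre pixel (where the candidate centroid sits by
#' construction - a hollow structure such as a lung-wall ring has no
#' foreground at its own centroid and scores 0). The score is
#'
#' `(|R n G n B n region| / |region|) x compactness(R n G n B n region)`
#'
#' with compactness `= 4 pi area / perimeter^2` clamped to `[0, 1]`. Other
#' structures that happen to fall inside the 64 x 64 window (lung-wall
#' transition arcs, neighbouring vessels) can therefore neither lend the
#' candidate their channel coincidence nor dilute it. A candidate with no
#' foreground at its own centre scores 0; so does one whose centre
#' foreground never coincides across the three channels.
#'
#' Spherical structures keep a compact, coincident core across the three
#' slices and score high; oblique vessels decohere across channels and
#' score near zero. Vertical vessels are the documented blind spot: their
#' cross-sections coincide like spheres.
#'
#' @param composite an [rgb_composite].
#' @param fg_byte_threshold see [coincidence_score()].
#' @return probability-like value in `[0, 1]`.
#' @export
baseline_score <- function(composite, fg_byte_threshold = 96) {
  ch <- composite$channels
  fg <- ch > fg_byte_threshold
  inter <- fg[, , 1] & fg[, , 2] & fg[, , 3]
  uni <- fg[, , 1] | fg[, , 2] | fg[, , 3]
  if (!any(inter)) return(0)
  d <- dim(inter)
  cr <- d[1] %/% 2L + 1L; cc <- d[2] %/% 2L + 1L
  ## candidate region: union-foreground component at the patch centre
  lab_u <- .cc_label_2d(uni, 8L)
  center_lab <- lab_u[cr, cc]
  if (center_lab == 0L) return(0)
  region <- matrix(lab_u == center_lab, d[1], d[2])
  core <- inter & region
  if (!any(core)) return(0)
  (sum(core) / sum(region)) * region_compactness(core)
}

## ---- scorer registry -------------------------------------------------

## A CandidateScorer maps an rgb_composite to a probability in [0, 1].
## Trained-model adapters register here by name; the pipeline looks scorers
## up by name so no pipeline code changes when one is added.
.scorer_registry <- new.env(parent = emptyenv())

#' Register a candidate scorer
#'
#' @param name scorer identity string.
#' @param fun `function(composite, ...)` returning a probability in
#'   `[0, 1]`.
#' @return `name`, invisibly.
#' @export
register_scorer <- function(name, fun) {
  stopifnot(is.character(name), is.function(fun))
  assign(name, fun, envir = .scorer_registry)
  invisible(name)
}

#' Look up a registered scorer by name
#'
#' @param name scorer identity string.
#' @return the scorer function.
#' @export
get_scorer <- function(name) {
  if (!exists(name, envir = .scorer_registry))
    stop("unknown scorer '", name, "'; registered: ",
         paste(ls(.scorer_registry), collapse = ", "))
  get(name, envir = .scorer_registry)
}

#' List registered scorer names
#' @return character vector.
#' @export
list_scorers <- function() ls(.scorer_registry)
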