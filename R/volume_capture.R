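#' Imaging Z-stack capture configuration
#'
#' Describes the axial extent imaged by a stack of focal planes. Defaults
#' model 7 planes spaced 1.5 um apart with a depth of field of 0.678 um
#' (imaging at 550 nm with a 60x / 1.4 NA oil objective). Half the depth of
#' field is added as a margin at both ends of the stack, giving one effective
#' capture slab used consistently for all cells; setting
#' `depth_of_field = 0` recovers plane-anchored boundaries.
#'
#' @param n_planes number of imaged Z planes (>= 1).
#' @param plane_spacing spacing between adjacent planes (um), > 0.
#' @param depth_of_field axial depth of field (um), >= 0.
#' @param bottom_plane_z Z coordinate of the bottom imaged plane (um).
#' @return an object of class `capture_config`.
#' @export
capture_config <- function(n_planes = 7L,
                           plane_spacing = 1.5,
                           depth_of_field = 0.678,
                           bottom_plane_z = 0) {
  if (n_planes < 1) stop("n_planes must be >= 1")
  if (plane_spacing <= 0) stop("plane_spacing must be positive")
  if (depth_of_field < 0) stop("depth_of_field must be nonnegative")
  structure(list(n_planes = as.integer(n_planes),
                 plane_spacing = plane_spacing,
                 depth_of_field = depth_of_field,
                 bottom_plane_z = bottom_plane_z),
            class = "capture_config")
}

#' Effective axial capture slab of a Z stack
#'
#' @param config a [capture_config()].
#' @return numeric vector `c(z_bot_eff, z_top_eff)`:
#'   `bottom_plane_z - 0.5 * depth_of_field` and
#'   `bottom_plane_z + (n_planes - 1) * plane_spacing + 0.5 * depth_of_field`.
#' @export
capture_bounds <- function(config) {
  stopifnot(inherits(config, "capture_config"))
  half <- 0.5 * config$depth_of_field
  top_plane <- config$bottom_plane_z +
    (config$n_planes - 1) * config$plane_spacing
  c(z_bot_eff = config$bottom_plane_z - half, z_top_eff = top_plane + half)
}

#' Spherical-cap volume fraction
#'
#' Fraction of a sphere of radius `r` contained in a cap of height `h`:
#' `h^2 * (3r - h) / (4 r^3)`. Used as the proportion of a spherical cell's
#' volume captured when the imaging slab cuts it at height `h`.
#'
#' @param r sphere radius (um), > 0.
#' @param h cap height (um), in \[0, 2r\]. Vectorized (recycled) with `r`.
#' @return fraction in \[0, 1\].
#' @export
cap_fraction <- function(r, h) {
  if (any(r <= 0)) stop("radius must be positive")
  n <- max(length(r), length(h))
  r <- rep_len(r, n)
  h <- rep_len(h, n)
  if (any(h < 0 | h > 2 * r)) stop("cap height must lie in [0, 2r]")
  h^2 * (3 * r - h) / (4 * r^3)
}

#' Classify cells by Z position and compute captured volume fraction
#'
#' Each spherical cell of radius `r` centred at `z_c` is intersected with the
#' effective capture slab of the Z stack. Cells fall into five groups:
#' 1 centre above the slab, partial (or zero) capture from above; 2 centre
#' inside, sphere crossing the top; 3 fully inside (fraction 1); 4 centre
#' inside, sphere crossing the bottom; 5 centre below the slab. A cell
#' crossing both boundaries is assigned to group 2 or 4 by its larger
#' overshoot and its fraction is `1 - cap(top) - cap(bottom)`, the unique
#' continuous extension of the per-group formulas. The captured fraction is
#' continuous in `z_c`.
#'
#' @param z_c numeric vector of cell centre Z positions (um).
#' @param r cell radii (um), recycled against `z_c`.
#' @param config a [capture_config()].
#' @return data.frame with columns `group` (integer 1..5) and
#'   `captured_fraction` (in \[0, 1\]).
#' @export
classify_and_capture <- function(z_c, r, config) {
  stopifnot(inherits(config, "capture_config"))
  if (any(r <= 0)) stop("radius must be positive")
  n <- max(length(z_c), length(r))
  z_c <- rep_len(z_c, n)
  r <- rep_len(r, n)
  b <- capture_bounds(config)
  bot <- b[["z_bot_eff"]]
  top <- b[["z_top_eff"]]

  h_top <- pmin(pmax(z_c + r - top, 0), 2 * r)   # cap height above the slab
  h_bot <- pmin(pmax(bot - (z_c - r), 0), 2 * r) # cap height below the slab
  pv <- pmin(pmax(1 - cap_fraction(r, h_top) - cap_fraction(r, h_bot), 0), 1)

  group <- integer(n)
  inside <- h_top == 0 & h_bot == 0
  group[inside] <- 3L
  above_center <- z_c > top
  below_center <- z_c < bot
  group[above_center] <- 1L
  group[below_center] <- 5L
  rest <- which(group == 0L)
  # centre inside the slab but sphere crossing one or both boundaries
  group[rest] <- ifelse(h_top[rest] >= h_bot[rest], 2L, 4L)

  data.frame(group = group, captured_fraction = pv)
}

#' Thin a count matrix by per-cell captured volume fractions
#'
#' @param counts genes x cells count matrix.
#' @param fractions per-cell capture fractions in \[0, 1\]; either unnamed in
#'   column order or named by cell id.
#' @param mode `"scale"` multiplies each cell's profile by its fraction
#'   (deterministic, fractional values allowed); `"binomial"` draws a seeded
#'   binomial thinning with probability equal to the fraction (integer
#'   output; requires integer counts).
#' @param seed integer seed (binomial mode only).
#' @return the thinned genes x cells matrix.
#' @export
apply_capture <- function(counts, fractions, mode = c("scale", "binomial"),
                          seed = 1L) {
  counts <- as_count_matrix(counts)
  mode <- match.arg(mode)
  if (!is.null(names(fractions))) {
    fractions <- fractions[colnames(counts)]
  }
  if (length(fractions) != ncol(counts)) {
    stop("need one capture fraction per cell")
  }
  if (any(is.na(fractions)) || any(fractions < 0 | fractions > 1)) {
    stop("capture fractions must lie in [0, 1]")
  }
  if (mode == "scale") {
    out <- sweep(counts, 2, fractions, `*`)
  } else {
    if (any(counts != round(counts))) {
      stop("binomial thinning requires integer counts")
    }
    out <- with_seed(derive_seed(seed, "capture_thinning"), {
      p <- matrix(rep(fractions, each = nrow(counts)), nrow = nrow(counts))
      matrix(stats::rbinom(length(counts), size = as.integer(counts), prob = p),
             nrow = nrow(counts), dimnames = dimnames(counts))
    })
  }
  out
}
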