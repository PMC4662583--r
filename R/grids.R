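# Regular shielding hypersurfaces over periodic dihedral axes and over
# hydrogen-bond (r, theta, rho) coordinates, with two interpolation modes:
#
#   * "cubic"   -- separable Catmull-Rom cubic convolution, exact on nodes,
#                  C1-continuous, wrapped across the +/-180 seam on periodic
#                  axes and edge-clamped on bounded axes;
#   * "nearest" -- value at the nearest node under periodic distance for
#                  dihedral axes (ties break toward the smaller node
#                  coordinate).
#
# Periodic axes cover [-180, 180) exactly: 360/spacing nodes, no duplicated
# seam node.

#' Describe one grid axis
#'
#' @param name axis name, one of `phi`, `psi`, `chi1`..`chi4`, `r`, `theta`,
#'   `rho`.
#' @param min coordinate of the first node.
#' @param spacing node spacing (degrees or Angstrom).
#' @param n number of nodes.
#' @param periodic logical; periodic axes must cover `[-180, 180)` exactly.
#' @return an object of class `grid_axis`.
#' @export
grid_axis <- function(name, min, spacing, n, periodic = FALSE) {
  stopifnot(is.character(name), length(name) == 1L,
            is.finite(min), is.finite(spacing), spacing > 0, n >= 2)
  n <- as.integer(n)
  if (periodic) {
    if (abs(min + 180) > 1e-9 || abs(spacing * n - 360) > 1e-9)
      stop(sprintf(
        "periodic axis '%s' must cover [-180, 180) exactly: %d nodes at %g spacing spans %g, expected 360 (seam node must not be duplicated)",
        name, n, spacing, spacing * n))
  }
  structure(list(name = name, min = min, spacing = spacing, n = n,
                 periodic = isTRUE(periodic)),
            class = "grid_axis")
}

axis_nodes <- function(ax) ax$min + (seq_len(ax$n) - 1L) * ax$spacing

axis_max <- function(ax) ax$min + (ax$n - 1L) * ax$spacing

#' Construct a shielding grid
#'
#' @param axes list of [grid_axis()] descriptors, slowest-varying first.
#' @param values numeric vector or array of shielding values (ppm); length
#'   must equal the product of axis lengths.  Vectors are taken in C order
#'   (last axis fastest), matching the on-disk bundle layout.
#' @param interp `"cubic"` or `"nearest"`.
#' @param res_type,role,atom optional identity metadata (`role` is one of
#'   `center`, `effect_on_next`, `effect_on_prev`, or an H-bond term id).
#' @param spec optional closed-form surface specification (see
#'   [surface_spec()]); kept so synthetic surfaces stay re-evaluable as
#'   oracles.
#' @return an object of class `shielding_grid`.
#' @export
shielding_grid <- function(axes, values, interp = c("cubic", "nearest"),
                           res_type = NA_character_, role = NA_character_,
                           atom = NA_character_, spec = NULL) {
  interp <- match.arg(interp)
  stopifnot(is.list(axes), length(axes) >= 1L)
  dims <- vapply(axes, function(a) a$n, integer(1))
  if (is.array(values)) {
    if (!identical(dim(values), dims))
      stop("value array dimensions do not match axis lengths")
    arr <- values
  } else {
    if (length(values) != prod(dims))
      stop(sprintf("value count %d does not equal product of axis lengths %d",
                   length(values), prod(dims)))
    # incoming vector is C-order (last axis fastest); R arrays are
    # column-major, so fill reversed then permute
    arr <- aperm(array(values, dim = rev(dims)), rev(seq_along(dims)))
    if (length(dims) == 1L) arr <- array(values, dim = dims)
  }
  if (!all(is.finite(arr))) stop("grid values must be finite")
  structure(list(axes = axes, values = arr, interp = interp,
                 res_type = res_type, role = role, atom = atom, spec = spec),
            class = "shielding_grid")
}

grid_values_c_order <- function(grid) {
  d <- length(grid$axes)
  if (d == 1L) return(as.numeric(grid$values))
  as.numeric(aperm(grid$values, rev(seq_len(d))))
}

# Catmull-Rom kernel weights for fractional position u in [0, 1)
catmull_rom_weights <- function(u) {
  u2 <- u * u
  u3 <- u2 * u
  c(-0.5 * u3 + u2 - 0.5 * u,
    1.5 * u3 - 2.5 * u2 + 1,
    -1.5 * u3 + 2 * u2 + 0.5 * u,
    0.5 * u3 - 0.5 * u2)
}

# per-axis cubic support: 4 node indices (1-based) and weights
axis_cubic_support <- function(ax, x) {
  if (ax$periodic) {
    t <- (wrap_angle(x) - ax$min) / ax$spacing
    j <- floor(t)
    u <- t - j
    idx <- (as.integer(j) + (-1L:2L)) %% ax$n + 1L
  } else {
    xmin <- ax$min
    xmax <- axis_max(ax)
    x <- min(max(x, xmin), xmax)          # clamp into the scanned range
    t <- (x - xmin) / ax$spacing
    j <- floor(t)
    if (j >= ax$n - 1L) { j <- ax$n - 2L }  # exact upper edge
    u <- t - j
    idx <- pmin(pmax(as.integer(j) + (-1L:2L), 0L), ax$n - 1L) + 1L
  }
  list(idx = idx, w = catmull_rom_weights(u))
}

axis_nearest_index <- function(ax, x) {
  nodes <- axis_nodes(ax)
  d <- if (ax$periodic) abs(wrap_angle(x - nodes)) else abs(x - nodes)
  # which.min returns the first (= smallest node coordinate) on exact ties;
  # guard against floating noise by snapping near-ties to the first minimum
  dmin <- min(d)
  which(d <= dmin + 1e-9)[1L]
}

#' Nearest grid node for a query point
#'
#' Per-axis nearest node under periodic distance for dihedral axes; exact
#' midpoints break toward the smaller node coordinate.
#'
#' @param grid a [shielding_grid()].
#' @param coords numeric vector, one value per axis.
#' @return integer vector of 1-based node indices, one per axis.
#' @export
nearest_node <- function(grid, coords) {
  check_coords(grid, coords)
  vapply(seq_along(grid$axes),
         function(k) axis_nearest_index(grid$axes[[k]], coords[k]),
         integer(1))
}

check_coords <- function(grid, coords) {
  if (length(coords) != length(grid$axes))
    stop(sprintf("coordinate count %d does not match axis count %d",
                 length(coords), length(grid$axes)))
  if (anyNA(coords) || !all(is.finite(coords))) {
    bad <- grid$axes[[which(!is.finite(coords))[1L]]]$name
    stop(sprintf("coordinate absent for axis '%s': caller must supply it or use a reduced grid", bad))
  }
  invisible(TRUE)
}

#' Interpolate a shielding grid at arbitrary coordinates
#'
#' Dispatches on the grid's declared mode: `cubic` uses separable
#' Catmull-Rom convolution (periodic axes wrap across the seam, bounded axes
#' clamp to the scanned range); `nearest` returns the value at the nearest
#' node.  Both modes reproduce node values exactly.
#'
#' @inheritParams nearest_node
#' @return interpolated shielding in ppm.
#' @export
interpolate_grid <- function(grid, coords) {
  check_coords(grid, coords)
  if (grid$interp == "nearest") {
    idx <- nearest_node(grid, coords)
    return(grid$values[matrix(idx, nrow = 1L)])
  }
  d <- length(grid$axes)
  sup <- lapply(seq_len(d), function(k)
    axis_cubic_support(grid$axes[[k]], coords[k]))
  # tensor-product contraction, one axis at a time
  idx_list <- lapply(sup, `[[`, "idx")
  sub <- do.call(`[`, c(list(grid$values), idx_list, list(drop = FALSE)))
  val <- sub
  for (k in d:1) {
    val <- apply_weights_axis(val, sup[[k]]$w, k)
  }
  as.numeric(val)
}

apply_weights_axis <- function(arr, w, k) {
  d <- length(dim(arr))
  if (d == 1L || is.null(dim(arr))) return(sum(arr * w))
  perm <- c(k, setdiff(seq_len(d), k))
  m <- aperm(arr, perm)
  dm <- dim(m)
  m <- matrix(m, nrow = dm[1L])
  out <- colSums(m * w)
  if (length(dm) > 2L) dim(out) <- dm[-1L]
  out
}
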