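# On-disk grid bundle: a directory holding manifest.json plus one raw
# little-endian float64 file per grid (C order, axes in manifest order).
# The original DFT-derived table store is ecosystem-specific and ~17 GB;
# this manifest+raw layout is portable, lazily loadable and bit-exact.

GRID_ROLES <- c("center", "effect_on_next", "effect_on_prev")
HB_TERMS <- c("HB1", "HB2", "HaB1", "HaB2")
ATOM_TYPES <- c("CA", "CB", "C", "HA", "HN", "N")
ACCEPTOR_CLASSES <- c("amide_carbonyl", "carboxyl", "hydroxyl")
SECONDARY_DONOR_KINDS <- c("amide_H", "amine_H", "alpha_H")

#' Identifier of a grid within a library
#'
#' Backbone grids are keyed `res_type.role.atom`; hydrogen-bond correction
#' surfaces are keyed `term.class_or_kind.atom`.
#' @param res_type residue type (backbone grids) or term id (H-bond grids).
#' @param role grid role or acceptor class / donor kind.
#' @param atom atom type.
#' @export
grid_id <- function(res_type, role, atom) paste(res_type, role, atom, sep = ".")

new_grid_library <- function(grids, sigma_ref, phi_std = -120, psi_std = 140,
                             delta_w = 2.07, delta_w_sign = -1,
                             rho_sign_convention = "right_hand",
                             meta = list()) {
  structure(list(grids = grids, sigma_ref = sigma_ref,
                 phi_std = phi_std, psi_std = psi_std,
                 delta_w = delta_w, delta_w_sign = delta_w_sign,
                 rho_sign_convention = rho_sign_convention,
                 meta = meta),
            class = "grid_library")
}

#' @export
print.grid_library <- function(x, ...) {
  cat(sprintf("<grid_library> %d grids, phi_std=%g psi_std=%g, delta_w=%g (sign %+d)\n",
              length(x$grids), x$phi_std, x$psi_std, x$delta_w, x$delta_w_sign))
  invisible(x)
}

lib_get_grid <- function(lib, id, required = TRUE) {
  g <- lib$grids[[id]]
  if (is.null(g) && required)
    stop(sprintf("grid library has no surface '%s'", id))
  g
}

axis_to_manifest <- function(ax) {
  list(name = ax$name, min = ax$min, spacing = ax$spacing, n = ax$n,
       periodic = ax$periodic)
}

axis_from_manifest <- function(m) {
  grid_axis(m$name, m$min, m$spacing, m$n, isTRUE(m$periodic))
}

write_f64 <- function(values, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(values), con, size = 8L, endian = "little")
  invisible(path)
}

read_f64 <- function(path, n) {
  info <- file.info(path)
  if (is.na(info$size) || info$size != 8L * n)
    stop(sprintf("corrupt bundle: '%s' holds %s bytes, expected %d",
                 basename(path), ifelse(is.na(info$size), "no", info$size),
                 8L * n))
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "double", n = n, size = 8L, endian = "little")
}

#' Save a grid library as a bundle directory
#'
#' Writes `manifest.json` (schema, axis descriptors, reference constants,
#' rho sign convention, md5 checksums) plus one raw little-endian float64
#' array file per grid.  Save -> load -> save round-trips byte-identically.
#'
#' @param lib a `grid_library`.
#' @param path bundle directory (created if missing).
#' @return `path`, invisibly.
#' @export
save_library <- function(lib, path) {
  stopifnot(inherits(lib, "grid_library"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  entries <- vector("list", length(lib$grids))
  ids <- names(lib$grids)
  for (k in seq_along(lib$grids)) {
    g <- lib$grids[[k]]
    fname <- paste0(gsub("[^A-Za-z0-9_.-]", "_", ids[k]), ".f64")
    write_f64(grid_values_c_order(g), file.path(path, fname))
    entries[[k]] <- list(
      id = ids[k], res_type = g$res_type, role = g$role, atom = g$atom,
      interp = g$interp,
      axes = lapply(g$axes, axis_to_manifest),
      file = fname,
      n_values = length(g$values),
      md5 = unname(tools::md5sum(file.path(path, fname))),
      surface_spec = if (!is.null(g$spec)) unclass(g$spec))
  }
  manifest <- list(
    schema_version = 1L,
    format = "shiftgrid-bundle",
    byte_order = "little",
    array_order = "C",
    rho_sign_convention = lib$rho_sign_convention,
    hydroxyl_rho_reference = "hydroxyl_hydrogen",
    phi_std = lib$phi_std, psi_std = lib$psi_std,
    delta_w = lib$delta_w, delta_w_sign = lib$delta_w_sign,
    sigma_ref = lib$sigma_ref,
    meta = lib$meta,
    grids = entries)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Load a grid bundle
#'
#' Validates array sizes and md5 checksums, reconstructs every grid, and
#' runs the internal-consistency check: when Ala neighbour-effect grids are
#' present, their interpolated value at (phi_std, psi_std) must reproduce
#' the stored sigma-reference constants to 1e-9.
#'
#' @param path bundle directory written by [save_library()] or
#'   [make_library()].
#' @return a `grid_library`.
#' @export
load_library <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop(sprintf("not a grid bundle: missing %s", mf))
  manifest <- jsonlite::read_json(mf, simplifyVector = FALSE)
  if (is.null(manifest$sigma_ref))
    stop("corrupt bundle: manifest lacks sigma_ref reference constants")
  grids <- list()
  for (e in manifest$grids) {
    axes <- lapply(e$axes, axis_from_manifest)
    n_expect <- prod(vapply(axes, function(a) a$n, integer(1)))
    if (!is.null(e$n_values) && e$n_values != n_expect)
      stop(sprintf("corrupt bundle: grid '%s' declares %d values, axes give %d",
                   e$id, e$n_values, n_expect))
    f <- file.path(path, e$file)
    vals <- read_f64(f, n_expect)
    if (!is.null(e$md5)) {
      got <- unname(tools::md5sum(f))
      if (!identical(got, e$md5))
        stop(sprintf("corrupt bundle: checksum mismatch for '%s'", e$file))
    }
    spec <- e$surface_spec
    g <- shielding_grid(axes, vals, interp = e$interp,
                        res_type = e$res_type %||% NA_character_,
                        role = e$role %||% NA_character_,
                        atom = e$atom %||% NA_character_,
                        spec = spec)
    grids[[e$id]] <- g
  }
  sigma_ref <- lapply(manifest$sigma_ref, function(side)
    lapply(side, as.numeric))
  lib <- new_grid_library(
    grids, sigma_ref,
    phi_std = as.numeric(manifest$phi_std %||% -120),
    psi_std = as.numeric(manifest$psi_std %||% 140),
    delta_w = as.numeric(manifest$delta_w %||% 2.07),
    delta_w_sign = as.numeric(manifest$delta_w_sign %||% -1),
    rho_sign_convention = manifest$rho_sign_convention %||% "right_hand",
    meta = manifest$meta %||% list())
  if (!identical(lib$rho_sign_convention, "right_hand"))
    lib <- convert_rho_convention(lib)
  check_sigma_ref_consistency(lib)
  lib
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Bundles may declare the opposite (left-hand) sign convention for the
# hydrogen-bond dihedral rho; convert on load by resampling each H-bond
# surface at negated rho nodes.
convert_rho_convention <- function(lib) {
  for (id in names(lib$grids)) {
    g <- lib$grids[[id]]
    k <- which(vapply(g$axes, function(a) a$name == "rho", logical(1)))
    if (length(k) != 1L) next
    ax <- g$axes[[k]]
    nodes <- axis_nodes(ax)
    # node at coordinate x takes the value the source stored at -x
    src <- vapply(wrap_angle(-nodes), function(x) axis_nearest_index(ax, x),
                  integer(1))
    idx <- rep(list(quote(expr = )), length(g$axes))
    perm_idx <- as.list(idx)
    perm_idx[[k]] <- src
    g$values <- do.call(`[`, c(list(g$values), perm_idx, list(drop = FALSE)))
    lib$grids[[id]] <- g
  }
  lib$rho_sign_convention <- "right_hand"
  lib
}

check_sigma_ref_consistency <- function(lib, tol = 1e-9) {
  for (side in c("effect_on_next", "effect_on_prev")) {
    ref <- lib$sigma_ref[[side]]
    if (is.null(ref)) next
    for (atom in names(ref)) {
      g <- lib$grids[[grid_id("ALA", side, atom)]]
      if (is.null(g)) next
      got <- interpolate_grid(g, c(lib$phi_std, lib$psi_std))
      if (abs(got - ref[[atom]]) > tol)
        warning(sprintf(
          "sigma_ref inconsistency: %s/%s grid gives %.12g at (phi_std, psi_std), manifest stores %.12g",
          side, atom, got, ref[[atom]]))
    }
  }
  invisible(TRUE)
}

#' Write a grid as a plain-text node table
#'
#' Exchange format for hand-written test grids: one row per node, axis
#' coordinates followed by the value, tab-separated.
#' @param grid a [shielding_grid()].
#' @param path output TSV path.
#' @export
grid_to_tsv <- function(grid, path) {
  nodes <- lapply(grid$axes, axis_nodes)
  names(nodes) <- vapply(grid$axes, `[[`, "", "name")
  co <- expand.grid(rev(nodes), KEEP.OUT.ATTRS = FALSE)
  co <- co[, rev(seq_along(nodes)), drop = FALSE]
  co$value <- grid_values_c_order(grid)
  utils::write.table(co, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plain-text node table as a grid
#'
#' Inverse of [grid_to_tsv()]: infers each axis from the distinct sorted
#' coordinates (spacing must be uniform); axes named `phi`, `psi`, `chi*`
#' or `rho` are treated as periodic.
#' @param path TSV with axis coordinate columns plus a `value` column.
#' @param interp interpolation mode for the resulting grid.
#' @export
grid_from_tsv <- function(path, interp = "cubic") {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  axnames <- setdiff(names(df), "value")
  axes <- lapply(axnames, function(nm) {
    u <- sort(unique(df[[nm]]))
    sp <- diff(u)
    if (length(sp) && max(abs(sp - sp[1L])) > 1e-9)
      stop(sprintf("axis '%s' is not uniformly spaced", nm))
    periodic <- nm %in% c("phi", "psi", "rho", paste0("chi", 1:4))
    grid_axis(nm, u[1L], if (length(sp)) sp[1L] else 1, length(u), periodic)
  })
  key <- do.call(order, df[axnames])
  df <- df[key, , drop = FALSE]
  dims <- vapply(axes, function(a) a$n, integer(1))
  # order() sorted with the first column slowest -> already C order reversed;
  # build column-major array directly: first axis fastest after this sort is
  # the LAST name, so fill reversed and permute
  arr <- aperm(array(df$value, dim = rev(dims)), rev(seq_along(dims)))
  if (length(dims) == 1L) arr <- array(df$value, dim = dims)
  shielding_grid(axes, arr, interp = interp)
}
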