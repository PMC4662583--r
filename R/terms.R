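# Evaluation of the individual contributions to the additive shielding sum
#
#   sigma = sigma_BB + d_BB(prev) + d_BB(next) + d_HB + d_HaB + d_RC + d_w
#
# Each function returns a plain numeric ppm value (or NULL when the
# quantity is structurally undefined for the residue, e.g. terminal
# residues without phi/psi).  Absent partners contribute exactly 0: the
# sum is a set of corrections to the tripeptide baseline, not a mean-field
# model.

#' Backbone (tripeptide) shielding term
#'
#' Interpolates the central-residue grid for `(res_type, atom)` at the
#' residue's `(phi, psi, chi...)`.  Returns `NULL` when phi or psi is
#' undefined (chain termini): no prediction is made for such atoms.
#'
#' @param lib a `grid_library`.
#' @param res_type residue type.
#' @param tors torsion list from [torsions()].
#' @param atom atom type (`CA`, `CB`, `C`, `HA`, `HN`, `N`).
#' @param strict if `TRUE` (default) a chi angle required by the grid but
#'   absent from the structure is an error; if `FALSE` missing chi values
#'   fall back to -60 degrees (the most common rotamer).
#' @return shielding in ppm, or `NULL`.
#' @export
backbone_term <- function(lib, res_type, tors, atom, strict = TRUE) {
  if (is.na(tors$phi) || is.na(tors$psi)) return(NULL)
  g <- lib_get_grid(lib, grid_id(res_type, "center", atom))
  n_chi_axes <- length(g$axes) - 2L
  chi <- tors$chi
  if (length(chi) < n_chi_axes) {
    if (strict)
      stop(sprintf("residue type %s: grid needs %d chi angles, structure provides %d (strict mode)",
                   res_type, n_chi_axes, length(chi)))
    chi <- c(chi, rep(-60, n_chi_axes - length(chi)))
  }
  interpolate_grid(g, c(tors$phi, tors$psi, chi[seq_len(n_chi_axes)]))
}

#' Neighbour side-chain correction term
#'
#' Effect of the side chain of the previous/next residue on the atom's
#' shielding: the neighbour's effect grid evaluated at the *neighbour's*
#' torsions, minus the alanine reference constant sigma^A taken at
#' (phi_std, psi_std) = (-120, 140).  A neighbour that is alanine sitting
#' exactly at the standard angles therefore contributes 0 by construction.
#' A missing neighbour (terminus, chain break) or one without phi/psi
#' contributes exactly 0 (provenance "absent").
#'
#' @param lib a `grid_library`.
#' @param side `"prev"` or `"next"` (which neighbour of the predicted
#'   residue).
#' @param neighbor_res_type neighbour residue type.
#' @param neighbor_tors neighbour's torsion list, or `NULL` when absent.
#' @param atom atom type of the predicted residue.
#' @inheritParams backbone_term
#' @return shielding correction in ppm (0 when the neighbour is absent).
#' @export
neighbor_term <- function(lib, side = c("prev", "next"), neighbor_res_type,
                          neighbor_tors, atom, strict = TRUE) {
  side <- match.arg(side)
  if (is.null(neighbor_tors) || is.na(neighbor_tors$phi) ||
      is.na(neighbor_tors$psi)) return(0)
  role <- if (side == "prev") "effect_on_next" else "effect_on_prev"
  g <- lib_get_grid(lib, grid_id(neighbor_res_type, role, atom))
  ref <- lib$sigma_ref[[role]][[atom]]
  if (is.null(ref)) stop(sprintf("library lacks sigma_ref for %s/%s", role, atom))
  n_chi_axes <- length(g$axes) - 2L
  chi <- neighbor_tors$chi
  if (length(chi) < n_chi_axes) {
    if (strict)
      stop(sprintf("neighbour %s: grid needs %d chi angles, structure provides %d (strict mode)",
                   neighbor_res_type, n_chi_axes, length(chi)))
    chi <- c(chi, rep(-60, n_chi_axes - length(chi)))
  }
  interpolate_grid(g, c(neighbor_tors$phi, neighbor_tors$psi,
                        chi[seq_len(n_chi_axes)])) - ref
}

#' Hydrogen-bond correction term
#'
#' Looks up the correction surface matching the term and the geometry's
#' acceptor class (primary terms) or donor kind (secondary terms) at
#' `(r, theta, rho)`.  A `NULL` geometry (no hydrogen bond) contributes
#' exactly 0, as does a distance beyond the surface maximum (defensive:
#' the geometry search already enforces the scan window).  The structural
#' models behind the amide hydrogen-bond scans contain no C-beta atom, so
#' requesting `HB1`/`HB2` for `CB` is a contract error.
#'
#' @param lib a `grid_library`.
#' @param term_id one of `HB1`, `HB2`, `HaB1`, `HaB2`.
#' @param geom geometry list from [find_primary_hbond()] /
#'   [find_secondary_hbonds()], or `NULL`.
#' @param atom atom type.
#' @return shielding correction in ppm.
#' @export
hbond_term <- function(lib, term_id, geom, atom) {
  stopifnot(term_id %in% HB_TERMS)
  if (atom == "CB" && term_id %in% c("HB1", "HB2"))
    stop("the amide hydrogen-bond model systems contain no C-beta atom: no HB surface exists for CB")
  if (is.null(geom)) return(0)
  expected_frame <- if (term_id %in% c("HB1", "HaB1")) "donor_centered" else
    "acceptor_centered"
  if (!identical(geom$frame, expected_frame))
    stop(sprintf("geometry frame '%s' does not match term %s (expected %s)",
                 geom$frame, term_id, expected_frame))
  key2 <- if (expected_frame == "donor_centered") geom$acceptor_class else
    geom$donor_kind
  g <- lib$grids[[grid_id(term_id, key2, atom)]]
  if (is.null(g))
    stop(sprintf("no hydrogen-bond surface configured for %s/%s/%s",
                 term_id, key2, atom))
  rax <- g$axes[[1L]]
  if (geom$r > axis_max(rax)) return(0)
  interpolate_grid(g, c(max(geom$r, rax$min), geom$theta, geom$rho))
}

#' Water hydrogen-bond term for solvent-exposed amide protons
#'
#' Amide protons without a protein hydrogen-bond partner receive the water
#' correction constant (default magnitude 2.07 ppm, applied as a decrease
#' in shielding); bonded ones receive exactly 0.  Only defined for `HN`.
#'
#' @param has_partner logical; does the amide proton have a primary
#'   hydrogen-bond partner within the protein?
#' @param lib a `grid_library` (carries `delta_w` and its sign).
#' @param atom must be `"HN"`.
#' @return ppm.
#' @export
water_term <- function(has_partner, lib, atom = "HN") {
  if (!identical(atom, "HN"))
    stop("the water term is defined for amide protons (HN) only")
  if (isTRUE(has_partner)) return(0)
  lib$delta_w_sign * lib$delta_w
}
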