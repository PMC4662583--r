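# Torsion extraction, hydrogen-bond descriptor search and aromatic
# ring-current geometry.
#
# Hydrogen-bond frames follow the parameterisation scans:
#   primary (donor-centred):   r  = H..O distance, theta = angle at the
#     acceptor oxygen along O=C (sp2) or O-C (hydroxyl), rho = dihedral
#     H..O=C-N (backbone / side-chain amide), H..O=C-C (carboxyl) or
#     H..O-C-H^O (hydroxyl, measured to the hydroxyl hydrogen);
#   secondary (acceptor-centred): the same three coordinates for each
#     donor hydrogen bonded to the residue's own carbonyl oxygen.

# chi1..chi4 defining atom quadruples, standard rotamer conventions
CHI_ATOMS <- list(
  ARG = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","NE"), c("CG","CD","NE","CZ")),
  ASN = list(c("N","CA","CB","CG"), c("CA","CB","CG","OD1")),
  ASP = list(c("N","CA","CB","CG"), c("CA","CB","CG","OD1")),
  CYS = list(c("N","CA","CB","SG")),
  GLN = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","OE1")),
  GLU = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","OE1")),
  HIS = list(c("N","CA","CB","CG"), c("CA","CB","CG","ND1")),
  ILE = list(c("N","CA","CB","CG1"), c("CA","CB","CG1","CD1")),
  LEU = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  LYS = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","CE"), c("CG","CD","CE","NZ")),
  MET = list(c("N","CA","CB","CG"), c("CA","CB","CG","SD"),
             c("CB","CG","SD","CE")),
  PHE = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  PRO = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD")),
  SER = list(c("N","CA","CB","OG")),
  THR = list(c("N","CA","CB","OG1")),
  TRP = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  TYR = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  VAL = list(c("N","CA","CB","CG1")),
  ALA = list(), GLY = list())

#' Number of side-chain torsion angles of a residue type
#' @param res_type three-letter residue code.
#' @export
n_chi <- function(res_type) {
  if (!res_type %in% AA3) stop(sprintf("unknown residue type '%s'", res_type))
  length(CHI_ATOMS[[res_type]])
}

#' Backbone and side-chain torsions of one residue
#'
#' phi = C(i-1)-N-CA-C, psi = N-CA-C-N(i+1), omega = CA(i-1)-C(i-1)-N-CA;
#' chi per the standard rotamer definitions.  Angles undefined at termini
#' or because of missing atoms are `NA`, never 0; a missing side-chain atom
#' truncates chi at the first undefined torsion with a warning.
#'
#' @param model a `protein_model`.
#' @param i residue index (position in the residue list).
#' @return list with elements `phi`, `psi`, `omega` (degrees or `NA`) and
#'   `chi` (numeric vector, possibly empty).
#' @export
torsions <- function(model, i) {
  res <- model$residues
  r <- res[[i]]
  p <- function(res_i, nm) get_atom(res[[res_i]], nm)
  phi <- psi <- omega <- NA_real_
  n <- p(i, "N"); ca <- p(i, "CA"); cc <- p(i, "C")
  if (!is.na(r$prev)) {
    cp <- p(r$prev, "C"); cap <- p(r$prev, "CA")
    if (!is.null(cp) && !is.null(n) && !is.null(ca) && !is.null(cc))
      phi <- dihedral(cp, n, ca, cc)
    if (!is.null(cap) && !is.null(cp) && !is.null(n) && !is.null(ca))
      omega <- dihedral(cap, cp, n, ca)
  }
  if (!is.na(r$next_)) {
    nn <- p(r$next_, "N")
    if (!is.null(n) && !is.null(ca) && !is.null(cc) && !is.null(nn))
      psi <- dihedral(n, ca, cc, nn)
  }
  chi <- numeric(0)
  defs <- CHI_ATOMS[[r$res_type]]
  for (k in seq_along(defs)) {
    pts <- lapply(defs[[k]], function(nm) get_atom(r, nm))
    if (any(vapply(pts, is.null, logical(1)))) {
      if (k <= n_chi(r$res_type))
        warning(sprintf("residue %d (%s): chi%d undefined (missing atom); chi truncated",
                        r$seq_index, r$res_type, k))
      break
    }
    chi <- c(chi, dihedral(pts[[1L]], pts[[2L]], pts[[3L]], pts[[4L]]))
  }
  list(phi = phi, psi = psi, omega = omega, chi = chi)
}

#' Default hydrogen-bond search and ring-current parameters
#'
#' Distance windows reproduce the parameterisation scan ranges (amide
#' donors 1.5-3.0 A, alpha donors 1.8-4.0 A; distances below the scanned
#' minimum clamp to the boundary).  The ring-current intensity factors
#' (relative to benzene) and the dipole constant B are configuration values
#' with literature-typical magnitudes; the source tables cite them from
#' external work without printing numbers, so they are data, not formula
#' constants.
#'
#' @return a named list (`amide_r_min/max`, `halpha_r_min/max`, `theta_min`,
#'   `ring_cutoff` (A), `ring_B` (ppm A^3), `ring_intensities`,
#'   `secondary_mode` = `"nearest"` or `"sum"`).
#' @export
default_search_config <- function() {
  list(amide_r_min = 1.5, amide_r_max = 3.0,
       halpha_r_min = 1.8, halpha_r_max = 4.0,
       theta_min = 90, ring_cutoff = 8.0,
       ring_B = 30.42,
       ring_intensities = c(PHE = 1.00, TYR = 0.84, HIS = 0.90,
                            TRP5 = 1.04, TRP6 = 1.02),
       secondary_mode = "nearest")
}

# acceptor oxygens of one residue: list of (name, class, anchor C, rho ref)
SIDECHAIN_ACCEPTORS <- list(
  ASP = list(list(o = "OD1", cls = "carboxyl", c = "CG", ref = "CB"),
             list(o = "OD2", cls = "carboxyl", c = "CG", ref = "CB")),
  GLU = list(list(o = "OE1", cls = "carboxyl", c = "CD", ref = "CG"),
             list(o = "OE2", cls = "carboxyl", c = "CD", ref = "CG")),
  ASN = list(list(o = "OD1", cls = "amide_carbonyl", c = "CG", ref = "ND2")),
  GLN = list(list(o = "OE1", cls = "amide_carbonyl", c = "CD", ref = "NE2")),
  SER = list(list(o = "OG",  cls = "hydroxyl", c = "CB", ref = "HG")),
  THR = list(list(o = "OG1", cls = "hydroxyl", c = "CB", ref = "HG1")),
  TYR = list(list(o = "OH",  cls = "hydroxyl", c = "CZ", ref = "HH")))

# side-chain N-H (amine / side-chain amide) donor hydrogens
AMINE_DONORS <- list(
  LYS = c("HZ1", "HZ2", "HZ3"),
  ARG = c("HE", "HH11", "HH12", "HH21", "HH22"),
  ASN = c("HD21", "HD22"),
  GLN = c("HE21", "HE22"),
  TRP = c("HE1"),
  HIS = c("HD1", "HE2"))

# geometry of one H against one acceptor oxygen; NULL when rho undefined
hb_geometry <- function(hpos, opos, cpos, refpos) {
  r <- vnorm(opos - hpos)
  theta <- angle_at(hpos, opos, cpos)
  rho <- if (is.null(refpos)) 0 else
    tryCatch(dihedral(hpos, opos, cpos, refpos), error = function(e) 0)
  list(r = r, theta = theta, rho = rho)
}

# Enumerate candidate acceptors for a donor hydrogen of residue i.
# Backbone carbonyls of i-1, i, i+1 are excluded (the tripeptide backbone
# term already contains them); side-chain acceptors of residue i are
# excluded (self).
acceptor_candidates <- function(model, i) {
  res <- model$residues
  ri <- res[[i]]
  excl_bb <- c(i, ri$prev, ri$next_)
  out <- list()
  for (j in seq_along(res)) {
    rj <- res[[j]]
    if (!(j %in% excl_bb)) {
      o <- get_atom(rj, "O")
      cc <- get_atom(rj, "C")
      if (!is.null(o) && !is.null(cc)) {
        ref <- if (!is.na(rj$next_)) get_atom(res[[rj$next_]], "N") else
          get_atom(rj, "CA")
        out[[length(out) + 1L]] <- list(res_index = j, name = "O",
                                        cls = "amide_carbonyl",
                                        o = o, c = cc, ref = ref)
      }
    }
    if (j != i) {
      for (sc in SIDECHAIN_ACCEPTORS[[rj$res_type]] %||% list()) {
        o <- get_atom(rj, sc$o); cc <- get_atom(rj, sc$c)
        if (is.null(o) || is.null(cc)) next
        out[[length(out) + 1L]] <- list(res_index = j, name = sc$o,
                                        cls = sc$cls, o = o, c = cc,
                                        ref = get_atom(rj, sc$ref))
      }
    }
  }
  out
}

#' Find the primary hydrogen bond of a donor hydrogen
#'
#' Scans all acceptor oxygens (backbone carbonyls outside residues i-1, i,
#' i+1; side-chain carboxyl / amide / hydroxyl oxygens outside residue i)
#' and returns the donor-centred geometry of the nearest acceptor with
#' `r <= r_max` for the donor kind and `theta` in `[theta_min, 180]`, or
#' `NULL` when none qualifies (absence is a valid result; Pro has no amide
#' hydrogen).  Distances below the scanned minimum clamp to the boundary.
#'
#' @param model a `protein_model`.
#' @param i residue index.
#' @param donor `"amide_H"` or `"alpha_H"`.
#' @param search configuration list, see [default_search_config()].
#' @param donor_atom optional explicit donor atom name (e.g. `"HA2"` for
#'   one glycine alpha proton).
#' @return list `(r, theta, rho, donor_kind, acceptor_class, frame,
#'   acceptor_res, acceptor_name)` or `NULL`.
#' @export
find_primary_hbond <- function(model, i, donor = c("amide_H", "alpha_H"),
                               search = default_search_config(),
                               donor_atom = NULL) {
  donor <- match.arg(donor)
  r <- model$residues[[i]]
  if (is.null(donor_atom))
    donor_atom <- if (donor == "amide_H") "H" else "HA"
  if (donor == "amide_H" && r$res_type == "PRO") return(NULL)
  h <- get_atom(r, donor_atom)
  if (is.null(h) && donor == "alpha_H" && r$res_type == "GLY")
    h <- get_atom(r, "HA2")
  if (is.null(h)) return(NULL)
  rmin <- if (donor == "amide_H") search$amide_r_min else search$halpha_r_min
  rmax <- if (donor == "amide_H") search$amide_r_max else search$halpha_r_max
  best <- NULL
  for (acc in acceptor_candidates(model, i)) {
    g <- hb_geometry(h, acc$o, acc$c, acc$ref)
    if (g$r > rmax) next
    if (g$theta < search$theta_min || g$theta > 180) next
    if (is.null(best) || g$r < best$r) {
      best <- list(r = max(g$r, rmin), theta = g$theta,
                   rho = wrap_angle(g$rho),
                   donor_kind = donor, acceptor_class = acc$cls,
                   frame = "donor_centered",
                   acceptor_res = acc$res_index, acceptor_name = acc$name)
    }
  }
  best
}

#' Find donors hydrogen-bonded to a residue's carbonyl oxygen
#'
#' Acceptor-centred search anchored on residue i's backbone C=O.  Donor
#' hydrogens are backbone amide H, side-chain amine/amide H, and alpha H of
#' other residues; backbone donors of residues i-1, i, i+1 and side-chain
#' donors of residue i are excluded (already contained in the tripeptide
#' model).  Per donor kind the single nearest in-range partner is kept
#' (`search$secondary_mode = "sum"` keeps all).
#'
#' @inheritParams find_primary_hbond
#' @return list of acceptor-centred geometry lists (possibly empty), each
#'   with `donor_kind` one of `amide_H`, `amine_H`, `alpha_H`.
#' @export
find_secondary_hbonds <- function(model, i, search = default_search_config()) {
  res <- model$residues
  ri <- res[[i]]
  o <- get_atom(ri, "O"); cc <- get_atom(ri, "C")
  if (is.null(o) || is.null(cc)) return(list())
  ref <- if (!is.na(ri$next_)) get_atom(res[[ri$next_]], "N") else
    get_atom(ri, "CA")
  excl_bb <- c(i, ri$prev, ri$next_)
  cand <- list()
  add <- function(cand, j, hname, kind) {
    h <- get_atom(res[[j]], hname)
    if (is.null(h)) return(cand)
    rmax <- if (kind == "alpha_H") search$halpha_r_max else search$amide_r_max
    rmin <- if (kind == "alpha_H") search$halpha_r_min else search$amide_r_min
    g <- hb_geometry(h, o, cc, ref)
    if (g$r > rmax || g$theta < search$theta_min || g$theta > 180) return(cand)
    cand[[length(cand) + 1L]] <- list(
      r = max(g$r, rmin), theta = g$theta, rho = wrap_angle(g$rho),
      donor_kind = kind, frame = "acceptor_centered",
      donor_res = j, donor_name = hname)
    cand
  }
  for (j in seq_along(res)) {
    rj <- res[[j]]
    if (!(j %in% excl_bb)) {
      cand <- add(cand, j, "H", "amide_H")
      for (ha in intersect(c("HA", "HA2", "HA3"),
                           rj$atoms$name))
        cand <- add(cand, j, ha, "alpha_H")
    }
    if (j != i) {
      for (hn in AMINE_DONORS[[rj$res_type]] %||% character(0))
        cand <- add(cand, j, hn, "amine_H")
    }
  }
  if (!length(cand)) return(list())
  if (identical(search$secondary_mode, "sum")) return(cand)
  out <- list()
  for (kind in unique(vapply(cand, `[[`, "", "donor_kind"))) {
    sub <- Filter(function(g) g$donor_kind == kind, cand)
    out[[length(out) + 1L]] <- sub[[which.min(vapply(sub, `[[`, 0, "r"))]]
  }
  out
}

RING_ATOMS <- list(
  PHE = list(PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(HIS = c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(TRP5 = c("CG", "CD1", "CD2", "NE1", "CE2"),
             TRP6 = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")))

#' Aromatic ring systems of a model
#'
#' One entry per aromatic ring: Phe/Tyr six-ring, His five-ring, and the
#' two tryptophan rings separately.  The centre is the mean of the ring
#' atoms, the normal the unit plane normal (smallest singular vector), and
#' the intensity comes from the configured table.
#'
#' @param model a `protein_model`.
#' @param intensities named intensity table
#'   (`PHE`, `TYR`, `HIS`, `TRP5`, `TRP6`), relative to benzene.
#' @return list of `ring_system` lists `(ring_id, res_type, intensity,
#'   center, normal)`.
#' @export
ring_systems <- function(model,
                         intensities = default_search_config()$ring_intensities) {
  out <- list()
  for (i in seq_along(model$residues)) {
    r <- model$residues[[i]]
    rings <- RING_ATOMS[[r$res_type]]
    if (is.null(rings)) next
    for (rid in names(rings)) {
      pts <- lapply(rings[[rid]], function(nm) get_atom(r, nm))
      if (any(vapply(pts, is.null, logical(1)))) {
        warning(sprintf("residue %d (%s): ring %s has missing atoms, skipped",
                        r$seq_index, r$res_type, rid))
        next
      }
      m <- do.call(rbind, pts)
      center <- colMeans(m)
      sv <- svd(sweep(m, 2L, center))
      normal <- sv$v[, 3L]
      normal <- normal / vnorm(normal)
      inten <- unname(intensities[rid])
      if (is.na(inten)) stop(sprintf("no ring intensity configured for '%s'", rid))
      out[[length(out) + 1L]] <- list(ring_id = sprintf("%d.%s", r$seq_index, rid),
                                      res_type = r$res_type,
                                      intensity = inten,
                                      center = center, normal = normal)
    }
  }
  out
}

#' Point-dipole ring-current shielding at a proton
#'
#' `sum over rings of i * B * (1 - 3 cos^2 theta) / r^3` where `r` is the
#' proton-to-ring-centre vector and `theta` the angle between `r` and the
#' ring normal.  Rings beyond the cutoff contribute exactly 0; the term
#' vanishes at the magic angle `theta = arccos(1/sqrt(3))` at any distance.
#'
#' @param proton_pos Cartesian position of the proton.
#' @param rings list from [ring_systems()].
#' @param B dipole constant, ppm A^3.
#' @param cutoff distance cutoff in Angstrom (default 8).
#' @return shielding contribution in ppm.
#' @export
ring_current <- function(proton_pos, rings, B = default_search_config()$ring_B,
                         cutoff = default_search_config()$ring_cutoff) {
  stopifnot(cutoff > 0)
  total <- 0
  for (ring in rings) {
    v <- ring$center - proton_pos
    r <- vnorm(v)
    if (r < 1e-9) stop("proton coincides with a ring centre (r = 0)")
    if (r > cutoff) next
    ct <- vdot(v / r, ring$normal)
    total <- total + ring$intensity * B * (1 - 3 * ct * ct) / r^3
  }
  total
}
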