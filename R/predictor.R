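# Per-atom shielding assembly under the published term mask, and
# ensemble averaging (average shieldings over models first, regress once).
#
# Term bookkeeping across the peptide bond: every term is attributed to
# the residue that owns the atom.  The amide group N(i)-H(i) pairs with
# the carbonyl C(i-1)=O(i-1), so
#   * HB1 (primary, donor-centred) for atoms HA, HN, N of residue i uses
#     residue i's own amide-H bond; for the carbonyl carbon C it uses the
#     amide H of residue i+1 (the proton actually bonded across C=O..H-N);
#   * HB2/HaB2 (secondary, acceptor-centred) for atoms CA, HA, C of
#     residue i anchor on residue i's own carbonyl oxygen, while for the
#     amide atoms N and HN they anchor on the carbonyl oxygen of residue
#     i-1 (the oxygen of the amide group those atoms belong to);
#   * HaB1 uses residue i's own alpha proton for all atoms.

#' Default term mask
#'
#' The published per-atom-type selection of active terms.  `BB` is always
#' active; `CB` keeps only the backbone and neighbour terms (the H-bond
#' model systems contain no C-beta); ring current is proton-only; the
#' water term applies to `HN` only; `N` drops the primary alpha-H-bond
#' term (it raises the error otherwise).
#'
#' @return named list mapping atom type to its active term ids.  The mask
#'   is data: override entries for ablation studies.
#' @export
default_mask <- function() {
  list(
    CA = c("BB", "BB_prev", "BB_next", "HB2", "HaB2"),
    CB = c("BB", "BB_prev", "BB_next"),
    C  = c("BB", "BB_prev", "BB_next", "HB2", "HaB2"),
    HA = c("BB", "BB_prev", "BB_next", "HB1", "HB2", "HaB1", "HaB2", "RC"),
    HN = c("BB", "BB_prev", "BB_next", "HB1", "HB2", "HaB1", "HaB2", "RC", "W"),
    N  = c("BB", "BB_prev", "BB_next", "HB1", "HB2", "HaB2"))
}

#' Default prediction configuration
#' @param strict error on missing chi angles (default) instead of falling
#'   back to the common rotamer.
#' @param search hydrogen-bond / ring search block, see
#'   [default_search_config()].
#' @export
default_config <- function(strict = TRUE, search = default_search_config()) {
  list(strict = strict, search = search)
}

# alpha-proton atom names of a residue (two for glycine)
alpha_proton_names <- function(res) {
  if (res$res_type == "GLY") intersect(c("HA2", "HA3"), res$atoms$name)
  else intersect("HA", res$atoms$name)
}

#' Predict per-atom shielding breakdowns for one model
#'
#' For each residue with defined phi and psi and each predictable atom
#' type, evaluates the active terms of the mask and sums them.  Terminal
#' residues, proline `HN` and glycine `CB` yield no entry.  Glycine `HA`
#' is reported as the mean over its two alpha protons (position-dependent
#' terms are evaluated per proton and averaged), mirroring the
#' methyl-averaging convention of the parameterisation models.
#'
#' @param model a `protein_model` (protonate first via
#'   [ensure_amide_hydrogens()] if needed).
#' @param lib a `grid_library`.
#' @param mask term mask, see [default_mask()].
#' @param config see [default_config()].
#' @return data frame with one row per predicted atom: `model_index`,
#'   `seq_index`, `res_type`, `atom_type`, the nine term columns (masked
#'   terms are `NA` and excluded from the sum; absent partners are 0) and
#'   `sigma_total`.
#' @export
predict_model <- function(model, lib, mask = default_mask(),
                          config = default_config()) {
  res <- model$residues
  n <- length(res)
  tors <- lapply(seq_len(n), function(i) torsions(model, i))
  search <- config$search
  rings <- ring_systems(model, search$ring_intensities)
  # lazy caches for geometry searches
  prim_amide <- vector("list", n); prim_amide_done <- logical(n)
  sec <- vector("list", n); sec_done <- logical(n)
  get_prim_amide <- function(i) {
    if (!prim_amide_done[i]) {
      prim_amide[i] <<- list(find_primary_hbond(model, i, "amide_H", search))
      prim_amide_done[i] <<- TRUE
    }
    prim_amide[[i]]
  }
  get_sec <- function(i) {
    if (!sec_done[i]) {
      sec[i] <<- list(find_secondary_hbonds(model, i, search))
      sec_done[i] <<- TRUE
    }
    sec[[i]]
  }
  sec_for_atom <- function(i, atom) {
    # amide atoms belong to the peptide group capped by O(i-1)
    j <- if (atom %in% c("N", "HN")) res[[i]]$prev else i
    if (is.na(j) || is.null(j)) return(list())
    get_sec(j)
  }
  sum_sec <- function(geoms, kinds, term_id, atom) {
    geoms <- Filter(function(g) g$donor_kind %in% kinds, geoms)
    if (!length(geoms)) return(0)
    sum(vapply(geoms, function(g) hbond_term(lib, term_id, g, atom),
               numeric(1)))
  }
  rows <- list()
  for (i in seq_len(n)) {
    ri <- res[[i]]
    ti <- tors[[i]]
    if (is.na(ti$phi) || is.na(ti$psi)) next
    tprev <- if (!is.na(ri$prev)) tors[[ri$prev]] else NULL
    tnext <- if (!is.na(ri$next_)) tors[[ri$next_]] else NULL
    for (atom in ATOM_TYPES) {
      if (atom == "CB" && ri$res_type == "GLY") next
      if (atom == "HN" && (ri$res_type == "PRO" || !has_atom(ri, "H"))) next
      if (atom == "HA" && !length(alpha_proton_names(ri))) next
      active <- mask[[atom]]
      if (is.null(active) || !("BB" %in% active))
        stop(sprintf("invalid mask for %s: BB must always be active", atom))
      protons <- if (atom == "HA") alpha_proton_names(ri) else NA_character_
      per_proton <- lapply(protons, function(pn) {
        vals <- stats::setNames(rep(NA_real_, length(TERM_IDS)), TERM_IDS)
        bb <- backbone_term(lib, ri$res_type, ti, atom, strict = config$strict)
        if (is.null(bb)) return(NULL)
        vals["BB"] <- bb
        if ("BB_prev" %in% active)
          vals["BB_prev"] <- if (is.null(tprev)) 0 else
            neighbor_term(lib, "prev", res[[ri$prev]]$res_type, tprev, atom,
                          strict = config$strict)
        if ("BB_next" %in% active)
          vals["BB_next"] <- if (is.null(tnext)) 0 else
            neighbor_term(lib, "next", res[[ri$next_]]$res_type, tnext, atom,
                          strict = config$strict)
        if ("HB1" %in% active) {
          g <- if (atom == "C") {
            if (!is.na(ri$next_)) get_prim_amide(ri$next_) else NULL
          } else get_prim_amide(i)
          vals["HB1"] <- hbond_term(lib, "HB1", g, atom)
        }
        if ("HB2" %in% active)
          vals["HB2"] <- sum_sec(sec_for_atom(i, atom),
                                 c("amide_H", "amine_H"), "HB2", atom)
        if ("HaB1" %in% active) {
          pa <- if (atom == "HA") pn else alpha_proton_names(ri)[1L]
          g <- if (is.na(pa)) NULL else
            find_primary_hbond(model, i, "alpha_H", search, donor_atom = pa)
          vals["HaB1"] <- hbond_term(lib, "HaB1", g, atom)
        }
        if ("HaB2" %in% active)
          vals["HaB2"] <- sum_sec(sec_for_atom(i, atom), "alpha_H", "HaB2",
                                  atom)
        if ("RC" %in% active) {
          ppos <- if (atom == "HA") get_atom(ri, pn) else get_atom(ri, "H")
          vals["RC"] <- if (is.null(ppos)) 0 else
            ring_current(ppos, rings, search$ring_B, search$ring_cutoff)
        }
        if ("W" %in% active)
          vals["W"] <- water_term(!is.null(get_prim_amide(i)), lib, "HN")
        vals
      })
      per_proton <- Filter(Negate(is.null), per_proton)
      if (!length(per_proton)) next
      vals <- Reduce(`+`, per_proton) / length(per_proton)
      row <- as.list(vals)
      row$model_index <- model$model_index
      row$seq_index <- ri$seq_index
      row$res_type <- ri$res_type
      row$atom_type <- atom
      row$sigma_total <- sum(vals[active])
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (!length(rows)) {
    return(data.frame(model_index = integer(0), seq_index = integer(0),
                      res_type = character(0), atom_type = character(0)))
  }
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  out <- out[, c("model_index", "seq_index", "res_type", "atom_type",
                 TERM_IDS, "sigma_total")]
  rownames(out) <- NULL
  out
}

#' Ensemble-averaged shieldings
#'
#' Arithmetic mean of `sigma_total` per `(seq_index, atom_type)` across the
#' models in which the atom was predictable; shieldings are averaged
#' *before* any regression to experiment.
#'
#' @param ens an `ensemble`.
#' @inheritParams predict_model
#' @return data frame `(seq_index, res_type, atom_type, sigma_total,
#'   n_models)` of class `ensemble_prediction`.
#' @export
predict_ensemble <- function(ens, lib, mask = default_mask(),
                             config = default_config()) {
  stopifnot(inherits(ens, "ensemble"), length(ens$models) >= 1L)
  per <- lapply(ens$models, predict_model, lib = lib, mask = mask,
                config = config)
  all <- do.call(rbind, per)
  if (is.null(all) || !nrow(all)) return(all)
  agg <- stats::aggregate(sigma_total ~ seq_index + res_type + atom_type,
                          data = all, FUN = mean)
  cnt <- stats::aggregate(sigma_total ~ seq_index + res_type + atom_type,
                          data = all, FUN = length)
  agg$n_models <- cnt$sigma_total
  agg <- agg[order(agg$seq_index, agg$atom_type), , drop = FALSE]
  rownames(agg) <- NULL
  class(agg) <- c("ensemble_prediction", "data.frame")
  agg
}
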