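# PDB reading/writing and amide-hydrogen construction.  Only the classic
# fixed-column ATOM/MODEL/ENDMDL/TER records are supported (all structures
# this engine targets are PDB-era; mmCIF is a non-goal).  Waters and hetero
# groups are excluded; aromatic ligand rings are therefore never seen by
# the ring-current term.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
AA1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")

new_residue <- function(res_type, seq_index, chain_id, atoms) {
  structure(list(res_type = res_type, seq_index = seq_index,
                 chain_id = chain_id, atoms = atoms,
                 prev = NA_integer_, next_ = NA_integer_),
            class = "residue_record")
}

new_model <- function(residues, model_index = 1L) {
  m <- structure(list(residues = residues, model_index = model_index),
                 class = "protein_model")
  link_adjacency(m)
}

new_ensemble <- function(models) {
  stopifnot(length(models) >= 1L)
  seqs <- lapply(models, function(m)
    vapply(m$residues, `[[`, "", "res_type"))
  for (k in seq_along(seqs)[-1L]) {
    if (!identical(seqs[[k]], seqs[[1L]]))
      stop(sprintf("ensemble sequence mismatch: model %d differs from model 1",
                   k))
  }
  structure(list(models = models), class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble> %d model(s), %d residues\n",
              length(x$models), length(x$models[[1L]]$residues)))
  invisible(x)
}

#' Position of a named atom within a residue
#'
#' @param res a residue record.
#' @param name atom name; `"H"` and `"HN"` are synonyms for the amide
#'   hydrogen.
#' @return numeric length-3 position, or `NULL` when absent.
#' @export
get_atom <- function(res, name) {
  a <- res$atoms
  hit <- which(a$name == name)
  if (!length(hit) && name %in% c("H", "HN"))
    hit <- which(a$name %in% c("H", "HN"))
  if (!length(hit)) return(NULL)
  c(a$x[hit[1L]], a$y[hit[1L]], a$z[hit[1L]])
}

has_atom <- function(res, name) !is.null(get_atom(res, name))

# file-order adjacency within a chain, broken where the peptide bond
# geometry is implausible (C-N distance > 2.5 A) or atoms are missing
link_adjacency <- function(model, break_tol = 2.5) {
  res <- model$residues
  n <- length(res)
  if (n == 0L) { model$residues <- res; return(model) }
  for (i in seq_len(n)) { res[[i]]$prev <- NA_integer_; res[[i]]$next_ <- NA_integer_ }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      same_chain <- identical(res[[i]]$chain_id, res[[i + 1L]]$chain_id)
      if (!same_chain) next
      cpos <- get_atom(res[[i]], "C")
      npos <- get_atom(res[[i + 1L]], "N")
      ok <- !is.null(cpos) && !is.null(npos) && vnorm(npos - cpos) <= break_tol
      if (ok) {
        res[[i]]$next_ <- i + 1L
        res[[i + 1L]]$prev <- i
      } else {
        warning(sprintf(
          "chain break between residues %d and %d (chain %s): no i+/-1 terms across the break",
          res[[i]]$seq_index, res[[i + 1L]]$seq_index, res[[i]]$chain_id))
      }
    }
  }
  model$residues <- res
  model
}

parse_pdb_atom_line <- function(line, lineno) {
  pad <- function(s, n) formatC(s, width = n, flag = "-")
  line <- pad(line, 80)
  f <- function(a, b) substr(line, a, b)
  serial <- suppressWarnings(as.integer(f(7, 11)))
  name <- trimws(f(13, 16))
  altloc <- f(17, 17)
  resname <- trimws(f(18, 20))
  chain <- f(22, 22)
  resseq <- suppressWarnings(as.integer(f(23, 26)))
  icode <- f(27, 27)
  x <- suppressWarnings(as.numeric(f(31, 38)))
  y <- suppressWarnings(as.numeric(f(39, 46)))
  z <- suppressWarnings(as.numeric(f(47, 54)))
  occ <- suppressWarnings(as.numeric(f(55, 60)))
  elem <- trimws(f(77, 78))
  if (is.na(x) || is.na(y) || is.na(z) || !nzchar(name))
    stop(sprintf("parse error at line %d: malformed ATOM record", lineno))
  if (icode != " ")
    stop(sprintf("parse error at line %d: insertion codes are unsupported",
                 lineno))
  if (elem == "") elem <- substr(gsub("[0-9]", "", name), 1, 1)
  list(serial = serial, name = name, altloc = altloc, resname = resname,
       chain = chain, resseq = resseq, x = x, y = y, z = z,
       occ = ifelse(is.na(occ), 1, occ), elem = elem)
}

build_model_from_atoms <- function(atoms, model_index) {
  if (!length(atoms)) stop("model contains no ATOM records")
  df <- do.call(rbind, lapply(atoms, function(a)
    data.frame(serial = a$serial, name = a$name, altloc = a$altloc,
               resname = a$resname, chain = a$chain, resseq = a$resseq,
               x = a$x, y = a$y, z = a$z, occ = a$occ, elem = a$elem,
               stringsAsFactors = FALSE)))
  key <- paste(df$chain, df$resseq, sep = "|")
  residues <- list()
  for (k in unique(key)) {
    sub <- df[key == k, , drop = FALSE]
    res_type <- sub$resname[1L]
    if (!res_type %in% AA3)
      stop(sprintf("non-standard residue '%s' at position %d (chain %s)",
                   res_type, sub$resseq[1L], sub$chain[1L]))
    # alternate locations: highest occupancy wins, then first seen
    keep <- integer(0)
    for (nm in unique(sub$name)) {
      rows <- which(sub$name == nm)
      if (length(rows) > 1L)
        rows <- rows[order(-sub$occ[rows], rows)][1L]
      keep <- c(keep, rows)
    }
    sub <- sub[sort(keep), , drop = FALSE]
    residues[[length(residues) + 1L]] <- new_residue(
      res_type, sub$resseq[1L], sub$chain[1L],
      data.frame(name = sub$name, element = sub$elem, x = sub$x, y = sub$y,
                 z = sub$z, serial = sub$serial, stringsAsFactors = FALSE))
  }
  new_model(residues, model_index)
}

#' Read a protein structure
#'
#' Parses a PDB file into an ensemble of one model per `MODEL` record (or a
#' single model for model-less files).  Waters and hetero groups (HETATM)
#' are excluded.  Alternate locations resolve to the highest occupancy,
#' then first seen.  Non-standard residues and insertion codes are errors;
#' chain breaks are warnings and break i+/-1 adjacency.
#'
#' @param path PDB file path.
#' @param format only `"pdb"` is supported.
#' @return an `ensemble` object.
#' @export
read_structure <- function(path, format = "pdb") {
  format <- match.arg(format, "pdb")
  if (!file.exists(path)) stop(sprintf("cannot read structure: '%s' does not exist", path))
  lines <- readLines(path, warn = FALSE)
  models <- list()
  current <- list()
  in_model <- FALSE
  saw_model_record <- FALSE
  idx <- 0L
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    rec <- substr(line, 1, 6)
    if (startsWith(rec, "MODEL")) {
      saw_model_record <- TRUE
      in_model <- TRUE
      current <- list()
    } else if (startsWith(rec, "ENDMDL")) {
      idx <- idx + 1L
      models[[idx]] <- build_model_from_atoms(current, idx)
      current <- list()
      in_model <- FALSE
    } else if (rec == "ATOM  ") {
      a <- parse_pdb_atom_line(line, ln)
      if (a$resname == "HOH") next
      current[[length(current) + 1L]] <- a
    }
    # HETATM (waters, ligands, aromatic ligands included) intentionally skipped
  }
  if (length(current)) {
    idx <- idx + 1L
    models[[idx]] <- build_model_from_atoms(current, idx)
  }
  if (!length(models)) stop(sprintf("parse error: no ATOM records found in '%s'", path))
  disulfide_warning(models[[1L]])
  new_ensemble(models)
}

disulfide_warning <- function(model) {
  cys <- which(vapply(model$residues, function(r) r$res_type == "CYS",
                      logical(1)))
  if (length(cys) < 2L) return(invisible(NULL))
  for (i in cys) for (j in cys) {
    if (j <= i) next
    sgi <- get_atom(model$residues[[i]], "SG")
    sgj <- get_atom(model$residues[[j]], "SG")
    if (!is.null(sgi) && !is.null(sgj) && vnorm(sgi - sgj) < 2.5)
      warning(sprintf(
        "residues %d and %d appear disulfide-bonded; both are modeled as free Cys",
        model$residues[[i]]$seq_index, model$residues[[j]]$seq_index))
  }
  invisible(NULL)
}

#' Write a model or ensemble in PDB format
#'
#' Fixture writer used by the synthetic-data generator; coordinates keep
#' the standard 3-decimal PDB precision.
#' @param x a `protein_model` or `ensemble`.
#' @param path output path.
#' @export
write_pdb <- function(x, path) {
  models <- if (inherits(x, "ensemble")) x$models else list(x)
  multi <- length(models) > 1L
  con <- file(path, "w")
  on.exit(close(con))
  for (mi in seq_along(models)) {
    if (multi) writeLines(sprintf("MODEL     %4d", mi), con)
    serial <- 0L
    for (res in models[[mi]]$residues) {
      a <- res$atoms
      for (r in seq_len(nrow(a))) {
        serial <- serial + 1L
        nm <- a$name[r]
        nmfmt <- if (nchar(nm) < 4L) sprintf(" %-3s", nm) else nm
        writeLines(sprintf(
          "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nmfmt, res$res_type, res$chain_id, res$seq_index,
          a$x[r], a$y[r], a$z[r], 1, 0, a$element[r]), con)
      }
    }
    writeLines(if (multi) "ENDMDL" else "TER", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Ensure amide hydrogens are present
#'
#' With `policy = "require"` every non-proline, non-N-terminal residue must
#' already carry an amide hydrogen.  With `policy = "build"` missing amide
#' hydrogens are constructed in the C(i-1)-N(i)-CA(i) plane along the
#' bisector of the two N bonds, at an N-H length of 1.01 Angstrom; existing
#' hydrogens are never moved.  Proline has no amide hydrogen and is always
#' skipped.
#'
#' @param model a `protein_model`.
#' @param policy `"require"` or `"build"`.
#' @return the (possibly augmented) model.
#' @export
ensure_amide_hydrogens <- function(model, policy = c("require", "build")) {
  policy <- match.arg(policy)
  res <- model$residues
  for (i in seq_along(res)) {
    r <- res[[i]]
    if (r$res_type == "PRO") next
    if (is.na(r$prev)) next   # N-terminal (or after a break): no amide H needed
    if (has_atom(r, "H")) next
    if (policy == "require")
      stop(sprintf("residue %d (%s) lacks an amide hydrogen (policy=require)",
                   r$seq_index, r$res_type))
    n <- get_atom(r, "N"); ca <- get_atom(r, "CA")
    cprev <- get_atom(res[[r$prev]], "C")
    if (is.null(n) || is.null(ca) || is.null(cprev)) next
    h <- n + 1.01 * vunit(-(vunit(ca - n) + vunit(cprev - n)))
    r$atoms <- rbind(r$atoms, data.frame(
      name = "H", element = "H", x = h[1L], y = h[2L], z = h[3L],
      serial = max(r$atoms$serial, 0L) + 1L, stringsAsFactors = FALSE))
    res[[i]] <- r
  }
  model$residues <- res
  model
}
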