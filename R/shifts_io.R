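# Flat-table I/O: experimental shift tables, random-coil tables and the
# per-atom prediction/calibration report.

normalize_atom_type <- function(x) {
  x <- toupper(x)
  x[x == "H"] <- "HN"
  x
}

#' Read an experimental chemical-shift table
#'
#' Whitespace- or comma-delimited columns `(seq_index, res_type, atom_type,
#' shift)`, optional header line.  Atom-type synonyms are normalized
#' (`H` -> `HN`); for glycine, `HA2`/`HA3` rows are averaged into a single
#' `HA` entry.  Duplicate keys are an error, as is a residue-type mismatch
#' against a supplied structure.
#'
#' @param path table path.
#' @param structure optional `protein_model` or `ensemble` for residue-type
#'   cross-checking.
#' @return `data.frame(seq_index, res_type, atom_type, shift)` of class
#'   `shift_table`.
#' @export
read_shift_table <- function(path, structure = NULL) {
  if (!file.exists(path)) stop(sprintf("cannot read shift table: '%s'", path))
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  probe <- strsplit(trimws(first), if (sep == ",") "," else "[[:space:]]+")[[1L]]
  header <- is.na(suppressWarnings(as.numeric(probe[1L])))
  df <- if (header) {
    utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  } else {
    utils::read.table(path, header = FALSE, sep = sep, stringsAsFactors = FALSE,
                      col.names = c("seq_index", "res_type", "atom_type", "shift"))
  }
  names(df) <- c("seq_index", "res_type", "atom_type", "shift")[seq_len(ncol(df))]
  if (ncol(df) < 4L) stop("shift table needs columns: seq_index, res_type, atom_type, shift")
  df$res_type <- toupper(df$res_type)
  df$atom_type <- normalize_atom_type(df$atom_type)
  if (!all(is.finite(df$shift))) stop("shift table contains non-finite values")
  # Gly alpha protons: average HA2/HA3 into one HA entry
  is_ha23 <- df$atom_type %in% c("HA2", "HA3")
  if (any(is_ha23)) {
    ha <- df[is_ha23, , drop = FALSE]
    agg <- stats::aggregate(shift ~ seq_index + res_type, data = ha, FUN = mean)
    agg$atom_type <- "HA"
    df <- rbind(df[!is_ha23, , drop = FALSE],
                agg[, c("seq_index", "res_type", "atom_type", "shift")])
  }
  key <- paste(df$seq_index, df$atom_type)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop(sprintf("duplicate shift-table entry for (seq_index, atom_type) = (%s)", d))
  }
  if (!is.null(structure)) {
    model <- if (inherits(structure, "ensemble")) structure$models[[1L]] else structure
    types <- stats::setNames(
      vapply(model$residues, `[[`, "", "res_type"),
      vapply(model$residues, `[[`, 0L, "seq_index"))
    for (r in seq_len(nrow(df))) {
      t_struct <- types[as.character(df$seq_index[r])]
      if (!is.na(t_struct) && t_struct != df$res_type[r])
        stop(sprintf("residue-type mismatch at %d: table says %s, structure says %s",
                     df$seq_index[r], df$res_type[r], t_struct))
    }
  }
  df <- df[order(df$seq_index, df$atom_type), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("shift_table", "data.frame")
  df
}

#' Read a sequence-corrected random-coil table
#'
#' Either keyed by `seq_index` (columns `seq_index, atom_type, value`) or by
#' `res_type` (columns `res_type, atom_type, value`, expanded against a
#' structure).  Shifts are in ppm.
#'
#' @param path table path.
#' @param structure required when the table is residue-type keyed.
#' @return `data.frame(seq_index, atom_type, value)`.
#' @export
read_random_coil <- function(path, structure = NULL) {
  if (!file.exists(path)) stop(sprintf("cannot read random-coil table: '%s'", path))
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  probe <- strsplit(trimws(first), if (sep == ",") "," else "[[:space:]]+")[[1L]]
  header <- is.na(suppressWarnings(as.numeric(probe[1L]))) &&
    !probe[1L] %in% AA3
  df <- utils::read.table(path, header = header, sep = sep,
                          stringsAsFactors = FALSE)
  names(df)[ncol(df)] <- "value"
  names(df)[2L] <- "atom_type"
  df$atom_type <- normalize_atom_type(df$atom_type)
  by_seq <- !is.na(suppressWarnings(as.numeric(df[[1L]][1L])))
  if (by_seq) {
    names(df)[1L] <- "seq_index"
    return(df[, c("seq_index", "atom_type", "value")])
  }
  if (is.null(structure))
    stop("residue-type keyed random-coil table needs a structure to expand against")
  names(df)[1L] <- "res_type"
  model <- if (inherits(structure, "ensemble")) structure$models[[1L]] else structure
  out <- do.call(rbind, lapply(model$residues, function(r) {
    sub <- df[toupper(df$res_type) == r$res_type, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    data.frame(seq_index = r$seq_index, atom_type = sub$atom_type,
               value = sub$value, stringsAsFactors = FALSE)
  }))
  out
}

#' Zero random-coil table for a structure
#'
#' Default that lets the pipeline run standalone; random-coil values are
#' user-supplied data.
#' @param structure a `protein_model` or `ensemble`.
#' @export
random_coil_zeros <- function(structure) {
  model <- if (inherits(structure, "ensemble")) structure$models[[1L]] else structure
  expand <- expand.grid(
    seq_index = vapply(model$residues, `[[`, 0L, "seq_index"),
    atom_type = ATOM_TYPES, stringsAsFactors = FALSE)
  expand$value <- 0
  expand
}

TERM_IDS <- c("BB", "BB_prev", "BB_next", "HB1", "HB2", "HaB1", "HaB2",
              "RC", "W")

#' Write the prediction / calibration report
#'
#' Tab-separated, bit-stable column order: `seq_index, res_type, atom_type`,
#' the nine term columns, `sigma_total`, then `delta_pred`, `delta_exp` and
#' `residual` (empty when no calibration / experimental value applies).
#' Masked terms are written as empty cells.
#'
#' @param predictions breakdown data frame from [predict_model()] (or the
#'   ensemble mean joined back onto a breakdown).
#' @param calibration optional list of `calibration_result` objects keyed by
#'   atom type (see [fit_shift_calibration()]).
#' @param path output TSV path.
#' @param exp optional `shift_table` of experimental values.
#' @return `path`, invisibly.
#' @export
write_report <- function(predictions, calibration = NULL, path, exp = NULL) {
  cols <- c("seq_index", "res_type", "atom_type", TERM_IDS, "sigma_total",
            "delta_pred", "delta_exp", "residual")
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.12g", x))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con)
  if (is.null(predictions) || !nrow(predictions)) return(invisible(path))
  exp_key <- if (!is.null(exp)) paste(exp$seq_index, exp$atom_type)
  for (r in seq_len(nrow(predictions))) {
    p <- predictions[r, ]
    at <- p$atom_type
    dpred <- NA_real_; dexp <- NA_real_; resid <- NA_real_
    cal <- if (!is.null(calibration)) calibration[[at]]
    if (!is.null(cal)) dpred <- cal$b - cal$a * p$sigma_total
    if (!is.null(exp)) {
      hit <- match(paste(p$seq_index, at), exp_key)
      if (!is.na(hit)) dexp <- exp$shift[hit]
    }
    if (!is.na(dpred) && !is.na(dexp)) resid <- dexp - dpred
    terms <- vapply(TERM_IDS, function(t)
      if (t %in% names(p)) p[[t]] else NA_real_, numeric(1))
    writeLines(paste(c(p$seq_index, p$res_type, at, fmt(terms),
                       fmt(p$sigma_total), fmt(dpred), fmt(dexp), fmt(resid)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read back a report written by [write_report()]
#' @param path report TSV.
#' @export
read_report <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "")
}
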