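# Shielding-to-shift calibration: delta = b - a * sigma fitted per atom
# type by ordinary least squares, RMSD and |r| computed after regression,
# random-coil subtraction for secondary-shift reporting, and Rosner's
# generalized extreme studentized deviate (GESD) outlier test on the
# regression residuals.

#' Fit the shielding-to-shift linear calibration
#'
#' Ordinary least squares of experimental shifts on predicted shieldings,
#' reported in the `delta = b - a * sigma` sign convention (`a` is minus
#' the OLS slope).  RMSD is the root mean square of the regression
#' residuals; the correlation is reported as `|r|`.
#'
#' @param sigma numeric vector of predicted shieldings (ppm).
#' @param delta_exp numeric vector of experimental shifts (ppm), paired
#'   with `sigma`.
#' @param atom_type optional label carried through to the result.
#' @return object of class `calibration_result`: list with `atom_type`,
#'   `a`, `b`, `n`, `rmsd`, `pearson_r` (absolute value), `residuals`,
#'   `outliers` (empty; filled by [evaluate_predictions()]).
#' @export
fit_shift_calibration <- function(sigma, delta_exp, atom_type = NA_character_) {
  ok <- is.finite(sigma) & is.finite(delta_exp)
  sigma <- sigma[ok]; delta_exp <- delta_exp[ok]
  n <- length(sigma)
  if (n < 3L) stop(sprintf("calibration needs at least 3 pairs, got %d", n))
  sx <- stats::sd(sigma)
  if (sx < 1e-12) stop("degenerate fit: zero variance in predicted shieldings")
  if (stats::sd(delta_exp) < 1e-12)
    stop("degenerate fit: experimental shifts are constant (r undefined)")
  slope <- stats::cov(sigma, delta_exp) / stats::var(sigma)
  b <- mean(delta_exp) - slope * mean(sigma)
  resid <- delta_exp - (b + slope * sigma)
  structure(list(atom_type = atom_type, a = -slope, b = b, n = n,
                 rmsd = sqrt(mean(resid^2)),
                 pearson_r = abs(stats::cor(sigma, delta_exp)),
                 residuals = resid, outliers = integer(0)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration> %s: a=%.4f b=%.3f n=%d rmsd=%.3f |r|=%.3f%s\n",
              x$atom_type, x$a, x$b, x$n, x$rmsd, x$pearson_r,
              if (length(x$outliers))
                sprintf(" outliers=[%s]", paste(x$outliers, collapse = ","))
              else ""))
  invisible(x)
}

#' Subtract sequence-corrected random-coil shifts
#'
#' Elementwise subtraction keyed by `(seq_index, atom_type)`; applied
#' identically to predicted and experimental shifts when reporting
#' secondary shifts.  Because the same value is subtracted from both
#' sides, it cancels in the residuals and the reported RMSD is unchanged;
#' refitting the regression on corrected pairs preserves the RMSD exactly
#' only at unit slope, and approximately otherwise.
#'
#' @param values data frame with `seq_index`, `atom_type` and a shift
#'   column (`shift`, `value` or `sigma_total` -- the first present is
#'   corrected).
#' @param rc random-coil table `(seq_index, atom_type, value)`; must cover
#'   every key being corrected.
#' @return `values` with the shift column corrected.
#' @export
apply_random_coil <- function(values, rc) {
  col <- intersect(c("shift", "value", "sigma_total"), names(values))[1L]
  if (is.na(col)) stop("no shift column found to correct")
  key_v <- paste(values$seq_index, values$atom_type)
  key_rc <- paste(rc$seq_index, rc$atom_type)
  hit <- match(key_v, key_rc)
  if (anyNA(hit))
    stop(sprintf("random-coil table lacks an entry for (%s)",
                 key_v[which(is.na(hit))[1L]]))
  values[[col]] <- values[[col]] - rc$value[hit]
  values
}

#' Generalized extreme studentized deviate outlier test
#'
#' Rosner's test for up to `max_k` outliers in approximately normal data:
#' iteratively remove the point with the largest studentized deviation
#' `R_j = max |x - mean| / sd` and compare each `R_j` to the critical
#' value `lambda_j` from the t distribution at level `alpha`; the flagged
#' set is everything removed up to the largest `j` with `R_j > lambda_j`.
#' A zero standard deviation at any iteration stops the procedure.
#'
#' @param residuals numeric vector.
#' @param alpha significance level (default 0.05).
#' @param max_k maximum number of outliers tested (default 5).
#' @return integer indices into `residuals` of flagged points (possibly
#'   empty).
#' @export
gesd_outliers <- function(residuals, alpha = 0.05, max_k = 5L) {
  stopifnot(alpha > 0, alpha < 1)
  x <- residuals
  n <- length(x)
  if (n <= max_k + 2L)
    stop(sprintf("GESD needs n > max_k + 2 (n=%d, max_k=%d)", n, max_k))
  idx <- seq_len(n)
  removed <- integer(0)
  R <- numeric(0)
  for (j in seq_len(max_k)) {
    s <- stats::sd(x)
    if (!is.finite(s) || s < 1e-12) break
    dev <- abs(x - mean(x))
    w <- which.max(dev)
    R[j] <- dev[w] / s
    removed[j] <- idx[w]
    x <- x[-w]; idx <- idx[-w]
  }
  if (!length(R)) return(integer(0))
  flagged_up_to <- 0L
  for (j in seq_along(R)) {
    nj <- n - j + 1L
    p <- 1 - alpha / (2 * nj)
    t <- stats::qt(p, df = nj - 2L)
    lambda <- (nj - 1L) * t / sqrt((nj - 2L + t^2) * nj)
    if (R[j] > lambda) flagged_up_to <- j
  }
  removed[seq_len(flagged_up_to)]
}

#' Calibrate predictions against an experimental shift table
#'
#' Per atom type: match prediction and experiment on `(seq_index,
#' atom_type)`, fit the linear calibration, optionally run the GESD pass
#' on the residuals (flagging only; a refit excluding flagged points is
#' reported alongside when requested, mirroring how single outliers are
#' reported rather than silently removed).  Atom types with fewer than 3
#' matched pairs are skipped with a warning.
#'
#' @param pred breakdown or ensemble-prediction data frame holding
#'   `seq_index`, `atom_type`, `sigma_total`.
#' @param exp a `shift_table`.
#' @param rc optional random-coil table used for secondary-shift columns
#'   in reports (it does not change the fit at unit slope).
#' @param options list: `gesd` (logical, default `TRUE`), `alpha`,
#'   `max_k`, `refit` (logical, default `FALSE`).
#' @return named list (by atom type) of `calibration_result`; when
#'   `refit` each result carries a `refit` sub-result without the flagged
#'   points.  Attribute `pairs` holds the matched table.
#' @export
evaluate_predictions <- function(pred, exp, rc = NULL,
                                 options = list()) {
  opt <- utils::modifyList(
    list(gesd = TRUE, alpha = 0.05, max_k = 5L, refit = FALSE), options)
  key_e <- paste(exp$seq_index, exp$atom_type)
  pred <- pred[!duplicated(paste(pred$seq_index, pred$atom_type)), , drop = FALSE]
  hit <- match(paste(pred$seq_index, pred$atom_type), key_e)
  pairs <- data.frame(seq_index = pred$seq_index,
                      atom_type = pred$atom_type,
                      sigma = pred$sigma_total,
                      delta = exp$shift[hit],
                      stringsAsFactors = FALSE)
  pairs <- pairs[!is.na(pairs$delta), , drop = FALSE]
  out <- list()
  for (at in intersect(ATOM_TYPES, unique(pairs$atom_type))) {
    sub <- pairs[pairs$atom_type == at, , drop = FALSE]
    if (nrow(sub) < 3L) {
      warning(sprintf("atom type %s skipped: only %d matched pairs",
                      at, nrow(sub)))
      next
    }
    fit <- fit_shift_calibration(sub$sigma, sub$delta, at)
    if (isTRUE(opt$gesd) && nrow(sub) > opt$max_k + 2L) {
      fl <- gesd_outliers(fit$residuals, alpha = opt$alpha,
                          max_k = opt$max_k)
      fit$outliers <- fl
      fit$outlier_keys <- sub$seq_index[fl]
      if (isTRUE(opt$refit) && length(fl)) {
        fit$refit <- fit_shift_calibration(sub$sigma[-fl], sub$delta[-fl], at)
      }
    }
    out[[at]] <- fit
  }
  if (!length(out)) stop("fewer than 3 matched pairs for every atom type")
  attr(out, "pairs") <- pairs
  out
}
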