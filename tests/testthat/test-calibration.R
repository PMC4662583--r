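# Linear calibration, random-coil handling and the GESD outlier test.

# closed-form OLS oracle written out longhand
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  b <- mean(y) - slope * mean(x)
  resid <- y - b - slope * x
  list(a = -slope, b = b, rmsd = sqrt(mean(resid^2)),
       r = abs(sum((x - mean(x)) * (y - mean(y))) /
                 sqrt(sxx * sum((y - mean(y))^2))))
}

test_that("fit recovers exact linear data and rejects degenerate inputs", {
  sigma <- c(118, 120, 122, 125, 119)
  delta <- 10 - 1 * sigma
  fit <- fit_shift_calibration(sigma, delta, "CA")
  expect_equal(fit$a, 1, tolerance = 1e-12)
  expect_equal(fit$b, 10, tolerance = 1e-12)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit$pearson_r, 1, tolerance = 1e-12)
  expect_error(fit_shift_calibration(c(1, 2), c(3, 4)), "at least 3")
  expect_error(fit_shift_calibration(rep(5, 6), rnorm(6)), "zero variance")
  expect_error(fit_shift_calibration(1:6, rep(2, 6)), "constant")
})

test_that("fit equals the closed-form OLS oracle and is affine-invariant in rmsd", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(5:60, 1)
    x <- rnorm(n, 120, 4)
    y <- 185 - 0.95 * x + rnorm(n, 0, 1)
    fit <- fit_shift_calibration(x, y)
    ora <- ols_oracle(x, y)
    expect_equal(fit$a, ora$a, tolerance = 1e-10)
    expect_equal(fit$b, ora$b, tolerance = 1e-10)
    expect_equal(fit$rmsd, ora$rmsd, tolerance = 1e-10)
    expect_equal(fit$pearson_r, ora$r, tolerance = 1e-10)
    # rmsd invariant under affine maps of sigma (the slope absorbs them)
    u <- runif(1, 0.2, 5) * sample(c(-1, 1), 1)
    v <- runif(1, -50, 50)
    fit2 <- fit_shift_calibration(u * x + v, y)
    expect_equal(fit2$rmsd, fit$rmsd, tolerance = 1e-9)
  }
})

test_that("noisy parameter recovery at n = 50 stays within 3 SE with rmsd near the noise level", {
  set.seed(42)
  n <- 50
  x <- rnorm(n, 120, 4)
  y <- 185 - 0.95 * x + rnorm(n, 0, 1)
  fit <- fit_shift_calibration(x, y)
  # standard errors of the OLS slope/intercept
  se_slope <- fit$rmsd / sqrt(sum((x - mean(x))^2)) * sqrt(n / (n - 2))
  se_b <- se_slope * sqrt(mean(x^2))
  expect_lt(abs(fit$a - 0.95), 3 * se_slope)
  expect_lt(abs(fit$b - 185), 3 * se_b)
  expect_gt(fit$rmsd, 0.7)
  expect_lt(fit$rmsd, 1.3)
})

test_that("random-coil subtraction: identity, inverse, unit-slope rmsd invariance, missing keys", {
  tab <- data.frame(seq_index = 1:6, atom_type = "CA",
                    shift = c(54, 55, 53, 58, 56, 57))
  rc0 <- data.frame(seq_index = 1:6, atom_type = "CA", value = 0)
  expect_equal(apply_random_coil(tab, rc0)$shift, tab$shift)
  rc <- data.frame(seq_index = 1:6, atom_type = "CA",
                   value = c(1.2, -0.4, 0.3, 2, -1, 0.5))
  sub <- apply_random_coil(tab, rc)
  add <- sub; add$shift <- add$shift + rc$value
  expect_equal(add$shift, tab$shift, tolerance = 1e-12)
  # subtracting rc from BOTH predicted and experimental shifts cancels in
  # the residuals, so the reported rmsd is unchanged (the pipeline's
  # secondary-shift convention)
  sigma <- c(120, 121, 119, 124, 122, 123)
  delta <- 175 - sigma + c(0.1, -0.2, 0.05, 0.15, -0.1, 0)
  f1 <- fit_shift_calibration(sigma, delta)
  pred_delta <- f1$b - f1$a * sigma
  resid_corrected <- (delta - rc$value) - (pred_delta - rc$value)
  expect_equal(sqrt(mean(resid_corrected^2)), f1$rmsd, tolerance = 1e-12)
  # refitting on corrected (predicted, experimental) shift pairs preserves
  # the rmsd exactly when the pair relation has unit slope
  exact <- 175 - sigma
  f_unit <- fit_shift_calibration(sigma, exact)
  f_unit2 <- fit_shift_calibration(exact - rc$value, exact - rc$value)
  expect_equal(f_unit$rmsd, 0, tolerance = 1e-9)
  expect_equal(f_unit2$rmsd, 0, tolerance = 1e-9)
  rc_short <- rc[-3, ]
  expect_error(apply_random_coil(tab, rc_short), "3 CA")
})

# exhaustive small-instance reimplementation of Rosner's procedure
gesd_oracle <- function(x, alpha, max_k) {
  n <- length(x)
  removed <- integer(0)
  xs <- x; idx <- seq_len(n)
  Rs <- numeric(0)
  for (j in seq_len(max_k)) {
    if (stats::sd(xs) < 1e-12) break
    devs <- abs(xs - mean(xs))
    w <- which.max(devs)
    Rs[j] <- devs[w] / stats::sd(xs)
    removed[j] <- idx[w]
    xs <- xs[-w]; idx <- idx[-w]
  }
  keep <- 0
  for (j in seq_along(Rs)) {
    nj <- n - j + 1
    p <- 1 - alpha / (2 * nj)
    tv <- stats::qt(p, nj - 2)
    lam <- (nj - 1) * tv / sqrt((nj - 2 + tv^2) * nj)
    if (Rs[j] > lam) keep <- j
  }
  removed[seq_len(keep)]
}

test_that("gesd agrees with the small-instance oracle and handles degenerate input", {
  for (seed in 1:30) {
    set.seed(seed)
    n <- sample(9:12, 1)
    x <- rnorm(n)
    if (seed %% 3 == 0) x[1] <- x[1] + 8   # sometimes inject an outlier
    expect_identical(gesd_outliers(x, alpha = 0.05, max_k = 5),
                     gesd_oracle(x, 0.05, 5))
  }
  expect_identical(gesd_outliers(rep(3, 10)), integer(0))
  expect_error(gesd_outliers(rnorm(6), max_k = 5), "max_k")
})

test_that("gesd flags an injected 10-sd displacement and controls type-I error", {
  set.seed(7)
  x <- rnorm(50)
  x[17] <- x[17] + 10 * sd(x)
  flagged <- gesd_outliers(x, alpha = 0.05, max_k = 5)
  expect_true(17 %in% flagged)
  # it is the iteration-1 extreme and R_1 exceeds lambda_1 (brute force)
  expect_equal(which.max(abs(x - mean(x))), 17L)
  R1 <- max(abs(x - mean(x))) / sd(x)
  n <- 50; p <- 1 - 0.05 / (2 * n); tv <- qt(p, n - 2)
  lam1 <- (n - 1) * tv / sqrt((n - 2 + tv^2) * n)
  expect_gt(R1, lam1)
  # type-I control: clean Gaussian samples almost never flag anything
  set.seed(123)
  false_pos <- sum(vapply(1:200, function(k)
    length(gesd_outliers(rnorm(50), alpha = 0.05, max_k = 5)) > 0,
    logical(1)))
  # nominal level ~5%; allow generous binomial slack around it
  expect_lt(false_pos / 200, 0.12)
})

test_that("evaluate_predictions: join semantics, gesd no-op path, per-type results", {
  lib <- fix_lib()
  set.seed(9)
  m <- make_toy_structure(rep(c("ALA", "SER", "GLY"), 5),
                          phi_psi = cbind(runif(15, -150, -60),
                                          runif(15, 100, 160)))
  pred <- predict_model(m, lib)
  obs <- make_observations(lib, m, a = 0.95, b = 185, noise_sd = 0.2,
                           seed = 11)
  # keys absent from predictions are ignored; n reflects matches
  extra <- rbind(obs, data.frame(seq_index = 99L, res_type = "ALA",
                                 atom_type = "CA", shift = 50))
  res <- evaluate_predictions(pred, extra)
  expect_equal(res$CA$n, sum(pred$atom_type == "CA"))
  for (at in names(res)) {
    # recovery within 4 standard errors of the generator truth (proton
    # surfaces have small dynamic range, so the SE-scaled bound is the
    # honest one)
    f <- res[[at]]
    sig <- pred$sigma_total[pred$atom_type == at]
    se_slope <- f$rmsd / sqrt(sum((sig - mean(sig))^2)) *
      sqrt(f$n / (f$n - 2))
    expect_lt(abs(f$a - 0.95), 4 * se_slope + 1e-6, label = at)
    expect_lt(f$rmsd, 0.5)
  }
  # gesd flagging alone never changes the fit (no refit requested)
  r_on <- evaluate_predictions(pred, obs, options = list(gesd = TRUE))
  r_off <- evaluate_predictions(pred, obs, options = list(gesd = FALSE))
  for (at in names(r_on)) {
    expect_length(r_off[[at]]$outliers, 0)
    expect_equal(r_on[[at]]$a, r_off[[at]]$a)
    expect_equal(r_on[[at]]$rmsd, r_off[[at]]$rmsd)
  }
  # refit excludes flagged points
  obs2 <- obs
  k <- which(obs2$atom_type == "CA")[3]
  obs2$shift[k] <- obs2$shift[k] + 25
  r2 <- evaluate_predictions(pred, obs2, options = list(refit = TRUE))
  expect_true(length(r2$CA$outliers) >= 1)
  expect_lt(r2$CA$refit$rmsd, r2$CA$rmsd)
})
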