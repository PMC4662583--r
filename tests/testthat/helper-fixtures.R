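# Shared fixtures, built in code.  Libraries are cached per session: the
# generators are deterministic, so caching only saves time.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .fixture_env))
    assign(key, build(), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# standard small synthetic library: ALA/GLY/SER, cosine surfaces, seed 7
fix_lib <- function() cached("lib7", function()
  make_library(c("ALA", "GLY", "SER"), seed = 7))

# library with every grid identically zero
fix_zero_lib <- function() cached("lib0", function()
  make_library(c("ALA", "GLY", "SER"), form = "constant", constant = 0,
               delta_w = 0))

# extended-strand 5-mer with mixed residue types (no H-bond partners)
fix_model <- function() cached("model5", function()
  make_toy_structure(c("ALA", "SER", "GLY", "ALA", "ALA"),
                     phi_psi = cbind(c(-140, -139, -141, -138, -140),
                                     c(120, 121, 119, 122, 120))))

# independent dense Catmull-Rom oracle: naive per-point evaluation with
# explicit loops, no shared code with interpolate_grid beyond the kernel
# definition written out longhand
oracle_catmull_1d <- function(nodes_vals, xmin, spacing, x, periodic) {
  n <- length(nodes_vals)
  if (periodic) {
    t <- (((x + 180) %% 360 - 180) - xmin) / spacing
    j <- floor(t); u <- t - j
    idx <- (as.integer(j) + (-1:2)) %% n + 1L
  } else {
    xmax <- xmin + (n - 1) * spacing
    x <- min(max(x, xmin), xmax)
    t <- (x - xmin) / spacing
    j <- floor(t); if (j >= n - 1) j <- n - 2
    u <- t - j
    idx <- pmin(pmax(as.integer(j) + (-1:2), 0L), n - 1L) + 1L
  }
  w <- c(-0.5 * u^3 + u^2 - 0.5 * u,
         1.5 * u^3 - 2.5 * u^2 + 1,
         -1.5 * u^3 + 2 * u^2 + 0.5 * u,
         0.5 * u^3 - 0.5 * u^2)
  sum(nodes_vals[idx] * w)
}

oracle_catmull_2d <- function(vals, ax1, ax2, x1, x2) {
  # contract axis 2 for each of the axis-1 node rows, then axis 1
  col <- vapply(seq_len(nrow(vals)), function(r)
    oracle_catmull_1d(vals[r, ], ax2$min, ax2$spacing, x2, ax2$periodic),
    numeric(1))
  oracle_catmull_1d(col, ax1$min, ax1$spacing, x1, ax1$periodic)
}

# random rigid-body transform
random_rigid <- function(seed) {
  set.seed(seed)
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  R <- matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]), 2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2), 2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)),
    nrow = 3, byrow = TRUE)
  t <- stats::rnorm(3, sd = 5)
  list(apply = function(p) as.numeric(R %*% p + t))
}
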