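# Torsions, hydrogen-bond descriptor search, ring geometry.

test_that("dihedral follows the right-hand convention on constructed cases", {
  # planar cis / trans
  expect_equal(dihedral(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)), 0)
  expect_equal(dihedral(c(-1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)), -180)
  # cross-product oracle case
  expect_equal(dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1)), -90)
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("dihedral is mirror-antisymmetric and rigid-motion invariant", {
  for (seed in 1:25) {
    set.seed(seed)
    pts <- lapply(1:4, function(i) rnorm(3))
    d0 <- tryCatch(do.call(dihedral, pts), error = function(e) NULL)
    if (is.null(d0)) next
    mir <- lapply(pts, function(p) p * c(1, 1, -1))
    # sign flips under reflection: d(mir) = -d0 modulo the 360 wrap
    expect_lt(abs(wrap_angle(do.call(dihedral, mir) + d0)), 1e-9)
    rig <- random_rigid(seed + 100)
    expect_equal(do.call(dihedral, lapply(pts, rig$apply)), d0,
                 tolerance = 1e-9)
  }
})

test_that("torsions round-trips builder angles and marks termini absent", {
  pp <- cbind(c(-60, -140, -70, -100), c(-45, 120, 150, 130))
  m <- make_toy_structure(c("ALA", "VAL", "SER", "ALA"), phi_psi = pp,
                          chi = list(numeric(0), 55, -65, numeric(0)))
  for (i in 2:3) {
    t <- torsions(m, i)
    expect_equal(t$phi, pp[i, 1], tolerance = 1e-6)
    expect_equal(t$psi, pp[i, 2], tolerance = 1e-6)
    expect_equal(abs(t$omega), 180, tolerance = 1e-6)
  }
  expect_true(is.na(torsions(m, 1)$phi))    # no C(i-1)
  expect_true(is.na(torsions(m, 4)$psi))    # no N(i+1)
  # Val has exactly one chi; Ser's chi1 recovered
  expect_length(torsions(m, 2)$chi, 1)
  expect_equal(torsions(m, 2)$chi, 55, tolerance = 1e-6)
  expect_equal(torsions(m, 3)$chi, -65, tolerance = 1e-6)
  expect_equal(n_chi("VAL"), 1L)
  expect_equal(n_chi("ALA"), 0L)
  expect_equal(n_chi("LYS"), 4L)
})

test_that("prescribed hydrogen-bond geometry is recovered by the search", {
  for (case in list(list(r = 2.0, theta = 160, rho = 0),
                    list(r = 2.4, theta = 120, rho = -75),
                    list(r = 2.8, theta = 95, rho = 140))) {
    m <- make_toy_structure(c("ALA", "ALA", "ALA", "ALA"),
                            phi_psi = c(-140, 135),
                            place_hbond = c(list(donor_res = 3,
                                                 donor = "amide_H"), case))
    g <- find_primary_hbond(m, 3, "amide_H")
    expect_false(is.null(g))
    expect_equal(g$r, case$r, tolerance = 1e-3)
    expect_equal(g$theta, case$theta, tolerance = 1e-3)
    expect_equal(g$rho, case$rho, tolerance = 1e-3)
    expect_identical(g$frame, "donor_centered")
    expect_identical(g$acceptor_class, "amide_carbonyl")
  }
})

test_that("primary search respects range, theta window and nearest-partner rule", {
  # beyond the amide scan maximum -> none
  m <- make_toy_structure(c("ALA", "ALA", "ALA", "ALA"), phi_psi = c(-140, 135),
                          place_hbond = list(donor_res = 3, donor = "amide_H",
                                             r = 3.4, theta = 170, rho = 0))
  expect_null(find_primary_hbond(m, 3, "amide_H"))
  # but an alpha donor reaches to 4.0
  m2 <- make_toy_structure(c("ALA", "ALA", "ALA", "ALA"), phi_psi = c(-140, 135),
                           place_hbond = list(donor_res = 3, donor = "alpha_H",
                                              r = 3.4, theta = 170, rho = 0))
  g2 <- find_primary_hbond(m2, 3, "alpha_H")
  expect_equal(g2$r, 3.4, tolerance = 1e-3)
  # theta below 90 rejected
  m3 <- make_toy_structure(c("ALA", "ALA", "ALA", "ALA"), phi_psi = c(-140, 135),
                           place_hbond = list(donor_res = 3, donor = "amide_H",
                                              r = 2.0, theta = 70, rho = 0))
  expect_null(find_primary_hbond(m3, 3, "amide_H"))
  # r below the scanned minimum clamps to the boundary
  m4 <- make_toy_structure(c("ALA", "ALA", "ALA", "ALA"), phi_psi = c(-140, 135),
                           place_hbond = list(donor_res = 3, donor = "amide_H",
                                              r = 1.2, theta = 170, rho = 0))
  g4 <- find_primary_hbond(m4, 3, "amide_H")
  expect_equal(g4$r, 1.5, tolerance = 1e-9)
  # property: search never returns out-of-window geometry
  set.seed(31)
  for (k in 1:10) {
    mm <- make_toy_structure(
      c("ALA", "ALA", "ALA", "ALA"), phi_psi = c(-140, 135),
      place_hbond = list(donor_res = 3, donor = "amide_H",
                         r = runif(1, 1.0, 3.5), theta = runif(1, 60, 180),
                         rho = runif(1, -180, 180)))
    gg <- find_primary_hbond(mm, 3, "amide_H")
    if (!is.null(gg)) {
      expect_true(gg$r >= 1.5 && gg$r <= 3.0)
      expect_true(gg$theta >= 90 && gg$theta <= 180)
    }
  }
})

test_that("secondary search is acceptor-centred and capped per donor kind", {
  # no partners in an extended strand
  m <- fix_model()
  expect_length(find_secondary_hbonds(m, 2), 0)
  # a donated amide H onto residue 1's carbonyl: build donor on the ghost
  # chain by reusing the primary prescription from the other side is not
  # possible, so verify the per-kind cap with secondary_mode toggling on a
  # compact helical fold where backbone partners exist
  set.seed(8)
  helix <- make_toy_structure(rep("ALA", 8), phi_psi = c(-57, -47))
  any_sec <- FALSE
  for (i in 1:8) {
    sec <- find_secondary_hbonds(helix, i)
    kinds <- vapply(sec, `[[`, "", "donor_kind")
    expect_false(anyDuplicated(kinds) > 0)   # nearest-only per kind
    for (g in sec) {
      expect_identical(g$frame, "acceptor_centered")
      expect_gte(g$theta, 90)
      any_sec <- any_sec || TRUE
    }
  }
  expect_true(any_sec)   # an ideal alpha-helix donates i+4 -> i
  # "sum" mode returns at least as many geometries
  cfg <- default_search_config(); cfg$secondary_mode <- "sum"
  for (i in 1:8) {
    expect_gte(length(find_secondary_hbonds(helix, i, cfg)),
               length(find_secondary_hbonds(helix, i)))
  }
})

test_that("ring systems: counts, hexagon centroid and normal", {
  m <- fix_model()
  expect_length(ring_systems(m), 0)
  mw <- make_toy_structure(c("ALA", "TRP", "ALA"), phi_psi = c(-140, 135))
  rw <- ring_systems(mw)
  expect_length(rw, 2)   # indole = fused 5- and 6-ring
  mf <- make_toy_structure(c("ALA", "PHE", "ALA"), phi_psi = c(-140, 135))
  rf <- ring_systems(mf)
  expect_length(rf, 1)
  # the builder's Phe ring is a regular planar hexagon: centroid equals
  # the atom mean and the normal is perpendicular to every ring bond
  res <- mf$residues[[2]]
  atoms <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
  pts <- do.call(rbind, lapply(atoms, function(a) get_atom(res, a)))
  expect_equal(rf[[1]]$center, colMeans(pts), tolerance = 1e-9)
  expect_equal(sqrt(sum(rf[[1]]$normal^2)), 1, tolerance = 1e-9)
  for (r in seq_len(nrow(pts)))
    expect_lt(abs(sum((pts[r, ] - rf[[1]]$center) * rf[[1]]$normal)), 1e-6)
})

test_that("ring_current: closed form, magic angle, cutoff, additivity, rigid invariance", {
  ring <- list(ring_id = "x", res_type = "PHE", intensity = 1,
               center = c(0, 0, 1), normal = c(0, 0, 1))
  # theta = 0 (proton on the axis, r = 1): 1 - 3 = -2
  expect_equal(ring_current(c(0, 0, 0), list(ring), B = 1, cutoff = 8), -2)
  # theta = 90 at r = 1
  ring2 <- ring; ring2$center <- c(1, 0, 0)
  expect_equal(ring_current(c(0, 0, 0), list(ring2), B = 1, cutoff = 8), 1)
  # magic angle: zero at any distance
  ct <- 1 / sqrt(3)
  st <- sqrt(1 - ct^2)
  for (r in c(0.8, 2, 7.9)) {
    ring3 <- ring; ring3$center <- r * c(st, 0, ct)
    expect_lt(abs(ring_current(c(0, 0, 0), list(ring3), B = 5, cutoff = 8)),
              1e-12)
  }
  # beyond the cutoff: exactly zero
  ring4 <- ring; ring4$center <- c(0, 0, 9)
  expect_identical(ring_current(c(0, 0, 0), list(ring4), B = 1, cutoff = 8), 0)
  ring5 <- ring; ring5$center <- c(0, 0, 7.9)
  expect_true(ring_current(c(0, 0, 0), list(ring5), B = 1, cutoff = 8) != 0)
  # r = 0 is an error
  expect_error(ring_current(c(0, 0, 1), list(ring), B = 1, cutoff = 8), "r = 0")
  # additivity over rings and rigid-body invariance
  set.seed(17)
  rings <- lapply(1:4, function(k) {
    n <- rnorm(3); n <- n / sqrt(sum(n^2))
    list(ring_id = paste0("r", k), res_type = "PHE",
         intensity = runif(1, 0.5, 1.2), center = rnorm(3, sd = 3),
         normal = n)
  })
  p <- c(0.3, -0.2, 0.1)
  total <- ring_current(p, rings, B = 2, cutoff = 8)
  expect_equal(total, sum(vapply(rings, function(r)
    ring_current(p, list(r), B = 2, cutoff = 8), numeric(1))),
    tolerance = 1e-12)
  rig <- random_rigid(99)
  rings_t <- lapply(rings, function(r) {
    r$center <- rig$apply(r$center)
    r$normal <- rig$apply(r$normal) - rig$apply(c(0, 0, 0))
    r
  })
  expect_equal(ring_current(rig$apply(p), rings_t, B = 2, cutoff = 8), total,
               tolerance = 1e-9)
})
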