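# Term-mask conformance, per-atom assembly and ensemble averaging.

test_that("default mask matches the published per-atom-type term table", {
  mask <- default_mask()
  expect_setequal(mask$CA, c("BB", "BB_prev", "BB_next", "HB2", "HaB2"))
  expect_setequal(mask$CB, c("BB", "BB_prev", "BB_next"))
  expect_setequal(mask$C,  c("BB", "BB_prev", "BB_next", "HB2", "HaB2"))
  expect_setequal(mask$HA, c("BB", "BB_prev", "BB_next", "HB1", "HB2",
                             "HaB1", "HaB2", "RC"))
  expect_setequal(mask$HN, c("BB", "BB_prev", "BB_next", "HB1", "HB2",
                             "HaB1", "HaB2", "RC", "W"))
  expect_length(mask$HN, 9)
  expect_setequal(mask$N,  c("BB", "BB_prev", "BB_next", "HB1", "HB2", "HaB2"))
  expect_false("HaB1" %in% mask$N)
  expect_false(any(c("HB1", "HB2", "HaB1", "HaB2", "RC", "W") %in% mask$CB))
  expect_false("RC" %in% mask$CA || "RC" %in% mask$C || "RC" %in% mask$N)
  expect_false("W" %in% unlist(mask[c("CA", "CB", "C", "HA", "N")]))
})

test_that("constant per-term libraries sum per the mask (hand-computed totals)", {
  # BB = 100, BB_prev = 1, BB_next = 2, HB2 = 0.5, HaB2 = 0.25 everywhere
  lib <- make_library(c("ALA", "GLY", "SER"), form = "constant", constant = 0,
                      delta_w = 0)
  for (id in names(lib$grids)) {
    g <- lib$grids[[id]]
    if (g$res_type %in% c("HB1", "HB2", "HaB1", "HaB2")) {
      lib$grids[[id]]$values[] <- switch(g$res_type, HB2 = 0.5, HaB2 = 0.25, 0)
    } else if (g$role == "center") {
      lib$grids[[id]]$values[] <- 100
    } else {
      # effect grids: sigma_ref is 0 (from the zero Ala grids), so a
      # constant grid value IS the term value
      lib$grids[[id]]$values[] <- if (g$role == "effect_on_next") 1 else 2
    }
  }
  # alpha-helical fold: interior residues have secondary partners of both
  # amide and alpha kinds feeding HB2 / HaB2
  helix <- make_toy_structure(rep("ALA", 10), phi_psi = c(-57, -47))
  p <- predict_model(helix, lib)
  mid <- p[p$seq_index == 5, ]
  with_partners <- function(at) {
    row <- mid[mid$atom_type == at, ]
    expect_equal(nrow(row), 1)
    row
  }
  ca <- with_partners("CA")
  # every interior carbonyl O here receives an amide H (HB2 = 0.5) and an
  # alpha H (HaB2 = 0.25): CA total = 100 + 1 + 2 + 0.5 + 0.25
  expect_equal(ca$sigma_total, 103.75, tolerance = 1e-9)
  cb <- with_partners("CB")
  expect_equal(cb$sigma_total, 103, tolerance = 1e-9)   # mask drops HB2/HaB2
  expect_true(is.na(cb$HB2) && is.na(cb$HaB2))
})

test_that("single-residue chains and termini yield no predictions", {
  lib <- fix_lib()
  m1 <- make_toy_structure("ALA", phi_psi = c(-60, -45))
  expect_equal(nrow(predict_model(m1, lib)), 0)
  m <- fix_model()
  p <- predict_model(m, lib)
  expect_false(1 %in% p$seq_index)
  expect_false(5 %in% p$seq_index)
  expect_false(any(p$atom_type == "CB" & p$res_type == "GLY"))
})

test_that("masked-term exclusion: perturbing a masked surface never changes the total", {
  lib <- fix_lib()
  m <- fix_model()
  base <- predict_model(m, lib)
  # CB ignores all H-bond surfaces: shift every HaB1 surface by 10 ppm
  lib2 <- lib
  for (id in names(lib2$grids)) {
    if (lib2$grids[[id]]$res_type == "HaB1")
      lib2$grids[[id]]$values <- lib2$grids[[id]]$values + 10
  }
  pert <- predict_model(m, lib2)
  cb0 <- base[base$atom_type == "CB", "sigma_total"]
  cb1 <- pert[pert$atom_type == "CB", "sigma_total"]
  n0 <- base[base$atom_type == "N", "sigma_total"]
  n1 <- pert[pert$atom_type == "N", "sigma_total"]
  expect_equal(cb1, cb0, tolerance = 1e-12)
  expect_equal(n1, n0, tolerance = 1e-12)   # N drops HaB1 too
})

test_that("additivity: shifting one active surface by delta shifts totals by exactly delta", {
  lib <- fix_lib()
  m <- fix_model()
  base <- predict_model(m, lib)
  delta <- 2.5
  lib2 <- lib
  for (rt in c("ALA", "GLY", "SER")) {
    id <- grid_id(rt, "center", "CA")
    lib2$grids[[id]]$values <- lib2$grids[[id]]$values + delta
  }
  pert <- predict_model(m, lib2)
  expect_equal(pert[pert$atom_type == "CA", "sigma_total"],
               base[base$atom_type == "CA", "sigma_total"] + delta,
               tolerance = 1e-9)
  expect_equal(pert[pert$atom_type == "HN", "sigma_total"],
               base[base$atom_type == "HN", "sigma_total"],
               tolerance = 1e-12)
})

test_that("ablation changes only atoms whose mask contained the removed term", {
  lib <- fix_lib()
  helix <- make_toy_structure(rep("ALA", 8), phi_psi = c(-57, -47))
  mask <- default_mask()
  base <- predict_model(helix, lib, mask)
  mask2 <- mask
  mask2$HN <- setdiff(mask2$HN, "HB1")
  abl <- predict_model(helix, lib, mask2)
  for (at in c("CA", "CB", "C", "HA", "N")) {
    expect_equal(abl[abl$atom_type == at, "sigma_total"],
                 base[base$atom_type == at, "sigma_total"],
                 tolerance = 1e-12, label = at)
  }
  hn0 <- base[base$atom_type == "HN", ]
  hn1 <- abl[abl$atom_type == "HN", ]
  bonded <- !is.na(hn0$HB1) & hn0$HB1 != 0
  expect_true(any(bonded))
  expect_false(isTRUE(all.equal(hn1$sigma_total[bonded],
                                hn0$sigma_total[bonded])))
})

test_that("glycine HA is the mean over the two alpha protons", {
  lib <- fix_lib()
  m <- fix_model()   # residue 3 is GLY
  p <- predict_model(m, lib)
  gly <- p[p$res_type == "GLY" & p$atom_type == "HA", ]
  expect_equal(nrow(gly), 1)
  # backbone/neighbour terms are proton-independent; the row must equal
  # the average of per-proton assemblies, which for this strand (no rings,
  # no H-bonds in range) is just the shared backbone value
  expect_equal(gly$sigma_total, sum(gly[, default_mask()$HA], na.rm = TRUE),
               tolerance = 1e-9)
})

test_that("ensemble averaging: identical models, two-model mean, large-ensemble two-pass oracle", {
  lib <- fix_lib()
  m <- fix_model()
  single <- predict_model(m, lib)
  ens <- shiftgrid:::new_ensemble(list(m, m, m))
  avg <- predict_ensemble(ens, lib)
  hit <- match(paste(single$seq_index, single$atom_type),
               paste(avg$seq_index, avg$atom_type))
  expect_equal(avg$sigma_total[hit], single$sigma_total, tolerance = 1e-12)
  expect_true(all(avg$n_models == 3))
  # two models -> arithmetic mean
  m2 <- make_toy_structure(c("ALA", "SER", "GLY", "ALA", "ALA"),
                           phi_psi = c(-70, 150), model_index = 2L)
  ens2 <- shiftgrid:::new_ensemble(list(m, m2))
  avg2 <- predict_ensemble(ens2, lib)
  p1 <- predict_model(m, lib); p2 <- predict_model(m2, lib)
  key <- paste(avg2$seq_index, avg2$atom_type)
  k1 <- match(key, paste(p1$seq_index, p1$atom_type))
  k2 <- match(key, paste(p2$seq_index, p2$atom_type))
  both <- !is.na(k1) & !is.na(k2)
  expect_equal(avg2$sigma_total[both],
               (p1$sigma_total[k1[both]] + p2$sigma_total[k2[both]]) / 2,
               tolerance = 1e-12)
})
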