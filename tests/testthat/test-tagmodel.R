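test_that("the chi1/chi2 scan in vacuum scores zero and exercises the tie-break", {
  s <- vacuum_residue()
  sc <- scan_chi12(s, site_ref("A", 1), grid_step = 30)
  expect_equal(sc$clash_score, 0L)
  # no clash partners: every pair ties at 0, so the smallest grid pair wins
  expect_equal(sc$chi1, -150)
  expect_equal(sc$chi2, -150)
})

test_that("the chi1/chi2 scan equals the exhaustive enumeration oracle", {
  s <- make_two_domain_structure(30, hinge_spec())
  site <- site_ref("A", 68)
  sc <- scan_chi12(s, site, grid_step = 30)
  or <- scan_oracle(s, site, grid_step = 30)
  expect_equal(sc$clash_score, or$score)
  expect_equal(sc$chi1, or$chi1)
  expect_equal(sc$chi2, or$chi2)
})

test_that("a caged site yields a positive minimum that matches the oracle", {
  s <- vacuum_residue()
  # enclose the residue in a spherical shell of pseudo-atoms at 5 A
  set.seed(3)
  n <- 80
  dirs <- matrix(stats::rnorm(3 * n), n, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  cage <- data.frame(atom_name = "CG", element = "C", res_name = "CAG",
                     res_seq = 500L + seq_len(n), chain_id = "A",
                     x = 5 * dirs[, 1], y = 5 * dirs[, 2], z = 5 * dirs[, 3],
                     het = TRUE, occupancy = 1)
  s <- deerscape:::append_atoms(s, cage)
  site <- site_ref("A", 1)
  sc <- scan_chi12(s, site, grid_step = 45)
  or <- scan_oracle(s, site, grid_step = 45)
  expect_gt(sc$clash_score, 0L)
  expect_equal(sc$clash_score, or$score)
  expect_equal(c(sc$chi1, sc$chi2), c(or$chi1, or$chi2))
})

test_that("the built tag reproduces the requested linker dihedrals", {
  s <- make_two_domain_structure(30, hinge_spec())
  g <- build_tag(s, site_ref("A", 68))
  a <- g$atoms
  expect_equal(measure_dihedral(a$NT3, a$CT4, a$C6, a$N7), 180,
               tolerance = 1e-4)
  expect_equal(measure_dihedral(a$N7, a$C8, a$C9, a$N10), -140,
               tolerance = 1e-4)
  expect_equal(measure_dihedral(a$C8, a$C9, a$N10, a$GD), 70,
               tolerance = 1e-4)
  # chi1/chi2 readback too
  expect_equal(measure_dihedral(a$N, a$CA, a$CB, a$CG), g$dihedrals$chi1,
               tolerance = 1e-4)
  # determinism: bit-identical rebuild
  g2 <- build_tag(s, site_ref("A", 68))
  expect_identical(g$gd_xyz, g2$gd_xyz)
})

test_that("the Calpha-Gd arm length is calibrated near 1 nm and matches the planar oracle for all-trans", {
  s <- make_two_domain_structure(30, hinge_spec())
  g <- build_tag(s, site_ref("A", 68))
  arm <- sqrt(sum((g$atoms$CA - g$gd_xyz)^2)) / 10
  expect_gt(arm, 0.95)
  expect_lt(arm, 1.15)
  # all-trans main chain is planar: 2-D zig-zag oracle for the end-to-end
  # distance along the path CA -> ... -> GD
  tpl <- tag_template()
  dih <- tag_dihedrals(chi1 = 180, chi2 = 180, chi6 = 180, chi9 = 180,
                       chi10 = 180)
  tpl$torsion[!is.na(tpl$slot)] <- 180
  path <- c("CB", "CG", "CD1", "CE1", "CZ", "NT1", "NT2", "NT3", "CT4",
            "C6", "N7", "C8", "C9", "N10", "GD")
  tp <- tpl[match(path, tpl$label), ]
  # zig-zag in the plane: heading turns by +/-(180 - bond angle) alternately
  pos2d <- c(0, 0); heading <- 0; sgn <- 1
  for (i in seq_len(nrow(tp))) {
    if (i > 1) {
      heading <- heading + sgn * (180 - tp$angle[i]) * pi / 180
      sgn <- -sgn
    }
    pos2d <- pos2d + tp$bond[i] * c(cos(heading), sin(heading))
  }
  oracle_len <- sqrt(sum(pos2d^2))
  # the same all-trans chain built in 3-D, with every frozen torsion at 180
  pos <- list(N = deerscape:::site_atom_xyz(s, site_ref("A", 68), "N"),
              CA = deerscape:::site_atom_xyz(s, site_ref("A", 68), "CA"),
              C = deerscape:::site_atom_xyz(s, site_ref("A", 68), "C"))
  tp3 <- tpl[match(path, tpl$label), ]
  for (i in seq_len(nrow(tp3))) {
    row <- tp3[i, ]
    pos[[row$label]] <- place_atom_nerf(pos[[row$p1]], pos[[row$p2]],
                                        pos[[row$p3]], row$bond, row$angle,
                                        180)
  }
  built_len <- sqrt(sum((pos$GD - pos$CB)^2))
  # oracle covers CB..GD (start of the zig-zag is CB at origin)
  oracle_cb_gd <- {
    p <- c(0, 0); h <- 0; sg <- 1; first <- TRUE
    for (i in 2:nrow(tp)) {
      h <- h + sg * (180 - tp$angle[i]) * pi / 180; sg <- -sg
      p <- p + tp$bond[i] * c(cos(h), sin(h))
    }
    sqrt(sum(p^2))
  }
  expect_equal(built_len, oracle_cb_gd, tolerance = 1e-6)
})

test_that("ensembles count conformers, keep vacuum conformers and sweep a circle", {
  s <- vacuum_residue()
  ens <- build_ensemble(s, site_ref("A", 1), chi9_step = 30,
                        dihedrals = tag_dihedrals(chi1 = 60, chi2 = 90))
  expect_length(ens$conformers, 36L)              # 12 x 3
  expect_false(any(ens$excluded))
  # for fixed chi10, Gd positions generated by the chi9 sweep lie on a
  # circle about the C8-C9 axis: equal axis distance, max spread = diameter
  is10 <- vapply(ens$conformers, function(g) g$dihedrals$chi10 == 70,
                 logical(1L))
  # chi10 values are -60/60/180 here; take the first chi10 group instead
  g10 <- vapply(ens$conformers, function(g) g$dihedrals$chi10,
                numeric(1L))
  sel <- ens$conformers[g10 == g10[1]]
  a0 <- sel[[1]]$atoms
  axis_p <- a0$C8; axis_d <- (a0$C9 - a0$C8) / sqrt(sum((a0$C9 - a0$C8)^2))
  axdist <- vapply(sel, function(g) {
    rel <- g$gd_xyz - axis_p
    sqrt(sum((rel - sum(rel * axis_d) * axis_d)^2))
  }, numeric(1L))
  expect_equal(diff(range(axdist)), 0, tolerance = 1e-9)
  gd <- do.call(rbind, lapply(sel, `[[`, "gd_xyz"))
  spread <- max(dist(gd))
  expect_equal(spread, 2 * axdist[1], tolerance = 1e-9)
})

test_that("gd_gd_distance is symmetric and its ensemble stays near the point mode", {
  s <- make_two_domain_structure(30, hinge_spec())
  d_ab <- gd_gd_distance(s, 68, 138, mode = "point")
  d_ba <- gd_gd_distance(s, 138, 68, mode = "point")
  expect_equal(d_ab, d_ba, tolerance = 1e-12)
  pd <- gd_gd_distance(s, 68, 138, mode = "ensemble", chi9_step = 45)
  expect_s3_class(pd, "distance_distribution")
  expect_equal(trapz(pd$r, pd$density), 1, tolerance = 1e-9)
  sm <- summarize_distribution(pd)
  # ensemble mean bounded by the extreme conformer pair distances
  ea <- build_ensemble(s, site_ref("A", 68), chi9_step = 45)
  eb <- build_ensemble(s, site_ref("A", 138), chi9_step = 45)
  xa <- do.call(rbind, lapply(ea$conformers[!ea$excluded], `[[`, "gd_xyz"))
  xb <- do.call(rbind, lapply(eb$conformers[!eb$excluded], `[[`, "gd_xyz"))
  dd <- as.numeric(sqrt(outer(rowSums(xa^2), rowSums(xb^2), "+") -
                          2 * xa %*% t(xb))) / 10
  expect_gte(sm$mean, min(dd) - 0.02)
  expect_lte(sm$mean, max(dd) + 0.02)
  # widening without large modal displacement relative to the point estimate
  expect_lt(abs(sm$peaks[1] - d_ab), 0.3)
})

test_that("trimer distances are symmetric for a C3 trimer and respond to translation as vectors do", {
  base <- make_two_domain_structure(20, hinge_spec())
  rot_z <- function(deg) {
    th <- deg * pi / 180
    matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
           byrow = TRUE)
  }
  shift <- c(60, 0, 0)
  chains <- lapply(0:2, function(k) {
    a <- base$atoms
    m <- as.matrix(a[, c("x", "y", "z")])
    m <- sweep(m, 2L, shift, "+") %*% t(rot_z(120 * k))
    a$x <- m[, 1]; a$y <- m[, 2]; a$z <- m[, 3]
    a$chain_id <- LETTERS[k + 1L]
    a
  })
  tri <- deerscape:::new_structure3d(do.call(rbind, chains),
                                     provenance = "synthetic C3 trimer")
  td <- trimer_distances(tri, 68)
  expect_length(td$distances, 3L)
  expect_equal(max(td$distances) - min(td$distances), 0, tolerance = 1e-9)
  expect_equal(td$mean, mean(td$distances))
  # rigid translation of one chain: distances follow vector arithmetic on
  # the untranslated Gd positions
  gd0 <- lapply(LETTERS[1:3], function(ch)
    build_tag(tri, site_ref(ch, 68))$gd_xyz)
  t3 <- c(0, 0, 7)
  moved <- tri
  selC <- moved$atoms$chain_id == "C"
  moved$atoms$z[selC] <- moved$atoms$z[selC] + t3[3]
  td2 <- trimer_distances(moved, 68)
  exp_ab <- sqrt(sum((gd0[[1]] - gd0[[2]])^2)) / 10
  exp_ac <- sqrt(sum((gd0[[1]] - (gd0[[3]] + t3))^2)) / 10
  exp_bc <- sqrt(sum((gd0[[2]] - (gd0[[3]] + t3))^2)) / 10
  expect_equal(unname(td2$distances[c("A-B", "A-C", "B-C")]),
               c(exp_ab, exp_ac, exp_bc), tolerance = 1e-9)
  # chain-count guard
  expect_error(trimer_distances(base, 68), "3 chains")
})
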