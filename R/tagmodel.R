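# Rigid-rotamer model of the propargyl-DO3A-Gd(III) tag ligated to an
# azidophenylalanine (AzF) site. The chemistry-defining dihedrals follow the
# published convention: chi1/chi2 from a least-clash scan of the aromatic
# ring, chi6 = 180 deg, chi9 = -140 deg and chi10 = 70 deg so that the Gd ion
# is coordinated by the nearest triazole nitrogen. All other torsions of the
# linker are frozen at template values. Bond lengths and angles are idealized
# (aromatic C-C 1.39 A, C-N 1.40 A, idealized triazole, Gd 2.4 A from the
# coordinating nitrogen); the template is calibrated so the Calpha-to-Gd arm
# is ~1.0-1.1 nm.

#' Tag dihedral set
#'
#' @param chi1,chi2 Ring dihedrals in degrees (typically from
#'   [scan_chi12()]).
#' @param chi6,chi9,chi10 Linker dihedrals; defaults are the values used for
#'   single-conformer distance prediction (180, -140, 70 degrees).
#' @return A `tag_dihedrals` object.
#' @export
tag_dihedrals <- function(chi1 = 180, chi2 = 90, chi6 = 180,
                          chi9 = -140, chi10 = 70) {
  v <- c(chi1 = chi1, chi2 = chi2, chi6 = chi6, chi9 = chi9, chi10 = chi10)
  if (any(v <= -180 | v > 180))
    stop("dihedrals must lie in (-180, 180]", call. = FALSE)
  structure(as.list(v), class = "tag_dihedrals")
}

#' Internal-coordinate template of the AzF + triazole + DO3A-Gd arm
#'
#' Each row places one atom by NeRF construction from three previously placed
#' atoms. `slot` names the tunable torsion filling that row (`chi1`, `chi2`,
#' `chi6`, `chi9`, `chi10`); `offset` is added to the slot value (used for the
#' second ortho carbon of the ring); rows without a slot use the frozen
#' `torsion` value.
#'
#' @return Data frame of internal coordinates.
#' @export
tag_template <- function() {
  tpl <- rbind(
    #      label  p1     p2     p3     bond  angle torsion slot    offset
    list("CB",  "N",   "C",   "CA",  1.53, 111.1, -122.6, NA,      0),
    list("CG",  "N",   "CA",  "CB",  1.51, 113.8,     NA, "chi1",  0),
    list("CD1", "CA",  "CB",  "CG",  1.39, 120.8,     NA, "chi2",  0),
    list("CD2", "CA",  "CB",  "CG",  1.39, 120.8,     NA, "chi2", 180),
    list("CE1", "CB",  "CG",  "CD1", 1.39, 120.0,  180.0, NA,      0),
    list("CE2", "CB",  "CG",  "CD2", 1.39, 120.0,  180.0, NA,      0),
    list("CZ",  "CG",  "CD1", "CE1", 1.39, 120.0,    0.0, NA,      0),
    list("NT1", "CD1", "CE1", "CZ",  1.40, 120.0,  180.0, NA,      0),
    list("NT2", "CE1", "CZ",  "NT1", 1.33, 120.5,    0.0, NA,      0),
    list("NT3", "CZ",  "NT1", "NT2", 1.31, 109.0,  180.0, NA,      0),
    list("CT4", "NT1", "NT2", "NT3", 1.35, 109.0,    0.0, NA,      0),
    list("CT5", "NT2", "NT3", "CT4", 1.37, 108.0,    0.0, NA,      0),
    list("C6",  "NT2", "NT3", "CT4", 1.49, 126.0,  180.0, NA,      0),
    list("N7",  "NT3", "CT4", "C6",  1.47, 112.0,     NA, "chi6",  0),
    list("C8",  "CT4", "C6",  "N7",  1.47, 112.0, -100.0, NA,      0),
    list("C9",  "C6",  "N7",  "C8",  1.52, 111.0,   90.0, NA,      0),
    list("N10", "N7",  "C8",  "C9",  1.47, 111.0,     NA, "chi9",  0),
    list("GD",  "C8",  "C9",  "N10", 2.40, 109.0,     NA, "chi10", 0)
  )
  out <- data.frame(label = unlist(tpl[, 1]), p1 = unlist(tpl[, 2]),
                    p2 = unlist(tpl[, 3]), p3 = unlist(tpl[, 4]),
                    bond = unlist(tpl[, 5]), angle = unlist(tpl[, 6]),
                    torsion = unlist(tpl[, 7]), slot = unlist(tpl[, 8]),
                    offset = unlist(tpl[, 9]), stringsAsFactors = FALSE)
  out
}

tag_element <- function(label) {
  ifelse(label == "GD", "GD", substr(label, 1L, 1L))
}

# Build the template atoms from a site's backbone; returns a named list of
# 3-vectors (Angstrom), including the backbone frame atoms.
build_tag_atoms <- function(s, site, dihedrals) {
  site <- as_site_ref(site, s)
  pos <- list(N = site_atom_xyz(s, site, "N"),
              CA = site_atom_xyz(s, site, "CA"),
              C = site_atom_xyz(s, site, "C"))
  tpl <- tag_template()
  for (i in seq_len(nrow(tpl))) {
    row <- tpl[i, ]
    tor <- if (is.na(row$slot)) row$torsion else
      dihedrals[[row$slot]] + row$offset
    tor <- ((tor + 180) %% 360) - 180
    if (tor == -180) tor <- 180
    pos[[row$label]] <- place_atom_nerf(pos[[row$p1]], pos[[row$p2]],
                                        pos[[row$p3]], row$bond, row$angle,
                                        tor)
  }
  pos
}

# Heavy atoms of the structure outside the tag site (clash partners).
clash_environment <- function(s, site) {
  a <- s$atoms
  keep <- a$element != "H" &
    !(a$chain_id == site$chain_id & a$res_seq == site$res_seq & !a$het)
  as.matrix(a[keep, c("x", "y", "z"), drop = FALSE])
}

# Published clash rule: number of probe heavy atoms within `cutoff` of any
# environment heavy atom (2.5 A default; same-residue atoms excluded).
count_clashes <- function(probe_xyz, env_xyz, cutoff = 2.5) {
  if (nrow(env_xyz) == 0L || nrow(probe_xyz) == 0L) return(0L)
  cut2 <- cutoff^2
  n <- 0L
  for (i in seq_len(nrow(probe_xyz))) {
    d2 <- (env_xyz[, 1] - probe_xyz[i, 1])^2 +
      (env_xyz[, 2] - probe_xyz[i, 2])^2 +
      (env_xyz[, 3] - probe_xyz[i, 3])^2
    if (any(d2 < cut2)) n <- n + 1L
  }
  n
}

ring_labels <- c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ")

#' Least-clash scan of the AzF ring dihedrals
#'
#' Builds the aromatic side-chain probe at every (chi1, chi2) pair on a
#' regular grid and counts steric clashes against the rest of the protein.
#' Returns the pair with the fewest clashes; ties are broken by the smallest
#' chi1, then the smallest chi2.
#'
#' @param s A `structure3d`.
#' @param site Tag site.
#' @param grid_step Grid step in degrees; must divide 360 (default 10).
#' @param cutoff Heavy-atom clash cutoff in Angstrom (default 2.5).
#' @return List with `chi1`, `chi2`, `clash_score` and the full score `grid`.
#' @export
scan_chi12 <- function(s, site, grid_step = 10, cutoff = 2.5) {
  if (360 %% grid_step != 0) stop("grid_step must divide 360", call. = FALSE)
  site <- as_site_ref(site, s)
  env <- clash_environment(s, site)
  vals <- seq(-180 + grid_step, 180, by = grid_step)
  grid <- expand.grid(chi2 = vals, chi1 = vals)[, c("chi1", "chi2")]
  score <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    pos <- build_ring_atoms(s, site, grid$chi1[i], grid$chi2[i])
    probe <- do.call(rbind, pos[ring_labels])
    score[i] <- count_clashes(probe, env, cutoff)
  }
  ord <- order(score, grid$chi1, grid$chi2)
  best <- ord[1L]
  list(chi1 = grid$chi1[best], chi2 = grid$chi2[best],
       clash_score = score[best],
       grid = cbind(grid, clash_score = score))
}

# Ring-only build (probe for the chi1/chi2 scan).
build_ring_atoms <- function(s, site, chi1, chi2) {
  pos <- list(N = site_atom_xyz(s, site, "N"),
              CA = site_atom_xyz(s, site, "CA"),
              C = site_atom_xyz(s, site, "C"))
  tpl <- tag_template()
  tpl <- tpl[tpl$label %in% ring_labels, , drop = FALSE]
  dih <- list(chi1 = chi1, chi2 = chi2)
  for (i in seq_len(nrow(tpl))) {
    row <- tpl[i, ]
    tor <- if (is.na(row$slot)) row$torsion else dih[[row$slot]] + row$offset
    pos[[row$label]] <- place_atom_nerf(pos[[row$p1]], pos[[row$p2]],
                                        pos[[row$p3]], row$bond, row$angle,
                                        tor)
  }
  pos
}

#' Build one tag conformer at a site
#'
#' @param s A `structure3d`.
#' @param site Tag site.
#' @param dihedrals A [tag_dihedrals()]. When chi1/chi2 are not supplied use
#'   [scan_chi12()] first.
#' @param cutoff Clash cutoff (Angstrom).
#' @return A `gd_site`: site, Gd position (Angstrom), dihedrals, clash score
#'   and the tag atom coordinates.
#' @export
build_tag <- function(s, site, dihedrals = NULL, cutoff = 2.5) {
  site <- as_site_ref(site, s)
  if (is.null(dihedrals)) {
    sc <- scan_chi12(s, site, cutoff = cutoff)
    dihedrals <- tag_dihedrals(chi1 = sc$chi1, chi2 = sc$chi2)
  }
  pos <- build_tag_atoms(s, site, dihedrals)
  tagl <- tag_template()$label
  probe <- do.call(rbind, pos[tagl])
  cls <- count_clashes(probe, clash_environment(s, site), cutoff)
  structure(list(site = site, gd_xyz = pos$GD, dihedrals = dihedrals,
                 clash_score = cls, atoms = pos),
            class = "gd_site")
}

#' @export
print.gd_site <- function(x, ...) {
  cat(sprintf("<gd_site> %s  Gd at (%.2f, %.2f, %.2f) A, clash score %d\n",
              format(x$site), x$gd_xyz[1], x$gd_xyz[2], x$gd_xyz[3],
              x$clash_score))
  invisible(x)
}

#' Conformer ensemble of the tag at a site
#'
#' Rotamers over a chi9 grid ("any angle") crossed with chi10 in
#' \{-60, 60, 180\} degrees. Conformers whose clash score exceeds `threshold`
#' are flagged excluded; if that removes every conformer the threshold is
#' relaxed to the ensemble minimum with a warning (or an error when
#' `relax = FALSE`).
#'
#' @param s A `structure3d`.
#' @param site Tag site.
#' @param chi9_step Grid step for chi9 in degrees (must divide 360).
#' @param chi10_set Values for chi10 (degrees).
#' @param threshold Maximum allowed clash score (default 0).
#' @param relax Relax the threshold when all conformers are excluded.
#' @param dihedrals Base dihedrals (chi1/chi2/chi6); from [scan_chi12()] when
#'   NULL.
#' @param cutoff Clash cutoff (Angstrom).
#' @return A `gd_ensemble` with one `gd_site` per conformer and an `excluded`
#'   flag vector.
#' @export
build_ensemble <- function(s, site, chi9_step = 10,
                           chi10_set = c(-60, 60, 180), threshold = 0L,
                           relax = TRUE, dihedrals = NULL, cutoff = 2.5) {
  if (360 %% chi9_step != 0) stop("chi9_step must divide 360", call. = FALSE)
  site <- as_site_ref(site, s)
  if (is.null(dihedrals)) {
    sc <- scan_chi12(s, site, cutoff = cutoff)
    dihedrals <- tag_dihedrals(chi1 = sc$chi1, chi2 = sc$chi2)
  }
  chi9_vals <- seq(-180 + chi9_step, 180, by = chi9_step)
  combos <- expand.grid(chi10 = chi10_set, chi9 = chi9_vals)[, c("chi9", "chi10")]
  conformers <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    d <- dihedrals
    d$chi9 <- combos$chi9[i]; d$chi10 <- combos$chi10[i]
    conformers[[i]] <- build_tag(s, site, d, cutoff = cutoff)
  }
  scores <- vapply(conformers, function(g) g$clash_score, integer(1L))
  excluded <- scores > threshold
  if (all(excluded)) {
    if (!relax)
      stop("all tag conformers excluded by the clash threshold; increase it",
           call. = FALSE)
    warning("all conformers exceeded the clash threshold; relaxing to the ensemble minimum",
            call. = FALSE)
    excluded <- scores > min(scores)
  }
  structure(list(site = site, conformers = conformers, excluded = excluded,
                 clash_scores = scores),
            class = "gd_ensemble")
}

#' @export
print.gd_ensemble <- function(x, ...) {
  cat(sprintf("<gd_ensemble> %s: %d conformers (%d excluded)\n",
              format(x$site), length(x$conformers), sum(x$excluded)))
  invisible(x)
}

ensemble_gd_xyz <- function(ens) {
  keep <- !ens$excluded
  do.call(rbind, lapply(ens$conformers[keep], function(g) g$gd_xyz))
}

#' Gd(III)-Gd(III) distance between two tagged sites
#'
#' Point mode places one conformer per site (least-clash chi1/chi2, default
#' linker dihedrals) and returns the single Gd-Gd distance. Ensemble mode
#' builds rotamer ensembles at both sites and histograms all cross-pair
#' distances on a distance grid.
#'
#' @param s A `structure3d`.
#' @param a,b Tag sites.
#' @param mode `"point"` or `"ensemble"`.
#' @param r_grid Distance grid (nm) for ensemble mode.
#' @param ... Passed to [build_tag()] / [build_ensemble()].
#' @return Point mode: distance in nm. Ensemble mode: a
#'   [distance_distribution()].
#' @export
gd_gd_distance <- function(s, a, b, mode = c("point", "ensemble"),
                           r_grid = default_r_grid(), ...) {
  mode <- match.arg(mode)
  a <- as_site_ref(a, s); b <- as_site_ref(b, s)
  if (mode == "point") {
    ga <- build_tag(s, a, ...)
    gb <- build_tag(s, b, ...)
    return(vec_norm(ga$gd_xyz - gb$gd_xyz) / A_PER_NM)
  }
  ea <- build_ensemble(s, a, ...)
  eb <- build_ensemble(s, b, ...)
  xa <- ensemble_gd_xyz(ea); xb <- ensemble_gd_xyz(eb)
  if (is.null(xa) || is.null(xb) || nrow(xa) == 0L || nrow(xb) == 0L)
    stop("empty tag ensemble", call. = FALSE)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * (xa %*% t(xb))
  d_nm <- sqrt(pmax(d2, 0)) / A_PER_NM
  distribution_from_samples(as.numeric(d_nm), r_grid)
}

#' Inter-chain Gd-Gd distances of a homotrimer tagged at one site per chain
#'
#' @param s A `structure3d` with exactly three chains that all contain the
#'   site residue.
#' @param site Residue number (applied per chain) or `site_ref` whose residue
#'   number is used.
#' @param ... Passed to [build_tag()].
#' @return List with the three pairwise distances (nm) and their mean.
#' @export
trimer_distances <- function(s, site, ...) {
  chains <- unique(s$atoms$chain_id[!s$atoms$het])
  if (length(chains) != 3L)
    stop(sprintf("expected exactly 3 chains, found %d", length(chains)),
         call. = FALSE)
  res <- if (inherits(site, "site_ref")) site$res_seq else as.integer(site)
  gd <- lapply(chains, function(ch)
    build_tag(s, site_ref(ch, res), ...)$gd_xyz)
  pairs <- utils::combn(3L, 2L)
  d <- apply(pairs, 2L, function(ix)
    vec_norm(gd[[ix[1]]] - gd[[ix[2]]]) / A_PER_NM)
  names(d) <- apply(pairs, 2L, function(ix)
    paste(chains[ix[1]], chains[ix[2]], sep = "-"))
  list(distances = d, mean = mean(d))
}

#' Append tag atoms to a structure as HETATM records
#'
#' For visual inspection of tagged models.
#'
#' @param s A `structure3d`.
#' @param gd A `gd_site` from [build_tag()].
#' @return Structure with the tag atoms appended (residue name `GDT`).
#' @export
add_tag_atoms <- function(s, gd) {
  labs <- tag_template()$label
  xyz <- do.call(rbind, gd$atoms[labs])
  atoms <- data.frame(atom_name = labs, element = tag_element(labs),
                      res_name = "GDT", res_seq = gd$site$res_seq,
                      chain_id = gd$site$chain_id,
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      het = TRUE, occupancy = 1,
                      stringsAsFactors = FALSE)
  append_atoms(s, atoms)
}
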