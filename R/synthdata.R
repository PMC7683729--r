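# Synthetic inputs with known ground truth: toy two-domain hinge structures
# whose inter-site Calpha-Calpha distance is controlled in closed form,
# Markov state-switching trajectories, and noisy DEER traces generated from
# Gaussian-mixture distance distributions.
#
# Hinge geometry. Site 1 sits at s1 = (r_site, 0, z_site) in domain 1 (held
# fixed); site 2 sits at s2(theta) = R_y(theta) %*% s2_0 with
# s2_0 = (r_site, 0, -z_site), i.e. domain 2 is a rigid body rotated about
# the y axis through the hinge at the origin. The closed-form site distance
# is therefore
#   d(theta) = | s1 - R_y(theta) s2_0 |,
# strictly increasing on [0, 120] degrees for the default geometry
# (d(0) = 2 z_site).

rot_y <- function(theta_deg) {
  th <- theta_deg * pi / 180
  matrix(c(cos(th), 0, sin(th),
           0, 1, 0,
           -sin(th), 0, cos(th)), 3L, 3L, byrow = TRUE)
}

#' Specification of a synthetic two-domain hinge structure
#'
#' @param n_per_domain Residues (Calpha atoms) per domain.
#' @param site1_res,site2_res Tag-site residue numbers; site 1 must fall in
#'   domain 1 (residues 1..n), site 2 in domain 2 (residues n+1..2n).
#' @param r_site,z_site Site placement (Angstrom): radial offset from the
#'   hinge axis and half-separation of the sites at theta = 0.
#' @param jitter Gaussian coordinate noise s.d. (Angstrom).
#' @param seed RNG seed (used only when `jitter > 0`).
#' @return A `hinge_spec`.
#' @export
hinge_spec <- function(n_per_domain = 100L, site1_res = 68L,
                       site2_res = 138L, r_site = 24, z_site = 13,
                       jitter = 0, seed = 1L) {
  stopifnot(site1_res >= 1L, site1_res <= n_per_domain,
            site2_res > n_per_domain, site2_res <= 2L * n_per_domain,
            r_site > 0, z_site > 0, jitter >= 0)
  structure(list(n_per_domain = as.integer(n_per_domain),
                 site1_res = as.integer(site1_res),
                 site2_res = as.integer(site2_res),
                 r_site = r_site, z_site = z_site, jitter = jitter,
                 seed = as.integer(seed)),
            class = "hinge_spec")
}

#' Closed-form inter-site distance of the hinge model
#'
#' @param theta Opening angle in degrees (vectorized), in \[0, 120\].
#' @param spec A [hinge_spec()].
#' @return Distance in nm.
#' @export
hinge_site_distance <- function(theta, spec = hinge_spec()) {
  s1 <- c(spec$r_site, 0, spec$z_site)
  s2 <- c(spec$r_site, 0, -spec$z_site)
  vapply(theta, function(th)
    vec_norm(s1 - rot_y(th) %*% s2) / A_PER_NM, numeric(1L))
}

#' Opening angle achieving a target inter-site distance
#'
#' Numeric inversion of [hinge_site_distance()] on \[0, 120\] degrees;
#' distances outside the achievable range are clamped to the boundary.
#'
#' @param d_nm Target distance (nm, vectorized).
#' @param spec A [hinge_spec()].
#' @return Angle in degrees.
#' @export
hinge_theta_for_distance <- function(d_nm, spec = hinge_spec()) {
  lo <- hinge_site_distance(0, spec)
  hi <- hinge_site_distance(120, spec)
  vapply(d_nm, function(d) {
    if (d <= lo) return(0)
    if (d >= hi) return(120)
    stats::uniroot(function(th) hinge_site_distance(th, spec) - d,
                   c(0, 120), tol = 1e-10)$root
  }, numeric(1L))
}

# Calpha positions of one domain: an ideal helix (rise 1.5 A, radius 2.3 A,
# 100 deg/residue) whose axis runs along y, translated so the site residue's
# Calpha lands exactly on `site_xyz`.
domain_calphas <- function(n, site_idx, site_xyz) {
  i <- seq_len(n)
  h <- cbind(2.3 * cos(i * 100 * pi / 180),
             1.5 * (i - site_idx),
             2.3 * sin(i * 100 * pi / 180))
  sweep(h, 2L, site_xyz - h[site_idx, ], "+")
}

# Backbone N and C flanking a site Calpha such that the template-built CB
# points approximately along the outward direction `ohat`.
site_backbone <- function(ca, ohat) {
  ohat <- ohat / vec_norm(ohat)
  w <- pracma::cross(ohat, c(0, 1, 0))
  if (vec_norm(w) < 1e-6) w <- pracma::cross(ohat, c(1, 0, 0))
  w <- w / vec_norm(w)
  rot_about <- function(v, axis, ang_deg) {
    th <- ang_deg * pi / 180
    v * cos(th) + pracma::cross(axis, v) * sin(th) +
      axis * sum(axis * v) * (1 - cos(th))
  }
  list(N = ca + 1.46 * rot_about(-ohat, w, 55),
       C = ca + 1.52 * rot_about(-ohat, w, -55))
}

#' Generate a synthetic two-domain hinge structure
#'
#' Two rigid Calpha helices joined at a hinge, opened by `theta` degrees.
#' The tag-site residues carry full backbone (N, CA, C) so that the tag
#' model can build on them, with the side-chain direction pointing away from
#' the protein body.
#'
#' @param theta Opening angle in degrees, in \[0, 120\].
#' @param spec A [hinge_spec()].
#' @return A `structure3d` (chain A).
#' @export
make_two_domain_structure <- function(theta, spec = hinge_spec()) {
  stopifnot(theta >= 0, theta <= 120)
  n <- spec$n_per_domain
  s1 <- c(spec$r_site, 0, spec$z_site)
  s2_0 <- c(spec$r_site, 0, -spec$z_site)
  d1 <- domain_calphas(n, spec$site1_res, s1)
  d2 <- domain_calphas(n, spec$site2_res - n, s2_0)
  R <- rot_y(theta)
  d2 <- d2 %*% t(R)
  if (min(pracma::distmat(d1, d2)) < 2)
    stop("domain collision at this opening angle", call. = FALSE)
  bb1 <- site_backbone(d1[spec$site1_res, ],
                       d1[spec$site1_res, ] - colMeans(d1))
  s2_ca <- d2[spec$site2_res - n, ]
  bb2 <- site_backbone(s2_ca, s2_ca - colMeans(d2))
  atom_row <- function(name, elem, res, xyz)
    data.frame(atom_name = name, element = elem, res_name = "ALA",
               res_seq = res, chain_id = "A",
               x = xyz[1], y = xyz[2], z = xyz[3], het = FALSE,
               occupancy = 1, stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(n)) {
    if (i == spec$site1_res) {
      rows[[length(rows) + 1L]] <- atom_row("N", "N", i, bb1$N)
      rows[[length(rows) + 1L]] <- atom_row("CA", "C", i, d1[i, ])
      rows[[length(rows) + 1L]] <- atom_row("C", "C", i, bb1$C)
    } else {
      rows[[length(rows) + 1L]] <- atom_row("CA", "C", i, d1[i, ])
    }
  }
  for (i in seq_len(n)) {
    res <- n + i
    if (res == spec$site2_res) {
      rows[[length(rows) + 1L]] <- atom_row("N", "N", res, bb2$N)
      rows[[length(rows) + 1L]] <- atom_row("CA", "C", res, d2[i, ])
      rows[[length(rows) + 1L]] <- atom_row("C", "C", res, bb2$C)
    } else {
      rows[[length(rows) + 1L]] <- atom_row("CA", "C", res, d2[i, ])
    }
  }
  atoms <- do.call(rbind, rows)
  if (spec$jitter > 0) {
    set.seed(spec$seed)
    atoms$x <- atoms$x + stats::rnorm(nrow(atoms), sd = spec$jitter)
    atoms$y <- atoms$y + stats::rnorm(nrow(atoms), sd = spec$jitter)
    atoms$z <- atoms$z + stats::rnorm(nrow(atoms), sd = spec$jitter)
  }
  new_structure3d(atoms, provenance = sprintf("synthetic hinge (theta=%.1f)",
                                              theta))
}

#' Stationary distribution of a Markov transition matrix
#'
#' @param P Row-stochastic transition matrix.
#' @return Stationary probability vector.
#' @export
stationary_distribution <- function(P) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  if (any(abs(rowSums(P) - 1) > 1e-9))
    stop("transition matrix rows must sum to 1", call. = FALSE)
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

#' Specification of a synthetic state-switching trajectory
#'
#' @param states Data frame with columns `name`, `ca_mean` (nm), `ca_sd`
#'   (nm).
#' @param P Row-stochastic transition matrix, one row per state.
#' @param n_frames Number of frames.
#' @param stride_ns Sampling stride (default 0.1 ns).
#' @param seed RNG seed.
#' @param hinge A [hinge_spec()] providing the coordinate model.
#' @return A `trajectory_spec`.
#' @export
trajectory_spec <- function(states, P, n_frames = 5000L, stride_ns = 0.1,
                            seed = 1L, hinge = hinge_spec()) {
  stopifnot(all(c("name", "ca_mean", "ca_sd") %in% names(states)),
            nrow(states) == nrow(P))
  if (any(abs(rowSums(P) - 1) > 1e-9))
    stop("transition matrix rows must sum to 1", call. = FALSE)
  structure(list(states = states, P = P, n_frames = as.integer(n_frames),
                 stride_ns = stride_ns, seed = as.integer(seed),
                 hinge = hinge),
            class = "trajectory_spec")
}

#' Generate a Markov state-switching trajectory
#'
#' Samples a Markov chain over the conformational states (initialized from
#' its stationary distribution), draws a per-frame inter-site distance as
#' state mean plus Gaussian jitter, and derives the matching hinge opening,
#' coordinates and radius of gyration from the rigid two-domain model.
#'
#' @param spec A [trajectory_spec()].
#' @param coords Also return the Calpha coordinate array (frames x atoms x
#'   3); off by default.
#' @return Data frame with `time_ns`, `state_true`, `ca_nm`, `rg_nm`; the
#'   coordinate array, when requested, is in attribute `coords`.
#' @export
make_trajectory <- function(spec, coords = FALSE) {
  stopifnot(inherits(spec, "trajectory_spec"))
  set.seed(spec$seed)
  ns <- nrow(spec$states)
  pi0 <- stationary_distribution(spec$P)
  st <- integer(spec$n_frames)
  st[1] <- sample.int(ns, 1L, prob = pi0)
  for (f in 2:spec$n_frames)
    st[f] <- sample.int(ns, 1L, prob = spec$P[st[f - 1L], ])
  d <- spec$states$ca_mean[st] +
    stats::rnorm(spec$n_frames, sd = spec$states$ca_sd[st])
  theta <- hinge_theta_for_distance(d, spec$hinge)
  # rigid-body coordinates: domain 1 fixed, domain 2 rotated per frame
  h <- spec$hinge
  s1 <- c(h$r_site, 0, h$z_site); s2_0 <- c(h$r_site, 0, -h$z_site)
  d1 <- domain_calphas(h$n_per_domain, h$site1_res, s1)
  d2_0 <- domain_calphas(h$n_per_domain, h$site2_res - h$n_per_domain, s2_0)
  na <- 2L * h$n_per_domain
  # rg(theta) in closed form: per-domain second moments are rotation
  # invariant, so rg^2 = (S1 + S2)/N - |centroid(theta)|^2
  S1 <- sum(d1^2); S2 <- sum(d2_0^2)
  m1 <- colSums(d1); m2 <- colSums(d2_0)
  rg <- vapply(theta, function(th) {
    ctr <- (m1 + rot_y(th) %*% m2) / na
    sqrt((S1 + S2) / na - sum(ctr^2)) / A_PER_NM
  }, numeric(1L))
  arr <- NULL
  if (coords) {
    arr <- array(NA_real_, c(spec$n_frames, na, 3L))
    for (f in seq_len(spec$n_frames))
      arr[f, , ] <- rbind(d1, d2_0 %*% t(rot_y(theta[f])))
  }
  out <- data.frame(time_ns = (seq_len(spec$n_frames) - 1L) * spec$stride_ns,
                    state_true = spec$states$name[st],
                    ca_nm = hinge_site_distance(theta, spec$hinge),
                    rg_nm = rg,
                    stringsAsFactors = FALSE)
  if (coords) attr(out, "coords") <- arr
  attr(out, "target_ca_nm") <- d
  out
}

#' Ground truth for a synthetic DEER dataset
#'
#' @param means,sds,weights Gaussian-mixture components (nm).
#' @param lambda Modulation depth.
#' @param k,d Background parameters.
#' @param snr Signal-to-noise ratio.
#' @param t_max,dt Trace extent and step (us).
#' @param seed RNG seed for the noise.
#' @param r_grid Distance grid (nm).
#' @return A `deer_ground_truth`.
#' @export
deer_ground_truth <- function(means, sds, weights = rep(1, length(means)),
                              lambda = 0.4, k = 0.1, d = 3, snr = 50,
                              t_max = 4, dt = 0.008, seed = 1L,
                              r_grid = default_r_grid()) {
  stopifnot(all(means > min(r_grid)), all(means < max(r_grid)))
  structure(list(means = means, sds = sds,
                 weights = weights / sum(weights), lambda = lambda, k = k,
                 d = d, snr = snr, t_max = t_max, dt = dt,
                 seed = as.integer(seed), r_grid = r_grid),
            class = "deer_ground_truth")
}

#' Generate a DEER trace together with its generating distribution
#'
#' @param truth A [deer_ground_truth()].
#' @return List with `trace` (a [deer_trace()]) and `truth` (the exact
#'   generating [distance_distribution()]).
#' @export
make_deer_dataset <- function(truth) {
  stopifnot(inherits(truth, "deer_ground_truth"))
  p <- gaussian_mixture(truth$means, truth$sds, truth$weights,
                        truth$r_grid)
  tr <- simulate_trace(p, lambda = truth$lambda, k = truth$k, d = truth$d,
                       snr = truth$snr, t_max = truth$t_max, dt = truth$dt,
                       seed = truth$seed)
  list(trace = tr, truth = p)
}
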