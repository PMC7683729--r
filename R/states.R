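# Classification of trajectory snapshots into closed / open / wide-open
# conformational states from the inter-site Calpha-Calpha distance, PCA
# disambiguation of overlapping windows, and conversion of distance
# distributions into state populations through the modelled Gd-Gd windows.

#' Build a state-definition table
#'
#' @param name State names.
#' @param ca_lo,ca_hi Calpha-Calpha window bounds (nm).
#' @param gd_lo,gd_hi Optional Gd-Gd window bounds (nm).
#' @return A `state_definitions` data frame.
#' @export
state_definitions <- function(name, ca_lo, ca_hi, gd_lo = NA_real_,
                              gd_hi = NA_real_) {
  stopifnot(all(ca_lo < ca_hi))
  if (any(!is.na(gd_lo) & !(gd_lo < gd_hi)))
    stop("gd_lo must be < gd_hi", call. = FALSE)
  out <- data.frame(name = name, ca_lo = ca_lo, ca_hi = ca_hi,
                    gd_lo = gd_lo, gd_hi = gd_hi,
                    stringsAsFactors = FALSE)
  class(out) <- c("state_definitions", "data.frame")
  out
}

#' Built-in per-protein state windows
#'
#' Loads the packaged configuration of Calpha-Calpha and Gd-Gd windows for
#' the studied proteins.
#'
#' @param protein One of the configured protein names, or NULL to list them.
#' @param file Alternative YAML config (per-protein blocks, nm units).
#' @return A `state_definitions` table, or the protein names when
#'   `protein = NULL`.
#' @export
load_state_definitions <- function(protein = NULL,
                                   file = system.file("extdata",
                                                      "state_definitions.yaml",
                                                      package = "deerscape")) {
  cfg <- yaml::read_yaml(file)
  if (is.null(protein)) return(names(cfg))
  if (!protein %in% names(cfg))
    stop(sprintf("unknown protein '%s'; configured: %s", protein,
                 paste(names(cfg), collapse = ", ")), call. = FALSE)
  blk <- cfg[[protein]]
  state_definitions(name = names(blk),
                    ca_lo = vapply(blk, function(b) b$ca[[1]], numeric(1L)),
                    ca_hi = vapply(blk, function(b) b$ca[[2]], numeric(1L)),
                    gd_lo = vapply(blk, function(b) b$gd[[1]], numeric(1L)),
                    gd_hi = vapply(blk, function(b) b$gd[[2]], numeric(1L)))
}

#' Classify snapshots by Calpha-Calpha distance
#'
#' Interval membership is closed on both ends. A distance inside more than
#' one window is `"ambiguous"`; inside none, `"unassigned"`.
#'
#' @param ca_nm Numeric vector of inter-site distances (nm).
#' @param defs A `state_definitions` table.
#' @return Character vector of labels.
#' @export
classify_snapshot <- function(ca_nm, defs) {
  stopifnot(nrow(defs) >= 1L)
  inside <- vapply(seq_len(nrow(defs)), function(i)
    ca_nm >= defs$ca_lo[i] & ca_nm <= defs$ca_hi[i],
    logical(length(ca_nm)))
  inside <- matrix(inside, nrow = length(ca_nm))
  hits <- rowSums(inside)
  lab <- rep("unassigned", length(ca_nm))
  one <- hits == 1L
  lab[one] <- defs$name[apply(inside[one, , drop = FALSE], 1L, which.max)]
  lab[hits > 1L] <- "ambiguous"
  lab
}

#' Least-squares superposition of coordinate frames on a reference subset
#'
#' Rigid (rotation + translation) fit of every frame onto the first frame,
#' using only the atoms in `fit_idx` (e.g. the large domain) to define the
#' fit.
#'
#' @param coords Array `n_frames x n_atoms x 3`.
#' @param fit_idx Atom indices used for the fit (default: all).
#' @return Array of superposed coordinates, same shape.
#' @export
superpose_frames <- function(coords, fit_idx = NULL) {
  stopifnot(length(dim(coords)) == 3L)
  nf <- dim(coords)[1]
  if (is.null(fit_idx)) fit_idx <- seq_len(dim(coords)[2])
  ref <- coords[1, fit_idx, , drop = TRUE]
  ref_ctr <- colMeans(ref)
  refc <- sweep(ref, 2L, ref_ctr)
  out <- coords
  for (f in seq_len(nf)) {
    mob <- coords[f, fit_idx, , drop = TRUE]
    ctr <- colMeans(mob)
    mobc <- sweep(mob, 2L, ctr)
    s <- svd(crossprod(mobc, refc))
    dsign <- sign(det(s$u %*% t(s$v)))
    R <- s$u %*% diag(c(1, 1, dsign)) %*% t(s$v)
    frame <- sweep(coords[f, , , drop = TRUE], 2L, ctr)
    out[f, , ] <- sweep(frame %*% R, 2L, ref_ctr, "+")
  }
  out
}

# Deterministic 1-D 2-means: initialized at the extreme scores.
two_means_1d <- function(x) {
  c1 <- min(x); c2 <- max(x)
  assign <- rep(1L, length(x))
  for (it in 1:100) {
    new_assign <- ifelse(abs(x - c1) <= abs(x - c2), 1L, 2L)
    if (all(new_assign == assign) && it > 1L) break
    assign <- new_assign
    c1 <- mean(x[assign == 1L]); c2 <- mean(x[assign == 2L])
  }
  assign
}

#' PCA disambiguation of frames in overlapping state windows
#'
#' Runs PCA on flattened, superposed Calpha coordinates of the ambiguous
#' frames, splits them along PC1 with a deterministic 2-means, and maps each
#' cluster to the candidate state whose unambiguous mean Calpha-Calpha
#' distance is closest to the cluster mean.
#'
#' @param coords Array `n_frames x n_atoms x 3` of the ambiguous frames,
#'   already superposed on the reference (large) domain (see
#'   [superpose_frames()]).
#' @param ca_nm Calpha-Calpha distance of each ambiguous frame (nm).
#' @param reference_means Named numeric vector: mean Calpha-Calpha distance
#'   of the unambiguously assigned frames of each candidate state.
#' @param var_tol Minimum PC1 variance (nm^2-scale) for a meaningful split.
#' @return Character vector of state labels (or `"ambiguous"` if no split is
#'   supported), with the PCA object in attribute `pca`.
#' @export
pca_disambiguate <- function(coords, ca_nm, reference_means,
                             var_tol = 1e-6) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[1] == length(ca_nm),
            length(reference_means) == 2L, !is.null(names(reference_means)))
  nf <- dim(coords)[1]
  if (nf < 2L) stop("need at least two ambiguous frames", call. = FALSE)
  X <- matrix(coords, nrow = nf)
  pca <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  pc1 <- pca$x[, 1]
  if (stats::var(pc1) < var_tol) {
    warning("PC1 variance below threshold; frames remain ambiguous",
            call. = FALSE)
    out <- rep("ambiguous", nf)
    attr(out, "pca") <- pca
    return(out)
  }
  cl <- two_means_1d(pc1)
  cl_mean <- tapply(ca_nm, cl, mean)
  # assign each cluster to the closer reference state, keeping the two
  # clusters on distinct states
  perms <- list(c(1L, 2L), c(2L, 1L))
  cost <- vapply(perms, function(p)
    sum(abs(cl_mean - reference_means[p])), numeric(1L))
  p <- perms[[which.min(cost)]]
  out <- names(reference_means)[p][cl]
  attr(out, "pca") <- pca
  out
}

#' State populations from classified snapshots
#'
#' @param labels Character labels (from [classify_snapshot()], possibly after
#'   [pca_disambiguate()]).
#' @param defs A `state_definitions` table.
#' @return A `state_populations` object: named fractions over the defined
#'   states plus `ambiguous` and `unassigned` buckets; all fractions sum
#'   to 1.
#' @export
populations_from_trajectory <- function(labels, defs) {
  if (length(labels) == 0L) stop("zero frames", call. = FALSE)
  lv <- c(defs$name, "ambiguous", "unassigned")
  frac <- table(factor(labels, levels = lv)) / length(labels)
  structure(list(fractions = as.numeric(frac), states = lv,
                 n_frames = length(labels)),
            class = "state_populations")
}

#' @export
print.state_populations <- function(x, ...) {
  cat("<state_populations>\n")
  for (i in seq_along(x$states))
    if (x$fractions[i] > 0 || !x$states[i] %in% c("ambiguous", "unassigned"))
      cat(sprintf("  %-10s %.3f\n", x$states[i], x$fractions[i]))
  invisible(x)
}

#' State populations from a Gd-Gd distance distribution
#'
#' Integrates the density over each state's Gd-Gd window. Probability mass in
#' a region covered by several windows is split equally among them; mass
#' outside every window is reported as `unassigned`.
#'
#' @param p A [distance_distribution()].
#' @param defs A `state_definitions` table with Gd windows.
#' @return A `state_populations` object.
#' @export
populations_from_distribution <- function(p, defs) {
  stopifnot(inherits(p, "distance_distribution"))
  if (any(is.na(defs$gd_lo)))
    stop("state definitions lack Gd-Gd windows", call. = FALSE)
  w <- trapz_weights(p$r)
  mass <- w * p$density
  inside <- vapply(seq_len(nrow(defs)), function(i)
    p$r >= defs$gd_lo[i] & p$r <= defs$gd_hi[i],
    logical(length(p$r)))
  inside <- matrix(inside, nrow = length(p$r))
  cover <- rowSums(inside)
  shares <- sweep(inside, 1L, pmax(cover, 1L), "/")
  frac <- as.numeric(crossprod(shares, mass))
  unassigned <- sum(mass[cover == 0L])
  tot <- sum(frac) + unassigned
  structure(list(fractions = c(frac, 0, unassigned) / tot,
                 states = c(defs$name, "ambiguous", "unassigned"),
                 n_frames = NA_integer_),
            class = "state_populations")
}

#' Fraction assigned to one state
#'
#' @param pops A `state_populations`.
#' @param state State name.
#' @return Numeric fraction.
#' @export
population <- function(pops, state) {
  i <- match(state, pops$states)
  if (is.na(i)) stop(sprintf("no state '%s'", state), call. = FALSE)
  pops$fractions[i]
}
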