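# Internal unit convention: coordinates are stored in Angstrom (PDB native);
# every user-facing distance is reported in nm.
A_PER_NM <- 10

#' Residue-numbering offsets for the study's deposited structures
#'
#' Maps PDB accession to the shift that converts deposited residue numbers to
#' the ancestral-alignment numbering used throughout the analysis
#' (paper = PDB + offset).
#'
#' @return Named integer vector of offsets keyed by PDB id.
#' @export
#' @examples
#' numbering_offsets()[["3KBR"]]  # -25
numbering_offsets <- function() {
  c("3KBR" = -25L, "5HPQ" = -11L, "6BQE" = -11L, "5T0W" = -11L,
    "5TUJ" = -11L, "5JOS" = -11L, "6WUP" = -11L)
}

#' Reference to a single residue site
#'
#' @param chain_id Single chain identifier character.
#' @param res_seq Integer residue number (analysis numbering).
#' @return A `site_ref` object.
#' @export
site_ref <- function(chain_id, res_seq) {
  stopifnot(is.character(chain_id), length(chain_id) == 1L, nchar(chain_id) == 1L)
  res_seq <- as.integer(res_seq)
  stopifnot(length(res_seq) == 1L, !is.na(res_seq))
  structure(list(chain_id = chain_id, res_seq = res_seq), class = "site_ref")
}

#' @export
format.site_ref <- function(x, ...) sprintf("%s/%d", x$chain_id, x$res_seq)

#' @export
print.site_ref <- function(x, ...) {
  cat("<site_ref>", format(x), "\n"); invisible(x)
}

as_site_ref <- function(x, s = NULL) {
  if (inherits(x, "site_ref")) return(x)
  if (is.numeric(x) && length(x) == 1L) {
    chain <- if (!is.null(s)) s$atoms$chain_id[1L] else "A"
    return(site_ref(chain, x))
  }
  stop("cannot interpret site reference; supply site_ref() or a residue number",
       call. = FALSE)
}

new_structure3d <- function(atoms, provenance = "unknown",
                            numbering_offset_applied = NULL) {
  s <- structure(list(atoms = atoms, provenance = provenance,
                      numbering_offset_applied = numbering_offset_applied),
                 class = "structure3d")
  validate_structure3d(s)
}

validate_structure3d <- function(s) {
  a <- s$atoms
  need <- c("atom_name", "element", "res_name", "res_seq", "chain_id",
            "x", "y", "z", "het")
  stopifnot(all(need %in% names(a)))
  if (nrow(a) == 0L) stop("structure contains no atoms", call. = FALSE)
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    stop("non-finite atom coordinates", call. = FALSE)
  if (any(a$res_seq != as.integer(a$res_seq)))
    stop("residue numbers must be integer", call. = FALSE)
  key <- paste(a$chain_id, a$res_seq, a$atom_name, a$het)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom) records after altloc filtering",
         call. = FALSE)
  s
}

#' @export
print.structure3d <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<structure3d> %s: %d atoms, %d residues, chains [%s]\n",
              x$provenance, nrow(a),
              length(unique(paste(a$chain_id, a$res_seq))),
              paste(unique(a$chain_id), collapse = ",")))
  if (!is.null(x$numbering_offset_applied))
    cat(sprintf("  numbering offset applied: %+d\n",
                x$numbering_offset_applied))
  invisible(x)
}

# Pre-scan of ATOM/HETATM lines producing the fixed-column errors the parser
# contract requires (bio3d is tolerant and silently repairs these).
prescan_pdb_lines <- function(lines) {
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop(sprintf("malformed PDB record at line %d: shorter than coordinate fields", i),
           call. = FALSE)
    for (fld in list(c(31, 38), c(39, 46), c(47, 54))) {
      v <- suppressWarnings(as.numeric(substr(ln, fld[1], fld[2])))
      if (is.na(v))
        stop(sprintf("malformed PDB record at line %d: non-numeric coordinate field", i),
             call. = FALSE)
    }
    if (is.na(suppressWarnings(as.integer(substr(ln, 23, 26)))))
      stop(sprintf("malformed PDB record at line %d: non-integer residue number", i),
           call. = FALSE)
    if (substr(ln, 27, 27) != " ")
      stop(sprintf("insertion code at line %d: insertion codes are not supported", i),
           call. = FALSE)
  }
  invisible(sum(rec))
}

atoms_from_bio3d <- function(atom) {
  elem <- trimws(atom$elesy)
  # fall back to first letter of the atom name when the element column is blank
  blank <- is.na(elem) | elem == ""
  if (any(blank))
    elem[blank] <- substr(gsub("[0-9 ]", "", atom$elety[blank]), 1L, 1L)
  ch <- atom$chain
  ch[is.na(ch) | ch == ""] <- "A"
  data.frame(atom_name = trimws(atom$elety),
             element = toupper(elem),
             res_name = trimws(atom$resid),
             res_seq = as.integer(atom$resno),
             chain_id = ch,
             x = atom$x, y = atom$y, z = atom$z,
             het = atom$type == "HETATM",
             occupancy = ifelse(is.na(atom$o), 1, atom$o),
             stringsAsFactors = FALSE)
}

# Keep a single altloc per atom: highest occupancy, first on tie.
filter_altloc <- function(atom) {
  alt <- atom$alt
  alt[is.na(alt)] <- ""
  if (all(alt == "")) return(atom)
  key <- paste(atom$chain, atom$resno, atom$elety, atom$type)
  occ <- ifelse(is.na(atom$o), 1, atom$o)
  ord <- order(factor(key, levels = unique(key)), -occ,
               seq_along(key))
  atom <- atom[ord, , drop = FALSE]
  atom[!duplicated(paste(atom$chain, atom$resno, atom$elety, atom$type)), ,
       drop = FALSE]
}

#' Parse a PDB-format structure
#'
#' Reads ATOM/HETATM records (via bio3d) into a `structure3d`. Only the first
#' MODEL is read unless `model` selects another or [parse_pdb_models()] is
#' used. Alternate locations are reduced to the highest-occupancy conformer
#' (first wins on ties); insertion codes are rejected.
#'
#' @param text Character vector of PDB lines, or a single string with
#'   embedded newlines. Ignored when `file` is given.
#' @param file Path to a PDB file.
#' @param model Integer model number to extract (default 1).
#' @param provenance Label recorded on the returned structure.
#' @return A `structure3d` object (coordinates in Angstrom internally).
#' @export
parse_pdb <- function(text = NULL, file = NULL, model = 1L,
                      provenance = NULL) {
  if (is.null(file)) {
    stopifnot(is.character(text))
    if (length(text) == 1L && grepl("\n", text))
      text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
    file <- tempfile(fileext = ".pdb")
    on.exit(unlink(file), add = TRUE)
    writeLines(text, file)
    if (is.null(provenance)) provenance <- "text"
  } else {
    text <- readLines(file, warn = FALSE)
    if (is.null(provenance)) provenance <- basename(file)
  }
  n_rec <- prescan_pdb_lines(text)
  if (n_rec == 0L) stop("no ATOM/HETATM records found (empty structure)",
                        call. = FALSE)
  multi <- sum(grepl("^MODEL", text)) > 1L
  pdb <- bio3d::read.pdb(file, multi = multi, rm.alt = FALSE,
                         verbose = FALSE)
  atom <- filter_altloc(pdb$atom)
  atoms <- atoms_from_bio3d(atom)
  if (multi && model != 1L) {
    xyz <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)
    # bio3d stores atom table for the first model only; atom count matches
    atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  }
  new_structure3d(atoms, provenance = provenance)
}

#' Parse every model of a multi-model PDB file
#'
#' @inheritParams parse_pdb
#' @return List of `structure3d`, one per MODEL block.
#' @export
parse_pdb_models <- function(text = NULL, file = NULL, provenance = NULL) {
  if (is.null(file)) {
    stopifnot(is.character(text))
    if (length(text) == 1L && grepl("\n", text))
      text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  } else {
    text <- readLines(file, warn = FALSE)
  }
  n_models <- max(1L, sum(grepl("^MODEL", text)))
  lapply(seq_len(n_models), function(m)
    parse_pdb(text = text, model = m, provenance = provenance))
}

#' Write a structure to PDB format
#'
#' @param s A `structure3d`.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_pdb <- function(s, file) {
  a <- s$atoms
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(file = file, xyz = xyz,
                   type = ifelse(a$het, "HETATM", "ATOM"),
                   resno = a$res_seq, resid = a$res_name,
                   eleno = seq_len(nrow(a)), elety = a$atom_name,
                   chain = a$chain_id, elesy = a$element,
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)))
  invisible(file)
}

#' Apply the analysis residue-numbering convention
#'
#' Shifts every residue number by `offset` (analysis = deposited + offset).
#' The applied offset is recorded and re-application raises an error.
#'
#' @param s A `structure3d`.
#' @param offset Integer shift. If missing, looked up from `pdb_id`.
#' @param pdb_id PDB accession used to look the shift up in
#'   [numbering_offsets()].
#' @return Renumbered `structure3d`.
#' @export
renumber <- function(s, offset = NULL, pdb_id = NULL) {
  stopifnot(inherits(s, "structure3d"))
  if (!is.null(s$numbering_offset_applied))
    stop("numbering offset already applied to this structure; refusing to re-apply",
         call. = FALSE)
  if (is.null(offset)) {
    if (is.null(pdb_id))
      stop("supply either an explicit offset or a pdb_id", call. = FALSE)
    tbl <- numbering_offsets()
    if (!toupper(pdb_id) %in% names(tbl))
      stop(sprintf("no built-in numbering offset for PDB id '%s'", pdb_id),
           call. = FALSE)
    offset <- tbl[[toupper(pdb_id)]]
  }
  offset <- as.integer(offset)
  s$atoms$res_seq <- s$atoms$res_seq + offset
  s$numbering_offset_applied <- offset
  s
}

site_atoms <- function(s, site) {
  a <- s$atoms
  a[a$chain_id == site$chain_id & a$res_seq == site$res_seq & !a$het, ,
    drop = FALSE]
}

site_atom_xyz <- function(s, site, atom_name) {
  a <- site_atoms(s, site)
  a <- a[a$atom_name == atom_name, , drop = FALSE]
  if (nrow(a) == 0L)
    stop(sprintf("site %s has no %s atom", format(site), atom_name),
         call. = FALSE)
  c(a$x[1L], a$y[1L], a$z[1L])
}

#' Distance between the alpha carbons of two sites
#'
#' @param s A `structure3d`.
#' @param a,b Sites (`site_ref` or bare residue numbers on the first chain).
#' @return Distance in nm.
#' @export
ca_distance <- function(s, a, b) {
  a <- as_site_ref(a, s); b <- as_site_ref(b, s)
  pa <- site_atom_xyz(s, a, "CA")
  pb <- site_atom_xyz(s, b, "CA")
  sqrt(sum((pa - pb)^2)) / A_PER_NM
}

#' Radius of gyration of an atom selection
#'
#' Mass-unweighted root-mean-square distance of the selected atoms from their
#' centroid. The default selection is all non-hydrogen atoms.
#'
#' @param s A `structure3d`.
#' @param selection Predicate `function(atoms) -> logical` over the atom
#'   table, or NULL for the heavy-atom default.
#' @return Radius of gyration in nm.
#' @export
radius_of_gyration <- function(s, selection = NULL) {
  a <- s$atoms
  keep <- if (is.null(selection)) a$element != "H" else selection(a)
  a <- a[keep, , drop = FALSE]
  if (nrow(a) == 0L) stop("empty atom selection", call. = FALSE)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2L, ctr)^2))) / A_PER_NM
}

vec_norm <- function(v) sqrt(sum(v^2))

#' Signed dihedral angle of four points
#'
#' IUPAC sign convention; result in degrees on (-180, 180].
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Angstrom; any consistent unit).
#' @return Angle in degrees.
#' @export
measure_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma::cross(b1, b2)
  n2 <- pracma::cross(b2, b3)
  if (vec_norm(n1) < 1e-9 * vec_norm(b1) * vec_norm(b2) ||
      vec_norm(n2) < 1e-9 * vec_norm(b2) * vec_norm(b3))
    stop("collinear points: dihedral undefined", call. = FALSE)
  m1 <- pracma::cross(n1, b2 / vec_norm(b2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Place an atom from internal coordinates (NeRF construction)
#'
#' Returns the point at distance `bond` from `p3`, forming angle `angle` at
#' `p3` with `p2`, and torsion `torsion` for the chain p1-p2-p3-new.
#'
#' @param p1,p2,p3 Frame points (3-vectors).
#' @param bond Bond length (Angstrom).
#' @param angle Bond angle in degrees, in (0, 180).
#' @param torsion Torsion in degrees.
#' @return 3-vector of the new atom position.
#' @export
place_atom_nerf <- function(p1, p2, p3, bond, angle, torsion) {
  stopifnot(bond > 0, angle > 0, angle < 180)
  bc <- p3 - p2
  if (vec_norm(bc) < 1e-9) stop("degenerate frame: p2 == p3", call. = FALSE)
  bc <- bc / vec_norm(bc)
  ab <- p2 - p1
  n <- pracma::cross(ab, bc)
  if (vec_norm(n) < 1e-9)
    stop("degenerate frame: p1, p2, p3 collinear", call. = FALSE)
  n <- n / vec_norm(n)
  m <- pracma::cross(n, bc)
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          -bond * sin(ang) * sin(tor))
  p3 + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Add atoms to a structure
#'
#' @param s A `structure3d`.
#' @param atoms Data frame with the `structure3d` atom columns.
#' @return Extended `structure3d`.
#' @keywords internal
append_atoms <- function(s, atoms) {
  atoms$occupancy <- if (is.null(atoms$occupancy)) 1 else atoms$occupancy
  s$atoms <- rbind(s$atoms[, names(s$atoms)], atoms[, names(s$atoms)])
  validate_structure3d(s)
}
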