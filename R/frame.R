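# Residue dictionaries used to tag partner identity at read time.
.protein_residues <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "HID", "HIE", "HIP", "CYX", "ASH", "GLH", "LYN"
)
.rna_residues <- c(
  "A", "U", "G", "C", "RA", "RU", "RG", "RC", "ADE", "URA", "GUA", "CYT",
  "A3", "A5", "U3", "U5", "G3", "G5", "C3", "C5"
)
.ion_residues <- c(NA. = "Na", MG = "Mg", CL = "Cl", SOD = "Na", CLA = "Cl")
names(.ion_residues)[1] <- "NA"
.solvent_residues <- c("HOH", "WAT", "TIP3", "SPC", "SOL")

#' Construct an atom table
#'
#' Atoms are stored as a plain data frame, one row per atom, with coordinates
#' in nanometres. This is the common currency of every analysis function.
#'
#' @param serial integer atom serial numbers (unique within a frame).
#' @param name atom name strings (PDB-style, e.g. `"OP1"`, `"CA"`).
#' @param element element symbols (`"C"`, `"N"`, `"O"`, `"P"`, `"Na"`, ...).
#' @param resname residue names (3-letter amino acids, 1-letter nucleotides,
#'   `"NA"`/`"MG"`/`"CL"` for ions).
#' @param resid integer residue numbers, taken verbatim from the source.
#' @param chain chain identifiers.
#' @param x,y,z coordinates, nm.
#' @param tag partner tag, one of `"protein"`, `"rna"`, `"ion"`, `"solvent"`,
#'   `"other"`; computed from `resname` when `NULL`.
#' @param charge formal charge in elementary charges (default 0).
#' @return a data.frame with the columns above.
#' @export
atom_table <- function(serial, name, element, resname, resid,
                       chain = "A", x, y, z, tag = NULL, charge = 0) {
  n <- length(serial)
  if (is.null(tag)) tag <- partner_tag(resname)
  df <- data.frame(
    serial = as.integer(serial),
    name = as.character(name),
    element = as.character(element),
    resname = as.character(resname),
    resid = as.integer(resid),
    chain = rep_len(as.character(chain), n),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    tag = rep_len(as.character(tag), n),
    charge = rep_len(as.numeric(charge), n),
    stringsAsFactors = FALSE
  )
  df
}

#' Assign partner tags from residue names
#'
#' Standard amino acids map to `"protein"`, standard (ribo)nucleotides to
#' `"rna"`, Na/Mg/Cl residues to `"ion"`, water to `"solvent"`; anything else
#' is `"other"` (retained, but excluded from partner selections).
#'
#' @param resname character vector of residue names.
#' @return character vector of tags.
#' @export
partner_tag <- function(resname) {
  rn <- toupper(trimws(resname))
  tag <- rep("other", length(rn))
  tag[rn %in% .protein_residues] <- "protein"
  tag[rn %in% .rna_residues] <- "rna"
  tag[rn %in% names(.ion_residues)] <- "ion"
  tag[rn %in% .solvent_residues] <- "solvent"
  tag
}

#' Ion species from residue name
#'
#' @param resname character vector of residue names.
#' @return character vector: `"Na"`, `"Mg"`, `"Cl"` or `NA` for non-ions.
#' @export
ion_species <- function(resname) {
  rn <- toupper(trimws(resname))
  out <- rep(NA_character_, length(rn))
  hit <- rn %in% names(.ion_residues)
  out[hit] <- unname(.ion_residues[rn[hit]])
  out
}

#' Construct a structure frame
#'
#' A frame is one structural snapshot: an atom table, an optional unit cell,
#' and a time stamp (ps, or a frame index).
#'
#' @param atoms an atom table (see [atom_table()]).
#' @param box an optional [unit_cell()].
#' @param time numeric time in ps (or frame index); default `NA`.
#' @return an object of class `"frame"`.
#' @export
frame <- function(atoms, box = NULL, time = NA_real_) {
  stopifnot(is.data.frame(atoms))
  need <- c("serial", "name", "element", "resname", "resid", "chain",
            "x", "y", "z", "tag", "charge")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(atoms$serial)) stop("atom serial numbers must be unique")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in atom table")
  }
  if (any(!nzchar(atoms$element))) stop("empty element symbol in atom table")
  if (!is.null(box)) stopifnot(inherits(box, "unit_cell"))
  structure(list(atoms = atoms, box = box, time = as.numeric(time)),
            class = "frame")
}

#' @export
print.frame <- function(x, ...) {
  nt <- table(factor(x$atoms$tag,
                     levels = c("protein", "rna", "ion", "solvent", "other")))
  cat(sprintf("<frame> %d atoms (%s)%s%s\n",
              nrow(x$atoms),
              paste(sprintf("%s %d", names(nt)[nt > 0], nt[nt > 0]),
                    collapse = ", "),
              if (!is.null(x$box)) sprintf(", cell %.3g x %.3g x %.3g nm",
                                           x$box$lengths[1], x$box$lengths[2],
                                           x$box$lengths[3]) else "",
              if (is.finite(x$time)) sprintf(", t = %g ps", x$time) else ""))
  invisible(x)
}

#' Coordinates of a frame (optionally restricted to a selection)
#'
#' @param frm a [frame()].
#' @param selection optional [selection] or integer serials.
#' @return numeric matrix, n x 3, nm.
#' @export
coords <- function(frm, selection = NULL) {
  at <- frm$atoms
  if (!is.null(selection)) {
    serials <- if (inherits(selection, "selection")) selection$serials else selection
    at <- at[match(serials, at$serial), , drop = FALSE]
    if (anyNA(at$serial)) stop("selection refers to serials absent from frame")
  }
  m <- as.matrix(at[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' Replace coordinates of (a subset of) a frame
#'
#' @param frm a [frame()].
#' @param xyz n x 3 matrix, nm.
#' @param selection optional selection or serials; defaults to all atoms.
#' @return the modified frame.
#' @export
set_coords <- function(frm, xyz, selection = NULL) {
  idx <- if (is.null(selection)) seq_len(nrow(frm$atoms)) else {
    serials <- if (inherits(selection, "selection")) selection$serials else selection
    match(serials, frm$atoms$serial)
  }
  stopifnot(length(idx) == nrow(xyz))
  frm$atoms[idx, c("x", "y", "z")] <- xyz
  frm
}

#' Construct a unit cell
#'
#' @param lengths cell edge lengths a, b, c in nm.
#' @param angles cell angles alpha, beta, gamma in degrees.
#' @param symops list of symmetry operations, each a list with a 3x3
#'   rotation matrix `R` and a translation `t` in fractional coordinates.
#'   The identity is always included (and prepended if missing).
#' @return an object of class `"unit_cell"`.
#' @export
unit_cell <- function(lengths, angles = c(90, 90, 90),
                      symops = list(list(R = diag(3), t = c(0, 0, 0)))) {
  lengths <- as.numeric(lengths); angles <- as.numeric(angles)
  stopifnot(length(lengths) == 3, length(angles) == 3)
  if (any(lengths <= 0)) stop("unit cell lengths must be positive")
  if (any(angles <= 0 | angles >= 180)) stop("unit cell angles must lie in (0, 180)")
  has_identity <- any(vapply(symops, function(op) {
    isTRUE(all.equal(op$R, diag(3))) && isTRUE(all.equal(as.numeric(op$t), c(0, 0, 0)))
  }, logical(1)))
  if (!has_identity) symops <- c(list(list(R = diag(3), t = c(0, 0, 0))), symops)
  structure(list(lengths = lengths, angles = angles, symops = symops),
            class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("<unit_cell> %.4g x %.4g x %.4g nm, angles %g/%g/%g, %d symop(s)\n",
              x$lengths[1], x$lengths[2], x$lengths[3],
              x$angles[1], x$angles[2], x$angles[3], length(x$symops)))
  invisible(x)
}

#' Construct a trajectory
#'
#' @param frames list of [frame()] objects with identical atom counts and
#'   non-decreasing times.
#' @param metadata free-form description of the source.
#' @return an object of class `"trajectory"`.
#' @export
trajectory <- function(frames, metadata = "") {
  stopifnot(is.list(frames))
  if (length(frames)) {
    counts <- vapply(frames, function(f) nrow(f$atoms), integer(1))
    if (length(unique(counts)) > 1) stop("atom count varies across frames")
    times <- vapply(frames, function(f) f$time, numeric(1))
    known <- times[is.finite(times)]
    if (length(known) > 1 && any(diff(known) < 0)) {
      stop("frame times must be non-decreasing")
    }
  }
  structure(list(frames = frames, metadata = metadata), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frame(s)%s%s\n", length(x$frames),
              if (length(x$frames)) sprintf(", %d atoms", nrow(x$frames[[1]]$atoms)) else "",
              if (nzchar(x$metadata)) paste0(" [", x$metadata, "]") else ""))
  invisible(x)
}

#' @export
length.trajectory <- function(x) length(x$frames)

#' @export
`[[.trajectory` <- function(x, i) x$frames[[i]]

#' Frame times of a trajectory
#' @param traj a [trajectory()].
#' @return numeric vector of times (ps); frame indices where unknown.
#' @export
frame_times <- function(traj) {
  t <- vapply(traj$frames, function(f) f$time, numeric(1))
  if (all(!is.finite(t))) t <- seq_along(traj$frames)
  t
}
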