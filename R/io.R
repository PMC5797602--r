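# Structure I/O. PDB ATOM/HETATM parsing and writing go through bio3d; the
# cell records (CRYST1, REMARK 290 SMTRY) are parsed here because bio3d does
# not expose them. Coordinates are converted Angstrom -> nm at this boundary
# and never anywhere else.

.A_PER_NM <- 10

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pdb", "ent")) return("pdb")
  if (ext == "xyz") return("xyz")
  stop("cannot guess format of '", path, "'; pass format explicitly")
}

#' Read a structure file into a frame
#'
#' Reads a PDB (first MODEL) or XYZ (first block) file. Coordinates are
#' converted from Angstrom to nm; partner tags are assigned from residue
#' dictionaries (standard amino acids -> protein, nucleotides -> rna,
#' NA/MG/CL -> ion, HOH/WAT -> solvent, anything else -> other, with a
#' warning naming the unknown residues).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"xyz"`.
#' @return a [frame()]; PDB files with a CRYST1 record carry a [unit_cell()]
#'   including any REMARK 290 symmetry operations.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "pdb") read_pdb_frame(path, model = 1L) else read_xyz_frame(path)
}

#' Read a multi-model PDB or multi-block XYZ file as a trajectory
#'
#' @inheritParams read_structure
#' @param dt time step between frames, ps (frame times are `0, dt, 2 dt, ...`).
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path, format = c("auto", "pdb", "xyz"), dt = 1) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  frames <- if (format == "pdb") read_pdb_models(path) else read_xyz_blocks(path)
  for (i in seq_along(frames)) frames[[i]]$time <- (i - 1) * dt
  trajectory(frames, metadata = path)
}

validate_pdb_lines <- function(lines) {
  rec <- substr(lines, 1, 6)
  atom_idx <- which(rec %in% c("ATOM  ", "HETATM"))
  for (i in atom_idx) {
    xyz <- suppressWarnings(as.numeric(c(substr(lines[i], 31, 38),
                                         substr(lines[i], 39, 46),
                                         substr(lines[i], 47, 54))))
    if (anyNA(xyz)) stop("malformed ATOM/HETATM record at line ", i, " of PDB file")
  }
  invisible(atom_idx)
}

parse_cryst1 <- function(lines) {
  hit <- grep("^CRYST1", lines, value = TRUE)
  if (!length(hit)) return(NULL)
  l <- hit[1]
  lengths <- as.numeric(c(substr(l, 7, 15), substr(l, 16, 24), substr(l, 25, 33))) / .A_PER_NM
  angles <- as.numeric(c(substr(l, 34, 40), substr(l, 41, 47), substr(l, 48, 54)))
  if (anyNA(lengths) || anyNA(angles)) stop("malformed CRYST1 record")
  list(lengths = lengths, angles = angles)
}

# REMARK 290 SMTRYn records hold cartesian rotations and Angstrom
# translations; convert to the package's fractional representation.
parse_smtry <- function(lines, box_lengths, box_angles) {
  hits <- grep("^REMARK 290\\s+SMTRY", lines, value = TRUE)
  if (!length(hits)) return(NULL)
  fields <- lapply(strsplit(trimws(sub("^REMARK 290", "", hits)), "\\s+"), identity)
  rows <- data.frame(
    axis = as.integer(sub("SMTRY", "", vapply(fields, `[`, "", 1))),
    op = as.integer(vapply(fields, `[`, "", 2)),
    r1 = as.numeric(vapply(fields, `[`, "", 3)),
    r2 = as.numeric(vapply(fields, `[`, "", 4)),
    r3 = as.numeric(vapply(fields, `[`, "", 5)),
    t = as.numeric(vapply(fields, `[`, "", 6))
  )
  cellM <- cell_matrix(unit_cell(box_lengths, box_angles))
  ops <- lapply(sort(unique(rows$op)), function(k) {
    sub <- rows[rows$op == k, ]
    sub <- sub[order(sub$axis), ]
    Rcart <- rbind(c(sub$r1[1], sub$r2[1], sub$r3[1]),
                   c(sub$r1[2], sub$r2[2], sub$r3[2]),
                   c(sub$r1[3], sub$r2[3], sub$r3[3]))
    tcart <- sub$t / .A_PER_NM
    list(R = solve(cellM, Rcart %*% cellM), t = as.numeric(solve(cellM, tcart)))
  })
  ops
}

pdb_to_atoms <- function(pdb, xyz_row) {
  a <- pdb$atom
  el <- trimws(a$elesy)
  noel <- is.na(el) | !nzchar(el)
  if (any(noel)) el[noel] <- gsub("[0-9']", "", trimws(a$elety[noel]))
  el[noel] <- substr(el[noel], 1, 1)
  xyz <- matrix(xyz_row, ncol = 3, byrow = TRUE) / .A_PER_NM
  at <- atom_table(
    serial = a$eleno, name = trimws(a$elety), element = el,
    resname = trimws(a$resid), resid = a$resno,
    chain = ifelse(is.na(a$chain) | !nzchar(a$chain), "A", a$chain),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  )
  unknown <- unique(at$resname[at$tag == "other"])
  if (length(unknown)) {
    warning("unknown residue(s) tagged 'other': ", paste(unknown, collapse = ", "),
            call. = FALSE)
  }
  at
}

read_pdb_box <- function(lines) {
  cr <- parse_cryst1(lines)
  if (is.null(cr)) return(NULL)
  ops <- parse_smtry(lines, cr$lengths, cr$angles)
  if (is.null(ops)) unit_cell(cr$lengths, cr$angles)
  else unit_cell(cr$lengths, cr$angles, symops = ops)
}

read_pdb_frame <- function(path, model = 1L) {
  lines <- readLines(path, warn = FALSE)
  validate_pdb_lines(lines)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[min(model, nrow(pdb$xyz)), ] else as.numeric(pdb$xyz)
  frame(pdb_to_atoms(pdb, xyz), box = read_pdb_box(lines))
}

read_pdb_models <- function(path) {
  lines <- readLines(path, warn = FALSE)
  validate_pdb_lines(lines)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  box <- read_pdb_box(lines)
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz else matrix(as.numeric(pdb$xyz), nrow = 1)
  lapply(seq_len(nrow(xyz)), function(i) frame(pdb_to_atoms(pdb, xyz[i, ]), box = box))
}

read_xyz_blocks <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1L
  while (i <= length(lines) && nzchar(trimws(lines[i]))) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ atom count at line ", i)
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(block), "\\s+")
    bad <- which(vapply(parts, length, integer(1)) < 4)
    if (length(bad)) stop("malformed XYZ record at line ", i + 1 + bad[1])
    el <- vapply(parts, `[`, "", 1)
    xyz <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))),
                  ncol = 3, byrow = TRUE) / .A_PER_NM
    if (anyNA(xyz)) stop("non-numeric XYZ coordinate in block starting at line ", i)
    at <- atom_table(serial = seq_len(n), name = el, element = el,
                     resname = "UNK", resid = seq_len(n),
                     x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], tag = "other")
    frames[[length(frames) + 1L]] <- frame(at)
    i <- i + 2L + n
  }
  if (!length(frames)) stop("no XYZ blocks found in ", path)
  frames
}

read_xyz_frame <- function(path) read_xyz_blocks(path)[[1]]

#' Write a frame (or trajectory) to PDB or XYZ
#'
#' PDB output goes through bio3d; coordinates are converted nm -> Angstrom.
#' Trajectories are written as MODEL/ENDMDL blocks (PDB) or stacked blocks
#' (XYZ).
#'
#' @param x a [frame()] or [trajectory()].
#' @param path output file path.
#' @param format `"auto"`, `"pdb"` or `"xyz"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  frames <- if (inherits(x, "trajectory")) x$frames else list(x)
  if (format == "xyz") {
    con <- file(path, "w")
    on.exit(close(con))
    for (f in frames) {
      at <- f$atoms
      writeLines(c(as.character(nrow(at)), "generated by complexion"), con)
      writeLines(sprintf("%-4s %12.5f %12.5f %12.5f", at$element,
                         at$x * .A_PER_NM, at$y * .A_PER_NM, at$z * .A_PER_NM), con)
    }
    return(invisible(path))
  }
  f1 <- frames[[1]]
  at <- f1$atoms
  xyz_list <- lapply(frames, function(f) as.vector(t(coords(f))) * .A_PER_NM)
  if (length(frames) == 1L) {
    bio3d::write.pdb(file = path, xyz = xyz_list[[1]], resno = at$resid,
                     resid = at$resname, eleno = at$serial, elety = at$name,
                     chain = substr(at$chain, 1, 1), elesy = at$element)
  } else {
    bio3d::write.pdb(file = path, xyz = do.call(rbind, xyz_list),
                     resno = at$resid, resid = at$resname, eleno = at$serial,
                     elety = at$name, chain = substr(at$chain, 1, 1),
                     elesy = at$element)
  }
  if (!is.null(f1$box)) {
    l <- f1$box$lengths * .A_PER_NM
    cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     l[1], l[2], l[3], f1$box$angles[1], f1$box$angles[2],
                     f1$box$angles[3])
    body <- readLines(path, warn = FALSE)
    writeLines(c(cryst, body), path)
  }
  invisible(path)
}
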