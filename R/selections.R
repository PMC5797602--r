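# Named atom selections. Membership is deterministic given the frame's
# partner tags, so every analysis is reproducible from (frame, rule).

.OP_NAMES <- c("OP1", "OP2", "O1P", "O2P")
.OD_OE_NAMES <- c("OD1", "OD2", "OE1", "OE2")
.HYDROGEN <- c("H", "D")

#' Build a named atom selection
#'
#' Rules follow the analysis conventions of protein-RNA ion studies:
#' \describe{
#'   \item{`OP`}{the two non-phosphodiester (free) phosphate oxygens of each
#'     RNA residue (atom names OP1/OP2 or O1P/O2P). Ester oxygens (O3', O5')
#'     are excluded, including at terminal phosphates.}
#'   \item{`OD_OE`}{carboxylate oxygens of aspartate and glutamate side
#'     chains (OD1/OD2/OE1/OE2) on protein residues.}
#'   \item{`nonH`}{all non-hydrogen atoms.}
#'   \item{`protein_all`, `rna_all`}{all atoms of the respective partner.}
#'   \item{`ions`}{ion atoms, optionally restricted by `species`.}
#' }
#' An empty result is returned with a warning, never an error.
#'
#' @param frm a [frame()] with partner tags assigned.
#' @param rule one of `"OP"`, `"OD_OE"`, `"nonH"`, `"protein_all"`,
#'   `"rna_all"`, `"ions"`.
#' @param species for `rule = "ions"`: character vector of species
#'   (`"Na"`, `"Mg"`, `"Cl"`); default all.
#' @param non_hydrogen drop hydrogens from the selection (default `TRUE` for
#'   partner rules, irrelevant for `nonH`).
#' @return an object of class `"selection"`: a list with `name` and `serials`.
#' @export
build_selection <- function(frm, rule = c("OP", "OD_OE", "nonH", "protein_all",
                                          "rna_all", "ions"),
                            species = NULL, non_hydrogen = TRUE) {
  rule <- match.arg(rule)
  at <- frm$atoms
  keep <- switch(rule,
    OP = at$tag == "rna" & toupper(at$name) %in% .OP_NAMES,
    OD_OE = at$tag == "protein" & toupper(at$name) %in% .OD_OE_NAMES &
      at$resname %in% c("ASP", "GLU", "ASH", "GLH"),
    nonH = !(toupper(at$element) %in% .HYDROGEN),
    protein_all = at$tag == "protein",
    rna_all = at$tag == "rna",
    ions = {
      k <- at$tag == "ion"
      if (!is.null(species)) k <- k & ion_species(at$resname) %in% species
      k
    }
  )
  if (rule %in% c("protein_all", "rna_all") && non_hydrogen) {
    keep <- keep & !(toupper(at$element) %in% .HYDROGEN)
  }
  name <- if (rule == "ions" && !is.null(species)) {
    paste0("ions_", paste(species, collapse = "_"))
  } else rule
  if (!any(keep)) {
    warning("selection '", name, "' is empty", call. = FALSE)
  }
  new_selection(name, at$serial[keep])
}

new_selection <- function(name, serials) {
  structure(list(name = name, serials = as.integer(serials)),
            class = "selection")
}

#' @export
print.selection <- function(x, ...) {
  cat(sprintf("<selection> '%s': %d atoms\n", x$name, length(x$serials)))
  invisible(x)
}

#' @export
length.selection <- function(x) length(x$serials)

#' Write a selection as a plain-text serial list
#' @param sel a selection.
#' @param path output path (one serial per line, `#`-comment header).
#' @return `path`, invisibly.
#' @export
write_selection <- function(sel, path) {
  writeLines(c(sprintf("# selection %s (%d atoms)", sel$name, length(sel$serials)),
               as.character(sel$serials)), path)
  invisible(path)
}
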