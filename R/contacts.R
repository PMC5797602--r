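# Protein-RNA coordination-number statistics. CN counts cross pairs of
# non-hydrogen atoms within d0 = 0.5 nm (ties inclusive); CN_n divides by the
# total residue count of both partners, which puts solution snapshots and
# expanded crystal structures on one scale.

#' Contact specification
#'
#' @param d0 distance threshold, nm (default 0.5).
#' @param switching `"sharp"` (Heaviside count) or `"smooth"` (logistic
#'   switch `s(r) = 1/(1 + exp((r - d0)/w))`, which tends to the sharp count
#'   as `w -> 0`).
#' @param smooth_width logistic width `w`, nm (used when `switching =
#'   "smooth"`).
#' @param use_pbc use minimum-image distances when the frame has a box.
#' @return an object of class `"contact_spec"`.
#' @export
contact_spec <- function(d0 = 0.5, switching = c("sharp", "smooth"),
                         smooth_width = 0.01, use_pbc = TRUE) {
  switching <- match.arg(switching)
  if (d0 <= 0) stop("d0 must be positive")
  if (switching == "smooth" && smooth_width <= 0) stop("smooth_width must be positive")
  structure(list(d0 = d0, switching = switching, smooth_width = smooth_width,
                 use_pbc = use_pbc), class = "contact_spec")
}

#' Coordination number between two selections
#'
#' Counts cross pairs (one atom from each selection) with distance at most
#' `spec$d0`; in smooth mode the Heaviside step is replaced by a logistic
#' switch. The two selections must be disjoint: a contact pair must span the
#' two partners.
#'
#' @param frm a [frame()].
#' @param sel_a,sel_b disjoint, non-empty [build_selection()] results (or
#'   integer serial vectors).
#' @param spec a [contact_spec()].
#' @return a number (an integer count in sharp mode).
#' @export
coordination_number <- function(frm, sel_a, sel_b, spec = contact_spec()) {
  sa <- if (inherits(sel_a, "selection")) sel_a$serials else as.integer(sel_a)
  sb <- if (inherits(sel_b, "selection")) sel_b$serials else as.integer(sel_b)
  if (!length(sa) || !length(sb)) stop("both selections must be non-empty")
  if (length(intersect(sa, sb))) {
    stop("selections overlap; contact pairs must span the two partners")
  }
  A <- coords(frm, sa); B <- coords(frm, sb)
  box <- if (spec$use_pbc) frm$box else NULL
  if (spec$switching == "sharp") {
    count_pairs_within(A, B, spec$d0, box)
  } else {
    smooth_pairs_within(A, B, spec$d0, spec$smooth_width, box)
  }
}

count_residues <- function(frm, tag) {
  at <- frm$atoms[frm$atoms$tag == tag, , drop = FALSE]
  if (!nrow(at)) return(0L)
  nrow(unique(at[, c("chain", "resid")]))
}

#' Residue-normalized contact number of a frame
#'
#' Computes `CN` between the non-hydrogen atoms of the protein and RNA
#' partners and normalizes by the total residue count, `CN_n = CN / (n_aa +
#' n_nt)`. Frames carrying a unit cell with more than one symmetry operation
#' are expanded to the full cell first and distances use the cell's periodic
#' boundary conditions; residue counts then refer to the full cell.
#'
#' @param frm a [frame()].
#' @param spec a [contact_spec()].
#' @param n_aa,n_nt residue counts of the two partners; counted from the
#'   (possibly expanded) frame when `NULL`.
#' @param expand expand the unit cell before counting (default: yes, when a
#'   box with >1 symmetry operation is present).
#' @return an object of class `"contact_report"`: a list with `CN`, `CN_n`,
#'   `n_aa`, `n_nt`, `residue_ratio` and `frame_time`.
#' @export
normalized_contact_number <- function(frm, spec = contact_spec(),
                                      n_aa = NULL, n_nt = NULL,
                                      expand = NULL) {
  if (is.null(expand)) {
    expand <- !is.null(frm$box) && length(frm$box$symops) > 1L
  }
  work <- if (expand) expand_unit_cell(frm) else frm
  if (is.null(n_aa)) n_aa <- count_residues(work, "protein")
  if (is.null(n_nt)) n_nt <- count_residues(work, "rna")
  if (n_aa < 1 || n_nt < 1) stop("both partners must contribute >= 1 residue")
  sel_p <- build_selection(work, "protein_all", non_hydrogen = TRUE)
  sel_r <- build_selection(work, "rna_all", non_hydrogen = TRUE)
  cn <- coordination_number(work, sel_p, sel_r, spec)
  structure(list(CN = cn, CN_n = cn / (n_aa + n_nt), n_aa = n_aa, n_nt = n_nt,
                 residue_ratio = n_aa / n_nt, frame_time = frm$time),
            class = "contact_report")
}

#' @export
print.contact_report <- function(x, ...) {
  cat(sprintf("<contact_report> CN = %g, CN_n = %.4g (n_aa %d, n_nt %d, ratio %.3g)\n",
              x$CN, x$CN_n, x$n_aa, x$n_nt, x$residue_ratio))
  invisible(x)
}

#' Residue-ratio survey filter
#'
#' Keeps structures whose protein/RNA residue ratio `n_aa/n_nt` lies in
#' `[ratio_min, ratio_max]` (inclusive on both ends), the window around the
#' 284/40 ~ 7 ratio of a 1:1 protein-aptamer complex.
#'
#' @param entries data frame with columns `id`, `n_aa`, `n_nt`.
#' @param ratio_min,ratio_max inclusive bounds (defaults 3 and 15).
#' @return the input with columns `residue_ratio` and logical `kept` added.
#' @export
survey_filter <- function(entries, ratio_min = 3, ratio_max = 15) {
  stopifnot(all(c("id", "n_aa", "n_nt") %in% names(entries)))
  if (any(entries$n_aa < 1 | entries$n_nt < 1)) stop("residue counts must be >= 1")
  entries$residue_ratio <- entries$n_aa / entries$n_nt
  entries$kept <- entries$residue_ratio >= ratio_min & entries$residue_ratio <= ratio_max
  entries
}

#' Contact time series over a trajectory
#'
#' One [normalized_contact_number()] report per frame, plus the frames at
#' which `CN_n` crosses reference thresholds (the crystallographic survey's
#' minimum 0.002, the protein-aptamer reference 0.02, and the survey maximum
#' 0.07, by default).
#'
#' @param traj a [trajectory()].
#' @param spec a [contact_spec()].
#' @param n_aa,n_nt residue counts (counted from the first frame when `NULL`).
#' @param thresholds numeric vector of reference `CN_n` levels to annotate.
#' @return a data.frame (`time`, `CN`, `CN_n`) of class `"contact_series"`
#'   with a `"crossings"` attribute: data.frame (`threshold`, `frame`,
#'   `direction`) listing every crossing (frame index of the first value on
#'   the new side).
#' @export
contact_timeseries <- function(traj, spec = contact_spec(), n_aa = NULL,
                               n_nt = NULL, thresholds = c(0.002, 0.02, 0.07)) {
  if (!length(traj$frames)) {
    out <- data.frame(time = numeric(0), CN = numeric(0), CN_n = numeric(0))
    attr(out, "crossings") <- data.frame(threshold = numeric(0),
                                         frame = integer(0),
                                         direction = character(0))
    class(out) <- c("contact_series", "data.frame")
    return(out)
  }
  reports <- lapply(traj$frames, normalized_contact_number, spec = spec,
                    n_aa = n_aa, n_nt = n_nt)
  out <- data.frame(time = frame_times(traj),
                    CN = vapply(reports, `[[`, numeric(1), "CN"),
                    CN_n = vapply(reports, `[[`, numeric(1), "CN_n"))
  attr(out, "crossings") <- series_crossings(out$CN_n, thresholds)
  class(out) <- c("contact_series", "data.frame")
  out
}

# Frames at which a series crosses each threshold (first frame on new side).
series_crossings <- function(v, thresholds) {
  rows <- list()
  for (th in thresholds) {
    above <- v >= th
    flip <- which(diff(above) != 0) + 1L
    if (length(flip)) {
      rows[[length(rows) + 1L]] <- data.frame(
        threshold = th, frame = flip,
        direction = ifelse(above[flip], "up", "down"))
    }
  }
  if (!length(rows)) {
    return(data.frame(threshold = numeric(0), frame = integer(0),
                      direction = character(0)))
  }
  do.call(rbind, rows)
}

#' Write a contact (or any time/value) series as TSV
#' @param series a data.frame.
#' @param path output path.
#' @param header comment lines to prepend (each prefixed `#`).
#' @return `path`, invisibly.
#' @export
write_series_tsv <- function(series, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(as.data.frame(series), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
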