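# Inter-partner Lennard-Jones complexation energy: the raw sum of 12-6 pair
# terms over cross pairs only (one atom per partner), so intramolecular and
# 1-4 exclusions never enter. The -50 kcal/mol level marks irreversible
# wrapping in the complexation analysis; -100 kcal/mol marks deep wrapping.

#' Lennard-Jones parameter table
#'
#' Per-class well depths and radii with a combining rule. The bundled
#' [default_lj_table()] carries generic element-class values for synthetic
#' fixtures; production force-field parameters are user-supplied input (see
#' [read_lj_table()]).
#'
#' @param classes data.frame with columns `class`, `epsilon_kcal_mol`,
#'   `sigma_nm`.
#' @param rule `"lorentz_berthelot"` (arithmetic sigma, geometric epsilon)
#'   or `"geometric"` (geometric both).
#' @param cutoff pair cutoff, nm; `Inf` for none. Plain truncation, no
#'   shifting, matching a raw pair-sum report; see `shift`.
#' @param shift if `TRUE`, shift each pair term to zero at the cutoff.
#' @return an object of class `"lj_table"`.
#' @export
lj_table <- function(classes, rule = c("lorentz_berthelot", "geometric"),
                     cutoff = 1.2, shift = FALSE) {
  rule <- match.arg(rule)
  stopifnot(all(c("class", "epsilon_kcal_mol", "sigma_nm") %in% names(classes)))
  if (any(classes$epsilon_kcal_mol < 0)) stop("epsilon must be >= 0")
  if (any(classes$sigma_nm <= 0)) stop("sigma must be positive")
  structure(list(classes = classes, rule = rule, cutoff = cutoff,
                 shift = shift), class = "lj_table")
}

#' Generic Lennard-Jones parameters for synthetic fixtures
#'
#' Element-class epsilon/sigma values of the magnitude typical for heavy
#' atoms in biomolecular force fields; adequate for fixture-scale energetics,
#' not a force-field redistribution.
#'
#' @inheritParams lj_table
#' @return an `"lj_table"` keyed by element symbol.
#' @export
default_lj_table <- function(cutoff = 1.2) {
  lj_table(data.frame(
    class = c("C", "N", "O", "P", "S", "H", "Na", "Mg", "Cl", "CA", "BEAD"),
    epsilon_kcal_mol = c(0.086, 0.17, 0.21, 0.20, 0.25, 0.016,
                         0.0028, 0.875, 0.10, 0.086, 0.10),
    sigma_nm = c(0.340, 0.325, 0.296, 0.374, 0.356, 0.247,
                 0.333, 0.141, 0.440, 0.340, 0.380)
  ), cutoff = cutoff)
}

#' Read a Lennard-Jones parameter table from CSV
#'
#' Expected columns: `class,epsilon_kcal_mol,sigma_nm`.
#'
#' @param path CSV path.
#' @inheritParams lj_table
#' @return an `"lj_table"`.
#' @export
read_lj_table <- function(path, rule = "lorentz_berthelot", cutoff = 1.2) {
  lj_table(utils::read.csv(path, stringsAsFactors = FALSE), rule = rule,
           cutoff = cutoff)
}

# Map atoms to parameter classes: explicit atom-name match first, then
# element symbol. Errors name the unmatched atoms.
lj_class_index <- function(atoms, params) {
  cls <- params$classes$class
  i <- match(atoms$name, cls)
  miss <- is.na(i)
  i[miss] <- match(atoms$element[miss], cls)
  if (anyNA(i)) {
    bad <- unique(paste0(atoms$name, "/", atoms$element)[is.na(i)])
    stop("no Lennard-Jones class for atom(s): ", paste(bad, collapse = ", "))
  }
  i
}

#' Inter-partner Lennard-Jones complexation energy
#'
#' `U = sum over cross pairs of 4 eps_ij [ (sig_ij/r)^12 - (sig_ij/r)^6 ]`,
#' with `i` running over one partner's atoms and `j` over the other's,
#' within the table's cutoff. Symmetric in the two selections by
#' construction.
#'
#' @param frm a [frame()].
#' @param sel_a,sel_b partner selections.
#' @param params an [lj_table()].
#' @return an object of class `"energy_report"`: `U_vdw` (kcal/mol),
#'   `pair_count` (pairs within cutoff), `frame_time`.
#' @export
lj_complexation_energy <- function(frm, sel_a, sel_b,
                                   params = default_lj_table()) {
  at <- frm$atoms
  ia <- match(if (inherits(sel_a, "selection")) sel_a$serials else sel_a, at$serial)
  ib <- match(if (inherits(sel_b, "selection")) sel_b$serials else sel_b, at$serial)
  A <- coords(frm)[ia, , drop = FALSE]
  B <- coords(frm)[ib, , drop = FALSE]
  ca <- lj_class_index(at[ia, ], params)
  cb <- lj_class_index(at[ib, ], params)
  eps <- params$classes$epsilon_kcal_mol
  sig <- params$classes$sigma_nm
  eps_ij <- sqrt(outer(eps[ca], eps[cb]))  # geometric epsilon in both rules
  sig_ij <- if (params$rule == "lorentz_berthelot") {
    outer(sig[ca], sig[cb], "+") / 2
  } else {
    sqrt(outer(sig[ca], sig[cb]))
  }
  D <- pair_dist(A, B, NULL)  # complexation energy: open boundaries
  if (any(D == 0)) stop("overlapping atoms (zero pair distance) between selections")
  within <- D <= params$cutoff
  sr6 <- (sig_ij[within] / D[within])^6
  u <- 4 * eps_ij[within] * (sr6^2 - sr6)
  if (params$shift && is.finite(params$cutoff)) {
    src6 <- (sig_ij[within] / params$cutoff)^6
    u <- u - 4 * eps_ij[within] * (src6^2 - src6)
  }
  structure(list(U_vdw = sum(u), pair_count = sum(within),
                 frame_time = frm$time),
            class = "energy_report")
}

#' @export
print.energy_report <- function(x, ...) {
  cat(sprintf("<energy_report> U_vdw = %.3f kcal/mol over %d pair(s)\n",
              x$U_vdw, x$pair_count))
  invisible(x)
}

#' Lennard-Jones energy time series
#'
#' Per-frame [lj_complexation_energy()] with threshold flags; the defaults
#' mark the irreversible-wrapping (-50 kcal/mol) and deep-wrapping
#' (-100 kcal/mol) levels.
#'
#' @param traj a [trajectory()].
#' @inheritParams lj_complexation_energy
#' @param thresholds energies (kcal/mol) below which frames are flagged.
#' @return data.frame (`time`, `U_vdw`, `pair_count`, one logical
#'   `below_<t>` column per threshold) of class `"energy_series"`.
#' @export
energy_timeseries <- function(traj, sel_a, sel_b, params = default_lj_table(),
                              thresholds = c(-50, -100)) {
  reports <- lapply(traj$frames, lj_complexation_energy, sel_a = sel_a,
                    sel_b = sel_b, params = params)
  out <- data.frame(time = frame_times(traj),
                    U_vdw = vapply(reports, `[[`, numeric(1), "U_vdw"),
                    pair_count = vapply(reports, `[[`, numeric(1), "pair_count"))
  for (th in thresholds) {
    out[[paste0("below_", abs(th))]] <- out$U_vdw < th
  }
  class(out) <- c("energy_series", "data.frame")
  out
}
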