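# Ion-atmosphere accounting. An ion is "adsorbed" by a partner when its
# minimum distance to that partner's selection is within the first
# coordination shell (0.28 nm); within both shells it is a salt bridge and
# contributes half its charge to each partner's ledger; within 3 nm of the
# RNA (default reference) it belongs to the diffuse condensation layer;
# beyond that it is bulk.

#' Ion shell specification
#'
#' @param d0_adsorption first-shell (adsorption) cutoff, nm (default 0.28,
#'   the first peak of the phosphate-oxygen/cation radial distribution
#'   function).
#' @param d_condensation condensation-layer cutoff, nm (default 3).
#' @param charges named numeric vector of ionic charges per species.
#' @param condensation_from measure the condensation layer from the RNA
#'   selection (default) or from either partner.
#' @return an object of class `"shell_spec"`.
#' @export
shell_spec <- function(d0_adsorption = 0.28, d_condensation = 3.0,
                       charges = c(Na = 1, Mg = 2, Cl = -1),
                       condensation_from = c("rna", "either")) {
  if (!(d0_adsorption > 0 && d0_adsorption < d_condensation)) {
    stop("need 0 < d0_adsorption < d_condensation")
  }
  structure(list(d0_adsorption = d0_adsorption,
                 d_condensation = d_condensation,
                 charges = charges,
                 condensation_from = match.arg(condensation_from)),
            class = "shell_spec")
}

#' Classify ions into adsorption/condensation shells
#'
#' Assigns every ion of the frame to exactly one of `protein_only`,
#' `rna_only`, `bridging` (within the first shell of both partners),
#' `condensed`, or `bulk`, from its minimum distances to the two partner
#' selections.
#'
#' @param frm a [frame()].
#' @param sel_protein,sel_rna partner selections (typically the O-atom
#'   selections `OD_OE` and `OP`, or the full non-H partners). One of the
#'   two may be empty (single-partner systems, e.g. the free RNA): distances
#'   to an empty selection are infinite.
#' @param shells a [shell_spec()].
#' @param ions optional ion selection; defaults to all ion-tagged atoms.
#' @return an object of class `"ion_inventory"`: list with `assignments`
#'   (per-ion data.frame: `serial`, `species`, `d_protein`, `d_rna`,
#'   `assignment`) and `counts` (per-species data.frame with exclusive
#'   shell counts, `n1_protein`/`n1_rna` totals including bridges, condensed
#'   and bulk).
#' @export
classify_ions <- function(frm, sel_protein, sel_rna, shells = shell_spec(),
                          ions = NULL) {
  if (is.null(ions)) ions <- build_selection(frm, "ions")
  if (!length(sel_protein$serials) && !length(sel_rna$serials)) {
    stop("at least one partner selection must be non-empty")
  }
  at <- frm$atoms
  idx <- match(ions$serials, at$serial)
  species <- ion_species(at$resname[idx])
  species[is.na(species)] <- at$element[idx][is.na(species)]
  unknown <- setdiff(unique(species), names(shells$charges))
  if (length(unknown)) {
    stop("no charge entry for ion species: ", paste(unknown, collapse = ", "))
  }
  P <- coords(frm, ions)
  d_p <- min_dist_to(P, coords(frm, sel_protein), frm$box)
  d_r <- min_dist_to(P, coords(frm, sel_rna), frm$box)
  in_p <- d_p <= shells$d0_adsorption
  in_r <- d_r <= shells$d0_adsorption
  d_cond <- if (shells$condensation_from == "rna") d_r else pmin(d_p, d_r)
  assignment <- ifelse(in_p & in_r, "bridging",
                ifelse(in_p, "protein_only",
                ifelse(in_r, "rna_only",
                ifelse(d_cond <= shells$d_condensation, "condensed", "bulk"))))
  assignments <- data.frame(serial = ions$serials, species = species,
                            d_protein = d_p, d_rna = d_r,
                            assignment = assignment,
                            stringsAsFactors = FALSE)
  new_ion_inventory(assignments, shells)
}

.ASSIGNMENT_LEVELS <- c("protein_only", "rna_only", "bridging", "condensed", "bulk")

new_ion_inventory <- function(assignments, shells) {
  sp <- sort(unique(assignments$species))
  tab <- table(factor(assignments$species, levels = sp),
               factor(assignments$assignment, levels = .ASSIGNMENT_LEVELS))
  counts <- data.frame(species = sp,
                       protein_only = as.integer(tab[, "protein_only"]),
                       rna_only = as.integer(tab[, "rna_only"]),
                       bridging = as.integer(tab[, "bridging"]),
                       condensed = as.integer(tab[, "condensed"]),
                       bulk = as.integer(tab[, "bulk"]),
                       stringsAsFactors = FALSE)
  counts$n1_protein <- counts$protein_only + counts$bridging
  counts$n1_rna <- counts$rna_only + counts$bridging
  structure(list(assignments = assignments, counts = counts, shells = shells),
            class = "ion_inventory")
}

#' Construct an ion inventory from counts
#'
#' For charge bookkeeping from tabulated counts (no geometry), e.g. when the
#' shell occupancies come from an external analysis.
#'
#' @param species character vector.
#' @param protein_only,rna_only,bridging,condensed,bulk integer counts per
#'   species (recycled).
#' @param shells a [shell_spec()] (supplies the charges).
#' @return an `"ion_inventory"` (with per-ion assignments synthesized).
#' @export
manual_inventory <- function(species, protein_only = 0, rna_only = 0,
                             bridging = 0, condensed = 0, bulk = 0,
                             shells = shell_spec()) {
  n <- length(species)
  df <- data.frame(species = species,
                   protein_only = rep_len(protein_only, n),
                   rna_only = rep_len(rna_only, n),
                   bridging = rep_len(bridging, n),
                   condensed = rep_len(condensed, n),
                   bulk = rep_len(bulk, n))
  rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    counts <- unlist(df[i, .ASSIGNMENT_LEVELS])
    if (sum(counts) == 0) return(NULL)
    data.frame(serial = NA_integer_, species = df$species[i],
               d_protein = NA_real_, d_rna = NA_real_,
               assignment = rep(.ASSIGNMENT_LEVELS, counts),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(serial = integer(0), species = character(0),
                       d_protein = numeric(0), d_rna = numeric(0),
                       assignment = character(0), stringsAsFactors = FALSE)
  }
  rows$serial <- seq_len(nrow(rows))
  new_ion_inventory(rows, shells)
}

#' @export
print.ion_inventory <- function(x, ...) {
  cat("<ion_inventory>\n")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Adsorption-corrected charge ledger
#'
#' Adds the charges of first-shell ions to the bare partner charges:
#' exclusively adsorbed ions contribute their full charge to their partner,
#' salt-bridging ions contribute half to each partner (which conserves total
#' charge exactly). The screening percentage reports the magnitude of the
#' residual total charge as a percentage of the bare total.
#'
#' @param inventory an [classify_ions()] / [manual_inventory()] result.
#' @param bare named numeric `c(protein = ..., rna = ...)` bare charges (a
#'   [bare_charges()] result works).
#' @return an object of class `"charge_ledger"`: `Q_a_protein`, `Q_a_rna`
#'   (synonyms `Q_eff_*`), `bare_total`, `screening_percent` (rounded to the
#'   nearest integer) and `screening_percent_raw`.
#' @export
charge_ledger <- function(inventory, bare) {
  stopifnot(inherits(inventory, "ion_inventory"))
  qp <- unname(bare["protein"]); qr <- unname(bare["rna"])
  if (is.na(qp) || is.na(qr)) stop("bare must carry 'protein' and 'rna' entries")
  ch <- inventory$shells$charges
  cnt <- inventory$counts
  z <- ch[cnt$species]
  Qp <- qp + sum(z * cnt$protein_only) + 0.5 * sum(z * cnt$bridging)
  Qr <- qr + sum(z * cnt$rna_only) + 0.5 * sum(z * cnt$bridging)
  structure(list(Q_a_protein = Qp, Q_a_rna = Qr,
                 Q_eff_protein = Qp, Q_eff_rna = Qr,
                 bare_total = qp + qr,
                 screening_percent_raw = 100 * abs(Qp + Qr) / abs(qp + qr),
                 screening_percent = round(100 * abs(Qp + Qr) / abs(qp + qr))),
            class = "charge_ledger")
}

#' @export
print.charge_ledger <- function(x, ...) {
  cat(sprintf("<charge_ledger> Q_a(protein) %+.2f, Q_a(RNA) %+.2f; residual %+.2f = %d%% of bare %+.0f\n",
              x$Q_a_protein, x$Q_a_rna, x$Q_a_protein + x$Q_a_rna,
              x$screening_percent, x$bare_total))
  invisible(x)
}

#' Residual-charge (screening) percentage from effective charges
#'
#' @param q_protein,q_rna effective partner charges.
#' @param bare_total total bare charge of the complex.
#' @return integer-rounded percentage `100 |q_protein + q_rna| / |bare_total|`.
#' @export
screening_percent <- function(q_protein, q_rna, bare_total) {
  round(100 * abs(q_protein + q_rna) / abs(bare_total))
}

#' Radial distribution function between two selections
#'
#' Histograms cross-pair distances and normalizes by the ideal-gas
#' expectation. Under periodic boundaries the pair density is
#' `n_a n_b / V_cell` and `r_max` must not exceed half the shortest box
#' length. Without a box, the pair density is taken over the bounding sphere
#' of the two selections (radius `max pairwise extent / 2 + r_max`), a
#' documented open-boundary convention.
#'
#' @param x a [frame()] or [trajectory()] (frames are averaged).
#' @param sel_a,sel_b selections.
#' @param bin_width bin width, nm.
#' @param r_max histogram range, nm.
#' @return an object of class `"rdf"`: data.frame with bin centers `r` and
#'   `g`.
#' @export
rdf <- function(x, sel_a, sel_b, bin_width = 0.01, r_max = 1.5) {
  if (bin_width <= 0) stop("bin_width must be positive")
  frames <- if (inherits(x, "trajectory")) x$frames else list(x)
  if (!length(frames)) stop("need at least one frame")
  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, r_max)
  counts <- numeric(length(edges) - 1L)
  norm <- numeric(length(edges) - 1L)
  shell_vol <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  for (f in frames) {
    A <- coords(f, sel_a); B <- coords(f, sel_b)
    if (!nrow(A) || !nrow(B)) next
    if (!is.null(f$box)) {
      if (r_max > min(f$box$lengths) / 2) {
        stop("r_max exceeds half the shortest box length")
      }
      V <- cell_volume(f$box)
      d <- pair_dists_upto(A, B, r_max, f$box)
    } else {
      ALL <- rbind(A, B)
      ctr <- colMeans(ALL)
      Rb <- max(sqrt(rowSums(sweep(ALL, 2, ctr)^2))) + r_max
      V <- 4 / 3 * pi * Rb^3
      d <- pair_dists_upto(A, B, r_max, NULL)
    }
    h <- graphics::hist(d, breaks = edges, plot = FALSE)$counts
    counts <- counts + h
    norm <- norm + nrow(A) * nrow(B) / V * shell_vol
  }
  g <- ifelse(norm > 0, counts / norm, 0)
  out <- data.frame(r = (edges[-1] + edges[-length(edges)]) / 2, g = g)
  class(out) <- c("rdf", "data.frame")
  out
}

#' First-peak calibration of the adsorption cutoff
#'
#' Returns the radius of the first interior local maximum of `g(r)`; this is
#' how the 0.28 nm first-shell cutoff is read off the phosphate-oxygen/cation
#' distribution. If `g` is monotone (no interior peak) the global maximum is
#' returned with a warning.
#'
#' @param g an [rdf()] result (or data.frame with `r`, `g`), >= 3 bins.
#' @return first-peak radius, nm.
#' @export
calibrate_d0 <- function(g) {
  stopifnot(nrow(g) >= 3)
  v <- g$g
  for (i in 2:(length(v) - 1L)) {
    if (v[i] > v[i - 1L] && v[i] >= v[i + 1L]) return(g$r[i])
  }
  warning("no interior peak in g(r); returning global maximum", call. = FALSE)
  g$r[which.max(v)]
}

#' Per-frame ion inventories with windowed statistics
#'
#' Runs [classify_ions()] on every frame and summarizes shell occupancies as
#' mean and standard deviation over windows of `window` frames (a window
#' longer than the trajectory collapses, with a warning, to one
#' whole-trajectory window).
#'
#' @param traj a [trajectory()].
#' @inheritParams classify_ions
#' @param window window length in frames; `NULL` for one window.
#' @return an object of class `"inventory_series"`: list with `series`
#'   (long-format data.frame: `frame`, `time`, `species`, `assignment`,
#'   `count`) and `window_stats` (`window`, `species`, `assignment`, `mean`,
#'   `sd`).
#' @export
inventory_timeseries <- function(traj, sel_protein, sel_rna,
                                 shells = shell_spec(), ions = NULL,
                                 window = NULL) {
  nf <- length(traj$frames)
  if (!nf) stop("empty trajectory")
  if (is.null(window)) window <- nf
  if (window > nf) {
    warning("window longer than trajectory; using one whole-trajectory window",
            call. = FALSE)
    window <- nf
  }
  times <- frame_times(traj)
  rows <- list()
  for (i in seq_len(nf)) {
    inv <- classify_ions(traj$frames[[i]], sel_protein, sel_rna, shells, ions)
    cnt <- inv$counts
    for (lev in .ASSIGNMENT_LEVELS) {
      rows[[length(rows) + 1L]] <- data.frame(
        frame = i, time = times[i], species = cnt$species,
        assignment = lev, count = cnt[[lev]], stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      frame = i, time = times[i], species = cnt$species,
      assignment = "n1_rna", count = cnt$n1_rna, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      frame = i, time = times[i], species = cnt$species,
      assignment = "n1_protein", count = cnt$n1_protein, stringsAsFactors = FALSE)
  }
  series <- do.call(rbind, rows)
  series$window <- (series$frame - 1L) %/% window + 1L
  agg <- stats::aggregate(count ~ window + species + assignment, data = series,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
  window_stats <- data.frame(window = agg$window, species = agg$species,
                             assignment = agg$assignment,
                             mean = agg$count[, "mean"],
                             sd = ifelse(is.na(agg$count[, "sd"]), 0,
                                         agg$count[, "sd"]))
  structure(list(series = series[, c("frame", "time", "species",
                                     "assignment", "count")],
                 window_stats = window_stats),
            class = "inventory_series")
}

#' @export
print.inventory_series <- function(x, ...) {
  cat(sprintf("<inventory_series> %d frame(s), %d species\n",
              max(x$series$frame), length(unique(x$series$species))))
  invisible(x)
}
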