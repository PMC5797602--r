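# Structural metrics: Kabsch-superposed RMSD, radius of gyration,
# Shrake-Rupley solvent-accessible surface area, and the dimensionless
# assembly-extent R (lower = tighter wrapping of the protein around the RNA).

#' Radius of gyration
#'
#' Mass-unweighted Rg about the centroid of the selected atoms.
#'
#' @param frm a [frame()].
#' @param selection optional selection (default: all atoms).
#' @return Rg, nm.
#' @export
radius_of_gyration <- function(frm, selection = NULL) {
  X <- coords(frm, selection)
  if (!nrow(X)) stop("empty selection")
  ctr <- colMeans(X)
  sqrt(mean(rowSums(sweep(X, 2, ctr)^2)))
}

# Optimal rotation (Kabsch, reflections excluded) aligning P onto Q after
# centering; both n x 3.
kabsch_rotation <- function(P, Q) {
  H <- crossprod(P, Q)
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' RMSD after optimal rigid superposition
#'
#' Minimum mass-unweighted root-mean-square deviation between matched atom
#' sets, after removing the optimal rigid rotation + translation (orthogonal
#' Procrustes with reflections excluded).
#'
#' @param frm a [frame()].
#' @param reference a [frame()] with a matching selection.
#' @param selection selection applied to both frames (default: all atoms;
#'   atom order defines the correspondence).
#' @param fit superpose before measuring (default `TRUE`).
#' @return RMSD, nm.
#' @export
rmsd <- function(frm, reference, selection = NULL, fit = TRUE) {
  P <- coords(frm, selection)
  Q <- coords(reference, selection)
  if (nrow(P) != nrow(Q)) stop("selections differ in atom count")
  if (fit) {
    P <- sweep(P, 2, colMeans(P))
    Q <- sweep(Q, 2, colMeans(Q))
    P <- P %*% kabsch_rotation(P, Q)
  }
  sqrt(mean(rowSums((P - Q)^2)))
}

# Built-in van der Waals radii (nm); override via the `radii` argument of
# sasa() or a CSV (element,radius_nm) through read_radii().
.vdw_radii <- c(C = 0.170, N = 0.155, O = 0.152, P = 0.180, S = 0.180,
                H = 0.120, Na = 0.227, Mg = 0.173, Cl = 0.175)

#' Read an element-radius override table
#' @param path CSV with columns `element`, `radius_nm`.
#' @return named numeric vector of radii, nm.
#' @export
read_radii <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(df$radius_nm, df$element)
}

# Deterministic quasi-uniform points on the unit sphere (golden-spiral
# lattice) for the Shrake-Rupley estimate.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe of radius `probe` over the selected atoms: each atom's
#' extended sphere (vdW radius + probe) is sampled with a deterministic
#' spiral lattice of `n_points` points, and points buried inside any other
#' selected atom's extended sphere are discarded.
#'
#' @param frm a [frame()].
#' @param selection atoms whose collective surface is measured (default:
#'   all atoms; occluders are the selected atoms themselves).
#' @param probe probe radius, nm (default 0.14, a water molecule).
#' @param n_points sphere sample points per atom (>= 50; default 960).
#' @param radii named per-element radius table, nm.
#' @return total accessible area, nm^2.
#' @export
sasa <- function(frm, selection = NULL, probe = 0.14, n_points = 960,
                 radii = .vdw_radii) {
  if (n_points < 50) stop("n_points must be >= 50")
  at <- frm$atoms
  if (!is.null(selection)) {
    serials <- if (inherits(selection, "selection")) selection$serials else selection
    at <- at[match(serials, at$serial), , drop = FALSE]
  }
  r <- radii[at$element]
  if (anyNA(r)) {
    stop("no radius for element(s): ",
         paste(unique(at$element[is.na(r)]), collapse = ", "))
  }
  r <- unname(r) + probe
  X <- as.matrix(at[, c("x", "y", "z")])
  pts <- sphere_points(n_points)
  total <- 0
  for (i in seq_len(nrow(X))) {
    d2 <- rowSums(sweep(X, 2, X[i, ])^2)
    nb <- which(d2 < (r + r[i])^2 & seq_along(d2) != i)
    surf <- sweep(pts * r[i], 2, X[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj <- rowSums(sweep(surf[acc, , drop = FALSE], 2, X[j, ])^2)
      acc[acc] <- dj >= r[j]^2
    }
    total <- total + 4 * pi * r[i]^2 * mean(acc)
  }
  total
}

#' Assembly extent of a two-partner complex
#'
#' A dimensionless wrapping readout. The default `"rg_ratio"` definition is
#' `R = Rg(union) / (Rg(protein) + Rg(rna))`: far-separated partners give
#' R > 1 (the union's Rg is dominated by the separation), coincident
#' identical partners give 0.5, and R decreases monotonically as the protein
#' wraps the RNA. Alternative definitions plug in through `method` as a
#' function `(frame, sel_protein, sel_rna) -> number`.
#'
#' @param frm a [frame()].
#' @param sel_protein,sel_rna non-empty partner selections.
#' @param method `"rg_ratio"` or a function implementing another definition.
#' @return R, dimensionless (> 0).
#' @export
assembly_extent <- function(frm, sel_protein, sel_rna, method = "rg_ratio") {
  if (is.function(method)) return(method(frm, sel_protein, sel_rna))
  stopifnot(identical(method, "rg_ratio"))
  if (!length(sel_protein$serials) || !length(sel_rna$serials)) {
    stop("partner selections must be non-empty")
  }
  both <- new_selection("union", c(sel_protein$serials, sel_rna$serials))
  radius_of_gyration(frm, both) /
    (radius_of_gyration(frm, sel_protein) + radius_of_gyration(frm, sel_rna))
}

#' Structural-metric time series
#'
#' Evaluates one of the structural metrics on every frame.
#'
#' @param traj a [trajectory()].
#' @param metric `"rmsd_nm"`, `"rg_nm"`, `"sasa_nm2"` or `"assembly_R"`.
#' @param selection selection for rmsd/rg/sasa.
#' @param reference reference frame for rmsd (default: first frame).
#' @param sel_protein,sel_rna partner selections for `assembly_R`.
#' @param ... passed to the metric function ([sasa()] options etc.).
#' @return data.frame (`time`, `value`) of class `"metric_series"` with a
#'   `"metric"` attribute.
#' @export
metric_timeseries <- function(traj, metric = c("rmsd_nm", "rg_nm", "sasa_nm2",
                                               "assembly_R"),
                              selection = NULL, reference = NULL,
                              sel_protein = NULL, sel_rna = NULL, ...) {
  metric <- match.arg(metric)
  if (metric == "rmsd_nm" && is.null(reference)) reference <- traj$frames[[1]]
  vals <- vapply(traj$frames, function(f) {
    switch(metric,
           rmsd_nm = rmsd(f, reference, selection),
           rg_nm = radius_of_gyration(f, selection),
           sasa_nm2 = sasa(f, selection, ...),
           assembly_R = assembly_extent(f, sel_protein, sel_rna))
  }, numeric(1))
  out <- data.frame(time = frame_times(traj), value = vals)
  attr(out, "metric") <- metric
  class(out) <- c("metric_series", "data.frame")
  out
}
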