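# Synthetic fixtures with planted statistics. Every generator is
# seed-deterministic, and every planted quantity (adsorbed/condensed ion
# counts, contact counts, survey pair counts, charges) is recoverable
# exactly by the corresponding analysis function; the closed loop is the
# package's central test harness. Scale is deliberately desk-sized (a few
# thousand atoms, no solvent): explicit water is irrelevant to every
# statistic computed here.

#' Charged-residue composition of the 284-residue disordered chain
#'
#' 47 D, 24 E, 18 K, 9 R: net charge -44 at physiological pH.
#'
#' @return a [composition_table()].
#' @export
opn_composition <- function() composition_table(D = 47, E = 24, K = 18, R = 9)

#' Generate a toy stem-loop polyanion
#'
#' A hairpin backbone curve (two antiparallel strands capped by a loop) with
#' one phosphate per residue except the 5' terminus; each phosphate carries
#' a -1 formal charge and two free (non-phosphodiester) oxygens named
#' OP1/OP2, so an `n_nt`-mer carries net charge `-(n_nt - 1)` and
#' `2 (n_nt - 1)` OP atoms. Base identity is geometric filler (no base
#' atoms).
#'
#' @param n_nt number of nucleotides (>= 4).
#' @param seed RNG seed (controls small coordinate jitter only; topology is
#'   seed-independent).
#' @param jitter_sd coordinate jitter, nm.
#' @return a [frame()] tagged `rna`.
#' @export
make_stemloop <- function(n_nt = 40, seed = 1L, jitter_sd = 0.01) {
  if (n_nt < 4) stop("n_nt must be >= 4")
  set.seed(seed)
  spacing <- 0.6
  n_loop <- max(2L, min(4L, n_nt - 2L))
  n1 <- ceiling((n_nt - n_loop) / 2)
  n2 <- n_nt - n_loop - n1
  z_top <- (n1 - 1) * spacing
  path <- rbind(
    cbind(0, 0, (seq_len(n1) - 1) * spacing),
    t(vapply(seq_len(n_loop), function(j) {
      phi <- pi - j * pi / (n_loop + 1)
      c(0.6 + 0.6 * cos(phi), 0, z_top + 0.6 * sin(phi))
    }, numeric(3))),
    cbind(1.2, 0, z_top - (seq_len(n2) - 1) * spacing)
  )
  bases <- rep(c("G", "C", "A", "U"), length.out = n_nt)
  rows <- list()
  for (i in seq_len(n_nt)) {
    p <- path[i, ]
    rows[[length(rows) + 1L]] <- data.frame(
      name = "C4'", element = "C", resname = bases[i], resid = i,
      x = p[1], y = p[2] + 0.25, z = p[3], charge = 0)
    if (i > 1L) {
      rows[[length(rows) + 1L]] <- data.frame(
        name = c("P", "OP1", "OP2"), element = c("P", "O", "O"),
        resname = bases[i], resid = i,
        x = p[1], y = p[2] + c(0, 0.15, -0.15), z = p[3] + c(0, 0.05, 0.05),
        charge = c(-1, 0, 0))
    }
  }
  at <- do.call(rbind, rows)
  at$x <- at$x + stats::rnorm(nrow(at), 0, jitter_sd)
  at$y <- at$y + stats::rnorm(nrow(at), 0, jitter_sd)
  at$z <- at$z + stats::rnorm(nrow(at), 0, jitter_sd)
  frame(atom_table(serial = seq_len(nrow(at)), name = at$name,
                   element = at$element, resname = at$resname,
                   resid = at$resid, chain = "R", x = at$x, y = at$y,
                   z = at$z, tag = "rna", charge = at$charge))
}

#' Generate a disordered polyampholyte chain
#'
#' A self-avoiding backbone-bead chain whose charged sites follow a placement
#' law concentrating acidity in the N-terminal stretch: by default 30 of the
#' acidic (D/E) and 4 of the basic (K/R) residues fall in the first
#' `nterm_span` (100) positions, so the first 100 residues carry net charge
#' -26 while the whole chain carries [net_charge()] of the composition
#' (-44 for the default).
#'
#' @param n_aa chain length (default 284).
#' @param composition a [composition_table()] (default [opn_composition()]).
#' @param placement list with `n_acid_nterm`, `n_base_nterm`, `nterm_span`.
#' @param seed RNG seed.
#' @param model a [chain_model()] template; the sequence is filled in.
#' @return list with `frame` (protein-tagged bead chain), `model` (the
#'   [chain_model()]) and `sequence`.
#' @export
make_polyampholyte <- function(n_aa = 284, composition = opn_composition(),
                               placement = list(n_acid_nterm = 30,
                                                n_base_nterm = 4,
                                                nterm_span = 100),
                               seed = 1L, model = NULL) {
  cnt <- composition$counts
  if (sum(cnt) > n_aa) stop("composition exceeds chain length")
  span <- min(placement$nterm_span, n_aa)
  n_acid <- cnt["D"] + cnt["E"]; n_base <- cnt["K"] + cnt["R"]
  na1 <- min(placement$n_acid_nterm, n_acid)
  nb1 <- min(placement$n_base_nterm, n_base)
  set.seed(seed)
  seq_out <- rep("G", n_aa)
  head_pos <- sample(seq_len(span), na1 + nb1)
  tail_n <- (n_acid - na1) + (n_base - nb1)
  tail_pos <- if (tail_n > 0) sample((span + 1L):n_aa, tail_n) else integer(0)
  acid_pos <- c(head_pos[seq_len(na1)], tail_pos[seq_len(n_acid - na1)])
  base_pos <- c(head_pos[na1 + seq_len(nb1)],
                tail_pos[n_acid - na1 + seq_len(n_base - nb1)])
  acid_id <- sample(rep(c("D", "E"), times = c(cnt["D"], cnt["E"])))
  base_id <- sample(rep(c("K", "R"), times = c(cnt["K"], cnt["R"])))
  seq_out[acid_pos] <- acid_id
  seq_out[base_pos] <- base_id
  mdl <- if (is.null(model)) chain_model(seq_out) else {
    model$sequence <- seq_out; model
  }
  frm <- build_random_coil(mdl, seed = seed + 1L)
  list(frame = frm, model = mdl, sequence = seq_out)
}

.ion_resname <- c(Na = "NA", Mg = "MG", Cl = "CL")

ion_atom_rows <- function(species, xyz, start_serial, start_resid, charge) {
  data.frame(serial = start_serial + seq_len(nrow(xyz)) - 1L,
             name = .ion_resname[species], element = species,
             resname = .ion_resname[species],
             resid = start_resid + seq_len(nrow(xyz)) - 1L, chain = "I",
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], tag = "ion",
             charge = charge, stringsAsFactors = FALSE)
}

# Rejection-sample one ion position satisfying distance windows to the two
# partner coordinate sets: d_r in r_window, d_p in p_window (Inf = open).
.sample_shell_point <- function(anchor_coords, other_coords, placed,
                                r_lo, r_hi, d_other_min, d_other_max = Inf,
                                d_ion_min = 0.1, tries = 400L) {
  for (k in seq_len(tries)) {
    a <- anchor_coords[sample(nrow(anchor_coords), 1L), ]
    pos <- a + stats::runif(1, r_lo, r_hi) * as.numeric(random_unit())
    d_anchor <- sqrt(min(rowSums(sweep(anchor_coords, 2, pos)^2)))
    if (d_anchor < r_lo || d_anchor > r_hi) next
    if (nrow(other_coords)) {
      d_o <- sqrt(min(rowSums(sweep(other_coords, 2, pos)^2)))
      if (d_o < d_other_min || d_o > d_other_max) next
    }
    if (length(placed) && nrow(placed)) {
      if (min(rowSums(sweep(placed, 2, pos)^2)) < d_ion_min^2) next
    }
    return(pos)
  }
  NULL
}

#' Plant ions with exactly known shell assignments
#'
#' Adds ions to a frame so that, per species, exactly the requested numbers
#' are first-shell adsorbed on the RNA only, on the protein only, bridging
#' (within the first shell of both), condensed (within the condensation
#' layer of the RNA), and bulk. The plant is verified by running
#' [classify_ions()] on the result; an infeasible geometry is an error.
#'
#' @param frm a [frame()] containing the two partners.
#' @param plant named list per species, each a named count vector using the
#'   names `protein_only`, `rna_only`, `bridging`, `condensed`, `bulk`,
#'   e.g. `list(Mg = c(rna_only = 9), Na = c(condensed = 20))`.
#' @param shells a [shell_spec()].
#' @param sel_protein,sel_rna partner selections used both for planting and
#'   verification (defaults: all protein / all RNA atoms).
#' @param seed RNG seed.
#' @return the input frame with ions appended; the plant (as a counts
#'   data.frame) is attached as attribute `"planted"`.
#' @export
plant_ions <- function(frm, plant, shells = shell_spec(),
                       sel_protein = NULL, sel_rna = NULL, seed = 1L) {
  set.seed(seed)
  if (is.null(sel_protein)) sel_protein <- build_selection(frm, "protein_all")
  if (is.null(sel_rna)) sel_rna <- build_selection(frm, "rna_all")
  Rc <- if (length(sel_rna$serials)) coords(frm, sel_rna) else matrix(numeric(0), 0, 3)
  Pc <- if (length(sel_protein$serials)) coords(frm, sel_protein) else matrix(numeric(0), 0, 3)
  d0 <- shells$d0_adsorption
  dc <- shells$d_condensation
  placed <- matrix(numeric(0), 0, 3)
  rows <- list()
  next_serial <- max(frm$atoms$serial) + 1L
  next_resid <- max(frm$atoms$resid) + 1L
  for (sp in names(plant)) {
    want <- plant[[sp]]
    charge <- shells$charges[sp]
    if (is.na(charge)) stop("no charge entry for species ", sp)
    for (class in names(want)) {
      for (k in seq_len(want[[class]])) {
        pos <- switch(class,
          rna_only = .sample_shell_point(Rc, Pc, placed,
                                         0.8 * d0, 0.95 * d0, 1.1 * d0),
          protein_only = .sample_shell_point(Pc, Rc, placed,
                                             0.8 * d0, 0.95 * d0, 1.1 * d0),
          bridging = .plant_bridge(Rc, Pc, placed, d0),
          condensed = .sample_shell_point(Rc, Pc, placed,
                                          min(2 * d0, 0.5 * dc),
                                          0.9 * dc, 1.25 * d0),
          bulk = .sample_shell_point(Rc, Pc, placed,
                                     dc + 0.5, dc + 3, dc + 0.2),
          stop("unknown plant class '", class, "'"))
        if (is.null(pos)) {
          stop("infeasible geometry: could not place ", sp, " as ", class)
        }
        placed <- rbind(placed, pos)
        rows[[length(rows) + 1L]] <-
          ion_atom_rows(sp, matrix(pos, 1, 3), next_serial, next_resid, charge)
        next_serial <- next_serial + 1L
        next_resid <- next_resid + 1L
      }
    }
  }
  out <- if (length(rows)) {
    frame(rbind(frm$atoms, do.call(rbind, rows)), box = frm$box, time = frm$time)
  } else frm
  # closed-loop verification of the plant
  planted <- do.call(rbind, lapply(names(plant), function(sp) {
    w <- plant[[sp]]
    full <- stats::setNames(rep(0L, 5), .ASSIGNMENT_LEVELS)
    full[names(w)] <- w
    data.frame(species = sp, t(full), stringsAsFactors = FALSE)
  }))
  if (is.null(planted)) {
    planted <- data.frame(species = character(0))
  }
  if (nrow(planted)) {
    inv <- classify_ions(out, sel_protein, sel_rna, shells)
    chk <- merge(planted, inv$counts, by = "species",
                 suffixes = c(".want", ".got"))
    for (cl in .ASSIGNMENT_LEVELS) {
      if (any(chk[[paste0(cl, ".want")]] != chk[[paste0(cl, ".got")]])) {
        stop("planted ion classes not recovered for class ", cl,
             "; geometry too crowded")
      }
    }
  }
  attr(out, "planted") <- planted
  out
}

# Bridge site: midpoint of a close RNA/protein atom pair, jittered.
.plant_bridge <- function(Rc, Pc, placed, d0, tries = 200L) {
  if (!nrow(Rc) || !nrow(Pc)) return(NULL)
  D <- pair_dist(Rc, Pc, NULL)
  cand <- which(D < 1.8 * d0, arr.ind = TRUE)
  if (!nrow(cand)) return(NULL)
  for (k in seq_len(tries)) {
    ij <- cand[sample(nrow(cand), 1L), ]
    mid <- (Rc[ij[1], ] + Pc[ij[2], ]) / 2 +
      stats::rnorm(3, 0, 0.01)
    d_r <- sqrt(min(rowSums(sweep(Rc, 2, mid)^2)))
    d_p <- sqrt(min(rowSums(sweep(Pc, 2, mid)^2)))
    if (d_r > 0.95 * d0 || d_p > 0.95 * d0) next
    if (nrow(placed) && min(rowSums(sweep(placed, 2, mid)^2)) < 0.01) next
    return(mid)
  }
  NULL
}

#' Generate a pseudo-trajectory with prescribed time courses
#'
#' Builds a fixed protein + RNA + ion system whose per-frame statistics
#' follow planted courses. Courses are supplied per quantity; omitted
#' quantities stay constant. Supported:
#' \describe{
#'   \item{`cn`}{integer vector: exact protein-RNA contact-pair count per
#'     frame (protein beads are placed as isolated contact pairs; overrides
#'     `separation`).}
#'   \item{`n1`}{named list per ion species of integer vectors: RNA-adsorbed
#'     count per frame (the remaining ions of that species sit in the
#'     condensation layer, so species totals are frame-constant).}
#'   \item{`separation`}{numeric vector, nm: protein-centroid-to-RNA-centroid
#'     distance per frame (drives assembly extent and LJ energy).}
#' }
#'
#' @param n_frames number of frames (>= 2).
#' @param courses list of planted courses, see above.
#' @param n_nt,n_aa partner sizes (defaults 40 / 60: desk scale).
#' @param seed RNG seed.
#' @param dt frame spacing, ps.
#' @param jitter_sd per-frame coordinate jitter applied to non-planted
#'   coordinates, nm.
#' @return a [trajectory()]; planted courses are attached as attribute
#'   `"planted"`.
#' @export
make_pseudo_trajectory <- function(n_frames = 10, courses = list(),
                                   n_nt = 40, n_aa = 60, seed = 1L,
                                   dt = 100, jitter_sd = 0.005) {
  if (n_frames < 2) stop("n_frames must be >= 2")
  set.seed(seed)
  rna <- make_stemloop(n_nt, seed = seed, jitter_sd = 0.004)
  Rall <- coords(rna)
  rctr <- colMeans(Rall)
  comp <- composition_table(D = min(10, n_aa %/% 6), E = 0,
                            K = min(4, n_aa %/% 15), R = 0)
  poly <- make_polyampholyte(n_aa, comp,
                             placement = list(n_acid_nterm = min(10, n_aa %/% 6),
                                              n_base_nterm = 0,
                                              nterm_span = max(10, n_aa %/% 3)),
                             seed = seed + 7L)
  prot0 <- poly$frame
  # normalize courses
  getc <- function(name, default) {
    v <- courses[[name]]
    if (is.null(v)) return(default)
    if (name != "n1") return(rep_len(v, n_frames))
    lapply(v, rep_len, n_frames)
  }
  cn_course <- if (is.null(courses$cn)) NULL else rep_len(as.integer(courses$cn), n_frames)
  sep_course <- getc("separation", rep(4, n_frames))
  n1_course <- if (is.null(courses$n1)) list() else lapply(courses$n1, rep_len, n_frames)
  n1_max <- vapply(n1_course, max, numeric(1))
  # contact sites: C4' atoms of every other residue (spaced >= 1.2 nm along
  # the backbone); a bead 0.45 nm along +y from a C4' is within 0.5 nm of
  # that atom only, so each planted bead contributes exactly one cross pair
  c4 <- rna$atoms[rna$atoms$name == "C4'", , drop = FALSE]
  sites <- as.matrix(c4[seq(1, nrow(c4), by = 2), c("x", "y", "z")])
  frames <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    set.seed(seed + 1000L + t)
    if (!is.null(cn_course)) {
      k <- cn_course[t]
      X <- matrix(NA_real_, n_aa, 3)
      if (k > nrow(sites)) stop("cn course exceeds available contact sites")
      for (j in seq_len(k)) {
        X[j, ] <- sites[j, ] + c(0, 0.45, 0)
      }
      if (k < n_aa) {
        far <- seq_len(n_aa - k)
        X[k + far, ] <- sweep(cbind(12 + (far %% 10), 12 + (far %/% 10), 0),
                              2, rctr, "+")
      }
      prot_at <- prot0$atoms
      prot_at[, c("x", "y", "z")] <- X
    } else {
      offset <- rctr + c(sep_course[t], 0, 0) - colMeans(coords(prot0))
      prot_at <- prot0$atoms
      prot_at[, c("x", "y", "z")] <-
        sweep(coords(prot0), 2, offset, "+") +
        matrix(stats::rnorm(3 * n_aa, 0, jitter_sd), n_aa, 3)
    }
    base_at <- rbind(rna$atoms, within(prot_at, {
      serial <- serial + max(rna$atoms$serial)
      resid <- resid + max(rna$atoms$resid)
    }))
    frm <- frame(base_at, time = (t - 1) * dt)
    if (length(n1_course)) {
      plant <- list()
      for (sp in names(n1_course)) {
        k1 <- as.integer(n1_course[[sp]][t])
        plant[[sp]] <- c(rna_only = k1,
                         condensed = as.integer(n1_max[sp]) - k1)
      }
      frm <- plant_ions(frm, plant, sel_protein = NULL, sel_rna = NULL,
                        seed = seed + 2000L + t)
      attr(frm, "planted") <- NULL
    }
    frames[[t]] <- frm
  }
  out <- trajectory(frames, metadata = "pseudo-trajectory (planted courses)")
  attr(out, "planted") <- list(cn = cn_course, separation = sep_course,
                               n1 = n1_course)
  out
}

#' Generate a synthetic crystal survey set with planted contact counts
#'
#' Builds `k` toy "crystal" entries: bead-per-residue protein and RNA chains
#' scattered on a grid inside a periodic cell, with exactly `CN` planted
#' cross pairs at 0.45 nm (every other cross distance exceeds 0.55 nm), so
#' the contact count at the 0.5 nm threshold is known by construction.
#' `n_kept` entries get residue ratios inside the survey window `[3, 15]`,
#' the rest outside. One entry (`id = "APT"`) is a protein-aptamer analog
#' planted to sit exactly at the reference level `CN_n = 0.02` (12 pairs,
#' 600 residues).
#'
#' @param k number of entries (default 41).
#' @param n_kept entries with ratio inside `[3, 15]` (default 26).
#' @param seed RNG seed.
#' @param include_aptamer_analog include the `CN_n = 0.02` entry (counted
#'   among the kept).
#' @return list with `frames` (named list of [frame()]) and `truth`
#'   (data.frame: `id`, `n_aa`, `n_nt`, `residue_ratio`, `CN`, `CN_n`,
#'   `kept`).
#' @export
make_survey_set <- function(k = 41, n_kept = 26, seed = 1L,
                            include_aptamer_analog = TRUE) {
  set.seed(seed)
  stopifnot(n_kept <= k)
  entries <- list()
  for (e in seq_len(k)) {
    if (include_aptamer_analog && e == 1L) {
      n_nt <- 40L; n_aa <- 560L; cn <- 12L; id <- "APT"
    } else {
      kept <- e <= n_kept
      n_nt <- sample(15:40, 1L)
      ratio <- if (kept) stats::runif(1, 3, 15) else {
        if (stats::runif(1) < 0.5) stats::runif(1, 0.5, 2.5) else stats::runif(1, 16, 25)
      }
      n_aa <- max(1L, as.integer(round(ratio * n_nt)))
      # keep the realized ratio on the intended side of the window
      if (kept) n_aa <- min(max(n_aa, as.integer(ceiling(3 * n_nt))),
                            as.integer(floor(15 * n_nt)))
      cn <- sample(0:min(25L, n_nt, n_aa), 1L)
      id <- sprintf("SYN%02d", e)
    }
    entries[[e]] <- list(id = id, n_aa = n_aa, n_nt = n_nt, cn = cn)
  }
  frames <- list(); truth <- list()
  for (en in entries) {
    frames[[en$id]] <- .survey_entry_frame(en$n_aa, en$n_nt, en$cn)
    truth[[length(truth) + 1L]] <- data.frame(
      id = en$id, n_aa = en$n_aa, n_nt = en$n_nt,
      residue_ratio = en$n_aa / en$n_nt, CN = en$cn,
      CN_n = en$cn / (en$n_aa + en$n_nt), stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  truth$kept <- truth$residue_ratio >= 3 & truth$residue_ratio <= 15
  list(frames = frames, truth = truth)
}

# One survey entry: all beads on a 1-nm grid strictly inside a periodic box;
# the first `cn` protein beads are shifted to 0.45 nm from an RNA bead.
.survey_entry_frame <- function(n_aa, n_nt, cn) {
  n <- n_aa + n_nt
  if (cn > min(n_aa, n_nt)) stop("cannot plant more pairs than beads")
  side <- ceiling(n^(1 / 3)) + 1L
  L <- side + 1.0
  g <- as.matrix(expand.grid(x = seq_len(side), y = seq_len(side),
                             z = seq_len(side)))[seq_len(n), , drop = FALSE]
  g <- g - 0.5  # strictly inside [0.5, side - 0.5], away from the boundary
  rna_xyz <- g[seq_len(n_nt), , drop = FALSE]
  prot_xyz <- g[n_nt + seq_len(n_aa), , drop = FALSE]
  if (cn > 0) {
    prot_xyz[seq_len(cn), ] <- rna_xyz[seq_len(cn), ] +
      matrix(c(0.45, 0, 0), cn, 3, byrow = TRUE)
  }
  at <- rbind(
    atom_table(serial = seq_len(n_nt), name = "P", element = "P",
               resname = "A", resid = seq_len(n_nt), chain = "R",
               x = rna_xyz[, 1], y = rna_xyz[, 2], z = rna_xyz[, 3],
               tag = "rna"),
    atom_table(serial = n_nt + seq_len(n_aa), name = "CA", element = "C",
               resname = "GLY", resid = n_nt + seq_len(n_aa), chain = "P",
               x = prot_xyz[, 1], y = prot_xyz[, 2], z = prot_xyz[, 3],
               tag = "protein")
  )
  frame(at, box = unit_cell(c(L, L, L)))
}
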