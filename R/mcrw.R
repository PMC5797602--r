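# Random-temperature Monte Carlo random walk (MC-RW): generates
# non-overlapping initial configurations of a disordered chain around a
# fixed partner, stopping each walk at the first configuration showing a
# manifest contact (>= 1 non-hydrogen cross pair within contact_d0). The
# walk's energy is hard-sphere only: the stage generates geometry, not an
# equilibrium ensemble.

.aa1to3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

#' Coarse-grained chain model
#'
#' One backbone bead per residue (the default representation): fixed
#' virtual-bond length between consecutive beads and a hard-sphere clash
#' radius for non-bonded pairs.
#'
#' @param sequence residue sequence: a 1-letter string or character vector.
#' @param bond_length consecutive-bead distance, nm (default 0.38, the
#'   trans CA-CA virtual bond).
#' @param clash_radius minimum non-bonded bead-bead distance, nm
#'   (default 0.36).
#' @param representation only `"backbone_beads"` is implemented; heavy-atom
#'   decoration is a separate post-step.
#' @return an object of class `"chain_model"`.
#' @export
chain_model <- function(sequence, bond_length = 0.38, clash_radius = 0.36,
                        representation = "backbone_beads") {
  if (length(sequence) == 1L && nchar(sequence) > 1L) {
    sequence <- strsplit(sequence, "")[[1]]
  }
  sequence <- toupper(sequence)
  stopifnot(length(sequence) >= 1, representation == "backbone_beads")
  if (clash_radius <= 0) stop("clash_radius must be positive")
  bad <- setdiff(unique(sequence), names(.aa1to3))
  if (length(bad)) stop("unknown residue code(s): ", paste(bad, collapse = ", "))
  structure(list(sequence = sequence, bond_length = bond_length,
                 clash_radius = clash_radius, representation = representation),
            class = "chain_model")
}

residue_charges <- function(sequence) {
  ch <- rep(0, length(sequence))
  ch[sequence %in% c("D", "E")] <- -1
  ch[sequence %in% c("K", "R")] <- 1
  ch
}

chain_to_frame <- function(model, X, time = NA_real_) {
  n <- length(model$sequence)
  frame(atom_table(serial = seq_len(n), name = "CA", element = "C",
                   resname = unname(.aa1to3[model$sequence]),
                   resid = seq_len(n), chain = "P",
                   x = X[, 1], y = X[, 2], z = X[, 3],
                   tag = "protein", charge = residue_charges(model$sequence)),
        time = time)
}

random_unit <- function(n = 1L) {
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v^2))
}

# Rotation matrix about unit axis u by angle a (Rodrigues).
axis_rotation <- function(u, a) {
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

# TRUE when bead set X (n x 3) has an internal non-bonded clash.
chain_has_clash <- function(X, clash) {
  n <- nrow(X)
  if (n < 3) return(FALSE)
  D <- pair_dist(X, X, NULL)
  D[cbind(seq_len(n), seq_len(n))] <- Inf
  D[cbind(seq_len(n - 1L), 2:n)] <- Inf
  D[cbind(2:n, seq_len(n - 1L))] <- Inf
  any(D < clash)
}

#' Grow a self-avoiding random coil
#'
#' Places beads sequentially at fixed bond length in uniformly random
#' directions, rejecting placements that clash with any previous non-bonded
#' bead; the chain restarts (bounded) when it traps itself.
#'
#' @param model a [chain_model()].
#' @param seed RNG seed (the build is deterministic given the seed).
#' @param origin coordinates of the first bead, nm.
#' @param max_restarts restarts allowed before giving up.
#' @return a [frame()] with one protein-tagged bead per residue.
#' @export
build_random_coil <- function(model, seed = 1L, origin = c(0, 0, 0),
                              max_restarts = 100L) {
  set.seed(seed)
  n <- length(model$sequence)
  for (attempt in seq_len(max_restarts)) {
    X <- matrix(NA_real_, n, 3)
    X[1, ] <- origin
    ok <- TRUE
    i <- 2L
    while (i <= n) {
      placed <- FALSE
      for (try in 1:100) {
        cand <- X[i - 1L, ] + model$bond_length * as.numeric(random_unit())
        if (i > 2L) {
          d2 <- rowSums(sweep(X[1:(i - 2L), , drop = FALSE], 2, cand)^2)
          if (min(d2) < model$clash_radius^2) next
        }
        X[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
      i <- i + 1L
    }
    if (ok) return(chain_to_frame(model, X))
  }
  stop("self-avoiding growth failed after ", max_restarts,
       " restarts; loosen clash_radius or shorten the chain")
}

#' MC-RW configuration
#'
#' @param n_samples number of independent walks (default 6).
#' @param seed base RNG seed; walk `s` uses `seed + s`.
#' @param contact_d0 manifest-contact distance, nm (default 0.5, the same
#'   cutoff used for nonspecific protein-RNA contacts).
#' @param max_steps Monte Carlo steps per walk before reporting failure.
#' @param move_weights proposal weights `c(pivot, crankshaft)`.
#' @param temperature_schedule `"random_per_step"` (temperature drawn
#'   log-uniformly from `temp_range` at every step) or `"fixed"`
#'   (`temp_range[1]`, plain Metropolis).
#' @param temp_range temperature range (reduced units).
#' @param partner_clash minimum chain-partner distance, nm (must be below
#'   `contact_d0` so that a contact zone exists).
#' @param anchor_clearance gap between the partner surface and the anchored
#'   C-terminal bead, nm.
#' @param max_pivot_angle,max_crank_angle proposal amplitudes, radians.
#' @param energy energy function `(X, partner_coords) -> number` for the
#'   Metropolis step; `NULL` means hard-sphere only (every non-clashing
#'   move is accepted, at any temperature).
#' @return an object of class `"mcrw_config"`.
#' @export
mcrw_config <- function(n_samples = 6L, seed = 1L, contact_d0 = 0.5,
                        max_steps = 20000L, move_weights = c(0.5, 0.5),
                        temperature_schedule = c("random_per_step", "fixed"),
                        temp_range = c(0.2, 5), partner_clash = 0.3,
                        anchor_clearance = 0.8, max_pivot_angle = pi,
                        max_crank_angle = pi / 2, energy = NULL) {
  stopifnot(n_samples >= 1, contact_d0 > 0, partner_clash < contact_d0)
  structure(list(n_samples = as.integer(n_samples), seed = as.integer(seed),
                 contact_d0 = contact_d0, max_steps = as.integer(max_steps),
                 move_weights = move_weights,
                 temperature_schedule = match.arg(temperature_schedule),
                 temp_range = temp_range, partner_clash = partner_clash,
                 anchor_clearance = anchor_clearance,
                 max_pivot_angle = max_pivot_angle,
                 max_crank_angle = max_crank_angle, energy = energy),
            class = "mcrw_config")
}

# Any chain bead within partner_clash of the partner?
partner_clash_q <- function(X, P, clash) {
  min(min_dist_to(X, P, NULL)) < clash
}

# Min cross distance and arg-min pair (chain bead index, partner row).
closest_cross_pair <- function(X, P) {
  best <- c(Inf, NA, NA)
  i <- 1L
  while (i <= nrow(X)) {
    j <- min(i + 255L, nrow(X))
    D <- pair_dist(X[i:j, , drop = FALSE], P, NULL)
    k <- arrayInd(which.min(D), dim(D))
    if (D[k] < best[1]) best <- c(D[k], i + k[1] - 1L, k[2])
    i <- j + 1L
  }
  best
}

place_chain_at_anchor <- function(X, anchor_pos, direction) {
  n <- nrow(X)
  Xc <- sweep(X, 2, X[n, ])               # anchor at origin
  ax <- as.numeric(random_unit())
  Xc <- Xc %*% axis_rotation(ax, stats::runif(1, 0, 2 * pi))
  sweep(Xc, 2, anchor_pos, "+")
}

#' Generate first-contact configurations by MC-RW
#'
#' Runs `n_samples` independent random-temperature Monte Carlo walks of the
#' chain around the fixed partner. The chain's C-terminal bead (the anchor)
#' is held fixed at a sample-specific position in front of the partner's
#' center; pivot and crankshaft moves (bond lengths conserved exactly)
#' propose new conformations, clashing moves are rejected outright, and the
#' first configuration with a manifest chain-partner contact (any
#' non-hydrogen cross pair within `contact_d0`) is returned for each walk.
#'
#' @param chain a chain [frame()] (e.g. from [build_random_coil()]); bead
#'   order defines the backbone, last bead = C-terminal anchor.
#' @param partner a [frame()] held fixed in space (non-hydrogen atoms are
#'   used for clash and contact tests).
#' @param config an [mcrw_config()].
#' @param model the [chain_model()] (supplies bond length and clash radius);
#'   derived from the chain frame's residue names by default.
#' @param reposition place the chain anew with the anchor fanned out around
#'   the partner (default); `FALSE` keeps the chain's given coordinates and
#'   anchors it where it stands.
#' @return list of class `"mcrw_result"`: per sample a list with `frame`
#'   (chain + partner combined), `steps` to first contact, `contact`
#'   (distance, chain bead, partner serial), `anchor` position, `seed`,
#'   `accepted`/`proposed`/`metropolis_rejected` counters and `failed` flag.
#' @export
mcrw_sample <- function(chain, partner, config = mcrw_config(),
                        model = NULL, reposition = TRUE) {
  if (is.null(model)) {
    aa3to1 <- stats::setNames(names(.aa1to3), unname(.aa1to3))
    model <- chain_model(unname(aa3to1[chain$atoms$resname]))
  }
  nonH <- build_selection(partner, "nonH")
  P <- coords(partner, nonH)
  pser <- nonH$serials
  ctr <- colMeans(P)
  Rpart <- max(sqrt(rowSums(sweep(P, 2, ctr)^2)))
  X0 <- coords(chain)
  n <- nrow(X0)
  out <- vector("list", config$n_samples)
  for (s in seq_len(config$n_samples)) {
    set.seed(config$seed + s)
    # anchor positions fan out around the partner on a ring
    th <- 2 * pi * (s - 1) / config$n_samples
    dir <- c(cos(th), sin(th), 0)
    anchor_pos <- ctr + (Rpart + config$anchor_clearance) * dir
    X <- NULL
    if (reposition) {
      for (try in 1:200) {
        cand <- place_chain_at_anchor(X0, anchor_pos, dir)
        if (!partner_clash_q(cand, P, config$partner_clash) &&
            !chain_has_clash(cand, model$clash_radius)) { X <- cand; break }
      }
    } else {
      anchor_pos <- X0[n, ]
      if (!partner_clash_q(X0, P, config$partner_clash) &&
          !chain_has_clash(X0, model$clash_radius)) X <- X0
    }
    if (is.null(X)) {
      out[[s]] <- list(failed = TRUE, reason = "no clash-free initial pose",
                       seed = config$seed + s)
      next
    }
    counters <- c(proposed = 0L, accepted = 0L, metropolis_rejected = 0L)
    E <- if (is.null(config$energy)) NULL else config$energy
    e_cur <- if (is.null(E)) 0 else E(X, P)
    res <- NULL
    for (step in 0:config$max_steps) {
      cp <- closest_cross_pair(X, P)
      if (cp[1] <= config$contact_d0) {
        res <- list(steps = step, contact = list(distance = cp[1],
                                                 chain_bead = as.integer(cp[2]),
                                                 partner_serial = pser[cp[3]]))
        break
      }
      if (step == config$max_steps) break
      counters["proposed"] <- counters["proposed"] + 1L
      Xn <- propose_move(X, config)
      if (partner_clash_q(Xn, P, config$partner_clash) ||
          chain_has_clash(Xn, model$clash_radius)) next
      if (!is.null(E)) {
        temp <- if (config$temperature_schedule == "random_per_step") {
          exp(stats::runif(1, log(config$temp_range[1]), log(config$temp_range[2])))
        } else config$temp_range[1]
        e_new <- E(Xn, P)
        if (e_new > e_cur && stats::runif(1) > exp(-(e_new - e_cur) / temp)) {
          counters["metropolis_rejected"] <- counters["metropolis_rejected"] + 1L
          next
        }
        e_cur <- e_new
      }
      X <- Xn
      counters["accepted"] <- counters["accepted"] + 1L
    }
    if (is.null(res)) {
      out[[s]] <- list(failed = TRUE, reason = "max_steps without contact",
                       seed = config$seed + s, counters = as.list(counters))
      next
    }
    combined <- combine_chain_partner(chain, X, partner)
    out[[s]] <- c(list(failed = FALSE, frame = combined,
                       anchor = anchor_pos, seed = config$seed + s,
                       counters = as.list(counters)), res)
  }
  structure(out, class = "mcrw_result")
}

propose_move <- function(X, config) {
  n <- nrow(X)
  if (n < 3L) return(X)
  if (stats::runif(1) < config$move_weights[1] / sum(config$move_weights)) {
    # pivot: rotate the free-end segment 1..(k-1) about bead k (anchor = n)
    k <- sample(2:(n - 1L), 1L)
    Rm <- axis_rotation(as.numeric(random_unit()),
                        stats::runif(1, -config$max_pivot_angle,
                                     config$max_pivot_angle))
    seg <- sweep(X[1:(k - 1L), , drop = FALSE], 2, X[k, ])
    X[1:(k - 1L), ] <- sweep(seg %*% Rm, 2, X[k, ], "+")
  } else {
    # crankshaft: rotate an interior block about the axis through its ends
    i <- sample(seq_len(n - 2L), 1L)
    j <- min(n, i + sample(2:5, 1L))
    if (j - i >= 2L) {
      ax <- X[j, ] - X[i, ]
      ax <- ax / sqrt(sum(ax^2))
      Rm <- axis_rotation(ax, stats::runif(1, -config$max_crank_angle,
                                           config$max_crank_angle))
      seg <- sweep(X[(i + 1L):(j - 1L), , drop = FALSE], 2, X[i, ])
      X[(i + 1L):(j - 1L), ] <- sweep(seg %*% Rm, 2, X[i, ], "+")
    }
  }
  X
}

combine_chain_partner <- function(chain, X, partner) {
  ca <- chain$atoms
  ca[, c("x", "y", "z")] <- X
  pa <- partner$atoms
  pa$serial <- pa$serial + max(ca$serial)
  frame(rbind(ca, pa), box = partner$box)
}

#' @export
print.mcrw_result <- function(x, ...) {
  ok <- vapply(x, function(r) !isTRUE(r$failed), logical(1))
  cat(sprintf("<mcrw_result> %d/%d walks reached first contact\n",
              sum(ok), length(x)))
  for (i in seq_along(x)) {
    r <- x[[i]]
    if (isTRUE(r$failed)) {
      cat(sprintf("  sample %d: FAILED (%s)\n", i, r$reason))
    } else {
      cat(sprintf("  sample %d: contact after %d step(s), d = %.3f nm\n",
                  i, r$steps, r$contact$distance))
    }
  }
  invisible(x)
}

#' Write MC-RW samples as numbered PDB files plus a JSON manifest
#'
#' @param result an [mcrw_sample()] result.
#' @param dir output directory (created if needed).
#' @return manifest path, invisibly.
#' @export
write_mcrw_samples <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  for (i in seq_along(result)) {
    r <- result[[i]]
    entry <- list(sample = i, seed = r$seed, failed = isTRUE(r$failed))
    if (!isTRUE(r$failed)) {
      f <- file.path(dir, sprintf("sample_%02d.pdb", i))
      write_structure(r$frame, f, "pdb")
      entry$file <- basename(f)
      entry$steps_to_contact <- r$steps
      entry$contact <- r$contact
      entry$anchor <- r$anchor
    } else entry$reason <- r$reason
    manifest[[i]] <- entry
  }
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(mf)
}
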