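# Independent brute-force oracles and tiny fixture builders. Oracles are
# deliberately naive (triple loops over the 27 periodic images, double loops
# over pairs) and share no code with the package internals they check.

# frame from a coordinate matrix, one bead per row
bead_frame <- function(xyz, tag = "protein", name = "CA", element = "C",
                       resname = "GLY", box = NULL, charge = 0) {
  n <- nrow(xyz)
  frame(atom_table(serial = seq_len(n), name = name, element = element,
                   resname = resname, resid = seq_len(n),
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   tag = tag, charge = charge),
        box = box)
}

# two-partner frame: A rows protein beads, B rows rna phosphorus
two_partner_frame <- function(A, B, box = NULL) {
  n <- nrow(A) + nrow(B)
  frame(atom_table(serial = seq_len(n), name = c(rep("CA", nrow(A)), rep("P", nrow(B))),
                   element = c(rep("C", nrow(A)), rep("P", nrow(B))),
                   resname = c(rep("GLY", nrow(A)), rep("A", nrow(B))),
                   resid = seq_len(n),
                   x = c(A[, 1], B[, 1]), y = c(A[, 2], B[, 2]),
                   z = c(A[, 3], B[, 3]),
                   tag = c(rep("protein", nrow(A)), rep("rna", nrow(B)))),
        box = box)
}

# two single-atom partners (C vs P) separated by r along x
lj_pair_frame <- function(r) {
  two_partner_frame(matrix(c(0, 0, 0), 1), matrix(c(r, 0, 0), 1))
}

# minimum-image distance by explicit scan over the 27 neighbour images
bf_min_image_dist <- function(a, b, box) {
  M <- cell_matrix(box)
  best <- Inf
  for (sx in -1:1) for (sy in -1:1) for (sz in -1:1) {
    d <- a - b + as.numeric(M %*% c(sx, sy, sz))
    best <- min(best, sqrt(sum(d * d)))
  }
  best
}

# brute-force cross-pair count within d0
bf_count_pairs <- function(A, B, d0, box = NULL) {
  n <- 0L
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    d <- if (is.null(box)) sqrt(sum((A[i, ] - B[j, ])^2))
         else bf_min_image_dist(A[i, ], B[j, ], box)
    if (d <= d0) n <- n + 1L
  }
  n
}

# brute-force per-ion shell assignment
bf_classify <- function(ions, P, R, d0, dc) {
  out <- character(nrow(ions))
  for (k in seq_len(nrow(ions))) {
    dp <- if (nrow(P)) min(sqrt(rowSums(sweep(P, 2, ions[k, ])^2))) else Inf
    dr <- if (nrow(R)) min(sqrt(rowSums(sweep(R, 2, ions[k, ])^2))) else Inf
    out[k] <- if (dp <= d0 && dr <= d0) "bridging"
      else if (dp <= d0) "protein_only"
      else if (dr <= d0) "rna_only"
      else if (dr <= dc) "condensed" else "bulk"
  }
  out
}

# brute-force Lennard-Jones cross sum (single class, Lorentz-Berthelot)
bf_lj <- function(A, B, eps_a, sig_a, eps_b, sig_b, cutoff) {
  u <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    r <- sqrt(sum((A[i, ] - B[j, ])^2))
    if (r <= cutoff) {
      e <- sqrt(eps_a * eps_b); s <- (sig_a + sig_b) / 2
      u <- u + 4 * e * ((s / r)^12 - (s / r)^6)
    }
  }
  u
}

# analytic accessible area of two fused spheres with extended radii R1, R2
# at centre distance d (each sphere loses one cap)
two_sphere_area <- function(R1, R2, d) {
  x1 <- (d^2 + R1^2 - R2^2) / (2 * d)
  h1 <- R1 - x1
  x2 <- d - x1
  h2 <- R2 - x2
  (4 * pi * R1^2 - 2 * pi * R1 * max(h1, 0)) +
    (4 * pi * R2^2 - 2 * pi * R2 * max(h2, 0))
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

rigid_transform_frame <- function(frm, Rm, shift) {
  set_coords(frm, sweep(coords(frm) %*% Rm, 2, shift, "+"))
}
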