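# Triclinic cell algebra and minimum-image distance kernels. Everything is
# vectorized base R; pair loops are chunked so that no temporary exceeds a
# few tens of MB even for expanded crystal frames.

#' Cell matrix of a unit cell
#'
#' Returns the 3x3 matrix whose columns are the cell vectors (nm), in the
#' standard crystallographic frame (a along x, b in the xy plane).
#'
#' @param box a [unit_cell()].
#' @return 3x3 numeric matrix.
#' @export
cell_matrix <- function(box) {
  l <- box$lengths
  ang <- box$angles * pi / 180
  ca <- cos(ang[1]); cb <- cos(ang[2]); cg <- cos(ang[3]); sg <- sin(ang[3])
  v <- sqrt(max(0, 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg))
  matrix(c(l[1], 0, 0,
           l[2] * cg, l[2] * sg, 0,
           l[3] * cb, l[3] * (ca - cb * cg) / sg, l[3] * v / sg),
         nrow = 3, ncol = 3)
}

cell_volume <- function(box) abs(det(cell_matrix(box)))

# Cartesian -> fractional (rows of xyz are points).
frac_coords <- function(xyz, box) {
  t(solve(cell_matrix(box), t(xyz)))
}

# Fractional -> cartesian.
cart_coords <- function(frac, box) {
  t(cell_matrix(box) %*% t(frac))
}

#' Expand a frame to the full unit cell
#'
#' Applies every symmetry operation of the frame's cell to every atom and
#' wraps the images into the primary cell (fractional coordinates in
#' `[0, 1)`). The output atom count is the input count times the number of
#' operations; serials are renumbered consecutively and residue numbers are
#' offset per image so that residues of distinct images stay distinct.
#'
#' @param frm a [frame()] whose `box` carries at least one symmetry operation.
#' @return a [frame()] holding all symmetry images, same cell.
#' @export
expand_unit_cell <- function(frm) {
  if (is.null(frm$box)) {
    stop("frame has no unit cell; supply a box (or assume P1 by attaching an ",
         "identity-only unit_cell)")
  }
  box <- frm$box
  at <- frm$atoms
  fr <- frac_coords(coords(frm), box)
  nres_span <- max(at$resid) - min(at$resid) + 1L
  pieces <- vector("list", length(box$symops))
  for (k in seq_along(box$symops)) {
    op <- box$symops[[k]]
    f2 <- t(op$R %*% t(fr)) + matrix(op$t, nrow(fr), 3, byrow = TRUE)
    f2 <- f2 - floor(f2)  # wrap into [0, 1)
    a2 <- at
    a2[, c("x", "y", "z")] <- cart_coords(f2, box)
    a2$resid <- a2$resid + (k - 1L) * nres_span
    a2$chain <- paste0(a2$chain, if (k > 1) k else "")
    pieces[[k]] <- a2
  }
  out <- do.call(rbind, pieces)
  out$serial <- seq_len(nrow(out))
  frame(out, box = box, time = frm$time)
}

# Minimum-image displacement for a matrix of cartesian differences (rows).
# Uses the nearest-lattice-point convention (exact for orthorhombic cells,
# standard approximation for moderately skewed cells).
min_image <- function(d, box) {
  M <- cell_matrix(box)
  f <- t(solve(M, t(d)))
  f <- f - round(f)
  t(M %*% t(f))
}

# Pairwise distance matrix between point sets A (m x 3) and B (n x 3),
# optionally under minimum-image PBC. Returns m x n matrix.
pair_dist <- function(A, B, box = NULL) {
  m <- nrow(A); n <- nrow(B)
  dx <- outer(A[, 1], B[, 1], "-")
  dy <- outer(A[, 2], B[, 2], "-")
  dz <- outer(A[, 3], B[, 3], "-")
  if (!is.null(box)) {
    d <- min_image(cbind(as.vector(dx), as.vector(dy), as.vector(dz)), box)
    return(matrix(sqrt(rowSums(d^2)), m, n))
  }
  sqrt(dx^2 + dy^2 + dz^2)
}

# Apply FUN(block_dist_matrix, row_index) over A-chunks of the cross pair
# distance computation and accumulate with `+`. Keeps memory bounded.
.chunk_pairs <- function(A, B, box, fun, chunk = 512L) {
  acc <- NULL
  i <- 1L
  while (i <= nrow(A)) {
    j <- min(i + chunk - 1L, nrow(A))
    D <- pair_dist(A[i:j, , drop = FALSE], B, box)
    val <- fun(D, i:j)
    acc <- if (is.null(acc)) val else acc + val
    i <- j + 1L
  }
  acc
}

# Count cross pairs with distance <= d0 (ties inclusive).
count_pairs_within <- function(A, B, d0, box = NULL) {
  if (!nrow(A) || !nrow(B)) return(0L)
  as.integer(.chunk_pairs(A, B, box, function(D, ii) sum(D <= d0)))
}

# Smooth (logistic switching) pair count: sum over pairs of
# s(r) = 1 / (1 + exp((r - d0)/w)), computed overflow-safely via plogis.
smooth_pairs_within <- function(A, B, d0, w, box = NULL) {
  if (!nrow(A) || !nrow(B)) return(0)
  .chunk_pairs(A, B, box, function(D, ii) sum(stats::plogis((d0 - D) / w)))
}

# For each row of P, the minimum distance to any row of S.
min_dist_to <- function(P, S, box = NULL, chunk = 512L) {
  if (!nrow(P)) return(numeric(0))
  if (!nrow(S)) return(rep(Inf, nrow(P)))
  out <- numeric(nrow(P))
  i <- 1L
  while (i <= nrow(P)) {
    j <- min(i + chunk - 1L, nrow(P))
    D <- pair_dist(P[i:j, , drop = FALSE], S, box)
    out[i:j] <- apply(D, 1, min)
    i <- j + 1L
  }
  out
}

# All cross-pair distances <= r_max, returned as a numeric vector (for RDF
# histograms). Self-pairs (zero distance between identical rows) are kept;
# callers using disjoint selections never produce them.
pair_dists_upto <- function(A, B, r_max, box = NULL, chunk = 512L) {
  if (!nrow(A) || !nrow(B)) return(numeric(0))
  res <- list()
  i <- 1L
  while (i <= nrow(A)) {
    j <- min(i + chunk - 1L, nrow(A))
    D <- pair_dist(A[i:j, , drop = FALSE], B, box)
    res[[length(res) + 1L]] <- D[D <= r_max]
    i <- j + 1L
  }
  unlist(res)
}
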