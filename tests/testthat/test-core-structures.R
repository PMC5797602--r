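# Structure model, I/O, unit-cell expansion, selections, charge arithmetic.

test_that("PDB coordinates are converted to nm and round-trip at PDB precision", {
  tf <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       4.500   5.500   6.500  1.00  0.00           C",
    "ATOM      3  P     A R   3       7.000   8.000   9.000  1.00  0.00           P",
    "END"), tf)
  f <- read_structure(tf)
  expect_equal(nrow(f$atoms), 3)
  expect_equal(coords(f)[1, ], c(0.1, 0.2, 0.3))
  expect_equal(f$atoms$tag, c("protein", "protein", "rna"))

  sl <- make_stemloop(12, seed = 3)
  tf2 <- tempfile(fileext = ".pdb")
  write_structure(sl, tf2)
  sl2 <- read_structure(tf2)
  expect_lt(max(abs(coords(sl2) - coords(sl))), 1e-3)
  expect_identical(sl2$atoms$tag, sl$atoms$tag)
})

test_that("multi-model PDB and multi-block XYZ read as trajectories", {
  sl <- make_stemloop(8, seed = 1)
  tr <- trajectory(list(sl, sl))
  for (fmt in c("pdb", "xyz")) {
    tf <- tempfile(fileext = paste0(".", fmt))
    write_structure(tr, tf)
    tr2 <- read_trajectory(tf, dt = 10)
    expect_equal(length(tr2), 2)
    expect_equal(frame_times(tr2), c(0, 10))
    expect_lt(max(abs(coords(tr2[[2]]) - coords(sl))), 1e-3)
  }
})

test_that("malformed records error with a line number; unknown residues warn", {
  tf <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       x.xxx   5.500   6.500  1.00  0.00           C"), tf)
  expect_error(read_structure(tf), "line 2")

  tf2 <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1       1.000   2.000   3.000  1.00  0.00           C",
    "HETATM    2  X1  XYZ A   2       1.000   1.000   1.000  1.00  0.00           C"), tf2)
  expect_warning(f <- read_structure(tf2), "XYZ")
  expect_equal(f$atoms$tag[2], "other")
})

test_that("unit-cell expansion multiplies atoms, wraps into the cell, and is trivial for identity", {
  f1 <- bead_frame(matrix(c(0.2, 0.2, 0.2), 1), box = unit_cell(c(2, 2, 2)))
  expect_equal(coords(expand_unit_cell(f1)), coords(f1))

  box2 <- unit_cell(c(2, 2, 2),
                    symops = list(list(R = diag(3), t = c(0.5, 0.5, 0.5))))
  f2 <- bead_frame(matrix(c(0.2, 0.2, 0.2), 1), box = box2)
  fe <- expand_unit_cell(f2)
  expect_equal(nrow(fe$atoms), 2)
  expect_equal(unname(coords(fe)[2, ]), c(1.2, 1.2, 1.2))

  expect_error(expand_unit_cell(bead_frame(matrix(0, 1, 3))), "unit cell")
})

test_that("expanded-cell minimum-image distances match a 27-image brute-force scan", {
  set.seed(42)
  # P21-like cell: identity + 2-fold screw
  box <- unit_cell(c(2.4, 3.1, 2.7),
                   symops = list(
                     list(R = diag(c(-1, 1, -1)), t = c(0, 0.5, 0)),
                     list(R = diag(c(1, -1, -1)), t = c(0.5, 0.5, 0)),
                     list(R = diag(c(-1, -1, 1)), t = c(0.5, 0, 0.5))))
  f <- bead_frame(cbind(runif(5, 0, 2.4), runif(5, 0, 3.1), runif(5, 0, 2.7)),
                  box = box)
  fe <- expand_unit_cell(f)
  expect_equal(nrow(fe$atoms), 20)
  fr <- complexion:::frac_coords(coords(fe), box)
  expect_true(all(fr >= -1e-12 & fr < 1 + 1e-12))
  X <- coords(fe)
  for (i in c(1, 7, 13)) for (j in c(4, 10, 19)) {
    got <- complexion:::pair_dist(X[i, , drop = FALSE], X[j, , drop = FALSE],
                                  box)[1, 1]
    expect_equal(got, bf_min_image_dist(X[i, ], X[j, ], box), tolerance = 1e-10)
  }
})

test_that("selections pick the advertised atoms and partition correctly", {
  sl <- make_stemloop(40, seed = 1)
  op <- build_selection(sl, "OP")
  expect_equal(length(op), 78)  # 2 oxygens x 39 phosphates (no 5' phosphate)

  # protein with 3 D and 2 E -> 10 carboxylate oxygens
  n <- 5
  at <- atom_table(serial = 1:10,
                   name = rep(c("OD1", "OD2", "OD1", "OD2", "OD1", "OD2",
                                "OE1", "OE2", "OE1", "OE2")),
                   element = "O",
                   resname = rep(c("ASP", "ASP", "ASP", "GLU", "GLU"), each = 2),
                   resid = rep(1:5, each = 2), x = 1:10, y = 0, z = 0,
                   tag = "protein")
  prot <- frame(at)
  expect_equal(length(build_selection(prot, "OD_OE")), 10)

  # no hydrogens present -> nonH selects everything
  expect_equal(length(build_selection(sl, "nonH")), nrow(sl$atoms))

  # partition invariants on a mixed fixture
  mixed <- suppressWarnings(
    plant_ions(sl, list(Na = c(condensed = 5)), seed = 2))
  op2 <- build_selection(mixed, "OP")
  rna <- build_selection(mixed, "rna_all")
  expect_true(all(op2$serials %in% rna$serials))
  expect_length(intersect(op2$serials,
                          suppressWarnings(build_selection(mixed, "OD_OE",
                                           non_hydrogen = FALSE))$serials), 0)
  expect_warning(build_selection(sl, "OD_OE"), "empty")
})

test_that("net charge matches the physiological-pH composition arithmetic", {
  expect_identical(net_charge(opn_composition()), -44)
  expect_identical(net_charge(composition_table()), 0)
  expect_identical(net_charge(composition_table(D = 1, K = 1)), 0)
  expect_error(composition_table(D = -1), "non-negative")

  # linearity in the counts
  set.seed(1)
  for (k in 1:10) {
    a <- sample(0:50, 4); b <- sample(0:50, 4)
    q <- function(v) net_charge(composition_table(v[1], v[2], v[3], v[4]))
    expect_identical(q(a + b), q(a) + q(b))
  }
})

test_that("bare complex charges follow the one-phosphate-per-linkage rule", {
  expect_equal(bare_charges(40, opn_composition()),
               c(protein = -44, rna = -39, total = -83))
  expect_equal(unname(bare_charges(1, composition_table())["rna"]), 0)
  expect_equal(unname(bare_charges(11, composition_table())["total"]), -10)
  expect_equal(unname(bare_charges(40, opn_composition(),
                                   five_prime_phosphate = TRUE)["rna"]), -40)
  expect_error(bare_charges(0, opn_composition()))
})
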