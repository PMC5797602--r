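# First-shell classification, half-split charge ledger, RDF, time series.

test_that("ions are assigned to shells by minimum distance to each partner", {
  # one OP-like rna atom at origin, protein bead far away
  f0 <- two_partner_frame(matrix(c(5, 0, 0), 1), matrix(c(0, 0, 0), 1))
  sel_p <- complexion:::new_selection("p", 1L)
  sel_r <- complexion:::new_selection("r", 2L)
  add_ion <- function(f, pos, sp = "NA") {
    at <- f$atoms
    ion <- atom_table(max(at$serial) + 1L, sp, ion_species(sp), sp,
                      max(at$resid) + 1L, x = pos[1], y = pos[2], z = pos[3],
                      tag = "ion")
    frame(rbind(at, ion))
  }
  f1 <- add_ion(f0, c(0.25, 0, 0))
  inv1 <- classify_ions(f1, sel_p, sel_r)
  expect_equal(inv1$assignments$assignment, "rna_only")

  # bridging: ion 0.25 nm from both partners
  fb <- two_partner_frame(matrix(c(0.5, 0, 0), 1), matrix(c(0, 0, 0), 1))
  fb <- add_ion(fb, c(0.25, 0, 0))
  invb <- classify_ions(fb, sel_p, sel_r)
  expect_equal(invb$assignments$assignment, "bridging")
  expect_equal(invb$counts$n1_protein, 1)
  expect_equal(invb$counts$n1_rna, 1)
})

test_that("classification equals the brute-force oracle and is exhaustive", {
  for (seed in 1:4) {
    set.seed(seed)
    P <- matrix(rnorm(15, sd = 0.4), 5) + 1.5
    R <- matrix(rnorm(24, sd = 0.4), 8)
    ions <- matrix(runif(150, -4, 6), 50)
    n <- 13 + 50
    at <- rbind(two_partner_frame(P, R)$atoms,
                atom_table(14:63, "NA", "Na", "NA", 14:63,
                           x = ions[, 1], y = ions[, 2], z = ions[, 3],
                           tag = "ion"))
    f <- frame(at)
    inv <- classify_ions(f, complexion:::new_selection("p", 1:5),
                         complexion:::new_selection("r", 6:13))
    expect_identical(inv$assignments$assignment,
                     bf_classify(ions, P, R, 0.28, 3))
    expect_equal(sum(inv$counts[, complexion:::.ASSIGNMENT_LEVELS]), 50)
  }
})

test_that("planted assignments are recovered exactly (closed loop)", {
  sl <- make_stemloop(30, seed = 4)
  planted <- suppressWarnings(
    plant_ions(sl, list(Mg = c(rna_only = 9), Na = c(rna_only = 2, condensed = 12,
                                                     bulk = 3)),
               seed = 6))
  inv <- suppressWarnings(classify_ions(
    planted, build_selection(planted, "protein_all"),
    build_selection(planted, "rna_all")))
  cnt <- inv$counts
  expect_equal(cnt$rna_only[cnt$species == "Mg"], 9)
  expect_equal(cnt$rna_only[cnt$species == "Na"], 2)
  expect_equal(cnt$condensed[cnt$species == "Na"], 12)
  expect_equal(cnt$bulk[cnt$species == "Na"], 3)
})

test_that("n1 over OP atoms never exceeds n1 over all RNA atoms", {
  sl <- make_stemloop(30, seed = 5)
  planted <- suppressWarnings(
    plant_ions(sl, list(Mg = c(rna_only = 7), Na = c(condensed = 10)), seed = 3))
  sel_op <- build_selection(planted, "OP")
  sel_rna <- build_selection(planted, "rna_all")
  dummy_p <- complexion:::new_selection("p", integer(0))
  inv_op <- suppressWarnings(classify_ions(planted, dummy_p, sel_op))
  inv_all <- suppressWarnings(classify_ions(planted, dummy_p, sel_rna))
  for (sp in inv_op$counts$species) {
    expect_lte(inv_op$counts$n1_rna[inv_op$counts$species == sp],
               inv_all$counts$n1_rna[inv_all$counts$species == sp])
  }
})

test_that("half-split ledger reproduces the screening arithmetic", {
  bare <- bare_charges(40, opn_composition())
  # 18 Mg + 16 Na adsorbed in any split across the two partners
  lg <- charge_ledger(manual_inventory(c("Mg", "Na"),
                                       protein_only = c(5, 9),
                                       rna_only = c(10, 5),
                                       bridging = c(3, 2)), bare)
  expect_equal(lg$Q_a_protein + lg$Q_a_rna, -31)
  expect_equal(lg$screening_percent, 37)

  expect_equal(screening_percent(-16.5, -27.5, -83), 53)
  expect_equal(screening_percent(-17.5, -13.5, -83), 37)

  lg0 <- charge_ledger(manual_inventory("Na", bridging = 1),
                       c(protein = 0, rna = 0))
  expect_equal(lg0$Q_a_protein, 0.5)
  expect_equal(lg0$Q_a_rna, 0.5)
})

test_that("half-charge splitting conserves total charge on random inventories", {
  set.seed(10)
  charges <- c(Na = 1, Mg = 2, Cl = -1)
  for (k in 1:200) {
    cnt <- matrix(sample(0:6, 9, replace = TRUE), 3)
    inv <- manual_inventory(c("Na", "Mg", "Cl"),
                            protein_only = cnt[, 1], rna_only = cnt[, 2],
                            bridging = cnt[, 3])
    bare <- c(protein = sample(-50:0, 1), rna = sample(-50:0, 1))
    lg <- charge_ledger(inv, bare)
    adsorbed <- sum(charges * (cnt[, 1] + cnt[, 2] + cnt[, 3]))
    expect_equal(lg$Q_a_protein + lg$Q_a_rna, sum(bare) + adsorbed)
  }
})

test_that("uniform ideal-gas RDF is flat at 1 within counting noise", {
  set.seed(1)
  box <- unit_cell(c(4, 4, 4))
  frames <- lapply(1:4, function(i) {
    ions <- matrix(runif(1800, 0, 4), 600)
    at <- rbind(atom_table(1, "P", "P", "A", 1, x = 2, y = 2, z = 2, tag = "rna"),
                atom_table(1 + 1:600, "NA", "Na", "NA", 1 + 1:600,
                           x = ions[, 1], y = ions[, 2], z = ions[, 3],
                           tag = "ion"))
    frame(at, box = box, time = i)
  })
  tr <- trajectory(frames)
  g <- rdf(tr, complexion:::new_selection("a", 1L),
           build_selection(frames[[1]], "ions"), bin_width = 0.1, r_max = 1.9)
  # counting noise: ~ 1/sqrt(expected pairs per bin), pooled over bins
  expect_lt(abs(mean(g$g[g$r > 0.3]) - 1), 0.1)
  expect_error(rdf(tr, complexion:::new_selection("a", 1L),
                   build_selection(frames[[1]], "ions"), r_max = 2.5),
               "half")
})

test_that("RDF of shell-planted ions peaks at the planted radius", {
  set.seed(2)
  centre <- matrix(c(0, 0, 0), 1)
  sh <- complexion:::random_unit(400) * 0.28
  at <- rbind(atom_table(1, "P", "P", "A", 1, x = 0, y = 0, z = 0, tag = "rna"),
              atom_table(1 + 1:400, "MG", "Mg", "MG", 1 + 1:400,
                         x = sh[, 1], y = sh[, 2], z = sh[, 3], tag = "ion"))
  f <- frame(at)
  g <- rdf(f, complexion:::new_selection("a", 1L), build_selection(f, "ions"),
           bin_width = 0.02, r_max = 1)
  expect_equal(g$r[which.max(g$g)], 0.27, tolerance = 0.011)
  expect_equal(calibrate_d0(g), 0.27, tolerance = 0.011)
})

test_that("d0 calibration returns the first peak, not the highest", {
  r <- seq(0.01, 1, by = 0.02)
  two_peaks <- data.frame(r = r, g = 2 * exp(-((r - 0.28) / 0.05)^2) +
                                     5 * exp(-((r - 0.5) / 0.05)^2))
  expect_lt(abs(calibrate_d0(two_peaks) - 0.28), 0.021)  # first, not highest
  mono <- data.frame(r = r, g = exp(-3 * r))
  expect_warning(d <- calibrate_d0(mono), "peak")
  expect_equal(d, r[1])
})

test_that("no cross pairs give an all-zero g(r)", {
  f <- two_partner_frame(matrix(c(50, 0, 0), 1), matrix(c(0, 0, 0), 1))
  g <- rdf(f, complexion:::new_selection("a", 1L),
           complexion:::new_selection("b", 2L), bin_width = 0.1, r_max = 1)
  expect_true(all(g$g == 0))
})

test_that("inventory time series recovers planted occupancy statistics", {
  set.seed(33)
  n_frames <- 16
  course <- pmax(0, pmin(12, round(rnorm(n_frames, 8, 2))))
  tr <- make_pseudo_trajectory(n_frames, courses = list(n1 = list(Mg = course)),
                               n_aa = 20, n_nt = 20, seed = 12)
  f1 <- tr[[1]]
  inv <- inventory_timeseries(tr, build_selection(f1, "protein_all"),
                              build_selection(f1, "rna_all"))
  sub <- inv$series[inv$series$species == "Mg" &
                    inv$series$assignment == "n1_rna", ]
  expect_identical(sub$count, as.integer(course))
  ws <- inv$window_stats
  m <- ws$mean[ws$species == "Mg" & ws$assignment == "n1_rna"]
  expect_equal(m, mean(course))

  # constant course -> zero sd; short trajectory window warning
  tr2 <- make_pseudo_trajectory(4, courses = list(n1 = list(Mg = rep(5, 4))),
                                n_aa = 20, n_nt = 20, seed = 13)
  expect_warning(
    inv2 <- inventory_timeseries(tr2, build_selection(tr2[[1]], "protein_all"),
                                 build_selection(tr2[[1]], "rna_all"),
                                 window = 10), "window")
  ws2 <- inv2$window_stats
  expect_equal(ws2$sd[ws2$species == "Mg" & ws2$assignment == "n1_rna"], 0)
})

test_that("planted Mg-up/Na-down exchange shows anticorrelation", {
  up <- c(0, 2, 4, 6, 8, 9)
  down <- c(9, 8, 6, 4, 2, 1)
  tr <- make_pseudo_trajectory(6, courses = list(n1 = list(Mg = up, Na = down)),
                               n_aa = 20, n_nt = 20, seed = 14)
  inv <- inventory_timeseries(tr, build_selection(tr[[1]], "protein_all"),
                              build_selection(tr[[1]], "rna_all"))
  s <- inv$series
  mg <- s$count[s$species == "Mg" & s$assignment == "n1_rna"]
  na <- s$count[s$species == "Na" & s$assignment == "n1_rna"]
  expect_lt(cor(mg, na), 0)
})
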