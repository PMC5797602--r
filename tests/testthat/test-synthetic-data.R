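# Generators: planted statistics must be recovered exactly by the analyses
# (the closed-loop harness), and everything is seed-deterministic.

test_that("stem-loop polyanion carries one phosphate per linkage", {
  sl <- make_stemloop(40, seed = 1)
  expect_equal(length(build_selection(sl, "OP")), 78)
  expect_equal(sum(sl$atoms$charge), -39)
  expect_equal(sum(sl$atoms$name == "P"), 39)

  sl4 <- make_stemloop(4, seed = 1)
  expect_equal(sum(sl4$atoms$name == "P"), 3)

  sl_b <- make_stemloop(40, seed = 2)
  expect_identical(sl$atoms$name, sl_b$atoms$name)
  expect_false(isTRUE(all.equal(coords(sl), coords(sl_b))))
  expect_identical(coords(make_stemloop(40, seed = 1)), coords(sl))
})

test_that("polyampholyte matches its composition and N-terminal charge law", {
  pa <- make_polyampholyte(seed = 1)
  expect_equal(sum(pa$frame$atoms$charge), -44)
  expect_equal(length(pa$sequence), 284)
  expect_equal(sum(pa$sequence == "D"), 47)
  expect_equal(sum(pa$sequence == "R"), 9)

  first100 <- vapply(1:3, function(s) {
    p <- make_polyampholyte(seed = s)
    sum(p$frame$atoms$charge[p$frame$atoms$resid <= 100])
  }, numeric(1))
  expect_true(all(first100 <= -20))

  neutral <- make_polyampholyte(60, composition_table(), seed = 2)
  expect_equal(sum(neutral$frame$atoms$charge), 0)
})

test_that("planted ion shells close the loop through classify_ions", {
  sl <- make_stemloop(40, seed = 3)
  planted <- suppressWarnings(
    plant_ions(sl, list(Mg = c(rna_only = 9)), seed = 4))
  inv <- suppressWarnings(classify_ions(
    planted, build_selection(planted, "protein_all"),
    build_selection(planted, "rna_all")))
  expect_equal(inv$counts$rna_only[inv$counts$species == "Mg"], 9)
  expect_equal(attr(planted, "planted")$rna_only, 9)

  none <- suppressWarnings(plant_ions(sl, list(), seed = 5))
  expect_equal(sum(none$atoms$tag == "ion"), 0)
})

test_that("three bridging Na on a neutral pair yield a (+1.5, +1.5) ledger", {
  # partners close enough to admit a shared first shell
  f <- two_partner_frame(matrix(c(0.4, 0, 0, 0.4, 1, 0, 0.4, 2, 0), 3,
                                byrow = TRUE),
                        matrix(c(0, 0, 0, 0, 1, 0, 0, 2, 0), 3, byrow = TRUE))
  sel_p <- complexion:::new_selection("p", 1:3)
  sel_r <- complexion:::new_selection("r", 4:6)
  planted <- plant_ions(f, list(Na = c(bridging = 3)),
                        sel_protein = sel_p, sel_rna = sel_r, seed = 6)
  inv <- classify_ions(planted, sel_p, sel_r)
  expect_equal(inv$counts$bridging[inv$counts$species == "Na"], 3)
  lg <- charge_ledger(inv, c(protein = 0, rna = 0))
  expect_equal(lg$Q_a_protein, 1.5)
  expect_equal(lg$Q_a_rna, 1.5)
})

test_that("infeasible plants are refused", {
  sl <- make_stemloop(10, seed = 7)
  # bridging needs a protein partner nearby; a lone RNA cannot host one
  expect_error(suppressWarnings(
    plant_ions(sl, list(Na = c(bridging = 1)), seed = 8)), "infeasible")
})

test_that("pseudo-trajectory step courses land on the planted frame", {
  course <- c(9, 9, 9, 0, 0)  # complete removal of adsorbed Mg at frame 4
  tr <- make_pseudo_trajectory(5, courses = list(n1 = list(Mg = course)),
                               n_aa = 20, n_nt = 20, seed = 9)
  inv <- inventory_timeseries(tr, build_selection(tr[[1]], "protein_all"),
                              build_selection(tr[[1]], "rna_all"))
  s <- inv$series
  mg <- s$count[s$species == "Mg" & s$assignment == "n1_rna"]
  expect_identical(mg, as.integer(course))
  expect_equal(which(diff(mg) != 0) + 1L, 4L)
  # species totals stay constant across frames (constant atom count)
  tot <- tapply(s$count[s$assignment %in% c("protein_only", "rna_only",
                                            "bridging", "condensed", "bulk")],
                s$frame[s$assignment %in% c("protein_only", "rna_only",
                                            "bridging", "condensed", "bulk")],
                sum)
  expect_true(all(tot == tot[[1]]))
})

test_that("survey set reproduces every planted contact statistic", {
  sv <- make_survey_set(k = 15, n_kept = 9, seed = 10)
  out <- run_survey(sv$frames, file.path(tempdir(), "survey_test"))
  m <- match(sv$truth$id, out$id)
  expect_identical(out$CN[m], as.integer(sv$truth$CN))
  expect_equal(out$CN_n[m], sv$truth$CN_n)
  expect_identical(out$kept[m], sv$truth$kept)
  expect_equal(sum(out$kept), 9)
  apt <- out[out$id == "APT", ]
  expect_equal(apt$CN_n, 0.02)
  expect_equal(apt$residue_ratio, 14)
  # min/max of the kept entries match the planted truth
  kept_truth <- sv$truth[sv$truth$kept, ]
  expect_equal(range(out$CN_n[out$kept]), range(kept_truth$CN_n))
})
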