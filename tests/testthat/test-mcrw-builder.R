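# Self-avoiding coil growth and the random-temperature MC-RW first-contact
# generator.

test_that("random coil growth respects bonds, clashes and determinism", {
  m1 <- chain_model("G")
  f1 <- build_random_coil(m1, seed = 1)
  expect_equal(nrow(f1$atoms), 1)
  expect_equal(unname(coords(f1)[1, ]), c(0, 0, 0))

  model <- chain_model(rep("G", 50))
  f <- build_random_coil(model, seed = 7)
  X <- coords(f)
  bonds <- sqrt(rowSums((X[-1, ] - X[-50, ])^2))
  expect_true(all(abs(bonds - model$bond_length) < 1e-9))
  D <- as.matrix(dist(X))
  nb <- abs(row(D) - col(D)) >= 2
  expect_true(all(D[nb] >= model$clash_radius))

  expect_identical(coords(build_random_coil(model, seed = 7)), X)
  expect_false(isTRUE(all.equal(coords(build_random_coil(model, seed = 8)), X)))
})

test_that("impossible growth fails with a clear error", {
  model <- chain_model(rep("G", 30), bond_length = 0.1, clash_radius = 0.5)
  expect_error(build_random_coil(model, seed = 1, max_restarts = 3), "growth failed")
})

test_that("a partner already in contact returns at step zero", {
  model <- chain_model(rep("G", 5))
  coil <- build_random_coil(model, seed = 2)
  end <- coords(coil)[5, ]
  partner <- bead_frame(matrix(end + c(0.4, 0, 0), 1), tag = "rna",
                        name = "P", element = "P", resname = "A")
  res <- mcrw_sample(coil, partner, mcrw_config(n_samples = 1, seed = 3),
                     reposition = FALSE)
  expect_false(res[[1]]$failed)
  expect_equal(res[[1]]$steps, 0)
  expect_lte(res[[1]]$contact$distance, 0.5)
})

test_that("every returned sample passes the exhaustive clash and contact audit", {
  sl <- make_stemloop(16, seed = 4)
  model <- chain_model(rep("G", 25))
  coil <- build_random_coil(model, seed = 5)
  cfg <- mcrw_config(n_samples = 6, seed = 11, max_steps = 4000)
  res <- mcrw_sample(coil, sl, cfg, model = model)
  expect_length(res, 6)
  for (r in res) {
    expect_false(r$failed)
    f <- r$frame
    Xc <- coords(f, build_selection(f, "protein_all"))
    Pp <- coords(f, build_selection(f, "rna_all"))
    # intra-chain: bonds exact, non-bonded pairs clash-free
    bonds <- sqrt(rowSums((Xc[-1, ] - Xc[-nrow(Xc), ])^2))
    expect_true(all(abs(bonds - model$bond_length) < 1e-9))
    D <- as.matrix(dist(Xc))
    nb <- abs(row(D) - col(D)) >= 2
    expect_true(all(D[nb] >= model$clash_radius))
    # chain-partner: no clash, but a manifest contact within d0
    cross <- complexion:::pair_dist(Xc, Pp, NULL)
    expect_gte(min(cross), cfg$partner_clash)
    expect_lte(min(cross), cfg$contact_d0)
    # the walk stopped at its first contact
    expect_gte(r$steps, 0)
    # C-terminal anchor stayed at its assigned pose
    expect_equal(unname(Xc[nrow(Xc), ]), unname(r$anchor), tolerance = 1e-9)
  }
  # anchors differ across samples; walks are seed-reproducible
  anchors <- t(vapply(res, function(r) r$anchor, numeric(3)))
  expect_equal(nrow(unique(round(anchors, 6))), 6)
  res2 <- mcrw_sample(coil, sl, cfg, model = model)
  expect_identical(coords(res2[[3]]$frame), coords(res[[3]]$frame))
  # distinct base seeds give distinct first-contact frames
  res3 <- mcrw_sample(coil, sl, mcrw_config(n_samples = 1, seed = 99,
                                            max_steps = 4000), model = model)
  expect_false(isTRUE(all.equal(coords(res3[[1]]$frame),
                                coords(res[[1]]$frame))))
})

test_that("hard-sphere MC-RW accepts every non-clashing move", {
  sl <- make_stemloop(12, seed = 6)
  model <- chain_model(rep("G", 20))
  coil <- build_random_coil(model, seed = 6)
  res <- mcrw_sample(coil, sl, mcrw_config(n_samples = 2, seed = 21,
                                           max_steps = 3000), model = model)
  for (r in res) {
    expect_equal(r$counters$metropolis_rejected, 0)
  }
})

test_that("fixed-temperature schedule runs plain Metropolis on a biased energy", {
  sl <- make_stemloop(12, seed = 7)
  model <- chain_model(rep("G", 15))
  coil <- build_random_coil(model, seed = 8)
  # strongly distance-penalizing energy with a cold fixed temperature:
  # Metropolis must reject some uphill moves
  pen <- function(X, P) 50 * min(complexion:::min_dist_to(X, P, NULL))
  res <- mcrw_sample(coil, sl,
                     mcrw_config(n_samples = 1, seed = 31, max_steps = 1500,
                                 temperature_schedule = "fixed",
                                 temp_range = c(0.05, 0.05), energy = pen),
                     model = model)
  expect_gt(res[[1]]$counters$metropolis_rejected, 0)
})
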