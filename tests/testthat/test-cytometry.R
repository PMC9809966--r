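# classifier unit tests run on a small 3-species panel; the full-size
# benchmark lives in test-acceptance.R
smallPanel <- makeSpeciesPanel(3, separation = 4, seed = 31)
smallMonos <- monoFixtures(smallPanel, n = 1200, seed = 300)

test_that("threshold gate keeps events strictly above the cutoff", {
  m <- matrix(5, 3, 23, dimnames = list(NULL, defaultChannels()))
  m[, "FL1-A"] <- c(4000, 3000, 5000)
  ev <- EventTable(m, sample_id = "x")
  kept <- thresholdGate(ev, "FL1-A", 3.5e3)
  expect_equal(nEvents(kept), 2)
  expect_equal(sort(eventMatrix(kept)[, "FL1-A"]), c(4000, 5000))
  expect_equal(sampleMeta(kept)$sample_id, "x")
  expect_equal(nEvents(thresholdGate(ev, threshold = 0)), 3)
  empty <- EventTable(m[0, , drop = FALSE])
  expect_equal(nEvents(thresholdGate(empty)), 0)
  expect_error(thresholdGate(ev, channel = "nope"), "unknown channel")
})

test_that("train/test split follows the one-seventh hold-out rule", {
  expect_equal(splitTrainTest(5000), list(n_train = 4286L, n_test = 714L))
  expect_equal(splitTrainTest(7), list(n_train = 6L, n_test = 1L))
  expect_equal(splitTrainTest(14), list(n_train = 12L, n_test = 2L))
  expect_error(splitTrainTest(6), "too small")
  for (n in c(10, 100, 4999, 5001))
    expect_equal(Reduce(`+`, splitTrainTest(n)), as.integer(n))
})

test_that("machine gating separates cells from debris on the fixture", {
  blank_sim <- simulateEvents(smallPanel, c(sp1 = 0, sp2 = 0, sp3 = 0),
                              debris_fraction = 0.999, n_events = 1200,
                              volume_ul = 10, seed = 32)
  gate <- fitGate(smallMonos[[1]], blank_sim$events, n_members = 6,
                  seed = 33)
  expect_length(gate@members, 6)
  expect_true(all(heldOutAccuracy(gate) > 0.99))
  # monoculture events pass, blank events are rejected
  expect_gt(nEvents(applyGate(gate, smallMonos[[1]])) /
              nEvents(smallMonos[[1]]), 0.95)
  expect_lt(nEvents(applyGate(gate, blank_sim$events)) /
              nEvents(blank_sim$events), 0.05)
  # empty input passes through
  em <- EventTable(eventMatrix(smallMonos[[1]])[0, , drop = FALSE])
  expect_equal(nEvents(applyGate(gate, em)), 0)
  # single-member gate honours the same contract
  g1 <- fitGate(smallMonos[[1]], blank_sim$events, n_members = 1,
                seed = 34)
  expect_length(g1@members, 1)
})

test_that("indistinguishable classes give chance-level gate accuracy", {
  a <- smallMonos[[1]]
  b <- EventTable(eventMatrix(monoFixtures(smallPanel, n = 1200,
                                           seed = 999)[[1]]))
  gate <- fitGate(a, b, n_members = 2, seed = 35)
  expect_equal(mean(heldOutAccuracy(gate)), 0.5, tolerance = 0.12)
})

test_that("vote rule equals the brute-force oracle and is monotone", {
  set.seed(36)
  species <- c("RI", "BH", "BT", "CA")
  votes <- matrix(sample(species, 500 * 10, replace = TRUE,
                         prob = c(0.5, 0.3, 0.15, 0.05)), 500, 10)
  for (thr in c(3, 5, 7, 10)) {
    got <- applyVoteRule(votes, thr, species = species)
    want <- apply(votes, 1, voteOracle, threshold = thr)
    expect_identical(got, unname(want), label = paste("threshold", thr))
  }
  # raising the threshold never decreases the unknown count
  unknowns <- vapply(1:10, function(thr)
    sum(applyVoteRule(votes, thr, species = species) == "unknown"),
    numeric(1))
  expect_true(all(diff(unknowns) >= 0))
  # worked examples: 7-3 split assigned, 6-4 split unknown, unanimity kept
  expect_identical(applyVoteRule(matrix(rep(c("BH", "BT"), c(7, 3)), 1), 7),
                   "BH")
  expect_identical(applyVoteRule(matrix(rep(c("BH", "BT"), c(6, 4)), 1), 7),
                   "unknown")
  expect_identical(applyVoteRule(matrix(rep("RI", 10), 1), 7), "RI")
  # a tie at or above a low threshold is unknown
  expect_identical(applyVoteRule(matrix(rep(c("A", "B"), 5), 1), 5),
                   "unknown")
})

test_that("species ensemble training, conservation and determinism", {
  ens <- fitSpeciesEnsemble(smallMonos, n_members = 4, n_events = 700,
                            vote_threshold = 3, seed = 37)
  expect_length(ens@members, 4)
  expect_equal(ens@nTrain + ens@nTest, 700L)
  expect_true(all(heldOutAccuracy(ens) > 0.9))
  mix <- assembleInSilicoCommunity(smallMonos,
                                   c(sp1 = 0.5, sp2 = 0.3, sp3 = 0.2),
                                   600, seed = 38)
  cc <- classifyEvents(ens, mix$events)
  expect_equal(sum(speciesCounts(cc)) + unknownCount(cc), 600)
  expect_equal(sum(speciesCounts(cc)) + unknownCount(cc),
               length(eventLabels(cc)))
  # fixed seeds reproduce the ensemble and the classification bit for bit
  ens2 <- fitSpeciesEnsemble(smallMonos, n_members = 4, n_events = 700,
                             vote_threshold = 3, seed = 37)
  cc2 <- classifyEvents(ens2, mix$events)
  expect_identical(eventLabels(cc), eventLabels(cc2))
  expect_identical(speciesCounts(cc), speciesCounts(cc2))
  expect_error(fitSpeciesEnsemble(smallMonos[1], seed = 1),
               "at least two species")
})

test_that("identical species distributions classify at chance", {
  twin <- list(a = smallMonos[[1]],
               b = monoFixtures(smallPanel, n = 1200, seed = 555)[[1]])
  ens <- fitSpeciesEnsemble(twin, n_members = 2, n_events = 700,
                            vote_threshold = 2, seed = 39)
  expect_equal(mean(heldOutAccuracy(ens)), 0.5, tolerance = 0.12)
})

test_that("in-silico assembly honours proportions and the rounding rule", {
  mix <- assembleInSilicoCommunity(smallMonos, c(sp1 = 1), 400, seed = 40)
  expect_true(all(mix$truth == "sp1"))
  mix2 <- assembleInSilicoCommunity(smallMonos,
                                    c(sp1 = 0.5, sp2 = 0.5), 1000,
                                    seed = 41)
  expect_equal(unname(table(mix2$truth)[c("sp1", "sp2")]),
               c(500L, 500L), ignore_attr = TRUE)
  mix3 <- assembleInSilicoCommunity(smallMonos,
                                    c(sp1 = 0.4, sp2 = 0.35, sp3 = 0.25),
                                    1000, seed = 42)
  expect_equal(as.vector(table(mix3$truth)[c("sp1", "sp2", "sp3")]),
               c(400L, 350L, 250L))
  expect_error(assembleInSilicoCommunity(smallMonos,
                                         c(sp1 = 0.6, sp2 = 0.3), 100),
               "sum to 1")
})

test_that("evaluation separates lenient and strict accuracy", {
  ens <- fitSpeciesEnsemble(smallMonos, n_members = 4, n_events = 700,
                            vote_threshold = 3, seed = 43)
  mix <- assembleInSilicoCommunity(smallMonos,
                                   c(sp1 = 0.4, sp2 = 0.3, sp3 = 0.3),
                                   600, seed = 44)
  ev <- evaluateEnsemble(ens, mix$events, mix$truth)
  expect_gte(ev$accuracy, ev$strict_accuracy)
  expect_equal(rowSums(ev$confusion),
               c(table(mix$truth)[rownames(ev$confusion)]),
               ignore_attr = TRUE)
  expect_equal(ev$strict_accuracy,
               ev$accuracy * (1 - ev$unknown_fraction), tolerance = 1e-12)
  expect_error(evaluateEnsemble(ens, mix$events, mix$truth[-1]),
               "length")
  # events from a species never seen in training cannot be scored correct
  alien <- monoFixtures(makeSpeciesPanel(4, separation = 6, seed = 77),
                        n = 300, seed = 700)[[4]]
  ev2 <- evaluateEnsemble(ens, alien, rep("sp9", nEvents(alien)))
  expect_equal(ev2$strict_accuracy, 0)
})
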