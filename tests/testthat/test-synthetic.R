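test_that("species panel geometry and determinism", {
  p0 <- makeSpeciesPanel(3, separation = 0, seed = 60)
  mus <- do.call(rbind, p0$species)
  expect_true(all(apply(mus, 2, function(x) diff(range(x))) == 0))
  p1 <- makeSpeciesPanel(3, separation = 4, seed = 60)
  p2 <- makeSpeciesPanel(3, separation = 4, seed = 60)
  expect_identical(p1, p2)
  # closest pair sits at the nominal Mahalanobis separation
  mus <- do.call(rbind, p1$species)
  dm <- as.matrix(dist(mus)) / p1$log_sd
  expect_equal(min(dm[upper.tri(dm)]), 4, tolerance = 1e-9)
  expect_error(makeSpeciesPanel(2, separation = -1), "separation")
  expect_error(makeSpeciesPanel(0), "n_species")
})

test_that("two separated clouds are nearly separable by the true model", {
  panel <- makeSpeciesPanel(2, separation = 4, seed = 61)
  mus <- do.call(rbind, panel$species)
  set.seed(62)
  n <- 20000
  y <- sample(2, n, replace = TRUE)
  x <- mus[y, ] + matrix(rnorm(n * 23, 0, panel$log_sd), n, 23)
  d2 <- sapply(1:2, function(i) rowSums(sweep(x, 2, mus[i, ])^2))
  err <- mean(max.col(-d2) != y)
  expect_lt(err, 0.05)                       # Gaussian overlap pnorm(-2)
  expect_equal(err, pnorm(-2), tolerance = 0.3)
})

test_that("simulated acquisitions carry recoverable densities", {
  panel <- makeSpeciesPanel(2, separation = 4, seed = 63)
  one <- simulateEvents(panel, c(sp1 = 1e6, sp2 = 0), n_events = 500,
                        seed = 64)
  expect_true(all(one$truth == "sp1"))
  sim <- simulateEvents(panel, c(sp1 = 3e6, sp2 = 1e6), n_events = 1e4,
                        seed = 65)
  md <- sampleMeta(sim$events)
  recovered <- volumetricCount(nEvents(sim$events), md$acquired_volume_ul,
                               md$dilution_factor)
  expect_equal(recovered / 4e6, 1, tolerance = 0.05)
  expect_equal(mean(sim$truth == "sp1"), 0.75, tolerance = 0.02)
  expect_error(simulateEvents(panel, c(sp1 = 0, sp2 = 0)), "zero")
  # determinism
  sim2 <- simulateEvents(panel, c(sp1 = 3e6, sp2 = 1e6), n_events = 1e4,
                         seed = 65)
  expect_identical(eventMatrix(sim$events), eventMatrix(sim2$events))
})

test_that("chemostat washout follows the closed form at D = 1/24", {
  traj <- defaultTrajectoryConfig(washout = TRUE)
  traj$sigma_bio <- 0
  traj$timepoints <- c(12, 36)
  truth <- simulateTimeseries(traj, seed = 66)
  pc <- truth$densities[, , "PC"]
  expect_equal(pc[1, "36"] / pc[1, "12"], exp(-1), tolerance = 1e-9)
  # all vessels identical without biological noise
  expect_true(all(apply(truth$densities, c(2, 3),
                        function(x) diff(range(x))) == 0))
})

test_that("washed-out species declines in relative abundance", {
  traj <- defaultTrajectoryConfig(washout = TRUE)
  truth <- simulateTimeseries(traj, seed = 67)
  rel_pc <- apply(truth$densities, 2, function(m) {
    mean(m[, "PC"] / rowSums(m))
  })
  expect_true(all(diff(rel_pc) < 0))
})

test_that("16S counts reflect density times copy number", {
  traj <- defaultTrajectoryConfig()
  traj$sigma_bio <- 0
  traj$sigma_tech <- 0
  traj$sigma_batch <- 0
  traj$depth <- 100000L
  truth <- simulateTimeseries(traj, seed = 68)
  tabs <- simulate16S(truth, traj, seed = 69)
  expect_length(tabs, 3)
  counts <- tableValues(tabs[[1]])
  expect_equal(nrow(counts), 36)
  expect_true(all(rowSums(counts) == traj$depth))
  copies <- setNames(traj$species$copy_number, traj$species$species)
  i <- 5  # arbitrary sample; noise-free shares are exact up to sampling
  vessel <- sampleMeta(tabs[[1]])$vessel[i]
  tp <- as.character(sampleMeta(tabs[[1]])$timepoint[i])
  expected <- truth$densities[vessel, tp, ] * copies
  expected <- expected / sum(expected)
  expect_equal(unname(counts[i, ] / sum(counts[i, ])), unname(expected),
               tolerance = 0.02)
  # copy-number correction then recovers the true composition
  rel <- correctCopyNumber(tabs[[1]], copies)
  truth_rel <- truth$densities[vessel, tp, ] /
    sum(truth$densities[vessel, tp, ])
  expect_equal(unname(tableValues(rel)[i, ]), unname(truth_rel),
               tolerance = 0.02)
})

test_that("multinomial sampling noise has the expected spread", {
  traj <- defaultTrajectoryConfig()
  traj$sigma_bio <- 0; traj$sigma_tech <- 0; traj$sigma_batch <- 0
  traj$depth <- 10000L
  traj$species$x0 <- rep(5e5, 4)
  traj$species$batch_rate <- rep(0.4, 4)
  traj$species$steady_state <- rep(2e8, 4)
  traj$species$copy_number <- rep(4, 4)
  traj$timepoints <- 12
  truth <- simulateTimeseries(traj, n_vessels = 2, seed = 70)
  tab <- simulate16S(truth, traj, n_tech = 1, seed = 71)[[1]]
  # equal densities, equal copies: 2500 per taxon +/- 3 multinomial SDs
  expect_true(all(abs(tableValues(tab) - 2500) <= 150))
})

test_that("technical noise exceeds vessel noise in across-group CVs", {
  traj <- defaultTrajectoryConfig()  # sigma_tech 0.5 > sigma_bio 0.15
  truth <- simulateTimeseries(traj, seed = 72)
  tabs <- simulate16S(truth, traj, seed = 73)
  copies <- setNames(traj$species$copy_number, traj$species$species)
  rels <- lapply(tabs, correctCopyNumber, copies = copies)
  # CV across technical replicates, per (vessel, timepoint, taxon)
  v1 <- tableValues(rels[[1]]); v2 <- tableValues(rels[[2]])
  v3 <- tableValues(rels[[3]])
  cv_tech <- mapply(function(a, b, c_) coefficientOfVariation(c(a, b, c_)),
                    v1, v2, v3)
  # CV across vessels for replicate 1, per (timepoint, taxon)
  cv_bio <- tableValues(cvTable(rels[[1]]))
  expect_gt(mean(cv_tech, na.rm = TRUE), mean(cv_bio, na.rm = TRUE))
})

test_that("metabolite templates behave as designed", {
  traj <- defaultTrajectoryConfig()
  traj$sigma_met <- 0
  met <- simulateMetabolites(traj, seed = 74)
  v <- tableValues(met)
  meta <- sampleMeta(met)
  # zero noise: vessels identical
  at <- function(tp) v[meta$timepoint == tp, , drop = FALSE]
  expect_true(all(apply(at(25), 2, function(x) diff(range(x))) == 0))
  tmpl <- setNames(traj$metabolites$template, traj$metabolites$metabolite)
  two_phase <- names(tmpl)[tmpl == "two_phase"]
  plateau <- names(tmpl)[tmpl == "plateau"]
  depleted <- names(tmpl)[tmpl == "depleted"]
  expect_true(all(at(25)[1, two_phase] > at(67)[1, two_phase]))
  expect_true(all(abs(at(67)[1, plateau] - at(61)[1, plateau]) <
                    0.02 * at(67)[1, plateau]))
  # substrates are essentially exhausted by the end of batch
  expect_true(all(at(12)[1, depleted] <
                    0.01 * traj$metabolites$scale[tmpl == "depleted"]))
  # determinism with noise on
  traj$sigma_met <- 0.05
  m1 <- simulateMetabolites(traj, seed = 75)
  m2 <- simulateMetabolites(traj, seed = 75)
  expect_identical(tableValues(m1), tableValues(m2))
})

test_that("per-vessel community acquisitions are generated and labelled", {
  traj <- defaultTrajectoryConfig()
  traj$timepoints <- c(12, 25)
  truth <- simulateTimeseries(traj, n_vessels = 2, seed = 76)
  panel <- makeSpeciesPanel(4, separation = 4, seed = 77)
  comm <- simulateCommunityEvents(truth, panel, n_events = 400, seed = 78)
  expect_length(comm, 4)
  expect_named(comm, c("V1_12", "V1_25", "V2_12", "V2_25"))
  expect_true(all(vapply(comm, function(s)
    all(s$truth %in% c(traj$species$species, "debris")), logical(1))))
  md <- sampleMeta(comm[["V2_25"]]$events)
  expect_equal(md$vessel, "V2")
  expect_equal(md$timepoint, 25)
})
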