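# Classifier-based processing of flow-cytometry events: threshold and
# machine gating (cells vs debris), per-species voting ensembles trained on
# gated monocultures, and in-silico community evaluation.

.subsetEvents <- function(events, idx) {
  md <- sampleMeta(events)
  new("EventTable", exprs = eventMatrix(events)[idx, , drop = FALSE],
      meta = md)
}

.rangerFit <- function(x, y, n_trees, seed) {
  ranger::ranger(x = as.data.frame(x), y = factor(y),
                 num.trees = n_trees, seed = seed, num.threads = 1,
                 verbose = FALSE)
}

.rangerPredict <- function(model, x) {
  # fixed prediction seed: ranger breaks per-tree vote ties randomly
  as.character(stats::predict(model, data = as.data.frame(x),
                              num.threads = 1, verbose = FALSE,
                              seed = 1L)$predictions)
}

#' Threshold gate on one fluorescence channel
#'
#' The manual-gating variant: retains events whose value on the given
#' channel strictly exceeds the threshold. The study gated SYBR-stained
#' samples against a medium blank on FL1-A at 3.5e3.
#'
#' @param events an \linkS4class{EventTable}.
#' @param channel channel to gate on (default \code{"FL1-A"}).
#' @param threshold non-negative gate value (default 3.5e3).
#' @return the gated \linkS4class{EventTable} (metadata preserved).
#' @export
thresholdGate <- function(events, channel = "FL1-A", threshold = 3.5e3) {
  m <- eventMatrix(events)
  if (!channel %in% colnames(m))
    stop("unknown channel '", channel, "'")
  if (threshold < 0) stop("threshold must be >= 0")
  .subsetEvents(events, which(m[, channel] > threshold))
}

#' Train a machine-gating model (cells vs debris)
#'
#' Trains \code{n_members} binary random-forest classifiers distinguishing
#' monoculture (cell) events from blank (debris/background) events. Members
#' differ only in their resampling/training seed; each reports accuracy on
#' its own held-out split (one seventh of the data, the same split rule
#' used for the species ensembles).
#'
#' @param monoculture \linkS4class{EventTable} of cell-dominated events.
#' @param blank \linkS4class{EventTable} of blank-vessel events.
#' @param n_members number of classifiers (default 6).
#' @param n_trees trees per forest (default 100).
#' @param seed integer seed.
#' @return A \linkS4class{GateModel}.
#' @export
fitGate <- function(monoculture, blank, n_members = 6L, n_trees = 100L,
                    seed = 1L) {
  if (nEvents(monoculture) == 0 || nEvents(blank) == 0)
    stop("monoculture and blank must be non-empty")
  if (!identical(channelNames(monoculture), channelNames(blank)))
    stop("channel mismatch between monoculture and blank")
  x <- rbind(eventMatrix(monoculture), eventMatrix(blank))
  y <- rep(c("cell", "debris"), c(nEvents(monoculture), nEvents(blank)))
  n <- nrow(x)
  n_test <- max(1L, n %/% 7L)
  members <- vector("list", n_members)
  acc <- numeric(n_members)
  for (m in seq_len(n_members)) {
    mseed <- seed + m - 1L
    test_idx <- .withSeed(mseed, sample.int(n, n_test))
    fit <- .rangerFit(x[-test_idx, , drop = FALSE], y[-test_idx],
                      n_trees, mseed)
    pred <- .rangerPredict(fit, x[test_idx, , drop = FALSE])
    acc[m] <- mean(pred == y[test_idx])
    members[[m]] <- fit
  }
  new("GateModel", members = members, channels = channelNames(monoculture),
      heldOutAccuracy = acc,
      trainSizes = list(cell = nEvents(monoculture),
                        debris = nEvents(blank)))
}

#' Apply a machine gate
#'
#' Retains events voted "cell" by at least \code{min_votes} gate members
#' (default: majority, \code{ceiling(n_members / 2)}).
#'
#' @param gate a \linkS4class{GateModel}.
#' @param events an \linkS4class{EventTable} on the gate's channels.
#' @param min_votes minimum "cell" votes to retain an event.
#' @return the gated \linkS4class{EventTable}.
#' @export
applyGate <- function(gate, events, min_votes = NULL) {
  if (!identical(channelNames(events), gate@channels))
    stop("channel mismatch between gate and events")
  k <- length(gate@members)
  if (is.null(min_votes)) min_votes <- as.integer(ceiling(k / 2))
  if (min_votes < 1L || min_votes > k)
    stop("min_votes must be between 1 and the number of members")
  if (nEvents(events) == 0) return(events)
  m <- eventMatrix(events)
  votes <- rowSums(vapply(gate@members,
                          function(f) .rangerPredict(f, m) == "cell",
                          logical(nrow(m))))
  .subsetEvents(events, which(votes >= min_votes))
}

#' Train/test split rule
#'
#' One seventh of the events (rounded down) is held out for testing and
#' the rest used for training: 5000 events split as 4286 training and 714
#' test.
#'
#' @param n_events total events per species (default 5000).
#' @return list with \code{n_train} and \code{n_test}.
#' @export
#' @examples
#' splitTrainTest(5000)  # 4286 / 714
splitTrainTest <- function(n_events = 5000L) {
  n_events <- as.integer(n_events)
  n_test <- n_events %/% 7L
  if (n_test < 1L)
    stop("n_events too small: at least 7 events required for a split")
  list(n_train = n_events - n_test, n_test = n_test)
}

#' Train a species-classification voting ensemble
#'
#' Trains \code{n_members} multiclass random forests, each on an
#' independent random draw of \code{n_events} events per gated monoculture
#' (without replacement when the monoculture is large enough, with
#' replacement otherwise), split into train and test portions by
#' \code{\link{splitTrainTest}}. Per-member held-out accuracy is recorded.
#'
#' @param gated_monocultures named list of gated
#'   \linkS4class{EventTable}s, one per species (>= 2 species).
#' @param n_members ensemble size (default 10).
#' @param n_events events sampled per species and member (default 5000).
#' @param vote_threshold minimum agreeing votes for a species call
#'   (default 7).
#' @param n_trees trees per forest (default 100).
#' @param seed integer seed; fixed seed gives bit-identical ensembles.
#' @return A \linkS4class{SpeciesEnsemble}.
#' @export
fitSpeciesEnsemble <- function(gated_monocultures, n_members = 10L,
                               n_events = 5000L, vote_threshold = 7L,
                               n_trees = 100L, seed = 1L) {
  species <- names(gated_monocultures)
  if (length(species) < 2L)
    stop("at least two species required for classification")
  ch <- channelNames(gated_monocultures[[1]])
  for (s in species)
    if (!identical(channelNames(gated_monocultures[[s]]), ch))
      stop("channel mismatch in monoculture '", s, "'")
  split <- splitTrainTest(n_events)
  members <- vector("list", n_members)
  acc <- numeric(n_members)
  for (m in seq_len(n_members)) {
    mseed <- seed + 1000L * m
    parts <- .withSeed(mseed, lapply(species, function(s) {
      pool <- eventMatrix(gated_monocultures[[s]])
      idx <- if (nrow(pool) >= n_events) sample.int(nrow(pool), n_events)
             else sample.int(nrow(pool), n_events, replace = TRUE)
      test <- sample.int(n_events, split$n_test)
      list(train = pool[idx[-test], , drop = FALSE],
           test = pool[idx[test], , drop = FALSE])
    }))
    xtr <- do.call(rbind, lapply(parts, `[[`, "train"))
    ytr <- rep(species, each = split$n_train)
    xte <- do.call(rbind, lapply(parts, `[[`, "test"))
    yte <- rep(species, each = split$n_test)
    fit <- .rangerFit(xtr, ytr, n_trees, mseed)
    acc[m] <- mean(.rangerPredict(fit, xte) == yte)
    members[[m]] <- fit
  }
  new("SpeciesEnsemble", members = members, speciesLabels = species,
      voteThreshold = as.integer(vote_threshold), heldOutAccuracy = acc,
      channels = ch, nTrain = as.integer(split$n_train),
      nTest = as.integer(split$n_test))
}

#' Vote-threshold rule
#'
#' Applies the agreement rule to a matrix of per-member species votes: an
#' event is assigned its modal species when that species received at least
#' \code{threshold} votes, and \code{"unknown"} otherwise. A tie between
#' two modal species at or above the threshold (possible only for
#' thresholds at or below half the members) also yields
#' \code{"unknown"}.
#'
#' @param votes character matrix, events x members.
#' @param threshold minimum agreeing votes.
#' @param species optional species universe (defaults to labels observed).
#' @return character vector of per-event labels.
#' @export
applyVoteRule <- function(votes, threshold, species = NULL) {
  votes <- as.matrix(votes)
  if (is.null(species)) species <- sort(unique(as.vector(votes)))
  tally <- vapply(species, function(s) rowSums(votes == s),
                  numeric(nrow(votes)))
  tally <- matrix(tally, nrow = nrow(votes),
                  dimnames = list(NULL, species))
  top <- max.col(tally, ties.method = "first")
  topcount <- tally[cbind(seq_len(nrow(tally)), top)]
  tied <- rowSums(tally == topcount) > 1L
  out <- ifelse(topcount >= threshold & !tied, species[top], "unknown")
  as.character(out)
}

#' Classify community events with a species ensemble
#'
#' Each ensemble member predicts a species for every event; events are
#' assigned by the vote-threshold rule (\code{\link{applyVoteRule}}), with
#' insufficient agreement labelled \code{"unknown"}.
#'
#' @param ensemble a \linkS4class{SpeciesEnsemble}.
#' @param community an \linkS4class{EventTable} (gated community sample).
#' @param keep_labels keep the per-event label vector (default TRUE).
#' @return A \linkS4class{ClassifiedCounts}; species counts plus unknown
#'   sum to the gated event count.
#' @export
classifyEvents <- function(ensemble, community, keep_labels = TRUE) {
  if (!identical(channelNames(community), ensemble@channels))
    stop("channel mismatch between ensemble and community events")
  m <- eventMatrix(community)
  sp <- ensemble@speciesLabels
  if (nrow(m) == 0) {
    return(new("ClassifiedCounts",
               counts = stats::setNames(numeric(length(sp)), sp),
               unknown = 0, labels = character(0),
               meta = sampleMeta(community)))
  }
  votes <- vapply(ensemble@members, function(f) .rangerPredict(f, m),
                  character(nrow(m)))
  votes <- matrix(votes, nrow = nrow(m))
  labels <- applyVoteRule(votes, ensemble@voteThreshold, species = sp)
  counts <- vapply(sp, function(s) sum(labels == s), numeric(1))
  new("ClassifiedCounts", counts = counts,
      unknown = sum(labels == "unknown"),
      labels = if (keep_labels) labels else character(0),
      meta = sampleMeta(community))
}

#' Assemble an in-silico community from monoculture events
#'
#' Samples events from gated monocultures at given proportions, shuffles
#' them, and returns the mixed events together with the hidden truth
#' labels, for classifier evaluation. Per-species event counts are
#' \code{floor(proportion * n_events)} with the rounding remainder given
#' to the species with the largest proportion.
#'
#' @param gated_monocultures named list of gated
#'   \linkS4class{EventTable}s.
#' @param proportions named numeric vector summing to 1 (within 1e-9).
#' @param n_events total events in the assembled community.
#' @param seed integer seed.
#' @return list with \code{events} (an \linkS4class{EventTable}, role
#'   "community") and \code{truth} (character vector of source species).
#' @export
assembleInSilicoCommunity <- function(gated_monocultures, proportions,
                                      n_events, seed = 1L) {
  if (abs(sum(proportions) - 1) > 1e-9)
    stop("proportions must sum to 1")
  sp <- names(proportions)
  if (!all(sp %in% names(gated_monocultures)))
    stop("missing monoculture for: ",
         paste(setdiff(sp, names(gated_monocultures)), collapse = ", "))
  counts <- floor(proportions * n_events)
  rem <- n_events - sum(counts)
  if (rem > 0) {
    big <- which.max(proportions)
    counts[big] <- counts[big] + rem
  }
  .withSeed(seed, {
    chunks <- lapply(sp, function(s) {
      pool <- eventMatrix(gated_monocultures[[s]])
      if (nrow(pool) < counts[s])
        stop("monoculture '", s, "' has fewer than ", counts[s], " events")
      pool[sample.int(nrow(pool), counts[s]), , drop = FALSE]
    })
    m <- do.call(rbind, chunks)
    truth <- rep(sp, counts)
    ord <- sample.int(nrow(m))
    list(events = EventTable(m[ord, , drop = FALSE],
                             sample_id = "in_silico",
                             role = "community"),
         truth = truth[ord])
  })
}

#' Evaluate a species ensemble on a community with known truth
#'
#' @param ensemble a \linkS4class{SpeciesEnsemble}.
#' @param community an \linkS4class{EventTable}.
#' @param truth character vector of true species labels, one per event.
#' @return list with \code{accuracy} (correct / classified, unknowns
#'   excluded; NA when everything is unknown), \code{strict_accuracy}
#'   (correct / total, unknowns counted as errors), \code{unknown_fraction},
#'   \code{confusion} (truth x predicted matrix whose rows sum to the truth
#'   counts) and the \linkS4class{ClassifiedCounts}.
#' @export
evaluateEnsemble <- function(ensemble, community, truth) {
  if (length(truth) != nEvents(community))
    stop("truth length must equal the event count")
  cc <- classifyEvents(ensemble, community, keep_labels = TRUE)
  pred <- eventLabels(cc)
  lev_t <- sort(unique(truth))
  lev_p <- c(ensemble@speciesLabels, "unknown")
  confusion <- table(factor(truth, levels = lev_t),
                     factor(pred, levels = lev_p))
  classified <- pred != "unknown"
  correct <- sum(pred == truth & classified)
  list(accuracy = if (any(classified)) correct / sum(classified)
                  else NA_real_,
       strict_accuracy = correct / length(truth),
       unknown_fraction = mean(!classified),
       confusion = unclass(confusion),
       counts = cc)
}
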