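# Shared fixtures and independent oracles, all built in code at test time.

# pure monoculture event tables (no debris) from a species panel
monoFixtures <- function(panel, n = 1500L, seed = 100L) {
  sp <- names(panel$species)
  out <- lapply(seq_along(sp), function(i) {
    comp <- stats::setNames(rep(0, length(sp)), sp)
    comp[i] <- 2e8
    simulateEvents(panel, comp, debris_fraction = 0, n_events = n,
                   seed = seed + i, sample_id = paste0("mono_", sp[i]),
                   role = "monoculture")$events
  })
  names(out) <- sp
  out
}

# brute-force signed-rank oracle: full 2^n enumeration over sign patterns,
# average ranks for tied absolute differences
wilcoxOracle <- function(d, alternative = "two.sided") {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 14)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  w_all <- vapply(0:(2^n - 1), function(mask) {
    sum(r[bitwAnd(bitwShiftR(mask, seq_len(n) - 1L), 1L) == 1L])
  }, numeric(1))
  p_le <- mean(w_all <= w_obs + 1e-12)
  p_ge <- mean(w_all >= w_obs - 1e-12)
  switch(alternative,
         greater = p_ge,
         less = p_le,
         two.sided = min(1, 2 * min(p_le, p_ge)))
}

# brute-force vote-rule oracle for a single event's votes
voteOracle <- function(votes, threshold) {
  tab <- table(votes)
  top <- max(tab)
  winners <- names(tab)[tab == top]
  if (top >= threshold && length(winners) == 1L) winners else "unknown"
}

# SampleTable spanning vessels x timepoints (replicate 1) with given values
gridSampleTable <- function(values, vessels, timepoints, kind = "relative") {
  ids <- paste(rep(vessels, each = length(timepoints)),
               rep(timepoints, times = length(vessels)), 1, sep = "_")
  rownames(values) <- ids
  meta <- data.frame(sample_id = ids,
                     vessel = rep(vessels, each = length(timepoints)),
                     timepoint = rep(timepoints, times = length(vessels)),
                     replicate = 1L, stringsAsFactors = FALSE)
  SampleTable(values, kind = kind, meta = meta)
}
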