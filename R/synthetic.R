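# Synthetic-data generator emulating the study design: species-specific
# log-normal event clouds in 23 channels, six replicate vessels sampled at
# {12, 25, 37, 49, 61, 67} h (12 h batch, then an emulated chemostat with
# a complete medium changeover in 24 h, D = 1/24 per h), triplicate 16S
# counts whose technical noise exceeds vessel-to-vessel noise, and
# two-phase metabolite trajectories.

#' Build a species event-cloud panel
#'
#' Species event distributions are multivariate log-normal over the
#' channel set (flow data are positive and right-skewed), with diagonal
#' log-scale covariance. Each species' mean is shifted from a common
#' baseline along its own pair of channels -- mirroring real panels, where
#' species differ strongly on a few informative detectors (size scatter,
#' specific fluorescence) rather than diffusely on all -- with magnitudes
#' chosen so the closest species pair sits exactly at Mahalanobis distance
#' \code{separation} and farther pairs progressively (15\% per species
#' index) beyond it. Separation 0 makes all species identical; the default
#' separation of 4 gives the well-separated benchmark panel (optimal
#' two-class error pnorm(-separation/2) = 0.023 for the closest pair). A
#' debris/blank cloud sits well below the species clouds with a wider
#' spread.
#'
#' @param n_species number of species (>= 1).
#' @param separation pairwise Mahalanobis distance between species means
#'   (>= 0; default 4).
#' @param channels channel names (default the 23-parameter set).
#' @param log_sd log-scale standard deviation of each channel (default
#'   0.3).
#' @param seed integer seed.
#' @return list with \code{species} (named list of log-mean vectors),
#'   \code{debris} (log-mean and log-sd), \code{channels}, \code{log_sd},
#'   \code{separation}.
#' @export
makeSpeciesPanel <- function(n_species, separation = 4,
                             channels = defaultChannels(), log_sd = 0.3,
                             seed = 1L) {
  if (n_species < 1L) stop("n_species must be >= 1")
  if (separation < 0) stop("separation must be >= 0")
  if (log_sd <= 0) stop("log_sd must be positive (covariance must be PD)")
  p <- length(channels)
  if (n_species > p %/% 2L)
    stop("at most ", p %/% 2L, " species supported on ", p, " channels")
  .withSeed(seed, {
    base <- stats::runif(p, log(2e3), log(3e4))
    mag <- 1 + 0.15 * (seq_len(n_species) - 1)
    if (n_species >= 2L) mag <- mag / sqrt((mag[1]^2 + mag[2]^2) / 2)
    sp <- lapply(seq_len(n_species), function(i) {
      u <- numeric(p)
      u[c(2L * i - 1L, 2L * i)] <- 1 / sqrt(2)
      stats::setNames(base + (separation / sqrt(2)) * log_sd * mag[i] * u,
                      channels)
    })
    names(sp) <- paste0("sp", seq_len(n_species))
    list(species = sp,
         debris = list(mean = stats::setNames(base - 2.5, channels),
                       log_sd = 2 * log_sd),
         channels = channels, log_sd = log_sd, separation = separation)
  })
}

.drawCloud <- function(n, mean_log, log_sd) {
  p <- length(mean_log)
  m <- matrix(stats::rnorm(n * p, rep(mean_log, each = n), log_sd),
              nrow = n, ncol = p, dimnames = list(NULL, names(mean_log)))
  exp(m)
}

#' Simulate one flow-cytometry acquisition
#'
#' Draws events from a species panel at given cell densities plus an
#' optional debris population. Event counts are Poisson around the
#' volumetric expectation, so \code{\link{volumetricCount}} applied to the
#' cell events recovers the summed density in expectation.
#'
#' @param panel a panel from \code{\link{makeSpeciesPanel}}.
#' @param composition named vector of cell densities (cells/ml); names
#'   must be panel species.
#' @param debris_fraction expected fraction of debris events in [0, 1).
#' @param n_events expected total number of events; used to choose the
#'   acquisition volume when \code{volume_ul} is NULL.
#' @param dilution dilution factor (default 100, as in the study).
#' @param volume_ul acquired volume in microlitres; computed from
#'   \code{n_events} when NULL.
#' @param seed integer seed.
#' @param sample_id,vessel,timepoint,role metadata for the returned table.
#' @return list with \code{events} (an \linkS4class{EventTable}) and
#'   \code{truth} (species label or \code{"debris"} per event).
#' @export
simulateEvents <- function(panel, composition, debris_fraction = 0,
                           n_events = 10000L, dilution = 100,
                           volume_ul = NULL, seed = 1L,
                           sample_id = "sim", vessel = NA_character_,
                           timepoint = NA_real_, role = "community") {
  if (any(composition < 0)) stop("densities must be >= 0")
  if (debris_fraction < 0 || debris_fraction >= 1)
    stop("debris_fraction must be in [0, 1)")
  total <- sum(composition)
  if (total == 0 && debris_fraction == 0)
    stop("all densities zero and no debris: nothing to simulate")
  if (is.null(volume_ul)) {
    if (total == 0) stop("volume_ul required when all densities are zero")
    volume_ul <- n_events * (1 - debris_fraction) * 1000 * dilution / total
  }
  lambda_cells <- total * volume_ul / (1000 * dilution)
  lambda_debris <- if (debris_fraction == 0) 0
    else if (total > 0) (lambda_cells * debris_fraction) /
      (1 - debris_fraction)
    else n_events  # blank acquisition: debris only
  if (lambda_cells == 0 && lambda_debris == 0)
    stop("nothing to simulate: zero cell and debris rates")
  .withSeed(seed, {
    n_cells <- stats::rpois(1, lambda_cells)
    n_debris <- stats::rpois(1, lambda_debris)
    sp_names <- names(composition)
    labels <- character(0)
    chunks <- list()
    if (n_cells > 0) {
      draw <- sample(sp_names, n_cells, replace = TRUE,
                     prob = composition / total)
      counts <- table(factor(draw, levels = sp_names))
      chunks <- lapply(sp_names, function(s) {
        .drawCloud(counts[[s]], panel$species[[s]], panel$log_sd)
      })
      labels <- rep(sp_names, counts)
    }
    if (n_debris > 0) {
      chunks <- c(chunks, list(.drawCloud(n_debris, panel$debris$mean,
                                          panel$debris$log_sd)))
      labels <- c(labels, rep("debris", n_debris))
    }
    m <- do.call(rbind, chunks)
    ord <- sample.int(nrow(m))
    list(events = EventTable(m[ord, , drop = FALSE], sample_id = sample_id,
                             vessel = vessel, timepoint = timepoint,
                             dilution_factor = dilution,
                             acquired_volume_ul = volume_ul, role = role),
         truth = labels[ord])
  })
}

#' Default trajectory configuration
#'
#' Mirrors the study design: six vessels, timepoints {12, 25, 37, 49, 61,
#' 67} h, 12 h of batch growth followed by an emulated chemostat whose
#' continuous feed replaces the medium completely in 24 h (dilution rate
#' D = 1/24 per h), three technical sequencing replicates per sample, and
#' technical noise (sigma_tech = 0.5) exceeding vessel-to-vessel noise
#' (sigma_bio = 0.15). Species parameters (initial densities around the
#' study's inoculation density, batch growth rates, chemostat steady
#' states) and 16S copy numbers are synthetic but realistic for gut
#' anaerobes; they are generator truth, not measurements.
#'
#' @param n_species number of growing species (default 4, matching the
#'   community consistently detected after batch).
#' @param washout add a non-growing species that washes out in chemostat
#'   mode (zero net growth; density decays as exp(-D (t - 12))); default
#'   FALSE.
#' @param contaminant spike a low-abundance contaminant taxon into two
#'   samples of the first sequencing replicate; default FALSE.
#' @return list of generator parameters (see the fields in the source or
#'   the methods vignette): species table, dilution rate \code{D},
#'   \code{batch_hours}, \code{timepoints}, \code{n_vessels},
#'   \code{n_tech}, \code{sigma_bio}, \code{sigma_tech},
#'   \code{sigma_batch}, sequencing \code{depth}, metabolite templates.
#' @export
defaultTrajectoryConfig <- function(n_species = 4L, washout = FALSE,
                                    contaminant = FALSE) {
  base <- data.frame(
    species = c("RI", "BH", "BT", "CA"),
    x0 = c(5e5, 5e5, 5e5, 5e5),
    batch_rate = c(0.35, 0.30, 0.50, 0.40),
    chemostat_rate = c(0.042, 0.042, 0.042, 0.042),
    steady_state = c(3e8, 6e8, 1.5e8, 2e8),
    copy_number = c(6, 5, 5, 3),
    stringsAsFactors = FALSE)
  species <- base[seq_len(min(n_species, 4L)), ]
  if (n_species > 4L) {
    extra <- data.frame(
      species = paste0("X", seq_len(n_species - 4L)),
      x0 = 5e5, batch_rate = 0.4, chemostat_rate = 0.042,
      steady_state = 2e8, copy_number = 4)
    species <- rbind(species, extra)
  }
  if (washout)
    species <- rbind(species, data.frame(
      species = "PC", x0 = 5e5, batch_rate = 0.45, chemostat_rate = 0,
      steady_state = 0, copy_number = 4))
  metabolites <- data.frame(
    metabolite = c("GLUCOSE", "TREHALOSE", "FORMIC", "PYRUVIC", "SUCCINIC",
                   "LACTIC", "ACETIC", "PROPIONIC", "BUTYRIC",
                   "ISO-VALERIC"),
    template = c("depleted", "depleted", "two_phase", "two_phase",
                 "two_phase", "two_phase", "plateau", "plateau", "plateau",
                 "plateau"),
    scale = c(30, 10, 12, 4, 8, 10, 40, 6, 15, 2),
    stringsAsFactors = FALSE)
  list(species = species, D = 1 / 24, batch_hours = 12,
       timepoints = c(12, 25, 37, 49, 61, 67), n_vessels = 6L,
       n_tech = 3L, sigma_bio = 0.15, sigma_tech = 0.5,
       sigma_batch = 0.25, depth = 10000L, sigma_met = 0.05,
       metabolites = metabolites, contaminant = contaminant)
}

#' Simulate vessel time series of true species densities
#'
#' Batch phase: exponential growth at the batch rate until
#' \code{batch_hours}. Chemostat phase: exponential relaxation towards the
#' per-species steady state at the dilution rate D,
#' x(t) = K + (x(12) - K) exp(-D (t - 12)); a species with zero chemostat
#' net growth has K = 0 and washes out as exp(-D (t - 12)). Each (vessel,
#' timepoint, species) density carries an independent log-normal
#' vessel-to-vessel multiplier with log-sd \code{sigma_bio}; with
#' \code{sigma_bio = 0} all vessels are identical.
#'
#' @param traj a configuration from \code{\link{defaultTrajectoryConfig}}
#'   (fields can be edited before the call).
#' @param n_vessels number of replicate vessels (default from config).
#' @param seed integer seed.
#' @return list (ground truth) with \code{densities}, a vessel x timepoint
#'   x species array (cells/ml), and \code{config}.
#' @export
simulateTimeseries <- function(traj = defaultTrajectoryConfig(),
                               n_vessels = traj$n_vessels, seed = 1L) {
  sp <- traj$species
  tp <- traj$timepoints
  det <- sapply(seq_len(nrow(sp)), function(i) {
    x12 <- sp$x0[i] * exp(sp$batch_rate[i] * traj$batch_hours)
    vapply(tp, function(t) {
      if (t <= traj$batch_hours) {
        sp$x0[i] * exp(sp$batch_rate[i] * t)
      } else {
        K <- if (sp$chemostat_rate[i] == 0) 0 else sp$steady_state[i]
        K + (x12 - K) * exp(-traj$D * (t - traj$batch_hours))
      }
    }, numeric(1))
  })
  det <- matrix(det, nrow = length(tp),
                dimnames = list(NULL, sp$species))
  vessels <- paste0("V", seq_len(n_vessels))
  dens <- array(NA_real_, c(n_vessels, length(tp), nrow(sp)),
                dimnames = list(vessels, as.character(tp), sp$species))
  .withSeed(seed, {
    for (v in seq_len(n_vessels)) {
      noise <- if (traj$sigma_bio > 0)
        exp(matrix(stats::rnorm(length(tp) * nrow(sp), 0, traj$sigma_bio),
                   length(tp), nrow(sp)))
      else matrix(1, length(tp), nrow(sp))
      dens[v, , ] <- det * noise
    }
  })
  list(densities = dens, config = traj)
}

#' Simulate triplicate 16S count tables
#'
#' Expected read shares are proportional to density times 16S copy number.
#' Each (sample, replicate, taxon) receives an independent multiplicative
#' log-normal technical factor with log-sd \code{sigma_tech}; replicates 2
#' and 3 additionally share a per-(sample, taxon) batch factor with log-sd
#' \code{sigma_batch}, mimicking replicates processed together being more
#' similar. Counts are multinomial at the configured depth. Optionally a
#' contaminant taxon is spiked into two samples of replicate 1 (so it is
#' identified in more than one sample and survives contaminant filtering).
#'
#' @param truth ground truth from \code{\link{simulateTimeseries}}.
#' @param traj the trajectory configuration (defaults to the one stored in
#'   \code{truth}).
#' @param n_tech number of technical replicates (default from config).
#' @param seed integer seed.
#' @return list of \linkS4class{SampleTable}s of kind \code{"counts"}, one
#'   per technical replicate, rows ordered vessel-major then timepoint.
#' @export
simulate16S <- function(truth, traj = truth$config,
                        n_tech = traj$n_tech, seed = 1L) {
  if (traj$depth < 1000) stop("sequencing depth must be >= 1000")
  dens <- truth$densities
  vessels <- dimnames(dens)[[1]]
  tps <- dimnames(dens)[[2]]
  taxa <- dimnames(dens)[[3]]
  copies <- stats::setNames(traj$species$copy_number, traj$species$species)
  out <- vector("list", n_tech)
  .withSeed(seed, {
    tabs <- lapply(seq_len(n_tech), function(r)
      matrix(0, length(vessels) * length(tps), length(taxa),
             dimnames = list(NULL, taxa)))
    ids <- character(length(vessels) * length(tps))
    meta <- vector("list", length(ids))
    i <- 0L
    for (v in seq_along(vessels)) {
      for (t in seq_along(tps)) {
        i <- i + 1L
        base_share <- dens[v, t, ] * copies[taxa]
        eta <- stats::rnorm(length(taxa), 0, traj$sigma_batch)
        for (r in seq_len(n_tech)) {
          eps <- stats::rnorm(length(taxa), 0, traj$sigma_tech)
          share <- base_share * exp(eps + if (r >= 2) eta else 0)
          if (sum(share) > 0) {
            tabs[[r]][i, ] <- stats::rmultinom(1, traj$depth,
                                               share / sum(share))[, 1]
          }
        }
        ids[i] <- paste(vessels[v], tps[t], sep = "_")
        meta[[i]] <- data.frame(vessel = vessels[v],
                                timepoint = as.numeric(tps[t]))
      }
    }
    meta <- do.call(rbind, meta)
    for (r in seq_len(n_tech)) {
      tab <- tabs[[r]]
      if (isTRUE(traj$contaminant) && r == 1L) {
        contam <- integer(nrow(tab))
        contam[c(1L, 2L)] <- stats::rpois(2, 20) + 1L
        tab <- cbind(tab, Contaminant = contam)
      }
      rownames(tab) <- paste(ids, r, sep = "_")
      m <- data.frame(sample_id = rownames(tab), meta, replicate = r,
                      stringsAsFactors = FALSE)
      out[[r]] <- SampleTable(tab, kind = "counts", meta = m)
    }
  })
  out
}

.metaboliteCurve <- function(template, scale, t) {
  switch(template,
    depleted = scale * exp(-0.5 * t),
    two_phase = {
      t_peak <- 18
      plateau <- 0.2 * scale
      ifelse(t <= t_peak, scale * t / t_peak,
             plateau + (scale - plateau) * exp(-0.08 * (t - t_peak)))
    },
    plateau = scale * (1 - exp(-0.12 * t)),
    stop("unknown metabolite template: ", template))
}

#' Simulate metabolite concentration trajectories
#'
#' Three templates: "depleted" (substrates such as glucose/trehalose,
#' essentially exhausted by the end of batch), "two_phase" (intermediates
#' such as formate, pyruvate, succinate and lactate: rise during batch,
#' peak between 12 and 25 h, decay towards a plateau), and "plateau"
#' (end products such as acetate and butyrate: monotone rise to a
#' plateau, near-constant by 61-67 h). Vessels get multiplicative
#' log-normal noise with log-sd \code{sigma_met}; zero noise makes all
#' vessels identical.
#'
#' @param traj trajectory configuration (uses fields \code{metabolites},
#'   \code{timepoints}, \code{n_vessels}, \code{sigma_met}).
#' @param n_vessels number of vessels (default from config).
#' @param seed integer seed.
#' @return a \linkS4class{SampleTable} of kind \code{"concentration"}
#'   (units mM).
#' @export
simulateMetabolites <- function(traj = defaultTrajectoryConfig(),
                                n_vessels = traj$n_vessels, seed = 1L) {
  met <- traj$metabolites
  tp <- traj$timepoints
  vessels <- paste0("V", seq_len(n_vessels))
  ids <- as.vector(outer(tp, vessels,
                         function(t, v) paste(v, t, sep = "_")))
  det <- vapply(seq_len(nrow(met)), function(j)
    .metaboliteCurve(met$template[j], met$scale[j], tp),
    numeric(length(tp)))
  .withSeed(seed, {
    rows <- do.call(rbind, lapply(vessels, function(v) {
      noise <- if (traj$sigma_met > 0)
        exp(matrix(stats::rnorm(length(tp) * nrow(met), 0, traj$sigma_met),
                   length(tp), nrow(met)))
      else 1
      det * noise
    }))
    colnames(rows) <- met$metabolite
    rownames(rows) <- paste(ids, 1, sep = "_")
    meta <- data.frame(sample_id = rownames(rows),
                       vessel = rep(vessels, each = length(tp)),
                       timepoint = rep(tp, times = n_vessels),
                       replicate = 1L, stringsAsFactors = FALSE)
    SampleTable(rows, kind = "concentration", meta = meta)
  })
}

#' Simulate community acquisitions for every vessel and timepoint
#'
#' Convenience wrapper: one \code{\link{simulateEvents}} call per (vessel,
#' timepoint) of a simulated ground truth, with per-sample seeds derived
#' from \code{seed}.
#'
#' @param truth ground truth from \code{\link{simulateTimeseries}}.
#' @param panel species panel whose species names must match the truth
#'   (by position: panel species are renamed to the truth's species).
#' @param n_events expected events per acquisition (default 5000).
#' @param debris_fraction expected debris fraction (default 0.05).
#' @param dilution dilution factor (default 100).
#' @param seed integer seed.
#' @return list with one element per sample (named vessel_timepoint), each
#'   a list with \code{events} and \code{truth}.
#' @export
simulateCommunityEvents <- function(truth, panel, n_events = 5000L,
                                    debris_fraction = 0.05, dilution = 100,
                                    seed = 1L) {
  dens <- truth$densities
  vessels <- dimnames(dens)[[1]]
  tps <- dimnames(dens)[[2]]
  taxa <- dimnames(dens)[[3]]
  if (length(panel$species) != length(taxa))
    stop("panel has ", length(panel$species), " species but truth has ",
         length(taxa))
  names(panel$species) <- taxa
  out <- list()
  k <- 0L
  for (v in vessels) {
    for (t in tps) {
      k <- k + 1L
      out[[paste(v, t, sep = "_")]] <- simulateEvents(
        panel, composition = stats::setNames(dens[v, t, ], taxa),
        debris_fraction = debris_fraction, n_events = n_events,
        dilution = dilution, seed = seed + k,
        sample_id = paste(v, t, sep = "_"), vessel = v,
        timepoint = as.numeric(t), role = "community")
    }
  }
  out
}
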