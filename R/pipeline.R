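# End-to-end orchestration: simulate -> gate -> classify -> abundances ->
# variability -> ordination, from a single config, with one root seed and
# a JSON manifest of outputs.

.defaultRunConfig <- function() {
  list(
    scenario = "synthetic",
    n_species = 4L,
    separation = 4,
    washout = FALSE,
    contaminant = FALSE,
    sigma_bio = NULL,      # NULL = generator default
    sigma_tech = NULL,
    gate = "threshold",    # or "machine"
    gate_members = 6L,
    n_members = 10L,
    n_events_train = 2000L,
    n_events_community = 3000L,
    vote_threshold = 7L,
    n_trees = 100L,
    debris_fraction = 0.05,
    ddof = 1L,
    heterogeneity_aggregation = "mean",
    axes = 2L,
    n_perm = 999L)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) a scenario, gates and classifies the
#' flow-cytometry samples, derives relative/absolute abundance tables from
#' both cytometry and sequencing, computes CV tables per method, the
#' paired Wilcoxon comparison of sequencing versus cytometry CVs,
#' per-sample heterogeneity, and a Bray-Curtis PCoA with metabolite vector
#' fitting. All outputs are TSV/JSON files under \code{out_dir}, listed in
#' a manifest with md5 hashes; a fixed seed reproduces them byte for byte.
#'
#' @param config named list of settings (missing entries take defaults) or
#'   a path to a YAML file with the same structure. Key settings:
#'   \code{n_species}, \code{separation}, \code{sigma_bio},
#'   \code{sigma_tech}, \code{gate} ("threshold" or "machine"),
#'   \code{n_members}, \code{n_events_train}, \code{n_events_community},
#'   \code{vote_threshold}, \code{ddof}, \code{axes}, \code{n_perm}.
#' @param out_dir output directory (created if absent).
#' @param seed integer root seed; every stochastic stage uses a substream
#'   derived from it.
#' @return the manifest, invisibly (also written to
#'   \code{out_dir/manifest.json}).
#' @export
runPipeline <- function(config = list(), out_dir = tempfile("gutvar_run_"),
                        seed = 1L) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(.defaultRunConfig(), config)
  if (!cfg$scenario %in% "synthetic")
    stop("unknown scenario '", cfg$scenario, "'")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(tab, name) {
    p <- file.path(out_dir, name)
    writeSampleTable(tab, p)
    files[[name]] <<- p
    p
  }

  traj <- .stage("configure", {
    tr <- defaultTrajectoryConfig(n_species = cfg$n_species,
                                  washout = isTRUE(cfg$washout),
                                  contaminant = isTRUE(cfg$contaminant))
    if (!is.null(cfg$sigma_bio)) tr$sigma_bio <- cfg$sigma_bio
    if (!is.null(cfg$sigma_tech)) tr$sigma_tech <- cfg$sigma_tech
    tr
  })
  species <- traj$species$species

  truth <- .stage("simulate_timeseries",
                  simulateTimeseries(traj, seed = seed))
  seqtabs <- .stage("simulate_16s", simulate16S(truth, traj,
                                                seed = seed + 1L))
  mets <- .stage("simulate_metabolites",
                 simulateMetabolites(traj, seed = seed + 2L))
  for (r in seq_along(seqtabs))
    put(seqtabs[[r]], sprintf("counts_16s_rep%d.tsv", r))
  put(mets, "metabolites.tsv")

  panel <- .stage("species_panel",
                  makeSpeciesPanel(length(species),
                                   separation = cfg$separation,
                                   seed = seed + 3L))
  names(panel$species) <- species

  monos <- .stage("simulate_monocultures", {
    lapply(stats::setNames(species, species), function(s) {
      comp <- stats::setNames(rep(0, length(species)), species)
      comp[s] <- 2e8
      sim <- simulateEvents(panel, comp, debris_fraction =
                              cfg$debris_fraction,
                            n_events = max(cfg$n_events_train * 2L, 5000L),
                            seed = seed + 10L + match(s, species),
                            sample_id = paste0("mono_", s), role =
                              "monoculture")
      sim$events
    })
  })
  blank <- .stage("simulate_blank", {
    comp <- stats::setNames(rep(0, length(species)), species)
    sim <- simulateEvents(panel, comp, debris_fraction = 0.999,
                          n_events = 5000L, volume_ul = 10,
                          seed = seed + 20L, sample_id = "blank",
                          role = "blank")
    sim$events
  })

  gate <- NULL
  gateEvents <- function(ev) thresholdGate(ev)
  if (cfg$gate == "machine") {
    gate <- .stage("fit_gate",
                   fitGate(monos[[1]], blank, n_members = cfg$gate_members,
                           n_trees = cfg$n_trees, seed = seed + 30L))
    gateEvents <- function(ev) applyGate(gate, ev)
  }
  gated_monos <- .stage("gate_monocultures", lapply(monos, gateEvents))

  ensemble <- .stage("fit_ensemble",
    fitSpeciesEnsemble(gated_monos, n_members = cfg$n_members,
                       n_events = cfg$n_events_train,
                       vote_threshold = cfg$vote_threshold,
                       n_trees = cfg$n_trees, seed = seed + 40L))

  comm <- .stage("simulate_communities",
    simulateCommunityEvents(truth, panel,
                            n_events = cfg$n_events_community,
                            debris_fraction = cfg$debris_fraction,
                            seed = seed + 100L))

  cyto <- .stage("classify_communities", {
    ids <- names(comm)
    rel <- abs_ <- matrix(NA_real_, length(ids),
                          length(species) + 1L,
                          dimnames = list(paste0(ids, "_1"),
                                          c(species, "unknown")))
    totals <- stats::setNames(numeric(length(ids)), ids)
    het <- stats::setNames(numeric(length(ids)), ids)
    for (i in seq_along(ids)) {
      ev <- gateEvents(comm[[ids[i]]]$events)
      md <- sampleMeta(ev)
      totals[i] <- volumetricCount(nEvents(ev), md$acquired_volume_ul,
                                   md$dilution_factor)
      het[i] <- heterogeneity(ev, cfg$heterogeneity_aggregation)$value
      cc <- classifyEvents(ensemble, ev, keep_labels = FALSE)
      ab <- classifiedToAbundance(cc, totals[i])
      if (!is.null(ab$rel_with_unknown)) {
        rel[i, ] <- ab$rel_with_unknown[colnames(rel)]
        abs_[i, ] <- ab$abs_with_unknown[colnames(rel)]
      }
    }
    meta <- data.frame(sample_id = rownames(rel),
                       vessel = sub("_.*", "", ids),
                       timepoint = as.numeric(sub("^[^_]+_", "", ids)),
                       replicate = 1L, stringsAsFactors = FALSE)
    list(rel = SampleTable(rel, "relative", meta),
         abs = SampleTable(abs_, "absolute", meta),
         totals = totals, heterogeneity = het)
  })
  put(cyto$rel, "cytometry_relative.tsv")
  put(cyto$abs, "cytometry_absolute.tsv")
  het_tab <- SampleTable(matrix(cyto$heterogeneity,
                                dimnames = list(names(cyto$heterogeneity),
                                                "heterogeneity")),
                         kind = "concentration")
  put(het_tab, "heterogeneity.tsv")
  tot_tab <- SampleTable(matrix(cyto$totals,
                                dimnames = list(names(cyto$totals),
                                                "cells_per_ml")),
                         kind = "concentration")
  put(tot_tab, "total_counts.tsv")

  copies <- stats::setNames(traj$species$copy_number, species)
  seq_out <- .stage("sequencing_abundances", {
    lapply(seq_along(seqtabs), function(r) {
      filt <- filterContaminants(seqtabs[[r]], members = species)
      if (isTRUE(cfg$contaminant) && "Contaminant" %in%
            colnames(tableValues(filt)))
        copies <- c(copies, Contaminant = 1)
      rel <- suppressWarnings(correctCopyNumber(filt, copies))
      totals <- stats::setNames(
        cyto$totals[sub("_[0-9]+$", "", rownames(tableValues(rel)))],
        rownames(tableValues(rel)))
      list(rel = rel, abs = toAbsolute(rel, totals))
    })
  })
  for (r in seq_along(seq_out)) {
    put(seq_out[[r]]$rel, sprintf("seq_relative_rep%d.tsv", r))
    put(seq_out[[r]]$abs, sprintf("seq_absolute_rep%d.tsv", r))
  }

  variability <- .stage("variability", {
    cv_seq <- cvTable(seq_out[[1]]$rel, ddof = cfg$ddof,
                      method = "seq_rel")
    cv_cyto <- cvTable(cyto$rel, ddof = cfg$ddof,
                       method = "cellscanner_rel")
    cv_met <- cvTable(mets, ddof = cfg$ddof, method = "HPLC")
    shared <- intersect(colnames(tableValues(cv_seq)),
                        colnames(tableValues(cv_cyto)))
    cmp <- compareMethodsCV(
      tableValues(cv_seq)[, shared, drop = FALSE],
      tableValues(cv_cyto)[, shared, drop = FALSE])
    list(cv_seq = cv_seq, cv_cyto = cv_cyto, cv_met = cv_met, cmp = cmp)
  })
  writeCV <- function(cv, name) {
    v <- tableValues(cv)
    ag <- aggregateCV(cv)
    out <- rbind(cbind(v, `Average per timepoint` = ag$row_means),
                 `Average per variable` = c(ag$col_means, NA))
    p <- file.path(out_dir, name)
    utils::write.table(
      data.frame(timepoint = rownames(out), out, check.names = FALSE),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    files[[name]] <<- p
  }
  writeCV(variability$cv_seq, "cv_seq_rel.tsv")
  writeCV(variability$cv_cyto, "cv_cellscanner_rel.tsv")
  writeCV(variability$cv_met, "cv_metabolites.tsv")

  ord <- .stage("ordination", {
    o <- pcoa(brayCurtis(seq_out[[1]]$rel), n_axes = cfg$axes)
    ef <- envFit(o, mets, n_perm = cfg$n_perm, seed = seed + 200L)
    coords <- ordCoordinates(o)
    p <- file.path(out_dir, "pcoa_coordinates.tsv")
    utils::write.table(data.frame(sample_id = rownames(coords), coords),
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    files[["pcoa_coordinates.tsv"]] <- p
    p2 <- file.path(out_dir, "envfit.tsv")
    utils::write.table(ef, p2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files[["envfit.tsv"]] <- p2
    list(ord = o, envfit = ef)
  })

  manifest <- list(
    package = "gutvar",
    version = as.character(utils::packageVersion("gutvar")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = cfg,
    summary = list(
      species = species,
      ensemble_held_out_accuracy = heldOutAccuracy(ensemble),
      wilcoxon_p_one_sided = variability$cmp$p_one_sided,
      wilcoxon_p_two_sided = variability$cmp$p_two_sided,
      wilcoxon_n_cells = length(variability$cmp$cells),
      mean_cv_ratio = variability$cmp$mean_ratio,
      mean_cv = list(
        seq_rel = aggregateCV(variability$cv_seq)$grand_mean,
        cellscanner_rel = aggregateCV(variability$cv_cyto)$grand_mean,
        HPLC = aggregateCV(variability$cv_met)$grand_mean),
      proportion_explained = ord$ord@proportionExplained,
      top_envfit = ord$envfit$variable[order(-ord$envfit$r2)][1:3]),
    files = lapply(files, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest$out_dir <- out_dir
  invisible(manifest)
}

#' Summarise a pipeline run
#'
#' Renders a short human-readable (markdown) report from a manifest:
#' mean CV per method, the Wilcoxon comparison, classifier held-out
#' accuracy, and the strongest fitted metabolite vectors. Regeneration
#' from the same manifest is idempotent.
#'
#' @param manifest a manifest returned by \code{\link{runPipeline}} or the
#'   path to a \code{manifest.json}.
#' @return character vector of report lines, invisibly; also printed.
#' @export
reportRun <- function(manifest) {
  if (is.character(manifest)) manifest <- jsonlite::read_json(
    manifest, simplifyVector = TRUE)
  s <- manifest$summary
  lines <- c(
    "# Pipeline run summary",
    sprintf("Seed: %s; package gutvar %s", manifest$seed,
            manifest$version),
    "",
    "## Mean CV per method",
    sprintf("- %s: %.4f", names(s$mean_cv), unlist(s$mean_cv)),
    "",
    sprintf(
      "Sequencing vs cytometry CV, paired Wilcoxon one-sided p = %.3g (mean ratio %.2f)",
      s$wilcoxon_p_one_sided, s$mean_cv_ratio),
    "",
    sprintf("Classifier held-out accuracy: %.3f-%.3f over %d members",
            min(unlist(s$ensemble_held_out_accuracy)),
            max(unlist(s$ensemble_held_out_accuracy)),
            length(unlist(s$ensemble_held_out_accuracy))),
    if (!is.null(s$top_envfit))
      sprintf("Top envfit variables: %s",
              paste(unlist(s$top_envfit), collapse = ", "))
    else "Ordination: no environmental table supplied")
  cat(lines, sep = "\n")
  invisible(lines)
}
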