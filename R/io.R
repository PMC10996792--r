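# Readers and writers for claims-like tables and networks, plus the
# end-to-end pipeline driver.

CLAIMS_SCHEMAS <- list(
  fills = c("patient_id", "prescriber_id", "drug_id", "drug_class",
            "start_day", "days_supply"),
  encounters = c("patient_id", "physician_id", "day"),
  physicians = c("physician_id", "specialty", "region"),
  patients = c("patient_id", "region")
)

#' Read and validate claims-like tables
#'
#' Reads comma-delimited tables with headers, checks required columns,
#' day ranges, drug classes and supply positivity, and reports offending
#' rows by line number.
#'
#' @param paths Named list/vector with elements `fills`, `encounters`,
#'   `physicians`, `patients` (paths to CSV files). Any subset may be
#'   given.
#' @param year_end Study-year length in days.
#' @return Named list of validated `data.table`s.
#' @export
read_claims <- function(paths, year_end = 365L) {
  out <- list()
  for (nm in intersect(names(CLAIMS_SCHEMAS), names(paths))) {
    tb <- fread(paths[[nm]], colClasses = NULL)
    need <- CLAIMS_SCHEMAS[[nm]]
    miss <- setdiff(need, names(tb))
    if (length(miss) > 0L) {
      stop(nm, ": missing column(s): ", paste(miss, collapse = ", "))
    }
    if (nrow(tb) == 0L) {
      warning(nm, ": empty table")
    }
    if (nm == "fills" && nrow(tb) > 0L) {
      bad <- which(!tb$drug_class %in% DRUG_CLASSES)
      if (length(bad) > 0L) {
        stop("fills: unknown drug_class in row(s) ",
             paste(head(bad, 5L), collapse = ", "))
      }
      bad <- which(tb$days_supply < 1 | is.na(tb$days_supply))
      if (length(bad) > 0L) {
        stop("fills: non-positive days_supply in row(s) ",
             paste(head(bad, 5L), collapse = ", "))
      }
      bad <- which(tb$start_day < 0 | tb$start_day >= year_end |
                     is.na(tb$start_day))
      if (length(bad) > 0L) {
        stop("fills: start_day outside [0, ", year_end, ") in row(s) ",
             paste(head(bad, 5L), collapse = ", "))
      }
    }
    if (nm == "encounters" && nrow(tb) > 0L) {
      bad <- which(tb$day < 0 | tb$day >= year_end | is.na(tb$day))
      if (length(bad) > 0L) {
        stop("encounters: day outside [0, ", year_end, ") in row(s) ",
             paste(head(bad, 5L), collapse = ", "))
      }
    }
    out[[nm]] <- tb
  }
  out
}

#' Write a cohort's tables as delimited text
#'
#' @param cohort An `rx_cohort` (or any list with the claims tables).
#' @param dir Output directory (created if needed).
#' @param truth Also write the ground-truth tables (planted deprescribing
#'   events, latent risks)? Intended for test harnesses.
#' @return Invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, dir, truth = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (nm in names(CLAIMS_SCHEMAS)) {
    if (is.null(cohort[[nm]])) next
    p <- file.path(dir, paste0(nm, ".csv"))
    fwrite(cohort[[nm]], p)
    paths[nm] <- p
  }
  if (truth && !is.null(cohort$truth)) {
    p <- file.path(dir, "truth_deprescribing.csv")
    fwrite(cohort$truth$deprescribing, p)
    paths["truth_deprescribing"] <- p
  }
  invisible(paths)
}

#' Write / read an undirected network as a two-column edge list
#'
#' Vertex names are preserved; isolated vertices are carried in a header
#' comment-free sidecar column convention: the file has columns `from`,
#' `to`, and isolated vertices appear as a `from` with empty `to`.
#'
#' @param net Undirected `igraph` network.
#' @param path File path.
#' @return `write_edgelist`: invisibly, the path. `read_edgelist`: an
#'   undirected `igraph` graph.
#' @export
write_edgelist <- function(net, path) {
  el <- igraph::as_edgelist(net)
  iso <- setdiff(igraph::V(net)$name,
                 unique(c(el[, 1], el[, 2])))
  tb <- rbind(data.table(from = el[, 1], to = el[, 2]),
              if (length(iso) > 0L) data.table(from = iso, to = "") else NULL)
  fwrite(tb, path)
  invisible(path)
}

#' @rdname write_edgelist
#' @export
read_edgelist <- function(path) {
  tb <- fread(path, colClasses = list(character = c("from", "to")))
  iso <- tb[to == "", from]
  ed <- tb[to != ""]
  verts <- sort(unique(c(ed$from, ed$to, iso)))
  igraph::graph_from_data_frame(ed, directed = FALSE,
                                vertices = data.frame(name = verts))
}

#' Write a network as GraphML with typed node attributes
#'
#' @param net `igraph` network.
#' @param path File path.
#' @return Invisibly, the path.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Stages, in order: simulate (or accept) a cohort; build the directed
#' shared-patient graph, binarize to mutual ties, restrict to
#' prescribers, take the largest connected component; merge refills,
#' segment prescription-state trajectories, extract prescribing
#' transitions and attribute deprescribing; build responsibility matrices
#' and prescribing profiles; fit dyad-independent homophily ERGMs (one
#' prescribing attribute at a time, adjusting for density, specialty
#' main effects and uniform specialty homophily); compute triadic
#' homophily statistics with permutation tests. All artifacts are written
#' under `out_dir` together with a manifest (config, its hash, seed,
#' package version).
#'
#' @param config An `rx_sim_config`, or an `rx_cohort` to skip simulation.
#' @param out_dir Output directory (`NULL` to skip writing).
#' @param merge_gap_fraction Refill-merge buffer fraction (default 0.2).
#' @param depresc_max_gap Deprescribing attribution window in days
#'   (default 30).
#' @param depresc_min_length Minimum target exposure length (default 30).
#' @param min_region_nodes Minimum region sub-network size (default 100).
#' @param n_perm Permutations for the triadic tests (default 30).
#' @param year_end Study-year length in days.
#' @return Invisibly, a list with every stage's outputs.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         merge_gap_fraction = 0.2,
                         depresc_max_gap = 30L,
                         depresc_min_length = 30L,
                         min_region_nodes = 100L,
                         n_perm = 30L,
                         year_end = 365L) {
  cohort <- if (inherits(config, "rx_cohort")) config
            else generate_cohort(config)
  cfg <- cohort$config

  # network stages
  g_dir <- build_directed_network(cohort$encounters)
  net_all <- to_mutual_binary(g_dir)
  net_presc <- restrict_to_prescribers(net_all, cohort$fills)
  lcc <- largest_connected_component(net_presc)
  funnel <- data.table(
    stage = c("physicians", "mutual_network", "prescribing_network", "lcc"),
    n_nodes = c(igraph::vcount(g_dir), igraph::vcount(net_all),
                igraph::vcount(net_presc), igraph::vcount(lcc)),
    n_edges = c(igraph::ecount(g_dir), igraph::ecount(net_all),
                igraph::ecount(net_presc), igraph::ecount(lcc))
  )
  message("network funnel: ",
          paste(funnel$stage, funnel$n_nodes, sep = "=", collapse = ", "))
  summaries <- rbindlist(list(
    cbind(data.table(network = "mutual"), network_summary(net_all)),
    cbind(data.table(network = "prescribing"), network_summary(net_presc)),
    cbind(data.table(network = "lcc"), network_summary(lcc))
  ))
  regions <- assign_regions(cohort$encounters, cohort$patients)
  subnets <- region_subnetworks(lcc, regions, min_nodes = min_region_nodes)

  # trajectory stages
  exposures <- merge_refills(cohort$fills, gap_fraction = merge_gap_fraction)
  intervals <- segment_intervals(exposures, year_end = year_end)
  presc_tx <- extract_prescribing_transitions(intervals, exposures)
  targets <- eligible_targets(exposures, min_length = depresc_min_length)
  depresc <- attribute_deprescribing(targets, cohort$encounters, intervals,
                                     max_gap = depresc_max_gap)
  transitions <- combine_transitions(presc_tx, depresc$transitions)
  diagnostics <- deprescribing_diagnostics(depresc)

  # responsibility stage
  ptrcms <- build_ptrcm(transitions)
  profiles <- prescribing_profiles(ptrcms)
  spec_map <- setNames(cohort$physicians$specialty,
                       cohort$physicians$physician_id)
  group_means <- summarize_by_group(profiles, spec_map)

  # ERGM stage on the LCC
  lcc_attr <- set_node_attributes(lcc, cohort$physicians[,
    .(physician_id, specialty, latent_risk)])
  lcc_attr <- set_node_attributes(lcc_attr, profiles)
  ergm_fits <- list()
  base_terms <- list(term_edges(),
                     term_nodefactor("specialty", ref = "primary_care"),
                     term_nodematch("specialty"))
  models <- list(
    IeverOBS = list(term_nodefactor("IeverOBS", ref = "0"),
                    term_nodematch("IeverOBS")),
    IOBS = list(term_nodecov("IOBS"), term_absdiff("IOBS")),
    Ipresc2mr = list(term_nodecov("Ipresc2mr"), term_absdiff("Ipresc2mr")),
    Idepresc2mr = list(term_nodecov("Idepresc2mr"),
                       term_absdiff("Idepresc2mr"))
  )
  for (nm in names(models)) {
    ergm_fits[[nm]] <- tryCatch(
      fit_ergm(lcc_attr, c(base_terms, models[[nm]])),
      error = function(e) {
        message("ERGM for ", nm, " failed: ", conditionMessage(e))
        NULL
      })
  }

  # triadic stage on the LCC, binary ever-OBS attribute
  xev <- igraph::vertex_attr(lcc_attr, "IeverOBS")
  xev[is.na(xev)] <- 0
  triads <- triad_stats(lcc_attr, xev)
  perm <- list()
  if (!is.na(triads$tri1)) {
    perm$tri1 <- permutation_test(lcc_attr, xev, "tri1", n_perm = n_perm,
                                  seed = cfg$seed + 1L)
  }
  if (!is.na(triads$tri2)) {
    perm$tri2 <- permutation_test(lcc_attr, xev, "tri2", n_perm = n_perm,
                                  seed = cfg$seed + 2L)
  }

  results <- list(cohort = cohort, directed = g_dir, network = net_all,
                  prescribing_network = net_presc, lcc = lcc_attr,
                  funnel = funnel, summaries = summaries,
                  regions = regions, subnetworks = subnets,
                  exposures = exposures, intervals = intervals,
                  transitions = transitions,
                  deprescribing = depresc, diagnostics = diagnostics,
                  ptrcms = ptrcms, profiles = profiles,
                  group_means = group_means, ergm_fits = ergm_fits,
                  triads = triads, permutation = perm)

  if (!is.null(out_dir)) {
    write_pipeline_outputs(results, out_dir,
                           params = list(
                             merge_gap_fraction = merge_gap_fraction,
                             depresc_max_gap = depresc_max_gap,
                             depresc_min_length = depresc_min_length,
                             min_region_nodes = min_region_nodes,
                             n_perm = n_perm, year_end = year_end))
  }
  invisible(results)
}

write_pipeline_outputs <- function(results, out_dir, params) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(results$cohort, file.path(out_dir, "cohort"), truth = TRUE)
  write_edgelist(results$lcc, file.path(out_dir, "lcc_edges.csv"))
  write_graphml(results$lcc, file.path(out_dir, "lcc.graphml"))
  fwrite(results$funnel, file.path(out_dir, "funnel.csv"))
  fwrite(results$summaries, file.path(out_dir, "network_summaries.csv"))
  fwrite(results$regions, file.path(out_dir, "physician_regions.csv"))
  fwrite(results$exposures, file.path(out_dir, "exposures.csv"))
  fwrite(results$intervals, file.path(out_dir, "intervals.csv"))
  fwrite(results$transitions, file.path(out_dir, "transitions.csv"))
  fwrite(results$diagnostics, file.path(out_dir, "deprescribing_diagnostics.csv"))
  fwrite(results$profiles, file.path(out_dir, "profiles.csv"))
  fwrite(results$group_means, file.path(out_dir, "group_means.csv"))
  for (nm in names(results$ergm_fits)) {
    if (is.null(results$ergm_fits[[nm]])) next
    fwrite(results$ergm_fits[[nm]]$coefficients,
           file.path(out_dir, paste0("ergm_", nm, ".csv")))
  }
  fwrite(results$triads, file.path(out_dir, "triad_stats.csv"))
  perm_rows <- lapply(names(results$permutation), function(nm) {
    pt <- results$permutation[[nm]]
    data.table(statistic = nm, observed = pt$observed,
               n_perm = pt$n_perm, p_value = pt$p_value,
               seed = pt$seed)
  })
  if (length(perm_rows) > 0L) {
    fwrite(rbindlist(perm_rows), file.path(out_dir, "permutation_tests.csv"))
    null_rows <- rbindlist(lapply(names(results$permutation), function(nm) {
      data.table(statistic = nm,
                 draw = seq_along(results$permutation[[nm]]$null_draws),
                 value = results$permutation[[nm]]$null_draws)
    }))
    fwrite(null_rows, file.path(out_dir, "permutation_null_draws.csv"))
  }
  cfg <- results$cohort$config
  cfg_json <- jsonlite::toJSON(c(unclass(cfg), params), auto_unbox = TRUE,
                               digits = NA)
  cfg_path <- file.path(out_dir, "config.json")
  writeLines(cfg_json, cfg_path)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("rxnet")),
    created = "see file mtimes",
    outputs = list.files(out_dir, recursive = TRUE)
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}
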