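# Construction of the shared-patient physician network from encounter
# sequences: a directed evidence graph (patient visited i strictly before
# j), binarized to mutual ties, restricted to prescribers, reduced to the
# largest connected component, and partitioned into region sub-networks.

#' Build the directed shared-patient graph from encounters
#'
#' An arc i -> j carries weight equal to the number of distinct patients
#' with at least one encounter with physician i on a day strictly earlier
#' than at least one encounter with physician j. Same-day visits to two
#' physicians create no directed evidence in either direction. With
#' `consecutive = TRUE` only physicians seen on consecutive distinct
#' encounter days of a patient are linked, a stricter reading of
#' "followed by".
#'
#' @param encounters Data frame with columns `patient_id`, `physician_id`,
#'   `day`.
#' @param consecutive Logical; see above (default `FALSE`: any strictly
#'   ordered pair of encounter days counts).
#' @return A directed `igraph` graph with edge attribute `weight`
#'   (distinct patients) over all physicians appearing in `encounters`.
#' @export
build_directed_network <- function(encounters, consecutive = FALSE) {
  en <- as.data.table(encounters)
  en <- unique(en[, .(patient_id = as.character(patient_id),
                      physician_id = as.character(physician_id),
                      day = as.integer(day))])
  verts <- sort(unique(en$physician_id))
  if (nrow(en) == 0L) {
    return(igraph::make_empty_graph(0, directed = TRUE))
  }
  if (!consecutive) {
    pp <- en[, .(mind = min(day), maxd = max(day)),
             by = .(patient_id, physician_id)]
    pairs <- merge(pp, pp, by = "patient_id", allow.cartesian = TRUE,
                   suffixes = c(".i", ".j"))
    pairs <- pairs[physician_id.i != physician_id.j & mind.i < maxd.j]
    arcs <- pairs[, .(weight = uniqueN(patient_id)),
                  by = .(from = physician_id.i, to = physician_id.j)]
  } else {
    setorder(en, patient_id, day)
    arcs_list <- en[, {
      ds <- sort(unique(day))
      if (length(ds) < 2L) {
        list(from = character(0), to = character(0))
      } else {
        f <- character(0); t <- character(0)
        for (q in seq_len(length(ds) - 1L)) {
          a <- physician_id[day == ds[q]]
          b <- physician_id[day == ds[q + 1L]]
          g <- expand.grid(from = a, to = b, stringsAsFactors = FALSE)
          g <- g[g$from != g$to, , drop = FALSE]
          f <- c(f, g$from); t <- c(t, g$to)
        }
        list(from = f, to = t)
      }
    }, by = patient_id]
    arcs <- unique(arcs_list)[, .(weight = uniqueN(patient_id)),
                              by = .(from, to)]
  }
  igraph::graph_from_data_frame(arcs, directed = TRUE,
                                vertices = data.frame(name = verts))
}

#' Binarize a directed shared-patient graph to mutual undirected ties
#'
#' An undirected edge \{i, j\} is kept iff both arcs i -> j and j -> i are
#' present with weight at least 1 (the threshold-0 convention: at least
#' one patient saw i then j, and at least one saw j then i).
#'
#' @param g Directed `igraph` graph from [build_directed_network()].
#' @return An undirected, unweighted `igraph` graph on the same vertices.
#' @export
to_mutual_binary <- function(g) {
  stopifnot(igraph::is_directed(g))
  if (igraph::ecount(g) == 0L) {
    return(igraph::as_undirected(g, mode = "collapse"))
  }
  mut <- igraph::which_mutual(g)
  gm <- igraph::subgraph_from_edges(g, which(mut), delete.vertices = FALSE)
  out <- igraph::as_undirected(gm, mode = "collapse")
  igraph::delete_edge_attr(out, "weight")
}

#' Restrict a network to prescribing physicians
#'
#' Induced subgraph on physicians with at least one fill in the monitored
#' drug classes (O, B, S).
#'
#' @param net Undirected `igraph` network.
#' @param fills Prescription fills table.
#' @return Induced `igraph` subgraph.
#' @export
restrict_to_prescribers <- function(net, fills) {
  ft <- as.data.table(fills)
  pres <- if (nrow(ft) == 0L) character(0) else {
    unique(as.character(ft[drug_class %in% DRUG_CLASSES, prescriber_id]))
  }
  keep <- intersect(igraph::V(net)$name, pres)
  igraph::induced_subgraph(net, keep)
}

#' Largest connected component
#'
#' Induced subgraph on the maximum-cardinality component. Ties are broken
#' deterministically: among equally large components, the one containing
#' the lexicographically smallest vertex name wins.
#'
#' @param net Undirected `igraph` network.
#' @return Induced `igraph` subgraph (empty graph in, empty graph out).
#' @export
largest_connected_component <- function(net) {
  if (igraph::vcount(net) == 0L) return(net)
  comp <- igraph::components(net)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1L) {
    nm <- igraph::V(net)$name
    if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(net)))
    firsts <- vapply(best, function(b) min(nm[comp$membership == b]),
                     character(1))
    best <- best[order(firsts)][1L]
  }
  igraph::induced_subgraph(net, which(comp$membership == best))
}

#' Assign each physician to the region of the plurality of their patients
#'
#' @param encounters Data frame with `patient_id`, `physician_id`, `day`.
#' @param patients Data frame with `patient_id` and `region`.
#' @return `data.table` with columns `physician_id`, `region`,
#'   `n_patients` (distinct patients supporting the assignment). Ties are
#'   broken by the lexicographically smallest region label. Physicians
#'   absent from `encounters` are absent from the result.
#' @export
assign_regions <- function(encounters, patients) {
  en <- unique(as.data.table(encounters)[, .(
    patient_id = as.character(patient_id),
    physician_id = as.character(physician_id))])
  pt <- as.data.table(patients)[, .(patient_id = as.character(patient_id),
                                    region = as.character(region))]
  j <- merge(en, pt, by = "patient_id")
  counts <- j[, .(n = uniqueN(patient_id)), by = .(physician_id, region)]
  setorder(counts, physician_id, -n, region)
  top <- counts[, .SD[1L], by = physician_id]
  top[, .(physician_id, region, n_patients = n)][]
}

#' Region sub-networks
#'
#' One induced subgraph per region; an edge belongs to a region's
#' sub-network only when both endpoints are assigned to that region.
#' Regions with fewer than `min_nodes` assigned physicians in the network
#' are dropped. Sub-networks are not re-restricted to their own largest
#' connected components.
#'
#' @param net Undirected `igraph` network.
#' @param mapping Output of [assign_regions()] (or a named character
#'   vector physician -> region).
#' @param min_nodes Minimum sub-network size to keep (default 100).
#' @return Named list of `igraph` graphs, one per retained region.
#' @export
region_subnetworks <- function(net, mapping, min_nodes = 100L) {
  if (is.data.frame(mapping)) {
    rmap <- setNames(as.character(mapping$region),
                     as.character(mapping$physician_id))
  } else {
    rmap <- mapping
  }
  regs <- rmap[igraph::V(net)$name]
  out <- list()
  for (rg in sort(unique(regs[!is.na(regs)]))) {
    members <- which(!is.na(regs) & regs == rg)
    if (length(members) < min_nodes) next
    out[[rg]] <- igraph::induced_subgraph(net, members)
  }
  out
}

#' Descriptive network statistics
#'
#' Density, component structure, degree summaries, global clustering
#' (3 times closed triangles over the number of 2-stars) and average
#' shortest-path length over reachable pairs.
#'
#' @param net Undirected `igraph` network.
#' @return One-row `data.table` with columns `n_nodes`, `n_edges`,
#'   `density`, `n_components`, `lcc_size`, `degree_mean`, `degree_iqr`,
#'   `degree_sd`, `global_clustering`, `avg_path_length`.
#' @export
network_summary <- function(net) {
  n <- igraph::vcount(net)
  m <- igraph::ecount(net)
  comp <- if (n > 0L) igraph::components(net) else list(no = 0L, csize = integer(0))
  deg <- igraph::degree(net)
  data.table(
    n_nodes = n,
    n_edges = m,
    density = if (n > 1L) m / (n * (n - 1) / 2) else NA_real_,
    n_components = comp$no,
    lcc_size = if (n > 0L) max(comp$csize) else 0L,
    degree_mean = if (n > 0L) mean(deg) else NA_real_,
    degree_iqr = if (n > 0L) IQR(deg) else NA_real_,
    degree_sd = if (n > 1L) sd(deg) else NA_real_,
    global_clustering = if (n > 0L) igraph::transitivity(net, type = "global")
                        else NA_real_,
    avg_path_length = if (m > 0L)
      igraph::mean_distance(net, directed = FALSE, unconnected = TRUE)
      else NA_real_
  )
}

#' Attach node attributes to a network from a keyed table
#'
#' @param net `igraph` network with vertex names.
#' @param attrs Data frame with an id column matching vertex names plus
#'   one column per attribute to attach.
#' @param id_col Name of the id column (default `"physician_id"`).
#' @return The network with vertex attributes set (`NA` for missing
#'   vertices).
#' @export
set_node_attributes <- function(net, attrs, id_col = "physician_id") {
  at <- as.data.frame(attrs)
  idx <- match(igraph::V(net)$name, as.character(at[[id_col]]))
  for (col in setdiff(names(at), id_col)) {
    net <- igraph::set_vertex_attr(net, col, value = at[[col]][idx])
  }
  net
}
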