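# Fixtures built in code.

# Six-physician shared-patient subgraph with four risky prescribers
# (A, B, C, D) and two non-risky ones (E, F): one all-risky triangle
# (A-B-C), a risky pendant (B-D), and a non-risky tail (D-E, E-F).
fig_risky_graph <- function() {
  g <- igraph::graph_from_edgelist(
    rbind(c("A", "B"), c("A", "C"), c("B", "C"), c("B", "D"),
          c("D", "E"), c("E", "F")),
    directed = FALSE)
  x <- as.numeric(igraph::V(g)$name %in% c("A", "B", "C", "D"))
  list(graph = g, risky = x)
}

make_fills <- function(patient, prescriber, drug, class, start, supply) {
  data.frame(patient_id = patient, prescriber_id = prescriber,
             drug_id = drug, drug_class = class, start_day = as.integer(start),
             days_supply = as.integer(supply), stringsAsFactors = FALSE)
}

make_encounters <- function(patient, physician, day) {
  data.frame(patient_id = patient, physician_id = physician,
             day = as.integer(day), stringsAsFactors = FALSE)
}

# random undirected graph with n nodes and tie probability p
random_graph <- function(n, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  igraph::sample_gnp(n, p)
}

# a PTRCM from a list of (from, to, weight) triples
make_ptrcm <- function(...) {
  triples <- list(...)
  m <- matrix(0, 8, 8)
  for (tr in triples) m[tr[1], tr[2]] <- m[tr[1], tr[2]] + tr[3]
  dimnames(m) <- list(rxnet:::STATE_LABELS, rxnet:::STATE_LABELS)
  m
}
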