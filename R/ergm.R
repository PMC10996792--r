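# Dyad-independent exponential random graph models (ERGMs).
#
# For an undirected binary network A with node attributes x, the ERGM is
#   Pr(A = a | x) = exp{ sum_p eta_p g_p(a, x) } / kappa(x).
# When every statistic g_p decomposes as a sum of per-dyad contributions
# that depend only on that dyad's status and the two nodes' attributes,
# the likelihood factorizes over dyads into independent Bernoulli-logistic
# terms, so the exact maximum-likelihood estimate is a logistic regression
# of the dyad indicators on the per-dyad change statistics. The module
# also enumerates all graphs on up to 5 nodes to expose the normalizing
# constant directly, and diagnoses the rank deficiency that arises when
# edges, nodefactor and both differential nodematch terms of a binary
# attribute are included together.

#' ERGM term constructors
#'
#' Build term specifications for dyad-independent ERGMs:
#' \describe{
#'   \item{`term_edges()`}{number of edges (density).}
#'   \item{`term_nodecov(attr)`}{sum of `x_i + x_j` over edges, for a
#'     continuous attribute.}
#'   \item{`term_nodefactor(attr, levels, ref)`}{number of edge endpoints
#'     carrying each level of a categorical attribute; by default all
#'     levels except a reference (the most frequent level, ties broken
#'     alphabetically).}
#'   \item{`term_nodematch(attr, diff, levels)`}{uniform homophily (one
#'     statistic: edges whose endpoints share the attribute value) or,
#'     with `diff = TRUE`, differential homophily (one statistic per
#'     level).}
#'   \item{`term_absdiff(attr)`}{sum of `|x_i - x_j|` over edges; a
#'     negative coefficient indicates homophily.}
#' }
#'
#' @param attr Node attribute name.
#' @param levels Optional explicit levels (categorical terms).
#' @param ref Optional reference level to drop (`term_nodefactor`).
#' @param diff Differential (per-level) homophily? (`term_nodematch`).
#' @return An object of class `ergm_term`.
#' @name ergm_terms
NULL

new_term <- function(kind, attr = NULL, levels = NULL, ref = NULL,
                     diff = FALSE) {
  structure(list(kind = kind, attr = attr, levels = levels, ref = ref,
                 diff = diff), class = "ergm_term")
}

#' @rdname ergm_terms
#' @export
term_edges <- function() new_term("edges")

#' @rdname ergm_terms
#' @export
term_nodecov <- function(attr) new_term("nodecov", attr)

#' @rdname ergm_terms
#' @export
term_nodefactor <- function(attr, levels = NULL, ref = NULL) {
  new_term("nodefactor", attr, levels = levels, ref = ref)
}

#' @rdname ergm_terms
#' @export
term_nodematch <- function(attr, diff = FALSE, levels = NULL) {
  new_term("nodematch", attr, levels = levels, diff = diff)
}

#' @rdname ergm_terms
#' @export
term_absdiff <- function(attr) new_term("absdiff", attr)

#' @export
print.ergm_term <- function(x, ...) {
  cat("<ergm_term>", x$kind,
      if (!is.null(x$attr)) paste0("(", x$attr, ")") else "", "\n")
  invisible(x)
}

term_attr_values <- function(term, attrs) {
  if (is.null(term$attr)) return(NULL)
  if (!term$attr %in% names(attrs)) {
    stop("node attribute not found: ", term$attr)
  }
  attrs[[term$attr]]
}

term_levels <- function(term, x) {
  if (!is.null(term$levels)) return(as.character(term$levels))
  lv <- sort(unique(as.character(x)))
  if (term$kind == "nodefactor") {
    ref <- term$ref
    if (is.null(ref)) {
      tab <- table(as.character(x))
      ref <- names(tab)[order(-tab, names(tab))][1L]
    }
    lv <- setdiff(lv, ref)
  }
  lv
}

# Per-dyad change-statistic columns for one term, given node indices i, j.
term_columns <- function(term, attrs, i, j) {
  switch(term$kind,
    edges = {
      cols <- matrix(1, length(i), 1L)
      colnames(cols) <- "edges"
      cols
    },
    nodecov = {
      x <- as.numeric(term_attr_values(term, attrs))
      cols <- matrix(x[i] + x[j], ncol = 1L)
      colnames(cols) <- paste0("nodecov.", term$attr)
      cols
    },
    absdiff = {
      x <- as.numeric(term_attr_values(term, attrs))
      cols <- matrix(abs(x[i] - x[j]), ncol = 1L)
      colnames(cols) <- paste0("absdiff.", term$attr)
      cols
    },
    nodefactor = {
      x <- as.character(term_attr_values(term, attrs))
      lv <- term_levels(term, x)
      cols <- vapply(lv, function(l) (x[i] == l) + (x[j] == l),
                     numeric(length(i)))
      cols <- matrix(cols, ncol = length(lv))
      colnames(cols) <- paste0("nodefactor.", term$attr, ".", lv)
      cols
    },
    nodematch = {
      x <- as.character(term_attr_values(term, attrs))
      if (isTRUE(term$diff)) {
        lv <- term_levels(term, x)
        cols <- vapply(lv, function(l) as.numeric(x[i] == l & x[j] == l),
                       numeric(length(i)))
        cols <- matrix(cols, ncol = length(lv))
        colnames(cols) <- paste0("nodematch.", term$attr, ".", lv)
      } else {
        cols <- matrix(as.numeric(x[i] == x[j]), ncol = 1L)
        colnames(cols) <- paste0("nodematch.", term$attr)
      }
      cols
    },
    stop("dyad-dependent or unknown term kind: ", term$kind)
  )
}

as_term_list <- function(terms) {
  if (inherits(terms, "ergm_term")) terms <- list(terms)
  stopifnot(all(vapply(terms, inherits, logical(1), "ergm_term")))
  terms
}

#' Per-dyad change-statistic design for dyad-independent terms
#'
#' Enumerates all unordered dyads of a node set and evaluates each term's
#' per-dyad contribution. Summing rows over the dyads that carry an edge
#' reproduces the network statistics exactly.
#'
#' @param attrs Data frame of node attributes, one row per node (row order
#'   defines node indices).
#' @param terms List of [ergm_terms] objects.
#' @return List with `X` (dyads x statistics design matrix) and `pairs`
#'   (two-column matrix of node indices, i < j).
#' @export
dyad_change_stats <- function(attrs, terms) {
  terms <- as_term_list(terms)
  n <- nrow(attrs)
  if (n < 2L) stop("need at least 2 nodes")
  pairs <- t(utils::combn(n, 2L))
  i <- pairs[, 1L]; j <- pairs[, 2L]
  X <- do.call(cbind, lapply(terms, term_columns, attrs = attrs, i = i, j = j))
  list(X = X, pairs = pairs)
}

graph_attr_table <- function(net, terms) {
  terms <- as_term_list(terms)
  used <- unique(unlist(lapply(terms, function(t) t$attr)))
  at <- data.frame(row.names = seq_len(igraph::vcount(net)))
  for (a in used) {
    if (!a %in% igraph::vertex_attr_names(net)) {
      stop("network lacks node attribute: ", a)
    }
    at[[a]] <- igraph::vertex_attr(net, a)
  }
  at
}

#' Dyad design matrix and response for a network
#'
#' @param net Undirected `igraph` network with node attributes.
#' @param terms List of [ergm_terms] objects.
#' @return List with `X` (design), `y` (0/1 dyad indicators) and `pairs`.
#' @export
dyad_design <- function(net, terms) {
  stopifnot(!igraph::is_directed(net))
  attrs <- graph_attr_table(net, terms)
  d <- dyad_change_stats(attrs, terms)
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  y <- as.numeric(A[d$pairs])
  list(X = d$X, y = y, pairs = d$pairs)
}

#' Network statistics for dyad-independent ERGM terms
#'
#' Evaluates each statistic directly over the network's edge list (each
#' unordered edge counted once), independently of the dyad design path.
#'
#' @param net Undirected `igraph` network with node attributes.
#' @param terms List of [ergm_terms] objects.
#' @return Named numeric vector of statistics.
#' @export
network_statistics <- function(net, terms) {
  stopifnot(!igraph::is_directed(net))
  terms <- as_term_list(terms)
  attrs <- graph_attr_table(net, terms)
  el <- igraph::as_edgelist(net, names = FALSE)
  if (nrow(el) == 0L) {
    cols <- do.call(cbind, lapply(terms, term_columns, attrs = attrs,
                                  i = integer(0), j = integer(0)))
    return(setNames(numeric(ncol(cols)), colnames(cols)))
  }
  cols <- do.call(cbind, lapply(terms, term_columns, attrs = attrs,
                                i = el[, 1L], j = el[, 2L]))
  colSums(cols)
}

#' Rank and collinearity diagnosis of a dyad design
#'
#' Computes the numeric rank of the design matrix (singular values below
#' `tol` times the largest are treated as zero) and, for each rank
#' deficiency, reports the set of columns involved in the linear
#' dependence. For a binary attribute, a design containing the edges term,
#' the nodefactor term and both differential nodematch terms always has
#' rank deficiency exactly one: the 0-level match column equals edges
#' minus nodefactor plus the 1-level match column.
#'
#' @param X Design matrix (or the list returned by [dyad_design()]).
#' @param tol Relative singular-value tolerance (default `1e-8`).
#' @return List with `rank`, `deficiency`, and `collinear_sets` (list of
#'   character vectors of column names, one per null direction).
#' @export
check_identifiability <- function(X, tol = 1e-8) {
  if (is.list(X) && !is.null(X$X)) X <- X$X
  sv <- svd(X)
  keep <- sv$d > tol * sv$d[1L]
  rank <- sum(keep)
  deficiency <- ncol(X) - rank
  sets <- list()
  if (deficiency > 0L) {
    for (q in seq_len(deficiency)) {
      v <- sv$v[, rank + q]
      sets[[q]] <- colnames(X)[abs(v) > 1e-6]
    }
  }
  list(rank = rank, deficiency = deficiency, collinear_sets = sets)
}

#' Fit a dyad-independent ERGM by exact maximum likelihood
#'
#' Fits the factorized per-dyad Bernoulli-logistic likelihood, which is
#' the exact ERGM MLE for dyad-independent terms. Standard errors come
#' from the observed information. Nodes with missing values on any
#' attribute used by the terms are dropped (with a message) before
#' fitting. Rank-deficient designs are refused with a diagnostic naming
#' the collinear terms. Coefficients on the boundary (perfect separation,
#' e.g. an empty or complete graph) are flagged as divergent.
#'
#' @param net Undirected `igraph` network with node attributes.
#' @param terms List of [ergm_terms] objects.
#' @param tol Rank tolerance passed to [check_identifiability()].
#' @return Object of class `ergm_fit`: list with `coefficients` (table of
#'   term, estimate, se, z, p, divergent), `loglik`, `n_nodes`, `n_dyads`,
#'   `n_dropped` and `rank` report.
#' @export
fit_ergm <- function(net, terms, tol = 1e-8) {
  stopifnot(!igraph::is_directed(net))
  terms <- as_term_list(terms)
  used <- unique(unlist(lapply(terms, function(t) t$attr)))
  n_dropped <- 0L
  if (length(used) > 0L) {
    at <- graph_attr_table(net, terms)
    ok <- stats::complete.cases(at)
    n_dropped <- sum(!ok)
    if (n_dropped > 0L) {
      message("fit_ergm: dropping ", n_dropped,
              " node(s) with missing attribute values")
      net <- igraph::induced_subgraph(net, which(ok))
    }
  }
  d <- dyad_design(net, terms)
  id <- check_identifiability(d$X, tol = tol)
  if (id$deficiency > 0L) {
    stop("design is rank deficient (deficiency ", id$deficiency,
         "); collinear terms: ",
         paste(vapply(id$collinear_sets, paste, character(1),
                      collapse = " + "), collapse = "; "))
  }
  fit <- suppressWarnings(
    glm.fit(d$X, d$y, family = binomial(), intercept = FALSE,
            control = list(epsilon = 1e-12, maxit = 100))
  )
  est <- fit$coefficients
  # observed information from the final IRLS weights
  p_hat <- fit$fitted.values
  W <- p_hat * (1 - p_hat)
  info <- crossprod(d$X, d$X * W)
  cov <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, length(est), length(est))
  })
  se <- sqrt(pmax(diag(cov), 0))
  divergent <- abs(est) > 15 | !is.finite(est)
  z <- est / se
  pval <- 2 * pnorm(-abs(z))
  ll <- sum(d$y * log(pmax(p_hat, 1e-300)) +
              (1 - d$y) * log(pmax(1 - p_hat, 1e-300)))
  structure(list(
    coefficients = data.frame(term = colnames(d$X), estimate = unname(est),
                              se = unname(se), z = unname(z),
                              p = unname(pval),
                              divergent = unname(divergent),
                              row.names = NULL),
    loglik = ll,
    n_nodes = igraph::vcount(net),
    n_dyads = length(d$y),
    n_dropped = n_dropped,
    rank = id
  ), class = "ergm_fit")
}

#' @export
print.ergm_fit <- function(x, ...) {
  cat("Dyad-independent ERGM fit (", x$n_nodes, " nodes, ", x$n_dyads,
      " dyads, logLik ", format(x$loglik, digits = 6), ")\n", sep = "")
  if (x$n_dropped > 0L) {
    cat("  (", x$n_dropped, " node(s) dropped for missing attributes)\n",
        sep = "")
  }
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Coefficient accessor for `ergm_fit`
#' @param object An `ergm_fit`.
#' @param ... Unused.
#' @return Named numeric vector of estimates.
#' @export
coef.ergm_fit <- function(object, ...) {
  setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Exact log-probabilities over all graphs on a small node set
#'
#' Enumerates every graph on `n <= 5` nodes (up to `2^10` graphs),
#' evaluates the ERGM sufficient statistics of each from the per-dyad
#' design, and returns the exactly normalized log-probabilities: the
#' normalizing constant is computed by direct summation, not by the
#' dyadwise factorization.
#'
#' @param attrs Data frame of node attributes (one row per node).
#' @param terms List of [ergm_terms] objects.
#' @param eta Coefficient vector (length = number of statistics).
#' @return List with `graphs` (2^m x m 0/1 matrix of dyad states, column
#'   order matching `pairs`), `pairs`, `stats` (per-graph statistics) and
#'   `logprob` (normalized log-probabilities summing to 1).
#' @export
exact_small_graph_loglik <- function(attrs, terms, eta) {
  n <- nrow(attrs)
  if (n > 5L) stop("exact enumeration is limited to n <= 5 nodes")
  d <- dyad_change_stats(attrs, terms)
  m <- nrow(d$X)
  combos <- as.matrix(expand.grid(rep(list(0:1), m)))
  colnames(combos) <- NULL
  G <- combos %*% d$X
  if (length(eta) != ncol(G)) stop("eta has wrong length")
  lp <- drop(G %*% eta)
  logZ <- max(lp) + log(sum(exp(lp - max(lp))))
  list(graphs = combos, pairs = d$pairs, stats = G, logprob = lp - logZ)
}

#' Simulate a network from a dyad-independent ERGM
#'
#' Each unordered dyad is present independently with probability
#' `plogis(eta . change statistics)`, which is the exact model
#' distribution for dyad-independent terms.
#'
#' @param attrs Data frame of node attributes; a column `name` (or
#'   `physician_id`) is used for vertex names if present.
#' @param terms List of [ergm_terms] objects.
#' @param eta Coefficient vector.
#' @param seed Optional integer seed.
#' @return Undirected `igraph` network with the attributes attached.
#' @export
generate_dyad_independent_network <- function(attrs, terms, eta,
                                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  attrs <- as.data.frame(attrs)
  d <- dyad_change_stats(attrs, terms)
  if (length(eta) != ncol(d$X)) stop("eta has wrong length")
  p <- plogis(drop(d$X %*% eta))
  a <- rbinom(length(p), 1L, p)
  n <- nrow(attrs)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (any(a == 1L)) {
    g <- igraph::add_edges(g, t(d$pairs[a == 1L, , drop = FALSE]))
  }
  nm_col <- intersect(c("name", "physician_id"), names(attrs))
  if (length(nm_col) > 0L) {
    g <- igraph::set_vertex_attr(g, "name",
                                 value = as.character(attrs[[nm_col[1L]]]))
  }
  for (col in setdiff(names(attrs), nm_col)) {
    g <- igraph::set_vertex_attr(g, col, value = attrs[[col]])
  }
  g
}
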