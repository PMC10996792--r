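# Attribute-restricted triadic homophily statistics.
#
# For a node attribute x in [0, 1]:
#   tri1 = sum over closed triangles {i,j,k} of x_i x_j x_k,
#          divided by the number of closed triangles;
#   tri2 = sum over closed 2-stars of x_i x_j x_k, divided by the same
#          sum over all 2-stars (center i, unordered neighbor pair
#          {j, k}); each triangle contributes three closed 2-stars.
# With all x = 1, tri1 = 1 and tri2 equals the global clustering
# coefficient. Significance is assessed by redistributing the attribute
# over the nodes uniformly at random while keeping the graph fixed.

#' Min-max standardize a node attribute to [0, 1]
#'
#' @param x Numeric vector. A constant vector maps to all zeros with a
#'   warning (the attribute carries no contrast).
#' @return Numeric vector in `[0, 1]`.
#' @export
standardize_attribute <- function(x) {
  x <- as.numeric(x)
  rng <- range(x, na.rm = TRUE)
  if (rng[1] == rng[2]) {
    warning("constant attribute: standardized to all zeros")
    return(rep(0, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

check_attr01 <- function(net, x) {
  x <- as.numeric(x)
  if (length(x) != igraph::vcount(net)) {
    stop("attribute length must equal the number of nodes")
  }
  if (anyNA(x)) stop("attribute contains NA")
  if (any(x < 0 | x > 1)) {
    stop("attribute must lie in [0, 1]; use standardize_attribute()")
  }
  x
}

# Precompute the triangle list and adjacency once so the statistics can
# be re-evaluated cheaply on permuted attributes.
triad_prep <- function(net) {
  stopifnot(!igraph::is_directed(net))
  tri <- igraph::triangles(net)
  tr <- if (length(tri) > 0L) matrix(as.integer(tri), nrow = 3L) else
    matrix(integer(0), nrow = 3L)
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  list(tr = tr, A = A, n = igraph::vcount(net))
}

triad_eval <- function(prep, x) {
  n_tri <- ncol(prep$tr)
  tri_w <- if (n_tri > 0L) {
    sum(x[prep$tr[1L, ]] * x[prep$tr[2L, ]] * x[prep$tr[3L, ]])
  } else 0
  s1 <- as.vector(prep$A %*% x)
  s2 <- as.vector(prep$A %*% (x^2))
  twostars_w <- sum(x * (s1^2 - s2)) / 2
  list(
    tri1 = if (n_tri > 0L) tri_w / n_tri else NA_real_,
    tri2 = if (twostars_w > 0) 3 * tri_w / twostars_w else NA_real_,
    n_triangles = n_tri,
    attr_triangles_weight = tri_w,
    attr_twostars_weight = twostars_w
  )
}

#' Triadic homophily statistics
#'
#' `tri1()` is the attribute-weighted proportion of closed triangles (for
#' a binary attribute: the proportion of triangles whose three nodes all
#' carry it); `tri2()` is the attribute-weighted proportion of 2-stars
#' that are closed (an attribute-restricted transitivity);
#' `triad_stats()` returns both plus the underlying counts.
#'
#' @param net Undirected `igraph` network.
#' @param x Numeric node attribute in `[0, 1]`, in vertex order.
#' @return `tri1()`/`tri2()`: a single number, `NA` when undefined (no
#'   triangles, or no attribute-weighted 2-stars). `triad_stats()`: a
#'   one-row `data.table` with `tri1`, `tri2`, `n_triangles`,
#'   `attr_triangles_weight`, `attr_twostars_weight`.
#' @export
triad_stats <- function(net, x) {
  x <- check_attr01(net, x)
  as.data.table(triad_eval(triad_prep(net), x))[]
}

#' @rdname triad_stats
#' @export
tri1 <- function(net, x) {
  x <- check_attr01(net, x)
  triad_eval(triad_prep(net), x)$tri1
}

#' @rdname triad_stats
#' @export
tri2 <- function(net, x) {
  x <- check_attr01(net, x)
  triad_eval(triad_prep(net), x)$tri2
}

#' Attribute-weighted 2-star count
#'
#' Sum over centers i and unordered neighbor pairs \{j, k\} of
#' `x_i * x_j * x_k`. For a binary attribute this counts 2-stars whose
#' three nodes all carry the attribute.
#'
#' @param net Undirected `igraph` network.
#' @param x Numeric node attribute in `[0, 1]`.
#' @param by_center Return the per-center vector instead of the total?
#' @return A single number, or a per-node numeric vector.
#' @export
count_attr_twostars <- function(net, x, by_center = FALSE) {
  x <- check_attr01(net, x)
  prep <- triad_prep(net)
  s1 <- as.vector(prep$A %*% x)
  s2 <- as.vector(prep$A %*% (x^2))
  per <- x * (s1^2 - s2) / 2
  if (by_center) setNames(per, igraph::V(net)$name) else sum(per)
}

#' Attribute-redistribution permutation test for triadic homophily
#'
#' Holds the graph fixed and redistributes the node attribute uniformly
#' at random over the nodes (preserving its empirical distribution),
#' re-evaluating the statistic on each replicate. The p-value is the
#' proportion of null draws at least as extreme as the observed value
#' (one-sided "greater" by default); with `correction = TRUE` the
#' add-one `(b + 1) / (m + 1)` estimate is used instead. Null draws on
#' which the statistic is undefined (possible for `tri2` when the
#' permuted attribute supports no 2-star) are scored as 0, i.e. as
#' showing no homophilic structure.
#'
#' @param net Undirected `igraph` network.
#' @param x Numeric node attribute in `[0, 1]`.
#' @param statistic `"tri1"`, `"tri2"`, or a function `f(net, x)`.
#' @param n_perm Number of permutations (default 30).
#' @param seed Optional integer seed.
#' @param alternative `"greater"` (default) or `"less"`.
#' @param correction Use the add-one p-value estimate?
#' @return Object of class `rx_perm_test`: list with `observed`,
#'   `null_draws`, `n_perm`, `p_value`, `seed`, `statistic`,
#'   `alternative`.
#' @export
permutation_test <- function(net, x, statistic = c("tri1", "tri2"),
                             n_perm = 30L, seed = NULL,
                             alternative = c("greater", "less"),
                             correction = FALSE) {
  if (n_perm < 1L) stop("n_perm must be at least 1")
  alternative <- match.arg(alternative)
  x <- check_attr01(net, x)
  if (is.function(statistic)) {
    statfun <- function(prep, xx) statistic(net, xx)
    statname <- "custom"
    prep <- NULL
  } else {
    statname <- match.arg(statistic)
    prep <- triad_prep(net)
    statfun <- function(prep, xx) triad_eval(prep, xx)[[statname]]
  }
  observed <- statfun(prep, x)
  if (is.na(observed)) {
    stop("statistic is undefined on the observed network")
  }
  if (!is.null(seed)) set.seed(seed)
  null_draws <- vapply(seq_len(n_perm), function(b) {
    statfun(prep, x[sample.int(length(x))])
  }, numeric(1))
  null_scored <- ifelse(is.na(null_draws), 0, null_draws)
  extreme <- if (alternative == "greater") null_scored >= observed
             else null_scored <= observed
  p <- if (correction) (sum(extreme) + 1) / (n_perm + 1) else mean(extreme)
  structure(list(observed = observed, null_draws = null_draws,
                 n_perm = as.integer(n_perm), p_value = p, seed = seed,
                 statistic = statname, alternative = alternative),
            class = "rx_perm_test")
}

#' @export
print.rx_perm_test <- function(x, ...) {
  cat("Attribute-redistribution permutation test (", x$statistic, ")\n",
      sep = "")
  cat("  observed:", format(x$observed, digits = 6),
      " permutations:", x$n_perm, "\n")
  cat("  p-value (", x$alternative, "): ", format(x$p_value, digits = 4),
      "\n", sep = "")
  invisible(x)
}
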