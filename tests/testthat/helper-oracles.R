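# Independent brute-force oracles used to cross-check the package's
# vectorized implementations. Deliberately written as plain loops over
# adjacency matrices and count matrices, sharing no code with R/.

# triangle / 2-star census by triple enumeration, O(n^3)
oracle_triads <- function(A, x) {
  n <- nrow(A)
  ntri <- 0L; tw <- 0
  if (n >= 3L) {
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      if (A[i, j] && A[j, k] && A[i, k]) {
        ntri <- ntri + 1L
        tw <- tw + x[i] * x[j] * x[k]
      }
    }
  }
  den <- 0; num2 <- 0
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1)
    if (length(nb) < 2L) next
    cp <- utils::combn(nb, 2L)
    for (c in seq_len(ncol(cp))) {
      j <- cp[1L, c]; k <- cp[2L, c]
      w <- x[i] * x[j] * x[k]
      den <- den + w
      if (A[j, k]) num2 <- num2 + w
    }
  }
  list(tri1 = if (ntri > 0L) tw / ntri else NA_real_,
       tri2 = if (den > 0) num2 / den else NA_real_,
       n_triangles = ntri, twostars_weight = den)
}

# connected components by flood fill
oracle_components <- function(A) {
  n <- nrow(A)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(A[v, ] == 1 & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# direct double-loop evaluation of the prescribing/deprescribing balance
oracle_index_alpha <- function(C, alpha) {
  dc <- c(0, 1, 1, 1, 2, 2, 2, 3)
  P <- 0; D <- 0
  for (i in 1:8) for (j in 1:8) {
    w <- abs(dc[i] - dc[j])^alpha
    if (alpha == 0) w <- 1
    if (i < j) P <- P + C[i, j] * w
    if (i > j) D <- D + C[i, j] * w
  }
  if (P + D == 0) return(NA_real_)
  (P - D) / (P + D)
}

# graph statistics computed directly from an adjacency matrix; terms are
# described by plain lists to stay independent of the package's term
# machinery: list(kind=, x=, level=)
oracle_graph_stats <- function(A, specs) {
  n <- nrow(A)
  vapply(specs, function(sp) {
    s <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (A[i, j] != 1) next
      s <- s + switch(sp$kind,
        edges = 1,
        nodecov = sp$x[i] + sp$x[j],
        absdiff = abs(sp$x[i] - sp$x[j]),
        nodefactor = (sp$x[i] == sp$level) + (sp$x[j] == sp$level),
        nodematch_uniform = as.numeric(sp$x[i] == sp$x[j]),
        nodematch_diff = as.numeric(sp$x[i] == sp$level &&
                                      sp$x[j] == sp$level),
        stop("unknown oracle spec"))
    }
    s
  }, numeric(1))
}

# exact ERGM MLE by full-graph enumeration: statistics of every graph on
# n nodes computed via oracle_graph_stats, likelihood maximized with
# optim (analytic gradient)
oracle_enum_mle <- function(specs, A_obs, eta0 = NULL) {
  n <- nrow(A_obs)
  pairs <- t(utils::combn(n, 2L))
  m <- nrow(pairs)
  combos <- as.matrix(expand.grid(rep(list(0:1), m)))
  S <- t(apply(combos, 1L, function(a) {
    A <- matrix(0L, n, n)
    on <- which(a == 1)
    if (length(on) > 0L) {
      A[pairs[on, , drop = FALSE]] <- 1L
      A[pairs[on, c(2, 1), drop = FALSE]] <- 1L
    }
    oracle_graph_stats(A, specs)
  }))
  if (length(specs) == 1L) S <- matrix(S, ncol = 1L)
  s_obs <- oracle_graph_stats(A_obs, specs)
  negll <- function(eta) {
    lp <- drop(S %*% eta)
    M <- max(lp)
    -(sum(eta * s_obs) - (M + log(sum(exp(lp - M)))))
  }
  grad <- function(eta) {
    lp <- drop(S %*% eta)
    w <- exp(lp - max(lp)); w <- w / sum(w)
    -(s_obs - colSums(S * w))
  }
  if (is.null(eta0)) eta0 <- rep(0, length(specs))
  opt <- stats::optim(eta0, negll, grad, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-15))
  # Newton polish: gradient s_obs - E[g], Hessian -Cov[g], both exact
  eta <- opt$par
  for (it in 1:25) {
    lp <- drop(S %*% eta)
    w <- exp(lp - max(lp)); w <- w / sum(w)
    mu <- colSums(S * w)
    Sc <- sweep(S, 2L, mu)
    H <- crossprod(Sc, Sc * w)
    step <- tryCatch(solve(H, s_obs - mu), error = function(e) NULL)
    if (is.null(step)) break
    eta <- eta + step
    if (max(abs(step)) < 1e-12) break
  }
  eta
}

graph_adjacency <- function(net) {
  as.matrix(igraph::as_adjacency_matrix(net, sparse = FALSE))
}
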