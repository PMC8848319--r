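# Independent oracles used to validate the package's statistics. Each is
# deliberately implemented by a different route than the package code
# (direct enumeration, naive normal equations, Newton iterations,
# distance-sum path membership) so agreement is meaningful.

# Exact Hardy-Weinberg test by full enumeration: probabilities of every
# attainable heterozygote count from the log-factorial formula.
oracle_hwe_enum <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_rare <- 2 * min(n_aa, n_bb) + n_ab
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  logp <- vapply(hets, function(h) {
    hom_rare <- (n_rare - h) / 2
    hom_com <- n - h - hom_rare
    h * log(2) + lfactorial(n) - lfactorial(hom_rare) - lfactorial(h) -
      lfactorial(hom_com) + lfactorial(n_rare) + lfactorial(2 * n - n_rare) -
      lfactorial(2 * n)
  }, 0)
  probs <- exp(logp)
  p_obs <- probs[match(n_ab, hets)]
  # same tie convention as the implementation: tables whose probability
  # equals the observed one (up to rounding) belong to the tail
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Upper-tail hypergeometric probability by exhaustive enumeration of all
# possible draws from the universe (feasible for tiny universes only).
oracle_hyper_enum <- function(universe_size, set_size, draws, k) {
  stopifnot(choose(universe_size, draws) < 2e5)
  combos <- utils::combn(universe_size, draws)
  overlaps <- colSums(combos <= set_size)  # items 1..set_size are "successes"
  mean(overlaps >= k)
}

# Logistic regression by plain Newton-Raphson on the log-likelihood.
oracle_logistic_newton <- function(X, y, tol = 1e-12, maxit = 50) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- as.vector(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    grad <- t(X) %*% (y - mu)
    H <- t(X) %*% (X * (mu * (1 - mu)))
    step <- solve(H, grad)
    beta <- beta + as.vector(step)
    if (max(abs(grad)) < tol) break
  }
  list(coefficients = beta,
       fitted = as.vector(1 / (1 + exp(-X %*% beta))))
}

# Ordinary least squares via explicit normal equations, with the t-test of
# a chosen coefficient.
oracle_ols <- function(X, y, coef_index) {
  XtX_inv <- solve(t(X) %*% X)
  beta <- XtX_inv %*% t(X) %*% y
  resid <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- sum(resid^2) / df
  se <- sqrt(s2 * diag(XtX_inv))
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df)
  list(beta = as.vector(beta), se = as.vector(se),
       t = as.vector(tstat), p = as.vector(p),
       beta_j = beta[coef_index], p_j = p[coef_index])
}

# Brute-force adaptive truncated product: direct products, explicit
# indicator sums, no log-space tricks.
oracle_atpm <- function(pmat, taus = c(0.001, 0.01, 0.05), alpha = 0.05) {
  B1 <- nrow(pmat)
  W <- matrix(NA_real_, B1, length(taus))
  for (b in seq_len(B1)) {
    for (t in seq_along(taus)) {
      p <- pmat[b, ]
      p <- p[!is.na(p)]
      W[b, t] <- prod(p[p <= taus[t]])
    }
  }
  pi_mat <- matrix(NA_real_, B1, length(taus))
  for (b in seq_len(B1)) {
    for (t in seq_along(taus)) {
      pi_mat[b, t] <- sum(W[b, t] >= W[, t]) / B1
    }
  }
  pi_star <- apply(pi_mat, 1, min)
  p0 <- sum(pi_star[1] >= pi_star) / B1
  list(W = W, pi = pi_mat, pi_star = pi_star, p0 = p0,
       significant = p0 <= alpha)
}

# All genes on any shortest path between a and b (direct edge removed),
# by the distance-sum criterion: x lies on a shortest path iff
# d(a,x) + d(x,b) = d(a,b). Plain BFS, no igraph.
oracle_path_genes <- function(edges_df, a, b) {
  edges <- edges_df[, c("gene_a", "gene_b")]
  drop <- (edges$gene_a == a & edges$gene_b == b) |
    (edges$gene_a == b & edges$gene_b == a)
  edges <- edges[!drop, , drop = FALSE]
  nodes <- unique(c(edges_df$gene_a, edges_df$gene_b))
  adj <- lapply(stats::setNames(nodes, nodes), function(x) {
    c(edges$gene_b[edges$gene_a == x], edges$gene_a[edges$gene_b == x])
  })
  bfs_dist <- function(src) {
    d <- stats::setNames(rep(Inf, length(nodes)), nodes)
    d[src] <- 0
    frontier <- src
    level <- 0
    while (length(frontier)) {
      level <- level + 1
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[is.infinite(d[nxt])]
      d[nxt] <- level
      frontier <- nxt
    }
    d
  }
  da <- bfs_dist(a)
  db <- bfs_dist(b)
  if (!is.finite(da[b])) return(NULL)
  sort(nodes[is.finite(da[nodes]) & is.finite(db[nodes]) &
               da[nodes] + db[nodes] == da[b]])
}

# Oracle application of the intermediate-gene rule on top of the path set.
oracle_neighborhood <- function(edges_df, a, b, sig_df) {
  path_genes <- oracle_path_genes(edges_df, a, b)
  if (is.null(path_genes)) return(sort(c(a, b)))
  sig_keys <- paste(sig_df$gene_a, sig_df$gene_b, sep = "|")
  inter <- setdiff(path_genes, c(a, b))
  keep <- vapply(inter, function(x) {
    partners <- setdiff(path_genes, x)
    any(paste(pmin(x, partners), pmax(x, partners), sep = "|") %in% sig_keys)
  }, TRUE)
  sort(unique(c(a, b, inter[keep])))
}
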