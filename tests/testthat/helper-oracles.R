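# Independent brute-force oracles. These deliberately avoid the code
# paths (and where possible the library routines) used by the package:
# exact choose() arithmetic for hypergeometric enumeration, log-factorial
# summation for binomial tails, and exhaustive path enumeration for graph
# metrics.

# Exact hypergeometric pmf of a 2x2 table with fixed margins, from
# binomial coefficients (safe for N <= ~1000 in doubles).
oracle_table_prob <- function(a, b, c, d) {
  choose(a + b, a) * choose(c + d, c) / choose(a + b + c + d, a + c)
}

# Minlike two-sided Fisher p by full enumeration of the support.
oracle_fisher_two_sided <- function(a, b, c, d) {
  m_row <- a + b
  k <- a + c
  n_col <- c + d
  support <- max(0, k - n_col):min(k, m_row)
  probs <- vapply(support, function(x) {
    oracle_table_prob(x, m_row - x, k - x, n_col - (k - x))
  }, numeric(1))
  p_obs <- oracle_table_prob(a, b, c, d)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# One-sided (greater) Fisher p by enumeration.
oracle_fisher_greater <- function(a, b, c, d) {
  m_row <- a + b
  k <- a + c
  n_col <- c + d
  support <- a:min(k, m_row)
  sum(vapply(support, function(x) {
    oracle_table_prob(x, m_row - x, k - x, n_col - (k - x))
  }, numeric(1)))
}

# Upper-tail binomial probability by explicit log-pmf summation.
oracle_binom_tail <- function(n_pos, n_total, p0) {
  if (n_pos == 0) return(1)
  ks <- n_pos:n_total
  lp <- lchoose(n_total, ks) + ks * log(p0) + (n_total - ks) * log1p(-p0)
  mx <- max(lp)
  exp(mx) * sum(exp(lp - mx))
}

# Adjacency list from a gene_network edge tibble.
oracle_adj <- function(net) {
  nodes <- attr(net, "nodes")
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(net))) {
    adj[[net$source[i]]] <- c(adj[[net$source[i]]], net$target[i])
  }
  adj
}

# All simple paths from s to t (depth-first); feasible for n <= 8.
oracle_all_simple_paths <- function(adj, s, t) {
  out <- list()
  walk <- function(path) {
    cur <- path[length(path)]
    if (cur == t) {
      out[[length(out) + 1]] <<- path
      return(invisible())
    }
    for (nxt in adj[[cur]]) {
      if (!(nxt %in% path)) walk(c(path, nxt))
    }
  }
  walk(s)
  out
}

# Directed shortest-path distances, average/diameter over reachable
# pairs, and normalized betweenness — all by exhaustive enumeration of
# simple paths.
oracle_path_and_betweenness <- function(net) {
  nodes <- attr(net, "nodes")
  n <- length(nodes)
  adj <- oracle_adj(net)
  btw <- stats::setNames(rep(0, n), nodes)
  dists <- c()
  for (s in nodes) for (t in nodes) {
    if (s == t) next
    paths <- oracle_all_simple_paths(adj, s, t)
    if (length(paths) == 0) next
    lens <- vapply(paths, length, integer(1)) - 1L
    dmin <- min(lens)
    dists <- c(dists, dmin)
    shortest <- paths[lens == dmin]
    sigma <- length(shortest)
    for (v in setdiff(nodes, c(s, t))) {
      through <- sum(vapply(shortest, function(p) v %in% p, logical(1)))
      btw[v] <- btw[v] + through / sigma
    }
  }
  list(
    average_path_length = if (length(dists)) mean(dists) else NA_real_,
    diameter = if (length(dists)) max(dists) else NA_integer_,
    betweenness = btw / ((n - 1) * (n - 2)),
    n_reachable = length(dists)
  )
}

# sample() treats a scalar first argument as 1:n; pick uniformly from the
# actual vector regardless of its length
sample1 <- function(v) v[sample.int(length(v), 1)]
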