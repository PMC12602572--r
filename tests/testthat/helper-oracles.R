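# Independent brute-force oracles used to cross-check the package.
# Deliberately naive: Floyd-Warshall distances, exhaustive shortest-path
# enumeration for betweenness, closed-form t / chi-square statistics.

fw_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# all shortest paths from s to t as a list of node-index vectors
enumerate_shortest_paths <- function(adj, d, s, t) {
  if (!is.finite(d[s, t])) return(list())
  if (s == t) return(list(s))
  nb <- which(adj[s, ] > 0)
  nb <- nb[d[nb, t] == d[s, t] - 1]
  out <- list()
  for (u in nb)
    for (p in enumerate_shortest_paths(adj, d, u, t))
      out[[length(out) + 1]] <- c(s, p)
  out
}

brute_node_metrics <- function(adj) {
  n <- nrow(adj)
  d <- fw_distances(adj)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  ge <- rowSums(inv) / (n - 1)
  deg <- rowSums(adj > 0)
  apl <- vapply(seq_len(n), function(i) {
    reach <- is.finite(d[i, ]) & d[i, ] > 0
    if (!any(reach)) NA_real_ else mean(d[i, reach])
  }, numeric(1))
  cc <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    if (length(nb) < 2) return(0)
    pairs <- utils::combn(nb, 2)
    mean(adj[t(pairs)] > 0)
  }, numeric(1))
  le <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    if (length(nb) < 2) return(0)
    sub <- adj[nb, nb, drop = FALSE]
    ds <- fw_distances(sub)
    invs <- 1 / ds
    diag(invs) <- 0
    invs[!is.finite(invs)] <- 0
    mean(rowSums(invs) / (length(nb) - 1))
  }, numeric(1))
  bc <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- enumerate_shortest_paths(adj, d, s, t)
    if (!length(paths)) next
    for (p in paths) {
      interior <- setdiff(p, c(s, t))
      bc[interior] <- bc[interior] + 1 / length(paths)
    }
  }
  bc <- bc / ((n - 1) * (n - 2) / 2)
  data.frame(GE = ge, LE = le, BC = bc, APL = apl, CC = cc,
             degree = as.integer(deg), cost = deg / (n - 1))
}

random_adjacency <- function(n, p = 0.35) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  a + t(a)
}

# closed-form one-sample / paired t on a vector of differences
oracle_one_sample_t <- function(x) {
  n <- length(x)
  t_stat <- mean(x) / (stats::sd(x) / sqrt(n))
  list(t = t_stat, df = n - 1, p = 2 * stats::pt(-abs(t_stat), n - 1),
       d = mean(x) / stats::sd(x))
}

# closed-form pooled-variance two-sample t
oracle_two_sample_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
    (nx + ny - 2)
  t_stat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  list(t = t_stat, df = df, p = 2 * stats::pt(-abs(t_stat), df),
       d = (mean(x) - mean(y)) / sqrt(sp2))
}

# closed-form Pearson chi-square (no continuity correction) on a 2D table
oracle_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  x2 <- sum((tab - e)^2 / e)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(x2 = x2, df = df, p = stats::pchisq(x2, df, lower.tail = FALSE),
       phi = sqrt(x2 / sum(tab)))
}

# small complete-pipeline fixture shared by several files
tiny_cohort <- function(n_subjects = 8, n_pairs = 4, seed = 11,
                        effects = NULL, n_timepoints = 96) {
  cfg <- simulation_config(n_subjects = n_subjects,
                           n_timepoints = n_timepoints, tr = 2,
                           n_pairs = n_pairs, effects = effects, seed = seed)
  simulate_cohort(cfg)
}
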