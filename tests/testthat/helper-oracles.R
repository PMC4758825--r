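# Independent oracles and fixture builders shared across the suite.
# The oracles deliberately use naive explicit loops so they share no code
# path with the package implementations they check.

# Newman-Girvan modularity via the explicit pairwise double sum:
# Q = (1 / 2W) * sum_ij (w_ij - k_i k_j / 2W) * [c_i == c_j]
oracle_modularity <- function(w, labels) {
  two_w <- sum(w)
  if (two_w == 0) return(0)
  k <- unname(rowSums(w))
  q <- 0
  n <- nrow(w)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (labels[i] == labels[j]) q <- q + w[i, j] - k[i] * k[j] / two_w
  }
  q / two_w
}

# Assortativity coefficient via an explicitly built c x c mixing matrix.
oracle_rcom <- function(P, labels) {
  diag(P) <- 0
  labs <- sort(unique(labels))
  e <- matrix(0, length(labs), length(labs))
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P))) {
    if (i == j) next
    x <- match(labels[i], labs); y <- match(labels[j], labs)
    e[x, y] <- e[x, y] + P[i, j]
  }
  e <- e / sum(e)
  a <- rowSums(e); b <- colSums(e)
  (sum(diag(e)) - sum(a * b)) / (1 - sum(a * b))
}

# All set partitions of 1..n as label vectors (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  rec <- function(labels, next_max) {
    i <- length(labels) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- labels; return(invisible()) }
    for (v in seq_len(next_max)) rec(c(labels, v), max(next_max, v + 1L))
  }
  rec(integer(0), 1L)
  out
}

# Exhaustive maximum-modularity partition (tiny n only).
oracle_best_partition <- function(w) {
  parts <- all_partitions(nrow(w))
  qs <- vapply(parts, function(p) oracle_modularity(w, p), numeric(1))
  list(labels = parts[[which.max(qs)]], Q = max(qs))
}

# Stream of two cliques always observed as separate, fully cohesive groups.
two_clique_stream <- function(reps = 20, sizes = c(3, 3)) {
  ids1 <- paste0("a", seq_len(sizes[1]))
  ids2 <- paste0("b", seq_len(sizes[2]))
  obs_stream(rep(list(ids1, ids2), reps), roster = c(ids1, ids2))
}

# Stream of groups drawn as i.i.d. random subsets of the roster (no social
# structure beyond sampling noise).
random_group_stream <- function(n_ids = 10, n_groups = 30, mean_size = 3) {
  ids <- paste0("r", seq_len(n_ids))
  units <- lapply(seq_len(n_groups), function(i) {
    sz <- max(1, min(n_ids, stats::rpois(1, mean_size)))
    sample(ids, sz)
  })
  obs_stream(units, roster = ids)
}

# Random symmetric co-membership proportion matrix plus random labels.
random_P_case <- function(n_max = 12, c_max = 4) {
  n <- sample(3:n_max, 1)
  P <- matrix(stats::runif(n * n), n, n)
  P <- (P + t(P)) / 2
  diag(P) <- 0
  labels <- sample.int(sample(2:c_max, 1), n, replace = TRUE)
  # ensure at least two labels actually used (non-degenerate denominator)
  if (length(unique(labels)) == 1L) labels[1] <- labels[1] + 1L
  list(P = P, labels = labels)
}

# Random weighted network over n nodes with edge density ~0.5.
random_weight_matrix <- function(n = 8) {
  w <- matrix(stats::runif(n * n), n, n) * (matrix(stats::runif(n * n), n, n) > 0.5)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  dimnames(w) <- list(paste0("v", 1:n), paste0("v", 1:n))
  w
}
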