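#' Weighted association networks
#'
#' An `assoc_network` holds an undirected weighted network over individual
#' IDs: a symmetric matrix of pairwise association indices in \[0, 1\] with a
#' zero diagonal. Usually built from an observation stream with
#' [build_sri_network()].
#'
#' @param weights symmetric numeric n x n matrix, entries in \[0, 1\],
#'   zero diagonal.
#' @param roster character vector of the n individual IDs (row/column order).
#' @return an object of class `assoc_network` with elements `roster` and
#'   `weights` (dimnames set to the roster).
#' @export
assoc_network <- function(weights, roster = rownames(weights)) {
  roster <- as.character(roster)
  dimnames(weights) <- list(roster, roster)
  out <- structure(list(roster = roster, weights = weights),
                   class = "assoc_network")
  validate_assoc_network(out)
  out
}

validate_assoc_network <- function(x) {
  stopifnot(inherits(x, "assoc_network"))
  w <- x$weights
  if (!is.matrix(w) || nrow(w) != ncol(w)) stop("weights must be square")
  if (nrow(w) != length(x$roster)) stop("weights do not match roster length")
  if (anyDuplicated(x$roster)) stop("duplicate IDs in roster")
  if (any(w < 0 | w > 1)) stop("association indices must lie in [0, 1]")
  if (!isTRUE(all.equal(w, t(w)))) stop("weights must be symmetric")
  if (any(diag(w) != 0)) stop("diagonal must be zero")
  invisible(x)
}

#' @export
print.assoc_network <- function(x, ...) {
  nz <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("Association network: %d individuals, %d non-zero edges, mean SRI %.3f\n",
              length(x$roster), nz,
              mean(x$weights[upper.tri(x$weights)])))
  invisible(x)
}

as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$weights, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Build a simple-ratio-index association network
#'
#' Computes, for every unordered pair of individuals, the simple ratio index
#' \deqn{SRI_{ij} = x / (x + y_{ij} + y_i + y_j)}
#' where, over all sampling units, `x` counts units in which the pair was
#' observed associating, `y_ij` units in which both were observed but not
#' together, and `y_i`, `y_j` units in which only one of them was observed.
#' In group mode the gambit of the group makes co-occurrence in a unit an
#' association, so `y_ij = 0`. In period mode an individual counts as
#' observed in a period when it has at least one association in it, and
#' `y_ij` counts periods where both were active but the dyad was not seen.
#' Pairs whose denominator is zero (never observed in any common or separate
#' unit) get weight 0.
#'
#' @param stream a non-empty [obs_stream()].
#' @return an [assoc_network] over the stream's roster.
#' @examples
#' s <- obs_stream(list(c("A", "B"), c("A", "B"), "A", "B"))
#' build_sri_network(s)$weights["A", "B"]  # 2 / (2 + 0 + 1 + 1) = 0.5
#' @export
build_sri_network <- function(stream) {
  validate_obs_stream(stream)
  if (length(stream$units) == 0L) stop("cannot build a network from an empty stream")
  pres <- presence_matrix(stream)
  b <- crossprod(pres)                 # units where both observed
  if (stream$mode == "group") {
    x <- b                             # co-occurrence = association
  } else {
    x <- Reduce(`+`, stream$units)     # dyadic association counts
    dimnames(x) <- dimnames(b)
  }
  n_i <- diag(b)
  denom <- outer(n_i, n_i, `+`) - b    # units where i or j observed
  w <- ifelse(denom > 0, x / denom, 0)
  diag(w) <- 0
  assoc_network(w, stream$roster)
}

# c x c mixing matrix of a weighted network under a labelling:
# e[x, y] = (weight between communities x and y) / (total weight), with each
# undirected edge counted once in each direction so that a_x = b_x.
mixing_matrix <- function(weights, labels) {
  f <- factor(labels)
  e <- rowsum(t(rowsum(weights, f)), f)
  tot <- sum(e)
  list(e = e / tot, total = tot)
}

#' Weighted modularity of a partition
#'
#' Modularity is the proportion of edge weight falling within communities
#' minus the proportion expected if edges were placed at random preserving
#' node strengths: \eqn{Q = \sum_x (e_{xx} - a_x^2)} on the community mixing
#' matrix, where \eqn{e_{xy}} is the fraction of total weight joining
#' communities x and y and \eqn{a_x = \sum_y e_{xy}}.
#'
#' @param net an [assoc_network].
#' @param labels community labels, one per roster member (any vector
#'   coercible to a factor; named vectors are matched against the roster).
#' @return the modularity Q, in \[-0.5, 1\]. A network with zero total
#'   weight has no structure to measure; Q is defined as 0 with a warning.
#' @export
modularity_q <- function(net, labels) {
  validate_assoc_network(net)
  labels <- align_labels(labels, net$roster)
  if (sum(net$weights) == 0) {
    warning("network has zero total weight; Q defined as 0")
    return(0)
  }
  mm <- mixing_matrix(net$weights, labels)
  a <- rowSums(mm$e)
  sum(diag(mm$e)) - sum(a^2)
}

align_labels <- function(labels, roster) {
  if (!is.null(names(labels))) {
    if (!all(roster %in% names(labels))) stop("labels do not cover the roster")
    labels <- labels[roster]
  } else if (length(labels) != length(roster)) {
    stop("labels must cover every roster member")
  }
  labels
}

#' Detect communities by fast-greedy modularity optimization
#'
#' Partitions the weighted network with the Clauset--Newman--Moore greedy
#' agglomerative algorithm (igraph's `cluster_fast_greedy`, the
#' `fastgreedy.community` of older igraph), cutting the merge sequence at the
#' step of maximum modularity. The result is deterministic given the roster
#' order. Isolated individuals form singleton communities.
#'
#' @param net an [assoc_network]; may contain isolated nodes.
#' @return an object of class `community_partition`: a list with `labels`
#'   (named integer vector, individual -> community index in 1..c), `c` (the
#'   number of communities) and `Q` (the partition's modularity on `net`,
#'   computed by [modularity_q()]).
#' @export
detect_communities <- function(net) {
  validate_assoc_network(net)
  n <- length(net$roster)
  if (n == 1L || sum(net$weights) == 0) {
    labels <- stats::setNames(seq_len(n), net$roster)
    q <- if (n == 1L) 0 else suppressWarnings(modularity_q(net, labels))
    return(structure(list(labels = labels, c = n, Q = q),
                     class = "community_partition"))
  }
  cl <- igraph::cluster_fast_greedy(as_igraph(net))
  # cut the merge sequence at the step of maximum modularity ourselves:
  # igraph's default membership can miss the global maximum of its own
  # modularity path when steps differ only by floating-point noise
  best_step <- which.max(cl$modularity) - 1L
  memb <- igraph::cut_at(cl, no = n - best_step)
  labels <- stats::setNames(as.integer(memb), net$roster)
  structure(list(labels = labels, c = length(unique(labels)),
                 Q = modularity_q(net, labels)),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("Community partition: %d communities over %d individuals, Q = %.4f\n",
              x$c, length(x$labels), x$Q))
  invisible(x)
}
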