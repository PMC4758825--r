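#' Bootstrap resample an observation stream
#'
#' Draws sampling units uniformly with replacement until the replicate has
#' exactly as many units as the original, then restricts the roster to the
#' individuals appearing in the drawn units (in period mode, individuals with
#' at least one association in a drawn period). Some original units appear
#' several times in a replicate and others not at all, so individuals with few
#' observations routinely drop out — which is exactly the sampling error the
#' co-presence matrix accounts for downstream.
#'
#' Randomness is taken from R's global RNG; call `set.seed()` (or use the
#' `seed` argument of [run_rcom()]) for reproducibility.
#'
#' @param stream a non-empty [obs_stream()].
#' @return an `obs_stream` of the same mode and unit count.
#' @export
bootstrap_replicate <- function(stream) {
  k <- length(stream$units)
  if (k == 0L) stop("cannot resample an empty stream")
  idx <- sample.int(k, k, replace = TRUE)
  units <- stream$units[idx]
  if (stream$mode == "group") {
    roster <- stream$roster[stream$roster %in% unique(unlist(units, use.names = FALSE))]
  } else {
    seen <- Reduce(`+`, units)
    roster <- stream$roster[rowSums(seen) > 0]
    units <- lapply(units, function(m) m[roster, roster, drop = FALSE])
  }
  structure(list(units = units, roster = roster, mode = stream$mode),
            class = "obs_stream")
}

#' Accumulate community co-membership across bootstrap replicates
#'
#' For each of `n_boot` bootstrap replicates of the stream, rebuilds the
#' simple-ratio network, reruns community detection, and accumulates two
#' n x n count matrices over the full empirical roster: `M_sum`, the number
#' of replicates in which a pair was present and assigned to the same
#' community, and `C_sum`, the number of replicates in which both members of
#' the pair were present at all (the co-presence matrix). The co-membership
#' proportion matrix is their elementwise ratio,
#' \deqn{P_{ij} = \sum M_{ij} / \sum C_{ij},}
#' the proportion of replicates, conditional on co-presence, in which the
#' pair landed in the same detected community. Pairs never co-present get
#' `P = 0` and are flagged in `never_copresent`; with zero weight they drop
#' out of the assortativity sums harmlessly.
#'
#' Replicates in which fewer than two individuals survive contribute nothing
#' to `M_sum`/`C_sum` but still record `Q = 0` and their node count.
#'
#' @param stream a non-empty [obs_stream()]; its roster fixes the matrix
#'   dimensions.
#' @param n_boot number of bootstrap replicates (default 100).
#' @return an object of class `comembership_summary`: list with `M_sum`,
#'   `C_sum`, `P`, `never_copresent` (logical matrix), `replicate_Q`,
#'   `replicate_c`, `n_boot`.
#' @export
comembership_proportions <- function(stream, n_boot = 100) {
  validate_obs_stream(stream)
  stopifnot(n_boot >= 1)
  roster <- stream$roster
  n <- length(roster)
  M <- C <- matrix(0L, n, n, dimnames = list(roster, roster))
  rep_Q <- rep_c <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    rep_stream <- bootstrap_replicate(stream)
    if (length(rep_stream$roster) < 2L) {
      rep_Q[b] <- 0
      rep_c[b] <- length(rep_stream$roster)
      next
    }
    part <- detect_communities(build_sri_network(rep_stream))
    rep_Q[b] <- part$Q
    rep_c[b] <- part$c
    pres <- match(rep_stream$roster, roster)
    C[pres, pres] <- C[pres, pres] + 1L
    same <- outer(part$labels, part$labels, `==`)
    M[pres, pres] <- M[pres, pres] + same
  }
  diag(M) <- diag(C) <- 0L
  P <- ifelse(C > 0, M / C, 0)
  diag(P) <- 0
  never <- C == 0; diag(never) <- FALSE
  structure(list(M_sum = M, C_sum = C, P = P, never_copresent = never,
                 replicate_Q = rep_Q, replicate_c = rep_c, n_boot = n_boot),
            class = "comembership_summary")
}

#' @export
print.comembership_summary <- function(x, ...) {
  cat(sprintf("Co-membership summary: %d individuals, %d bootstrap replicates\n",
              nrow(x$P), x$n_boot))
  cat(sprintf("  replicate community counts: %s\n",
              paste(names(table(x$replicate_c)), table(x$replicate_c),
                    sep = "x", collapse = ", ")))
  invisible(x)
}

#' Community assortativity of a co-membership matrix
#'
#' Treats the co-membership proportion matrix `P` as a weighted network and
#' measures how much its weight is concentrated within the empirical
#' communities, as an assortativity coefficient:
#' \deqn{r_{com} = \frac{\sum_x e_{xx} - \sum_x a_x b_x}{1 - \sum_x a_x b_x}}
#' where \eqn{e_{xy}} is the proportion of total `P` weight joining nodes of
#' empirical community x to nodes of community y (each unordered pair counted
#' once in each direction, so \eqn{a_x = b_x = \sum_y e_{xy}}).
#'
#' `r_com = 1` when every bootstrap replicate reproduces the empirical
#' assignments exactly (P is 1 within communities, 0 between); values near 0
#' mean replicate assignments are random with respect to the empirical
#' partition (in practice random association floors near ~0.2 rather than 0);
#' negative values mean pairs from *different* empirical communities are
#' co-assigned more often than pairs from the same one.
#'
#' @param P symmetric numeric matrix of co-membership proportions; the
#'   diagonal is ignored.
#' @param labels empirical community labels covering the rows of `P` (named
#'   vectors are matched against `rownames(P)`).
#' @return the assortativity coefficient, in \[-1, 1\]. `NaN` with a warning
#'   when all of `P` is zero or when all weight falls inside a single
#'   community (degenerate denominator).
#' @examples
#' P <- matrix(0.2, 4, 4, dimnames = rep(list(c("A", "B", "C", "D")), 2))
#' P["A", "B"] <- P["B", "A"] <- P["C", "D"] <- P["D", "C"] <- 0.8
#' diag(P) <- 0
#' assortativity_rcom(P, c(A = 1, B = 1, C = 2, D = 2))  # 1/3
#' @export
assortativity_rcom <- function(P, labels) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  if (!isTRUE(all.equal(P, t(P)))) stop("P must be symmetric")
  labels <- align_labels(labels, if (!is.null(rownames(P))) rownames(P) else seq_len(nrow(P)))
  P <- unname(P)
  diag(P) <- 0
  if (sum(P) == 0) {
    warning("all co-membership proportions are zero; r_com undefined")
    return(NaN)
  }
  mm <- mixing_matrix(P, labels)
  a <- rowSums(mm$e)
  denom <- 1 - sum(a^2)
  if (denom == 0) {
    warning("all weight within a single community; r_com undefined")
    return(NaN)
  }
  (sum(diag(mm$e)) - sum(a^2)) / denom
}

#' Bootstrap assessment of community-assignment robustness
#'
#' The full pipeline behind the community-assortativity coefficient: build
#' the empirical simple-ratio network and its fast-greedy partition, bootstrap
#' the observation stream `n_boot` times ([comembership_proportions()]),
#' and measure the assortativity of the resulting co-membership proportions
#' with respect to the empirical communities ([assortativity_rcom()]). Also
#' reports the 2.5/97.5 percentile bootstrap confidence interval for
#' modularity and the distribution of community counts across replicates —
#' useful diagnostics, since replicates are frequently partitioned into a
#' different number of communities than the empirical network.
#'
#' @param stream a non-empty [obs_stream()].
#' @param n_boot number of bootstrap replicates (default 100).
#' @param seed optional integer seed for reproducibility; recorded in the
#'   result.
#' @return an object of class `rcom_result`: list with `r_com`, `Q_emp`,
#'   `Q_ci` (named length-2 vector), `empirical_partition`
#'   (a `community_partition`), `summary` (a `comembership_summary`),
#'   `c_histogram` (table of replicate community counts), `n_boot`, `seed`.
#' @examples
#' s <- obs_stream(rep(list(c("A", "B", "C"), c("D", "E", "F")), 10))
#' run_rcom(s, n_boot = 25, seed = 1)
#' @export
run_rcom <- function(stream, n_boot = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  validate_obs_stream(stream)
  net <- build_sri_network(stream)
  part <- detect_communities(net)
  summ <- comembership_proportions(stream, n_boot = n_boot)
  r <- assortativity_rcom(summ$P, part$labels)
  structure(list(
    r_com = r,
    Q_emp = part$Q,
    Q_ci = stats::quantile(summ$replicate_Q, c(0.025, 0.975), names = TRUE),
    empirical_partition = part,
    summary = summ,
    c_histogram = table(summ$replicate_c),
    n_boot = n_boot,
    seed = seed), class = "rcom_result")
}

#' @export
print.rcom_result <- function(x, ...) {
  cat("Community-assignment robustness (bootstrap assortativity)\n")
  cat(sprintf("  communities: %d   Q = %.4f   95%% bootstrap CI [%.4f, %.4f]\n",
              x$empirical_partition$c, x$Q_emp, x$Q_ci[1], x$Q_ci[2]))
  cat(sprintf("  r_com = %.4f   (%d bootstrap replicates%s)\n", x$r_com, x$n_boot,
              if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  invisible(x)
}

#' Export an rcom_result to JSON (plus the P matrix as CSV)
#'
#' Writes the headline numbers (`r_com`, `Q`, its CI, seed, community labels
#' and the replicate community-count histogram) as JSON, and optionally the
#' full co-membership proportion matrix as CSV alongside.
#'
#' @param result an [run_rcom()] result.
#' @param path output JSON path.
#' @param p_matrix_path optional CSV path for the P matrix.
#' @return `path`, invisibly.
#' @export
write_rcom_json <- function(result, path, p_matrix_path = NULL) {
  stopifnot(inherits(result, "rcom_result"))
  obj <- list(
    r_com = result$r_com,
    Q = result$Q_emp,
    Q_ci = as.numeric(result$Q_ci),
    n_boot = result$n_boot,
    seed = result$seed,
    communities = as.list(result$empirical_partition$labels),
    replicate_c_histogram = as.list(stats::setNames(
      as.integer(result$c_histogram), names(result$c_histogram))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(p_matrix_path))
    utils::write.csv(as.data.frame(result$summary$P), p_matrix_path)
  invisible(path)
}
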