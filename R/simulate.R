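#' Generate a synthetic population with known community structure
#'
#' Creates a fission--fusion population in which each individual is assigned
#' uniformly at random to one of `c` communities. The population-level
#' community fidelity `p_w` (the proportion of an individual's association
#' tendency directed inside its own community) is perturbed per individual by
#' a Normal(1, `attachment_sd`) multiplier to give attachment values
#' `p_wi`, clamped into \[0, 1\]; the outside-community propensity is
#' `p_bi = 1 - p_wi`. True dyadic association probabilities are products of
#' attachments: `e_ij = p_wi * p_wj` within a community and `p_bi * p_bj`
#' between communities. At `p_w = 0.5` within and between probabilities
#' coincide and the population is structureless.
#'
#' Communities can come out empty by chance at small `n`; the population is
#' kept as drawn and realized community sizes can be read off `true_labels`.
#'
#' @param n number of individuals (>= 2). IDs are `"i1" ... "in"`.
#' @param c number of communities (>= 1).
#' @param p_w population-level community fidelity in \[0, 1\].
#' @param p_obs per-period probability that an associating dyad is actually
#'   observed, in (0, 1]; stored for [simulate_stream()].
#' @param attachment_sd standard deviation of the individual attachment
#'   multiplier (default 0.1; 0 gives a block-constant true network).
#' @param seed optional integer seed.
#' @return an object of class `sim_population`: list with `n`, `c`,
#'   `true_labels` (named integer vector), `p_w`, `p_wi`, `p_bi`,
#'   `true_edges` (n x n probability matrix), `p_obs`, `seed`.
#' @export
make_population <- function(n, c, p_w, p_obs, attachment_sd = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n >= 2, c >= 1, p_w >= 0, p_w <= 1, p_obs > 0, p_obs <= 1,
            attachment_sd >= 0)
  ids <- paste0("i", seq_len(n))
  labels <- stats::setNames(sample.int(c, n, replace = TRUE), ids)
  p_wi <- p_w * stats::rnorm(n, mean = 1, sd = attachment_sd)
  n_clamped <- sum(p_wi > 1 | p_wi < 0)
  if (n_clamped > 0)
    message(n_clamped, " attachment value(s) clamped into [0, 1]")
  p_wi <- pmin(pmax(p_wi, 0), 1)
  p_bi <- 1 - p_wi
  same <- outer(labels, labels, `==`)
  e <- ifelse(same, outer(p_wi, p_wi), outer(p_bi, p_bi))
  diag(e) <- 0
  dimnames(e) <- list(ids, ids)
  structure(list(n = n, c = c, true_labels = labels, p_w = p_w,
                 p_wi = stats::setNames(p_wi, ids),
                 p_bi = stats::setNames(p_bi, ids),
                 true_edges = e, p_obs = p_obs, seed = seed),
            class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf("Simulated population: n = %d, c = %d, p_w = %.2f, p_obs = %.2f\n",
              x$n, x$c, x$p_w, x$p_obs))
  cat("  realized community sizes:",
      paste(tabulate(x$true_labels, x$c), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate an observation stream of sampling periods
#'
#' Generates `n_periods` sampling periods for a [make_population()]
#' population. In each period every dyad independently associates (and is
#' observed doing so) with probability `p_obs * e_ij`, producing a symmetric
#' 0/1 dyadic matrix; the stream aggregates the periods in order. Low
#' detectability (`p_obs` small) thus yields the sparse, noisy observation
#' data typical of field studies. Dyadic draws are independent across pairs
#' and periods; there is no triadic closure.
#'
#' @param pop a `sim_population`.
#' @param n_periods number of sampling periods (default 100).
#' @param seed optional integer seed.
#' @return a period-mode [obs_stream()] over the population's IDs.
#' @export
simulate_stream <- function(pop, n_periods = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(pop, "sim_population"), n_periods >= 1)
  ids <- names(pop$true_labels)
  n <- pop$n
  ut <- upper.tri(pop$true_edges)
  probs <- pop$p_obs * pop$true_edges[ut]
  units <- vector("list", n_periods)
  for (t in seq_len(n_periods)) {
    m <- matrix(0L, n, n, dimnames = list(ids, ids))
    m[ut] <- stats::rbinom(length(probs), 1L, probs)
    m <- m + t(m)
    units[[t]] <- m
  }
  obs_stream(units, roster = ids, mode = "period")
}

#' Sweep the simulator over a parameter grid
#'
#' Runs the full pipeline — simulate a population and its observation stream,
#' build the simple-ratio network, detect communities, bootstrap r_com — for
#' every combination of the supplied parameter values, `reps` independent
#' populations per cell. Returns one row per replicate with the modularity,
#' community assortativity and detected community count, in a tidy table
#' ready for summarizing with [sweep_summary()].
#'
#' @param n,c,p_w,p_obs numeric vectors of parameter values to cross.
#' @param reps replicate populations per grid cell (default 100).
#' @param n_boot bootstrap replicates per r_com estimate (default 100).
#' @param n_periods sampling periods per simulated stream (default 100).
#' @param attachment_sd individual attachment spread (default 0.1).
#' @param seed optional integer seed for the whole sweep.
#' @return data.frame with columns `n, c, p_w, p_obs, rep, Q, r_com,
#'   c_detected, c_true`.
#' @export
rcom_sweep <- function(n, c, p_w, p_obs, reps = 100, n_boot = 100,
                       n_periods = 100, attachment_sd = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(n = n, c = c, p_w = p_w, p_obs = p_obs,
                      rep = seq_len(reps), KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    pop <- make_population(g$n, g$c, g$p_w, g$p_obs,
                           attachment_sd = attachment_sd)
    stream <- simulate_stream(pop, n_periods = n_periods)
    r <- run_rcom(stream, n_boot = n_boot)
    data.frame(g, Q = r$Q_emp, r_com = r$r_com,
               c_detected = r$empirical_partition$c,
               c_true = length(unique(pop$true_labels)))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Summarize a simulator sweep per grid cell
#'
#' @param results a [rcom_sweep()] table.
#' @return data.frame with one row per (n, c, p_w, p_obs) cell: replicate
#'   count and mean plus 2.5/97.5 percentiles of Q and r_com.
#' @export
sweep_summary <- function(results) {
  key <- interaction(results$n, results$c, results$p_w, results$p_obs, drop = TRUE)
  rows <- lapply(split(results, key), function(d) {
    data.frame(n = d$n[1], c = d$c[1], p_w = d$p_w[1], p_obs = d$p_obs[1],
               reps = nrow(d),
               mean_Q = mean(d$Q),
               Q_lo = unname(stats::quantile(d$Q, 0.025)),
               Q_hi = unname(stats::quantile(d$Q, 0.975)),
               mean_rcom = mean(d$r_com, na.rm = TRUE),
               rcom_lo = unname(stats::quantile(d$r_com, 0.025, na.rm = TRUE)),
               rcom_hi = unname(stats::quantile(d$r_com, 0.975, na.rm = TRUE)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$n, out$c, out$p_w, out$p_obs), ]
}
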