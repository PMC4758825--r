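#' How Q and r_com change with the number of observations
#'
#' Repeatedly subsamples the observation stream at increasing sample sizes —
#' drawing units uniformly *without* replacement, so the largest size is a
#' reordering of the full data — and runs the bootstrap robustness pipeline
#' on each subsample. Averaging modularity and community assortativity over
#' replicates at each size shows whether confidence in the community
#' assignments is limited by sampling effort (r_com climbing with size) or
#' by the structure itself (r_com flat).
#'
#' Sizes run from `start` in steps of `step` up to the total number of units;
#' the total is always included as the final size.
#'
#' @param stream a non-empty [obs_stream()] with at least `start` units.
#' @param start smallest subsample size (default 50).
#' @param step size increment (default 10).
#' @param reps replicate subsamples per size (default 50).
#' @param n_boot bootstrap replicates per r_com estimate (default 100).
#' @param seed optional integer seed.
#' @return an object of class `subsample_curve`: list with `sizes`,
#'   `mean_Q`, `mean_rcom`, `reps`, `n_boot`, `seed`, and `results` (the
#'   per-replicate data.frame with columns `size, rep, Q, r_com`).
#' @export
subsample_curve <- function(stream, start = 50, step = 10, reps = 50,
                            n_boot = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  validate_obs_stream(stream)
  total <- length(stream$units)
  if (start > total)
    stop("start (", start, ") exceeds the number of units (", total, ")")
  sizes <- seq(start, total, by = step)
  if (sizes[length(sizes)] != total) sizes <- c(sizes, total)
  rows <- lapply(sizes, function(sz) {
    do.call(rbind, lapply(seq_len(reps), function(r) {
      idx <- sample.int(total, sz, replace = FALSE)
      sub <- structure(list(units = stream$units[idx],
                            roster = stream$roster, mode = stream$mode),
                       class = "obs_stream")
      sub <- prune_unobserved(sub)
      res <- run_rcom(sub, n_boot = n_boot)
      data.frame(size = sz, rep = r, Q = res$Q_emp, r_com = res$r_com)
    }))
  })
  results <- do.call(rbind, rows)
  mean_by <- function(v) tapply(v, results$size, mean, na.rm = TRUE)
  structure(list(sizes = sizes,
                 mean_Q = unname(mean_by(results$Q)[as.character(sizes)]),
                 mean_rcom = unname(mean_by(results$r_com)[as.character(sizes)]),
                 reps = reps, n_boot = n_boot, seed = seed,
                 results = results),
            class = "subsample_curve")
}

# restrict the roster to individuals observed in at least one unit
prune_unobserved <- function(stream) {
  seen <- observation_counts(stream) > 0
  roster <- stream$roster[seen]
  units <- if (stream$mode == "group") stream$units else
    lapply(stream$units, function(m) m[roster, roster, drop = FALSE])
  structure(list(units = units, roster = roster, mode = stream$mode),
            class = "obs_stream")
}

#' @export
print.subsample_curve <- function(x, ...) {
  cat(sprintf("Subsample curve: %d sizes (%d..%d), %d replicates each\n",
              length(x$sizes), min(x$sizes), max(x$sizes), x$reps))
  print(data.frame(size = x$sizes, mean_Q = round(x$mean_Q, 4),
                   mean_rcom = round(x$mean_rcom, 4)))
  invisible(x)
}
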