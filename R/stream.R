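#' Observation streams of social groups or sampling periods
#'
#' An `obs_stream` is the ordered record of sampling units that underlies a
#' "gambit of the group" social network. It comes in two modes:
#'
#' * **group** mode: each unit is a set of individual IDs observed together
#'   in one group (flock, herd, ...); everyone in a group is assumed to be
#'   associating with everyone else.
#' * **period** mode: each unit is a symmetric 0/1 dyadic matrix over the
#'   roster, recording which pairs were observed associating during one
#'   sampling period (the form produced by [simulate_stream()]).
#'
#' The unit is the resampling atom for bootstrapping ([bootstrap_replicate()])
#' and the swap substrate for the permutation null ([stream_swap()]).
#'
#' @param units in group mode, a list of character vectors of individual IDs
#'   (each non-empty, no duplicates within a unit); in period mode, a list of
#'   symmetric 0/1 matrices with zero diagonal, all with `dimnames` equal to
#'   the roster.
#' @param roster character vector of all individual IDs, in a stable order.
#'   Defaults to the IDs present in `units`, in order of first appearance.
#' @param mode `"group"` or `"period"`.
#'
#' @return An object of class `obs_stream`: a list with elements `units`,
#'   `roster` and `mode`.
#' @seealso [read_gbi()], [build_sri_network()], [filter_rare_individuals()]
#' @examples
#' s <- obs_stream(list(c("A", "B"), c("A", "B"), "A", "B"))
#' n_units(s)
#' @export
obs_stream <- function(units, roster = NULL, mode = c("group", "period")) {
  mode <- match.arg(mode)
  stopifnot(is.list(units))
  if (mode == "group") {
    units <- lapply(units, as.character)
    if (is.null(roster)) roster <- unique(unlist(units, use.names = FALSE))
    roster <- as.character(roster)
    # canonical within-unit order (roster order): groups are sets, and a
    # canonical order makes serialization round-trip exactly
    units <- lapply(units, function(u) u[order(match(u, roster))])
  } else {
    if (is.null(roster)) {
      if (length(units) == 0L) stop("period-mode stream needs an explicit roster")
      roster <- rownames(units[[1]])
      if (is.null(roster)) stop("period-mode units must carry the roster as dimnames")
    }
    roster <- as.character(roster)
  }
  out <- structure(list(units = units, roster = roster, mode = mode),
                   class = "obs_stream")
  validate_obs_stream(out)
  out
}

validate_obs_stream <- function(x) {
  stopifnot(inherits(x, "obs_stream"))
  if (anyDuplicated(x$roster)) stop("duplicate IDs in roster")
  if (x$mode == "group") {
    for (u in x$units) {
      if (length(u) == 0L) stop("group-mode units must be non-empty")
      if (anyDuplicated(u)) stop("duplicate ID within a group")
      if (!all(u %in% x$roster)) stop("unit contains IDs missing from roster")
    }
  } else {
    n <- length(x$roster)
    for (m in x$units) {
      if (!is.matrix(m) || nrow(m) != n || ncol(m) != n)
        stop("period-mode units must be n x n matrices over the roster")
      if (!all(m %in% c(0, 1))) stop("period-mode units must be 0/1")
      if (!isTRUE(all.equal(m, t(m)))) stop("period-mode units must be symmetric")
      if (any(diag(m) != 0)) stop("period-mode units must have zero diagonal")
    }
  }
  invisible(x)
}

#' @rdname obs_stream
#' @param x an `obs_stream`.
#' @export
n_units <- function(x) {
  stopifnot(inherits(x, "obs_stream"))
  length(x$units)
}

#' @export
print.obs_stream <- function(x, ...) {
  cat(sprintf("Observation stream (%s mode): %d units, %d individuals\n",
              x$mode, length(x$units), length(x$roster)))
  invisible(x)
}

# units x n presence matrix: 1 if the individual was observed in the unit.
# In period mode "observed" means at least one association in that period.
presence_matrix <- function(stream) {
  n <- length(stream$roster)
  k <- length(stream$units)
  out <- matrix(0L, nrow = k, ncol = n, dimnames = list(NULL, stream$roster))
  if (k == 0L) return(out)
  if (stream$mode == "group") {
    for (i in seq_len(k)) out[i, match(stream$units[[i]], stream$roster)] <- 1L
  } else {
    for (i in seq_len(k)) out[i, ] <- as.integer(rowSums(stream$units[[i]]) > 0)
  }
  out
}

# per-individual number of units in which each roster member was observed
observation_counts <- function(stream) {
  colSums(presence_matrix(stream))
}

#' Drop rarely observed individuals from an observation stream
#'
#' Individuals seen in fewer than `min_obs` sampling units are removed from
#' the roster and from every unit; units left empty are dropped. Association
#' networks over sparsely observed individuals carry edges estimated from one
#' or two encounters, so studies routinely apply such a filter (e.g. removing
#' individuals observed fewer than three times) before community detection.
#'
#' Appearances are counted at the unit level: being in a flock once counts
#' once, however many associates it contained.
#'
#' @param stream an [obs_stream()].
#' @param min_obs minimum number of unit appearances required to be kept
#'   (non-negative integer); `min_obs = 0` returns the stream unchanged.
#' @return a new `obs_stream`; the input is not modified.
#' @examples
#' s <- obs_stream(list(c("A", "B"), c("A", "B"), "A", "B", "C"))
#' filter_rare_individuals(s, min_obs = 3)$roster  # C is dropped
#' @export
filter_rare_individuals <- function(stream, min_obs) {
  validate_obs_stream(stream)
  stopifnot(length(min_obs) == 1L, min_obs >= 0)
  keep <- names(which(observation_counts(stream) >= min_obs))
  keep <- stream$roster[stream$roster %in% keep]   # preserve roster order
  if (stream$mode == "group") {
    units <- lapply(stream$units, function(u) u[u %in% keep])
    units <- units[lengths(units) > 0L]
  } else {
    units <- lapply(stream$units, function(m) m[keep, keep, drop = FALSE])
    units <- units[vapply(units, sum, numeric(1)) > 0]
  }
  structure(list(units = units, roster = keep, mode = stream$mode),
            class = "obs_stream")
}
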