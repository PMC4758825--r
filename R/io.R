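#' Read a group-by-individual observation stream from CSV
#'
#' Two tabular dialects are supported:
#'
#' * `"wide"`: a group-by-individual (GBI) matrix. Rows are observed groups,
#'   columns are individual IDs (the header), cells are 0/1. The roster is the
#'   column order.
#' * `"long"`: one row per detection, with columns `group_id` and
#'   `individual_id`. Groups keep file order; the roster is the order of first
#'   appearance, preserving observation chronology for resampling.
#'
#' IDs are kept as opaque strings (ring and colour codes are alphanumeric);
#' no numeric coercion is attempted. Duplicate `(group_id, individual_id)`
#' rows in long format are collapsed with a warning; all-zero rows in wide
#' format (empty groups) are dropped with a warning.
#'
#' @param path path to a UTF-8 comma-separated file with a header row.
#' @param format `"wide"` or `"long"`.
#' @return an [obs_stream()] in group mode.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("A,B,C", "1,1,0", "1,1,0", "1,0,0", "0,1,0"), f)
#' read_gbi(f, format = "wide")
#' @export
read_gbi <- function(path, format = c("wide", "long")) {
  format <- match.arg(format)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = if (format == "long") "character" else NA)
  if (nrow(df) == 0L) stop("empty observation file: ", path)
  if (format == "wide") {
    m <- as.matrix(df)
    if (!all(m %in% c(0, 1)))
      stop("wide GBI cells must be 0/1; offending values: ",
           paste(utils::head(setdiff(unique(c(m)), c(0, 1))), collapse = ", "))
    storage.mode(m) <- "integer"
    roster <- colnames(df)
    empty <- rowSums(m) == 0L
    if (any(empty)) {
      warning(sum(empty), " empty group row(s) dropped")
      m <- m[!empty, , drop = FALSE]
    }
    units <- lapply(seq_len(nrow(m)), function(i) roster[m[i, ] == 1L])
    obs_stream(units, roster = roster, mode = "group")
  } else {
    if (!all(c("group_id", "individual_id") %in% names(df)))
      stop("long format requires columns group_id and individual_id")
    dup <- duplicated(df[c("group_id", "individual_id")])
    if (any(dup)) {
      warning(sum(dup), " duplicate (group_id, individual_id) row(s) collapsed")
      df <- df[!dup, , drop = FALSE]
    }
    groups <- split(df$individual_id, factor(df$group_id, levels = unique(df$group_id)))
    obs_stream(unname(groups), roster = unique(df$individual_id), mode = "group")
  }
}

#' Write an observation stream to CSV
#'
#' Inverse of [read_gbi()]: `"wide"` writes the group-by-individual 0/1
#' matrix (one row per unit, columns in roster order); `"long"` writes
#' `group_id, individual_id` detection rows with generated group IDs
#' `g1, g2, ...` in unit order.
#'
#' @param stream a group-mode [obs_stream()].
#' @param path output file path.
#' @param format `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_gbi <- function(stream, path, format = c("wide", "long")) {
  format <- match.arg(format)
  validate_obs_stream(stream)
  stopifnot(stream$mode == "group")
  if (format == "wide") {
    m <- presence_matrix(stream)
    utils::write.csv(as.data.frame(m, check.names = FALSE), path, row.names = FALSE)
  } else {
    df <- data.frame(
      group_id = rep(paste0("g", seq_along(stream$units)), lengths(stream$units)),
      individual_id = unlist(stream$units, use.names = FALSE),
      stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Write an association network to disk
#'
#' `"edgelist_csv"` writes columns `id_i, id_j, weight`, one row per pair
#' with non-zero weight, `i` before `j` in roster order. `"graphml"` writes
#' a GraphML graph with the edge `weight` attribute and, when `partition` is
#' given, a vertex `community` attribute.
#'
#' @param net an [assoc_network].
#' @param path output file path.
#' @param format `"edgelist_csv"` or `"graphml"`.
#' @param partition optional [detect_communities()] result whose labels are
#'   exported as a vertex attribute in GraphML output.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("edgelist_csv", "graphml"),
                          partition = NULL) {
  format <- match.arg(format)
  validate_assoc_network(net)
  if (format == "edgelist_csv") {
    idx <- which(upper.tri(net$weights) & net$weights > 0, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    df <- data.frame(id_i = net$roster[idx[, 1]], id_j = net$roster[idx[, 2]],
                     weight = net$weights[idx], stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    g <- as_igraph(net)
    if (!is.null(partition))
      igraph::V(g)$community <- unname(partition$labels[net$roster])
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read an association network from an edge-list CSV
#'
#' Reads the `id_i, id_j, weight` format written by [write_network()].
#' Isolated individuals do not appear in an edge list, so a full `roster`
#' should be supplied when the network may contain them; otherwise the roster
#' is the IDs in order of first appearance in the file.
#'
#' @param path path to the edge-list CSV.
#' @param roster optional character vector of all individual IDs.
#' @return an [assoc_network].
#' @export
read_network <- function(path, roster = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "character", "numeric"))
  if (is.null(roster)) roster <- unique(c(rbind(df$id_i, df$id_j)))
  w <- matrix(0, length(roster), length(roster), dimnames = list(roster, roster))
  if (nrow(df) > 0L) {
    w[cbind(df$id_i, df$id_j)] <- df$weight
    w[cbind(df$id_j, df$id_i)] <- df$weight
  }
  assoc_network(w, roster)
}
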