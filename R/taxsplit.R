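# Cluster-splitting heuristic: classify-then-cluster. Sequences are grouped by
# their taxonomic label at a chosen rank, each taxon is clustered
# independently, and the per-taxon OTU lists are merged. Close pairs whose
# members fall in different taxa can never be co-clustered, so they are forced
# false negatives of the merged partition; the merged result is evaluated
# against the FULL graph so this degradation is visible in its MCC.

.tax_ranks <- c("kingdom", "phylum", "class", "order", "family", "genus")

#' Read a taxonomy table
#'
#' Parses the `name<TAB>lineage` dialect emitted by naive Bayesian
#' classifiers: the lineage is a semicolon-delimited list of rank labels from
#' kingdom down, optionally carrying bootstrap confidence values in
#' parentheses, which are stripped. Confidence filtering is assumed to have
#' happened upstream.
#'
#' @param con File path, connection, or character vector of lines.
#' @return Data frame with columns `name` and `taxonomy` (cleaned lineage
#'   string).
#' @export
read_taxonomy <- function(con) {
  lines <- .read_lines_of(con)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(toks) < 2L)
  if (length(bad)) {
    .data_error(sprintf("taxonomy line %d: expected name<TAB>lineage", bad[1L]))
  }
  nm <- vapply(toks, `[[`, "", 1L)
  if (anyDuplicated(nm)) {
    .data_error(paste0("duplicate taxonomy entries: ",
                       paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  lin <- gsub("\\([^)]*\\)", "", vapply(toks, `[[`, "", 2L))
  data.frame(name = nm, taxonomy = trimws(lin))
}

# Label of a lineage string at a rank index (1 = kingdom .. 6 = genus).
# Lineages shallower than the rank, or "unclassified" at the rank, inherit the
# deepest classified label as "<label>_unclassified".
.taxon_at_rank <- function(lineage, rank_idx) {
  parts <- strsplit(lineage, ";", fixed = TRUE)[[1L]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  is_unclass <- function(x) {
    tolower(x) == "unclassified" | grepl("_unclassified$", x)
  }
  deepest <- ""
  out <- character(rank_idx)
  for (k in seq_len(rank_idx)) {
    lab <- if (k <= length(parts)) parts[k] else "unclassified"
    if (is_unclass(lab)) {
      lab <- if (nzchar(deepest)) {
        if (grepl("_unclassified$", deepest)) deepest
        else paste0(deepest, "_unclassified")
      } else "unclassified"
    }
    deepest <- lab
    out[k] <- lab
  }
  out[rank_idx]
}

.taxon_labels <- function(taxonomy, names, rank) {
  rank_idx <- match(rank, .tax_ranks)
  if (is.na(rank_idx)) {
    stop("rank must be one of: ", paste(.tax_ranks, collapse = ", "))
  }
  if (is.data.frame(taxonomy)) {
    lin <- taxonomy$taxonomy
    names(lin) <- taxonomy$name
  } else {
    lin <- taxonomy
  }
  missing <- setdiff(names, names(lin))
  if (length(missing)) {
    .data_error(paste0("sequences missing from taxonomy: ",
                       paste(missing, collapse = ", ")))
  }
  vapply(unname(lin[names]), .taxon_at_rank, "", rank_idx = rank_idx)
}

#' Split a close-pair graph by taxonomic classification
#'
#' Groups the roster by taxon label at `rank` and builds one sub-graph per
#' taxon holding only within-taxon close pairs. Close pairs that straddle two
#' taxa are dropped from every sub-graph and reported: they are guaranteed
#' false negatives of any downstream merged clustering.
#'
#' @param graph A [close_pair_graph()].
#' @param taxonomy A data frame from [read_taxonomy()] (or a named character
#'   vector of lineage strings) covering the whole roster.
#' @param rank Rank to split at: `"kingdom"`, `"phylum"`, `"class"`,
#'   `"order"`, `"family"`, or `"genus"`.
#' @return List with `subgraphs` (named list of [close_pair_graph()], one per
#'   taxon), `cross_close_pairs` (count of close pairs straddling taxa), and
#'   `cross_pairs` (two-column character matrix of those pairs).
#' @export
split_roster <- function(graph, taxonomy, rank = "genus") {
  stopifnot(inherits(graph, "close_pair_graph"))
  lab <- .taxon_labels(taxonomy, graph$names, rank)
  e <- graph$edges
  cross <- if (nrow(e)) lab[e[, 1L]] != lab[e[, 2L]] else logical(0)
  groups <- split(seq_len(graph$n), lab)
  subgraphs <- lapply(groups, function(idx) {
    keep <- if (nrow(e)) (e[, 1L] %in% idx) & (e[, 2L] %in% idx) else logical(0)
    pairs <- cbind(graph$names[e[keep, 1L]], graph$names[e[keep, 2L]])
    close_pair_graph(graph$names[idx], pairs, graph$cutoff)
  })
  cross_pairs <- cbind(graph$names[e[cross, 1L]], graph$names[e[cross, 2L]])
  list(
    subgraphs = subgraphs,
    cross_close_pairs = sum(cross),
    cross_pairs = cross_pairs
  )
}

#' Cluster each taxon independently and merge the OTU lists
#'
#' Runs [opti_cluster()] on every taxon sub-graph (with per-taxon shuffle
#' seeds derived from `shuffle_seed` and a stable hash of the taxon label, so
#' the result does not depend on taxon processing order), merges the per-taxon
#' partitions, and evaluates the merged partition against the full graph.
#' Splitting can only forbid co-clustering, never enable better solutions, so
#' the merged MCC is at most the plain-clustering optimum and each cross-taxon
#' close pair appears as a forced false negative.
#'
#' @inheritParams split_roster
#' @inheritParams opti_cluster
#' @param ... Further arguments passed to [opti_cluster()] (metric,
#'   seed_mode, delta, max_iterations, ...).
#' @return An object of class `opti_split`: a list with `partition` (merged
#'   [otu_partition()] over the full roster), `per_taxon` (named list of
#'   `opti_cluster` fits), `confusion` (merged partition vs the FULL graph),
#'   `final_metric` (MCC of the merged partition), `cross_close_pairs`, and
#'   `rank`.
#' @export
split_cluster <- function(graph, taxonomy, rank = "genus",
                          shuffle_seed = 1L, label = format(graph$cutoff),
                          ...) {
  sp <- split_roster(graph, taxonomy, rank)
  per_taxon <- lapply(names(sp$subgraphs), function(tx) {
    seed <- (as.numeric(shuffle_seed) + .str_hash(tx)) %% 2147483647
    opti_cluster(sp$subgraphs[[tx]], shuffle_seed = as.integer(seed),
                 label = label, ...)
  })
  names(per_taxon) <- names(sp$subgraphs)
  merged <- otu_partition(
    unlist(lapply(per_taxon, function(r) r$partition$otus), recursive = FALSE),
    label = label
  )
  confusion <- evaluate_partition(merged, graph)
  structure(
    list(
      partition = merged,
      per_taxon = per_taxon,
      confusion = confusion,
      final_metric = mcc(confusion),
      cross_close_pairs = sp$cross_close_pairs,
      rank = rank
    ),
    class = "opti_split"
  )
}

#' @export
print.opti_split <- function(x, ...) {
  cat(sprintf(
    "Split clustering at rank '%s': %d taxa, %d OTUs, merged MCC %.4f\n",
    x$rank, length(x$per_taxon), n_otus(x$partition), x$final_metric
  ))
  cat(sprintf("Cross-taxon close pairs (forced FN): %d\n", x$cross_close_pairs))
  invisible(x)
}
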