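# OTU partitions and the mothur-style list dialect.

#' Construct an OTU partition
#'
#' A partition assigns every sequence in a roster to exactly one OTU. OTUs are
#' stored canonically: members sorted within each OTU, OTUs ordered by
#' decreasing size with ties broken by the lexicographically smallest member.
#'
#' @param otus List of character vectors, each a non-empty OTU; the vectors
#'   must be pairwise disjoint. Empty OTUs are dropped.
#' @param label User-facing distance label, e.g. `"0.03"`.
#' @return An object of class `otu_partition` with elements `otus` and `label`.
#' @export
otu_partition <- function(otus, label = "0.03") {
  otus <- unname(lapply(otus, function(x) unname(as.character(x))))
  otus <- otus[lengths(otus) > 0L]
  if (length(otus) == 0L) stop("partition must contain at least one sequence")
  all_names <- unlist(otus, use.names = FALSE)
  if (anyDuplicated(all_names)) {
    .data_error(paste0("sequence assigned to more than one OTU: ",
                       paste(unique(all_names[duplicated(all_names)]), collapse = ", ")))
  }
  otus <- lapply(otus, sort)
  first <- vapply(otus, `[[`, "", 1L)
  otus <- otus[order(-lengths(otus), first)]
  structure(list(otus = otus, label = as.character(label)),
            class = "otu_partition")
}

#' @export
print.otu_partition <- function(x, ...) {
  sizes <- lengths(x$otus)
  cat(sprintf("OTU partition '%s': %d sequences in %d OTUs (largest %d)\n",
              x$label, sum(sizes), length(sizes), max(sizes)))
  invisible(x)
}

#' Number of OTUs in a partition
#' @param partition An [otu_partition()].
#' @return Integer count of OTUs.
#' @export
n_otus <- function(partition) {
  stopifnot(inherits(partition, "otu_partition"))
  length(partition$otus)
}

#' Roster of a partition
#' @param partition An [otu_partition()].
#' @return Sorted character vector of all member names.
#' @export
partition_roster <- function(partition) {
  sort(unlist(partition$otus, use.names = FALSE))
}

#' Seed an initial partition for the optimizer
#'
#' The optimizer starts either from every sequence in its own OTU
#' (`"singletons"`, the default and the better-performing seeding) or from all
#' sequences in one OTU (`"one_otu"`).
#'
#' @param graph A [close_pair_graph()].
#' @param mode `"singletons"` or `"one_otu"`.
#' @param label Distance label carried into the partition.
#' @return An [otu_partition()].
#' @export
seed_partition <- function(graph, mode = c("singletons", "one_otu"),
                           label = format(graph$cutoff)) {
  stopifnot(inherits(graph, "close_pair_graph"))
  mode <- match.arg(mode)
  if (graph$n == 0L) stop("empty roster")
  otus <- if (mode == "singletons") as.list(graph$names) else list(graph$names)
  otu_partition(otus, label = label)
}

# ---- list-file dialect -------------------------------------------------------

#' Write a partition as a mothur-style list line
#'
#' One line: label, tab, OTU count, tab, then each OTU as its comma-joined,
#' lexicographically sorted member names, OTUs separated by tabs and ordered
#' by decreasing size (ties by smallest member). The output round-trips
#' through [read_otu_list()].
#'
#' @param partition An [otu_partition()].
#' @param con File path or connection; omit to return the line invisibly only.
#' @return The formatted line, invisibly.
#' @export
write_otu_list <- function(partition, con = NULL) {
  stopifnot(inherits(partition, "otu_partition"))
  fields <- vapply(partition$otus, paste, "", collapse = ",")
  line <- paste(c(partition$label, length(fields), fields), collapse = "\t")
  if (!is.null(con)) writeLines(line, con)
  invisible(line)
}

#' Read a mothur-style list line into a partition
#'
#' @param con File path, connection, or a character vector whose first
#'   non-blank line is parsed.
#' @return An [otu_partition()].
#' @export
read_otu_list <- function(con) {
  lines <- .read_lines_of(con)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) .data_error("empty list stream")
  toks <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(toks) < 3L) {
    .data_error("list line needs at least label, count, and one OTU")
  }
  label <- toks[1L]
  declared <- suppressWarnings(as.integer(toks[2L]))
  otus <- strsplit(toks[-(1:2)], ",", fixed = TRUE)
  if (is.na(declared) || declared != length(otus)) {
    .data_error(sprintf("list OTU count mismatch: declared %s, parsed %d",
                        toks[2L], length(otus)))
  }
  otu_partition(otus, label = label)
}
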