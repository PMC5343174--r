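# Sparse close-pair graph: the only thing the optimizer needs from the
# distances is which unordered pairs are at or below the cutoff.

#' Construct a close-pair graph
#'
#' A `close_pair_graph` records, for a roster of unique sequence names, exactly
#' the unordered pairs whose dissimilarity is at or below a cutoff ("close"
#' pairs). Distances themselves are not retained: the clustering algorithm and
#' the pairwise confusion matrix depend only on the boolean close/far relation,
#' which keeps memory proportional to the number of close pairs rather than to
#' all \eqn{n(n-1)/2} pairs.
#'
#' @param names Character vector of unique sequence identifiers (the roster).
#' @param pairs Two-column character matrix (or data.frame) of close pairs;
#'   may be empty. Self-pairs are an error; duplicate pairs are collapsed.
#' @param cutoff Dissimilarity threshold that defined the pairs, a fraction in
#'   `[0, 1]`. Stored for reporting only.
#' @return An object of class `close_pair_graph` with elements `names`,
#'   `edges` (integer matrix, one row per close pair, first column < second),
#'   `adj` (per-sequence integer neighbor lists), `cutoff`, `n`, `total_close`.
#' @seealso [read_dist_column()], [read_dist_phylip()], [total_pairs()]
#' @export
close_pair_graph <- function(names, pairs = NULL, cutoff = 0.03) {
  names <- as.character(names)
  if (anyDuplicated(names)) {
    stop("duplicate sequence names in roster: ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  }
  if (length(names) == 0L) stop("empty roster")
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff < 0 || cutoff > 1) {
    stop("cutoff must be a single fraction in [0, 1]")
  }
  if (is.null(pairs) || NROW(pairs) == 0L) {
    e <- matrix(integer(0), ncol = 2L)
  } else {
    pairs <- as.matrix(pairs)
    i <- match(pairs[, 1L], names)
    j <- match(pairs[, 2L], names)
    if (anyNA(i) || anyNA(j)) {
      bad <- unique(c(pairs[, 1L][is.na(i)], pairs[, 2L][is.na(j)]))
      stop("pair member(s) not in roster: ", paste(bad, collapse = ", "))
    }
    if (any(i == j)) stop("self-pair not allowed: ", pairs[which(i == j)[1L], 1L])
    e <- cbind(pmin(i, j), pmax(i, j))
    e <- unique(e)
    e <- e[order(e[, 1L], e[, 2L]), , drop = FALSE]
  }
  structure(
    list(
      names = names,
      edges = e,
      adj = .adj_from_edges(e, length(names)),
      cutoff = cutoff,
      n = length(names),
      total_close = nrow(e)
    ),
    class = "close_pair_graph"
  )
}

.adj_from_edges <- function(edges, n) {
  adj <- vector("list", n)
  for (k in seq_len(n)) adj[[k]] <- integer(0)
  if (nrow(edges)) {
    by_a <- split(edges[, 2L], factor(edges[, 1L], levels = seq_len(n)))
    by_b <- split(edges[, 1L], factor(edges[, 2L], levels = seq_len(n)))
    for (k in seq_len(n)) {
      adj[[k]] <- sort(c(by_a[[k]], by_b[[k]]))
    }
  }
  adj
}

#' Total number of sequence pairs in a graph
#'
#' @param graph A [close_pair_graph()].
#' @return \eqn{n(n-1)/2} as a double (exact for all practical rosters).
#' @export
total_pairs <- function(graph) {
  stopifnot(inherits(graph, "close_pair_graph"))
  n <- graph$n
  n * (n - 1) / 2
}

#' @export
print.close_pair_graph <- function(x, ...) {
  cat(sprintf(
    "Close-pair graph: %d sequences, %d close pairs of %s total (cutoff %g)\n",
    x$n, x$total_close, format(total_pairs(x), big.mark = ","), x$cutoff
  ))
  invisible(x)
}

# ---- readers ----------------------------------------------------------------

.data_error <- function(msg) {
  stop(errorCondition(msg, class = c("opticlustr_data_error", "error")))
}

.read_lines_of <- function(con) {
  if (inherits(con, "connection")) {
    readLines(con, warn = FALSE)
  } else if (is.character(con) && length(con) == 1L && !grepl("\n", con) &&
             file.exists(con)) {
    readLines(con, warn = FALSE)
  } else if (is.character(con) && length(con) == 1L && grepl("\n", con)) {
    strsplit(con, "\n", fixed = TRUE)[[1L]]
  } else {
    as.character(con)
  }
}

#' Read a column-format (triplet) distance file into a close-pair graph
#'
#' Each non-blank line holds `nameA nameB distance` separated by whitespace.
#' Pairs with distance greater than the cutoff are dropped, but both names
#' still join the roster, so sequences with no close neighbor are clustered
#' as isolated vertices. The cutoff is inclusive: a pair at exactly the cutoff
#' is close.
#'
#' Duplicate records for the same unordered pair are tolerated when their
#' distances agree and are an error otherwise.
#'
#' @param con File path, connection, or character vector of lines.
#' @param cutoff Inclusive dissimilarity threshold (default 0.03).
#' @param roster Optional character vector of sequence names to include even
#'   when absent from every pair (e.g. from a name or count file). Must not
#'   contain duplicates.
#' @return A [close_pair_graph()].
#' @export
read_dist_column <- function(con, cutoff = 0.03, roster = NULL) {
  lines <- .read_lines_of(con)
  keep <- nzchar(trimws(lines))
  lnum <- which(keep)
  lines <- lines[keep]
  if (!is.null(roster)) {
    roster <- as.character(roster)
    if (anyDuplicated(roster)) {
      .data_error(paste0("roster name collision: ",
                         paste(unique(roster[duplicated(roster)]), collapse = ", ")))
    }
  }

  if (length(lines)) {
    toks <- strsplit(trimws(lines), "[ \t]+")
    nf <- lengths(toks)
    if (any(nf != 3L)) {
      k <- which(nf != 3L)[1L]
      .data_error(sprintf("line %d: expected 3 fields, found %d",
                          lnum[k], nf[k]))
    }
    a <- vapply(toks, `[[`, "", 1L)
    b <- vapply(toks, `[[`, "", 2L)
    d <- suppressWarnings(as.numeric(vapply(toks, `[[`, "", 3L)))
    bad <- which(is.na(d) | d < 0 | d > 1)
    if (length(bad)) {
      k <- bad[1L]
      .data_error(sprintf("line %d: distance '%s' is not a number in [0, 1]",
                          lnum[k], toks[[k]][3L]))
    }
    if (any(a == b)) {
      k <- which(a == b)[1L]
      .data_error(sprintf("line %d: self-pair '%s'", lnum[k], a[k]))
    }
    key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
    if (anyDuplicated(key)) {
      rng <- tapply(d, key, function(x) diff(range(x)))
      if (any(rng > 0)) {
        pair <- names(rng)[which(rng > 0)[1L]]
        k <- which(key == pair)
        .data_error(sprintf(
          "line %d: conflicting duplicate distance for pair (%s): %s",
          lnum[k[2L]], gsub("\r", ", ", pair),
          paste(unique(d[k]), collapse = " vs ")))
      }
      keep <- !duplicated(key)
      a <- a[keep]; b <- b[keep]; d <- d[keep]
    }
    names_seen <- unique(c(a, b))
    is_close <- d <= cutoff
    pairs <- cbind(a[is_close], b[is_close])
  } else {
    names_seen <- character(0)
    pairs <- NULL
  }

  all_names <- unique(c(names_seen, roster))
  if (length(all_names) == 0L) {
    .data_error("no sequences: empty input and no roster")
  }
  close_pair_graph(sort(all_names), pairs, cutoff)
}

#' Read a PHYLIP-dialect distance matrix into a close-pair graph
#'
#' The first line gives the sequence count `n`; each following line is a
#' sequence name followed by its distances. Square and lower-triangle layouts
#' are auto-detected from the second data row. All `n` names enter the roster
#' regardless of the cutoff; only pairs at or below the cutoff are stored.
#'
#' @inheritParams read_dist_column
#' @return A [close_pair_graph()].
#' @export
read_dist_phylip <- function(con, cutoff = 0.03) {
  lines <- .read_lines_of(con)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) .data_error("empty PHYLIP stream")
  n <- suppressWarnings(as.integer(trimws(lines[[1L]])))
  if (is.na(n) || n < 1L) {
    .data_error("first PHYLIP line must be a positive sequence count")
  }
  body <- lines[-1L]
  if (length(body) != n) {
    .data_error(sprintf("PHYLIP row/count mismatch: declared %d, found %d rows",
                        n, length(body)))
  }
  rows <- lapply(body, function(l) strsplit(trimws(l), "[ \t]+")[[1L]])
  nm <- vapply(rows, `[[`, "", 1L)

  lower <- if (n >= 2L) length(rows[[2L]]) == 2L else TRUE
  vals <- vector("list", n)
  for (i in seq_len(n)) {
    expect <- if (lower) i - 1L else n
    v <- suppressWarnings(as.numeric(rows[[i]][-1L]))
    if (length(v) != expect) {
      .data_error(sprintf("PHYLIP row %d ('%s'): expected %d distances, found %d",
                          i, nm[i], expect, length(v)))
    }
    if (anyNA(v)) {
      .data_error(sprintf("PHYLIP row %d ('%s'): non-numeric cell", i, nm[i]))
    }
    vals[[i]] <- v
  }

  if (!lower && n >= 2L) {
    m <- do.call(rbind, vals)
    if (max(abs(m - t(m))) > 1e-9) {
      .data_error("asymmetric square PHYLIP matrix (beyond 1e-9 tolerance)")
    }
  }

  a <- character(0); b <- character(0)
  for (i in seq_len(n)) {
    js <- if (lower) seq_len(i - 1L) else seq_len(i - 1L)
    if (length(js)) {
      d <- vals[[i]][js]
      hit <- which(d <= cutoff)
      if (length(hit)) {
        a <- c(a, rep(nm[i], length(hit)))
        b <- c(b, nm[hit])
      }
    }
  }
  close_pair_graph(sort(nm), cbind(a, b), cutoff)
}

#' Read a roster of sequence names, optionally with abundances
#'
#' Accepts one name per line or a two-column `name<TAB>count` table (a count
#' file). Counts are returned as an attribute for reporting; they never affect
#' clustering, which operates on unique sequences.
#'
#' @param con File path, connection, or character vector of lines.
#' @return Character vector of names; if counts were present they are attached
#'   as the `counts` attribute (named integer vector).
#' @export
read_roster <- function(con) {
  lines <- .read_lines_of(con)
  lines <- lines[nzchar(trimws(lines))]
  toks <- lapply(lines, function(l) strsplit(trimws(l), "[ \t]+")[[1L]])
  nf <- lengths(toks)
  nms <- vapply(toks, `[[`, "", 1L)
  if (anyDuplicated(nms)) {
    .data_error(paste0("roster name collision: ",
                       paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  }
  if (all(nf >= 2L) && length(nf)) {
    cnt <- suppressWarnings(as.integer(vapply(toks, `[[`, "", 2L)))
    if (!anyNA(cnt)) {
      names(cnt) <- nms
      attr(nms, "counts") <- cnt
    }
  }
  nms
}
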