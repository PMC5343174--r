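# Planted-partition fixtures: synthetic distance files with a known ground
# truth, plus abundance profiles and taxonomy tables, so the whole pipeline is
# testable without any external data.

#' Generate a planted-partition distance instance
#'
#' Builds a set of sequences grouped into ground-truth clusters. Pairs within
#' a cluster draw their distance uniformly from `within` (at or below the
#' cutoff: close) and pairs across clusters from `between` (above the cutoff:
#' far). With probability `noise_rate` a pair's close/far status is flipped by
#' redrawing its distance from the opposite range, emulating sequencing error
#' pushing pairs across the threshold. The generator is a pure function of its
#' arguments and `seed`.
#'
#' @param cluster_sizes Integer vector of ground-truth cluster sizes.
#' @param within Length-2 numeric range for within-cluster distances; must lie
#'   inside `[0, cutoff]`. Default `c(0.005, 0.03)`.
#' @param between Length-2 numeric range for between-cluster distances; must
#'   lie inside `(cutoff, 1]`. Default `c(0.05, 0.25)`.
#' @param noise_rate Per-pair flip probability in `[0, 0.5)`. Default 0.
#' @param cutoff Dissimilarity threshold. Default 0.03.
#' @param seed RNG seed.
#' @return List with `records` (data frame `name_a`, `name_b`, `distance`
#'   covering every unordered pair), `truth` (the planted [otu_partition()]),
#'   `cutoff`, and `n_flipped` (number of noise-flipped pairs).
#' @export
simulate_planted <- function(cluster_sizes,
                             within = c(0.005, 0.03),
                             between = c(0.05, 0.25),
                             noise_rate = 0,
                             cutoff = 0.03,
                             seed = 1L) {
  cluster_sizes <- as.integer(cluster_sizes)
  if (length(cluster_sizes) == 0L || any(is.na(cluster_sizes)) ||
      any(cluster_sizes < 1L)) {
    stop("cluster_sizes must be positive integers")
  }
  if (length(within) != 2L || within[1L] > within[2L] ||
      within[1L] < 0 || within[2L] > cutoff) {
    stop("within range must lie inside [0, cutoff]")
  }
  if (length(between) != 2L || between[1L] > between[2L] ||
      between[1L] <= cutoff || between[2L] > 1) {
    stop("between range must lie inside (cutoff, 1]")
  }
  if (noise_rate < 0 || noise_rate >= 0.5) {
    stop("noise_rate must be in [0, 0.5)")
  }
  n <- sum(cluster_sizes)
  names <- sprintf("seq%04d", seq_len(n))
  truth_memb <- rep(seq_along(cluster_sizes), cluster_sizes)

  if (n >= 2L) {
    idx <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
    i <- idx[, 1L]; j <- idx[, 2L]
    same <- truth_memb[i] == truth_memb[j]
    np <- length(i)
    out <- .with_seed(seed, {
      flip <- if (noise_rate > 0) stats::runif(np) < noise_rate
              else rep(FALSE, np)
      close <- xor(same, flip)
      d <- numeric(np)
      d[close] <- stats::runif(sum(close), within[1L], within[2L])
      d[!close] <- stats::runif(sum(!close), between[1L], between[2L])
      list(d = d, n_flipped = sum(flip))
    })
    records <- data.frame(name_a = names[i], name_b = names[j],
                          distance = out$d)
    n_flipped <- out$n_flipped
  } else {
    records <- data.frame(name_a = character(0), name_b = character(0),
                          distance = numeric(0))
    n_flipped <- 0L
  }

  list(
    records = records,
    truth = otu_partition(split(names, truth_memb), label = format(cutoff)),
    cutoff = cutoff,
    n_flipped = n_flipped
  )
}

#' Write distance records as a column-format distance file
#'
#' @param records Data frame with columns `name_a`, `name_b`, `distance`
#'   (e.g. from [simulate_planted()]).
#' @param con Optional file path or connection.
#' @return Character vector of lines, invisibly (readable directly by
#'   [read_dist_column()]).
#' @export
write_dist_column <- function(records, con = NULL) {
  lines <- sprintf("%s\t%s\t%.6f",
                   records$name_a, records$name_b, records$distance)
  if (!is.null(con)) writeLines(lines, con)
  invisible(lines)
}

#' Graph of a simulated instance
#'
#' Convenience wrapper: serializes the instance's records through the column
#' dialect and reads them back, so the real file-parsing path (including the
#' inclusive cutoff boundary) is exercised.
#'
#' @param sim Result of [simulate_planted()].
#' @return A [close_pair_graph()].
#' @export
planted_graph <- function(sim) {
  if (nrow(sim$records) == 0L) {
    return(close_pair_graph(partition_roster(sim$truth), NULL, sim$cutoff))
  }
  read_dist_column(write_dist_column(sim$records), cutoff = sim$cutoff,
                   roster = NULL)
}

#' Generate an abundance profile
#'
#' Emulates the abundance structure of synthetic benchmark communities: an
#' `"even"` community gives every sequence the same read count (default 100
#' reads); a `"staggered"` community draws each count uniformly from an
#' integer range (default 1 to 200). Counts are reporting metadata only; the
#' clustering operates on unique sequences.
#'
#' @param mode `"even"` or `"staggered"`.
#' @param n_taxa Number of sequences.
#' @param even_depth Reads per sequence for the even profile. Default 100.
#' @param staggered_range Integer range for the staggered profile. Default
#'   `c(1, 200)`.
#' @param seed RNG seed (staggered mode).
#' @param names Optional sequence names; defaults to `seq0001`, ...
#' @return Data frame with columns `name` and `count`.
#' @export
simulate_abundance <- function(mode = c("even", "staggered"),
                               n_taxa,
                               even_depth = 100L,
                               staggered_range = c(1L, 200L),
                               seed = 1L,
                               names = NULL) {
  mode <- match.arg(mode)
  n_taxa <- as.integer(n_taxa)
  if (is.na(n_taxa) || n_taxa < 0L) stop("n_taxa must be >= 0")
  if (n_taxa == 0L) {
    return(data.frame(name = character(0), count = integer(0)))
  }
  if (is.null(names)) names <- sprintf("seq%04d", seq_len(n_taxa))
  stopifnot(length(names) == n_taxa)
  counts <- if (mode == "even") {
    if (even_depth < 1L) stop("even_depth must be >= 1")
    rep(as.integer(even_depth), n_taxa)
  } else {
    lo <- as.integer(staggered_range[1L]); hi <- as.integer(staggered_range[2L])
    if (lo < 1L || hi < lo) stop("invalid staggered_range")
    .with_seed(seed, sample.int(hi - lo + 1L, n_taxa, replace = TRUE) + lo - 1L)
  }
  data.frame(name = names, count = counts)
}

#' Generate a taxonomy table for a planted truth partition
#'
#' Assigns each ground-truth OTU wholly to one of `k_genera` genus-level
#' lineages (cycling), then reassigns each sequence to a uniformly chosen
#' different genus with probability `cross_rate`, emulating misclassification
#' — the error source that turns within-OTU close pairs into cross-taxon
#' pairs under the splitting heuristic.
#'
#' @param truth An [otu_partition()] (e.g. from [simulate_planted()]).
#' @param k_genera Number of distinct genus lineages.
#' @param cross_rate Per-sequence misassignment probability in `[0, 1]`.
#' @param seed RNG seed.
#' @return Data frame with columns `name` and `taxonomy` (six-rank
#'   semicolon-delimited lineage), as from [read_taxonomy()].
#' @export
simulate_taxonomy <- function(truth, k_genera, cross_rate = 0, seed = 1L) {
  stopifnot(inherits(truth, "otu_partition"))
  k_genera <- as.integer(k_genera)
  if (is.na(k_genera) || k_genera < 1L) stop("k_genera must be >= 1")
  if (cross_rate < 0 || cross_rate > 1) stop("cross_rate must be in [0, 1]")
  lineage_of <- function(g) {
    sprintf("Bacteria;Phylum%02d;Class%02d;Order%02d;Family%02d;Genus%02d;",
            g, g, g, g, g)
  }
  otu_genus <- ((seq_along(truth$otus) - 1L) %% k_genera) + 1L
  nm <- unlist(truth$otus, use.names = FALSE)
  genus <- rep(otu_genus, lengths(truth$otus))
  if (cross_rate > 0 && k_genera >= 2L) {
    genus <- .with_seed(seed, {
      flip <- stats::runif(length(nm)) < cross_rate
      shifted <- genus
      if (any(flip)) {
        # uniform over the k-1 other genera
        offs <- sample.int(k_genera - 1L, sum(flip), replace = TRUE)
        shifted[flip] <- ((genus[flip] - 1L + offs) %% k_genera) + 1L
      }
      shifted
    })
  }
  data.frame(name = nm, taxonomy = vapply(genus, lineage_of, ""))
}
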