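# Independent oracles: deliberately naive routes to the same quantities the
# package computes, used to cross-check it. None of these call the package's
# evaluation or clustering code paths.

# All set partitions of n labeled elements as membership vectors
# (restricted-growth strings); 877 partitions for n = 7.
rgs_partitions <- function(n) {
  out <- vector("list", 0L)
  rec <- function(prefix, maxblock) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (b in seq_len(maxblock + 1L)) rec(c(prefix, b), max(maxblock, b))
  }
  rec(integer(0), 0L)
  out
}

# Brute-force confusion counts: enumerate every unordered pair and classify it
# against an n x n logical close-relation matrix.
brute_confusion <- function(memb, close) {
  ij <- which(upper.tri(close), arr.ind = TRUE)
  together <- memb[ij[, 1L]] == memb[ij[, 2L]]
  cl <- close[ij]
  c(tp = sum(cl & together), tn = sum(!cl & !together),
    fp = sum(!cl & together), fn = sum(cl & !together))
}

# The MCC equation evaluated directly, with the documented degenerate-case
# conventions replicated independently of the package.
mcc_oracle <- function(tp, tn, fp, fn) {
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  if (fp == 0 && fn == 0) return(1)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

# Random Erdos-Renyi close/far structure; the graph object is built through
# the column-file dialect so tests exercise the real parsing path.
random_instance <- function(n, p, seed) {
  set.seed(seed)
  nm <- sprintf("s%03d", seq_len(n))
  close <- matrix(FALSE, n, n)
  if (n >= 2L) {
    ij <- which(upper.tri(close), arr.ind = TRUE)
    is_close <- stats::runif(nrow(ij)) < p
    close[ij] <- is_close
    close[ij[, c(2L, 1L), drop = FALSE]] <- is_close
    d <- numeric(nrow(ij))
    d[is_close] <- stats::runif(sum(is_close), 0, 0.0299)
    d[!is_close] <- stats::runif(sum(!is_close), 0.0301, 0.5)
    lines <- sprintf("%s %s %.6f", nm[ij[, 1L]], nm[ij[, 2L]], d)
  } else {
    lines <- character(0)
  }
  graph <- read_dist_column(lines, cutoff = 0.03, roster = nm)
  list(names = nm, close = close, graph = graph)
}

# Random partition of the names of an instance, as both a membership vector
# (aligned with inst$names) and an otu_partition.
random_partition <- function(inst, seed) {
  set.seed(seed)
  n <- length(inst$names)
  k <- sample.int(n, 1L)
  memb <- sample.int(k, n, replace = TRUE)
  memb <- match(memb, sort(unique(memb)))   # drop empty blocks
  partition <- otu_partition(split(inst$names, memb))
  # realign block ids with the canonicalized OTU order
  list(memb = membership_vec(partition, inst$names), partition = partition)
}

# Membership vector of an otu_partition aligned with a name vector.
membership_vec <- function(partition, names) {
  memb <- integer(length(names))
  for (k in seq_along(partition$otus)) {
    memb[match(partition$otus[[k]], names)] <- k
  }
  memb
}

expect_cm_equal <- function(cm, expected) {
  expect_identical(
    c(tp = cm$tp, tn = cm$tn, fp = cm$fp, fn = cm$fn),
    c(tp = as.numeric(expected[["tp"]]), tn = as.numeric(expected[["tn"]]),
      fp = as.numeric(expected[["fp"]]), fn = as.numeric(expected[["fn"]]))
  )
}
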