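# The optimizer: metric-directed local search over partitions.
#
# One iteration interrogates every sequence in a fixed seeded order and, for
# each, scores keeping it where it is, moving it to any OTU that contains at
# least one of its close neighbors, or giving it a new OTU of its own. The
# best-scoring placement is committed immediately. The confusion matrix is
# maintained incrementally: relative to the interrogated sequence's
# fully-removed (singleton) state, placing it into an OTU of size m that holds
# c of its close neighbors adds c true positives and m - c false positives,
# with the false-negative and true-negative counts adjusting by complement.
#
# Restricting candidates to neighbor-containing OTUs is lossless for every
# registered maximize metric and for the minimize metrics: joining an OTU with
# no close neighbor changes the confusion matrix from the new-OTU option only
# by converting TNs into FPs, which can never score better.

# ---- engine state ------------------------------------------------------------

.engine_init <- function(graph, seed_mode) {
  n <- graph$n
  tc <- graph$total_close
  tpairs <- total_pairs(graph)
  if (seed_mode == "singletons") {
    memb <- seq_len(n)
    sizes <- rep(1L, n)
    free <- integer(0)
    cm <- c(tp = 0, tn = tpairs - tc, fp = 0, fn = tc)
  } else {
    memb <- rep(1L, n)
    sizes <- c(n, rep(0L, n - 1L))
    free <- rev(seq_len(n)[-1L])        # stack: pop from the end
    cm <- c(tp = tc, tn = 0, fp = tpairs - tc, fn = 0)
  }
  list(memb = memb, sizes = sizes, free = free, cm = cm)
}

.cm_obj <- function(v) {
  structure(list(tp = v[[1L]], tn = v[[2L]], fp = v[[3L]], fn = v[[4L]]),
            class = "confusion_matrix")
}

# Score all placements of sequence s given engine state st.
# Returns list(kind = "stay"|"new"|"move", otu, c_in, score, cm).
.engine_best_move <- function(st, s, graph, spec) {
  nb <- graph$adj[[s]]
  nb_memb <- st$memb[nb]
  o_cur <- st$memb[s]
  m_cur <- st$sizes[o_cur]
  c_cur <- sum(nb_memb == o_cur)
  fp_cur <- (m_cur - 1L) - c_cur

  # state with s removed into its own singleton OTU
  base <- c(st$cm[[1L]] - c_cur,           # tp
            st$cm[[2L]] + fp_cur,          # tn
            st$cm[[3L]] - fp_cur,          # fp
            st$cm[[4L]] + c_cur)           # fn

  cm_for <- function(m, c) {
    c(base[1L] + c, base[2L] - (m - c), base[3L] + (m - c), base[4L] - c)
  }
  score_for <- function(v) spec$fun(.cm_obj(v))

  stay_cm <- cm_for(m_cur - 1L, c_cur)
  best <- list(kind = "stay", otu = o_cur, c_in = c_cur,
               score = score_for(stay_cm), cm = stay_cm)

  new_cm <- base
  new_score <- score_for(new_cm)
  if (.better(new_score, best$score, spec$direction)) {
    best <- list(kind = "new", otu = NA_integer_, c_in = 0L,
                 score = new_score, cm = new_cm)
  }

  u <- unique(nb_memb)
  u <- u[u != o_cur]
  if (length(u)) {
    if (length(u) > 1L) {
      # deterministic enumeration: size desc, then lexicographically
      # smallest member (only consulted on exact metric ties)
      minmem <- vapply(u, function(o) min(graph$names[st$memb == o]), "")
      u <- u[order(-st$sizes[u], minmem)]
    }
    for (o in u) {
      c_in <- sum(nb_memb == o)
      v <- cm_for(st$sizes[o], c_in)
      sc <- score_for(v)
      if (.better(sc, best$score, spec$direction)) {
        best <- list(kind = "move", otu = o, c_in = c_in, score = sc, cm = v)
      }
    }
  }
  best
}

.engine_commit <- function(st, s, mv) {
  if (mv$kind == "stay") return(st)
  o_cur <- st$memb[s]
  st$sizes[o_cur] <- st$sizes[o_cur] - 1L
  if (st$sizes[o_cur] == 0L) st$free <- c(st$free, o_cur)
  if (mv$kind == "new") {
    o_new <- st$free[length(st$free)]
    st$free <- st$free[-length(st$free)]
    st$memb[s] <- o_new
    st$sizes[o_new] <- 1L
  } else {
    st$memb[s] <- mv$otu
    st$sizes[mv$otu] <- st$sizes[mv$otu] + 1L
  }
  st$cm <- mv$cm
  st
}

.engine_partition <- function(st, graph, label) {
  otu_partition(split(graph$names, st$memb), label = label)
}

# ---- user-facing fitting function --------------------------------------------

#' Cluster sequences into OTUs by optimizing a clustering-quality metric
#'
#' Assigns every sequence of a close-pair graph to an OTU by local search:
#' starting from a seed partition, each iteration interrogates every sequence
#' in a seeded random order and moves it to the placement — its current OTU,
#' any OTU containing at least one of its close neighbors, or a brand-new
#' OTU — that best improves the optimization metric, committing each move
#' immediately. Iteration stops when the per-iteration change in the metric
#' falls below `delta` (with `delta = 0`, when the metric is exactly
#' unchanged: "full convergence"), or after `max_iterations`.
#'
#' Ties are broken deterministically: the current OTU is preferred, then the
#' new-OTU option, then candidate OTUs in order of decreasing size with ties
#' by lexicographically smallest member. Together with the seeded shuffle this
#' makes runs exactly reproducible.
#'
#' @param graph A [close_pair_graph()].
#' @param metric Optimization metric name (see [opti_metrics()]); default
#'   `"mcc"`, the Matthews correlation coefficient over sequence pairs.
#' @param seed_mode `"singletons"` (default: every sequence starts in its own
#'   OTU) or `"one_otu"` (all sequences start together).
#' @param delta Non-negative convergence threshold on the per-iteration metric
#'   change; default `1e-4`. `0` requests full convergence.
#' @param max_iterations Iteration cap, default 100.
#' @param shuffle_seed Integer seed for the interrogation order (one shuffle
#'   per run, reused across iterations).
#' @param label Distance label for the returned partition.
#' @param check_moves If `TRUE`, recompute the confusion matrix from scratch
#'   after every committed move and stop on any disagreement with the
#'   incrementally maintained one (a self-check for debugging; quadratic cost).
#' @return An object of class `opti_cluster`: a list with `partition`
#'   ([otu_partition()]), `confusion` ([confusion_matrix()]), `final_metric`,
#'   `trace` (data frame: `iteration`, `metric`, `otus`, `seconds`; iteration
#'   0 is the seeding state), `converged`, `reason` (`"delta_reached"`,
#'   `"fully_converged"`, or `"max_iterations"`), `iterations`, and `config`.
#' @examples
#' g <- read_dist_column(c("A B 0.02", "B C 0.01", "A C 0.05"), cutoff = 0.03)
#' fit <- opti_cluster(g, shuffle_seed = 1)
#' fit$partition
#' mcc(fit$confusion)
#' @export
opti_cluster <- function(graph,
                         metric = "mcc",
                         seed_mode = c("singletons", "one_otu"),
                         delta = 1e-4,
                         max_iterations = 100L,
                         shuffle_seed = 1L,
                         label = format(graph$cutoff),
                         check_moves = FALSE) {
  stopifnot(inherits(graph, "close_pair_graph"))
  seed_mode <- match.arg(seed_mode)
  if (!is.numeric(delta) || delta < 0) stop("delta must be >= 0")
  max_iterations <- as.integer(max_iterations)
  if (is.na(max_iterations) || max_iterations < 1L) {
    stop("max_iterations must be a positive integer")
  }
  spec <- .metric_spec(metric)
  if (graph$n < 1L) stop("empty graph")

  st <- .engine_init(graph, seed_mode)
  order <- .with_seed(shuffle_seed, sample.int(graph$n))
  t0 <- proc.time()[["elapsed"]]

  prev <- spec$fun(.cm_obj(st$cm))
  trace_metric <- prev
  trace_otus <- sum(st$sizes > 0L)
  trace_sec <- 0
  converged <- FALSE
  reason <- "max_iterations"

  for (it in seq_len(max_iterations)) {
    for (s in order) {
      mv <- .engine_best_move(st, s, graph, spec)
      st <- .engine_commit(st, s, mv)
      if (check_moves) {
        ref <- .confusion_from_membership(st$memb, graph)
        if (st$cm[[1L]] != ref$tp || st$cm[[2L]] != ref$tn ||
            st$cm[[3L]] != ref$fp || st$cm[[4L]] != ref$fn) {
          stop("internal error: incremental confusion matrix diverged from ",
               "full recomputation at sequence '", graph$names[s], "'")
        }
      }
    }
    cur <- spec$fun(.cm_obj(st$cm))
    trace_metric <- c(trace_metric, cur)
    trace_otus <- c(trace_otus, sum(st$sizes > 0L))
    trace_sec <- c(trace_sec, proc.time()[["elapsed"]] - t0)
    if (delta > 0 && abs(cur - prev) < delta) {
      converged <- TRUE
      reason <- "delta_reached"
      break
    }
    if (delta == 0 && cur == prev) {
      converged <- TRUE
      reason <- "fully_converged"
      break
    }
    prev <- cur
  }

  partition <- .engine_partition(st, graph, label)
  confusion <- .cm_obj(st$cm)
  structure(
    list(
      partition = partition,
      confusion = confusion,
      final_metric = spec$fun(confusion),
      trace = data.frame(
        iteration = seq_along(trace_metric) - 1L,
        metric = trace_metric,
        otus = trace_otus,
        seconds = trace_sec
      ),
      converged = converged,
      reason = reason,
      iterations = length(trace_metric) - 1L,
      config = list(
        metric = spec$name, direction = spec$direction,
        seed_mode = seed_mode, delta = delta,
        max_iterations = max_iterations, shuffle_seed = shuffle_seed,
        cutoff = graph$cutoff, n = graph$n
      )
    ),
    class = "opti_cluster"
  )
}

#' Score every placement of one sequence
#'
#' The elementary step of the optimizer, exposed for inspection: given a
#' partition, enumerate the placements of `seq` (stay in its current OTU, move
#' to any OTU containing a close neighbor, or open a new OTU), score each
#' incrementally, and return the winner under the metric's direction with the
#' tie-break order current > new > largest/lexicographically-first candidate.
#'
#' @param seq A sequence name in the graph roster.
#' @param partition An [otu_partition()] over the graph roster.
#' @param graph A [close_pair_graph()].
#' @param metric Metric name (see [opti_metrics()]).
#' @return List with `target` (`"current"`, `"new"`, or the integer index of
#'   the destination OTU in `partition$otus`), `confusion` (the
#'   [confusion_matrix()] after the move), and `score`.
#' @export
best_move <- function(seq, partition, graph, metric = "mcc") {
  stopifnot(inherits(partition, "otu_partition"),
            inherits(graph, "close_pair_graph"))
  s <- match(seq, graph$names)
  if (is.na(s)) stop("sequence '", seq, "' not in graph roster")
  spec <- .metric_spec(metric)
  memb <- .membership_of(partition, graph)
  cm0 <- .confusion_from_membership(memb, graph)
  st <- list(
    memb = memb,
    sizes = tabulate(memb, nbins = max(memb)),
    free = integer(0),
    cm = c(cm0$tp, cm0$tn, cm0$fp, cm0$fn)
  )
  mv <- .engine_best_move(st, s, graph, spec)
  list(
    target = switch(mv$kind, stay = "current", new = "new", move = mv$otu),
    confusion = .cm_obj(mv$cm),
    score = mv$score
  )
}

#' Replicate clusterings under reshuffled sequence orders
#'
#' Runs [opti_cluster()] `n_reps` times with interrogation-order seeds derived
#' deterministically from `shuffle_seed` (seed, seed + 1, ...), the protocol
#' for assessing stability of the assignments to the order sequences are
#' presented in. Summarize with [stability_report()].
#'
#' @inheritParams opti_cluster
#' @param n_reps Number of replicate runs (>= 1).
#' @param ... Further arguments passed to [opti_cluster()].
#' @return List of `opti_cluster` objects, one per replicate, with class
#'   `opti_cluster_reps`.
#' @export
opti_cluster_reps <- function(graph, n_reps = 10L, shuffle_seed = 1L, ...) {
  n_reps <- as.integer(n_reps)
  if (is.na(n_reps) || n_reps < 1L) stop("n_reps must be >= 1")
  out <- lapply(seq_len(n_reps) - 1L, function(k) {
    opti_cluster(graph, shuffle_seed = shuffle_seed + k, ...)
  })
  class(out) <- "opti_cluster_reps"
  out
}

#' @export
print.opti_cluster_reps <- function(x, ...) {
  cat(sprintf("%d replicate clusterings\n", length(x)))
  if (length(x) >= 2L) print(stability_report(x))
  invisible(x)
}

# ---- methods ------------------------------------------------------------------

#' @export
print.opti_cluster <- function(x, ...) {
  cat(sprintf(
    "OTU clustering (%s %s): %d sequences -> %d OTUs, %s = %.4f\n",
    x$config$direction, x$config$metric, x$config$n, n_otus(x$partition),
    x$config$metric, x$final_metric
  ))
  cat(sprintf("%d iteration(s); %s%s\n", x$iterations,
              if (x$converged) "converged: " else "stopped: ", x$reason))
  invisible(x)
}

#' @export
summary.opti_cluster <- function(object, ...) {
  structure(list(fit = object), class = "summary.opti_cluster")
}

#' @export
print.summary.opti_cluster <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nSeeding:", f$config$seed_mode,
      " delta:", format(f$config$delta),
      " max iterations:", f$config$max_iterations,
      " shuffle seed:", f$config$shuffle_seed, "\n")
  print(f$confusion)
  sizes <- lengths(f$partition$otus)
  cat(sprintf("OTU sizes: largest %d, median %g, singletons %d\n",
              max(sizes), stats::median(sizes), sum(sizes == 1L)))
  cat("\nMetric trace:\n")
  print(f$trace[, c("iteration", "metric", "otus")], row.names = FALSE)
  invisible(x)
}

#' Plot the per-iteration metric trace of a clustering
#'
#' @param x An `opti_cluster` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.opti_cluster <- function(x, ...) {
  graphics::plot(x$trace$iteration, x$trace$metric, type = "b", pch = 16,
                 xlab = "Iteration", ylab = x$config$metric, ...)
  invisible(x)
}
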