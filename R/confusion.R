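# Pairwise confusion matrix over sequence pairs and the metric registry.
#
# Over all n(n-1)/2 unordered pairs:
#   TP  close pair co-clustered      FN  close pair split
#   FP  far pair co-clustered        TN  far pair split
# Counts are kept as doubles so products stay exact well past 2^31 pairs.

#' Construct a pairwise confusion matrix
#'
#' @param tp,tn,fp,fn Non-negative counts of true positives (close pairs
#'   co-clustered), true negatives (far pairs split), false positives (far
#'   pairs co-clustered), and false negatives (close pairs split).
#' @return An object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, tn, fp, fn) {
  v <- c(tp = as.numeric(tp), tn = as.numeric(tn),
         fp = as.numeric(fp), fn = as.numeric(fn))
  if (anyNA(v) || any(v < 0)) stop("confusion counts must be non-negative numbers")
  structure(as.list(v), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("Pairwise confusion: TP=%g TN=%g FP=%g FN=%g (MCC %.4f)\n",
              x$tp, x$tn, x$fp, x$fn, mcc(x)))
  invisible(x)
}

#' Matthews correlation coefficient of a pairwise confusion matrix
#'
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#'
#' Conventions for degenerate matrices: a clustering with `FP = FN = 0` makes
#' no pair-level errors and scores 1 even when the denominator vanishes (this
#' covers, e.g., an all-singleton partition of a graph with no close pairs);
#' otherwise any zero marginal factor yields 0.
#'
#' @param cm A [confusion_matrix()].
#' @return A score in `[-1, 1]`.
#' @export
mcc <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$tp; tn <- cm$tn; fp <- cm$fp; fn <- cm$fn
  if (fp == 0 && fn == 0) return(1)
  m1 <- tp + fp; m2 <- tp + fn; m3 <- tn + fp; m4 <- tn + fn
  if (m1 == 0 || m2 == 0 || m3 == 0 || m4 == 0) return(0)
  # product of sqrts avoids overflow of the 4-way product for huge pair counts
  (tp * tn - fp * fn) / (sqrt(m1) * sqrt(m2) * sqrt(m3) * sqrt(m4))
}

# registry: every optimization/assessment metric derivable from the four counts.
# Ratio metrics with an empty denominator return the optimum under their
# direction so degenerate seedings are not artificially penalized.
.metric_registry <- list(
  mcc         = list(direction = "maximize", fun = function(cm) mcc(cm)),
  sensitivity = list(direction = "maximize",
                     fun = function(cm) .ratio(cm$tp, cm$tp + cm$fn, 1)),
  specificity = list(direction = "maximize",
                     fun = function(cm) .ratio(cm$tn, cm$tn + cm$fp, 1)),
  ppv         = list(direction = "maximize",
                     fun = function(cm) .ratio(cm$tp, cm$tp + cm$fp, 1)),
  npv         = list(direction = "maximize",
                     fun = function(cm) .ratio(cm$tn, cm$tn + cm$fn, 1)),
  fdr         = list(direction = "minimize",
                     fun = function(cm) .ratio(cm$fp, cm$tp + cm$fp, 0)),
  accuracy    = list(direction = "maximize",
                     fun = function(cm) .ratio(cm$tp + cm$tn,
                                               cm$tp + cm$tn + cm$fp + cm$fn, 1)),
  f1          = list(direction = "maximize",
                     fun = function(cm) .ratio(2 * cm$tp,
                                               2 * cm$tp + cm$fp + cm$fn, 1)),
  tptn        = list(direction = "maximize", fun = function(cm) cm$tp + cm$tn),
  fpfn        = list(direction = "minimize", fun = function(cm) cm$fp + cm$fn),
  tp          = list(direction = "maximize", fun = function(cm) cm$tp),
  tn          = list(direction = "maximize", fun = function(cm) cm$tn),
  fp          = list(direction = "minimize", fun = function(cm) cm$fp),
  fn          = list(direction = "minimize", fun = function(cm) cm$fn)
)

.ratio <- function(num, den, empty) if (den == 0) empty else num / den

#' Available optimization metrics
#'
#' @return Data frame with columns `metric` and `direction` listing every
#'   registered optimization target.
#' @export
opti_metrics <- function() {
  data.frame(
    metric = names(.metric_registry),
    direction = vapply(.metric_registry, `[[`, "", "direction"),
    row.names = NULL
  )
}

.metric_spec <- function(name) {
  spec <- .metric_registry[[name]]
  if (is.null(spec)) {
    stop("unknown metric '", name, "'; see opti_metrics() for choices")
  }
  c(spec, list(name = name))
}

#' Evaluate a registered metric on a confusion matrix
#'
#' @param metric Metric name; one of the rows of [opti_metrics()].
#' @param cm A [confusion_matrix()].
#' @return The metric value. Ratio metrics with an empty denominator return
#'   the optimum under the metric's direction.
#' @export
metric_value <- function(metric, cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  .metric_spec(metric)$fun(cm)
}

# TRUE if score a is strictly better than b under the metric's direction
.better <- function(a, b, direction) {
  if (direction == "maximize") a > b else a < b
}

# ---- partition evaluation ----------------------------------------------------

#' Compute the pairwise confusion matrix of a partition against a graph
#'
#' Counts, over every unordered pair of roster sequences, how the partition's
#' co-clustering decisions agree with the close/far relation of the graph.
#' This is the post-hoc benchmarking operation: it scores any OTU assignment,
#' not only ones produced by [opti_cluster()].
#'
#' @param partition An [otu_partition()] over exactly the graph's roster.
#' @param graph A [close_pair_graph()].
#' @return A [confusion_matrix()].
#' @export
evaluate_partition <- function(partition, graph) {
  stopifnot(inherits(partition, "otu_partition"),
            inherits(graph, "close_pair_graph"))
  memb <- .membership_of(partition, graph)
  .confusion_from_membership(memb, graph)
}

# membership: integer OTU id per graph$names position
.membership_of <- function(partition, graph) {
  memb <- integer(graph$n)
  for (k in seq_along(partition$otus)) {
    idx <- match(partition$otus[[k]], graph$names)
    if (anyNA(idx)) {
      .data_error(paste0("partition names missing from graph roster: ",
                         paste(partition$otus[[k]][is.na(idx)], collapse = ", ")))
    }
    memb[idx] <- k
  }
  if (any(memb == 0L)) {
    .data_error(paste0("graph names missing from partition: ",
                       paste(graph$names[memb == 0L], collapse = ", ")))
  }
  memb
}

.confusion_from_membership <- function(memb, graph) {
  e <- graph$edges
  tp <- if (nrow(e)) sum(memb[e[, 1L]] == memb[e[, 2L]]) else 0
  sizes <- tabulate(memb)
  within <- sum(sizes * (sizes - 1) / 2)
  tpairs <- total_pairs(graph)
  fp <- within - tp
  fn <- graph$total_close - tp
  tn <- tpairs - within - fn
  confusion_matrix(tp = tp, tn = tn, fp = fp, fn = fn)
}

#' Full metric panel for a partition
#'
#' One evaluation-report row in the style of a sens.spec record: the four
#' confusion counts plus every ratio metric.
#'
#' @inheritParams evaluate_partition
#' @return One-row data frame with columns `label`, `cutoff`, `tp`, `tn`,
#'   `fp`, `fn`, `sensitivity`, `specificity`, `ppv`, `npv`, `fdr`,
#'   `accuracy`, `mcc`, `f1`.
#' @export
evaluation_report <- function(partition, graph) {
  .metric_panel(partition$label, graph$cutoff,
                evaluate_partition(partition, graph))
}

.metric_panel <- function(label, cutoff, cm) {
  data.frame(
    label = label,
    cutoff = cutoff,
    tp = cm$tp, tn = cm$tn, fp = cm$fp, fn = cm$fn,
    sensitivity = metric_value("sensitivity", cm),
    specificity = metric_value("specificity", cm),
    ppv = metric_value("ppv", cm),
    npv = metric_value("npv", cm),
    fdr = metric_value("fdr", cm),
    accuracy = metric_value("accuracy", cm),
    mcc = mcc(cm),
    f1 = metric_value("f1", cm)
  )
}

#' Stability summary across replicate clusterings
#'
#' Summarizes replicate runs (e.g. from [opti_cluster_reps()]) by the mean,
#' sample standard deviation, and percent coefficient of variation
#' (100 * sd / mean) of the final optimized metric and of the OTU count.
#'
#' @param results List of at least two [opti_cluster()] results on the same
#'   graph.
#' @return Data frame with one row per quantity (`metric`, `otu_count`) and
#'   columns `quantity`, `mean`, `sd`, `cv_percent`.
#' @export
stability_report <- function(results) {
  if (!is.list(results) || length(results) < 2L) {
    stop("stability_report needs at least 2 replicate results")
  }
  vals <- vapply(results, function(r) r$final_metric, 0)
  otus <- vapply(results, function(r) as.numeric(n_otus(r$partition)), 0)
  row <- function(q, x) {
    m <- mean(x); s <- stats::sd(x)
    data.frame(quantity = q, mean = m, sd = s,
               cv_percent = if (m == 0) NA_real_ else 100 * s / m)
  }
  rbind(row("metric", vals), row("otu_count", otus))
}
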