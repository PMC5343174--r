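test_that("mcc evaluates the correlation formula and its conventions", {
  expect_equal(mcc(confusion_matrix(10, 10, 0, 0)), 1)
  expect_equal(mcc(confusion_matrix(5, 5, 5, 5)), 0)
  expect_equal(mcc(confusion_matrix(20, 70, 5, 5)), 1375 / 1875,
               tolerance = 1e-14)
  # perfect classification wins over the zero-denominator rule
  expect_equal(mcc(confusion_matrix(0, 3, 0, 0)), 1)
  # any other zero marginal scores 0
  expect_equal(mcc(confusion_matrix(0, 3, 0, 2)), 0)
  expect_equal(mcc(confusion_matrix(1, 0, 0, 2)), 0)
})

test_that("mcc is antisymmetric under swapping tp<->fp, tn<->fn", {
  set.seed(11)
  for (k in 1:50) {
    v <- sample(1:500, 4L, replace = TRUE)
    a <- mcc(confusion_matrix(v[1], v[2], v[3], v[4]))
    b <- mcc(confusion_matrix(v[3], v[4], v[1], v[2]))
    expect_equal(a, -b, tolerance = 1e-12)
  }
})

test_that("the metric registry evaluates each metric with its conventions", {
  cm <- confusion_matrix(20, 70, 5, 5)
  expect_equal(metric_value("f1", cm), 0.8)
  expect_equal(metric_value("sensitivity", cm), 20 / 25)
  expect_equal(metric_value("specificity", cm), 70 / 75)
  expect_equal(metric_value("ppv", cm), 0.8)
  expect_equal(metric_value("npv", cm), 70 / 75)
  expect_equal(metric_value("fdr", cm), 0.2)
  expect_equal(metric_value("accuracy", cm), 0.9)
  expect_equal(metric_value("tptn", cm), 90)
  expect_equal(metric_value("fpfn", cm), 10)
  expect_equal(metric_value("tp", cm), 20)

  # empty denominators return the optimum under the metric's direction
  empty <- confusion_matrix(0, 3, 0, 0)
  expect_equal(metric_value("fdr", empty), 0)
  expect_equal(metric_value("sensitivity", empty), 1)
  expect_equal(metric_value("ppv", empty), 1)

  expect_equal(metric_value("tptn", confusion_matrix(2, 3, 1, 0)), 5)
  expect_error(metric_value("rand_index", cm), "unknown metric")

  reg <- opti_metrics()
  expect_setequal(
    reg$metric[reg$direction == "minimize"], c("fdr", "fpfn", "fp", "fn"))
  expect_equal(nrow(reg), 14L)
})

test_that("maximize-direction ratio metrics stay within [0, 1]", {
  set.seed(4)
  ratio_max <- c("sensitivity", "specificity", "ppv", "npv", "accuracy", "f1")
  for (k in 1:30) {
    v <- sample(0:40, 4L, replace = TRUE)
    cm <- confusion_matrix(v[1], v[2], v[3], v[4])
    for (m in ratio_max) {
      val <- metric_value(m, cm)
      expect_gte(val, 0)
      expect_lte(val, 1)
    }
    expect_gte(mcc(cm), -1)
    expect_lte(mcc(cm), 1)
  }
})

test_that("evaluate_partition counts the worked four-sequence example", {
  g <- read_dist_column(
    c("A B 0.02", "B C 0.01", "A C 0.05", "A D 0.5", "B D 0.5", "C D 0.5"))
  cm <- evaluate_partition(otu_partition(list(c("A", "B", "C"), "D")), g)
  expect_cm_equal(cm, c(tp = 2, tn = 3, fp = 1, fn = 0))

  # all-singleton partition co-clusters nothing
  singles <- otu_partition(as.list(g$names))
  expect_cm_equal(evaluate_partition(singles, g),
                  c(tp = 0, tn = total_pairs(g) - g$total_close,
                    fp = 0, fn = g$total_close))

  # a single OTU holding everything saturates the within-pair count
  g_all <- read_dist_column(c("A B 0.01", "A C 0.01", "B C 0.02"))
  one <- otu_partition(list(g_all$names))
  expect_cm_equal(evaluate_partition(one, g_all),
                  c(tp = 3, tn = 0, fp = 0, fn = 0))
})

test_that("evaluate_partition errors on roster mismatches", {
  g <- read_dist_column("A B 0.01")
  expect_error(evaluate_partition(otu_partition(list(c("A", "B"), "Z")), g),
               "missing from graph roster")
  expect_error(evaluate_partition(otu_partition(list("A")), g),
               "missing from partition")
})

test_that("evaluate_partition agrees with the brute-force pair loop", {
  for (seed in 1:25) {
    inst <- random_instance(n = sample(2:50, 1L), p = stats::runif(1, 0.1, 0.6),
                            seed = seed)
    rp <- random_partition(inst, seed + 1000L)
    cm <- evaluate_partition(rp$partition, inst$graph)
    expect_cm_equal(cm, brute_confusion(rp$memb, inst$close))
    n <- length(inst$names)
    expect_equal(cm$tp + cm$tn + cm$fp + cm$fn, n * (n - 1) / 2)
    expect_equal(cm$tp + cm$fn, inst$graph$total_close)
  }
})

test_that("evaluation_report mirrors a sens.spec-style record", {
  g <- read_dist_column(
    c("A B 0.02", "B C 0.01", "A C 0.05", "A D 0.5", "B D 0.5", "C D 0.5"))
  rep <- evaluation_report(otu_partition(list(c("A", "B", "C"), "D")), g)
  expect_identical(
    names(rep),
    c("label", "cutoff", "tp", "tn", "fp", "fn", "sensitivity", "specificity",
      "ppv", "npv", "fdr", "accuracy", "mcc", "f1"))
  expect_equal(rep$sensitivity, 1)
  expect_equal(rep$specificity, 0.75)
  expect_equal(rep$mcc, mcc_oracle(2, 3, 1, 0))
})

test_that("stability_report computes percent CV with the sample sd", {
  stub <- function(m, k) {
    list(final_metric = m,
         partition = otu_partition(as.list(sprintf("s%d", seq_len(k)))))
  }
  same <- stability_report(list(stub(0.9, 3), stub(0.9, 3), stub(0.9, 3)))
  expect_equal(same$cv_percent[same$quantity == "metric"], 0)

  two <- stability_report(list(stub(0.8, 4), stub(1.0, 4)))
  expect_equal(two$mean[two$quantity == "metric"], 0.9)
  expect_equal(two$sd[two$quantity == "metric"], stats::sd(c(0.8, 1.0)))
  expect_equal(two$cv_percent[two$quantity == "metric"],
               100 * stats::sd(c(0.8, 1.0)) / 0.9, tolerance = 1e-12)
  expect_equal(two$cv_percent[two$quantity == "metric"], 15.713, tolerance = 1e-4)

  expect_error(stability_report(list(stub(1, 2))), "at least 2")
})
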