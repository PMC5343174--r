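test_that("seed_partition builds the two documented starting states", {
  g <- read_dist_column(c("A B 0.02", "B C 0.01"))
  expect_identical(seed_partition(g, "singletons")$otus,
                   list("A", "B", "C"))
  expect_identical(seed_partition(g, "one_otu")$otus,
                   list(c("A", "B", "C")))
  g1 <- read_dist_column(character(0), roster = "A")
  expect_identical(seed_partition(g1, "singletons")$otus, list("A"))
  expect_identical(seed_partition(g1, "one_otu")$otus, list("A"))
})

test_that("best_move scores all placements and picks the metric winner", {
  # joining the close neighbor turns the lone FN into a TP: MCC 0 -> 1
  g <- read_dist_column("A B 0.01", roster = "C")
  singles <- otu_partition(list("A", "B", "C"))
  bm <- best_move("B", singles, g)
  expect_equal(bm$target, which(vapply(singles$otus, identical, TRUE, "A")))
  expect_equal(bm$score, 1)
  expect_cm_equal(bm$confusion, c(tp = 1, tn = 2, fp = 0, fn = 0))

  # an isolated sequence has nowhere better to go: stays (tie prefers current)
  bm_c <- best_move("C", singles, g)
  expect_identical(bm_c$target, "current")

  # staying can beat leaving: removing A loses tp(A,B) and fp(A,C)
  g4 <- read_dist_column(
    c("A B 0.02", "B C 0.01", "A C 0.05", "A D 0.5", "B D 0.5", "C D 0.5"))
  p <- otu_partition(list(c("A", "B", "C"), "D"))
  bm_a <- best_move("A", p, g4)
  expect_identical(bm_a$target, "current")
  expect_equal(bm_a$score, mcc_oracle(2, 3, 1, 0), tolerance = 1e-12)
  # and the rejected alternatives score what the brute force says
  expect_equal(mcc_oracle(1, 4, 0, 1), 0.6324555, tolerance = 1e-6)
  expect_lt(mcc_oracle(1, 4, 0, 1), bm_a$score)
})

test_that("best_move candidates score identically to from-scratch evaluation", {
  for (seed in 1:10) {
    inst <- random_instance(n = sample(4:25, 1L), p = 0.35, seed = seed + 70L)
    rp <- random_partition(inst, seed + 170L)
    for (s in sample(inst$names, 3L)) {
      bm <- best_move(s, rp$partition, inst$graph)
      # apply the chosen move by hand and re-evaluate from scratch
      memb <- rp$memb
      si <- match(s, inst$names)
      memb[si] <- if (identical(bm$target, "current")) memb[si]
                  else if (identical(bm$target, "new")) max(memb) + 1L
                  else bm$target
      expect_cm_equal(bm$confusion, brute_confusion(memb, inst$close))
    }
  }
})

test_that("clustering a toy instance attains the exhaustive-partition optimum", {
  g4 <- read_dist_column(
    c("A B 0.02", "B C 0.01", "A C 0.05", "A D 0.5", "B D 0.5", "C D 0.5"))
  # oracle: score all 15 set partitions of 4 elements
  parts <- rgs_partitions(4L)
  expect_length(parts, 15L)
  close <- matrix(FALSE, 4, 4)
  close[1, 2] <- close[2, 1] <- TRUE  # A-B
  close[2, 3] <- close[3, 2] <- TRUE  # B-C
  best <- max(vapply(parts, function(m) {
    v <- brute_confusion(m, close)
    mcc_oracle(v["tp"], v["tn"], v["fp"], v["fn"])
  }, 0))
  expect_equal(best, 6 / sqrt(72), tolerance = 1e-12)

  for (seed in 1:5) {
    fit <- opti_cluster(g4, delta = 0, shuffle_seed = seed)
    expect_equal(fit$final_metric, best, tolerance = 1e-12)
    expect_identical(fit$partition$otus, list(c("A", "B", "C"), "D"))
  }
})

test_that("graphs with no close pairs converge immediately to singletons", {
  g <- read_dist_column(character(0), roster = c("A", "B", "C"))
  fit <- opti_cluster(g)
  expect_equal(n_otus(fit$partition), 3L)
  expect_equal(fit$final_metric, 1)     # FP = FN = 0
  expect_true(fit$converged)
  expect_equal(fit$iterations, 1L)
})

test_that("planted two-clique instances are recovered perfectly", {
  sim <- simulate_planted(c(3, 3), seed = 42)
  g <- planted_graph(sim)
  fit <- opti_cluster(g, delta = 0)
  expect_equal(fit$final_metric, 1)
  expect_identical(fit$partition$otus, sim$truth$otus)
  expect_cm_equal(fit$confusion, c(tp = 6, tn = 9, fp = 0, fn = 0))
})

test_that("the maintained confusion matrix matches the final partition", {
  for (seed in 1:6) {
    inst <- random_instance(n = sample(5:40, 1L), p = 0.3, seed = seed + 300L)
    fit <- opti_cluster(inst$graph, delta = 0, shuffle_seed = seed)
    expect_cm_equal(fit$confusion,
                    brute_confusion(membership_vec(fit$partition, inst$names),
                                    inst$close))
  }
})

test_that("every roster sequence lands in exactly one OTU", {
  inst <- random_instance(30, 0.25, seed = 77)
  fit <- opti_cluster(inst$graph, delta = 0)
  expect_identical(partition_roster(fit$partition), sort(inst$names))
  expect_false(any(lengths(fit$partition$otus) == 0L))
})

test_that("metric traces are monotone in the metric's direction", {
  for (seed in 1:6) {
    inst <- random_instance(n = 25, p = 0.3, seed = seed + 500L)
    up <- opti_cluster(inst$graph, metric = "mcc", delta = 0,
                       shuffle_seed = seed)
    expect_true(all(diff(up$trace$metric) >= 0))
    down <- opti_cluster(inst$graph, metric = "fpfn", delta = 0,
                         shuffle_seed = seed)
    expect_true(all(diff(down$trace$metric) <= 0))
  }
})

test_that("delta controls partial vs full convergence and the cap binds", {
  inst <- random_instance(n = 60, p = 0.15, seed = 901)
  partial <- opti_cluster(inst$graph, delta = 1e-4, shuffle_seed = 2)
  expect_true(partial$converged)
  expect_identical(partial$reason, "delta_reached")
  steps <- abs(diff(partial$trace$metric))
  if (length(steps) > 1L) expect_true(all(steps[-length(steps)] >= 1e-4))
  expect_lt(steps[length(steps)], 1e-4)

  full <- opti_cluster(inst$graph, delta = 0, shuffle_seed = 2)
  expect_identical(full$reason, "fully_converged")
  k <- nrow(full$trace)
  expect_identical(full$trace$metric[k], full$trace$metric[k - 1L])
  # full convergence never stops at a worse metric than partial
  expect_gte(full$final_metric, partial$final_metric)

  capped <- opti_cluster(inst$graph, delta = 0, max_iterations = 1L,
                         shuffle_seed = 2)
  expect_identical(capped$reason, "max_iterations")
  expect_false(capped$converged)
  expect_equal(capped$iterations, 1L)
})

test_that("identical configuration reproduces identical results", {
  inst <- random_instance(n = 40, p = 0.2, seed = 64)
  a <- opti_cluster(inst$graph, delta = 0, shuffle_seed = 9)
  b <- opti_cluster(inst$graph, delta = 0, shuffle_seed = 9)
  expect_identical(a$partition$otus, b$partition$otus)
  expect_identical(a$trace$metric, b$trace$metric)
  c <- opti_cluster(inst$graph, delta = 0, shuffle_seed = 10)
  expect_identical(c$config$shuffle_seed, 10)
})

test_that("replicate runs derive consecutive seeds and feed stability_report", {
  sim <- simulate_planted(c(4, 3, 5), seed = 12)
  g <- planted_graph(sim)
  reps <- opti_cluster_reps(g, n_reps = 10L, shuffle_seed = 5L, delta = 0)
  expect_length(reps, 10L)
  expect_equal(reps[[1L]]$config$shuffle_seed, 5)
  expect_equal(reps[[10L]]$config$shuffle_seed, 14)
  one <- opti_cluster(g, shuffle_seed = 5L, delta = 0)
  expect_identical(reps[[1L]]$partition$otus, one$partition$otus)

  st <- stability_report(reps)
  expect_equal(st$cv_percent[st$quantity == "metric"], 0)
  expect_equal(st$cv_percent[st$quantity == "otu_count"], 0)
  expect_true(all(vapply(reps, `[[`, 0, "final_metric") == 1))
})

test_that("fitted objects print, summarize and plot", {
  sim <- simulate_planted(c(3, 2), seed = 3)
  fit <- opti_cluster(planted_graph(sim))
  expect_output(print(fit), "OTU clustering .*maximize mcc")
  expect_output(print(summary(fit)), "Metric trace")
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
})
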