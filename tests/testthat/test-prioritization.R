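test_that("assignment solver matches brute force on random small instances", {
  set.seed(5)
  for (rep in 1:60) {
    n <- sample(1:6, 1)
    cost <- matrix(runif(n * n, 0, 10), n, n)
    sol <- solve_assignment(cost)
    perms <- function(v) {
      if (length(v) <= 1) return(list(v))
      out <- list()
      for (i in seq_along(v)) for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
      out
    }
    best <- min(vapply(perms(seq_len(n)),
                       function(p) sum(cost[cbind(seq_len(n), p)]), numeric(1)))
    expect_equal(sol$cost, best, tolerance = 1e-9)
    expect_setequal(sol$assignment, seq_len(n))
  }
})

test_that("detection KPI follows the clamped inverse-MAE definition", {
  gt3 <- rbind(c(1, 2), c(5, 5), c(9, 1))
  expect_equal(kpi_detection(gt3, gt3), 1)
  expect_equal(kpi_detection(rbind(c(3, 4)), rbind(c(0, 0))), 0.2) # MAE 5
  expect_equal(matching_error(rbind(c(3, 4)), rbind(c(0, 0))), 5)
  # crossed 4 vs 4: optimal matching, not greedy
  pred <- rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10))
  gt <- rbind(c(10, 10.5), c(0.5, 10), c(10, 0.2), c(0.1, 0))
  expect_equal(matching_error(pred, gt), brute_force_mae(pred, gt, Inf),
               tolerance = 1e-9)
  # unmatched predictions/gts are charged the penalty
  expect_equal(matching_error(matrix(numeric(0), 0, 2), rbind(c(1, 1)),
                              penalty = 12), 12)
  expect_equal(matching_error(rbind(c(0, 0), c(50, 50)), rbind(c(0, 0)),
                              penalty = 12), 6) # (0 + 12)/2
  expect_error(kpi_detection(gt3, matrix(numeric(0), 0, 2)), "empty")
})

test_that("segmentation KPI handles identity, disjoint and empty masks", {
  m <- matrix(0, 10, 10); m[1:5, ] <- 1
  expect_equal(kpi_segmentation(m, m), 1)
  expect_equal(kpi_segmentation(1 - m, m), 1 / 101, tolerance = 1e-9)
  z <- matrix(0, 10, 10)
  expect_equal(kpi_segmentation(z, z), 1)
  expect_equal(kpi_segmentation(m, m, metric = "dice"), 1)
})

test_that("EMA update honours its limits and stays clamped", {
  expect_equal(ema_update(0.4, 0.8, 1), 0.8)
  expect_equal(ema_update(0.4, 0.8, 0), 0.4)
  expect_equal(ema_update(0.4, 0.8, 0.5), 0.6)
  expect_error(ema_update(0.4, 0.8, 1.5), "alpha")
  set.seed(9)
  k <- runif(1)
  for (i in 1:2000) {
    k <- ema_update(k, runif(1), runif(1))
    expect_true(k > 0 && k <= 1)
  }
})

test_that("top-k schedule interpolates linearly from 70% to 30%", {
  st <- priority_state(k_schedule = list(start = 0.7, end = 0.3, total = 100L))
  expect_equal(current_k_fraction(st), 0.70)
  st$tau <- 50L
  expect_equal(current_k_fraction(st), 0.50)
  st$tau <- 100L
  expect_equal(current_k_fraction(st), 0.30)
  st$tau <- 500L # constant after the schedule ends
  expect_equal(current_k_fraction(st), 0.30)
})

test_that("sample deltas implement all four assignment modes", {
  d <- c(0.9, 0.5, 0.1)
  expect_equal(sample_deltas(d, 2 / 3, "topk_hard"), c(1, 1, 0))
  expect_equal(sample_deltas(d, 1, "topk_hard"), c(1, 1, 1))
  expect_equal(sample_deltas(d, 2 / 3, "topk_soft"), c(1, 0.5 / 0.9, 0))
  expect_equal(sample_deltas(d, 1, "soft"), d / 0.9)
  expect_equal(sample_deltas(d, 1, "hard", eta = 0.5), c(1, 1, 0)) # 0.555 > 0.5
  # ties at the K-th rank break toward the lower index
  expect_equal(sample_deltas(c(1, 1, 1, 1), 0.5, "topk_hard"), c(1, 1, 0, 0))
  expect_error(sample_deltas(numeric(0), 0.5, "topk_hard"), "empty")
  # count contract on a randomized sweep
  set.seed(3)
  for (rep in 1:100) {
    n <- sample(1:200, 1)
    k <- runif(1, 0.01, 1)
    delta <- sample_deltas(runif(n, 0.01, 5), k, "topk_hard")
    expect_equal(sum(delta), ceiling(k * n))
  }
})

test_that("total loss is the inverse-KPI weighted sum", {
  expect_equal(total_loss(1, 2, 1, 1), 3.0)
  expect_equal(total_loss(1, 2, 0.5, 1), 4.0)
  expect_error(total_loss(1, 2, 0, 1), "nonpositive")
  # weight is nonincreasing in kappa_bar
  ks <- seq(0.1, 1, by = 0.1)
  vals <- vapply(ks, function(k) total_loss(1, 0, k, 1), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("state updates track KPIs, difficulties and the iteration counter", {
  st <- priority_state(alpha = 1)
  st <- update_state(st, list(s = c(a = 0.25, b = 0.25)))
  expect_equal(unname(st$kappa_bar[["s"]]), 0.25)
  expect_equal(sample_difficulties(st, "s", "a"), 4)
  expect_equal(sample_difficulties(st, "s", "unseen"), 2) # kappa 0.5 default
  expect_equal(st$tau, 1L)
  # two tasks: weight ratio 1/0.2 vs 1/0.8 = 4
  st2 <- update_state(priority_state(alpha = 1),
                      list(d = c(a = 0.2), s = c(a = 0.8)))
  expect_equal((1 / st2$kappa_bar[["d"]]) / (1 / st2$kappa_bar[["s"]]), 4)
  expect_error(update_state(st, list(d = c(a = 1.2))), "KPI")
  # EMA convergence to a repeated KPI is monotone
  st3 <- priority_state(alpha = 0.3)
  prev <- st3$kappa_bar[["s"]]
  gaps <- numeric(10)
  for (i in 1:10) {
    st3 <- update_state(st3, list(s = c(x = 0.4)))
    gaps[i] <- abs(st3$kappa_bar[["s"]] - 0.4)
  }
  expect_true(all(diff(gaps) < 1e-12))
})

test_that("momentum smooths per-sample difficulty trajectories", {
  set.seed(21)
  kpis <- pmin(pmax(0.5 + rnorm(200, 0, 0.2), 0.01), 1)
  run <- function(alpha) {
    st <- priority_state(alpha = alpha)
    traj <- numeric(length(kpis))
    for (i in seq_along(kpis)) {
      st <- update_state(st, list(s = c(s1 = kpis[i])))
      traj[i] <- sample_difficulties(st, "s", "s1")
    }
    sum(abs(diff(traj)))
  }
  expect_lt(run(0.1), run(1))
})
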