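test_that("interval discrepancy follows its definition and sign convention", {
  perf <- cbind("0" = rep(0.30, 5), "1" = rep(0.90, 5))
  out <- compute_interval_sudo(perf)
  expect_equal(out$sudo, 0.60)
  expect_equal(out$majority_class_call, 1L)

  tie <- cbind("0" = rep(0.7, 3), "1" = rep(0.7, 3))
  out <- compute_interval_sudo(tie)
  expect_equal(out$sudo, 0)
  expect_true(is.na(out$majority_class_call))

  # small |sudo| below tau withholds the call
  near <- cbind("0" = rep(0.52, 4), "1" = rep(0.50, 4))
  expect_true(is.na(compute_interval_sudo(near, tau = 0.05)$majority_class_call))
  expect_equal(compute_interval_sudo(near, tau = 0)$majority_class_call, 0L)

  expect_error(compute_interval_sudo(list("0" = c(.5, .6), "1" = c(.5))),
               "mismatched replicate counts")
})

test_that("exchanging the pseudo-label roles negates the discrepancy exactly", {
  withr::with_seed(13, {
    for (rep in 1:25) {
      k <- sample(1:6, 1)
      perf <- cbind("0" = runif(k), "1" = runif(k))
      swapped <- perf[, c(2, 1), drop = FALSE]
      colnames(swapped) <- c("0", "1")
      expect_equal(compute_interval_sudo(swapped)$sudo,
                   -compute_interval_sudo(perf)$sudo)
    }
  })
})

test_that("a full run is reproducible byte-for-byte and bounded", {
  w <- small_world()
  grid <- interval_grid(5)
  cfg <- sudo_config(m = 40, k = 2, base_seed = 3)
  r1 <- suppressWarnings(run_sudo(w$wild, w$train, w$heldout, grid, cfg))
  r2 <- suppressWarnings(run_sudo(w$wild, w$train, w$heldout, grid, cfg))
  expect_identical(serialize(r1, NULL), serialize(r2, NULL))
  ok <- !is.na(r1$intervals$sudo)
  expect_true(any(ok))
  expect_true(all(abs(r1$intervals$sudo[ok]) <= 1))
  perfs <- unlist(r1$detail[ok])
  expect_true(all(perfs >= 0 & perfs <= 1))
  # reliability flag consistent with tau
  expect_equal(r1$intervals$reliable[ok],
               abs(r1$intervals$sudo[ok]) >= cfg$tau)
})

test_that("halving the replicate count only perturbs the discrepancy mildly", {
  w <- small_world()
  grid <- quantile_grid(w$wild$score, 6)
  r5 <- suppressWarnings(run_sudo(w$wild, w$train, w$heldout, grid,
                                  sudo_config(m = 50, k = 5, base_seed = 1)))
  r2 <- suppressWarnings(run_sudo(w$wild, w$train, w$heldout, grid,
                                  sudo_config(m = 50, k = 2, base_seed = 1)))
  d <- abs(r5$intervals$sudo - r2$intervals$sudo)
  expect_true(all(d[!is.na(d)] <= 0.1))
})

test_that("empty and under-occupied intervals are skipped with a warning, not an error", {
  w <- small_world()
  # a grid whose upper range is nearly empty under the skewed scores
  grid <- interval_grid(edges = c(0, 0.5, 0.97, 0.985, 1))
  expect_warning(
    res <- run_sudo(w$wild, w$train, w$heldout, grid,
                    sudo_config(m = 100, k = 1, base_seed = 1)),
    "skipped")
  expect_true(any(is.na(res$intervals$sudo)))
  expect_true(any(!is.na(res$intervals$sudo)))
  expect_true(length(res$warnings) >= 1)
})

test_that("unreliable intervals are flagged by the absolute-value rule", {
  w <- small_world()
  res <- suppressWarnings(run_sudo(w$wild, w$train, w$heldout,
                                   quantile_grid(w$wild$score, 5),
                                   sudo_config(m = 50, k = 2, base_seed = 2)))
  fl <- flag_unreliable(res, tau = 0.05)
  ok <- !is.na(fl$sudo)
  expect_equal(fl$reliable[ok], abs(fl$sudo[ok]) >= 0.05)
  expect_true(all(is.na(fl$call[!fl$reliable])))
  expect_equal(fl$call[fl$reliable & fl$sudo > 0],
               rep(1L, sum(fl$reliable & fl$sudo > 0)))
  # tau = 0: every non-tied interval is reliable
  fl0 <- flag_unreliable(res, tau = 0)
  expect_true(all(fl0$reliable[ok] | fl0$sudo[ok] == 0))
  # synthetic example from the threshold rule
  fake <- res
  fake$intervals <- fake$intervals[1:3, ]
  fake$intervals$sudo <- c(-0.6, 0.02, 0.4)
  fl3 <- flag_unreliable(fake, tau = 0.05)
  expect_equal(fl3$reliable, c(TRUE, FALSE, TRUE))
  expect_equal(fl3$call, c(0L, NA_integer_, 1L))
})

test_that("pure intervals dominate mixed intervals and call the right class", {
  # well-separated wild classes scored so that intervals are pure by
  # construction: class 0 at low scores, class 1 at high, a 50/50 mix in
  # the middle
  sudo_pure0 <- c(); sudo_pure1 <- c(); sudo_mixed <- c()
  for (seed in 1:5) {
    withr::with_seed(seed, {
      pool <- rbind(cbind(rnorm(150, -2, .5), rnorm(150, 0, .5)),
                    cbind(rnorm(150, 2, .5), rnorm(150, 0, .5)))
      lab <- rep(0:1, each = 150)
      train <- score_table(pool, label = lab, id = paste0("t", 1:300))
      ho <- rbind(cbind(rnorm(80, -2, .5), rnorm(80, 0, .5)),
                  cbind(rnorm(80, 2, .5), rnorm(80, 0, .5)))
      heldout <- score_table(ho, label = rep(0:1, each = 80),
                             id = paste0("h", 1:160))
      wx0 <- cbind(rnorm(60, -2, .5), rnorm(60, 0, .5))
      wx1 <- cbind(rnorm(60, 2, .5), rnorm(60, 0, .5))
      wmix <- rbind(cbind(rnorm(30, -2, .5), rnorm(30, 0, .5)),
                    cbind(rnorm(30, 2, .5), rnorm(30, 0, .5)))
    })
    wild <- score_table(rbind(wx0, wmix, wx1),
                        score = c(runif(60, 0.01, 0.33),
                                  runif(60, 0.34, 0.66),
                                  runif(60, 0.67, 1.0)),
                        label = c(rep(0L, 60), rep(0:1, each = 30),
                                  rep(1L, 60)),
                        id = paste0("w", 1:180))
    res <- suppressWarnings(
      run_sudo(wild, train, heldout, interval_grid(3),
               sudo_config(m = 40, k = 3, base_seed = seed)))
    sudo_pure0 <- c(sudo_pure0, res$intervals$sudo[1])
    sudo_mixed <- c(sudo_mixed, res$intervals$sudo[2])
    sudo_pure1 <- c(sudo_pure1, res$intervals$sudo[3])
  }
  expect_lt(mean(sudo_pure0), 0)  # correct call: class 0
  expect_gt(mean(sudo_pure1), 0)  # correct call: class 1
  expect_gt(abs(mean(sudo_pure0)), abs(mean(sudo_mixed)))
  expect_gt(abs(mean(sudo_pure1)), abs(mean(sudo_mixed)))
})

test_that("the majority-class calls are invariant to the evaluation metric", {
  # thresholded metrics (accuracy, F1) shrink and can reorder |sudo|
  # relative to the threshold-free AUROC, but the direction of the
  # discrepancy -- hence every call in an informative interval -- agrees
  # across metrics
  spec <- scenario_spec("clean", seed = 1)
  spec$wild <- list(gaussian_class_spec(c(1, 1), c(.8, .8), 1000, 0L),
                    gaussian_class_spec(c(2, 2), c(.1, .1), 1000, 1L))
  sc <- generate_scenario(spec)
  scorer <- fit_base_scorer(sc$train)
  sc$wild$score <- predict(scorer, sc$wild)
  grid <- quantile_grid(sc$wild$score, 10)
  profile <- function(metric) {
    rowMeans(vapply(1:2, function(bs) {
      suppressWarnings(run_sudo(sc$wild, sc$train, sc$heldout, grid,
        sudo_config(m = 50, k = 5, base_seed = bs,
                    metric = metric_spec(metric))))$intervals$sudo
    }, numeric(10)))
  }
  s_auc <- profile("auc"); s_acc <- profile("accuracy"); s_f1 <- profile("f1")
  informative <- abs(s_auc) >= 0.1 & abs(s_acc) >= 0.05 & abs(s_f1) >= 0.05
  expect_gte(sum(informative), 4)
  expect_equal(sign(s_acc[informative]), sign(s_auc[informative]))
  expect_equal(sign(s_f1[informative]), sign(s_auc[informative]))
})

test_that("swapping the probe family preserves the discrepancy-truth correlation", {
  skip_if_not_installed("randomForest")
  w <- small_world(seed = 2)
  grid <- quantile_grid(w$wild$score, 10)
  pf <- positive_fraction_per_interval(w$wild, grid)
  res_rf <- suppressWarnings(run_sudo(w$wild, w$train, w$heldout, grid,
    sudo_config(m = 50, k = 5, base_seed = 2,
                probe = probe_spec("random_forest"))))
  rho <- correlate(res_rf$intervals$sudo, pf)$rho
  expect_gte(abs(rho), 0.9)
})
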