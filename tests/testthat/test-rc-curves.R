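test_that("tiering partitions every score into exactly one of 0/1/abstain", {
  sch <- threshold_scheme(A = 0.2, B = 0.5)
  expect_equal(as.character(tier_predictions(0.1, sch)), "0")
  expect_equal(as.character(tier_predictions(0.35, sch)), "abstain")
  expect_equal(as.character(tier_predictions(0.5, sch)), "1")
  withr::with_seed(1, s <- runif(200))
  tiers <- tier_predictions(s, sch)
  expect_equal(length(tiers), 200L)
  expect_false(anyNA(tiers))
  # the clinical banding: low (0,0.2], uncertain (0.2,0.5), high [0.5,1)
  expect_equal(as.character(tier_predictions(c(0.15, 0.3, 0.7), sch)),
               c("0", "abstain", "1"))
  # touching bands: the boundary point goes to the low branch
  sch_touch <- threshold_scheme(A = 0.5, B = 0.5)
  expect_equal(as.character(tier_predictions(0.5, sch_touch)), "0")
  expect_error(threshold_scheme(A = 0.6, B = 0.5), "max\\(A\\) <= min\\(B\\)")
  expect_error(threshold_scheme(A = numeric(0), B = 0.5), "non-empty")
})

test_that("reliability implements the threshold double sum", {
  fn1 <- function(threshold, tail) if (tail == "low") 0.6 else 0.8
  expect_equal(reliability(fn1, threshold_scheme(0.2, 0.8)), 0.7)
  expect_equal(reliability(function(t, tail) 0, threshold_scheme(0.2, 0.8)), 0)
  # 3 x 2 scheme against a direct enumeration oracle
  A <- c(0.1, 0.2, 0.3); B <- c(0.7, 0.9)
  lowv <- c("0.1" = 0.9, "0.2" = 0.5, "0.3" = 0.2)
  highv <- c("0.7" = 0.4, "0.9" = 0.8)
  fn <- function(threshold, tail) {
    if (tail == "low") lowv[[as.character(threshold)]]
    else highv[[as.character(threshold)]]
  }
  oracle <- 0
  for (a in A) for (b in B) {
    oracle <- oracle + abs(fn(a, "low")) + abs(fn(b, "high"))
  }
  oracle <- oracle / (2 * length(A) * length(B))
  expect_equal(reliability(fn, threshold_scheme(A, B)), oracle)
})

test_that("the double sum equals its closed form on random inputs", {
  withr::with_seed(17, {
    for (rep in 1:20) {
      nA <- sample(1:4, 1); nB <- sample(1:4, 1)
      A <- sort(runif(nA, 0, 0.4)); B <- sort(runif(nB, 0.6, 1))
      lowv <- stats::setNames(runif(nA, -1, 1), sprintf("%.12f", A))
      highv <- stats::setNames(runif(nB, -1, 1), sprintf("%.12f", B))
      fn <- function(threshold, tail) {
        v <- if (tail == "low") lowv else highv
        v[[sprintf("%.12f", threshold)]]
      }
      closed <- (mean(abs(lowv)) + mean(abs(highv))) / 2
      expect_equal(reliability(fn, threshold_scheme(A, B)), closed)
    }
  })
})

test_that("completeness counts the captured fraction and is monotone", {
  expect_equal(completeness(c(0.1, 0.3, 0.9), threshold_scheme(0.2, 0.8)),
               2 / 3)
  expect_equal(completeness(runif(50), threshold_scheme(1, 1)), 1)
  expect_error(completeness(numeric(0), threshold_scheme(0.2, 0.8)), "empty")
  withr::with_seed(2, s <- runif(100))
  # indicator-sum oracle for an excluded band (0.2, 0.5)
  expect_equal(completeness(s, threshold_scheme(0.2, 0.5)),
               sum(s <= 0.2 | s >= 0.5) / 100)
  # enlarging A or B never loses points
  base <- completeness(s, threshold_scheme(0.2, 0.8))
  expect_gte(completeness(s, threshold_scheme(c(0.2, 0.3), 0.8)), base)
  expect_gte(completeness(s, threshold_scheme(0.2, c(0.7, 0.8))), base)
  for (t2 in seq(0.25, 0.5, 0.05)) {
    expect_gte(completeness(s, threshold_scheme(t2, 1 - t2)),
               completeness(s, threshold_scheme(t2 - 0.05, 1 - t2 + 0.05)))
  }
})

test_that("aurcc hits the closed-form flat, zero, and triangle values", {
  flat <- data.frame(completeness = seq(0, 1, 0.1), reliability = 1)
  expect_equal(aurcc(flat), 1)
  zero <- data.frame(completeness = seq(0, 1, 0.1), reliability = 0)
  expect_equal(aurcc(zero), 0)
  tri <- data.frame(completeness = seq(0, 1, 0.1),
                    reliability = seq(1, 0, -0.1))
  expect_equal(aurcc(tri), 0.5)
  # inserting a collinear point changes nothing
  tri2 <- rbind(tri, data.frame(completeness = 0.55, reliability = 0.45))
  expect_equal(aurcc(tri2), aurcc(tri))
  # random curves stay in [0, 1] when reliabilities do
  withr::with_seed(23, {
    for (rep in 1:20) {
      k <- sample(3:12, 1)
      crv <- data.frame(completeness = sort(runif(k)),
                        reliability = runif(k))
      if (diff(range(crv$completeness)) == 0) next
      a <- aurcc(crv)
      expect_gte(a, 0); expect_lte(a, 1)
    }
  })
  expect_error(aurcc(data.frame(completeness = c(.5, .5),
                                reliability = c(0, 1))), "span")
})

test_that("curves decline as completeness grows when the middle is contaminated", {
  w <- small_world()
  curve <- suppressWarnings(
    build_rc_curve(w$wild, w$train, w$heldout,
                   config = sudo_config(m = 200, k = 2, base_seed = 1),
                   schemes = symmetric_schemes(6)))
  pts <- curve$points
  expect_true(all(diff(pts$completeness) >= 0))
  # extremes purer than the middle: reliability at the narrowest scheme
  # exceeds reliability at full completeness
  expect_gt(pts$reliability[1], pts$reliability[nrow(pts)])
  expect_gte(curve$aurcc, 0)
  expect_lte(curve$aurcc, 1)
})

test_that("model comparison ranks by area and reports ties", {
  mk_curve <- function(r_top, fingerprint = "fp", schemes = 1:3) {
    structure(list(points = data.frame(completeness = c(0, 0.5, 1),
                                       reliability = c(r_top, r_top / 2, 0.1)),
                   schemes = lapply(schemes / 10,
                                    function(t) threshold_scheme(t, 1 - t)),
                   wild_fingerprint = fingerprint,
                   metric = "auc"),
              class = "rc_curve") -> crv
    crv$aurcc <- aurcc(crv)
    crv
  }
  good <- mk_curve(0.9); weak <- mk_curve(0.3)
  out <- compare_models(list(good = good, weak = weak))
  expect_equal(out$model, c("good", "weak"))
  expect_equal(out$rank, c(1L, 2L))
  tie <- compare_models(list(a = good, b = good))
  expect_equal(tie$rank, c(1L, 1L))
  expect_error(compare_models(list(a = good, b = mk_curve(0.3, "other"))),
               "different wild")
  expect_error(compare_models(list(a = good,
                                   b = mk_curve(0.3, schemes = 2:4))),
               "scheme families")
})

test_that("a calibrated scorer outranks a label-shuffled scorer", {
  wins <- 0
  for (seed in 1:5) {
    sc <- generate_scenario(scenario_spec("clean", seed = seed))
    good <- fit_base_scorer(sc$train)
    shuffled <- sc$train
    shuffled$label <- withr::with_seed(seed, sample(shuffled$label))
    bad <- fit_base_scorer(shuffled)
    cfg <- sudo_config(m = 150, k = 1, base_seed = seed)
    schemes <- symmetric_schemes(10)
    wg <- sc$wild; wg$score <- predict(good, wg)
    wb <- sc$wild; wb$score <- predict(bad, wb)
    cg <- suppressWarnings(build_rc_curve(wg, sc$train, sc$heldout,
                                          config = cfg, schemes = schemes))
    # a shuffled scorer can concentrate every score in a sliver, leaving
    # too few populated schemes for a curve at all -- a loss by default
    cb <- tryCatch(
      suppressWarnings(build_rc_curve(wb, sc$train, sc$heldout,
                                      config = cfg, schemes = schemes)),
      error = function(e) NULL)
    if (is.null(cb) || cg$aurcc > cb$aurcc) wins <- wins + 1
  }
  expect_gte(wins, 4)
})
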