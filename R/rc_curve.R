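#' Threshold scheme for prediction tiering
#'
#' A scheme is a set `A` of low probability thresholds and a set `B` of high
#' probability thresholds. Points with scores at or below `max(A)` are
#' predicted class 0, points at or above `min(B)` class 1, and the middle
#' band abstains (routed to human review).
#'
#' @param A numeric vector of low thresholds in `[0, 1]`.
#' @param B numeric vector of high thresholds in `[0, 1]`;
#'   `max(A) <= min(B)` is required (equality closes the abstention band).
#' @return A `threshold_scheme`.
#' @export
threshold_scheme <- function(A, B) {
  if (length(A) == 0 || length(B) == 0) stop("A and B must be non-empty")
  if (any(c(A, B) < 0) || any(c(A, B) > 1)) {
    stop("thresholds must lie in [0, 1]")
  }
  if (max(A) > min(B)) stop("require max(A) <= min(B)")
  structure(list(A = sort(as.numeric(A)), B = sort(as.numeric(B))),
            class = "threshold_scheme")
}

#' Tier predictions into class 0 / class 1 / abstain
#'
#' Applies the thresholding rule: predict 0 when `s <= max(A)`, 1 when
#' `s >= min(B)`, abstain otherwise. When the two bands touch
#' (`max(A) == min(B)`), the boundary point resolves to the low branch.
#'
#' @param scores numeric vector of probabilities.
#' @param scheme a [threshold_scheme()].
#' @return factor with levels `"0"`, `"1"`, `"abstain"`, one per score.
#' @export
tier_predictions <- function(scores, scheme) {
  out <- rep("abstain", length(scores))
  out[scores >= min(scheme$B)] <- "1"
  out[scores <= max(scheme$A)] <- "0"
  factor(out, levels = c("0", "1", "abstain"))
}

#' Reliability of tiered predictions
#'
#' Averages the absolute discrepancy over all threshold pairs: the double
#' sum over `alpha in A, beta in B` of `|SUDO(alpha)| + |SUDO(beta)|`,
#' scaled by `1 / (2 |A| |B|)`. Algebraically this equals the mean of the
#' two per-set means of absolute tail discrepancies.
#'
#' @param sudo_fn function `(threshold, tail)` returning the signed
#'   discrepancy of the pooled tail region: `tail = "low"` evaluates on
#'   points with `s <= threshold`, `tail = "high"` on `s >= threshold`.
#'   See [tail_sudo_fn()]. A tail with no data returns `NA`; such
#'   thresholds produce no predictions and are excluded from the average
#'   (a scheme whose tails are all empty has `NA` reliability).
#' @param scheme a [threshold_scheme()].
#' @return scalar reliability (within the metric's range width), or `NA`.
#' @export
reliability <- function(sudo_fn, scheme) {
  low <- vapply(scheme$A, function(a) abs(sudo_fn(a, "low")), numeric(1))
  high <- vapply(scheme$B, function(b) abs(sudo_fn(b, "high")), numeric(1))
  low <- low[!is.na(low)]
  high <- high[!is.na(high)]
  if (length(low) && length(high)) {
    (mean(low) + mean(high)) / 2
  } else if (length(low)) {
    mean(low)
  } else if (length(high)) {
    mean(high)
  } else {
    NA_real_
  }
}

#' Completeness of tiered predictions
#'
#' The fraction of all deployment points that receive a hard prediction
#' under the scheme (score at or below `max(A)`, or at or above `min(B)`),
#' so `C` always lies in `[0, 1]`.
#'
#' @param wild_scores numeric vector of all deployment scores.
#' @param scheme a [threshold_scheme()].
#' @return scalar in `[0, 1]`.
#' @export
completeness <- function(wild_scores, scheme) {
  if (length(wild_scores) == 0) stop("empty wild score set")
  mean(wild_scores <= max(scheme$A) | wild_scores >= min(scheme$B))
}

#' Default symmetric scheme family
#'
#' Sweeps singleton schemes `(alpha, beta) = (t, 1 - t)` over `n_steps`
#' values of `t` from 0.05 to 0.5; the widest scheme closes the abstention
#' band, reaching completeness 1.
#'
#' @param n_steps number of schemes (default 10).
#' @return list of [threshold_scheme()]s ordered by increasing width.
#' @export
symmetric_schemes <- function(n_steps = 10) {
  ts <- seq(0.05, 0.5, length.out = n_steps)
  lapply(ts, function(t) threshold_scheme(A = t, B = 1 - t))
}

#' Tail-region discrepancy function for reliability curves
#'
#' Builds and memoizes the function that the reliability computation
#' queries: for a threshold `alpha` it computes the signed discrepancy of
#' the pooled region `{s <= alpha}` treated as a single interval (mirrored
#' for `beta` and `{s >= beta}`). The alternative `"binned"` mode averages
#' the signed discrepancies of the grid intervals inside the tail instead
#' of pooling.
#'
#' @param wild,reference_pool,heldout score tables as in [run_sudo()].
#' @param config a [sudo_config()]; with `m = "auto"` each tail uses all of
#'   its points, otherwise at most `m` are sampled per replicate.
#' @param mode `"pooled"` (default) or `"binned"`.
#' @param grid grid used by `"binned"` mode.
#' @return function `(threshold, tail)` returning a signed discrepancy
#'   (`NA` when the tail holds fewer than 2 points).
#' @export
tail_sudo_fn <- function(wild, reference_pool, heldout, config,
                         mode = c("pooled", "binned"),
                         grid = interval_grid(10)) {
  mode <- match.arg(mode)
  cache <- new.env(parent = emptyenv())
  binned <- NULL
  if (mode == "binned") {
    binned <- run_sudo(wild, reference_pool, heldout, grid, config)
  }
  function(threshold, tail = c("low", "high")) {
    tail <- match.arg(tail)
    key <- sprintf("%s:%.10f", tail, threshold)
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- if (mode == "pooled") {
      idx <- if (tail == "low") {
        which(wild$score <= threshold)
      } else {
        which(wild$score >= threshold)
      }
      seed_tag <- round(1e5 * threshold) + if (tail == "high") 1e6 else 2e6
      sudo_for_points(wild, idx, reference_pool, heldout, config, seed_tag)
    } else {
      iv <- binned$intervals
      inside <- if (tail == "low") {
        iv$upper <= threshold + 1e-12
      } else {
        iv$lower >= threshold - 1e-12
      }
      vals <- iv$sudo[inside & !is.na(iv$sudo)]
      if (length(vals) == 0) NA_real_ else mean(vals)
    }
    cache[[key]] <- val
    val
  }
}

#' Build a reliability-completeness curve
#'
#' Evaluates reliability and completeness for each scheme in a family and
#' assembles the curve: points are sorted by completeness, duplicate
#' completeness values keep the maximum reliability (conservative curve),
#' and a conceptual anchor at completeness 0 extends the narrowest scheme's
#' reliability leftwards. The area under the curve (AURCC) summarizes it.
#'
#' @inheritParams tail_sudo_fn
#' @param schemes list of [threshold_scheme()]s (>= 2, yielding >= 2
#'   distinct completeness values); defaults to [symmetric_schemes()].
#' @param tail_mode `"pooled"` or `"binned"`, see [tail_sudo_fn()].
#' @param grid grid for `"binned"` mode.
#' @return An `rc_curve`: list with `points` (data.frame of completeness and
#'   reliability per scheme), `aurcc`, the scheme family, and a fingerprint
#'   of the wild data used for comparability checks.
#' @export
build_rc_curve <- function(wild, reference_pool, heldout,
                           config = sudo_config(),
                           schemes = symmetric_schemes(),
                           tail_mode = "pooled", grid = interval_grid(10)) {
  if (length(schemes) < 2) stop("need at least 2 schemes")
  fn <- tail_sudo_fn(wild, reference_pool, heldout, config,
                     mode = tail_mode, grid = grid)
  pts <- data.frame(
    scheme = seq_along(schemes),
    max_A = vapply(schemes, function(s) max(s$A), numeric(1)),
    min_B = vapply(schemes, function(s) min(s$B), numeric(1)),
    completeness = vapply(schemes, function(s) completeness(wild$score, s),
                          numeric(1)),
    reliability = vapply(schemes, function(s) reliability(fn, s), numeric(1))
  )
  pts <- pts[!is.na(pts$reliability), , drop = FALSE]
  if (length(unique(pts$completeness)) < 2) {
    stop("schemes yield fewer than 2 distinct completeness values")
  }
  # keep max reliability per completeness, sort, anchor at C = 0
  pts <- pts[order(pts$completeness, -pts$reliability), , drop = FALSE]
  pts <- pts[!duplicated(pts$completeness), , drop = FALSE]
  anchor <- pts[1, , drop = FALSE]
  anchor$scheme <- NA_integer_
  anchor$completeness <- 0
  if (pts$completeness[1] > 0) pts <- rbind(anchor, pts)
  rownames(pts) <- NULL
  curve <- structure(list(points = pts,
                          schemes = schemes,
                          wild_fingerprint = wild_fingerprint(wild),
                          metric = config$metric$name),
                     class = "rc_curve")
  curve$aurcc <- aurcc(curve)
  curve
}

# Identifies the wild dataset (points, not scores) so that curves for
# different models over the same deployment data remain comparable.
wild_fingerprint <- function(wild) {
  fm <- feature_matrix(wild)
  sprintf("M=%d;d=%d;sum=%.12g;ss=%.12g;ids=%s",
          nrow(fm), ncol(fm), sum(fm), sum(fm^2),
          substr(paste(wild$id[c(1, nrow(fm))], collapse = "|"), 1, 40))
}

#' Area under the reliability-completeness curve
#'
#' Trapezoidal area of reliability over completeness, normalized by the
#' spanned completeness range so the area lies in `[0, 1]` whenever the
#' reliabilities do. Inserting a collinear point leaves the area unchanged.
#' Higher areas indicate models whose confident predictions stay reliable
#' as more of the deployment data is accepted, enabling label-free model
#' ranking.
#'
#' @param curve an `rc_curve`, or a data.frame with `completeness` and
#'   `reliability` columns.
#' @return scalar area.
#' @export
aurcc <- function(curve) {
  pts <- if (inherits(curve, "rc_curve")) curve$points else curve
  pts <- pts[order(pts$completeness), , drop = FALSE]
  C <- pts$completeness
  R <- pts$reliability
  span <- C[length(C)] - C[1]
  if (span <= 0) stop("zero completeness span; cannot integrate")
  area <- sum((R[-1] + R[-length(R)]) / 2 * diff(C))
  area / span
}

#' @export
print.rc_curve <- function(x, ...) {
  cat(sprintf("<rc_curve: %d points, AURCC = %.3f (%s metric)>\n",
              nrow(x$points), x$aurcc, x$metric))
  print(x$points, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Rank competing models by AURCC
#'
#' Compares reliability-completeness curves built for different models on
#' the same deployment data and scheme family; models are ranked by
#' descending area. Ties are reported as shared ranks, not broken.
#'
#' @param curves named list of `rc_curve` objects (>= 2), all built from the
#'   same wild score set and scheme family.
#' @return data.frame with `model`, `aurcc`, `rank` (descending by area).
#' @export
compare_models <- function(curves) {
  if (length(curves) < 2) stop("need at least 2 models to compare")
  if (is.null(names(curves)) || any(names(curves) == "")) {
    stop("curves must be named by model")
  }
  fps <- vapply(curves, function(x) x$wild_fingerprint, character(1))
  if (length(unique(fps)) != 1) {
    stop("curves were built on different wild datasets; not comparable")
  }
  sch <- vapply(curves, function(x) {
    paste(vapply(x$schemes, function(s)
      sprintf("%.6f|%.6f", max(s$A), min(s$B)), character(1)), collapse = ";")
  }, character(1))
  if (length(unique(sch)) != 1) {
    stop("curves use different scheme families; not comparable")
  }
  a <- vapply(curves, function(x) x$aurcc, numeric(1))
  out <- data.frame(model = names(curves), aurcc = unname(a),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$aurcc), , drop = FALSE]
  out$rank <- rank(-out$aurcc, ties.method = "min")
  rownames(out) <- NULL
  out
}
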