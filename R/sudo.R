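#' SUDO run configuration
#'
#' @param m per-interval sample count, or `"auto"` to use the minimum
#'   occupancy across non-empty intervals (so every interval is sampled
#'   equally, without replacement).
#' @param k number of replicates; each replicate redraws the interval sample
#'   (default 5).
#' @param base_seed integer master seed; every draw in a run derives its own
#'   child seed deterministically from `(base_seed, interval, replicate,
#'   role)`, so adding intervals never perturbs existing draws.
#' @param probe a [probe_spec()] for the pseudo-label probe classifier.
#' @param metric a [metric_spec()] for held-out probe evaluation.
#' @param tau non-negative reliability cutoff: intervals with `|sudo| < tau`
#'   are flagged unreliable and carry no majority-class call.
#' @return A `sudo_config` list.
#' @export
sudo_config <- function(m = "auto", k = 5, base_seed = 0L,
                        probe = probe_spec(), metric = metric_spec(),
                        tau = 0.05) {
  if (!identical(m, "auto")) {
    m <- as.integer(m)
    if (m < 2) stop("explicit m must be >= 2")
  }
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1")
  if (tau < 0) stop("tau must be non-negative")
  structure(list(m = m, k = k, base_seed = as.integer(base_seed),
                 probe = probe, metric = metric, tau = tau),
            class = "sudo_config")
}

# Deterministic child-seed derivation (multiplicative folding mod 2^31 - 1;
# exact in doubles). Distinct component tuples give distinct streams.
derive_seed <- function(base, ...) {
  h <- (as.double(base) %% 2147483647) + 1
  for (x in c(...)) {
    h <- (h * 69069 + as.double(x) + 1) %% 2147483647
  }
  as.integer(h)
}

# Probe performance matrix for one set of candidate points.
# Returns a k x n_classes matrix: entry [r, l+1] is the held-out performance
# of the probe trained (replicate r) under pseudo-label l, plus the seed log.
probe_perf_matrix <- function(wild, idx_pool, m, reference_pool, heldout,
                              config, n_classes, seed_tag) {
  k <- config$k
  classes <- seq_len(n_classes) - 1L
  perf <- matrix(NA_real_, nrow = k, ncol = n_classes,
                 dimnames = list(NULL, as.character(classes)))
  seeds <- list()
  for (r in seq_len(k)) {
    seed_wild <- derive_seed(config$base_seed, seed_tag, r, 0)
    widx <- withr::with_seed(seed_wild,
                             idx_pool[sample.int(length(idx_pool), m)])
    wild_sub <- wild[widx, , drop = FALSE]
    for (l in classes) {
      seed_ref <- derive_seed(config$base_seed, seed_tag, r, 1 + l)
      seed_fit <- derive_seed(config$base_seed, seed_tag, r, 100 + l)
      task <- build_probe_task(wild_sub, l, reference_pool, m, seed_ref,
                               n_classes = n_classes)
      probe <- train_probe(task, config$probe, seed_fit)
      perf[r, l + 1L] <- evaluate_probe(probe, heldout, config$metric,
                                        positive_class = l)
      seeds[[length(seeds) + 1L]] <-
        data.frame(tag = seed_tag, replicate = r, pseudo_class = l,
                   seed_wild = seed_wild, seed_ref = seed_ref,
                   seed_fit = seed_fit)
    }
  }
  list(perf = perf, seeds = do.call(rbind, seeds))
}

#' Derive the pseudo-label discrepancy from probe performances
#'
#' In the binary setting the signed discrepancy is the replicate mean of
#' `perf(pseudo = 1) - perf(pseudo = 0)`: positive values indicate the
#' interval's points behave like class 1, negative like class 0. In the
#' multi-class setting the discrepancy is the (non-negative) difference
#' between the best- and worst-performing probes across all pseudo-labels,
#' and the call is the best performer's pseudo-label.
#'
#' Interpretation should rest on the absolute value first: small
#' discrepancies can flip sign between sample sizes while `|sudo|` stays
#' stable, so the direction of a small-`|sudo|` interval is not meaningful.
#'
#' @param perf matrix of probe performances, replicates in rows, one column
#'   per pseudo-label (column names are the class indices). A list of
#'   per-pseudo-label numeric vectors is also accepted; all vectors must
#'   share one replicate count.
#' @param tau reliability cutoff used only to suppress the call when
#'   `|sudo| < tau`.
#' @param mode `"binary"` (signed, requires exactly 2 pseudo-labels) or
#'   `"multiclass"` (max - min).
#' @return list with `sudo` (signed scalar), `majority_class_call` (class
#'   index or `NA`), and the per-class replicate-mean performances.
#' @export
compute_interval_sudo <- function(perf, tau = 0,
                                  mode = c("binary", "multiclass")) {
  mode <- match.arg(mode)
  if (is.list(perf) && !is.matrix(perf)) {
    if (length(unique(lengths(perf))) != 1) {
      stop("mismatched replicate counts across pseudo-labels")
    }
    perf <- do.call(cbind, perf)
  }
  perf <- as.matrix(perf)
  if (is.null(colnames(perf))) {
    colnames(perf) <- as.character(seq_len(ncol(perf)) - 1L)
  }
  if (anyNA(perf)) stop("probe performances contain missing values")
  class_means <- colMeans(perf)
  if (mode == "binary") {
    if (ncol(perf) != 2) stop("binary mode requires exactly 2 pseudo-labels")
    sudo <- unname(class_means["1"] - class_means["0"])
    call <- if (abs(sudo) < max(tau, .Machine$double.eps)) {
      NA_integer_
    } else if (sudo > 0) 1L else 0L
  } else {
    sudo <- unname(max(class_means) - min(class_means))
    call <- if (sudo < max(tau, .Machine$double.eps)) {
      NA_integer_
    } else {
      as.integer(colnames(perf)[which.max(class_means)])
    }
  }
  list(sudo = sudo, majority_class_call = call, class_means = class_means)
}

#' Run the SUDO framework over a probability-interval grid
#'
#' Orchestrates the full pipeline on binary predictions: bin the deployment
#' ("wild") scores into intervals, resolve the shared sample size `m`, and
#' for each interval x replicate x pseudo-label sample `m` wild points
#' (the same subset for both pseudo-labels of a replicate), pair them with
#' `m` ground-truth reference points of the opposing class, train a probe,
#' and evaluate it on the labelled held-out set. The per-interval signed
#' discrepancy is the replicate mean of the performance difference between
#' the two pseudo-label settings.
#'
#' Empty or under-occupied intervals are skipped with a warning and appear
#' in the result with a missing discrepancy rather than failing the run.
#'
#' @param wild `score_table` of deployment points (scores required, labels
#'   not used).
#' @param reference_pool labelled `score_table` supplying ground-truth
#'   opposing-class points for probe training.
#' @param heldout labelled `score_table` used for probe evaluation; must
#'   contain both classes and should have minimal label noise (the
#'   discrepancy degrades sharply when held-out labels are corrupted).
#' @param grid an [interval_grid()].
#' @param config a [sudo_config()].
#' @return A `sudo_result`: list with `intervals` (per-interval report
#'   data.frame), `detail` (per-interval replicate performance matrices),
#'   `m`, `config`, `grid`, `seeds_used`, `out_of_span`, `warnings`.
#' @examples
#' \donttest{
#' sc <- generate_scenario(scenario_spec("clean", seed = 1))
#' scorer <- fit_base_scorer(sc$train)
#' sc$wild$score <- predict(scorer, sc$wild)
#' res <- run_sudo(sc$wild, sc$train, sc$heldout,
#'                 config = sudo_config(m = 50, k = 2, base_seed = 1))
#' res$intervals
#' }
#' @export
run_sudo <- function(wild, reference_pool, heldout, grid = interval_grid(10),
                     config = sudo_config()) {
  run_sudo_engine(wild, reference_pool, heldout, grid, config, n_classes = 2L,
                  mode = "binary")
}

#' Run SUDO with more than two candidate classes
#'
#' Cycles through all `n_classes` pseudo-labels per interval, pairing each
#' with reference points from the mutually-exclusive classes and training
#' one probe per pseudo-label; the discrepancy is the maximum minus the
#' minimum probe performance, and the call is the best performer's class.
#' With `n_classes = 2` the absolute discrepancy equals the binary one under
#' the same seeds.
#'
#' @inheritParams run_sudo
#' @param n_classes number of candidate classes (>= 2); the reference pool
#'   and held-out set must contain every class.
#' @return A `sudo_result` (see [run_sudo()]); `sudo` is non-negative.
#' @export
run_sudo_multiclass <- function(wild, reference_pool, heldout,
                                grid = interval_grid(10),
                                config = sudo_config(), n_classes) {
  n_classes <- as.integer(n_classes)
  if (n_classes < 2) stop("n_classes must be >= 2")
  run_sudo_engine(wild, reference_pool, heldout, grid, config,
                  n_classes = n_classes, mode = "multiclass")
}

run_sudo_engine <- function(wild, reference_pool, heldout, grid, config,
                            n_classes, mode) {
  validate_score_table(wild)
  validate_score_table(reference_pool)
  validate_score_table(heldout)
  check_classes_present(reference_pool, n_classes, "reference pool")
  check_classes_present(heldout, n_classes, "held-out set")

  warnings_log <- character()
  note <- function(msg) {
    warnings_log <<- c(warnings_log, msg)
    warning(msg, call. = FALSE)
  }

  asg <- assign_intervals(wild, grid)
  if (length(asg$out_of_span)) {
    note(sprintf("%d wild point(s) fall outside the grid span and were set aside",
                 length(asg$out_of_span)))
  }
  m <- withCallingHandlers(
    resolve_sample_size(asg, config),
    warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  ni <- n_intervals(grid)
  labels <- interval_labels(grid)
  detail <- vector("list", ni)
  names(detail) <- labels
  seed_log <- list()
  sudo <- rep(NA_real_, ni)
  call <- rep(NA_integer_, ni)
  class_mean_rows <- matrix(NA_real_, nrow = ni, ncol = n_classes,
                            dimnames = list(NULL, paste0("perf_", seq_len(n_classes) - 1L)))

  for (i in seq_len(ni)) {
    occ <- asg$occupancy[i]
    if (occ == 0) {
      note(sprintf("interval %s is empty; skipped", labels[i]))
      next
    }
    if (occ < m) {
      note(sprintf("interval %s holds %d < m = %d points; skipped",
                   labels[i], occ, m))
      next
    }
    pm <- probe_perf_matrix(wild, asg$index_sets[[i]], m, reference_pool,
                            heldout, config, n_classes, seed_tag = i)
    detail[[i]] <- pm$perf
    seed_log[[length(seed_log) + 1L]] <- pm$seeds
    cis <- compute_interval_sudo(pm$perf, tau = config$tau, mode = mode)
    sudo[i] <- cis$sudo
    call[i] <- cis$majority_class_call
    class_mean_rows[i, ] <- cis$class_means
  }

  intervals <- data.frame(
    interval = labels,
    lower = grid$lower,
    upper = grid$upper,
    n = as.integer(asg$occupancy),
    stringsAsFactors = FALSE
  )
  intervals <- cbind(intervals, as.data.frame(class_mean_rows))
  intervals$sudo <- sudo
  intervals$call <- call
  intervals$reliable <- !is.na(sudo) & abs(sudo) >= config$tau
  intervals$call[!intervals$reliable] <- NA_integer_

  structure(list(
    intervals = intervals,
    detail = detail,
    m = m,
    config = config,
    grid = grid,
    mode = mode,
    n_classes = n_classes,
    seeds_used = if (length(seed_log)) do.call(rbind, seed_log) else NULL,
    out_of_span = asg$out_of_span,
    warnings = warnings_log
  ), class = "sudo_result")
}

#' @export
print.sudo_result <- function(x, ...) {
  cat(sprintf("<sudo_result: %d intervals, m = %d, k = %d, probe = %s, metric = %s>\n",
              nrow(x$intervals), x$m, x$config$k, x$config$probe$family,
              x$config$metric$name))
  print(x$intervals, digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.sudo_result <- function(x, ...) x$intervals

#' Flag unreliable probability intervals
#'
#' An interval is unreliable when the absolute discrepancy falls below the
#' cutoff `tau` (high class contamination); reliable intervals carry their
#' majority-class call. Predictions in unreliable intervals should be routed
#' to human review rather than consumed downstream.
#'
#' @param result a `sudo_result`.
#' @param tau non-negative cutoff; defaults to the run's configured value.
#' @return data.frame with `interval`, `sudo`, `reliable`, `call`.
#' @export
flag_unreliable <- function(result, tau = result$config$tau) {
  if (tau < 0) stop("tau must be non-negative")
  iv <- result$intervals
  reliable <- !is.na(iv$sudo) & abs(iv$sudo) >= tau
  call <- rep(NA_integer_, nrow(iv))
  if (identical(result$mode, "binary")) {
    call[reliable & iv$sudo > 0] <- 1L
    call[reliable & iv$sudo < 0] <- 0L
  } else {
    call[reliable] <- iv$call[reliable]
  }
  data.frame(interval = iv$interval, sudo = iv$sudo,
             reliable = reliable, call = call,
             stringsAsFactors = FALSE)
}

# Signed SUDO for an arbitrary pooled set of wild points (used by the
# reliability-completeness machinery, which treats each tail region
# {s <= alpha} or {s >= beta} as a single interval).
sudo_for_points <- function(wild, point_idx, reference_pool, heldout, config,
                            seed_tag) {
  if (length(point_idx) < 2) return(NA_real_)
  m <- if (identical(config$m, "auto")) {
    length(point_idx)
  } else {
    min(config$m, length(point_idx))
  }
  pm <- probe_perf_matrix(wild, point_idx, m, reference_pool, heldout,
                          config, n_classes = 2L, seed_tag = seed_tag)
  compute_interval_sudo(pm$perf, tau = 0, mode = "binary")$sudo
}
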