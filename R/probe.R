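#' Probe classifier specifications and registry
#'
#' A probe is the lightweight binary classifier `g` trained to separate
#' pseudo-labelled deployment points from ground-truth points of the
#' opposing class. It is deliberately distinct from (and need not resemble)
#' the inference model that produced the probability scores. The default is
#' a logistic regression on standardized features; a random forest is also
#' registered, and users may register their own families.
#'
#' @param family registered family name, e.g. `"logistic"` or
#'   `"random_forest"`.
#' @param ... hyperparameters forwarded to the family's fitting function.
#' @return A `probe_spec` list with `family` and `hyperparameters`.
#' @export
probe_spec <- function(family = "logistic", ...) {
  if (!family %in% ls(probe_registry)) {
    stop("unknown probe family '", family, "'; registered: ",
         paste(ls(probe_registry), collapse = ", "))
  }
  structure(list(family = family, hyperparameters = list(...)),
            class = "probe_spec")
}

probe_registry <- new.env(parent = emptyenv())

#' Register a probe family
#'
#' @param family name under which the family is registered.
#' @param fit function `(x, y, seed, hyperparameters)` returning a fitted
#'   object; `x` is a standardized feature matrix, `y` a 0/1 integer vector.
#' @param predict_scores function `(fit, x)` returning class-1 scores for a
#'   feature matrix `x` (already standardized with the training statistics).
#'   Scores need only be monotone in the class-1 probability, on any scale:
#'   the logistic family returns the linear predictor, because on separable
#'   probe tasks the response scale saturates to exactly 0/1 in double
#'   precision, and the resulting ties would bias rank-based metrics toward
#'   chance.
#' @param decision_threshold score cutoff above which a point is called
#'   class 1 by thresholded metrics (accuracy, F1) on the family's score
#'   scale.
#' @export
register_probe <- function(family, fit, predict_scores,
                           decision_threshold = 0.5) {
  assign(family, list(fit = fit, predict_scores = predict_scores,
                      decision_threshold = decision_threshold),
         envir = probe_registry)
  invisible(family)
}

register_probe("logistic",
  fit = function(x, y, seed, hyperparameters) {
    df <- data.frame(x, .y = y)
    suppressWarnings(
      stats::glm(.y ~ ., data = df, family = stats::binomial())
    )
  },
  predict_scores = function(fit, x) {
    as.numeric(stats::predict(fit, newdata = data.frame(x), type = "link"))
  },
  decision_threshold = 0)

register_probe("random_forest",
  fit = function(x, y, seed, hyperparameters) {
    if (!requireNamespace("randomForest", quietly = TRUE)) {
      stop("probe family 'random_forest' requires the randomForest package")
    }
    ntree <- hyperparameters$ntree %||% 100
    withr::with_seed(seed,
      randomForest::randomForest(x, factor(y, levels = c(0, 1)),
                                 ntree = ntree))
  },
  predict_scores = function(fit, x) {
    as.numeric(stats::predict(fit, newdata = x, type = "prob")[, "1"])
  },
  decision_threshold = 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Performance metric specification
#'
#' The held-out performance metric used to score probes. The framework is
#' metric-agnostic: the discrepancy's rank order across intervals is stable
#' under reasonable metric swaps, so the default AUROC can be replaced by
#' accuracy or F1.
#'
#' @param name one of `"auc"`, `"accuracy"`, `"f1"`.
#' @return A `metric_spec` with the metric function, its finite `range`, and
#'   a higher-is-better `orientation` flag.
#' @export
metric_spec <- function(name = c("auc", "accuracy", "f1")) {
  name <- match.arg(name)
  fn <- switch(name,
    auc = function(scores, labels, threshold = 0.5) metric_auc(scores, labels),
    accuracy = function(scores, labels, threshold = 0.5) {
      mean((scores >= threshold) == (labels == 1))
    },
    f1 = function(scores, labels, threshold = 0.5) {
      pred <- scores >= threshold
      tp <- sum(pred & labels == 1)
      if (tp == 0) return(0)
      2 * tp / (2 * tp + sum(pred & labels == 0) + sum(!pred & labels == 1))
    })
  structure(list(name = name, fn = fn, range = c(0, 1),
                 higher_is_better = TRUE),
            class = "metric_spec")
}

# Mann-Whitney AUROC; ties between a positive and a negative score count as
# half-concordant.
metric_auc <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: held-out set missing a class")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Build one probe training task
#'
#' Pairs `m` sampled deployment ("wild") points, temporarily labelled with
#' `pseudo_class`, against `m` ground-truth points of the opposing class
#' drawn without replacement from the reference pool. In the multi-class
#' setting the opposing points are drawn from the pool of all classes other
#' than `pseudo_class`.
#'
#' @param wild_subset a `score_table` of the sampled wild points.
#' @param pseudo_class class index temporarily assigned to the wild points.
#' @param reference_pool labelled `score_table` to draw opposing points from.
#' @param m sample count (must equal `nrow(wild_subset)`).
#' @param seed seed for the reference draw.
#' @param n_classes total number of classes (2 for the binary setting).
#' @return A `probe_task`: list with `x` (feature matrix), `y` (1 for the
#'   pseudo-labelled wild points, 0 for reference points), `pseudo_class`,
#'   and the contributing ids.
#' @export
build_probe_task <- function(wild_subset, pseudo_class, reference_pool, m,
                             seed, n_classes = 2) {
  if (nrow(wild_subset) != m) stop("wild subset must hold exactly m points")
  opposing <- which(!is.na(reference_pool$label) &
                    reference_pool$label != pseudo_class)
  if (length(opposing) < m) {
    stop("reference pool holds ", length(opposing), " points of class(es) != ",
         pseudo_class, "; cannot sample m = ", m)
  }
  ref_idx <- withr::with_seed(seed, opposing[sample.int(length(opposing), m)])
  ref <- reference_pool[ref_idx, , drop = FALSE]
  ids <- c(wild_subset$id, ref$id)
  if (anyDuplicated(ids)) stop("a point id appears twice in the probe task")
  structure(list(
    x = rbind(feature_matrix(wild_subset), feature_matrix(ref)),
    y = rep(c(1L, 0L), each = m),
    pseudo_class = pseudo_class,
    ids = ids
  ), class = "probe_task")
}

#' Train a probe classifier on a task
#'
#' Features are standardized with the task's own mean/sd (zero-variance
#' columns get unit scale so constant features degrade gracefully rather
#' than erroring). Deterministic given `seed`.
#'
#' @param task a [build_probe_task()] result.
#' @param probe a [probe_spec()].
#' @param seed integer seed for stochastic probe families.
#' @return A `fitted_probe` exposing class-1 scores via [probe_scores()].
#' @export
train_probe <- function(task, probe = probe_spec(), seed = 0L) {
  if (!all(is.finite(task$x))) stop("probe task features must be finite")
  ctr <- colMeans(task$x)
  scl <- apply(task$x, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  xs <- scale(task$x, center = ctr, scale = scl)
  entry <- get(probe$family, envir = probe_registry)
  fit <- entry$fit(xs, task$y, seed, probe$hyperparameters)
  structure(list(fit = fit, family = probe$family, center = ctr, scale = scl,
                 predict_scores = entry$predict_scores,
                 decision_threshold = entry$decision_threshold),
            class = "fitted_probe")
}

#' Score new feature vectors with a fitted probe
#'
#' @param probe a [train_probe()] result.
#' @param x feature matrix (raw scale; the probe applies its own training
#'   standardization).
#' @return numeric vector of class-1 scores.
#' @export
probe_scores <- function(probe, x) {
  xs <- scale(as.matrix(x), center = probe$center, scale = probe$scale)
  colnames(xs) <- names(probe$center)
  probe$predict_scores(probe$fit, xs)
}

#' Evaluate a fitted probe on a labelled held-out set
#'
#' @param probe a `fitted_probe`.
#' @param heldout labelled `score_table`; must contain both classes of the
#'   binary task (`positive_class` vs the rest).
#' @param metric a [metric_spec()].
#' @param positive_class which held-out class counts as positive
#'   (the probe's hypothesized class); default 1.
#' @return scalar performance inside the metric's range.
#' @export
evaluate_probe <- function(probe, heldout, metric = metric_spec(),
                           positive_class = 1) {
  if (is.null(heldout$label)) stop("held-out set must carry labels")
  y <- as.integer(heldout$label == positive_class)
  if (length(unique(y)) < 2) {
    stop("held-out set missing a class for positive_class = ", positive_class)
  }
  s <- probe_scores(probe, feature_matrix(heldout))
  perf <- metric$fn(s, y, probe$decision_threshold %||% 0.5)
  stopifnot(perf >= metric$range[1] - 1e-12, perf <= metric$range[2] + 1e-12)
  perf
}
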