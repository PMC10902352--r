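#' Stratify a score table by protected group
#'
#' Partitions deployment points by a categorical group tag (e.g. Fitzpatrick
#' skin-tone bands) ahead of a per-group discrepancy audit. Records with a
#' missing tag are routed to an `"ungrouped"` stratum with a warning rather
#' than dropped.
#'
#' @param wild a `score_table`.
#' @param group_field column holding the group tag (default `"group"`).
#' @return named list of `score_table`s; names are the group levels. At
#'   least two groups are required.
#' @export
stratify_by_group <- function(wild, group_field = "group") {
  validate_score_table(wild)
  if (!group_field %in% names(wild)) {
    stop("no column '", group_field, "' in the score table")
  }
  g <- as.character(wild[[group_field]])
  missing <- is.na(g) | g == ""
  if (any(missing)) {
    warning(sum(missing), " record(s) have no group tag; routed to 'ungrouped'",
            call. = FALSE)
    g[missing] <- "ungrouped"
  }
  levels <- unique(g)
  if (length(levels) < 2) {
    stop("only one group present ('", levels, "'); nothing to compare")
  }
  out <- lapply(levels, function(lv) {
    st <- wild[g == lv, , drop = FALSE]
    new_score_table(st)
  })
  names(out) <- levels
  out
}

#' Per-group SUDO audit
#'
#' Runs the discrepancy computation separately for each group on the same
#' grid, configuration, and seeds, so differences in the resulting values
#' reflect the data, not sampling noise. A difference in group-level
#' discrepancies indicates a higher degree of class contamination — and
#' hence poorer model performance — for one group, serving as a label-free
#' bias surrogate. A single wide interval (e.g. `(0, 0.2]` with `m = 200`
#' per group) or a full grid may be audited.
#'
#' Group/interval cells whose occupancy falls below `min_occupancy`
#' (default `2 * m`) are nulled with a warning.
#'
#' @param groups named list of `score_table`s from [stratify_by_group()].
#' @param audit_grid an [interval_grid()]; often a single interval.
#' @param reference_pool,heldout labelled score tables shared by all groups.
#' @param config a [sudo_config()]; an explicit `m` is recommended so all
#'   groups are sampled identically (`"auto"` resolves per group and warns).
#' @param min_occupancy minimum group/interval occupancy; `NULL` means
#'   `2 * m` (or `2 * resolved m` under `"auto"`).
#' @return A `group_audit`: list with `sudo` (groups x intervals matrix),
#'   `sizes`, per-group `runs`, the grid and config.
#' @export
group_sudo <- function(groups, audit_grid, reference_pool, heldout,
                       config = sudo_config(), min_occupancy = NULL) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (identical(config$m, "auto")) {
    warning("m = 'auto' resolves separately per group; ",
            "an explicit m keeps groups directly comparable", call. = FALSE)
  }
  runs <- lapply(groups, function(g) {
    suppressWarnings(
      run_sudo(g, reference_pool, heldout, grid = audit_grid, config = config)
    )
  })
  ni <- n_intervals(audit_grid)
  sudo <- matrix(unlist(lapply(runs, function(r) r$intervals$sudo)),
                 nrow = length(runs), ncol = ni, byrow = TRUE)
  occ <- matrix(unlist(lapply(runs, function(r) as.numeric(r$intervals$n))),
                nrow = length(runs), ncol = ni, byrow = TRUE)
  dimnames(sudo) <- dimnames(occ) <-
    list(names(groups), interval_labels(audit_grid))
  min_occ <- vapply(runs, function(r) {
    if (is.null(min_occupancy)) 2 * r$m else min_occupancy
  }, numeric(1))
  low <- occ < matrix(min_occ, nrow = nrow(occ), ncol = ncol(occ))
  if (any(low & !is.na(sudo))) {
    warning("group/interval cell(s) below minimum occupancy were nulled: ",
            paste(which(low & !is.na(sudo)), collapse = ", "), call. = FALSE)
    sudo[low] <- NA_real_
  }
  structure(list(sudo = sudo,
                 sizes = vapply(groups, nrow, integer(1)),
                 occupancy = occ,
                 runs = runs,
                 grid = audit_grid,
                 config = config),
            class = "group_audit")
}

#' @export
print.group_audit <- function(x, ...) {
  cat(sprintf("<group_audit: %d groups x %d interval(s)>\n",
              nrow(x$sudo), ncol(x$sudo)))
  print(round(x$sudo, 3))
  invisible(x)
}

#' Summarize group discrepancies from an audit
#'
#' For every audited interval, reports the pairwise absolute difference in
#' group-level discrepancy values, the maximum over pairs, and the
#' advantaged group per pair — the group with the larger `|sudo|`, i.e.
#' lower class contamination and hence better-served by the model.
#'
#' @param audit a [group_sudo()] result.
#' @return list with `pairwise` (data.frame of interval, pair, the two sudo
#'   values, `delta`, `advantaged`), `matrix` (per-interval symmetric
#'   discrepancy matrices), and `max_discrepancy`.
#' @export
bias_discrepancy <- function(audit) {
  sudo <- audit$sudo
  groups <- rownames(sudo)
  ok <- rowSums(!is.na(sudo)) > 0
  if (sum(ok) < 2) stop("fewer than 2 groups with non-null sudo values")
  rows <- list()
  mats <- list()
  for (j in seq_len(ncol(sudo))) {
    v <- sudo[, j]
    d <- abs(outer(v, v, `-`))
    dimnames(d) <- list(groups, groups)
    mats[[colnames(sudo)[j]]] <- d
    pairs <- utils::combn(seq_along(groups), 2)
    for (p in seq_len(ncol(pairs))) {
      g1 <- pairs[1, p]; g2 <- pairs[2, p]
      if (is.na(v[g1]) || is.na(v[g2])) next
      delta <- abs(v[g1] - v[g2])
      adv <- if (abs(v[g1]) > abs(v[g2])) {
        groups[g1]
      } else if (abs(v[g2]) > abs(v[g1])) {
        groups[g2]
      } else {
        NA_character_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        interval = colnames(sudo)[j],
        group_1 = groups[g1], group_2 = groups[g2],
        sudo_1 = unname(v[g1]), sudo_2 = unname(v[g2]),
        delta = delta, advantaged = adv,
        stringsAsFactors = FALSE)
    }
  }
  pairwise <- do.call(rbind, rows)
  list(pairwise = pairwise,
       matrix = mats,
       max_discrepancy = max(pairwise$delta))
}
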