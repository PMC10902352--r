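#' Read a score table from delimited text
#'
#' Reads a comma- or tab-delimited file (dialect auto-detected) with a
#' header into a validated `score_table`. Required columns are `id` and
#' `score`; feature columns carry an `f_` prefix; `label` and `group` are
#' optional. `schema` remaps non-standard column names, e.g.
#' `list(id = "patient", score = "prob", group = "skin_tone")`.
#'
#' Malformed rows (scores outside `[0, 1]`, non-numeric features) are
#' rejected with row-level messages, never silently dropped.
#'
#' @param path file path.
#' @param schema optional named list mapping standard names (`id`, `score`,
#'   `label`, `group`, `feature_prefix`) to the file's column names/prefix.
#' @return a `score_table`.
#' @export
read_score_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          na.strings = c("NA", ""))
  if (nrow(dt) == 0) stop("empty score table: ", path)
  rename <- function(std, default) {
    from <- schema[[std]] %||% default
    if (from %in% names(dt) && from != std) {
      names(dt)[names(dt) == from] <<- std
    }
  }
  rename("id", "id"); rename("score", "score")
  rename("label", "label"); rename("group", "group")
  prefix <- schema$feature_prefix %||% "f_"
  if (prefix != "f_") {
    hit <- startsWith(names(dt), prefix) &
      !names(dt) %in% c("id", "score", "label", "group")
    names(dt)[hit] <- paste0("f_", substring(names(dt)[hit], nchar(prefix) + 1))
  }
  for (req in c("id", "score")) {
    if (!req %in% names(dt)) {
      stop("missing required column '", req, "' in ", path)
    }
  }
  fc <- grep("^f_", names(dt), value = TRUE)
  if (length(fc) == 0) stop("no feature columns (prefix 'f_') in ", path)
  for (cc in c("score", fc)) {
    v <- suppressWarnings(as.numeric(dt[[cc]]))
    bad <- which(is.na(v) & !is.na(dt[[cc]]) | !is.finite(v))
    if (length(bad)) {
      stop("non-numeric or non-finite '", cc, "' at row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
    dt[[cc]] <- v
  }
  bad_s <- which(dt$score < 0 | dt$score > 1)
  if (length(bad_s)) {
    stop("score outside [0, 1] at row(s): ",
         paste(utils::head(bad_s, 5), collapse = ", "))
  }
  dt$id <- as.character(dt$id)
  keep <- c("id", "score", fc, intersect(c("label", "group"), names(dt)))
  dt <- dt[, keep, drop = FALSE]
  if ("label" %in% names(dt)) dt$label <- as.integer(dt$label)
  validate_score_table(new_score_table(dt))
  new_score_table(dt)
}

#' Write a score table to delimited text
#'
#' @param table a `score_table`.
#' @param path output path; `.tsv` extension selects tab, otherwise comma.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(table, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(as.data.frame(table), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

digest_of <- function(object) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(object, tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}

config_manifest <- function(config) {
  list(m = config$m, k = config$k, base_seed = config$base_seed,
       probe = list(family = config$probe$family,
                    hyperparameters = config$probe$hyperparameters),
       metric = config$metric$name, tau = config$tau)
}

config_from_manifest <- function(mc) {
  sudo_config(
    m = if (identical(mc$m, "auto")) "auto" else as.integer(mc$m),
    k = mc$k, base_seed = mc$base_seed,
    probe = do.call(probe_spec, c(list(family = mc$probe$family),
                                  mc$probe$hyperparameters)),
    metric = metric_spec(mc$metric), tau = mc$tau)
}

#' Write results and a run manifest to a directory
#'
#' Emits a plain-text tabular report plus a JSON manifest holding the
#' configuration snapshot, the resolved sample size, the full seed log,
#' warnings, package version, and content digests of the inputs — enough to
#' re-execute the run bit-identically (see [replay_run()]). Output content
#' is deterministic given deterministic inputs.
#'
#' @param result a `sudo_result`, `rc_curve`, `group_audit`, or
#'   `validation_report`.
#' @param out_dir output directory (created if needed).
#' @param inputs optional named list of the input tables (or file paths)
#'   whose digests go into the manifest.
#' @return character vector of files written, invisibly.
#' @export
write_results <- function(result, out_dir, inputs = NULL) {
  UseMethod("write_results")
}

write_manifest <- function(manifest, out_dir) {
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  path
}

input_digests <- function(inputs) {
  if (is.null(inputs)) return(NULL)
  lapply(inputs, function(x) {
    if (is.character(x) && length(x) == 1 && file.exists(x)) {
      unname(tools::md5sum(x))
    } else {
      digest_of(as.data.frame(x))
    }
  })
}

#' @export
write_results.sudo_result <- function(result, out_dir, inputs = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- file.path(out_dir, "sudo_report.tsv")
  utils::write.table(result$intervals, report, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  manifest <- list(
    kind = "sudo_result",
    package_version = as.character(utils::packageVersion("sudoeval")),
    config = config_manifest(result$config),
    resolved_m = result$m,
    mode = result$mode,
    n_classes = result$n_classes,
    grid_edges = result$grid$edges,
    seeds_used = result$seeds_used,
    warnings = result$warnings,
    input_digests = input_digests(inputs))
  mpath <- write_manifest(manifest, out_dir)
  invisible(c(report, mpath))
}

#' @export
write_results.rc_curve <- function(result, out_dir, inputs = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- file.path(out_dir, "rc_curve.tsv")
  utils::write.table(result$points, report, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  manifest <- list(
    kind = "rc_curve",
    package_version = as.character(utils::packageVersion("sudoeval")),
    aurcc = result$aurcc,
    metric = result$metric,
    wild_fingerprint = result$wild_fingerprint,
    schemes = lapply(result$schemes, function(s) list(A = s$A, B = s$B)),
    input_digests = input_digests(inputs))
  mpath <- write_manifest(manifest, out_dir)
  invisible(c(report, mpath))
}

#' @export
write_results.group_audit <- function(result, out_dir, inputs = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- data.frame(group = rownames(result$sudo),
                    size = as.integer(result$sizes),
                    result$sudo, check.names = FALSE)
  report <- file.path(out_dir, "group_audit.tsv")
  utils::write.table(tab, report, sep = "\t", row.names = FALSE, quote = FALSE)
  disc <- bias_discrepancy(result)
  dpath <- file.path(out_dir, "group_discrepancy.tsv")
  utils::write.table(disc$pairwise, dpath, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  manifest <- list(
    kind = "group_audit",
    package_version = as.character(utils::packageVersion("sudoeval")),
    config = config_manifest(result$config),
    grid_edges = result$grid$edges,
    max_discrepancy = disc$max_discrepancy,
    input_digests = input_digests(inputs))
  mpath <- write_manifest(manifest, out_dir)
  invisible(c(report, dpath, mpath))
}

#' @export
write_results.validation_report <- function(result, out_dir, inputs = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- file.path(out_dir,
                      paste0("validation_", result$scenario, ".tsv"))
  utils::write.table(result$per_interval, report, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  manifest <- list(
    kind = "validation_report",
    package_version = as.character(utils::packageVersion("sudoeval")),
    scenario = result$scenario,
    rho = result$rho, p = result$p, n = result$n,
    config = config_manifest(result$result$config),
    input_digests = input_digests(inputs))
  mpath <- write_manifest(manifest, out_dir)
  invisible(c(report, mpath))
}

#' Re-execute a run from its manifest
#'
#' Reads the configuration snapshot out of a `manifest.json` written by
#' [write_results()] and re-runs the analysis on the supplied inputs,
#' reproducing the original `sudo_result` bit-identically.
#'
#' @param manifest_path path to a `manifest.json` of kind `sudo_result`.
#' @param wild,reference_pool,heldout the original input tables.
#' @return a `sudo_result`.
#' @export
replay_run <- function(manifest_path, wild, reference_pool, heldout) {
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (!identical(manifest$kind, "sudo_result")) {
    stop("manifest is of kind '", manifest$kind, "', expected 'sudo_result'")
  }
  config <- config_from_manifest(manifest$config)
  grid <- interval_grid(edges = manifest$grid_edges)
  if (identical(manifest$mode, "multiclass")) {
    run_sudo_multiclass(wild, reference_pool, heldout, grid, config,
                        n_classes = manifest$n_classes)
  } else {
    run_sudo(wild, reference_pool, heldout, grid, config)
  }
}
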