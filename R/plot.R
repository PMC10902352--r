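#' Bar chart of per-interval discrepancies
#'
#' Bars are colour-coded by the majority-class call; unreliable intervals
#' (|sudo| below the configured cutoff) are greyed out.
#'
#' @param result a `sudo_result`.
#' @return a ggplot object.
#' @export
plot_sudo <- function(result) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_sudo() requires ggplot2")
  }
  iv <- result$intervals
  iv$status <- ifelse(is.na(iv$sudo), "skipped",
                      ifelse(!iv$reliable, "unreliable",
                             paste0("class ", iv$call)))
  ggplot2::ggplot(iv, ggplot2::aes(x = factor(interval, levels = interval),
                                   y = sudo, fill = status)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(-1, 1) * result$config$tau,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "probability interval", y = "signed discrepancy",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot one or more reliability-completeness curves
#'
#' @param ... named `rc_curve` objects (or a single one).
#' @return a ggplot object.
#' @export
plot_rc_curve <- function(...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_rc_curve() requires ggplot2")
  }
  curves <- list(...)
  if (length(curves) == 1 && is.list(curves[[1]]) &&
      !inherits(curves[[1]], "rc_curve")) {
    curves <- curves[[1]]
  }
  if (is.null(names(curves)) || any(names(curves) == "")) {
    names(curves) <- paste0("model_", seq_along(curves))
  }
  df <- do.call(rbind, lapply(names(curves), function(nm) {
    p <- curves[[nm]]$points
    data.frame(model = sprintf("%s (AURCC %.2f)", nm, curves[[nm]]$aurcc),
               completeness = p$completeness, reliability = p$reliability)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = completeness,
                                   y = reliability,
                                   colour = model)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "completeness", y = "reliability", colour = NULL) +
    ggplot2::theme_minimal()
}
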