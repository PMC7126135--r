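#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a conservation scan
#'
#' @param x A [scan_alignment()] result.
#' @param ... Unused.
#' @return A plain tibble of the per-column records.
#' @exportS3Method generics::tidy
tidy.conservation_scan <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "conservation_scan")
  attr(out, "threshold") <- NULL
  attr(out, "background_label") <- NULL
  attr(out, "n_rows") <- NULL
  out
}

#' One-row summary of a conservation scan
#'
#' @param x A [scan_alignment()] result.
#' @param ... Unused.
#' @return A tibble with `n_columns`, `n_rows`, `n_conserved`, `threshold`
#'   (bits), `background_label`, `max_g_w`.
#' @exportS3Method generics::glance
glance.conservation_scan <- function(x, ...) {
  tibble(
    n_columns = nrow(x),
    n_rows = attr(x, "n_rows"),
    n_conserved = sum(x$conserved),
    threshold = attr(x, "threshold"),
    background_label = attr(x, "background_label"),
    max_g_w = max(x$g_w, na.rm = TRUE)
  )
}

#' @export
print.conservation_scan <- function(x, ...) {
  cat("# Conservation scan: ", nrow(x), " columns, ",
      sum(x$conserved), " conserved (threshold ",
      format(attr(x, "threshold"), digits = 6), " bits, background: ",
      attr(x, "background_label"), ")\n", sep = "")
  NextMethod()
}

#' Plot per-column conservation scores
#'
#' Gap-weighted conservation score by alignment column, conserved columns
#' highlighted, with the threshold as a dashed line.
#'
#' @param object A [scan_alignment()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.conservation_scan <- function(object, ...) {
  thr <- attr(object, "threshold")
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$column, y = .data$g_w,
                               fill = .data$conserved)) +
    ggplot2::geom_col(width = 0.8, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "#b2182b"),
                               guide = "none") +
    ggplot2::labs(x = "Alignment column",
                  y = "Gap-weighted relative entropy (bits)",
                  title = "Per-column conservation",
                  subtitle = paste0("threshold = ",
                                    format(thr, digits = 6), " bits")) +
    ggplot2::theme_minimal()
}

#' Box plot of charged-residue density by group
#'
#' Mirrors the standard presentation of per-group arginine-lysine
#' frequency distributions: one box per group with the individual
#' per-sequence frequencies jittered alongside.
#'
#' @param composition A tibble with `group` and `frequency` columns (e.g.
#'   from [group_composition()]).
#' @return A ggplot object.
#' @export
plot_composition <- function(composition) {
  ggplot2::ggplot(composition,
                  ggplot2::aes(x = .data$group, y = .data$frequency)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5,
                          fill = "grey85") +
    ggplot2::geom_jitter(width = 0.12, height = 0, alpha = 0.6, size = 1) +
    ggplot2::labs(x = NULL, y = "Arginine-lysine frequency") +
    ggplot2::theme_minimal()
}
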