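#' Shift-versus-sister share pies
#'
#' One pie per shift event showing the shift-side and sister-side shares
#' of the nonsynonymous proportion (the style of per-clade comparison
#' pies on a life-form phylogeny figure).
#'
#' @param x A `shift_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_shift_pies <- function(x, ...) {
  comp <- x$comparisons
  dat <- tidyr::pivot_longer(
    select(comp, "event", "derived_state", "shift_share_pct", "sister_share_pct"),
    cols = c("shift_share_pct", "sister_share_pct"),
    names_to = "side", values_to = "share")
  dat$side <- ifelse(dat$side == "shift_share_pct", "shift", "sister")
  ggplot2::ggplot(dat, ggplot2::aes(x = "", y = .data$share, fill = .data$side)) +
    ggplot2::geom_col(width = 1, colour = "white") +
    ggplot2::coord_polar(theta = "y") +
    ggplot2::facet_wrap(~ paste0("event ", .data$event, ": ", .data$derived_state)) +
    ggplot2::labs(x = NULL, y = "share of nonsynonymous proportion (%)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.shift_comparison <- function(object, ...) plot_shift_pies(object, ...)

#' Nonsynonymous proportion against branch age
#'
#' Scatter of P = dN/(dN+dS) against branch age with per-group OLS lines
#' and confidence ribbons (ancestral versus alternative life-form state).
#'
#' @param x An `age_regression` (or a `branch_proportions` tibble, which
#'   is fit first).
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_proportion_age <- function(x, ...) {
  if (inherits(x, "branch_proportions")) x <- regression_vs_age(x)
  ggplot2::ggplot(x$data, ggplot2::aes(x = .data$age, y = .data$P,
                                       colour = .data$group)) +
    ggplot2::geom_ribbon(data = x$bands,
                         ggplot2::aes(x = .data$age, ymin = .data$lwr,
                                      ymax = .data$upr, fill = .data$group),
                         alpha = 0.2, inherit.aes = FALSE) +
    ggplot2::geom_line(data = x$bands,
                       ggplot2::aes(x = .data$age, y = .data$fit,
                                    colour = .data$group),
                       inherit.aes = FALSE) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "branch age (Ma)", y = "dN / (dN + dS)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.age_regression <- function(object, ...) plot_proportion_age(object, ...)

#' Physicochemical z-score profile
#'
#' Per-property z-scores for the radical categories (7 and 8) along the
#' sliding windows, with the |z| = 3.09 threshold marked.
#'
#' @param x A `physchem_scan`.
#' @param properties Optional property subset.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_physchem_windows <- function(x, properties = NULL, ...) {
  dat <- filter(x$window_profiles, .data$category >= 7)
  if (!is.null(properties)) dat <- filter(dat, .data$property %in% properties)
  thr <- radical_z_threshold()
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$start, y = .data$z,
                                    colour = factor(.data$category))) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = c(-thr, thr), linetype = 2) +
    ggplot2::facet_wrap(~ .data$property) +
    ggplot2::labs(x = "window start (codon)", y = "z", colour = "category") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.physchem_scan <- function(object, ...) plot_physchem_windows(object, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
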