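# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a mating-system fit
#'
#' @param x a `mating_fit` from [fit_mating_system()].
#' @param ... unused.
#' @return A tibble with columns `term`, `estimate`, `se`.
#' @method tidy mating_fit
#' @export
tidy.mating_fit <- function(x, ...) {
  dplyr::mutate(x$estimates, population = x$population,
                .before = "term")
}

#' One-row summary of a mating-system fit
#'
#' @param x a `mating_fit`.
#' @param ... unused.
#' @return A one-row tibble: log composite likelihood, convergence,
#'   iteration and sample counts.
#' @method glance mating_fit
#' @export
glance.mating_fit <- function(x, ...) {
  tibble::tibble(population = x$population, loglik = x$loglik,
                 converged = x$converged, n_iter = x$n_iter,
                 n_families = x$n_families, n_offspring = x$n_offspring,
                 n_bootstrap = x$n_bootstrap,
                 n_bootstrap_failed = x$n_bootstrap_failed)
}

#' Tidy an isolation-by-distance fit
#'
#' @param x an `ibd_fit` from [ibd_regression()].
#' @param ... unused.
#' @return A one-row tibble: `a`, `b`, `r_squared`, `p_a`, `p_b`,
#'   `mantel_p`, `n_pairs`.
#' @method tidy ibd_fit
#' @export
tidy.ibd_fit <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, r_squared = x$r_squared, p_a = x$p_a,
                 p_b = x$p_b, mantel_p = x$mantel_p, n_pairs = x$n_pairs)
}

#' Plot an isolation-by-distance fit
#'
#' Scatter of `F_st/(1-F_st)` against ln(distance) for all population pairs
#' with the fitted regression line.
#'
#' @param object an `ibd_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot ibd_fit
#' @export
autoplot.ibd_fit <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$a, slope = object$b,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "ln(geographical distance, km)",
      y = expression(F[st] / (1 - F[st])),
      subtitle = sprintf("slope b = %.3f, R² = %.3f%s", object$b,
                         object$r_squared,
                         if (!is.na(object$mantel_p))
                           sprintf(", Mantel p = %.3g", object$mantel_p)
                         else "")) +
    ggplot2::theme_minimal()
}

#' Plot mating-system estimates with bootstrap error bars
#'
#' @param object a `mating_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot mating_fit
#' @export
autoplot.mating_fit <- function(object, ...) {
  d <- object$estimates
  d$term <- factor(d$term, levels = rev(d$term))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$estimate - 2 * .data$se,
                   xmax = .data$estimate + 2 * .data$se),
      height = 0.2, na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = "estimate (± 2 SE)", y = NULL,
                  subtitle = paste("population", object$population)) +
    ggplot2::theme_minimal()
}

#' Heatmap of pairwise F_st
#'
#' @param fst_pairs tibble from [pairwise_fst()].
#' @return A ggplot object.
#' @export
plot_pairwise_fst <- function(fst_pairs) {
  d <- dplyr::bind_rows(
    fst_pairs,
    dplyr::rename(fst_pairs, pop1 = "pop2", pop2 = "pop1"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pop1, y = .data$pop2,
                                  fill = .data$fst)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = expression(F[st])) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
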