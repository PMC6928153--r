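#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_hline
#'   geom_vline scale_x_log10 scale_y_log10 labs theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot an ensemble-mean order-parameter curve
#'
#' Log-log growth/decay curve of `<R(t)>`.
#'
#' @param object a `kuramoto_ensemble`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.kuramoto_ensemble <- function(object, ...) {
  df <- object$mean_R[!is.na(object$mean_R$mean_R), ]
  ggplot(df, aes(x = .data$t, y = .data$mean_R)) +
    geom_line() +
    geom_point(size = 0.8) +
    geom_hline(yintercept = object$threshold, linetype = "dashed") +
    scale_x_log10() + scale_y_log10() +
    labs(x = "t", y = "⟨R(t)⟩",
         title = sprintf("K = %.4g, %d realizations",
                         object$config$coupling_K, object$n_realizations)) +
    theme_minimal()
}

#' Plot a duration histogram
#'
#' Log-log first-passage density `p(t_x)`, optionally with a fitted tail.
#'
#' @param object a `duration_histogram`.
#' @param fit optional `exponent_fit` from [fit_tail()] to overlay.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.duration_histogram <- function(object, fit = NULL, ...) {
  df <- object$bins[object$bins$count > 0, ]
  p <- ggplot(df, aes(x = .data$center, y = .data$density)) +
    geom_point() +
    scale_x_log10() + scale_y_log10() +
    labs(x = "t_x", y = "p(t_x)") +
    theme_minimal()
  if (!is.null(fit)) {
    sel <- df$center >= fit$fit_window[1] & df$center <= fit$fit_window[2]
    ref <- df[sel, ]
    anchor <- stats::median(log(ref$density) + fit$exponent * log(ref$center))
    p <- p + geom_line(
      data = tibble(center = ref$center,
                    density = exp(anchor - fit$exponent * log(ref$center))),
      aes(x = .data$center, y = .data$density),
      linetype = "dashed", colour = "red")
  }
  p
}

#' Plot effective-exponent series against inverse time
#'
#' The standard criticality diagnostic: one curve per coupling, flat at
#' `K_c`, veering up (supercritical) or down (subcritical) as `1/t -> 0`.
#'
#' @param eta_family stacked [effective_exponent()] tibbles.
#' @return a ggplot.
#' @export
plot_effective_exponent <- function(eta_family) {
  df <- eta_family[is.finite(eta_family$eta_eff), ]
  ggplot(df, aes(x = .data$inv_t, y = .data$eta_eff,
                 colour = factor(.data$K), group = factor(.data$K))) +
    geom_line() +
    labs(x = "1/t", y = expression(eta[eff]), colour = "K") +
    theme_minimal()
}

#' @rdname locate_transition
#' @param object a `transition_estimate`.
#' @export
autoplot.transition_estimate <- function(object, ...) {
  ggplot(object$trends, aes(x = .data$K, y = .data$trend)) +
    geom_point() + geom_line() +
    geom_hline(yintercept = 0, linetype = "dashed") +
    geom_vline(xintercept = object$K_c, colour = "red",
               linetype = "dotted") +
    labs(x = "K", y = "late-time trend of η_eff") +
    theme_minimal()
}

#' @rdname topological_dimension
#' @param object a `dimension_fit`.
#' @export
autoplot.dimension_fit <- function(object, ...) {
  df <- object$shells[object$shells$mean_cumulative > 0, ]
  ggplot(df, aes(x = .data$r, y = .data$mean_cumulative)) +
    geom_point() +
    scale_x_log10() + scale_y_log10() +
    geom_vline(xintercept = object$fit_window, linetype = "dotted") +
    labs(x = "r", y = "⟨N_r⟩ (cumulative)",
         title = sprintf("d = %.2f", object$d_estimate)) +
    theme_minimal()
}
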