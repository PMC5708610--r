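#' Plot the symmetric equilibrium curve
#'
#' Draws the branch of the totally mixed equilibrium conic that intersects
#' the unit square of `(alpha, gamma)` — tolerance to defection against
#' reciprocal cooperation — optionally with empirical session points and the
#' maximum-tolerance point that separates the low- and high-cooperation
#' segments.
#'
#' @param points Optional data frame with columns `alpha` and `gamma` (and
#'   optionally `stage`, mapped to colour), e.g. the `deviations` element of
#'   [run_full_analysis()] renamed, or [estimate_strategy()] output with
#'   `alpha_hat`/`gamma_hat` renamed.
#' @param payoffs A [pd_payoffs()] object.
#' @param show_max_tolerance Mark the [max_tolerance_point()].
#' @param n Number of curve evaluation points.
#'
#' @return A ggplot object.
#' @examples
#' plot_equilibrium_curve()
#' @export
plot_equilibrium_curve <- function(points = NULL, payoffs = pd_payoffs(),
                                   show_max_tolerance = TRUE, n = 400) {
  payoffs <- as_pd_payoffs(payoffs)
  cc <- curve_coefs(payoffs)
  # the in-square branch spans the gammas where the constant term of the
  # alpha-quadratic is nonpositive (1/9 <= gamma <= 1 for default payoffs)
  disc <- (cc$qg)^2 - 4 * cc$qg2 * cc$q0
  g_lo <- (-cc$qg - sqrt(disc)) / (2 * cc$qg2)
  gamma <- seq(g_lo, 1, length.out = n)
  curve <- tibble(gamma = gamma,
                  alpha = curve_alpha_given_gamma(gamma, payoffs))
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$alpha, y = .data$gamma)) +
    ggplot2::geom_path(linewidth = 0.7) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = expression("tolerance to defection" ~ alpha),
      y = expression("reciprocal cooperation" ~ gamma),
      title = "Symmetric totally mixed equilibria in memory-one strategies"
    ) +
    ggplot2::theme_minimal()
  if (show_max_tolerance) {
    mt <- max_tolerance_point(payoffs)
    p <- p + ggplot2::geom_point(data = mt, shape = 4, size = 3, stroke = 1.2)
  }
  if (!is.null(points)) {
    points <- as_tibble(points)
    if ("stage" %in% names(points)) {
      p <- p + ggplot2::geom_point(
        data = points,
        ggplot2::aes(colour = .data$stage), size = 2
      ) +
        ggplot2::labs(colour = "stage")
    } else {
      p <- p + ggplot2::geom_point(data = points, size = 2)
    }
  }
  p
}

#' @rdname run_full_analysis
#' @param object A `coopeq_report` object.
#' @export
autoplot.coopeq_report <- function(object, ...) {
  dev <- object$deviations |>
    dplyr::arrange(dplyr::desc(.data$deviation_pct)) |>
    dplyr::mutate(rank = dplyr::row_number())
  ggplot2::ggplot(dev, ggplot2::aes(x = .data$rank, y = .data$deviation_pct,
                                    fill = .data$stage)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$params$small_loss_pct,
                        linetype = "dashed") +
    ggplot2::labs(
      x = "session-stage points, ordered by deviation",
      y = "payoff deviation from equilibrium (%)",
      fill = "stage",
      title = "Epsilon-equilibrium payoff deviations"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname fit_lambda_tg
#' @param object A `tg_qre_fit` object.
#' @param lambda_grid Precision values tracing the forecast path.
#' @export
autoplot.tg_qre_fit <- function(object, lambda_grid = seq(0, 0.6, by = 0.01), ...) {
  path <- forecast_trust_gratefulness(lambda_grid)
  obs <- tibble(trust = object$trust, gratefulness = object$gratefulness,
                what = "observed")
  fit <- tibble(trust = object$trust_fit, gratefulness = object$gratefulness_fit,
                what = "fitted forecast")
  ggplot2::ggplot(path, ggplot2::aes(x = .data$trust, y = .data$gratefulness)) +
    ggplot2::geom_path(colour = "grey50") +
    ggplot2::geom_point(data = dplyr::bind_rows(obs, fit),
                        ggplot2::aes(shape = .data$what), size = 3) +
    ggplot2::labs(
      x = "average trust", y = "average gratefulness", shape = NULL,
      title = sprintf("Trust Game QRE forecast path (fitted lambda = %.3f)",
                      object$lambda)
    ) +
    ggplot2::theme_minimal()
}
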