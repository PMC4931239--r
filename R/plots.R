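#' Plot a mean-field degree distribution
#'
#' Bar plot of the stationary degree distribution, optionally overlaid
#' with an empirical degree histogram (e.g. pooled over simulated
#' replicate networks).
#'
#' @param object a [stationary_degree_distribution()] result.
#' @param empirical optional integer vector of observed degrees to
#'   overlay as a normalised histogram.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.si_meanfield <- function(object, empirical = NULL, ...) {
  df <- object$distribution
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$d, y = .data$phi)) +
    ggplot2::geom_col(fill = "grey40", width = 0.9) +
    ggplot2::labs(x = "degree", y = expression(phi[d]),
                  title = sprintf("Mean-field degree distribution (p_n = %g, p_r = %g)",
                                  object$params$p_n, object$params$p_r)) +
    ggplot2::theme_minimal()
  if (!is.null(empirical)) {
    emp <- as.data.frame(table(factor(empirical, levels = df$d)))
    emp$d <- as.integer(as.character(emp$Var1))
    emp$phi <- emp$Freq / sum(emp$Freq)
    p <- p + ggplot2::geom_point(data = emp, colour = "firebrick", size = 1.2)
  }
  p
}

#' Plot an assortativity experiment
#'
#' Observed versus trait-shuffled assortativity across replicates.
#'
#' @param object an [assortativity_experiment()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.si_assort_experiment <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("r", "r_null"),
                              names_to = "which", values_to = "value")
  long$which <- ifelse(long$which == "r", "model", "shuffled")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$which, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "assortativity coefficient") +
    ggplot2::theme_minimal()
}

#' Plot a heritability experiment
#'
#' Distribution of offspring-on-mother centrality regression slopes as
#' a function of the social-inheritance probability.
#'
#' @param object a [heritability_experiment()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.si_herit_experiment <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$p_n), y = .data$slope)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = expression(p[n]), y = "offspring ~ mother slope") +
    ggplot2::theme_minimal()
}

#' Plot a population-size trajectory
#'
#' @param object a [simulate_varying_size()] trajectory.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.si_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$step, y = .data$size)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "birth-death step", y = "population size") +
    ggplot2::theme_minimal()
}
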