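# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Posterior of the headline slope of a transfer sub-model
#'
#' @param object An `audience_size_fit`, `audience_comp_fit` or
#'   `transfer_choice_fit`.
#' @param interval_mass Shaded credible-interval mass (default 0.89).
#' @param ... Unused.
#' @return A ggplot: posterior density with median and equal-tailed
#'   interval marked.
#' @export
autoplot.transfer_fit <- function(object, interval_mass = 0.89, ...) {
  d <- object$draws[[object$slope]]
  s <- summarize_posterior(d, interval_mass)
  ggplot2::ggplot(tibble::tibble(draw = d), ggplot2::aes(x = .data$draw)) +
    ggplot2::geom_density(fill = "grey85") +
    ggplot2::geom_vline(xintercept = s$median, linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = c(s$lower, s$upper), linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, colour = "red", alpha = 0.5) +
    ggplot2::labs(
      x = object$slope, y = "posterior density",
      title = sprintf(
        "%s: median %.2f, %d%% CI [%.2f, %.2f]",
        object$slope, s$median, round(100 * interval_mass), s$lower, s$upper
      )
    ) +
    ggplot2::theme_minimal()
}

#' Predicted transfer-type probabilities by shared social level
#'
#' @param object An `ordinal_fit` whose fixed effects include
#'   `social_level`.
#' @param ... Unused.
#' @return A ggplot of population-level category probabilities
#'   (random effects at 0, sexes at female/female).
#' @export
autoplot.ordinal_fit <- function(object, ...) {
  levels3 <- c("same_unit_same_party", "diff_unit_same_party", "diff_unit_diff_party")
  nd <- tibble::tibble(
    social_level = factor(levels3, levels = levels3),
    possessor_sex = 0, recipient_sex = 0
  )
  pr <- predict(object, nd)
  cats <- c("steal", "scavenge/succeed", "share")[seq_len(ncol(pr))]
  long <- tibble::tibble(
    social_level = rep(nd$social_level, times = ncol(pr)),
    type = factor(rep(cats, each = nrow(nd)), levels = cats),
    probability = as.numeric(pr)
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$social_level, y = .data$probability, fill = .data$type
  )) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(
      x = "shared social level", y = "predicted probability",
      title = "Transfer-type tolerance across social levels"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))
}

#' Choice probability versus affinity for small audiences
#'
#' Illustrates the softmax choice rule: the probability that an audience
#' member with affinity `a` receives meat when the remaining members sit
#' at affinity 0, for audiences of size 2 and 3.
#'
#' @param slope Affinity slope (e.g. the posterior median of `b_affi`).
#' @param affinity_range Range of affinities displayed.
#' @return A ggplot.
#' @export
plot_choice_curve <- function(slope, affinity_range = c(-2.5, 2.5)) {
  a <- seq(affinity_range[1], affinity_range[2], length.out = 121)
  d <- dplyr::bind_rows(lapply(c(2, 3), function(n) {
    tibble::tibble(
      affinity = a,
      audience_size = factor(n),
      probability = vapply(
        a, function(x) choice_probs(c(x, rep(0, n - 1)), slope)[1], 0
      )
    )
  }))
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$affinity, y = .data$probability,
    colour = .data$audience_size
  )) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 3) +
    ggplot2::labs(
      x = "affinity with possessor", y = "P(receives meat)",
      colour = "audience size",
      title = sprintf("Softmax choice rule, slope = %.2f", slope)
    ) +
    ggplot2::theme_minimal()
}
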