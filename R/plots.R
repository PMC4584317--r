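# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_errorbar
#'   geom_col geom_tile labs theme_minimal scale_fill_gradient2
#'   position_dodge facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot a familial correlation table
#'
#' Point (+/- 1.96 SE when available) display of the tetrachoric
#' correlation per relative-pair class, in canonical class order.
#'
#' @param object A [family_correlations()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot kinliab_fam_cor
#' @export
autoplot.kinliab_fam_cor <- function(object, ...) {
  d <- as_tibble(object)
  d$class <- factor(d$class, levels = PAIR_CLASSES)
  p <- ggplot(d, aes(x = .data$class, y = .data$r)) +
    geom_point(size = 2) +
    labs(x = NULL, y = "tetrachoric correlation",
         title = attr(object, "trait") %||% NULL) +
    theme_minimal()
  if (all(is.finite(d$se))) {
    p <- p + geom_errorbar(aes(ymin = .data$r - 1.96 * .data$se,
                               ymax = .data$r + 1.96 * .data$se),
                           width = 0.2)
  }
  p
}

#' Plot fitted variance components
#'
#' Stacked per-sex decomposition of the liability variance from a model
#' fit.
#'
#' @param object A `kinliab_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot kinliab_fit
#' @export
autoplot.kinliab_fit <- function(object, ...) {
  vc <- object$estimates
  d <- tibble(
    sex = rep(c("male", "female"), each = 3),
    component = factor(rep(c("A", if (object$spec$variant == "ACE") "C"
                             else "D", "E"), 2),
                       levels = c("A", "D", "C", "E")),
    value = c(vc$Am, vc$Dm + vc$Cm, vc$Em, vc$Af, vc$Df + vc$Cf, vc$Ef)
  )
  ggplot(d, aes(x = .data$sex, y = .data$value, fill = .data$component)) +
    geom_col() +
    labs(x = NULL, y = "proportion of liability variance",
         title = sprintf("%s model (%s fit)", object$spec$variant,
                         object$method)) +
    theme_minimal()
}

#' Plot observed versus model-implied pair correlations
#'
#' @param fit A `kinliab_fit` from [fit_wls()].
#' @return A ggplot.
#' @export
plot_fit_correlations <- function(fit) {
  d <- fit$fitted
  d$class <- factor(d$class, levels = PAIR_CLASSES)
  d <- tidyr::pivot_longer(d, c("observed", "expected"),
                           names_to = "which", values_to = "r")
  ggplot(d, aes(x = .data$class, y = .data$r, colour = .data$which)) +
    geom_point(position = position_dodge(width = 0.4), size = 2) +
    labs(x = NULL, y = "pair correlation", colour = NULL) +
    theme_minimal()
}

#' Heatmap of a genetic relationship matrix
#'
#' @param object A `kinliab_grm`.
#' @param max_n Downsample to at most this many individuals for display.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot kinliab_grm
#' @export
autoplot.kinliab_grm <- function(object, max_n = 200, ...) {
  n <- length(object$ids)
  idx <- if (n > max_n) round(seq(1, n, length.out = max_n)) else seq_len(n)
  A <- object$mat[idx, idx]
  d <- tibble(
    i = rep(seq_along(idx), times = length(idx)),
    j = rep(seq_along(idx), each = length(idx)),
    value = as.vector(A)
  )
  ggplot(d, aes(x = .data$i, y = .data$j, fill = .data$value)) +
    geom_tile() +
    scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick",
                         midpoint = 0) +
    labs(x = NULL, y = NULL, fill = "relatedness") +
    theme_minimal()
}
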