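#' Liability-threshold arithmetic
#'
#' Under the liability-threshold model a binary trait is the dichotomisation
#' of an unobserved standard-normal liability. A trait with prevalence K
#' corresponds to a threshold t with `pnorm(t) == K`: an individual is a
#' *case* when their liability falls **below** the threshold, so a larger
#' threshold means a more common trait (threshold 0 gives prevalence 0.50,
#' threshold 1 gives ~84%, threshold -1 gives ~16%). This orientation follows
#' the twin-modelling convention for prevalence-threshold tables; it is the
#' mirror image of the "affected above threshold" convention sometimes used
#' elsewhere, and is applied consistently across the package (in particular
#' by the pedigree simulator).
#'
#' @param prevalence Trait prevalence, strictly between 0 and 1.
#' @param threshold Finite threshold on the standard-normal liability scale.
#' @return `prevalence_to_threshold()` returns the threshold (a numeric
#'   scalar or vector); `threshold_to_prevalence()` returns the prevalence.
#' @examples
#' prevalence_to_threshold(0.5)
#' threshold_to_prevalence(1) # ~0.84
#' prevalence_to_threshold(0.394) # blond hair in the Dutch cohort
#' @export
prevalence_to_threshold <- function(prevalence) {
  if (!is.numeric(prevalence) || any(!is.finite(prevalence)) ||
      any(prevalence <= 0) || any(prevalence >= 1)) {
    abort("`prevalence` must lie strictly between 0 and 1.",
          class = "kinliab_domain_error")
  }
  qnorm(prevalence)
}

#' @rdname prevalence_to_threshold
#' @export
threshold_to_prevalence <- function(threshold) {
  if (!is.numeric(threshold) || any(!is.finite(threshold))) {
    abort("`threshold` must be finite.", class = "kinliab_domain_error")
  }
  pnorm(threshold)
}

# Standard bivariate-normal CDF P(X < h, Y < k) with correlation r,
# vectorised over (h, k) for a common r. Deterministic quadrature of the
# angular (Sheppard/Owen) representation
#   P = Phi(h) Phi(k) + (1/2pi) int_0^{asin r}
#         exp(-(h^2 - 2 h k sin t + k^2) / (2 cos^2 t)) dt,
# whose integrand stays smooth as |r| -> 1; 64 Gauss-Legendre nodes give
# absolute accuracy well below 1e-10. |r| = 1 uses the comonotone /
# countermonotone limits.
pbinorm <- function(h, k, r) {
  stopifnot(length(r) == 1)
  if (!is.finite(r) || abs(r) > 1) {
    abort("correlation must lie in [-1, 1].", class = "kinliab_domain_error")
  }
  if (r == 0) return(pnorm(h) * pnorm(k))
  if (r >= 1 - 1e-12) return(pnorm(pmin(h, k)))
  if (r <= -1 + 1e-12) return(pmax(0, pnorm(h) + pnorm(k) - 1))
  gl <- pracma::gaussLegendre(64, 0, asin(r))
  acc <- 0
  for (j in seq_along(gl$x)) {
    st <- sin(gl$x[j])
    c2 <- cos(gl$x[j])^2
    acc <- acc + gl$w[j] * exp(-(h^2 - 2 * h * k * st + k^2) / (2 * c2))
  }
  pmin(1, pmax(0, pnorm(h) * pnorm(k) + acc / (2 * pi)))
}

#' Bivariate-normal orthant (cell) probabilities
#'
#' Probabilities of the four cells of a 2x2 table implied by two thresholds
#' on a standard bivariate-normal liability with correlation `r`. Cell `p11`
#' is the probability that both members are cases (both liabilities below
#' their thresholds), `p10` that only the first is, and so on. This is the
#' kernel of the tetrachoric likelihood.
#'
#' @param t1,t2 Thresholds for the two members.
#' @param r Liability correlation in `[-1, 1]`.
#' @return A tibble with one row and columns `p11`, `p10`, `p01`, `p00`
#'   (summing to 1; margins equal `pnorm(t1)` and `pnorm(t2)`).
#' @examples
#' bivariate_orthant(0, 0, 0.5) # p11 = 1/4 + asin(0.5)/(2*pi) = 1/3
#' @export
bivariate_orthant <- function(t1, t2, r) {
  if (!is.finite(t1) || !is.finite(t2)) {
    abort("thresholds must be finite.", class = "kinliab_domain_error")
  }
  if (!is.finite(r) || abs(r) > 1) {
    abort("correlation must lie in [-1, 1].", class = "kinliab_domain_error")
  }
  p11 <- pbinorm(t1, t2, r)
  p1. <- pnorm(t1)
  p.1 <- pnorm(t2)
  p10 <- max(0, p1. - p11)
  p01 <- max(0, p.1 - p11)
  p00 <- max(0, 1 - p11 - p10 - p01)
  tibble(p11 = p11, p10 = p10, p01 = p01, p00 = p00)
}
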