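# Shared fixtures and small oracles for the suite.

# Published variance components for blond hair (sex-specific ADE with
# assortment): the canonical "truth" for recovery tests.
blond_vc <- function() {
  variance_components(Am = 0.39, Dm = 0.57, Em = 0.04,
                      Af = 0.73, Df = 0.24, Ef = 0.03, mu = 0.210)
}

published_correlations <- function() {
  read_correlation_table(
    system.file("extdata", "hair_color_family_correlations.tsv",
                package = "kinliab"))
}

# bivariate normal density (for information-based SEs in oracles)
phi2 <- function(t1, t2, r) {
  exp(-(t1^2 - 2 * r * t1 * t2 + t2^2) / (2 * (1 - r^2))) /
    (2 * pi * sqrt(1 - r^2))
}

# model correlation matrix of a family assembled directly from the
# pair-class formulas (independent of the factor decomposition used by
# fit_ml). members: tibble(role, sex) with sex "m"/"f".
family_cor_from_formulas <- function(members, vc) {
  r <- expected_pair_vec_oracle(vc)
  k <- nrow(members)
  R <- diag(k)
  class_of <- function(i, j) {
    ri <- members$role[i]; rj <- members$role[j]
    si <- members$sex[i]; sj <- members$sex[j]
    par <- c("father", "mother")
    if (ri %in% par && rj %in% par) return("spouse")
    if (ri %in% par || rj %in% par) {
      p <- if (ri %in% par) i else j
      o <- if (ri %in% par) j else i
      return(paste0(ifelse(members$role[p] == "father", "F", "M"),
                    ifelse(members$sex[o] == "m", "S", "D")))
    }
    mz <- c("MZ1", "MZ2")
    if (ri %in% mz && rj %in% mz) {
      return(if (si == "m") "MZM" else "MZF")
    }
    # everything else behaves as full sibs
    if (si != sj) return("DOS")
    if (si == "m") "DZM" else "DZF"
  }
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    R[i, j] <- R[j, i] <- r[[class_of(i, j)]]
  }
  R
}

# an independent re-statement of the expected-correlation algebra, written
# out long-hand (kept separate from the package's vectorised version)
expected_pair_vec_oracle <- function(vc) {
  a_m <- sqrt(vc$Am); a_f <- sqrt(vc$Af)
  rhoA <- vc$mu * a_m * a_f
  po <- function(ax, axbar, ay) 0.5 * ay * (ax + vc$mu * axbar)
  list(
    spouse = vc$mu,
    FS = po(a_m, a_f, a_m), FD = po(a_m, a_f, a_f),
    MS = po(a_f, a_m, a_m), MD = po(a_f, a_m, a_f),
    MZM = vc$Am + vc$Dm + vc$Cm,
    MZF = vc$Af + vc$Df + vc$Cf,
    DZM = 0.5 * vc$Am * (1 + rhoA) + 0.25 * vc$Dm + vc$Cm,
    DZF = 0.5 * vc$Af * (1 + rhoA) + 0.25 * vc$Df + vc$Cf,
    DOS = 0.5 * a_m * a_f * (1 + rhoA) +
      0.25 * sqrt(vc$Dm * vc$Df) + sqrt(vc$Cm * vc$Cf)
  )
}

# random valid variance components on the per-sex simplex
random_vc <- function(variant = "ADE", mu_max = 0.5) {
  draw <- function() {
    x <- -log(runif(3))
    x / sum(x)
  }
  pm <- draw(); pf <- draw()
  mu <- runif(1, -mu_max, mu_max)
  if (variant == "ADE") {
    variance_components(Am = pm[1], Dm = pm[2], Em = pm[3],
                        Af = pf[1], Df = pf[2], Ef = pf[3], mu = mu)
  } else if (variant == "ACE") {
    variance_components(Am = pm[1], Cm = pm[2], Em = pm[3],
                        Af = pf[1], Cf = pf[2], Ef = pf[3], mu = mu)
  } else {
    variance_components(Am = pm[1], Em = 1 - pm[1],
                        Af = pf[1], Ef = 1 - pf[1], mu = mu)
  }
}

# couples-only composition (spouse pairs), used by assortment tests
couples_only <- function() {
  tibble::tibble(twin_type = "none", n_sibs = 0L,
                 include_parents = TRUE, weight = 1)
}
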