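#' Specify a twin-family variance-components model
#'
#' @param variant `"ADE"` (additive + dominance + unique environment),
#'   `"ACE"` (additive + shared environment + unique environment) or `"AE"`.
#' @param sex_limitation Quantitative sex limitation: if `TRUE`, variance
#'   proportions are sex-specific (the cross-sex genetic correlation is fixed
#'   at 1 either way).
#' @param assortment If `TRUE`, a spousal liability correlation `mu`
#'   (phenotypic assortative mating) is part of the model.
#' @param covariates Character vector of threshold covariates for ML fitting
#'   (e.g. `"age_z"`, `"pc1"`); ignored by WLS.
#' @param estimation Default estimation method, `"WLS"` or `"ML"`.
#' @return An object of class `kinliab_model_spec`.
#' @export
#' @examples
#' model_spec("ADE", sex_limitation = TRUE, assortment = TRUE)
model_spec <- function(variant = c("ADE", "ACE", "AE"),
                       sex_limitation = TRUE,
                       assortment = TRUE,
                       covariates = character(),
                       estimation = c("WLS", "ML")) {
  variant <- match.arg(variant)
  estimation <- match.arg(estimation)
  structure(
    list(variant = variant,
         sex_limitation = isTRUE(sex_limitation),
         assortment = isTRUE(assortment),
         covariates = as.character(covariates),
         estimation = estimation),
    class = "kinliab_model_spec"
  )
}

#' @export
print.kinliab_model_spec <- function(x, ...) {
  cat(sprintf("<%s model: sex limitation %s, assortment %s%s>\n",
              x$variant,
              if (x$sex_limitation) "on" else "off",
              if (x$assortment) "on" else "off",
              if (length(x$covariates))
                paste0(", covariates: ", paste(x$covariates, collapse = ", "))
              else ""))
  invisible(x)
}

#' Sex-specific liability variance components
#'
#' Proportions of liability variance per sex: additive (`Am`, `Af`),
#' dominance (`Dm`, `Df`) or shared environment (`Cm`, `Cf`), unique
#' environment (`Em`, `Ef`), plus the spousal liability correlation `mu`
#' (the assortative-mating coefficient). Each sex's components must sum to 1.
#'
#' @param Am,Dm,Cm,Em Male proportions.
#' @param Af,Df,Cf,Ef Female proportions (default to the male values).
#' @param mu Spousal liability correlation, in `(-1, 1)`.
#' @return An object of class `kinliab_vc`.
#' @export
#' @examples
#' # Blond hair, sex-specific ADE with assortment:
#' variance_components(Am = 0.39, Dm = 0.57, Em = 0.04,
#'                     Af = 0.73, Df = 0.24, Ef = 0.03, mu = 0.210)
variance_components <- function(Am, Dm = 0, Cm = 0, Em,
                                Af = Am, Df = Dm, Cf = Cm, Ef = Em,
                                mu = 0) {
  vals <- c(Am = Am, Dm = Dm, Cm = Cm, Em = Em,
            Af = Af, Df = Df, Cf = Cf, Ef = Ef)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1)) {
    abort("variance proportions must lie in [0, 1].",
          class = "kinliab_domain_error")
  }
  if (abs(Am + Dm + Cm + Em - 1) > 1e-8 || abs(Af + Df + Cf + Ef - 1) > 1e-8) {
    abort("components must sum to 1 within each sex.",
          class = "kinliab_domain_error")
  }
  if (Dm > 0 && Cm > 0) {
    abort("D and C are not jointly identifiable; supply one of them.",
          class = "kinliab_domain_error")
  }
  if (!is.finite(mu) || abs(mu) >= 1) {
    abort("`mu` must lie strictly inside (-1, 1).",
          class = "kinliab_domain_error")
  }
  structure(list(Am = Am, Dm = Dm, Cm = Cm, Em = Em,
                 Af = Af, Df = Df, Cf = Cf, Ef = Ef, mu = mu),
            class = "kinliab_vc")
}

#' @export
print.kinliab_vc <- function(x, ...) {
  cat(sprintf("males:   A = %.3f  D = %.3f  C = %.3f  E = %.3f\n",
              x$Am, x$Dm, x$Cm, x$Em))
  cat(sprintf("females: A = %.3f  D = %.3f  C = %.3f  E = %.3f\n",
              x$Af, x$Df, x$Cf, x$Ef))
  cat(sprintf("spousal correlation mu = %.3f\n", x$mu))
  invisible(x)
}

#' @method tidy kinliab_vc
#' @export
tidy.kinliab_vc <- function(x, ...) {
  tibble(term = c("Am", "Dm", "Cm", "Em", "Af", "Df", "Cf", "Ef", "mu"),
         estimate = unlist(x, use.names = FALSE))
}

check_vc_spec <- function(vc, spec) {
  if (spec$variant %in% c("ACE", "AE") && (vc$Dm > 0 || vc$Df > 0)) {
    abort(sprintf("dominance components supplied under the %s model.",
                  spec$variant), class = "kinliab_spec_error")
  }
  if (spec$variant %in% c("ADE", "AE") && (vc$Cm > 0 || vc$Cf > 0)) {
    abort(sprintf("shared-environment components supplied under the %s model.",
                  spec$variant), class = "kinliab_spec_error")
  }
  if (!spec$assortment && vc$mu != 0) {
    abort("nonzero `mu` supplied with assortment off.",
          class = "kinliab_spec_error")
  }
  invisible(TRUE)
}

# Named vector of expected correlations over the 13 pair classes.
expected_pair_vec <- function(vc) {
  a_m <- sqrt(vc$Am); a_f <- sqrt(vc$Af)
  d_m <- sqrt(vc$Dm); d_f <- sqrt(vc$Df)
  c_m <- sqrt(vc$Cm); c_f <- sqrt(vc$Cf)
  mu <- vc$mu
  rhoA <- mu * a_m * a_f # parental additive correlation under assortment
  c(
    spouse = mu,
    FS = 0.5 * a_m * (a_m + mu * a_f),
    FD = 0.5 * a_f * (a_m + mu * a_f),
    MS = 0.5 * a_m * (a_f + mu * a_m),
    MD = 0.5 * a_f * (a_f + mu * a_m),
    MZM = vc$Am + vc$Dm + vc$Cm,
    MZF = vc$Af + vc$Df + vc$Cf,
    DZM = 0.5 * vc$Am * (1 + rhoA) + 0.25 * vc$Dm + vc$Cm,
    DZF = 0.5 * vc$Af * (1 + rhoA) + 0.25 * vc$Df + vc$Cf,
    DOS = 0.5 * a_m * a_f * (1 + rhoA) + 0.25 * d_m * d_f + c_m * c_f,
    BB = 0.5 * vc$Am * (1 + rhoA) + 0.25 * vc$Dm + vc$Cm,
    SS = 0.5 * vc$Af * (1 + rhoA) + 0.25 * vc$Df + vc$Cf,
    BS = 0.5 * a_m * a_f * (1 + rhoA) + 0.25 * d_m * d_f + c_m * c_f
  )
}

#' Expected relative-pair liability correlations
#'
#' Model-implied correlations for the 13 relative-pair classes under a
#' sex-specific ADE/ACE/AE decomposition with single-generation phenotypic
#' assortative mating. Writing `a_s = sqrt(A_s)` etc. and the parental
#' additive correlation `rho_A = mu * a_m * a_f`:
#' * spouse: `mu`;
#' * MZ twins (sex s): `A_s + D_s` (or `+ C_s`);
#' * same-sex DZ twins / siblings: `0.5 A_s (1 + rho_A) + 0.25 D_s` (`+ C_s`);
#' * opposite-sex DZ / siblings:
#'   `0.5 a_m a_f (1 + rho_A) + 0.25 d_m d_f` (`+ c_m c_f`);
#' * parent of sex x, offspring of sex y: `0.5 a_y (a_x + mu a_xbar)` with
#'   `xbar` the other parent's sex (D and C are not shared across
#'   generations).
#'
#' @param vc A [variance_components()] object.
#' @param spec A [model_spec()]; used to validate that `vc` matches the
#'   model variant.
#' @return A tibble with columns `class` and `r`.
#' @export
#' @examples
#' vc <- variance_components(Am = 0.39, Dm = 0.57, Em = 0.04,
#'                           Af = 0.73, Df = 0.24, Ef = 0.03, mu = 0.210)
#' expected_pair_correlations(vc, model_spec("ADE"))
expected_pair_correlations <- function(vc, spec = model_spec("ADE")) {
  check_vc_spec(vc, spec)
  r <- expected_pair_vec(vc)
  stopifnot(all(abs(r) <= 1 + 1e-12))
  tibble(class = names(r), r = pmin(1, pmax(-1, unname(r))))
}

#' Heritability from variance components
#'
#' Broad-sense heritability `A + D` under the ADE model; narrow-sense
#' heritability `A` under ACE and AE.
#'
#' @inheritParams expected_pair_correlations
#' @return A tibble with columns `sex` (`"m"`, `"f"`) and `h2`.
#' @export
#' @examples
#' heritability(variance_components(Am = 0.39, Dm = 0.57, Em = 0.04,
#'                                  Af = 0.73, Df = 0.24, Ef = 0.03,
#'                                  mu = 0.210),
#'              model_spec("ADE")) # 0.96, 0.97
heritability <- function(vc, spec = model_spec("ADE")) {
  check_vc_spec(vc, spec)
  if (spec$variant == "ADE") {
    h2 <- c(vc$Am + vc$Dm, vc$Af + vc$Df)
  } else {
    h2 <- c(vc$Am, vc$Af)
  }
  tibble(sex = c("m", "f"), h2 = h2)
}

# --- parameter transform: unconstrained theta <-> vc --------------------

# Per sex the non-E components get log-ratio parameters against E
# (multinomial-logit on the simplex); mu gets atanh. Names depend on spec.
theta_names <- function(spec) {
  comp <- switch(spec$variant, ADE = c("A", "D"), ACE = c("A", "C"), AE = "A")
  nm <- paste0("l", comp, "_m")
  if (spec$sex_limitation) nm <- c(nm, paste0("l", comp, "_f"))
  if (spec$assortment) nm <- c(nm, "z_mu")
  nm
}

theta_to_vc <- function(theta, spec) {
  comp <- switch(spec$variant, ADE = c("A", "D"), ACE = c("A", "C"), AE = "A")
  k <- length(comp)
  unpack <- function(th) {
    e <- exp(pmin(unname(th), 30))
    tot <- 1 + sum(e)
    c(e / tot, 1 / tot) # components then E
  }
  pm <- unpack(theta[seq_len(k)])
  pf <- if (spec$sex_limitation) unpack(theta[k + seq_len(k)]) else pm
  mu <- if (spec$assortment) tanh(max(-7, min(7, theta[length(theta)]))) else 0
  get <- function(p, which) if (which %in% comp) p[match(which, comp)] else 0
  variance_components(
    Am = get(pm, "A"), Dm = get(pm, "D"), Cm = get(pm, "C"), Em = pm[k + 1],
    Af = get(pf, "A"), Df = get(pf, "D"), Cf = get(pf, "C"), Ef = pf[k + 1],
    mu = mu
  )
}

vc_to_theta <- function(vc, spec) {
  comp <- switch(spec$variant, ADE = c("A", "D"), ACE = c("A", "C"), AE = "A")
  pick <- function(sex) {
    v <- switch(sex, m = c(A = vc$Am, D = vc$Dm, C = vc$Cm, E = vc$Em),
                f = c(A = vc$Af, D = vc$Df, C = vc$Cf, E = vc$Ef))
    log(pmax(v[comp], 1e-8) / pmax(v["E"], 1e-8))
  }
  th <- pick("m")
  if (spec$sex_limitation) th <- c(th, pick("f"))
  if (spec$assortment) th <- c(th, atanh(pmin(pmax(vc$mu, -0.99), 0.99)))
  setNames(as.numeric(th), theta_names(spec))
}

# Deterministic multi-start grid in component space (A, D-or-C, E) + mu.
wls_starts <- function(spec) {
  grid <- list(c(0.60, 0.30, 0.10), c(0.30, 0.60, 0.10), c(0.85, 0.10, 0.05),
               c(0.33, 0.33, 0.34), c(0.50, 0.10, 0.40))
  mu0 <- c(0.0, 0.2, 0.0, 0.4, 0.1)
  purrr::map2(grid, mu0, function(g, m) {
    if (spec$variant == "AE") {
      a <- g[1] + g[2]
      vc <- variance_components(Am = a, Em = 1 - a,
                                mu = if (spec$assortment) m else 0)
    } else if (spec$variant == "ADE") {
      vc <- variance_components(Am = g[1], Dm = g[2], Em = g[3],
                                mu = if (spec$assortment) m else 0)
    } else {
      vc <- variance_components(Am = g[1], Cm = g[2], Em = g[3],
                                mu = if (spec$assortment) m else 0)
    }
    vc_to_theta(vc, spec)
  })
}

#' Fit a twin-family model to pair correlations by weighted least squares
#'
#' Minimises `sum_k w_k (r_obs_k - r_model_k)^2` over the variance
#' components (constrained to the per-sex simplex via a log-ratio
#' reparameterisation) and, when the model includes assortment, the spousal
#' correlation `mu` (via `atanh`). Weights are pair counts when available,
#' otherwise inverse squared standard errors, otherwise equal. Optimisation
#' uses BFGS from a fixed 5-point multi-start grid, so the fit is
#' deterministic.
#'
#' @param obs A [family_correlations()] tibble (columns `class`, `r`, and
#'   optionally `se`, `n_pairs`). Classes with missing `r` are dropped.
#' @param spec A [model_spec()].
#' @param weights `"auto"` (pair counts, then SEs, then equal), `"n_pairs"`,
#'   `"se"`, or `"equal"`.
#' @return A `kinliab_fit` object; see [tidy.kinliab_fit()] and
#'   [glance.kinliab_fit()].
#' @export
fit_wls <- function(obs, spec = model_spec("ADE"),
                    weights = c("auto", "n_pairs", "se", "equal")) {
  weights <- match.arg(weights)
  obs <- as_tibble(obs)
  stopifnot(all(c("class", "r") %in% names(obs)))
  obs <- obs[!is.na(obs$r) & obs$class %in% PAIR_CLASSES, ]
  w <- switch(weights,
    auto = if ("n_pairs" %in% names(obs) && all(is.finite(obs$n_pairs)) &&
               any(obs$n_pairs > 0)) obs$n_pairs
           else if ("se" %in% names(obs) && all(is.finite(obs$se)) &&
                    all(obs$se > 0)) 1 / obs$se^2
           else rep(1, nrow(obs)),
    n_pairs = obs$n_pairs,
    se = 1 / obs$se^2,
    equal = rep(1, nrow(obs))
  )
  keep <- is.finite(w) & w > 0
  obs <- obs[keep, ]; w <- w[keep]
  n_free <- length(theta_names(spec))
  if (nrow(obs) < n_free) {
    abort(sprintf(
      "under-identified model: %d free parameters but only %d informative pair classes.",
      n_free, nrow(obs)), class = "kinliab_identifiability_error")
  }
  idx <- match(obs$class, PAIR_CLASSES)
  objective <- function(theta) {
    vc <- theta_to_vc(theta, spec)
    r_exp <- expected_pair_vec(vc)[idx]
    sum(w * (obs$r - r_exp)^2)
  }
  fits <- purrr::map(wls_starts(spec), function(th0) {
    optim(th0, objective, method = "BFGS",
          control = list(maxit = 500, reltol = 1e-12))
  })
  best <- fits[[which.min(purrr::map_dbl(fits, "value"))]]
  vc <- theta_to_vc(best$par, spec)
  r_exp <- expected_pair_vec(vc)[idx]
  new_kinliab_fit(
    spec = spec, estimates = vc, method = "WLS",
    objective = best$value, loglik = NA_real_,
    n_free = n_free, n_stats = nrow(obs),
    df = nrow(obs) - n_free,
    converged = best$convergence == 0,
    se = setNames(rep(NA_real_, n_free), theta_names(spec)),
    covariate_effects = tibble(term = character(), estimate = numeric()),
    fitted = tibble(class = obs$class, observed = obs$r,
                    expected = unname(r_exp), weight = w)
  )
}

new_kinliab_fit <- function(spec, estimates, method, objective, loglik,
                            n_free, n_stats, df, converged, se,
                            covariate_effects, fitted,
                            thresholds = NULL, n_families = NA_integer_) {
  structure(
    list(spec = spec, estimates = estimates, method = method,
         objective = objective, loglik = loglik, n_free = n_free,
         n_stats = n_stats, df = df, converged = converged, se = se,
         covariate_effects = covariate_effects, fitted = fitted,
         thresholds = thresholds, n_families = n_families),
    class = "kinliab_fit"
  )
}

#' @export
print.kinliab_fit <- function(x, ...) {
  cat(sprintf("<kinliab %s fit: %s model%s>\n", x$method, x$spec$variant,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  print(x$estimates)
  h2 <- heritability(x$estimates, x$spec)
  cat(sprintf("h2 (males) = %.3f, h2 (females) = %.3f\n",
              h2$h2[1], h2$h2[2]))
  if (x$method == "WLS") {
    cat(sprintf("weighted SSQ = %.6g on %d df\n", x$objective, x$df))
  } else {
    cat(sprintf("logLik = %.3f, %d free parameters\n", x$loglik, x$n_free))
  }
  invisible(x)
}

#' Tidy a twin-family model fit
#'
#' @param x A `kinliab_fit` from [fit_wls()] or [fit_ml()].
#' @param ... Unused.
#' @return `tidy()` returns one row per parameter (variance components, `mu`,
#'   thresholds and covariate effects for ML fits) with columns `term`,
#'   `estimate`, `se`. `glance()` returns a one-row fit summary.
#' @method tidy kinliab_fit
#' @export
tidy.kinliab_fit <- function(x, ...) {
  vc <- x$estimates
  h2 <- heritability(vc, x$spec)
  out <- tibble(
    term = c("Am", "Dm", "Cm", "Em", "Af", "Df", "Cf", "Ef", "mu",
             "h2_m", "h2_f"),
    estimate = c(vc$Am, vc$Dm, vc$Cm, vc$Em, vc$Af, vc$Df, vc$Cf, vc$Ef,
                 vc$mu, h2$h2[1], h2$h2[2]),
    se = NA_real_
  )
  if (!is.null(x$thresholds)) {
    out <- dplyr::bind_rows(out, tibble(
      term = names(x$thresholds), estimate = unname(x$thresholds),
      se = NA_real_))
  }
  if (nrow(x$covariate_effects) > 0) {
    ce <- x$covariate_effects
    ce$se <- if ("se" %in% names(ce)) ce$se else NA_real_
    out <- dplyr::bind_rows(out, ce[, c("term", "estimate", "se")])
  }
  out
}

#' @rdname tidy.kinliab_fit
#' @method glance kinliab_fit
#' @export
glance.kinliab_fit <- function(x, ...) {
  tibble(method = x$method, variant = x$spec$variant,
         sex_limitation = x$spec$sex_limitation,
         assortment = x$spec$assortment,
         objective = x$objective, loglik = x$loglik,
         n_free = x$n_free, df = x$df, converged = x$converged)
}

# TRUE if `reduced` is nested in `full`.
spec_nested <- function(full, reduced) {
  variant_ok <- reduced$variant == full$variant ||
    (reduced$variant == "AE" && full$variant %in% c("ADE", "ACE"))
  variant_ok &&
    (!reduced$sex_limitation || full$sex_limitation) &&
    (!reduced$assortment || full$assortment) &&
    all(reduced$covariates %in% full$covariates)
}

#' Likelihood-ratio test between nested twin-family fits
#'
#' Twice the log-likelihood difference of two nested ML fits, referred to a
#' chi-square with df equal to the difference in free parameters. Following
#' the large-sample design this package targets, the default significance
#' level is a stringent 0.0001.
#'
#' @param full,reduced Converged `kinliab_fit` objects from [fit_ml()], with
#'   `reduced` nested in `full`.
#' @param alpha Significance level for the `significant` flag.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `significant`,
#'   `alpha`.
#' @export
likelihood_ratio_test <- function(full, reduced, alpha = 1e-4) {
  stopifnot(inherits(full, "kinliab_fit"), inherits(reduced, "kinliab_fit"))
  if (full$method != "ML" || reduced$method != "ML") {
    abort("likelihood-ratio tests require ML fits.",
          class = "kinliab_spec_error")
  }
  if (!spec_nested(full$spec, reduced$spec)) {
    abort("`reduced` is not nested in `full`.", class = "kinliab_spec_error")
  }
  stat <- 2 * (full$loglik - reduced$loglik)
  if (stat < -1e-6) {
    warn(sprintf(
      "negative LR statistic (%.3g): one of the fits has not converged to its optimum.",
      stat), class = "kinliab_convergence_warning")
  }
  stat <- max(0, stat)
  df <- full$n_free - reduced$n_free
  p <- if (df > 0) pchisq(stat, df = df, lower.tail = FALSE) else 1
  tibble(statistic = stat, df = df, p_value = p,
         significant = p < alpha, alpha = alpha)
}
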