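test_that("the factor decomposition reproduces the pair-class correlation matrix", {
  set.seed(31)
  structures <- list(
    tibble::tibble(role = c("father", "mother", "MZ1", "MZ2", "sib", "sib"),
                   sex = c("m", "f", "f", "f", "m", "f")),
    tibble::tibble(role = c("father", "mother", "DZ1", "DZ2"),
                   sex = c("m", "f", "m", "f")),
    tibble::tibble(role = c("father", "mother"), sex = c("m", "f")),
    tibble::tibble(role = c("MZ1", "MZ2", "sib"), sex = c("m", "m", "f"))
  )
  for (i in 1:30) {
    vc <- random_vc(sample(c("ADE", "ACE", "AE"), 1), mu_max = 0.6)
    for (mem in structures) {
      fac <- kinliab:::family_factorization(mem, vc)
      if (!fac$ok) next
      R_fac <- tcrossprod(fac$L) + diag(fac$idio^2)
      if (length(fac$mz_idx) == 2) {
        R_fac[fac$mz_idx, fac$mz_idx] <- R_fac[fac$mz_idx, fac$mz_idx] +
          fac$delta^2
      }
      R_form <- family_cor_from_formulas(mem, vc)
      expect_equal(R_fac, R_form, tolerance = 1e-10)
    }
  }
})

test_that("pattern probabilities agree with a multivariate-normal oracle", {
  skip_if_not_installed("mvtnorm")
  vc <- blond_vc()
  mem <- tibble::tibble(role = c("father", "mother", "MZ1", "MZ2", "sib"),
                        sex = c("m", "f", "m", "m", "f"))
  fac <- kinliab:::family_factorization(mem, vc)
  R <- tcrossprod(fac$L) + diag(fac$idio^2)
  R[fac$mz_idx, fac$mz_idx] <- R[fac$mz_idx, fac$mz_idx] + fac$delta^2
  diag(R) <- 1
  thr <- c(-0.3, 0.2, -0.3, -0.3, 0.2)
  probs <- kinliab:::all_pattern_probs(fac, thr)
  expect_equal(sum(probs), 1, tolerance = 1e-8)
  for (pat in c("11111", "00000", "10101", "01100", "11010")) {
    y <- as.integer(strsplit(pat, "")[[1]])
    lo <- ifelse(y == 1, -Inf, thr)
    hi <- ifelse(y == 1, thr, Inf)
    oracle <- mvtnorm::pmvnorm(lower = lo, upper = hi, corr = R,
                               algorithm = mvtnorm::Miwa(steps = 512))
    expect_equal(unname(probs[pat]), as.numeric(oracle), tolerance = 1e-5)
  }
})

test_that("threshold MLE from independent individuals equals the sample quantile", {
  vc <- variance_components(Am = 0.5, Em = 0.5, mu = 0)
  singles <- tibble::tibble(twin_type = "none", n_sibs = 1L,
                            include_parents = FALSE, weight = 1)
  fam <- simulate_families(600, vc, prevalence = c(m = 0.35, f = 0.55),
                           composition = singles, seed = 13)
  expect_true(all(table(fam$family_id) == 1))
  fit <- fit_ml(fam, model_spec("AE", FALSE, FALSE))
  prev_m <- mean(fam$phenotype[fam$sex == 1])
  prev_f <- mean(fam$phenotype[fam$sex == 2])
  expect_equal(unname(fit$thresholds["t_m"]), qnorm(prev_m), tolerance = 1e-4)
  expect_equal(unname(fit$thresholds["t_f"]), qnorm(prev_f), tolerance = 1e-4)
})

test_that("spousal assortment is recovered from couple data by ML", {
  vc <- variance_components(Am = 0.4, Dm = 0.4, Em = 0.2, mu = 0.3)
  fam <- simulate_families(3000, vc, prevalence = 0.4,
                           composition = couples_only(), seed = 77)
  fit <- fit_ml(fam, model_spec("AE", FALSE, TRUE))
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates$mu - 0.3), 0.05)
  reduced <- fit_ml(fam, model_spec("AE", FALSE, FALSE))
  lrt <- likelihood_ratio_test(reduced = reduced, full = fit)
  expect_lt(lrt$p_value, 1e-4)
})

test_that("age effects on the threshold are estimated under ML", {
  vc <- variance_components(Am = 0.5, Em = 0.5, mu = 0)
  singles <- tibble::tibble(twin_type = "none", n_sibs = 1L,
                            include_parents = FALSE, weight = 1)
  fam <- simulate_families(1500, vc, prevalence = 0.4, beta_age = 0.4,
                           composition = singles, seed = 29)
  spec <- model_spec("AE", FALSE, FALSE, covariates = "age_z")
  fit <- fit_ml(fam, spec, se = TRUE)
  b <- fit$covariate_effects
  expect_equal(b$term, "age_z")
  expect_lt(abs(b$estimate - 0.4), 0.15)
  # probit regression as an independent oracle for singleton data
  age_z <- as.numeric(scale(fam$age))
  or <- stats::glm(fam$phenotype ~ age_z + factor(fam$sex),
                   family = stats::binomial(link = "probit"))
  expect_equal(b$estimate, unname(stats::coef(or)["age_z"]),
               tolerance = 1e-3)
})

test_that("families larger than six members are rejected", {
  fam <- tibble::tibble(
    family_id = "f1",
    individual_id = paste0("i", 1:7),
    role = c("father", "mother", "DZ1", "DZ2", "sib", "sib", "sib"),
    sex = c(1L, 2L, 1L, 2L, 1L, 2L, 1L),
    phenotype = rep(0:1, length.out = 7)
  )
  expect_error(fit_ml(fam, model_spec("ADE")),
               class = "kinliab_domain_error")
})
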