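test_that("expected correlations reduce to textbook values without assortment", {
  # fully additive limit
  vc <- variance_components(Am = 1, Em = 0, mu = 0)
  r <- tibble::deframe(expected_pair_correlations(vc, model_spec("AE", assortment = FALSE)))
  expect_equal(unname(r[c("MZM", "MZF")]), c(1, 1))
  expect_equal(unname(r[c("DZM", "DZF", "DOS", "BB", "SS", "BS")]),
               rep(0.5, 6))
  expect_equal(unname(r[c("FS", "FD", "MS", "MD")]), rep(0.5, 4))
  expect_equal(unname(r["spouse"]), 0)
  # generic ACE/ADE textbook reductions at mu = 0
  vc2 <- variance_components(Am = 0.5, Dm = 0.3, Em = 0.2, mu = 0)
  r2 <- tibble::deframe(expected_pair_correlations(vc2, model_spec("ADE", assortment = FALSE)))
  expect_equal(unname(r2["MZM"]), 0.8)
  expect_equal(unname(r2["DZM"]), 0.5 * 0.5 + 0.25 * 0.3)
  expect_equal(unname(r2["FS"]), 0.25)
  vc3 <- variance_components(Am = 0.5, Cm = 0.3, Em = 0.2, mu = 0)
  r3 <- tibble::deframe(expected_pair_correlations(vc3, model_spec("ACE", assortment = FALSE)))
  expect_equal(unname(r3["MZF"]), 0.8)
  expect_equal(unname(r3["SS"]), 0.25 + 0.3)
})

test_that("published blond components imply the published MZ and parent-offspring correlations", {
  r <- tibble::deframe(expected_pair_correlations(blond_vc(), model_spec("ADE")))
  expect_equal(unname(r["MZM"]), 0.96, tolerance = 1e-12)
  expect_equal(unname(r["MZF"]), 0.97, tolerance = 1e-12)
  # father-son, written out long-hand from the path rules
  expect_equal(unname(r["FS"]),
               0.5 * sqrt(0.39) * (sqrt(0.39) + 0.210 * sqrt(0.73)),
               tolerance = 1e-12)
  expect_equal(unname(r["FS"]), 0.251, tolerance = 1e-3)
  expect_equal(unname(r["spouse"]), 0.210)
})

test_that("expected correlations match an independently written oracle for random parameters", {
  set.seed(11)
  for (i in 1:50) {
    variant <- sample(c("ADE", "ACE", "AE"), 1)
    vc <- random_vc(variant)
    r <- tibble::deframe(expected_pair_correlations(vc, model_spec(variant)))
    o <- expected_pair_vec_oracle(vc)
    for (cl in names(o)) {
      expect_equal(unname(r[cl]), o[[cl]], tolerance = 1e-12)
    }
  }
})

test_that("non-spouse correlations are non-decreasing in mu", {
  mus <- seq(0, 0.8, by = 0.1)
  for (cl in setdiff(pair_classes(), "spouse")) {
    vals <- vapply(mus, function(m) {
      vc <- variance_components(Am = 0.4, Dm = 0.3, Em = 0.3,
                                Af = 0.5, Df = 0.2, Ef = 0.3, mu = m)
      r <- tibble::deframe(expected_pair_correlations(vc, model_spec("ADE")))
      unname(r[cl])
    }, numeric(1))
    expect_true(all(diff(vals) >= -1e-12))
  }
})

test_that("model correlation matrices for 6-member families are positive semi-definite", {
  set.seed(7)
  members <- tibble::tibble(
    role = c("father", "mother", "MZ1", "MZ2", "sib", "sib"),
    sex = c("m", "f", "m", "m", "m", "f"))
  for (i in 1:1000) {
    vc <- random_vc(sample(c("ADE", "ACE"), 1), mu_max = 0.9)
    R <- family_cor_from_formulas(members, vc)
    expect_gt(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values),
              -1e-8)
  }
})

test_that("vc/spec mismatches are rejected", {
  vc <- variance_components(Am = 0.5, Dm = 0.3, Em = 0.2)
  expect_error(expected_pair_correlations(vc, model_spec("ACE")),
               class = "kinliab_spec_error")
  expect_error(heritability(vc, model_spec("AE")),
               class = "kinliab_spec_error")
  vc2 <- variance_components(Am = 0.5, Em = 0.5, mu = 0.3)
  expect_error(expected_pair_correlations(
    vc2, model_spec("AE", assortment = FALSE)),
    class = "kinliab_spec_error")
})

test_that("heritability is broad-sense under ADE and narrow-sense otherwise", {
  h <- heritability(blond_vc(), model_spec("ADE"))
  expect_equal(h$h2, c(0.96, 0.97))
  red <- variance_components(Am = 0.73, Cm = 0.26, Em = 0.01, mu = 0.704)
  expect_equal(heritability(red, model_spec("ACE"))$h2, c(0.73, 0.73))
  null <- variance_components(Am = 0, Em = 1)
  expect_equal(heritability(null, model_spec("AE", assortment = FALSE))$h2,
               c(0, 0))
})

test_that("WLS refits noiseless model-generated correlations exactly", {
  for (variant in c("ADE", "ACE")) {
    vc <- if (variant == "ADE") blond_vc() else
      variance_components(Am = 0.5, Cm = 0.2, Em = 0.3,
                          Af = 0.6, Cf = 0.1, Ef = 0.3, mu = 0.15)
    spec <- model_spec(variant, sex_limitation = TRUE, assortment = TRUE)
    obs <- expected_pair_correlations(vc, spec)
    fit <- fit_wls(obs, spec)
    expect_true(fit$converged)
    expect_lt(fit$objective, 1e-10)
    est <- fit$estimates
    for (p in c("Am", "Dm", "Cm", "Em", "Af", "Df", "Cf", "Ef", "mu")) {
      expect_equal(est[[p]], vc[[p]], tolerance = 1e-4)
    }
  }
})

test_that("WLS errors on under-identified inputs and respects weights", {
  spec <- model_spec("ADE", TRUE, TRUE)
  obs <- family_correlations(c("MZM", "MZF", "DZM"), c(0.9, 0.9, 0.5))
  expect_error(fit_wls(obs, spec), class = "kinliab_identifiability_error")
  # inverse-variance and count weights give different compromises on
  # inconsistent data
  tab <- published_correlations()
  obs_b <- correlation_table_row(tab, "red", n_pairs = default_pair_counts())
  f_np <- fit_wls(obs_b, model_spec("ACE", FALSE, TRUE), weights = "n_pairs")
  f_eq <- fit_wls(obs_b, model_spec("ACE", FALSE, TRUE), weights = "equal")
  expect_false(isTRUE(all.equal(f_np$objective, f_eq$objective)))
})

test_that("likelihood-ratio tests require nested converged ML fits", {
  vc <- variance_components(Am = 0.4, Dm = 0.4, Em = 0.2, mu = 0.3)
  fam <- simulate_families(400, vc, prevalence = 0.4,
                           composition = couples_only(), seed = 5)
  full <- fit_ml(fam, model_spec("AE", FALSE, TRUE))
  reduced <- fit_ml(fam, model_spec("AE", FALSE, FALSE))
  lrt <- likelihood_ratio_test(full, reduced)
  expect_equal(lrt$df, 1)
  expect_gte(lrt$statistic, 0)
  # identical fits give statistic 0, p = 1
  self <- likelihood_ratio_test(full, full)
  expect_equal(self$statistic, 0)
  expect_equal(self$p_value, 1)
  # non-nested specs are an error
  ace <- fit_ml(fam, model_spec("ACE", FALSE, FALSE))
  ade <- fit_ml(fam, model_spec("ADE", FALSE, FALSE))
  expect_error(likelihood_ratio_test(ade, ace), class = "kinliab_spec_error")
  # WLS fits are refused
  spec_w <- model_spec("ADE")
  wls <- fit_wls(expected_pair_correlations(blond_vc(), spec_w), spec_w)
  expect_error(likelihood_ratio_test(wls, wls), class = "kinliab_spec_error")
})

test_that("tidy and glance return the broom-shaped summaries", {
  spec <- model_spec("ADE")
  fit <- fit_wls(expected_pair_correlations(blond_vc(), spec), spec)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "se") %in% names(td)))
  expect_true(all(c("h2_m", "h2_f", "mu") %in% td$term))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$converged)
})
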