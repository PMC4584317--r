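#' Default family-composition mix
#'
#' Families of up to six members: a twin pair (or none), up to two
#' additional siblings, and the two parents. The default twin-type weights
#' mirror the zygosity composition of the Dutch hair-colour cohort (MZM
#' 2345, MZF 4651, DZM 1678, DZF 2710, DOS 3975 twin individuals) and the
#' sibling-count distribution gives ~0.27 extra siblings per family.
#'
#' @param twin_weights Named weights over `MZM`, `MZF`, `DZM`, `DZF`, `DOS`
#'   (and optionally `none`).
#' @param sib_probs Probabilities of 0, 1, 2 extra siblings.
#' @param include_parents Logical, include both parents.
#' @return A tibble with columns `twin_type`, `n_sibs`, `include_parents`,
#'   `weight`.
#' @export
default_composition <- function(twin_weights = c(MZM = 2345, MZF = 4651,
                                                 DZM = 1678, DZF = 2710,
                                                 DOS = 3975),
                                sib_probs = c(0.765, 0.20, 0.035),
                                include_parents = TRUE) {
  stopifnot(length(sib_probs) == 3, all(sib_probs >= 0), sum(sib_probs) > 0)
  grid <- tidyr::expand_grid(
    twin_type = names(twin_weights),
    n_sibs = 0:2
  )
  grid$include_parents <- include_parents
  grid$weight <- twin_weights[grid$twin_type] *
    (sib_probs / sum(sib_probs))[grid$n_sibs + 1]
  grid[grid$weight > 0, ]
}

sex_loadings <- function(vc, sex) {
  if (sex == "m") c(a = sqrt(vc$Am), dc = sqrt(vc$Dm + vc$Cm), e = sqrt(vc$Em))
  else c(a = sqrt(vc$Af), dc = sqrt(vc$Df + vc$Cf), e = sqrt(vc$Ef))
}

#' Simulate twin families under the liability-threshold model
#'
#' Generates families with the exact covariance structure assumed by the
#' family model: sex-specific A/D-or-C/E liability components, phenotypic
#' assortative mating with spousal liability correlation `mu`, Mendelian
#' transmission of additive values, and dichotomisation at per-sex
#' thresholds. Specifically, the father's liability is built from
#' independent standard-normal components; the mother's component vector is
#' regressed on the father's realised liability (regression coefficients
#' `mu` times her loadings, residual covariance chosen so each component
#' keeps unit variance), giving corr(liabilities) = `mu` and parental
#' additive correlation `mu * a_m * a_f`; offspring additive values are the
#' parental mean plus segregation noise of variance `(1 - mu*a_m*a_f)/2`;
#' MZ co-twins share their additive and dominance values exactly, DZ twins
#' and siblings share dominance with correlation 0.25 (a family-level plus
#' an individual-level part) and shared environment C fully; an individual
#' is a case when their liability falls below the sex-specific threshold.
#'
#' @param n_families Number of families.
#' @param vc A [variance_components()] object (the generating truth).
#' @param spec A [model_spec()]; checked against `vc`.
#' @param prevalence Target trait prevalence; a scalar or `c(m = , f = )`.
#' @param composition A composition tibble as from [default_composition()].
#' @param age_range Age range (years) for the uniform age covariate.
#' @param beta_age Linear effect of z-scored age on the threshold
#'   (default 0).
#' @param seed Mandatory integer seed; all randomness flows from it.
#' @return A tibble with one row per individual: `family_id`,
#'   `individual_id`, `father_id`, `mother_id`, `role`, `sex` (1 = male,
#'   2 = female), `age`, latent components `A`, `D`, `C`, `E`, `liability`,
#'   and binary `phenotype`.
#' @export
#' @examples
#' vc <- variance_components(Am = 0.39, Dm = 0.57, Em = 0.04,
#'                           Af = 0.73, Df = 0.24, Ef = 0.03, mu = 0.210)
#' fam <- simulate_families(100, vc, prevalence = 0.394, seed = 1)
#' mean(fam$phenotype)
simulate_families <- function(n_families, vc, spec = model_spec("ADE"),
                              prevalence = 0.5,
                              composition = default_composition(),
                              age_range = c(14, 80), beta_age = 0,
                              seed) {
  if (missing(seed) || !is.numeric(seed)) {
    abort("`seed` is mandatory: all randomness must flow from it.",
          class = "kinliab_domain_error")
  }
  check_vc_spec(vc, spec)
  stopifnot(all(composition$weight >= 0), sum(composition$weight) > 0,
            all(composition$n_sibs %in% 0:2))
  if (length(prevalence) == 1) prevalence <- c(m = prevalence, f = prevalence)
  thr <- c(m = prevalence_to_threshold(prevalence[["m"]]),
           f = prevalence_to_threshold(prevalence[["f"]]))
  set.seed(as.integer(seed))

  lam_m <- sex_loadings(vc, "m")
  lam_f <- sex_loadings(vc, "f")
  is_ace <- vc$Cm > 0 || vc$Cf > 0
  mu <- vc$mu
  rhoA <- mu * lam_m["a"] * lam_f["a"]
  segsd <- sqrt(0.5 * (1 - rhoA))

  nf <- n_families
  ci <- sample.int(nrow(composition), nf, replace = TRUE,
                   prob = composition$weight)
  twin_type <- composition$twin_type[ci]
  n_sibs <- composition$n_sibs[ci]
  with_parents <- composition$include_parents[ci]
  fam_id <- sprintf("F%05d", seq_len(nf))

  # parents (always generated; emitted only when included)
  XF <- matrix(rnorm(3 * nf), nf, 3) # father's A, D-or-C, E
  PF <- drop(XF %*% lam_m)
  m_vec <- mu * lam_f
  Sig_eps <- diag(3) - tcrossprod(m_vec)
  R_eps <- chol(Sig_eps)
  XM <- tcrossprod(PF, m_vec) + matrix(rnorm(3 * nf), nf, 3) %*% R_eps
  PM <- drop(XM %*% lam_f)

  mid <- 0.5 * (XF[, 1] + XM[, 1])
  DCfam <- rnorm(nf) # family-level dominance part or shared C

  kid_latents <- function(shared_with = NULL) {
    # returns list(A, DC, E) for one child; `shared_with` duplicates the
    # genetic draws of a previous child (MZ co-twin)
    if (is.null(shared_with)) {
      s <- rnorm(nf, 0, segsd)
      own <- rnorm(nf)
    } else {
      s <- shared_with$s
      own <- shared_with$own
    }
    A <- mid + s
    DC <- if (is_ace) DCfam else 0.5 * DCfam + sqrt(0.75) * own
    list(A = A, DC = DC, E = rnorm(nf), s = s, own = own)
  }

  rows <- list()
  emit <- function(role, sex, lat, keep = rep(TRUE, nf)) {
    lam <- if (sex == 1) lam_m else lam_f
    liab <- lam["a"] * lat$A + lam["dc"] * lat$DC + lam["e"] * lat$E
    tibble(
      family_id = fam_id, role = role, sex = as.integer(sex),
      A = lat$A, D = if (is_ace) 0 else lat$DC,
      C = if (is_ace) lat$DC else 0, E = lat$E,
      liability = liab
    )[keep, ]
  }

  rows$father <- emit("father", 1L,
                      list(A = XF[, 1], DC = XF[, 2], E = XF[, 3]),
                      with_parents)
  rows$mother <- emit("mother", 2L,
                      list(A = XM[, 1], DC = XM[, 2], E = XM[, 3]),
                      with_parents)

  has_twins <- twin_type != "none"
  tw_sex1 <- ifelse(twin_type %in% c("MZM", "DZM", "DOS"), 1L, 2L)
  tw_sex2 <- ifelse(twin_type %in% c("MZM", "DZM"), 1L,
                    ifelse(twin_type %in% c("MZF", "DZF"), 2L,
                           ifelse(twin_type == "DOS", 2L, 2L)))
  is_mz <- twin_type %in% c("MZM", "MZF")
  t1 <- kid_latents()
  t2_new <- kid_latents()
  t2 <- list(A = ifelse(is_mz, t1$A, t2_new$A),
             DC = ifelse(is_mz, t1$DC, t2_new$DC),
             E = t2_new$E)
  z1 <- ifelse(is_mz, "MZ1", "DZ1")
  z2 <- ifelse(is_mz, "MZ2", "DZ2")
  # emit twins per sex so liability loadings match
  for (s in 1:2) {
    rows[[paste0("tw1_", s)]] <- emit(z1, s, t1, has_twins & tw_sex1 == s)
    rows[[paste0("tw2_", s)]] <- emit(z2, s, t2, has_twins & tw_sex2 == s)
  }
  for (k in 1:2) {
    lat <- kid_latents()
    sexk <- sample(1:2, nf, replace = TRUE)
    for (s in 1:2) {
      rows[[paste0("sib", k, "_", s)]] <-
        emit("sib", s, lat, n_sibs >= k & sexk == s)
    }
  }
  out <- dplyr::bind_rows(rows)
  # stable ordering: family, then father, mother, twins, sibs
  role_rank <- match(out$role, c("father", "mother", "MZ1", "MZ2",
                                 "DZ1", "DZ2", "sib"))
  out <- out[order(out$family_id, role_rank), ]
  out <- out %>%
    dplyr::group_by(.data$family_id) %>%
    dplyr::mutate(individual_id = paste0(.data$family_id, "_",
                                         dplyr::row_number())) %>%
    dplyr::ungroup()
  out$father_id <- ifelse(out$role %in% c("father", "mother"), NA_character_,
                          paste0(out$family_id, "_1"))
  out$mother_id <- ifelse(out$role %in% c("father", "mother"), NA_character_,
                          paste0(out$family_id, "_2"))
  # parent ids only resolve when parents are in the table
  kids_no_parents <- !(out$family_id %in% out$family_id[out$role == "father"])
  out$father_id[kids_no_parents] <- NA_character_
  out$mother_id[kids_no_parents] <- NA_character_

  out$age <- runif(nrow(out), age_range[1], age_range[2])
  age_z <- as.numeric(scale(out$age))
  t_i <- unname(thr[ifelse(out$sex == 1, "m", "f")]) + beta_age * age_z
  out$phenotype <- as.integer(out$liability < t_i)
  out[, c("family_id", "individual_id", "father_id", "mother_id", "role",
          "sex", "age", "A", "D", "C", "E", "liability", "phenotype")]
}

#' Simulate independent SNP genotypes with a polygenic phenotype
#'
#' SNPs are independent (no LD), sampled in Hardy-Weinberg proportions at
#' allele frequencies drawn uniformly from `maf_range`. A subset of
#' `n_causal` SNPs receives normal effects on the standardised genotype
#' scale, scaled so the genetic variance fraction equals `h2` in
#' expectation; the residual makes the liability unit-variance. With
#' `binary = TRUE` the phenotype is dichotomised at the liability threshold
#' for `prevalence`.
#'
#' @param n_individuals,n_snps Matrix dimensions.
#' @param maf_range Allele-frequency range, within (0, 0.5].
#' @param n_causal Number of causal SNPs (at most `n_snps`).
#' @param h2 Target proportion of liability variance from SNPs, in [0, 1).
#' @param binary Dichotomise the phenotype?
#' @param prevalence Case proportion used when `binary = TRUE`.
#' @param seed Mandatory integer seed.
#' @return A list of class `kinliab_genotypes`: `dosages` (n x m matrix,
#'   values 0/1/2), `freq` (length-m allele frequencies), `effects`
#'   (per-SNP causal effects, standardised scale), and `phenotypes`
#'   (tibble: `individual_id`, `liability`, `phenotype`).
#' @export
simulate_genotypes <- function(n_individuals, n_snps,
                               maf_range = c(0.05, 0.5),
                               n_causal = min(100L, n_snps),
                               h2 = 0.5, binary = FALSE, prevalence = 0.5,
                               seed) {
  if (missing(seed) || !is.numeric(seed)) {
    abort("`seed` is mandatory.", class = "kinliab_domain_error")
  }
  if (!is.finite(h2) || h2 < 0 || h2 >= 1) {
    abort("`h2` must lie in [0, 1).", class = "kinliab_domain_error")
  }
  if (n_causal > n_snps) {
    abort("`n_causal` must not exceed `n_snps`.",
          class = "kinliab_domain_error")
  }
  stopifnot(maf_range[1] > 0, maf_range[2] <= 0.5)
  set.seed(as.integer(seed))
  p <- runif(n_snps, maf_range[1], maf_range[2])
  X <- matrix(rbinom(n_individuals * n_snps, 2L, rep(p, each = n_individuals)),
              n_individuals, n_snps)
  ids <- sprintf("I%05d", seq_len(n_individuals))
  rownames(X) <- ids
  colnames(X) <- sprintf("snp%05d", seq_len(n_snps))
  beta <- numeric(n_snps)
  g <- numeric(n_individuals)
  if (h2 > 0 && n_causal > 0) {
    causal <- sample.int(n_snps, n_causal)
    beta[causal] <- rnorm(n_causal, 0, sqrt(h2 / n_causal))
    W <- sweep(sweep(X[, causal, drop = FALSE], 2, 2 * p[causal]), 2,
               sqrt(2 * p[causal] * (1 - p[causal])), "/")
    g <- drop(W %*% beta[causal])
  }
  liab <- g + rnorm(n_individuals, 0, sqrt(1 - h2))
  y <- if (binary) {
    as.integer(liab < prevalence_to_threshold(prevalence))
  } else liab
  structure(
    list(dosages = X, freq = p, effects = beta,
         phenotypes = tibble(individual_id = ids, liability = liab,
                             phenotype = y)),
    class = "kinliab_genotypes"
  )
}

#' Write a deterministic miniature fixture suite
#'
#' Writes small, fully synthetic pedigree/phenotype/genotype files
#' (<= 200 individuals) for tests and documentation: `pedigree.tsv`,
#' `phenotypes.tsv` (raw five-category hair colour plus age),
#' `dosages.tsv`, `snps.tsv` (id + allele frequency sidecar) and a
#' `manifest.json` with the counts. Identical seeds give byte-identical
#' files.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, a named character vector of the file paths.
#' @export
make_fixture_suite <- function(dir, seed = 20260920) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vc <- variance_components(Am = 0.39, Dm = 0.57, Em = 0.04,
                            Af = 0.73, Df = 0.24, Ef = 0.03, mu = 0.210)
  fam <- simulate_families(40, vc, prevalence = 0.394, seed = seed)
  fam$age <- round(fam$age, 1)
  ped <- fam[, c("family_id", "individual_id", "father_id", "mother_id",
                 "sex", "role")]
  # raw hair-colour categories consistent with the simulated blond trait
  set.seed(as.integer(seed) + 1L)
  other <- sample(c("light brown", "dark brown", "red/auburn", "black"),
                  nrow(fam), replace = TRUE,
                  prob = c(0.45, 0.42, 0.07, 0.06))
  phe <- tibble(
    individual_id = fam$individual_id,
    hair_color = ifelse(fam$phenotype == 1, "fair/blond", other),
    age = fam$age
  )
  gen <- simulate_genotypes(50, 100, n_causal = 20, h2 = 0.5,
                            seed = as.integer(seed) + 2L)
  paths <- c(
    pedigree = file.path(dir, "pedigree.tsv"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    dosages = file.path(dir, "dosages.tsv"),
    snps = file.path(dir, "snps.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  write_pedigree(ped, paths[["pedigree"]])
  write_phenotypes(phe, paths[["phenotypes"]])
  dos <- as.data.frame(gen$dosages)
  dos <- cbind(individual_id = rownames(gen$dosages), dos)
  readr::write_tsv(tibble::as_tibble(dos), paths[["dosages"]])
  readr::write_tsv(tibble(snp_id = colnames(gen$dosages),
                          freq = round(gen$freq, 6)), paths[["snps"]])
  manifest <- sprintf(
    paste0('{"n_families": %d, "n_individuals": %d, "n_genotyped": %d, ',
           '"n_snps": %d, "seed": %d}'),
    length(unique(fam$family_id)), nrow(fam), nrow(gen$dosages),
    ncol(gen$dosages), as.integer(seed))
  writeLines(manifest, paths[["manifest"]])
  invisible(paths)
}
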