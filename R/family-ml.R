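# Full maximum-likelihood fitting of the liability model to binary family
# data. Each family's model correlation matrix is represented exactly as a
# low-rank factor structure:
#   T1   transmitted-additive factor (parents and offspring),
#   DC   family dominance part (loading d_s/2) or shared environment C,
#   SP   residual spousal factor carrying the part of mu not routed
#        through T1,
#   MZ   one extra factor per MZ pair (shared segregation + dominance),
# plus member-specific idiosyncratic variance. Conditional on the factors,
# members are independent, so the orthant (rectangle) probability of a
# case/control pattern is a product of univariate normal probabilities
# integrated over a low-dimensional Gauss-Hermite grid - deterministic and
# fast. Families with identical role/sex structure and no covariates are
# aggregated by phenotype pattern.

# Factor loadings for one family. members: tibble(role, sex) with sex
# "m"/"f". Returns list(L, idio, ok).
family_factorization <- function(members, vc) {
  a_m <- sqrt(vc$Am); a_f <- sqrt(vc$Af)
  mu <- vc$mu
  rhoA <- mu * a_m * a_f
  t1 <- sqrt(0.5 * (1 + rhoA))
  tauF <- 0.5 * (a_m + mu * a_f)
  tauM <- 0.5 * (a_f + mu * a_m)
  phi1 <- tauF / t1
  mu1 <- tauM / t1
  kap <- mu - phi1 * mu1

  k <- nrow(members)
  is_kid <- members$role %in% KID_ROLES
  is_mz <- members$role %in% c("MZ1", "MZ2")
  L <- matrix(0, k, 4,
              dimnames = list(NULL, c("T1", "DC", "SP", "MZ")))
  for (i in seq_len(k)) {
    s <- members$sex[i]
    A_s <- if (s == "m") vc$Am else vc$Af
    D_s <- if (s == "m") vc$Dm else vc$Df
    C_s <- if (s == "m") vc$Cm else vc$Cf
    a_s <- sqrt(A_s)
    if (members$role[i] == "father") {
      L[i, "T1"] <- phi1
      L[i, "SP"] <- sign(kap) * sqrt(abs(kap))
    } else if (members$role[i] == "mother") {
      L[i, "T1"] <- mu1
      L[i, "SP"] <- sqrt(abs(kap))
    } else {
      L[i, "T1"] <- a_s * t1
      L[i, "DC"] <- if (C_s > 0) sqrt(C_s) else 0.5 * sqrt(D_s)
      if (is_mz[i]) {
        L[i, "MZ"] <- sqrt(0.5 * A_s * (1 - rhoA) + 0.75 * D_s)
      }
    }
  }
  keep <- colSums(L != 0) >= 2
  L <- L[, keep, drop = FALSE]
  idio2 <- 1 - rowSums(L^2)
  if (any(idio2 < 1e-8) || !is.finite(t1)) {
    return(list(ok = FALSE))
  }
  # the MZ-pair factor is integrated analytically (bivariate normal), not
  # on the quadrature grid
  mz_idx <- which(is_mz)
  delta <- 0
  if ("MZ" %in% colnames(L)) {
    delta <- L[mz_idx[1], "MZ"]
    L <- L[, colnames(L) != "MZ", drop = FALSE]
  } else {
    mz_idx <- integer()
  }
  list(L = L, idio = sqrt(idio2), mz_idx = mz_idx, delta = delta, ok = TRUE)
}

# cached standard-normal product Gauss-Hermite grids
gh_env <- new.env(parent = emptyenv())
gh_grid <- function(q) {
  key <- as.character(q)
  if (!is.null(gh_env[[key]])) return(gh_env[[key]])
  n_per_dim <- c(40L, 24L, 16L, 12L)[min(q, 4L)]
  gh <- pracma::gaussHermite(n_per_dim)
  x <- gh$x * sqrt(2)
  w <- gh$w / sqrt(pi)
  nodes <- as.matrix(expand.grid(rep(list(x), q)))
  wts <- apply(as.matrix(expand.grid(rep(list(w), q))), 1, prod)
  out <- list(nodes = nodes, w = wts)
  gh_env[[key]] <- out
  out
}

# Conditional case-probability machinery shared by the pattern evaluators:
# per quadrature node, non-MZ members contribute univariate probabilities;
# an MZ pair (identical loadings, so identical conditional means) is
# integrated analytically as a bivariate normal with residual variance
# idio^2 + delta^2 and correlation delta^2 / (idio^2 + delta^2).
fac_node_probs <- function(fac, thr) {
  k <- length(thr)
  q <- ncol(fac$L)
  if (q == 0) {
    M <- matrix(0, 1, k)
    w <- 1
  } else {
    g <- gh_grid(q)
    M <- g$nodes %*% t(fac$L)
    w <- g$w
  }
  list(M = M, w = w)
}

mz_pair_cells <- function(fac, thr, M) {
  i1 <- fac$mz_idx[1]
  v <- fac$idio[i1]^2 + fac$delta^2
  r <- fac$delta^2 / v
  h <- (thr[i1] - M[, i1]) / sqrt(v)
  k2 <- (thr[fac$mz_idx[2]] - M[, fac$mz_idx[2]]) / sqrt(v)
  p11 <- pbinorm(h, k2, r)
  ph <- pnorm(h); pk <- pnorm(k2)
  list(p11 = p11, p10 = pmax(0, ph - p11), p01 = pmax(0, pk - p11),
       p00 = pmax(0, 1 - ph - pk + p11))
}

# probabilities of all 2^k case/control patterns of one family structure.
# Returns a named vector; names are pattern strings in member order,
# "1" = case.
all_pattern_probs <- function(fac, thr) {
  k <- length(thr)
  if (k == 1) {
    p <- pnorm(thr)
    return(setNames(c(p, 1 - p), c("1", "0")))
  }
  if (k == 2) {
    r <- sum(fac$L[1, ] * fac$L[2, ]) +
      if (length(fac$mz_idx) == 2) fac$delta^2 else 0
    p <- bivariate_orthant(thr[1], thr[2], max(-1, min(1, r)))
    return(setNames(c(p$p11, p$p10, p$p01, p$p00),
                    c("11", "10", "01", "00")))
  }
  np <- fac_node_probs(fac, thr)
  M <- np$M
  mz <- if (length(fac$mz_idx) == 2) mz_pair_cells(fac, thr, M) else NULL
  acc <- matrix(np$w, ncol = 1)
  keys <- ""
  i <- 1L
  while (i <= k) {
    if (!is.null(mz) && i == fac$mz_idx[1]) {
      acc <- cbind(acc * mz$p11, acc * mz$p10, acc * mz$p01, acc * mz$p00)
      keys <- c(paste0(keys, "11"), paste0(keys, "10"),
                paste0(keys, "01"), paste0(keys, "00"))
      i <- i + 2L
    } else {
      p_i <- pnorm((thr[i] - M[, i]) / fac$idio[i])
      acc <- cbind(acc * p_i, acc * (1 - p_i))
      keys <- c(paste0(keys, "1"), paste0(keys, "0"))
      i <- i + 1L
    }
  }
  setNames(colSums(acc), keys)
}

# probability of one specific pattern (used on the covariate path)
single_pattern_prob <- function(fac, thr, y) {
  k <- length(thr)
  if (k <= 2) {
    probs <- all_pattern_probs(fac, thr)
    return(unname(probs[paste(y, collapse = "")]))
  }
  np <- fac_node_probs(fac, thr)
  M <- np$M
  acc <- np$w
  i <- 1L
  while (i <= k) {
    if (length(fac$mz_idx) == 2 && i == fac$mz_idx[1]) {
      mz <- mz_pair_cells(fac, thr, M)
      cell <- paste0(y[fac$mz_idx[1]], y[fac$mz_idx[2]])
      acc <- acc * switch(cell, "11" = mz$p11, "10" = mz$p10,
                          "01" = mz$p01, "00" = mz$p00)
      i <- i + 2L
    } else {
      p_i <- pnorm((thr[i] - M[, i]) / fac$idio[i])
      acc <- acc * if (y[i] == 1) p_i else 1 - p_i
      i <- i + 1L
    }
  }
  sum(acc)
}

ml_theta_names <- function(spec) {
  c("t_m", "t_f", theta_names(spec),
    if (length(spec$covariates)) paste0("beta_", spec$covariates))
}

canonical_order <- function(d) {
  rank <- match(d$role, c("father", "mother", "MZ1", "MZ2",
                          "DZ1", "DZ2", "sib"))
  order(d$family_id, rank, d$sex, d$individual_id)
}

#' Fit the liability model to binary family data by maximum likelihood
#'
#' The log-likelihood of each family is the multivariate-normal rectangle
#' probability over its members' case/control orthants, with member
#' thresholds `t_i = t_sex + sum_j beta_j x_ij` and the correlation
#' structure implied by [expected_pair_correlations()]. Rectangle
#' probabilities are evaluated by an exact factor decomposition of the
#' family correlation matrix plus deterministic Gauss-Hermite quadrature
#' (see the methods vignette); parameter points whose implied structure is
#' not a valid correlation matrix are rejected before likelihood
#' evaluation. Without covariates, families with the same role/sex
#' structure are aggregated by phenotype pattern, so the cost is
#' independent of the number of families.
#'
#' @param data Pedigree-with-phenotype tibble as for
#'   [pair_correlation_table()]; families of more than 6 phenotyped members
#'   are an error. An `age` column is z-scored in-module when `"age_z"` is
#'   among the spec covariates.
#' @param spec A [model_spec()]; its `covariates` name threshold covariates
#'   (columns of `data`, or `"age_z"`).
#' @param trait Name of the binary trait column.
#' @param init Optional starting values: a `kinliab_vc` or a previous
#'   `kinliab_fit` (e.g. a WLS fit).
#' @param se Compute observed-information standard errors (numerical
#'   Hessian; adds roughly one optimisation's worth of work).
#' @param control Passed to [stats::optim()] (method BFGS).
#' @return A `kinliab_fit` with `loglik`, threshold and covariate
#'   estimates; see [tidy.kinliab_fit()].
#' @export
fit_ml <- function(data, spec = model_spec("ADE"), trait = "phenotype",
                   init = NULL, se = FALSE, control = list()) {
  stopifnot(trait %in% names(data))
  d <- tibble(
    family_id = data$family_id,
    individual_id = data$individual_id,
    role = data$role,
    sex = sex_of(data$sex),
    y = as.integer(data[[trait]])
  )
  fam_size <- table(d$family_id)
  if (any(fam_size > 6)) {
    abort(sprintf("family %s has %d members; at most 6 are supported.",
                  names(fam_size)[which.max(fam_size)], max(fam_size)),
          class = "kinliab_domain_error")
  }
  covs <- spec$covariates
  Xc <- NULL
  if (length(covs)) {
    Xc <- matrix(0, nrow(d), length(covs), dimnames = list(NULL, covs))
    for (j in covs) {
      if (j == "age_z") {
        stopifnot("age" %in% names(data))
        Xc[, j] <- as.numeric(scale(data$age))
      } else {
        stopifnot(j %in% names(data))
        Xc[, j] <- data[[j]]
      }
    }
  }
  keep <- !is.na(d$y)
  d <- d[keep, ]
  if (!is.null(Xc)) Xc <- Xc[keep, , drop = FALSE]
  ord <- canonical_order(d)
  d <- d[ord, ]
  if (!is.null(Xc)) Xc <- Xc[ord, , drop = FALSE]

  nm <- ml_theta_names(spec)
  n_free <- length(nm)
  n_obs <- nrow(d)
  prev_m <- mean(d$y[d$sex == "m"])
  prev_f <- mean(d$y[d$sex == "f"])
  clamp01 <- function(p) min(max(p, 1e-4), 1 - 1e-4)
  t0 <- c(qnorm(clamp01(ifelse(is.finite(prev_m) && !is.nan(prev_m),
                               prev_m, 0.5))),
          qnorm(clamp01(ifelse(is.finite(prev_f) && !is.nan(prev_f),
                               prev_f, 0.5))))
  init_vc <- if (inherits(init, "kinliab_fit")) init$estimates
             else if (inherits(init, "kinliab_vc")) init
             else NULL
  th_comp <- if (!is.null(init_vc)) {
    vc0 <- init_vc
    # project the init onto the spec's variant if needed
    tryCatch(vc_to_theta(vc0, spec), error = function(e) wls_starts(spec)[[1]])
  } else wls_starts(spec)[[1]]
  theta0 <- c(t0, th_comp, if (length(covs)) rep(0, length(covs)))
  names(theta0) <- nm

  has_covs <- length(covs) > 0
  if (!has_covs) {
    # aggregate families by structure and phenotype pattern
    agg <- d %>%
      dplyr::group_by(.data$family_id) %>%
      dplyr::summarise(
        key = paste(.data$role, .data$sex, sep = ":", collapse = ","),
        pat = paste(.data$y, collapse = ""), .groups = "drop") %>%
      dplyr::count(.data$key, .data$pat)
    structs <- unique(agg$key)
    members_of <- purrr::map(structs, function(k) {
      parts <- strsplit(strsplit(k, ",")[[1]], ":")
      tibble(role = purrr::map_chr(parts, 1),
             sex = purrr::map_chr(parts, 2))
    })
    names(members_of) <- structs
    negll <- function(theta) {
      vc <- tryCatch(theta_to_vc(theta[2 + seq_len(n_free - 2)], spec),
                     error = function(e) NULL)
      if (is.null(vc)) return(1e10)
      ll <- 0
      for (s in structs) {
        mem <- members_of[[s]]
        fac <- family_factorization(mem, vc)
        if (!fac$ok) return(1e10)
        thr <- ifelse(mem$sex == "m", theta[1], theta[2])
        probs <- all_pattern_probs(fac, thr)
        rows <- agg[agg$key == s, ]
        p <- pmax(probs[rows$pat], 1e-300)
        ll <- ll + sum(rows$n * log(p))
      }
      -ll
    }
  } else {
    fam_idx <- split(seq_len(nrow(d)), d$family_id)
    negll <- function(theta) {
      vc <- tryCatch(theta_to_vc(theta[2 + seq_len(n_free - 2 - length(covs))],
                                 spec),
                     error = function(e) NULL)
      if (is.null(vc)) return(1e10)
      beta <- theta[n_free - length(covs) + seq_along(covs)]
      fac_cache <- new.env(parent = emptyenv())
      ll <- 0
      for (idx in fam_idx) {
        mem <- d[idx, ]
        key <- paste(mem$role, mem$sex, sep = ":", collapse = ",")
        fac <- fac_cache[[key]]
        if (is.null(fac)) {
          fac <- family_factorization(mem[, c("role", "sex")], vc)
          fac_cache[[key]] <- fac
        }
        if (!fac$ok) return(1e10)
        thr <- ifelse(mem$sex == "m", theta[1], theta[2]) +
          drop(Xc[idx, , drop = FALSE] %*% beta)
        p <- max(single_pattern_prob(fac, thr, mem$y), 1e-300)
        ll <- ll + log(p)
      }
      -ll
    }
  }

  ctrl <- modifyList(list(maxit = 500, reltol = 1e-10), control)
  opt <- optim(theta0, negll, method = "BFGS", control = ctrl)
  theta_hat <- opt$par
  vc_hat <- theta_to_vc(theta_hat[2 + seq_len(n_free - 2 - length(covs))],
                        spec)
  beta_hat <- if (has_covs) {
    theta_hat[n_free - length(covs) + seq_along(covs)]
  } else numeric()

  se_vec <- setNames(rep(NA_real_, n_free), nm)
  boundary <- min(vc_hat$Em, vc_hat$Ef) < 1e-3 ||
    (spec$variant != "AE" &&
       min(vc_hat$Am, vc_hat$Af, vc_hat$Dm + vc_hat$Cm,
           vc_hat$Df + vc_hat$Cf) < 1e-3)
  if (se && !boundary) {
    H <- tryCatch(stats::optimHess(theta_hat, negll), error = function(e) NULL)
    if (!is.null(H)) {
      Vth <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(Vth) && all(diag(Vth) > 0)) {
        se_vec <- setNames(sqrt(diag(Vth)), nm)
      }
    }
  } else if (se && boundary) {
    warn("estimate at a simplex boundary; SEs reported as missing.",
         class = "kinliab_boundary_warning")
  }

  new_kinliab_fit(
    spec = spec, estimates = vc_hat, method = "ML",
    objective = opt$value, loglik = -opt$value,
    n_free = n_free, n_stats = n_obs, df = n_obs - n_free,
    converged = opt$convergence == 0,
    se = se_vec,
    covariate_effects = tibble(term = covs[seq_along(beta_hat)],
                               estimate = unname(beta_hat),
                               se = unname(se_vec[paste0("beta_", covs)[seq_along(beta_hat)]])),
    fitted = tibble(class = character(), observed = numeric(),
                    expected = numeric(), weight = numeric()),
    thresholds = c(t_m = unname(theta_hat[1]), t_f = unname(theta_hat[2])),
    n_families = length(unique(d$family_id))
  )
}
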