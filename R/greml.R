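#' Compute a genetic relationship matrix (GRM) from SNP dosages
#'
#' Entry (j, k) is the average over SNPs of
#' `(x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))`, the standard
#' GCTA-style estimator. Monomorphic SNPs and SNPs below the MAF filter are
#' excluded (with a message).
#'
#' @param dosages n x m matrix of dosages in `[0, 2]` (rows = individuals,
#'   which must be named) or a `kinliab_genotypes` object.
#' @param maf_min Minor-allele-frequency filter in `[0, 0.5)`.
#' @param freq Optional per-SNP allele frequencies; estimated from the
#'   sample when omitted.
#' @return An object of class `kinliab_grm`: list with `mat` (symmetric
#'   n x n), `ids`, `n_snps`.
#' @export
compute_grm <- function(dosages, maf_min = 0.01, freq = NULL) {
  if (inherits(dosages, "kinliab_genotypes")) dosages <- dosages$dosages
  stopifnot(is.matrix(dosages), !is.null(rownames(dosages)))
  if (any(dosages < 0) || any(dosages > 2)) {
    abort("dosages must lie in [0, 2].", class = "kinliab_domain_error")
  }
  if (maf_min < 0 || maf_min >= 0.5) {
    abort("`maf_min` must lie in [0, 0.5).", class = "kinliab_domain_error")
  }
  p <- if (is.null(freq)) colMeans(dosages) / 2 else freq
  maf <- pmin(p, 1 - p)
  keep <- maf > 0 & maf >= maf_min
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    inform(sprintf("excluding %d monomorphic or low-MAF SNP(s).", n_dropped))
  }
  if (!any(keep)) {
    abort("no SNPs survive the MAF filter.", class = "kinliab_domain_error")
  }
  W <- sweep(dosages[, keep, drop = FALSE], 2, 2 * p[keep])
  W <- sweep(W, 2, sqrt(2 * p[keep] * (1 - p[keep])), "/")
  A <- tcrossprod(W) / sum(keep)
  A <- (A + t(A)) / 2
  dimnames(A) <- NULL
  structure(list(mat = A, ids = rownames(dosages), n_snps = sum(keep)),
            class = "kinliab_grm")
}

#' @export
print.kinliab_grm <- function(x, ...) {
  cat(sprintf("<GRM: %d individuals, %d SNPs; mean diagonal %.3f>\n",
              length(x$ids), x$n_snps, mean(diag(x$mat))))
  invisible(x)
}

#' Merge per-chromosome GRMs
#'
#' SNP-count-weighted average of GRMs over identical individuals (e.g. the
#' 22 per-chromosome matrices merged into a single autosomal GRM). Merging
#' per-chromosome GRMs built with the same allele frequencies reproduces
#' the pooled-SNP GRM exactly.
#'
#' @param parts List of `kinliab_grm` objects with identical id lists.
#' @param weights SNP counts (default: each part's `n_snps`).
#' @return A `kinliab_grm`.
#' @export
merge_grms <- function(parts, weights = NULL) {
  stopifnot(length(parts) >= 1)
  ids <- parts[[1]]$ids
  for (i in seq_along(parts)) {
    mism <- which(parts[[i]]$ids != ids)
    if (length(mism)) {
      abort(sprintf("id mismatch in part %d at position %d ('%s' vs '%s').",
                    i, mism[1], parts[[i]]$ids[mism[1]], ids[mism[1]]),
            class = "kinliab_domain_error")
    }
  }
  if (is.null(weights)) weights <- purrr::map_dbl(parts, "n_snps")
  stopifnot(length(weights) == length(parts), sum(weights) > 0)
  A <- Reduce(`+`, purrr::map2(parts, weights, ~ .x$mat * .y)) / sum(weights)
  structure(list(mat = A, ids = ids, n_snps = sum(weights)),
            class = "kinliab_grm")
}

#' Select a subset of mutually unrelated individuals
#'
#' Greedy thinning with the standard GRM cut-off (default 0.025): while any
#' off-diagonal relatedness exceeds the cutoff, remove the individual
#' involved in the most violations (ties broken by id order), so the result
#' is deterministic and all retained pairwise values are below the cutoff.
#'
#' @param grm A `kinliab_grm`.
#' @param cutoff Relatedness cut-off (> 0).
#' @return Character vector of retained ids.
#' @export
select_unrelated <- function(grm, cutoff = 0.025) {
  stopifnot(cutoff > 0)
  A <- grm$mat
  diag(A) <- 0
  keep <- rep(TRUE, nrow(A))
  repeat {
    V <- (abs(A) > cutoff) & outer(keep, keep)
    nviol <- rowSums(V)
    if (all(nviol == 0)) break
    worst <- which(nviol == max(nviol))[1]
    keep[worst] <- FALSE
  }
  grm$ids[keep]
}

# restricted log-likelihood of (Vg, Ve) in the eigenspace of the GRM;
# lam = eigenvalues, yt/Xt = rotated phenotype/design.
reml_loglik <- function(Vg, Ve, lam, yt, Xt) {
  dv <- Vg * lam + Ve
  if (any(dv <= 0)) return(-Inf)
  XtVX <- crossprod(Xt / dv, Xt)
  XtVy <- crossprod(Xt / dv, yt)
  beta <- solve(XtVX, XtVy)
  Py <- (yt - Xt %*% beta) / dv
  -0.5 * (sum(log(dv)) + determinant(XtVX, logarithm = TRUE)$modulus +
            sum(yt * Py))
}

#' GREML: REML estimation of the SNP-explained variance proportion
#'
#' Fits `y = X beta + g + e` with `var(g) = Vg * GRM`, `var(e) = Ve * I` by
#' average-information REML with EM fallback steps (the first step is EM;
#' later steps fall back to EM whenever the AI update leaves the parameter
#' space or decreases the restricted likelihood, which keeps the
#' log-likelihood non-decreasing along fallbacks). The proportion
#' `Vg / (Vg + Ve)` is reported on the observed scale - for a 0/1
#' case-control phenotype no liability transformation is applied by
#' default, matching how such analyses are usually tabulated. Fixed-effect
#' covariates are projected out inside the restricted likelihood.
#'
#' @param grm A `kinliab_grm`.
#' @param phenotype Named numeric vector (names = ids), or a tibble with
#'   columns `individual_id` and `phenotype`.
#' @param covariates Optional numeric matrix or tibble of fixed-effect
#'   covariates (rows aligned to ids); an intercept is always included.
#' @param max_iter,tol Convergence controls: stop when the restricted
#'   log-likelihood changes by less than `tol` (default 1e-8).
#' @return A `kinliab_greml` object: `Vg`, `Ve`, `proportion`, `se`
#'   (delta-method SE of the proportion from the inverse AI matrix),
#'   `se_Vg`, `loglik`, `n_iterations`, `converged`, `n`.
#' @export
greml_reml <- function(grm, phenotype, covariates = NULL,
                       max_iter = 100L, tol = 1e-8) {
  if (is.data.frame(phenotype)) {
    phenotype <- setNames(phenotype$phenotype, phenotype$individual_id)
  }
  ids <- grm$ids
  if (is.null(names(phenotype))) {
    stopifnot(length(phenotype) == length(ids))
    names(phenotype) <- ids
  }
  if (!all(ids %in% names(phenotype))) {
    abort("phenotype ids do not cover the GRM ids.",
          class = "kinliab_domain_error")
  }
  y <- as.numeric(phenotype[ids])
  n <- length(y)
  if (n < 50) {
    abort("at least 50 individuals are required.",
          class = "kinliab_domain_error")
  }
  X <- matrix(1, n, 1)
  if (!is.null(covariates)) {
    X <- cbind(X, as.matrix(covariates))
  }
  eg <- eigen(grm$mat, symmetric = TRUE)
  lam <- eg$values
  if (stats::sd(lam) < 1e-8) {
    abort("GRM is (numerically) a multiple of the identity: Vg and Ve are not identifiable.",
          class = "kinliab_identifiability_error")
  }
  yt <- drop(crossprod(eg$vectors, y))
  Xt <- crossprod(eg$vectors, X)

  Vp <- stats::var(y)
  theta <- c(Vg = Vp / 2, Ve = Vp / 2)
  floor_v <- 1e-6 * Vp
  ll <- reml_loglik(theta[1], theta[2], lam, yt, Xt)

  em_step <- function(th) {
    # EM-REML update for each component
    dv <- th[1] * lam + th[2]
    XtVX <- crossprod(Xt / dv, Xt)
    beta <- solve(XtVX, crossprod(Xt / dv, yt))
    Py <- (yt - Xt %*% beta) / dv
    # tr(P A) = tr(Vinv A) - tr((X'VinvX)^-1 X'Vinv A Vinv X)
    trPA <- function(alam) {
      B <- crossprod(Xt / dv, Xt * alam / dv)
      sum(alam / dv) - sum(diag(solve(XtVX, B)))
    }
    yPAPy <- function(alam) sum(Py^2 * alam)
    g_new <- th[1] + th[1]^2 * (yPAPy(lam) - trPA(lam)) / n
    e_new <- th[2] + th[2]^2 * (yPAPy(rep(1, n)) - trPA(rep(1, n))) / n
    pmax(c(g_new, e_new), floor_v)
  }

  ai_step <- function(th) {
    dv <- th[1] * lam + th[2]
    XtVX <- crossprod(Xt / dv, Xt)
    beta <- solve(XtVX, crossprod(Xt / dv, yt))
    Py <- drop(yt - Xt %*% beta) / dv
    trPA <- function(alam) {
      B <- crossprod(Xt / dv, Xt * alam / dv)
      sum(alam / dv) - sum(diag(solve(XtVX, B)))
    }
    # P (A_i P y): apply P to a vector in eigenspace
    Pv <- function(v) {
      v / dv - (Xt / dv) %*% solve(XtVX, crossprod(Xt / dv, v))
    }
    APy <- list(lam * Py, Py)
    score <- c(-0.5 * (trPA(lam) - sum(Py * APy[[1]])),
               -0.5 * (trPA(rep(1, n)) - sum(Py * APy[[2]])))
    AI <- matrix(0, 2, 2)
    PAPy <- lapply(APy, Pv)
    for (i in 1:2) for (j in 1:2) {
      AI[i, j] <- 0.5 * sum(APy[[i]] * PAPy[[j]])
    }
    list(step = drop(solve(AI, score)), AI = AI)
  }

  n_it <- 0L
  converged <- FALSE
  AI_last <- NULL
  for (it in seq_len(max_iter)) {
    n_it <- it
    if (it == 1) {
      theta_new <- em_step(theta)
    } else {
      ai <- tryCatch(ai_step(theta), error = function(e) NULL)
      AI_last <- if (!is.null(ai)) ai$AI else AI_last
      if (!is.null(ai) && all(is.finite(ai$step))) {
        # AI proposal, components clamped at the small positive floor;
        # halve the step while it still decreases the likelihood
        step <- ai$step
        theta_new <- pmax(theta + step, floor_v)
        for (half in 1:8) {
          ll_try <- reml_loglik(theta_new[1], theta_new[2], lam, yt, Xt)
          if (is.finite(ll_try) && ll_try >= ll - 1e-10) break
          step <- step / 2
          theta_new <- pmax(theta + step, floor_v)
        }
        ll_try <- reml_loglik(theta_new[1], theta_new[2], lam, yt, Xt)
        if (!is.finite(ll_try) || ll_try < ll - 1e-10) {
          theta_new <- em_step(theta) # EM fallback: guaranteed ascent
        }
      } else {
        theta_new <- em_step(theta)
      }
    }
    ll_new <- reml_loglik(theta_new[1], theta_new[2], lam, yt, Xt)
    done <- abs(ll_new - ll) < tol ||
      max(abs(theta_new - theta)) < 1e-12 * Vp
    theta <- setNames(theta_new, c("Vg", "Ve"))
    ll <- ll_new
    if (done && it > 1) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf("REML did not converge in %d iterations.", max_iter),
         class = "kinliab_convergence_warning")
  }
  ai <- tryCatch(ai_step(theta), error = function(e) NULL)
  if (!is.null(ai)) AI_last <- ai$AI
  Vg <- theta[["Vg"]]; Ve <- theta[["Ve"]]
  Vp_hat <- Vg + Ve
  prop <- Vg / Vp_hat
  se_prop <- NA_real_
  se_Vg <- NA_real_
  if (!is.null(AI_last)) {
    Vcov <- tryCatch(solve(AI_last), error = function(e) NULL)
    if (!is.null(Vcov) && all(diag(Vcov) > 0)) {
      se_Vg <- sqrt(Vcov[1, 1])
      grad <- c(Ve, -Vg) / Vp_hat^2
      v <- drop(t(grad) %*% Vcov %*% grad)
      if (v > 0) se_prop <- sqrt(v)
    }
  }
  structure(
    list(Vg = Vg, Ve = Ve, proportion = prop, se = se_prop, se_Vg = se_Vg,
         loglik = ll, n_iterations = n_it, converged = converged, n = n),
    class = "kinliab_greml"
  )
}

#' @export
print.kinliab_greml <- function(x, ...) {
  cat(sprintf("GREML (n = %d): Vg = %.4f, Ve = %.4f\n", x$n, x$Vg, x$Ve))
  cat(sprintf("V(G)/V(P) = %.4f (SE %.4f), logLik = %.3f, %d iterations%s\n",
              x$proportion, x$se, x$loglik, x$n_iterations,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

#' @method tidy kinliab_greml
#' @export
tidy.kinliab_greml <- function(x, ...) {
  tibble(term = c("Vg", "Ve", "proportion"),
         estimate = c(x$Vg, x$Ve, x$proportion),
         se = c(x$se_Vg, NA_real_, x$se))
}

#' @method glance kinliab_greml
#' @export
glance.kinliab_greml <- function(x, ...) {
  tibble(loglik = x$loglik, n = x$n, n_iterations = x$n_iterations,
         converged = x$converged)
}
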