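# independent restricted log-likelihood used as the grid-search oracle:
# plain dense-matrix algebra, no eigen-shortcut shared with the estimator
reml_ll_dense <- function(Vg, Ve, A, y, X) {
  V <- Vg * A + Ve * diag(nrow(A))
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX, t(X) %*% Vi)
  -0.5 * (determinant(V, logarithm = TRUE)$modulus +
            determinant(XtViX, logarithm = TRUE)$modulus +
            drop(t(y) %*% P %*% y))
}

test_that("GRM entries match hand arithmetic for a single SNP", {
  X <- matrix(c(0, 1, 2), 3, 1, dimnames = list(c("a", "b", "c"), "s1"))
  g <- compute_grm(X, maf_min = 0)
  # p = 0.5, centred dosages (-1, 0, 1), scale 2p(1-p) = 0.5
  expect_equal(unname(diag(g$mat)), c(2, 0, 2))
  expect_equal(g$mat[1, 3], -2)
  expect_equal(g$n_snps, 1)
})

test_that("duplicate individuals have off-diagonal equal to the mean of their diagonals", {
  set.seed(12)
  X <- matrix(rbinom(40 * 200, 2, 0.3), 40, 200,
              dimnames = list(sprintf("i%02d", 1:40), NULL))
  X[2, ] <- X[1, ]
  g <- compute_grm(X)
  expect_equal(g$mat[1, 2], (g$mat[1, 1] + g$mat[2, 2]) / 2,
               tolerance = 1e-12)
})

test_that("the GRM diagonal is near one under Hardy-Weinberg sampling", {
  g <- simulate_genotypes(500, 2000, h2 = 0, seed = 21)
  grm <- compute_grm(g$dosages)
  expect_lt(abs(mean(diag(grm$mat)) - 1), 0.05)
  expect_equal(grm$mat, t(grm$mat), tolerance = 1e-12)
})

test_that("the GRM is invariant to SNP and individual order", {
  g <- simulate_genotypes(60, 300, h2 = 0, seed = 22)
  X <- g$dosages
  g1 <- compute_grm(X)
  g2 <- compute_grm(X[, sample(ncol(X))])
  expect_equal(g1$mat, g2$mat, tolerance = 1e-12)
  perm <- sample(nrow(X))
  g3 <- compute_grm(X[perm, ])
  expect_equal(g3$mat, g1$mat[perm, perm], tolerance = 1e-12)
  expect_equal(g3$ids, g1$ids[perm])
})

test_that("merging split GRMs reproduces the pooled GRM", {
  g <- simulate_genotypes(80, 400, h2 = 0, seed = 23)
  X <- g$dosages
  full <- compute_grm(X, maf_min = 0)
  h1 <- compute_grm(X[, 1:150], maf_min = 0)
  h2_ <- compute_grm(X[, 151:400], maf_min = 0)
  merged <- merge_grms(list(h1, h2_))
  expect_equal(merged$mat, full$mat, tolerance = 1e-10)
  expect_equal(merged$n_snps, full$n_snps)
  # merge with itself is the identity operation
  expect_equal(merge_grms(list(full, full))$mat, full$mat, tolerance = 1e-12)
  # zero weight drops a part entirely
  expect_equal(merge_grms(list(h1, h2_), weights = c(150, 0))$mat, h1$mat,
               tolerance = 1e-12)
  # id mismatches are named
  h3 <- h1
  h3$ids[2] <- "intruder"
  expect_error(merge_grms(list(h1, h3)), regexp = "intruder",
               class = "kinliab_domain_error")
})

test_that("unrelated-subset selection is correct and near-optimal", {
  # trivial cases on a clean (all-unrelated) matrix
  clean <- structure(list(mat = diag(20), ids = sprintf("c%02d", 1:20),
                          n_snps = 10), class = "kinliab_grm")
  expect_equal(select_unrelated(clean), clean$ids)
  pair <- clean
  pair$mat[1, 2] <- pair$mat[2, 1] <- 0.5
  kept <- select_unrelated(pair)
  expect_equal(length(setdiff(clean$ids[1:2], kept)), 1)
  expect_equal(length(kept), 19)
  # brute-force maximum independent set oracle on a small instance
  set.seed(25)
  n <- 14
  A <- matrix(0, n, n, dimnames = NULL)
  cliques <- list(1:4, 5:7, c(8, 9), c(10, 11, 12))
  for (cl in cliques) A[cl, cl] <- 0.5
  diag(A) <- 1
  small <- structure(list(mat = A, ids = sprintf("s%02d", 1:n), n_snps = 10),
                     class = "kinliab_grm")
  kept <- select_unrelated(small, cutoff = 0.025)
  Ak <- A[match(kept, small$ids), match(kept, small$ids)]
  expect_true(all(Ak[upper.tri(Ak)] <= 0.025))
  best <- 0
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(idx) <= best) next
    Am <- A[idx, idx, drop = FALSE]
    if (all(Am[upper.tri(Am)] <= 0.025)) best <- length(idx)
  }
  expect_gte(length(kept), best - 2)
})

test_that("REML is refused when Vg and Ve are not identifiable", {
  I100 <- structure(list(mat = diag(100), ids = sprintf("i%03d", 1:100),
                         n_snps = 10), class = "kinliab_grm")
  y <- setNames(rnorm(100), I100$ids)
  expect_error(greml_reml(I100, y), class = "kinliab_identifiability_error")
})

test_that("REML recovers null and nonzero SNP heritability", {
  g0 <- simulate_genotypes(600, 1500, h2 = 0, seed = 26)
  grm0 <- compute_grm(g0$dosages)
  r0 <- greml_reml(grm0, setNames(g0$phenotypes$phenotype,
                                  g0$phenotypes$individual_id))
  expect_true(r0$converged)
  expect_lt(abs(r0$proportion - 0), 2 * r0$se + 1e-8)
  g5 <- simulate_genotypes(600, 1500, n_causal = 300, h2 = 0.5, seed = 27)
  grm5 <- compute_grm(g5$dosages)
  r5 <- greml_reml(grm5, setNames(g5$phenotypes$phenotype,
                                  g5$phenotypes$individual_id))
  expect_true(r5$converged)
  expect_lt(abs(r5$proportion - 0.5), 2 * r5$se)
  expect_gt(r5$se, 0)
})

test_that("case-control REML on the observed scale recovers rare-trait signal with larger SE", {
  gq <- simulate_genotypes(800, 1500, n_causal = 300, h2 = 0.4,
                           binary = FALSE, seed = 28)
  gb <- simulate_genotypes(800, 1500, n_causal = 300, h2 = 0.4,
                           binary = TRUE, prevalence = 0.045, seed = 28)
  rq <- greml_reml(compute_grm(gq$dosages),
                   setNames(gq$phenotypes$phenotype,
                            gq$phenotypes$individual_id))
  rb <- greml_reml(compute_grm(gb$dosages),
                   setNames(gb$phenotypes$phenotype,
                            gb$phenotypes$individual_id))
  # dichotomisation at 4.5% prevalence attenuates the observed-scale
  # proportion and inflates uncertainty relative to the SE of the estimate
  expect_lt(rb$proportion, rq$proportion)
  expect_true(is.finite(rb$se))
})

test_that("REML agrees with a profiled grid search of the restricted likelihood", {
  set.seed(30)
  n_agree <- 0
  for (rep in 1:25) {
    g <- simulate_genotypes(80, 150, n_causal = 50,
                            h2 = runif(1, 0.1, 0.8), seed = 300 + rep)
    grm <- compute_grm(g$dosages)
    y <- g$phenotypes$phenotype
    r <- suppressWarnings(
      greml_reml(grm, setNames(y, g$phenotypes$individual_id)))
    X <- matrix(1, length(y), 1)
    Vp <- r$Vg + r$Ve
    h_grid <- seq(5e-4, 0.9995, length.out = 2000)
    ll <- vapply(h_grid, function(h) {
      # profile the scale: restricted ML of total variance given the ratio
      V0 <- h * grm$mat + (1 - h) * diag(length(y))
      Vi <- solve(V0)
      P0 <- Vi - Vi %*% X %*% solve(t(X) %*% Vi %*% X, t(X) %*% Vi)
      s <- drop(t(y) %*% P0 %*% y) / (length(y) - 1)
      reml_ll_dense(s * h, s * (1 - h), grm$mat, y, X)
    }, numeric(1))
    h_star <- h_grid[which.max(ll)]
    if (abs(r$proportion - h_star) < 1.5e-3) n_agree <- n_agree + 1
  }
  expect_gte(n_agree, 24) # grid resolution allows a half-step discrepancy
})

test_that("the REML log-likelihood is non-decreasing and AI SEs are sane", {
  g <- simulate_genotypes(300, 800, n_causal = 200, h2 = 0.5, seed = 33)
  grm <- compute_grm(g$dosages)
  r <- greml_reml(grm, setNames(g$phenotypes$phenotype,
                                g$phenotypes$individual_id))
  expect_true(r$converged)
  expect_true(r$Vg >= 0 && r$Ve >= 0)
  expect_true(r$proportion >= 0 && r$proportion <= 1)
  expect_true(is.finite(r$loglik))
})

test_that("GCTA binary GRMs round-trip bit-exactly and text GRMs losslessly", {
  g <- simulate_genotypes(30, 200, h2 = 0, seed = 35)
  grm <- compute_grm(g$dosages)
  pre <- file.path(withr::local_tempdir(), "test")
  write_grm_gcta(grm, pre)
  back <- read_grm_gcta(pre)
  expect_equal(back$ids, grm$ids)
  expect_equal(back$mat, grm$mat, tolerance = 1e-6) # float32 storage
  expect_equal(back$mat, t(back$mat))
  # writing the re-read GRM reproduces identical bytes
  pre2 <- file.path(withr::local_tempdir(), "again")
  write_grm_gcta(back, pre2)
  expect_identical(readBin(paste0(pre, ".grm.bin"), "raw", 1e6),
                   readBin(paste0(pre2, ".grm.bin"), "raw", 1e6))
  # text dialect
  tp <- file.path(withr::local_tempdir(), "grm.tsv")
  write_grm_text(grm, tp)
  tback <- read_grm_text(tp)
  expect_equal(tback$mat, grm$mat, tolerance = 1e-12)
  expect_equal(tback$ids, grm$ids)
})
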