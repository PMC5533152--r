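test_that("average_specimens means on the mm scale before log10", {
  one <- average_specimens(data.frame(species = "a", keel = 50))
  expect_equal(one$log10_keel, log10(50), tolerance = 1e-12)

  two <- average_specimens(data.frame(species = c("a", "a"), keel = c(40, 60)))
  expect_equal(two$log10_keel, log10(50))   # mean(40, 60) = 50, NOT 10^mean(log10)
  expect_equal(two$n_specimens, 2L)

  # many specimens collapse to one row per species
  spec <- data.frame(species = rep(c("a", "b", "c"), c(3, 2, 1)),
                     keel = c(10, 12, 14, 30, 34, 50),
                     ilium = c(20, 22, 24, 60, 64, 90))
  out <- average_specimens(spec)
  expect_equal(nrow(out), 3)
  expect_equal(out$log10_ilium[out$species == "b"], log10(62))

  expect_error(average_specimens(data.frame(species = "a", keel = -1)),
               "nonpositive")
})

test_that("pgls_fit reduces to OLS on a star tree", {
  set.seed(5)
  tr <- star_tree(20)
  x <- setNames(rnorm(20), tr$tip.label)
  y <- setNames(1 + 2 * x + rnorm(20, sd = 0.3), tr$tip.label)
  fit <- pgls_fit(tr, x, y)
  ols <- lm(y ~ x)
  expect_equal(unname(fit$coefficients), unname(coef(ols)), tolerance = 1e-10)
})

test_that("pgls_fit recovers an exact linear relation with zero residuals", {
  set.seed(6)
  tr <- simulate_tree(15, seed = 6)
  x <- setNames(rnorm(15), sort(tr$tip.label))
  y <- 2 + 3 * x
  fit <- pgls_fit(tr, x, y)
  expect_equal(unname(fit$coefficients), c(2, 3), tolerance = 1e-10)
  expect_lt(max(abs(fit$residuals)), 1e-10)
})

test_that("pgls_fit matches the brute-force GLS oracle on a 5-taxon tree", {
  set.seed(8)
  tr <- simulate_tree(5, seed = 8)
  C <- phylo_vcv(tr)
  x <- setNames(c(0.2, 1.1, -0.5, 0.9, 0.0), rownames(C))
  y <- setNames(c(1.0, 2.5, -0.3, 1.9, 0.6), rownames(C))
  fit <- pgls_fit(tr, x, y)
  oracle <- gls_oracle(C, x, y)
  expect_equal(unname(fit$coefficients), unname(oracle$beta), tolerance = 1e-8)
  expect_equal(unname(fit$residuals), unname(oracle$resid), tolerance = 1e-8)
  expect_equal(fit$sigma2, oracle$sigma2, tolerance = 1e-8)
})

test_that("pgls residuals satisfy the weighted orthogonality conditions", {
  set.seed(9)
  for (i in 1:10) {
    tr <- simulate_tree(sample(8:40, 1))
    C <- phylo_vcv(tr)
    x <- setNames(rnorm(nrow(C)), rownames(C))
    y <- setNames(rnorm(nrow(C)), rownames(C))
    e <- pgls_fit(x = x, y = y, C = C)$residuals
    Ci <- solve(C)
    expect_lt(abs(sum(Ci %*% e)), 1e-8)
    expect_lt(abs(drop(t(x) %*% Ci %*% e)), 1e-8)
  }
})

test_that("pgls_fit rejects a constant size variable", {
  tr <- star_tree(6)
  x <- setNames(rep(1, 6), tr$tip.label)
  y <- setNames(rnorm(6), tr$tip.label)
  expect_error(pgls_fit(tr, x, y), "no variance")
})

test_that("residuals agree with phytools::phyl.resid (independent implementation)", {
  set.seed(10)
  tr <- simulate_tree(25, seed = 10)
  x <- setNames(rnorm(25, sd = 0.5), sort(tr$tip.label))
  y <- setNames(0.5 + 0.3 * x + rnorm(25, sd = 0.2), sort(tr$tip.label))
  mine <- pgls_fit(tr, x, y)
  ref <- phytools::phyl.resid(tr, x[tr$tip.label], y[tr$tip.label])
  expect_equal(mine$residuals[rownames(ref$resid)], ref$resid[, 1],
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(unname(mine$coefficients), unname(ref$beta[, 1]),
               tolerance = 1e-6)
})

test_that("size_correct returns near-centered traits when slope is zero", {
  set.seed(12)
  tr <- simulate_tree(60, seed = 12)
  resid <- simulate_bm_traits(tr, c(0, 0), diag(0.01, 2), seed = 13)
  traits <- add_allometry(tr, resid, alpha = c(1, 2), beta = c(0, 0),
                          seed = 14)
  out <- size_correct(tr, traits)
  # with beta = 0 the GLS fit removes (approximately) only the weighted mean
  C <- phylo_vcv(tr)
  Ci <- solve(C)
  one <- rep(1, nrow(C))
  for (j in 1:2) {
    y <- traits[[c("log10_keel", "log10_ilium")[j]]]
    names(y) <- rownames(traits)
    mu <- drop(t(one) %*% Ci %*% y) / drop(t(one) %*% Ci %*% one)
    centered <- y - mu
    expect_gt(cor(out[, j], centered[rownames(out)]), 0.98)
  }
})

test_that("size_correct annihilates perfectly allometric traits", {
  set.seed(15)
  tr <- simulate_tree(30, seed = 15)
  zero <- matrix(0, 30, 2, dimnames = list(sort(tr$tip.label), NULL))
  traits <- add_allometry(tr, zero, alpha = c(0.5, 0.8), beta = c(1, 1),
                          seed = 16)
  out <- size_correct(tr, traits)
  expect_lt(max(abs(out)), 1e-10)
})

test_that("allometric slope is recovered within 3 SEs at n = 50 and 200", {
  for (n in c(50, 200)) {
    set.seed(n)
    tr <- simulate_tree(n, birth = 0.1)
    resid <- simulate_bm_traits(tr, c(0, 0), diag(0.002, 2))
    traits <- add_allometry(tr, resid, alpha = c(0.9, 0.9), beta = c(1/3, 1/3),
                            size_rate = 0.004)
    C <- phylo_vcv(tr)
    x <- setNames(traits$log10_size, rownames(traits))
    y <- setNames(traits$log10_keel, rownames(traits))
    fit <- pgls_fit(x = x, y = y, C = C)
    # analytic GLS slope SE at the fitted sigma^2
    LC <- chol(C)
    D <- cbind(1, x)
    WD <- backsolve(LC, D, transpose = TRUE)
    se <- sqrt(fit$sigma2 * solve(crossprod(WD))[2, 2] * n / (n - 2))
    expect_lt(abs(fit$coefficients[2] - 1/3), 3 * se)
  }
})

test_that("GLS estimates are invariant to rescaling all branch lengths", {
  set.seed(17)
  tr <- simulate_tree(20, seed = 17)
  x <- setNames(rnorm(20), sort(tr$tip.label))
  y <- setNames(rnorm(20), sort(tr$tip.label))
  f1 <- pgls_fit(tr, x, y)
  tr2 <- tr; tr2$edge.length <- tr2$edge.length * 7.3
  f2 <- pgls_fit(tr2, x, y)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-9)
  expect_equal(f1$residuals, f2$residuals, tolerance = 1e-9)
})
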