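# Escoufier species selection and redundancy analysis.

make_hellinger_env <- function(n = 12, n_sp = 5, n_env = 3, seed = 1,
                               link = 0) {
  set.seed(seed)
  x <- matrix(rnorm(n * n_env), n, n_env,
              dimnames = list(NULL, paste0("e", seq_len(n_env))))
  counts <- matrix(rlnorm(n * n_sp, 2, 0.5), n, n_sp)
  if (link > 0)
    counts <- counts * exp(link * x[, 1] %o% seq(-1, 1, length.out = n_sp))
  ab <- make_abundance(counts, "cell", lineages = paste0("sp", seq_len(n_sp)))
  env <- make_env(n, as.data.frame(x))
  list(species = hellinger(ab), env = preprocess_env(env, "identity"))
}

test_that("the RV coefficient behaves as a matrix correlation", {
  set.seed(4)
  x <- matrix(rnorm(30), 10)
  expect_equal(rv_coefficient(x, x), 1, tolerance = 1e-12)
  expect_equal(rv_coefficient(x, x %*% matrix(c(0, 1, 0, 0, 0, 1, 1, 0, 0), 3)),
               1, tolerance = 1e-12)   # invariant to column permutation
  y <- matrix(rnorm(30), 10)
  rv <- rv_coefficient(x, y)
  expect_gte(rv, 0); expect_lte(rv, 1)
})

test_that("Escoufier selection stops at the RV threshold and keeps structure", {
  set.seed(9)
  base <- matrix(rnorm(40), 20, 2)
  # four columns, but only two independent directions
  m <- cbind(base, base %*% matrix(c(1, 0.2, -0.4, 1), 2))
  colnames(m) <- paste0("s", 1:4)
  sel <- escoufier_select(m, threshold = 0.9)
  expect_lt(length(sel$selected), 4)
  expect_gte(tail(sel$rv, 1), 0.9)

  full <- escoufier_select(m, threshold = 1 + 1e-9)
  expect_identical(sort(full$selected), sort(colnames(m)))
})

test_that("species spanned by the environment give constrained fraction 1", {
  set.seed(21)
  n <- 10
  x <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("e1", "e2")))
  env <- preprocess_env(make_env(n, as.data.frame(x)), "identity")
  # species matrix lying exactly in the environmental column space
  y <- 0.3 + 0.1 * (x %*% matrix(rnorm(8), 2, 4))
  h2 <- structure(y, mode = "hellinger",
                  class = c("abundance_table", "matrix", "array"))
  dimnames(h2) <- list(env$sample_id, paste0("sp", 1:4))
  res <- rda_species(h2, env, escoufier_threshold = 1, n_perm = 99,
                     alpha = 1, vif_max = Inf, seed = 2)
  expect_equal(res$constrained_fraction, 1, tolerance = 1e-10)
})

test_that("biplot coordinates equal a hand-rolled regression + SVD oracle", {
  f <- make_hellinger_env(n = 6, n_sp = 4, n_env = 2, seed = 13, link = 0.5)
  res <- rda_species(f$species, f$env, escoufier_threshold = 1,
                     n_perm = 99, alpha = 1, vif_max = Inf, seed = 5)
  # oracle: centre, multivariate OLS via normal equations, SVD of fitted
  y <- unclass(f$species)[, res$selected_species, drop = FALSE]
  yc <- sweep(y, 2, colMeans(y))
  x <- as.matrix(as.data.frame(f$env)[attr(f$env, "variables")])
  xc <- sweep(x, 2, colMeans(x))
  b <- solve(t(xc) %*% xc) %*% t(xc) %*% yc
  fitted <- xc %*% b
  sv <- svd(fitted)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  for (j in seq_len(rank)) {
    o_site <- sv$u[, j] * sv$d[j]
    err <- min(max(abs(res$sample_scores[, j] - o_site)),
               max(abs(res$sample_scores[, j] + o_site)))
    expect_lt(err, 1e-8)
    vs <- res$species_scores[colnames(y), j]
    err_sp <- min(max(abs(vs - sv$v[, j])), max(abs(vs + sv$v[, j])))
    expect_lt(err_sp, 1e-8)
  }
  expect_equal(res$constrained_fraction, sum(fitted^2) / sum(yc^2),
               tolerance = 1e-12)
})

test_that("constrained fraction matches vegan and ignores env rescaling", {
  skip_if_not_installed("vegan")
  f <- make_hellinger_env(n = 15, n_sp = 6, n_env = 3, seed = 31, link = 0.4)
  res <- rda_species(f$species, f$env, escoufier_threshold = 1,
                     n_perm = 49, alpha = 1, vif_max = Inf, seed = 5)
  x <- as.data.frame(f$env)[attr(f$env, "variables")]
  v <- vegan::rda(unclass(f$species) ~ ., data = x)
  expect_equal(res$constrained_fraction,
               v$CCA$tot.chi / v$tot.chi, tolerance = 1e-8)

  # affine rescaling of the constraints leaves the fraction unchanged
  env2 <- f$env
  env2$e1 <- 100 * env2$e1 - 3
  env2$e2 <- env2$e2 / 7 + 42
  res2 <- rda_species(f$species, env2, escoufier_threshold = 1,
                      n_perm = 49, alpha = 1, vif_max = Inf, seed = 5)
  expect_equal(res2$constrained_fraction, res$constrained_fraction,
               tolerance = 1e-10)
})

test_that("permutation p-values are seed-reproducible and calibrated on noise", {
  f <- make_hellinger_env(n = 20, n_sp = 5, n_env = 3, seed = 8, link = 0.6)
  a <- rda_species(f$species, f$env, n_perm = 199, seed = 42)
  b <- rda_species(f$species, f$env, n_perm = 199, seed = 42)
  expect_identical(a$perm_p, b$perm_p)
  c_ <- rda_species(f$species, f$env, n_perm = 199, seed = 43)
  expect_false(identical(a$perm_p, c_$perm_p))

  # pure-noise env columns should rarely pass the screen
  null_p <- sapply(1:20, function(s) {
    f0 <- make_hellinger_env(n = 20, n_sp = 5, n_env = 1, seed = 100 + s,
                             link = 0)
    suppressWarnings(            # an unconstrained fall-back is expected here
      rda_species(f0$species, f0$env, n_perm = 99, seed = s,
                  escoufier_threshold = 1))$perm_p[["e1"]]
  })
  expect_gte(mean(null_p > 0.05), 0.8)
})

test_that("VIF screening prunes collinear constraints and can unconstrain", {
  set.seed(6)
  n <- 15
  e1 <- rnorm(n)
  env <- preprocess_env(make_env(n, data.frame(e1 = e1,
                                               e2 = e1 + rnorm(n, 0, 0.01),
                                               e3 = rnorm(n))), "identity")
  counts <- matrix(rlnorm(n * 4, 2, 0.3), n) * exp(0.5 * e1 %o% c(-1, 0, 1, 2))
  h <- hellinger(make_abundance(counts, "cell", lineages = paste0("sp", 1:4)))
  res <- rda_species(h, env, n_perm = 99, alpha = 1, vif_max = 10, seed = 3)
  expect_true(all(res$vif <= 10))
  expect_lt(length(res$selected_env), 3)

  expect_warning(
    un <- rda_species(h, env, n_perm = 99, alpha = 1e-9, vif_max = 10, seed = 3),
    "unconstrained")
  expect_false(un$constrained)
  expect_true(is.na(un$constrained_fraction))
})
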