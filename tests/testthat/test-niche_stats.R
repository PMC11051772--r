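# Hellinger transform, environmental PCA, smoothers, regressions, ANOVA.

test_that("Hellinger rows are square-rooted relative abundances with unit norm", {
  ab <- make_abundance(matrix(c(1, 1, 1, 1, 4, 0, 0, 0), 2, byrow = TRUE),
                       lineages = paste0("L", 1:4))
  h <- hellinger(ab)
  expect_equal(as.numeric(h[1, ]), rep(0.5, 4))
  expect_equal(as.numeric(h[2, ]), c(1, 0, 0, 0))
  expect_identical(abundance_mode(h), "hellinger")

  set.seed(5)
  r <- make_abundance(matrix(rlnorm(60), 6), lineages = paste0("L", 1:10))
  hr <- hellinger(r)
  expect_equal(unname(rowSums(unclass(hr)^2)), rep(1, 6), tolerance = 1e-12)

  z <- make_abundance(matrix(c(1, 2, 0, 0), 2, byrow = TRUE),
                      lineages = c("a", "b"))
  expect_warning(hz <- hellinger(z), "zero-sum")
  expect_equal(as.numeric(hz[2, ]), c(0, 0))
})

test_that("two perfectly correlated variables load entirely on the first axis", {
  x <- c(1, 3, 2, 5, 4)
  env <- make_env(5, data.frame(a = x, b = 2 * x))
  p <- pca_env(env)
  expect_equal(p$r2_per_axis[1], 1, tolerance = 1e-12)
})

test_that("PCA agrees with a brute-force covariance eigendecomposition", {
  set.seed(31)
  m <- matrix(rnorm(20), 5, 4)
  env <- make_env(5, as.data.frame(`colnames<-`(m, paste0("v", 1:4))))
  p <- pca_env(env, scale. = FALSE)
  eig <- eigen(cov(m), symmetric = TRUE)      # independent oracle
  expect_equal(p$r2_per_axis, eig$values / sum(eig$values), tolerance = 1e-8)
  for (j in 1:4) {                            # loadings equal up to sign
    err <- min(sum((p$loadings[, j] - eig$vectors[, j])^2),
               sum((p$loadings[, j] + eig$vectors[, j])^2))
    expect_lt(err, 1e-16)
  }
  centred <- scale(m, center = TRUE, scale = FALSE)
  expect_equal(unname(p$scores), unname(centred %*% p$loadings),
               tolerance = 1e-8)
})

test_that("PCA reconstruction and deterministic sign convention hold", {
  set.seed(8)
  m <- matrix(rnorm(48), 8, 6)
  env <- make_env(8, as.data.frame(`colnames<-`(m, paste0("v", 1:6))))
  p <- pca_env(env, scale. = TRUE)
  rec <- sweep(sweep(p$scores %*% t(p$loadings), 2, p$scale, `*`),
               2, p$center, `+`)
  expect_equal(unname(rec), unname(m), tolerance = 1e-8)
  for (j in seq_along(p$r2_per_axis))
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  expect_true(all(diff(p$r2_per_axis) <= 1e-12))
  expect_lte(sum(p$r2_per_axis), 1 + 1e-12)
})

test_that("smoother recovers linear, flat and unimodal shapes", {
  set.seed(2)
  x <- runif(150, -2, 2)
  lin <- fit_ti_smoother(x, 0.1 * x)
  expect_identical(lin$shape, "increasing")
  expect_lt(max(abs(lin$fit - 0.1 * lin$grid)), 1e-6)

  flat <- fit_ti_smoother(x, rep(0.3, 150))
  expect_identical(flat$shape, "flat")

  y <- -(x - 1)^2 + rnorm(150, 0, 0.05)
  uni <- fit_ti_smoother(x, y)
  expect_identical(uni$shape, "unimodal")
  expect_lt(abs(uni$peak - 1), 0.2)

  dec <- fit_ti_smoother(x, -0.2 * x)
  expect_identical(dec$shape, "decreasing")
})

test_that("smoother guards its inputs and shrinks the basis when needed", {
  expect_error(fit_ti_smoother(1:5, 1:5), "at least 10")
  x <- rep(1:6, 3)
  expect_warning(f <- fit_ti_smoother(x, x + rnorm(18, 0, 0.01)), "shrunk")
  expect_identical(f$shape, "increasing")
})

test_that("single-variable regression matches closed forms and conventions", {
  x <- seq(1, 10)
  r <- regress_ti(2 * x, x)
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_lt(r$p_value, 1e-12)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)

  # log-transform flag: slope on the log10 axis
  r2 <- regress_ti(c(1, 2, 3), c(10, 100, 1000), log_x = TRUE)
  expect_equal(r2$slope, 1, tolerance = 1e-12)
  expect_error(regress_ti(1:5, rep(3, 5)), "zero-variance")
})

test_that("regression confidence intervals cover a null slope at the nominal rate", {
  set.seed(123)
  hits <- 0L
  n_sim <- 400L
  for (i in seq_len(n_sim)) {
    x <- rnorm(50)
    y <- rnorm(50)              # independent of x: true slope 0
    ci <- regress_ti(y, x)$conf_int
    if (ci["lower"] <= 0 && ci["upper"] >= 0) hits <- hits + 1L
  }
  expect_gt(hits / n_sim, 0.91)
  expect_lt(hits / n_sim, 0.985)
})

test_that("stepwise selection finds an exact predictor and resists pure noise", {
  set.seed(77)
  m <- matrix(rnorm(500), 50, 10)
  env <- make_env(50, as.data.frame(`colnames<-`(m, paste0("x", 1:10))))
  sw <- suppressWarnings(stepwise_ti(m[, 3], env))  # exact fit is intended here
  expect_identical(sw$selected, "x3")

  sizes <- sapply(1:30, function(s) {
    set.seed(1000 + s)
    mm <- matrix(rnorm(29 * 60), 60, 29)
    ee <- make_env(60, as.data.frame(`colnames<-`(mm, paste0("v", 1:29))))
    c(bic = length(stepwise_ti(rnorm(60), ee, criterion = "BIC")$selected),
      aic = length(stepwise_ti(rnorm(60), ee)$selected))
  })
  expect_lte(median(sizes["bic", ]), 2)   # BIC keeps false selections rare
  expect_lte(median(sizes["aic", ]), 8)   # AIC admits a known modest excess
})

test_that("stepwise recovers strong light and nutrient effects among 29 candidates", {
  both <- sapply(1:20, function(s) {
    sim <- simulate_community(community_sim_config(n_stations = 60,
                                                   cml_stations = 0,
                                                   missing_rate = 0),
                              seed = 4000 + s)
    asn <- assign_modes(sim$taxonomy, sim$db)
    ti <- compute_ti(gene_to_cell(sim$abundance, sim$taxonomy), asn)
    sw <- stepwise_ti(ti$TI_M, preprocess_env(sim$env))
    all(c("par_8d", "no3_no2") %in% sw$selected)
  })
  expect_gte(sum(both), 18)
})

test_that("ANOVA matches a sums-of-squares oracle and the df conventions", {
  # 3-group fixture, printed in-line
  y <- c(6.1, 5.8, 6.4, 7.9, 8.2, 8.0, 4.1, 4.5, 3.9)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- anova_rates(y, data.frame(light = g), combinations = list("light"))
  # brute-force sums of squares
  grand <- mean(y)
  ss_b <- sum(tapply(y, g, function(v) length(v) * (mean(v) - grand)^2))
  ss_w <- sum(unlist(tapply(y, g, function(v) (v - mean(v))^2)))
  f_oracle <- (ss_b / 2) / (ss_w / 6)
  expect_equal(res$F[1], f_oracle, tolerance = 1e-8)
  expect_equal(res$Dfn[1], 2)
  expect_equal(res$Dfd[1], 6)

  # two groups, equal means, equal spread: F = 0, p = 1
  y0 <- c(1, 2, 3, 1, 2, 3)
  r0 <- anova_rates(y0, data.frame(light = rep(c("lo", "hi"), each = 3)),
                    combinations = list("light"))
  expect_equal(r0$F[1], 0)
  expect_equal(r0$p[1], 1)
  expect_equal(r0$Dfn[1], 1)   # 2 levels -> numerator df 1
})

test_that("multi-factor ANOVA keeps the df bookkeeping consistent", {
  set.seed(14)
  d <- expand.grid(light = c("hi", "lo"), nutrient = c("hi", "lo"),
                   species = paste0("sp", 1:3))
  d <- d[rep(seq_len(nrow(d)), 2), ]
  y <- rnorm(nrow(d))
  res <- anova_rates(y, d, combinations = list(c("light", "nutrient"),
                                               c("light", "nutrient", "species")))
  multi <- res[res$model == "light + nutrient + species", ]
  expect_equal(sum(multi$Dfn) + multi$Dfd[1], length(y) - 1)
  expect_error(anova_rates(c(1, 2), data.frame(light = c("a", "b"))),
               "saturated")
})
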