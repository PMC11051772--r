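# Community-environment statistics: Hellinger transform, environmental
# PCA, additive-model smoothers of trophic indices over gradients, and
# single-variable / stepwise regressions, plus the ANOVA used for the
# culture experiments.

#' Hellinger transform of an abundance table
#'
#' Replaces each entry by the square root of its within-sample relative
#' abundance, `sqrt(x / rowsum)`, giving each non-empty sample a
#' unit-L2-norm composition suitable for linear ordination. Zero-sum rows
#' are emitted as zeros with a warning.
#'
#' @param table an `abundance_table` (mode gene or cell).
#' @return an `abundance_table` with mode `"hellinger"`.
#' @export
hellinger <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (!abundance_mode(table) %in% c("gene", "cell"))
    stop("hellinger expects mode 'gene' or 'cell'")
  v <- unclass(table)
  rs <- rowSums(v)
  if (any(rs == 0)) {
    warning("zero-sum sample(s) emitted as zeros: ",
            paste(rownames(v)[rs == 0], collapse = ", "))
    rs[rs == 0] <- 1
  }
  as_abundance(sqrt(v / rs), "hellinger")
}

#' Principal component analysis of an environmental table
#'
#' Centred (and optionally unit-variance scaled) PCA of the preprocessed
#' environmental variables, with a deterministic sign convention: each
#' component is flipped so that its largest-magnitude loading is positive.
#'
#' @param env a preprocessed `env_table` (no missing values; see
#'   [preprocess_env()]).
#' @param scale. scale variables to unit variance before decomposition
#'   (default `TRUE`, so axes are correlation-based as usual when variables
#'   carry heterogeneous units).
#' @return object of class `env_pca`: `loadings` (variable x component),
#'   `scores` (sample x component), `r2_per_axis`, `center`, `scale`.
#' @export
pca_env <- function(env, scale. = TRUE) {
  vars <- attr(env, "variables")
  x <- as.matrix(as.data.frame(env)[vars])
  rownames(x) <- env$sample_id
  if (anyNA(x)) stop("env table has missing values; run preprocess_env() first")
  if (ncol(x) < 2L || nrow(x) < 3L)
    stop("need at least 2 variables and 3 samples")
  if (scale.) {
    s <- apply(x, 2L, sd)
    if (any(s == 0))
      stop("constant variable(s) cannot be z-scored: ",
           paste(colnames(x)[s == 0], collapse = ", "))
  }
  p <- prcomp(x, center = TRUE, scale. = scale.)
  # sign convention: largest |loading| of each component is positive
  for (j in seq_len(ncol(p$rotation))) {
    k <- which.max(abs(p$rotation[, j]))
    if (p$rotation[k, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  structure(list(loadings = p$rotation,
                 scores = p$x,
                 r2_per_axis = p$sdev^2 / sum(p$sdev^2),
                 center = p$center,
                 scale = if (scale.) p$scale else rep(1, ncol(x))),
            class = "env_pca")
}

#' @export
print.env_pca <- function(x, ...) {
  k <- min(4L, length(x$r2_per_axis))
  cat(sprintf("Environmental PCA: %d variables, %d samples\n",
              nrow(x$loadings), nrow(x$scores)))
  cat("  variance explained:",
      paste(sprintf("PC%d %.2f", seq_len(k), x$r2_per_axis[seq_len(k)]),
            collapse = ", "), "\n")
  for (j in 1:min(2L, ncol(x$loadings))) {
    top <- order(abs(x$loadings[, j]), decreasing = TRUE)[1:min(3L, nrow(x$loadings))]
    cat(sprintf("  PC%d top loadings: %s\n", j,
                paste(sprintf("%s (%.2f)", rownames(x$loadings)[top],
                              x$loadings[top, j]), collapse = ", ")))
  }
  invisible(x)
}

#' Smoothed trend of a trophic index over a gradient
#'
#' Fits a penalised cubic regression spline (basis dimension `k`,
#' smoothness chosen by generalised cross-validation) of the index on a
#' gradient (typically a principal-component axis), with a pointwise 95%
#' confidence band, and classifies the trend shape from the sign pattern of
#' the fitted first derivative on an evaluation grid.
#'
#' @param x gradient values (e.g. PC scores).
#' @param y trophic-index values, same length.
#' @param k spline basis dimension (default 10; shrunk automatically with a
#'   warning when there are too few unique points).
#' @param grid_n number of grid points for evaluation.
#' @return object of class `ti_trend`: `grid`, `fit`, `lower`, `upper`,
#'   `edf` (effective degrees of freedom), `shape` (increasing /
#'   decreasing / unimodal / flat / complex), `peak` (grid abscissa of the
#'   maximum, for unimodal fits), and the underlying `gam`.
#' @export
fit_ti_smoother <- function(x, y, k = 10, grid_n = 200) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 10L) stop("need at least 10 paired observations")
  nu <- length(unique(x))
  if (nu < k + 1L) {
    k <- max(3L, nu - 1L)
    warning("basis dimension shrunk to k = ", k)
  }
  dat <- data.frame(x = x, y = y)
  g <- mgcv::gam(y ~ s(x, bs = "cr", k = k), data = dat, method = "GCV.Cp")
  grid <- seq(min(x), max(x), length.out = grid_n)
  pr <- predict(g, newdata = data.frame(x = grid), se.fit = TRUE)
  fit <- as.numeric(pr$fit)
  se <- as.numeric(pr$se.fit)
  d1 <- diff(fit) / diff(grid)
  # derivative signs judged against the fitted range, not raw noise
  tol <- max(1e-8, 0.05 * diff(range(fit)) / diff(range(grid)))
  sgn <- sign(d1) * (abs(d1) > tol)
  runs <- rle(sgn[sgn != 0])$values
  shape <-
    if (diff(range(fit)) < 1e-8 || length(runs) == 0L) "flat"
    else if (all(runs == 1)) "increasing"
    else if (all(runs == -1)) "decreasing"
    else if (identical(runs, c(1, -1))) "unimodal"
    else "complex"
  structure(list(grid = grid, fit = fit,
                 lower = fit - 1.96 * se, upper = fit + 1.96 * se,
                 edf = sum(g$edf),
                 shape = shape,
                 peak = if (shape == "unimodal") grid[which.max(fit)] else NA_real_,
                 gam = g),
            class = "ti_trend")
}

#' @export
print.ti_trend <- function(x, ...) {
  cat(sprintf("Smoothed trend (edf = %.2f): shape '%s'", x$edf, x$shape))
  if (!is.na(x$peak)) cat(sprintf(", peak at %.3g", x$peak))
  cat("\n")
  invisible(x)
}

#' @export
plot.ti_trend <- function(x, xlab = "gradient", ylab = "trophic index", ...) {
  plot(x$grid, x$fit, type = "n", ylim = range(x$lower, x$upper),
       xlab = xlab, ylab = ylab, ...)
  polygon(c(x$grid, rev(x$grid)), c(x$lower, rev(x$upper)),
          col = "grey85", border = NA)
  lines(x$grid, x$fit, col = "steelblue", lwd = 2)
  invisible(x)
}

#' Single-variable regression of a trophic index
#'
#' Ordinary least squares of a trophic index on one predictor, optionally
#' log10-transforming the predictor first (as is customary for nutrient or
#' irradiance gradients spanning orders of magnitude).
#'
#' @param y trophic-index values.
#' @param x predictor values, same length.
#' @param log_x log10-transform the predictor (with the same shifted-log
#'   convention as [preprocess_env()] when non-positive values occur).
#' @param predictor,response optional names carried into the result.
#' @return object of class `ti_regression`: `coefficients` (with standard
#'   errors), `slope`, `p_value` (two-sided, for the slope), `r_squared`,
#'   `n`, `conf_int` (95% for the slope), and the underlying `lm`.
#' @export
regress_ti <- function(y, x, log_x = FALSE, predictor = "x", response = "TI") {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (log_x) {
    if (any(x <= 0)) {
      pos <- x[x > 0]
      eps <- if (length(pos)) min(pos) / 2 else 1
      x <- log10(x + eps)
    } else x <- log10(x)
  }
  if (sd(x) == 0) stop("zero-variance predictor")
  fit <- lm(y ~ x)
  s <- suppressWarnings(summary(fit))    # perfect fits are a valid input
  ci <- suppressWarnings(stats::confint(fit, "x", level = 0.95))
  structure(list(response = response, predictor = predictor, log_x = log_x,
                 coefficients = s$coefficients,
                 slope = unname(coef(fit)[2L]),
                 p_value = s$coefficients["x", "Pr(>|t|)"],
                 r_squared = s$r.squared,
                 n = length(x),
                 conf_int = c(lower = ci[1L], upper = ci[2L]),
                 lm = fit),
            class = "ti_regression")
}

#' @export
print.ti_regression <- function(x, ...) {
  cat(sprintf("%s ~ %s%s: slope %.4g (95%% CI %.4g to %.4g), p = %.3g, R^2 = %.3f, n = %d\n",
              x$response, if (x$log_x) "log10 " else "", x$predictor,
              x$slope, x$conf_int["lower"], x$conf_int["upper"],
              x$p_value, x$r_squared, x$n))
  invisible(x)
}

#' Stepwise selection of environmental predictors of a trophic index
#'
#' Bidirectional stepwise ordinary least squares from the intercept-only
#' model over all (preprocessed) environmental variables, minimising AIC
#' (BIC by flag). Complete cases only; with more candidates than
#' observations the search is forward-only with a warning. The add/drop
#' trace is recorded. Raw p-values are reported as-is; Benjamini-Hochberg
#' q-values over the marginal single-variable screens are also emitted
#' because a 29-variable battery inflates false positives.
#'
#' @param y trophic-index values, one per env row.
#' @param env a preprocessed `env_table`.
#' @param criterion `"AIC"` (default) or `"BIC"`.
#' @return object of class `ti_stepwise`: `selected` (variable names),
#'   `coefficients`, `r_squared`, `trace` (data.frame of steps),
#'   `marginal` (per-variable slope p-values and BH q-values), and the
#'   final `lm`.
#' @export
stepwise_ti <- function(y, env, criterion = c("AIC", "BIC")) {
  criterion <- match.arg(criterion)
  vars <- attr(env, "variables")
  dat <- as.data.frame(env)[vars]
  dat$.y <- y
  dat <- dat[complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  if (n < 3L) stop("need at least 3 complete cases")
  k_pen <- if (criterion == "AIC") 2 else log(n)
  direction <- "both"
  if (length(vars) >= n) {
    warning("more candidates than observations; forward-only search")
    direction <- "forward"
  }
  null_fit <- lm(.y ~ 1, data = dat)
  scope <- as.formula(paste("~", paste(vars, collapse = " + ")))
  sel <- step(null_fit, scope = list(lower = ~1, upper = scope),
              direction = direction, trace = 0, k = k_pen)
  marg_p <- vapply(vars, function(v) {
    if (sd(dat[[v]]) == 0) return(NA_real_)
    suppressWarnings(summary(lm(dat$.y ~ dat[[v]])))$coefficients[2L, 4L]
  }, numeric(1L))
  structure(list(selected = setdiff(names(coef(sel)), "(Intercept)"),
                 coefficients = summary(sel)$coefficients,
                 r_squared = summary(sel)$r.squared,
                 trace = sel$anova,
                 criterion = criterion,
                 marginal = data.frame(variable = vars, p = marg_p,
                                       q = p.adjust(marg_p, "BH"),
                                       row.names = NULL),
                 lm = sel),
            class = "ti_stepwise")
}

#' @export
print.ti_stepwise <- function(x, ...) {
  cat(sprintf("Stepwise (%s) selection: %d variable(s), R^2 = %.3f\n",
              x$criterion, length(x$selected), x$r_squared))
  if (length(x$selected)) cat("  ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' @importFrom stats p.adjust confint pf
NULL

#' ANOVA of culture rates over treatment factors
#'
#' Single-factor ANOVAs for each factor alone and a multi-factor
#' main-effects ANOVA for each requested factor combination, as used to
#' test light, nutrient and species effects on growth and clearance rates.
#' Numerator df equals levels - 1 per factor; denominator df is the
#' residual df.
#'
#' @param values numeric response (e.g. growth or clearance rates).
#' @param factors data.frame of factors, one row per value (e.g. `light`,
#'   `nutrient`, `species`).
#' @param combinations list of character vectors naming the factor sets to
#'   fit jointly (main effects only); defaults to all factors together.
#' @return object of class `rate_anova`: a data.frame with one row per
#'   fitted term (`model`, `term`, `F`, `p`, `Dfn`, `Dfd`).
#' @export
anova_rates <- function(values, factors,
                        combinations = list(names(factors))) {
  stopifnot(is.data.frame(factors), nrow(factors) == length(values))
  factors[] <- lapply(factors, factor)
  for (f in names(factors))
    if (nlevels(factors[[f]]) < 2L)
      stop("factor '", f, "' has fewer than 2 levels")
  dat <- cbind(.y = values, factors)
  fit_one <- function(terms) {
    fml <- as.formula(paste(".y ~", paste(terms, collapse = " + ")))
    fit <- aov(fml, data = dat)
    tab <- summary(fit)[[1L]]
    rownames(tab) <- trimws(rownames(tab))
    dfd <- if ("Residuals" %in% rownames(tab)) tab["Residuals", "Df"] else 0
    if (dfd < 1L) stop("saturated model: no residual degrees of freedom")
    rows <- setdiff(rownames(tab), "Residuals")
    data.frame(model = paste(terms, collapse = " + "),
               term = rows,
               F = tab[rows, "F value"],
               p = tab[rows, "Pr(>F)"],
               Dfn = tab[rows, "Df"],
               Dfd = dfd, row.names = NULL)
  }
  singles <- do.call(rbind, lapply(names(factors), fit_one))
  multis <- do.call(rbind, lapply(combinations, fit_one))
  structure(rbind(singles, multis), class = c("rate_anova", "data.frame"))
}

#' @export
print.rate_anova <- function(x, ...) {
  cat("ANOVA of culture rates\n")
  df <- as.data.frame(x)
  df$F <- signif(df$F, 3); df$p <- signif(df$p, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
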