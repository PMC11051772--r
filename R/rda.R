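# Constrained ordination: Escoufier equivalent-vectors selection of the
# species (response) matrix by RV coefficient, marginal permutation and
# collinearity screening of the environmental variables, and redundancy
# analysis as multivariate least squares followed by a singular value
# decomposition of the fitted matrix.

#' RV coefficient between two multivariate data sets
#'
#' The RV coefficient is a matrix correlation between two column-centred
#' data sets sharing rows: `tr(S_xy S_yx) / sqrt(tr(S_xx^2) tr(S_yy^2))`
#' with `S` the cross-product matrices. It is 1 when the two configurations
#' are identical up to rotation/scaling.
#'
#' @param x,y numeric matrices with the same number of rows.
#' @return scalar in \[0, 1\].
#' @export
rv_coefficient <- function(x, y) {
  x <- scale(as.matrix(x), center = TRUE, scale = FALSE)
  y <- scale(as.matrix(y), center = TRUE, scale = FALSE)
  sxy <- crossprod(x, y)
  sxx <- crossprod(x)
  syy <- crossprod(y)
  num <- sum(sxy * sxy)                # tr(Sxy Syx)
  den <- sqrt(sum(sxx * sxx) * sum(syy * syy))
  if (den == 0) return(0)
  num / den
}

#' Escoufier equivalent-vectors selection
#'
#' Greedy forward selection of columns (species) whose sub-matrix best
#' represents the full multivariate configuration: at each step the column
#' maximising the RV coefficient between the selected set and the full
#' matrix is added, stopping once RV >= `threshold`.
#'
#' @param x numeric matrix (samples x species) or `abundance_table`.
#' @param threshold RV stopping rule, default 0.9.
#' @return list with `selected` (column names in selection order), `rv`
#'   (RV trace, one value per step).
#' @export
escoufier_select <- function(x, threshold = 0.9) {
  m <- unclass(as.matrix(x))
  if (is.null(colnames(m))) colnames(m) <- paste0("sp", seq_len(ncol(m)))
  keep <- integer(0)
  rv_trace <- numeric(0)
  candidates <- seq_len(ncol(m))
  repeat {
    best <- NA_integer_; best_rv <- -Inf
    for (j in setdiff(candidates, keep)) {
      rv <- rv_coefficient(m[, c(keep, j), drop = FALSE], m)
      if (rv > best_rv) { best_rv <- rv; best <- j }
    }
    keep <- c(keep, best)
    rv_trace <- c(rv_trace, best_rv)
    if (best_rv >= threshold || length(keep) == ncol(m)) break
  }
  list(selected = colnames(m)[keep], rv = rv_trace)
}

# R^2 of the multivariate regression of centred y on centred x
rda_r2 <- function(yc, xc) {
  fit <- qr.fitted(qr(xc), yc)
  sum(fit^2) / sum(yc^2)
}

#' Variance inflation factors
#'
#' @param x numeric matrix of predictors (columns).
#' @return named vector of VIFs (1 for a single predictor).
#' @export
vif_screen <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) == 1L) return(setNames(1, colnames(x)))
  vapply(seq_len(ncol(x)), function(j) {
    r2 <- summary(lm(x[, j] ~ x[, -j, drop = FALSE]))$r.squared
    1 / max(1 - r2, .Machine$double.eps)
  }, numeric(1L)) |> setNames(colnames(x))
}

#' Redundancy analysis of trophic species on environmental gradients
#'
#' The Hellinger-transformed species matrix is first reduced with
#' [escoufier_select()]; each environmental variable is then screened by a
#' seeded marginal permutation test (single-variable constrained variance
#' against permuted rows, `alpha` level) and, among survivors, by iterative
#' removal of the highest variance inflation factor until all VIF <=
#' `vif_max`. The RDA itself is multivariate least squares of the centred
#' species matrix on the centred surviving variables followed by a
#' singular value decomposition of the fitted matrix. If no variable
#' survives, an unconstrained ordination (PCA of the species matrix) is
#' returned with a warning.
#'
#' @param species an `abundance_table` in mode `"hellinger"` (see
#'   [hellinger()]).
#' @param env a preprocessed `env_table` on the same samples.
#' @param escoufier_threshold RV stopping rule for species selection.
#' @param n_perm permutations for the marginal significance screen.
#' @param alpha significance level of the screen.
#' @param vif_max collinearity ceiling.
#' @param seed integer seed making the permutation p-values reproducible.
#' @return object of class `trophic_rda`: `species_scores` (V of the SVD),
#'   `sample_scores` (U D), `env_scores` (correlations of surviving
#'   variables with the sample scores), `eig` (squared singular values),
#'   `constrained_fraction`, `perm_p` (per-variable permutation p),
#'   `vif` (per surviving variable), `selected_species`,
#'   `selected_env`, `constrained` (logical).
#' @export
rda_species <- function(species, env, escoufier_threshold = 0.9,
                        n_perm = 999, alpha = 0.05, vif_max = 10,
                        seed = 1L) {
  stopifnot(inherits(species, "abundance_table"))
  if (abundance_mode(species) != "hellinger")
    stop("rda_species expects a Hellinger-transformed table; see hellinger()")
  vars <- attr(env, "variables")
  x_all <- as.matrix(as.data.frame(env)[vars])
  rownames(x_all) <- env$sample_id
  if (!identical(rownames(species), rownames(x_all)))
    x_all <- x_all[rownames(species), , drop = FALSE]
  if (anyNA(x_all)) stop("env table has missing values; run preprocess_env()")

  sel <- escoufier_select(species, threshold = escoufier_threshold)
  y <- unclass(species)[, sel$selected, drop = FALSE]
  yc <- scale(y, center = TRUE, scale = FALSE)

  set.seed(seed)
  n <- nrow(yc)
  perm_p <- setNames(rep(NA_real_, length(vars)), vars)
  for (v in vars) {
    xv <- scale(x_all[, v, drop = FALSE], center = TRUE, scale = FALSE)
    if (sd(xv) == 0) { perm_p[v] <- 1; next }
    obs <- rda_r2(yc, xv)
    exceed <- 0L
    for (b in seq_len(n_perm))
      if (rda_r2(yc, xv[sample.int(n), , drop = FALSE]) >= obs)
        exceed <- exceed + 1L
    perm_p[v] <- (1 + exceed) / (n_perm + 1)
  }
  surv <- vars[perm_p <= alpha]

  vif <- NULL
  if (length(surv)) {
    repeat {
      vif <- vif_screen(x_all[, surv, drop = FALSE])
      if (all(vif <= vif_max) || length(surv) == 1L) break
      surv <- setdiff(surv, names(which.max(vif)))
    }
    vif <- vif_screen(x_all[, surv, drop = FALSE])
  }

  if (!length(surv)) {
    warning("no environmental variable passed both screens; ",
            "returning an unconstrained ordination")
    sv <- svd(yc)
    return(structure(list(
      species_scores = structure(sv$v, dimnames = list(colnames(yc), NULL)),
      sample_scores = structure(sv$u %*% diag(sv$d, length(sv$d)),
                                dimnames = list(rownames(yc), NULL)),
      env_scores = NULL, eig = sv$d^2,
      constrained_fraction = NA_real_,
      perm_p = perm_p, vif = NULL,
      selected_species = sel$selected, selected_env = character(0),
      constrained = FALSE), class = "trophic_rda"))
  }

  xc <- scale(x_all[, surv, drop = FALSE], center = TRUE, scale = FALSE)
  fitted <- qr.fitted(qr(xc), yc)
  sv <- svd(fitted)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  d <- sv$d[seq_len(rank)]
  u <- sv$u[, seq_len(rank), drop = FALSE]
  vmat <- sv$v[, seq_len(rank), drop = FALSE]
  sample_scores <- u %*% diag(d, rank)
  dimnames(sample_scores) <- list(rownames(yc), paste0("RDA", seq_len(rank)))
  dimnames(vmat) <- list(colnames(yc), paste0("RDA", seq_len(rank)))
  env_scores <- stats::cor(xc, sample_scores)
  structure(list(species_scores = vmat,
                 sample_scores = sample_scores,
                 env_scores = env_scores,
                 eig = d^2,
                 constrained_fraction = sum(fitted^2) / sum(yc^2),
                 perm_p = perm_p,
                 vif = vif,
                 selected_species = sel$selected,
                 selected_env = surv,
                 constrained = TRUE),
            class = "trophic_rda")
}

#' @export
print.trophic_rda <- function(x, ...) {
  if (x$constrained) {
    cat(sprintf("Redundancy analysis: %d species (Escoufier-selected), %d constraining variable(s)\n",
                length(x$selected_species), length(x$selected_env)))
    cat(sprintf("  constrained variance fraction: %.3f\n", x$constrained_fraction))
    cat("  constraints:", paste(x$selected_env, collapse = ", "), "\n")
  } else {
    cat("Unconstrained ordination (no environmental variable passed screening)\n")
  }
  invisible(x)
}

#' @export
plot.trophic_rda <- function(x, ...) {
  ss <- x$sample_scores
  plot(ss[, 1L], ss[, 2L], pch = 16, col = "grey40",
       xlab = "axis 1", ylab = "axis 2", ...)
  sc <- x$species_scores * max(abs(ss)) / max(abs(x$species_scores))
  points(sc[, 1L], sc[, 2L], pch = 3, col = "firebrick")
  if (!is.null(x$env_scores)) {
    ar <- x$env_scores * max(abs(ss))
    for (i in seq_len(nrow(ar))) {
      lines(c(0, ar[i, 1L]), c(0, ar[i, 2L]), col = "steelblue")
    }
  }
  invisible(x)
}

#' @importFrom stats cor
NULL
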