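# rRNA copy-number correction: per-group linear model of 18S copies per
# cell on cellular biovolume, a correction factor (the fitted line at a
# reference biovolume), and division of gene counts into cell abundances.

#' Built-in correction-factor presets
#'
#' `"smallcell2024"` is the default set derived from calibration of small
#' cells (biovolumes 65-523 um^3, line evaluated at 65 um^3):
#' dinoflagellate 59.3, diatom 10.5, other 4.7 copies per cell.
#' `"martin2022"` is an alternative literature set (27.1, 4.4, 0.9) useful
#' for sensitivity analysis.
#'
#' @param name preset name.
#' @return named numeric vector with entries `dinoflagellate`, `diatom`,
#'   `other`.
#' @export
cf_preset <- function(name = c("smallcell2024", "martin2022")) {
  name <- match.arg(name)
  switch(name,
    smallcell2024 = c(dinoflagellate = 59.3, diatom = 10.5, other = 4.7),
    martin2022    = c(dinoflagellate = 27.1, diatom = 4.4,  other = 0.9))
}

#' Fit a copies-per-cell vs biovolume model
#'
#' Ordinary least squares of 18S rRNA gene copies per cell on cellular
#' biovolume for one taxonomic group. The correction factor (C.F.) is the
#' fitted line evaluated at a reference biovolume `v_ref` (default 65 um^3,
#' the calibration range boundary used for small 0.8-5 um plankton).
#'
#' @param points data.frame with columns `biovolume_um3`, `copies_per_cell`
#'   and optionally `group`.
#' @param group if `points` has a `group` column, fit only rows of this
#'   group; otherwise ignored.
#' @param v_ref reference biovolume (um^3) at which the correction factor is
#'   evaluated.
#' @param log_log fit `log10(copies) ~ log10(biovolume)` instead of the
#'   default linear axes; the correction factor is then back-transformed.
#' @return object of class `copy_model` with components `group`, `slope`,
#'   `intercept`, `v_ref`, `cf`, `n_points`, `r_squared`, `residual_sd`,
#'   `log_log` and the underlying `lm` fit.
#' @examples
#' pts <- data.frame(biovolume_um3 = c(65, 130), copies_per_cell = c(10, 20))
#' fit_copy_model(pts)$cf   # 10
#' @export
fit_copy_model <- function(points, group = NULL, v_ref = 65, log_log = FALSE) {
  stopifnot(is.data.frame(points),
            all(c("biovolume_um3", "copies_per_cell") %in% names(points)))
  if (!is.null(group) && "group" %in% names(points))
    points <- points[points$group == group, , drop = FALSE]
  v <- points$biovolume_um3
  y <- points$copies_per_cell
  if (any(v <= 0)) stop("biovolumes must be positive")
  if (any(y <= 0)) stop("copies per cell must be positive")
  if (length(v) < 2L || length(unique(v)) < 2L)
    stop("degenerate fit: need at least 2 points with distinct biovolumes",
         if (!is.null(group)) paste0(" for group '", group, "'"))
  fit <- if (log_log) lm(log10(y) ~ log10(v)) else lm(y ~ v)
  cf <- predict_cf(coef(fit), v_ref, log_log)
  if (cf <= 0)
    stop("fitted correction factor is non-positive at v_ref = ", v_ref,
         "; consider a through-origin or log-log refit (log_log = TRUE)")
  s <- suppressWarnings(summary(fit))   # exact two-point fits are legitimate
  structure(list(group = if (is.null(group)) NA_character_ else group,
                 slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 v_ref = v_ref,
                 cf = cf,
                 n_points = length(v),
                 r_squared = s$r.squared,
                 residual_sd = s$sigma,
                 log_log = log_log,
                 fit = fit),
            class = "copy_model")
}

predict_cf <- function(beta, v_ref, log_log) {
  if (log_log) 10^(beta[1L] + beta[2L] * log10(v_ref))
  else unname(beta[1L] + beta[2L] * v_ref)
}

#' Correction factor of a fitted copy model
#'
#' Evaluates the fitted copies-vs-biovolume line at a reference biovolume.
#'
#' @param model a `copy_model`.
#' @param v_ref reference biovolume (um^3); defaults to the model's stored
#'   value.
#' @return the correction factor (copies per cell), a positive scalar.
#' @export
correction_factor <- function(model, v_ref = model$v_ref) {
  stopifnot(inherits(model, "copy_model"))
  cf <- predict_cf(c(model$intercept, model$slope), v_ref, model$log_log)
  if (cf <= 0) stop("correction factor non-positive at v_ref = ", v_ref)
  cf
}

#' @export
print.copy_model <- function(x, ...) {
  cat(sprintf("Copy-number model (%s axes)%s\n",
              if (x$log_log) "log-log" else "linear",
              if (is.na(x$group)) "" else paste0(" for group '", x$group, "'")))
  cat(sprintf("  copies/cell = %.4g + %.4g * biovolume  (n = %d, R^2 = %.3f)\n",
              x$intercept, x$slope, x$n_points, x$r_squared))
  cat(sprintf("  correction factor at %g um^3: %.4g copies/cell\n",
              x$v_ref, x$cf))
  invisible(x)
}

#' @export
coef.copy_model <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.copy_model <- function(object, biovolume_um3, ...) {
  sapply(biovolume_um3, function(v)
    predict_cf(c(object$intercept, object$slope), v, object$log_log))
}

#' @export
summary.copy_model <- function(object, ...) {
  print(object)
  cat(sprintf("  residual SD: %.4g copies/cell\n", object$residual_sd))
  invisible(object)
}

#' Fit copy models for all groups in a calibration table
#'
#' @param calibration data.frame with `group`, `biovolume_um3`,
#'   `copies_per_cell`.
#' @inheritParams fit_copy_model
#' @return named list of `copy_model` objects, one per group present.
#' @export
fit_copy_models <- function(calibration, v_ref = 65, log_log = FALSE) {
  groups <- unique(calibration$group)
  setNames(lapply(groups, function(g)
    fit_copy_model(calibration, group = g, v_ref = v_ref, log_log = log_log)),
    groups)
}

#' Convert gene abundances to cell abundances
#'
#' Divides each lineage's gene counts by the correction factor of its
#' copy-number group (dinoflagellate / diatom / other, derived from the
#' taxonomy). Within-group relative composition is unchanged; the returned
#' table has mode `"cell"`.
#'
#' @param table an `abundance_table` with mode `"gene"`.
#' @param taxonomy taxonomy data.frame covering the table's lineages (see
#'   [read_taxonomy()]).
#' @param cf_map named numeric vector of correction factors per group, e.g.
#'   [cf_preset()], or a list of fitted `copy_model`s.
#' @param overrides optional named vector of per-lineage correction factors
#'   taking precedence over the group map.
#' @return an `abundance_table` with mode `"cell"`.
#' @export
gene_to_cell <- function(table, taxonomy, cf_map = cf_preset(),
                         overrides = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  if (abundance_mode(table) != "gene")
    stop("gene_to_cell expects a table in mode 'gene', got '",
         abundance_mode(table), "'")
  if (is.list(cf_map) && all(vapply(cf_map, inherits, TRUE, "copy_model")))
    cf_map <- vapply(cf_map, `[[`, numeric(1L), "cf")
  if (any(cf_map <= 0)) stop("all correction factors must be positive")
  grp <- setNames(taxonomy$cf_group, taxonomy$lineage_id)
  missing <- setdiff(colnames(table), names(grp))
  if (length(missing))
    stop("lineage(s) without taxonomy/group: ", paste(missing, collapse = ", "))
  cf <- cf_map[grp[colnames(table)]]
  if (anyNA(cf))
    stop("no correction factor for group(s): ",
         paste(unique(grp[colnames(table)][is.na(cf)]), collapse = ", "))
  if (!is.null(overrides)) {
    hit <- intersect(names(overrides), colnames(table))
    if (any(overrides[hit] <= 0)) stop("override correction factors must be positive")
    cf[match(hit, colnames(table))] <- overrides[hit]
  }
  out <- sweep(unclass(table), 2L, cf, `/`)
  as_abundance(out, "cell")
}

#' Read a copy-number calibration CSV
#'
#' Expected columns: `group,biovolume_um3,copies_per_cell`.
#'
#' @param path path to the CSV.
#' @return validated calibration data.frame.
#' @export
read_calibration <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "biovolume_um3", "copies_per_cell")
  if (!all(need %in% names(df)))
    stop("calibration file must have columns: ", paste(need, collapse = ", "))
  if (any(df$biovolume_um3 <= 0)) stop("biovolumes must be positive")
  if (any(df$copies_per_cell < 1)) stop("copies per cell must be >= 1")
  df
}
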