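# Per-sample trophic indices TI_M / TI_A / TI_H (relative abundance of
# each trophic group against the community total) and paired comparison of
# indices between the surface and the chlorophyll maximum layer.

#' Compute per-sample trophic indices
#'
#' For each sample, the trophic index of group g (mixotroph M, autotroph A,
#' heterotroph H) is the summed abundance of mode-g lineages divided by a
#' community total T. With `denominator = "all_retained"` (default) T
#' includes unknown-mode lineages, so TI_M + TI_A + TI_H <= 1; with
#' `"annotated_only"` T covers only annotated lineages and the indices sum
#' to 1. Samples with zero denominator are flagged and returned with `NA`
#' indices.
#'
#' @param table an `abundance_table` in mode `"gene"` or `"cell"`.
#' @param modes a `mode_assignment` covering the table's lineages (see
#'   [assign_modes()]).
#' @param denominator `"all_retained"` or `"annotated_only"`.
#' @return data.frame of class `trophic_index`: `sample_id`, `TI_M`,
#'   `TI_A`, `TI_H`, `total`; attributes `denominator`, `abundance_mode`,
#'   `flagged` (samples with zero denominator).
#' @examples
#' m <- matrix(c(3, 2, 5), 1, dimnames = list("s1", c("L1", "L2", "L3")))
#' ab <- abundance_table(m, "cell")
#' asn <- structure(data.frame(lineage_id = c("L1", "L2", "L3"),
#'                             mode = c("M", "A", "H"),
#'                             resolution_rank = "species"),
#'                  class = c("mode_assignment", "data.frame"))
#' compute_ti(ab, asn)   # TI = 0.3 / 0.2 / 0.5
#' @export
compute_ti <- function(table, modes,
                       denominator = c("all_retained", "annotated_only")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(table, "abundance_table"))
  if (!abundance_mode(table) %in% c("gene", "cell"))
    stop("compute_ti expects mode 'gene' or 'cell'")
  mode_of <- setNames(modes$mode, modes$lineage_id)
  missing <- setdiff(colnames(table), names(mode_of))
  if (length(missing))
    stop("lineage(s) without a mode assignment: ",
         paste(missing, collapse = ", "))
  m <- mode_of[colnames(table)]
  v <- unclass(table)
  sum_mode <- function(g) {
    cols <- which(m == g)
    if (!length(cols)) return(rep(0, nrow(v)))
    rowSums(v[, cols, drop = FALSE])
  }
  M <- sum_mode("M"); A <- sum_mode("A"); H <- sum_mode("H")
  total <- if (denominator == "all_retained") rowSums(v) else M + A + H
  flagged <- rownames(v)[total == 0]
  total[total == 0] <- NA_real_
  out <- data.frame(sample_id = rownames(v),
                    TI_M = M / total, TI_A = A / total, TI_H = H / total,
                    total = ifelse(is.na(total), 0, total),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out,
            denominator = denominator,
            abundance_mode = abundance_mode(table),
            flagged = flagged,
            class = c("trophic_index", "data.frame"))
}

#' @export
print.trophic_index <- function(x, ...) {
  cat(sprintf(
    "Trophic indices for %d samples (%s abundances, denominator = %s)\n",
    nrow(x), attr(x, "abundance_mode"), attr(x, "denominator")))
  cat(sprintf("  medians: TI_M %.3f | TI_A %.3f | TI_H %.3f\n",
              median(x$TI_M, na.rm = TRUE), median(x$TI_A, na.rm = TRUE),
              median(x$TI_H, na.rm = TRUE)))
  fl <- attr(x, "flagged")
  if (length(fl)) cat("  zero-denominator samples:", paste(fl, collapse = ", "), "\n")
  invisible(x)
}

#' Regional aggregation of trophic indices
#'
#' Summarises per-sample indices within groups (e.g. latitudinal bands),
#' reporting the median (the headline convention) and the mean of each
#' index.
#'
#' @param ti a `trophic_index` table.
#' @param groups factor/character vector, one entry per sample.
#' @return data.frame with one row per group: n, median and mean of each
#'   index.
#' @export
aggregate_ti <- function(ti, groups) {
  stopifnot(length(groups) == nrow(ti))
  do.call(rbind, lapply(split(seq_len(nrow(ti)), groups), function(i) {
    data.frame(group = as.character(groups[i[1L]]), n = length(i),
               TI_M_median = median(ti$TI_M[i], na.rm = TRUE),
               TI_A_median = median(ti$TI_A[i], na.rm = TRUE),
               TI_H_median = median(ti$TI_H[i], na.rm = TRUE),
               TI_M_mean = mean(ti$TI_M[i], na.rm = TRUE),
               TI_A_mean = mean(ti$TI_A[i], na.rm = TRUE),
               TI_H_mean = mean(ti$TI_H[i], na.rm = TRUE),
               row.names = NULL)
  }))
}

#' Paired surface-versus-depth comparison of a trophic index
#'
#' Pairs samples by station across the two depth layers (surface SUR and
#' chlorophyll maximum CML) and tests the within-station difference with a
#' paired t-test (df = pairs - 1); a paired Wilcoxon signed-rank test is
#' reported alongside as a robustness companion. The t statistic is
#' positive when the surface mean exceeds the depth mean.
#'
#' @param ti a `trophic_index` table covering samples of both layers.
#' @param env an `env_table` mapping `sample_id` to `station_id` and
#'   `layer`.
#' @param index which index to compare: `"TI_M"`, `"TI_A"` or `"TI_H"`.
#' @return object of class `layer_test`: `n_pairs`, `statistic`, `df`,
#'   `p_value`, `wilcoxon_p`, `medians` (per layer), `mean_difference`
#'   (SUR - CML).
#' @export
compare_layers <- function(ti, env, index = c("TI_M", "TI_A", "TI_H")) {
  index <- match.arg(index)
  idx <- match(ti$sample_id, env$sample_id)
  if (anyNA(idx))
    stop("sample(s) missing from env table: ",
         paste(ti$sample_id[is.na(idx)], collapse = ", "))
  d <- data.frame(station = env$station_id[idx], layer = env$layer[idx],
                  y = ti[[index]])
  wide <- merge(d[d$layer == "SUR", c("station", "y")],
                d[d$layer == "CML", c("station", "y")],
                by = "station", suffixes = c("_sur", "_cml"))
  wide <- wide[complete.cases(wide), , drop = FALSE]
  n <- nrow(wide)
  if (n < 3L) stop("need at least 3 stations with both SUR and CML samples")
  d <- wide$y_sur - wide$y_cml
  if (sd(d) == 0) {
    # degenerate paired test: no within-pair variance
    tt <- list(statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
               parameter = n - 1L,
               p.value = if (mean(d) == 0) 1 else 0)
  } else {
    tt <- t.test(wide$y_sur, wide$y_cml, paired = TRUE)
  }
  wt <- if (all(d == 0)) list(p.value = 1) else
    suppressWarnings(wilcox.test(wide$y_sur, wide$y_cml, paired = TRUE,
                                 exact = FALSE))
  structure(list(index = index,
                 n_pairs = n,
                 statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value,
                 wilcoxon_p = wt$p.value,
                 medians = c(SUR = median(wide$y_sur), CML = median(wide$y_cml)),
                 mean_difference = mean(wide$y_sur - wide$y_cml)),
            class = "layer_test")
}

#' @export
print.layer_test <- function(x, ...) {
  cat(sprintf("Paired SUR vs CML comparison of %s (%d station pairs)\n",
              x$index, x$n_pairs))
  cat(sprintf("  medians: SUR %.3f vs CML %.3f\n",
              x$medians["SUR"], x$medians["CML"]))
  cat(sprintf("  paired t = %.3f, df = %d, p = %.3g (Wilcoxon p = %.3g)\n",
              x$statistic, x$df, x$p_value, x$wilcoxon_p))
  invisible(x)
}
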