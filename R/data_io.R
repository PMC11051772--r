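# Tabular I/O: lineage-by-sample abundance matrices, ranked taxonomy,
# environmental context tables, and the environmental preprocessing
# (mean imputation + log transform) applied before ordination.

PR2_RANKS <- c("domain", "supergroup", "division", "class",
               "order", "family", "genus", "species")

#' Construct an abundance table
#'
#' An abundance table is a non-negative numeric matrix with samples as rows
#' and lineages as columns, tagged with the scale its values are on:
#' `"gene"` (raw 18S rRNA gene counts), `"cell"` (copy-number corrected cell
#' abundances) or `"hellinger"` (square-rooted relative abundances).
#'
#' @param values numeric matrix, samples x lineages, with dimnames.
#' @param mode one of `"gene"`, `"cell"`, `"hellinger"`.
#' @param check_integer enforce integer-valued counts when `mode = "gene"`.
#'   Gene tables read from sequencing output are counts; the noise-free
#'   synthetic generator disables the check because its exact gene values
#'   are cell abundances times a fractional copy-number factor.
#' @return a matrix of class `abundance_table` with a `mode` attribute.
#' @export
abundance_table <- function(values, mode = c("gene", "cell", "hellinger"),
                            check_integer = TRUE) {
  mode <- match.arg(mode)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (samples x lineages)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry sample ids as rownames and lineage ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate lineage ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (any(!is.finite(values)) || any(values < 0))
    stop("abundance values must be finite and non-negative")
  if (mode == "gene" && check_integer && any(abs(values - round(values)) > 1e-6))
    stop("mode 'gene' requires integer-valued counts")
  structure(values, mode = mode, class = c("abundance_table", "matrix", "array"))
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("Abundance table: %d samples x %d lineages (mode = %s)\n",
              nrow(x), ncol(x), abundance_mode(x)))
  n <- min(5L, nrow(x)); m <- min(5L, ncol(x))
  print(unclass(x)[seq_len(n), seq_len(m), drop = FALSE], ...)
  if (nrow(x) > n || ncol(x) > m) cat("...\n")
  invisible(x)
}

#' Abundance mode tag
#' @param x an `abundance_table`.
#' @return `"gene"`, `"cell"` or `"hellinger"`.
#' @export
abundance_mode <- function(x) attr(x, "mode")

# rebuild the class after subsetting-like operations
as_abundance <- function(values, mode) {
  structure(values, mode = mode, class = c("abundance_table", "matrix", "array"))
}

#' Read an abundance + taxonomy bundle
#'
#' Reads the lineage-by-sample count matrix (TSV, first column `lineage_id`,
#' remaining columns sample ids; a transposed file with leading `sample_id`
#' column is auto-detected) and the companion taxonomy (TSV with
#' `lineage_id` and a semicolon-delimited 8-rank path,
#' domain;supergroup;division;class;order;family;genus;species).
#'
#' @param abundance_path path to the count TSV.
#' @param taxonomy_path path to the taxonomy TSV.
#' @param mode abundance scale of the file, default `"gene"`.
#' @return list with elements `abundance` (an [abundance_table()]),
#'   `taxonomy` (see [read_taxonomy()]), and `unmapped` (lineage ids present
#'   in the matrix but absent from the taxonomy).
#' @export
read_community_bundle <- function(abundance_path, taxonomy_path, mode = "gene") {
  ab <- read_abundance(abundance_path, mode = mode)
  tx <- read_taxonomy(taxonomy_path)
  unmapped <- setdiff(colnames(ab), tx$lineage_id)
  if (length(unmapped))
    warning(length(unmapped), " lineage(s) missing from taxonomy: ",
            paste(head(unmapped, 5L), collapse = ", "))
  list(abundance = ab, taxonomy = tx, unmapped = unmapped)
}

#' Read a lineage-by-sample abundance TSV
#'
#' @inheritParams read_community_bundle
#' @param path path to the TSV.
#' @return an [abundance_table()] with samples as rows.
#' @export
read_abundance <- function(path, mode = "gene") {
  raw <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (nrow(raw) == 0L || ncol(raw) < 2L) stop("empty abundance table: ", path)
  sentinel <- tolower(names(raw)[1L])
  if (sentinel == "sample_id") {          # samples-as-rows dialect
    ids <- raw[[1L]]
    body <- raw[-1L]
    m <- parse_numeric_block(body, ids, names(body), path)
  } else if (sentinel == "lineage_id") {  # lineages-as-rows (default dialect)
    ids <- raw[[1L]]
    body <- raw[-1L]
    m <- t(parse_numeric_block(body, ids, names(body), path))
  } else {
    stop("first column of ", path, " must be 'lineage_id' or 'sample_id', got '",
         names(raw)[1L], "'")
  }
  abundance_table(m, mode = mode)
}

# parse a character data.frame to a numeric matrix, citing bad cells
parse_numeric_block <- function(df, row_ids, col_ids, path) {
  if (anyDuplicated(row_ids))
    stop("duplicate ids in first column of ", path, ": ",
         paste(unique(row_ids[duplicated(row_ids)]), collapse = ", "))
  m <- matrix(NA_real_, nrow = length(row_ids), ncol = length(col_ids),
              dimnames = list(row_ids, col_ids))
  for (j in seq_along(col_ids)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !(df[[j]] %in% c("", "NA", NA)))
    if (length(bad))
      stop(sprintf("malformed numeric cell '%s' (row '%s', column '%s') in %s",
                   df[[j]][bad[1L]], row_ids[bad[1L]], col_ids[j], path))
    m[, j] <- v
  }
  if (anyNA(m)) stop("missing values are not allowed in abundance matrices: ", path)
  m
}

#' Read a ranked taxonomy TSV
#'
#' Expects columns `lineage_id` and `ranked_path`, the latter a
#' semicolon-delimited 8-rank path. The copy-number correction group is
#' derived from the path: any rank equal to `Dinoflagellata` maps to
#' `dinoflagellate`, `Bacillariophyta` to `diatom`, anything else to
#' `other`.
#'
#' @param path path to the taxonomy TSV.
#' @return data.frame with `lineage_id`, one column per rank
#'   (domain...species), `phylum` (the division rank), and `cf_group`.
#' @export
read_taxonomy <- function(path) {
  raw <- read.delim(path, check.names = FALSE, colClasses = "character")
  need <- c("lineage_id", "ranked_path")
  if (!all(need %in% names(raw)))
    stop("taxonomy file must have columns 'lineage_id' and 'ranked_path'")
  if (nrow(raw) == 0L) stop("empty taxonomy table: ", path)
  if (anyDuplicated(raw$lineage_id))
    stop("duplicate lineage_id in taxonomy: ",
         paste(unique(raw$lineage_id[duplicated(raw$lineage_id)]), collapse = ", "))
  taxonomy_table(raw$lineage_id, raw$ranked_path)
}

#' Build a taxonomy table from ranked paths
#'
#' @param lineage_id character vector of unique lineage ids.
#' @param ranked_path semicolon-delimited 8-rank paths, one per lineage.
#' @return data.frame as in [read_taxonomy()].
#' @export
taxonomy_table <- function(lineage_id, ranked_path) {
  stopifnot(length(lineage_id) == length(ranked_path))
  if (anyDuplicated(lineage_id)) stop("duplicate lineage_id")
  parts <- strsplit(ranked_path, ";", fixed = TRUE)
  parts <- lapply(parts, function(p) {
    p <- trimws(p)
    length(p) <- length(PR2_RANKS)   # pad short paths with NA
    p
  })
  ranks <- do.call(rbind, parts)
  colnames(ranks) <- PR2_RANKS
  tx <- data.frame(lineage_id = lineage_id, ranks,
                   stringsAsFactors = FALSE, check.names = FALSE)
  tx$phylum <- tx$division
  tx$cf_group <- apply(ranks, 1L, function(p) {
    if ("Dinoflagellata" %in% p) "dinoflagellate"
    else if ("Bacillariophyta" %in% p) "diatom"
    else "other"
  })
  tx
}

#' Read an environmental context table
#'
#' CSV with mandatory `sample_id`, `station_id`, `layer` columns (layer one
#' of `SUR` — surface — or `CML` — chlorophyll maximum layer) followed by
#' environmental variable columns. Blank cells and `NA` denote missing
#' values; they are preserved, not imputed. Variable columns not present in
#' the shipped 29-variable registry are loaded and flagged.
#'
#' @param path path to the CSV.
#' @return data.frame of class `env_table` with attributes `mask` (logical
#'   missing-value matrix over variable columns), `variables` (variable
#'   column names) and `non_registry` (variables outside the registry).
#' @export
read_env_table <- function(path) {
  raw <- read.csv(path, check.names = FALSE)
  env_table(raw)
}

#' Validate/construct an environmental table
#'
#' @param df data.frame with `sample_id`, `station_id`, `layer` plus numeric
#'   variable columns.
#' @return the validated `env_table` (see [read_env_table()]).
#' @export
env_table <- function(df) {
  need <- c("sample_id", "station_id", "layer")
  if (!all(need %in% names(df)))
    stop("env table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in env table: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  bad <- !df$layer %in% c("SUR", "CML")
  if (any(bad))
    stop("layer must be 'SUR' or 'CML'; offending sample(s): ",
         paste(df$sample_id[bad], collapse = ", "))
  vars <- setdiff(names(df), need)
  for (v in vars) df[[v]] <- suppressWarnings(as.numeric(df[[v]]))
  mask <- sapply(df[vars], is.na)
  if (length(vars) == 1L) mask <- matrix(mask, ncol = 1L, dimnames = list(NULL, vars))
  rownames(mask) <- df$sample_id
  registry <- env_registry()$variable
  structure(df,
            mask = mask,
            variables = vars,
            non_registry = setdiff(vars, registry),
            class = c("env_table", "data.frame"))
}

#' @export
print.env_table <- function(x, ...) {
  vars <- attr(x, "variables")
  cat(sprintf("Environmental table: %d samples, %d variables (%d missing cells)\n",
              nrow(x), length(vars), sum(attr(x, "mask"))))
  nr <- attr(x, "non_registry")
  if (length(nr)) cat("Non-registry variables:", paste(nr, collapse = ", "), "\n")
  NextMethod()
}

#' The environmental variable registry
#'
#' The set of 29 contextual variables the pipeline recognises: physics
#' (temperature, salinity, density, light attenuation, layer depths),
#' climatology (photosynthetically available radiation, sunshine duration),
#' biogeochemistry (chlorophyll, oxygen, nutrients, carbonate system,
#' particulate carbon) and bacterial abundances. Shipped as a plain-text
#' fixture in `inst/extdata/env_registry.csv`.
#'
#' @return data.frame with columns `variable`, `unit`, `description`.
#' @export
env_registry <- function() {
  path <- system.file("extdata", "env_registry.csv", package = "mixoniche")
  if (path == "") path <- file.path("inst", "extdata", "env_registry.csv")
  read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Impute and log-transform an environmental table
#'
#' Missing entries of each variable are replaced by that variable's mean
#' (computed before any transform), then each variable is log10-transformed.
#' Variables containing non-positive values use a shifted log,
#' `log10(x + eps)` with `eps` = half the smallest positive observed value;
#' the shift is recorded per variable. Optionally z-scores the result for
#' ordination input.
#'
#' @param env an `env_table`.
#' @param transform `"log10"` (default), or `"identity"` to impute only.
#' @param scale logical; additionally centre and scale each variable to unit
#'   variance (for principal component input). Default `FALSE`.
#' @return an `env_table` with no missing values; attribute `shifts` records
#'   the per-variable shift used (0 where a plain log applied), attribute
#'   `preprocessed = TRUE`.
#' @export
preprocess_env <- function(env, transform = c("log10", "identity"),
                           scale = FALSE) {
  transform <- match.arg(transform)
  vars <- attr(env, "variables")
  shifts <- setNames(numeric(length(vars)), vars)
  out <- env
  for (v in vars) {
    x <- env[[v]]
    if (all(is.na(x))) stop("variable '", v, "' is entirely missing")
    mu <- mean(x, na.rm = TRUE)
    x[is.na(x)] <- mu
    if (transform == "log10") {
      if (any(x <= 0)) {
        pos <- x[x > 0]
        eps <- if (length(pos)) min(pos) / 2 else 1
        shifts[v] <- eps
        x <- log10(x + eps)
      } else {
        x <- log10(x)
      }
    }
    if (scale) {
      s <- sd(x)
      if (s == 0) stop("variable '", v, "' is constant and cannot be z-scored")
      x <- (x - mean(x)) / s
    }
    out[[v]] <- x
  }
  attr(out, "mask") <- attr(env, "mask") & FALSE
  attr(out, "shifts") <- shifts
  attr(out, "preprocessed") <- TRUE
  attr(out, "transform") <- transform
  out
}

#' Write an abundance table to TSV
#'
#' Lineages-as-rows dialect: first column `lineage_id`, remaining columns
#' sample ids. UTF-8, LF line endings.
#'
#' @param x an `abundance_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(x, path) {
  df <- data.frame(lineage_id = colnames(x), t(unclass(x)),
                   check.names = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Write an environmental table to CSV
#'
#' @param env an `env_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_env_table <- function(env, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(as.data.frame(env), con, sep = ",", quote = FALSE,
              row.names = FALSE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' @importFrom utils write.table
NULL
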