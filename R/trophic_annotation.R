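# Trophic-mode annotation: taxon exclusion policy and rank-fallback
# assignment of mixotroph (M) / autotroph (A) / heterotroph (H) modes from
# a curated lookup table.

#' Default taxon exclusion policy
#'
#' Two sets of taxa are removed before trophic analysis of small
#' constitutive mixotrophs: `excluded_taxa` are groups whose reads derive
#' mostly from large-celled populations (Ciliophora, Radiolaria,
#' Foraminifera); `unannotatable_taxa` are groups that cannot be given a
#' trophic mode in this framework (unknown Eukaryota placeholders, Fungi,
#' Amoebozoa, and the parasitic Syndiniales). Both are matched against any
#' rank of a lineage's taxonomy path. Non-Syndiniales Dinoflagellata are
#' kept; a `blocklist` of explicit lineage ids handles finer cases.
#'
#' @param excluded_taxa character set matched at any rank.
#' @param unannotatable_taxa character set matched at any rank.
#' @param blocklist explicit lineage ids to drop.
#' @return object of class `exclusion_policy`.
#' @export
exclusion_policy <- function(excluded_taxa = c("Ciliophora", "Radiolaria",
                                               "Foraminifera"),
                             unannotatable_taxa = c("Eukaryota_X", "Fungi",
                                                    "Amoebozoa", "Syndiniales"),
                             blocklist = character()) {
  structure(list(excluded_taxa = excluded_taxa,
                 unannotatable_taxa = unannotatable_taxa,
                 blocklist = blocklist),
            class = "exclusion_policy")
}

#' Drop excluded lineages from a community
#'
#' Removes lineages whose ranked taxonomy path contains any taxon of the
#' policy's exclusion or unannotatable sets (or whose id is blocklisted),
#' and reports which taxon triggered each removal.
#'
#' @param table an `abundance_table`.
#' @param taxonomy taxonomy covering the table's lineages.
#' @param policy an [exclusion_policy()].
#' @return list with `table` (filtered `abundance_table`) and `report`
#'   (named list: triggering taxon -> dropped lineage ids).
#' @export
apply_exclusions <- function(table, taxonomy, policy = exclusion_policy()) {
  stopifnot(inherits(table, "abundance_table"))
  tx <- taxonomy[match(colnames(table), taxonomy$lineage_id), , drop = FALSE]
  if (anyNA(tx$lineage_id))
    stop("taxonomy does not cover lineage(s): ",
         paste(colnames(table)[is.na(tx$lineage_id)], collapse = ", "))
  ranks <- as.matrix(tx[, PR2_RANKS, drop = FALSE])
  triggers <- c(policy$excluded_taxa, policy$unannotatable_taxa)
  report <- list()
  drop <- rep(FALSE, ncol(table))
  for (taxon in triggers) {
    hit <- apply(ranks, 1L, function(p) taxon %in% p)
    hit <- hit & !drop             # first trigger wins in the report
    if (any(hit)) report[[taxon]] <- colnames(table)[hit]
    drop <- drop | hit
  }
  bl <- colnames(table) %in% policy$blocklist & !drop
  if (any(bl)) report[["blocklist"]] <- colnames(table)[bl]
  drop <- drop | bl
  if (all(drop)) warning("all lineages excluded; returning an empty table")
  kept <- unclass(table)[, !drop, drop = FALSE]
  list(table = as_abundance(kept, abundance_mode(table)), report = report)
}

#' Read a trophic annotation table
#'
#' TSV with columns `taxon`, `rank` (one of species/genus/family), `mode`
#' (M = mixotroph, A = autotroph, H = heterotroph) and optional `source`.
#' Conflicting entries (same taxon and rank, different modes) are an error
#' at load time.
#'
#' @param path path to the TSV; defaults to the small demonstration table
#'   shipped with the package.
#' @return object of class `trophic_db`: data.frame `taxon`, `rank`,
#'   `mode`, `source`.
#' @export
read_trophic_db <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "trophic_db_demo.tsv", package = "mixoniche")
    if (path == "") path <- file.path("inst", "extdata", "trophic_db_demo.tsv")
  }
  df <- read.delim(path, stringsAsFactors = FALSE)
  trophic_db(df)
}

#' Construct/validate a trophic annotation table
#'
#' @param df data.frame with `taxon`, `rank`, `mode` (and optional
#'   `source`).
#' @return object of class `trophic_db`.
#' @export
trophic_db <- function(df) {
  need <- c("taxon", "rank", "mode")
  if (!all(need %in% names(df)))
    stop("trophic db needs columns: ", paste(need, collapse = ", "))
  if (!"source" %in% names(df)) df$source <- NA_character_
  df$taxon <- gsub("\\s+", " ", trimws(df$taxon))
  if (!all(df$rank %in% c("species", "genus", "family")))
    stop("rank must be species, genus or family")
  if (!all(df$mode %in% c("M", "A", "H")))
    stop("mode must be one of M, A, H")
  key <- paste(df$taxon, df$rank)
  for (k in unique(key[duplicated(key)])) {
    modes <- unique(df$mode[key == k])
    if (length(modes) > 1L)
      stop("conflicting trophic modes for ", k, ": ",
           paste(modes, collapse = " vs "))
  }
  df <- df[!duplicated(key), , drop = FALSE]
  structure(df, class = c("trophic_db", "data.frame"))
}

#' Assign trophic modes with rank fallback
#'
#' Looks each lineage up in the annotation table at species rank first,
#' then genus, then family; the first hit wins and the resolving rank is
#' recorded. Lineages with no hit at any rank get mode `"unknown"`.
#' Matching is by exact name after whitespace normalisation (placeholder
#' names such as `Chrysophyceae_Clade_G_sp.` match verbatim at species
#' rank).
#'
#' @param taxonomy taxonomy data.frame (see [read_taxonomy()]).
#' @param db a [trophic_db()].
#' @return data.frame of class `mode_assignment`: `lineage_id`, `mode`
#'   (M/A/H/unknown), `resolution_rank` (species/genus/family/none).
#' @export
assign_modes <- function(taxonomy, db) {
  stopifnot(inherits(db, "trophic_db"))
  if (nrow(db) == 0L) stop("empty trophic annotation table")
  lookup <- function(rank) {
    sub <- db[db$rank == rank, , drop = FALSE]
    setNames(sub$mode, sub$taxon)
  }
  maps <- list(species = lookup("species"),
               genus = lookup("genus"),
               family = lookup("family"))
  norm <- function(x) gsub("\\s+", " ", trimws(x))
  mode <- rep("unknown", nrow(taxonomy))
  res <- rep("none", nrow(taxonomy))
  for (rank in c("species", "genus", "family")) {
    names_at <- norm(taxonomy[[rank]])
    hit <- mode == "unknown" & !is.na(names_at) & names_at %in% names(maps[[rank]])
    mode[hit] <- maps[[rank]][names_at[hit]]
    res[hit] <- rank
  }
  structure(data.frame(lineage_id = taxonomy$lineage_id,
                       mode = mode, resolution_rank = res,
                       stringsAsFactors = FALSE),
            class = c("mode_assignment", "data.frame"))
}

#' @export
print.mode_assignment <- function(x, ...) {
  tab <- table(factor(x$mode, levels = c("M", "A", "H", "unknown")))
  cat(sprintf("Trophic mode assignment for %d lineages:\n", nrow(x)))
  cat(sprintf("  mixotroph %d | autotroph %d | heterotroph %d | unknown %d\n",
              tab["M"], tab["A"], tab["H"], tab["unknown"]))
  invisible(x)
}
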