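# Fixtures built in code: tiny abundance/taxonomy/env tables and mode
# assignments shared across the test files.

make_assignment <- function(lineage_id, mode) {
  structure(data.frame(lineage_id = lineage_id, mode = mode,
                       resolution_rank = ifelse(mode == "unknown",
                                                "none", "species"),
                       stringsAsFactors = FALSE),
            class = c("mode_assignment", "data.frame"))
}

make_abundance <- function(values, mode = "cell",
                           samples = sprintf("s%d", seq_len(nrow(values))),
                           lineages = sprintf("L%d", seq_len(ncol(values)))) {
  dimnames(values) <- list(samples, lineages)
  abundance_table(values, mode, check_integer = FALSE)
}

make_env <- function(n, vars, station = sprintf("ST%02d", seq_len(n)),
                     layer = rep("SUR", n)) {
  df <- data.frame(sample_id = sprintf("s%d", seq_len(n)),
                   station_id = station, layer = layer,
                   stringsAsFactors = FALSE)
  env_table(cbind(df, vars))
}

# small ranked-path taxonomy; division/class control the copy-number group
make_taxonomy <- function(lineage_id,
                          division = rep("Haptophyta", length(lineage_id)),
                          class_ = rep("Prymnesiophyceae", length(lineage_id)),
                          order = paste0("Ord_", lineage_id),
                          species = paste0(lineage_id, "_sp.")) {
  path <- paste("Eukaryota", "SAR", division, class_, order,
                paste0("Fam_", lineage_id), paste0("Gen_", lineage_id),
                species, sep = ";")
  taxonomy_table(lineage_id, path)
}

write_tsv_fixture <- function(lines, name) {
  path <- file.path(tempdir(), name)
  writeLines(lines, path)
  path
}
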