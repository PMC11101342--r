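# Small in-code fixture writers for the profile formats.

write_metaphlan_fixture <- function(path, percent = TRUE) {
  scale <- if (percent) 100 else 1
  lines <- c(
    "#clade_name\tsampleA\tsampleB",
    paste0("k__Bacteria\t", 100 * scale / 100, "\t", 100 * scale / 100),
    paste0("k__Bacteria|p__Proteobacteria\t", 50 * scale / 100, "\t",
           30 * scale / 100),
    paste0("k__Bacteria|p__Proteobacteria|c__G|o__E|f__E|g__Escherichia|",
           "s__Escherichia_coli\t", 50 * scale / 100, "\t", 30 * scale / 100),
    paste0("k__Bacteria|p__Firmicutes|c__C|o__C|f__L|g__Lactobacillus|",
           "s__Lactobacillus_reuteri\t", 50 * scale / 100, "\t",
           70 * scale / 100))
  writeLines(lines, path)
  path
}

write_humann_fixture <- function(path) {
  lines <- c(
    "# Gene Family\ts1\ts2",
    "UNMAPPED\t30\t10",
    "UniRef90_A\t10\t20",
    "UniRef90_A|g__Escherichia.s__Escherichia_coli\t6\t12",
    "UniRef90_A|g__Anaerostipes.s__Anaerostipes_hadrus\t4\t8",
    "UniRef90_B\t60\t70",
    "UniRef90_B|unclassified\t60\t70")
  writeLines(lines, path)
  path
}

write_metadata_fixture <- function(path, n = 10) {
  df <- data.frame(
    subject_id = sprintf("S%02d", 1:n),
    sample_id = sprintf("S%02d_early", 1:n),
    cohort = "A", sex = rep(c("male", "female"), length.out = n),
    srs2_tscore = seq(40, 58, length.out = n),
    sample_age_window = "early",
    gestational_age = 39 + (1:n) / 10,
    maternal_smoking = c("NA", "NA", rep("0", n - 3), "1"),
    paternal_age = c("", rep("33", n - 1)),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

write_catalog_fixture <- function(sets_path, mapping_path) {
  writeLines(c("set_name\tko",
               "butyrate_synthesis\tK00001",
               "butyrate_synthesis\tK00002",
               "butyrate_synthesis\tK00099",
               "acetate_synthesis\tK00002",
               "acetate_synthesis\tK00003",
               "orphan_set\tK00098",
               "orphan_set\tK00097"), sets_path)
  writeLines(c("ko\tuniref90",
               "K00001\tUniRef90_U1",
               "K00001\tUniRef90_U2",
               "K00002\tUniRef90_U3",
               "K00003\tUniRef90_U4",
               "K00003\tUniRef90_U5"), mapping_path)
  list(sets = sets_path, mapping = mapping_path)
}

# tiny config for fast cohort generation in tests
small_config <- function(seed, ...) {
  args <- list(...)
  defaults <- list(seed = seed, n_subjects = c(A = 40, B = 30),
                   n_species = 30, n_genefamilies = 60, n_sets = 4,
                   set_size = c(5, 10), n_metabolites = 4)
  do.call(simulation_config, utils::modifyList(defaults, args))
}
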