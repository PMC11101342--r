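test_that("taxonomic reader extracts the requested rank and rescales percent", {
  path <- write_metaphlan_fixture(tempfile(fileext = ".tsv"))
  tab <- read_taxonomic_profiles(path, level = "species")
  expect_s3_class(tab, "abundance_table")
  expect_setequal(feature_ids(tab), c("Escherichia_coli",
                                      "Lactobacillus_reuteri"))
  expect_equal(tab$values["sampleA", "Escherichia_coli"], 0.5)
  expect_equal(tab$values["sampleB", "Lactobacillus_reuteri"], 0.7)
  # proportion-scale file passes through without rescaling
  p2 <- write_metaphlan_fixture(tempfile(fileext = ".tsv"), percent = FALSE)
  tab2 <- read_taxonomic_profiles(p2, level = "species")
  expect_equal(tab2$values, tab$values)
})

test_that("taxonomic reader handles empty ranks, bad lineages, duplicates", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("#clade_name\ts1", "k__Bacteria\t100"), path)
  expect_warning(tab <- read_taxonomic_profiles(path, "species"),
                 "no rows at rank")
  expect_equal(ncol(tab$values), 0L)

  writeLines(c("#clade_name\ts1", "not_a_lineage\t10"), path)
  expect_error(read_taxonomic_profiles(path), "malformed lineage.*line 1")

  writeLines(c("#clade_name\ts1\ts1",
               "k__B|p__P|c__C|o__O|f__F|g__G|s__X\t10\t10"), path)
  expect_error(read_taxonomic_profiles(path), "duplicate sample")
})

test_that("taxonomic write/read round-trip preserves values", {
  set.seed(42)
  m <- matrix(stats::runif(8), 2, 4,
              dimnames = list(c("sA", "sB"), paste0("Species_", 1:4)))
  m <- m / rowSums(m)
  tab <- abundance_table(m, "taxon")
  path <- tempfile(fileext = ".tsv")
  write_taxonomic_profiles(tab, path)
  back <- read_taxonomic_profiles(path, "species")
  expect_equal(back$values[rownames(m), colnames(m)], m, tolerance = 1e-12)
})

test_that("gene-family reader parses stratified rows and UNMAPPED mass", {
  path <- write_humann_fixture(tempfile(fileext = ".tsv"))
  tab <- read_genefamily_profiles(path)
  expect_equal(tab$values["s1", "UniRef90_A"], 10)
  st <- tab$stratified
  a1 <- st[st$feature_id == "UniRef90_A" & st$sample_id == "s1", ]
  expect_setequal(a1$value, c(6, 4))
  expect_equal(sum(a1$value), tab$values["s1", "UniRef90_A"])
  expect_equal(unname(tab$unmapped["s1"]), 30)

  # UNMAPPED in the normalization denominator: 70 of 100 units are features
  norm <- tss_normalize(tab)
  expect_equal(unname(sum(norm$values["s1", ])), 0.7, tolerance = 1e-12)

  flat <- read_genefamily_profiles(path, keep_stratified = FALSE)
  expect_null(flat$stratified)
  expect_equal(flat$values, tab$values)
})

test_that("orphan stratified rows synthesize their parent with a warning", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("# Gene Family\ts1",
               "UniRef90_C|g__X.s__X_y\t3",
               "UniRef90_C|g__Z.s__Z_w\t4"), path)
  expect_warning(tab <- read_genefamily_profiles(path), "synthesized")
  expect_equal(unname(tab$values["s1", "UniRef90_C"]), 7)
})

test_that("gene-family write/read round-trip preserves values and strata", {
  path <- write_humann_fixture(tempfile(fileext = ".tsv"))
  tab <- read_genefamily_profiles(path)
  out <- tempfile(fileext = ".tsv")
  write_genefamily_profiles(tab, out)
  back <- read_genefamily_profiles(out)
  expect_equal(back$values[rownames(tab$values), colnames(tab$values)],
               tab$values, tolerance = 1e-12)
  expect_equal(unname(back$unmapped), unname(tab$unmapped))
  key <- function(s) paste(s$feature_id, s$taxon, s$sample_id)
  expect_equal(back$stratified$value[match(key(tab$stratified),
                                           key(back$stratified))],
               tab$stratified$value, tolerance = 1e-12)
})

test_that("metadata reader types covariates and masks missing codes", {
  path <- write_metadata_fixture(tempfile(fileext = ".csv"))
  md <- read_metadata(path)
  expect_s3_class(md, "sample_metadata")
  expect_true(is.na(md$paternal_age[1]))
  expect_equal(sum(is.na(md$maternal_smoking)), 2L)
  ms <- missingness_summary(md)
  expect_equal(unname(ms["maternal_smoking"]), 2L)
  expect_equal(unname(ms["paternal_age"]), 1L)
})

test_that("metadata reader rejects duplicates, bad levels, missing columns", {
  path <- write_metadata_fixture(tempfile(fileext = ".csv"))
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  md$subject_id[2] <- md$subject_id[1]
  p2 <- tempfile(fileext = ".csv")
  utils::write.csv(md, p2, row.names = FALSE, quote = FALSE)
  expect_error(read_metadata(p2), "duplicate subject_id")

  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  md$maternal_smoking[5] <- "2"
  utils::write.csv(md, p2, row.names = FALSE, quote = FALSE)
  expect_error(read_metadata(p2), "unknown level.*maternal_smoking")

  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  md$srs2_tscore <- NULL
  utils::write.csv(md, p2, row.names = FALSE, quote = FALSE)
  expect_error(read_metadata(p2), "srs2_tscore")
})

test_that("gene-set catalog resolves KO unions, overlap, unmapped counts", {
  paths <- write_catalog_fixture(tempfile(fileext = ".tsv"),
                                 tempfile(fileext = ".tsv"))
  expect_warning(cat <- load_geneset_catalog(paths$sets, paths$mapping),
                 "orphan_set")
  expect_setequal(cat$sets$butyrate_synthesis,
                  c("UniRef90_U1", "UniRef90_U2", "UniRef90_U3"))
  expect_setequal(cat$sets$acetate_synthesis,
                  c("UniRef90_U3", "UniRef90_U4", "UniRef90_U5"))
  # shared KO K00002 puts UniRef90_U3 in both sets
  expect_true("UniRef90_U3" %in% cat$sets$butyrate_synthesis &&
              "UniRef90_U3" %in% cat$sets$acetate_synthesis)
  expect_equal(unname(cat$unmapped_kos["butyrate_synthesis"]), 1L)
  expect_equal(unname(cat$unmapped_kos["orphan_set"]), 2L)
  expect_equal(cat$empty_sets, "orphan_set")
  # catalog expansion bound: |set| <= sum of per-KO mapping sizes
  for (s in names(cat$sets)) {
    kos <- intersect(cat$ko_members[[s]], names(cat$mapping))
    expect_lte(length(cat$sets[[s]]), sum(lengths(cat$mapping[kos])))
  }
})

test_that("tss_normalize rescales, is idempotent, preserves zero patterns", {
  m <- rbind(s1 = c(2, 2, 4), s2 = c(0.25, 0.25, 0.5), s3 = c(0, 0, 0))
  colnames(m) <- paste0("f", 1:3)
  tab <- abundance_table(m, "taxon")
  expect_warning(norm <- tss_normalize(tab), "all-zero")
  expect_equal(unname(norm$values["s1", ]), c(0.25, 0.25, 0.5))
  expect_equal(unname(norm$values["s2", ]), c(0.25, 0.25, 0.5),
               tolerance = 1e-12)
  expect_equal(unname(norm$values["s3", ]), c(0, 0, 0))
  expect_equal(attr(norm, "zero_samples"), "s3")
  norm2 <- suppressWarnings(tss_normalize(norm))
  expect_equal(norm2$values, norm$values, tolerance = 1e-12)
  expect_identical(norm2$values == 0, m == 0)
})

test_that("abundance_table validates inputs", {
  m <- matrix(c(-1, 1), 1, 2, dimnames = list("s1", c("a", "b")))
  expect_error(abundance_table(m, "taxon"), "non-negative")
  m2 <- matrix(1, 1, 2, dimnames = list("s1", c("a", "a")))
  expect_error(abundance_table(m2, "taxon"), "unique")
  m3 <- matrix(1, 1, 1, dimnames = list("s1", "f"))
  strat <- data.frame(feature_id = "f", taxon = "t", sample_id = "s1",
                      value = 2)
  expect_error(abundance_table(m3, "genefamily", stratified = strat),
               "exceed")
})
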