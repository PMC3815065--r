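test_that("annotation invariants are enforced", {
  expect_error(site_annotation(c("a", "a"), c(1, 2), "A", "G"),
               "duplicate site_id")
  expect_error(site_annotation(c("a", "b"), c(2, 1), "A", "G"),
               "strictly increasing")
  expect_error(site_annotation("a", 1, "A", "A"), "identical")
  ann <- site_annotation("indel1", 10, NA, "T", kind = "indel")
  expect_true(is.na(ann$ancestral))
})

test_that("TSV panels recode alleles against the annotation", {
  sites <- tiny_sites(3)
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\thap_index\tpopulation\ts1\ts2\ts3",
               "S1\t0\tP1\tA\tA\tA",
               "S1\t1\tP1\tA\tA\tA"), tsv)
  p <- read_phased_panel(tsv, sites, dialect = "tsv")
  expect_identical(unname(p$geno), matrix(0L, 2, 3))

  writeLines(c("sample_id\thap_index\tpopulation\ts1\ts2\ts3",
               "S1\t0\tP1\tA\tT\tA"), tsv)
  expect_error(read_phased_panel(tsv, sites, dialect = "tsv"),
               "matches neither")
})

test_that("phased VCF genotypes split into two coded chromosomes", {
  sites <- tiny_sites(1)
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
               "chr15\t100\ts1\tA\tG\t.\tPASS\t.\tGT\t0|1"), vcf)
  p <- read_phased_panel(vcf, sites, dialect = "vcf")
  expect_identical(unname(p$geno[, 1]), c(0L, 1L))
  expect_identical(p$meta$hap_index, c(0L, 1L))

  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
               "chr15\t100\ts1\tA\tG\t.\tPASS\t.\tGT\t0/1"), vcf)
  expect_error(read_phased_panel(vcf, sites, dialect = "vcf"),
               "unphased genotype for sample S1 at site s1")

  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
               "chr15\t100\ts1\tA\tG,T\t.\tPASS\t.\tGT\t0|1"), vcf)
  expect_error(read_phased_panel(vcf, sites, dialect = "vcf"),
               "multiallelic")
})

test_that("round-trips are bit-exact in every dialect", {
  for (seed in 1:3) {
    panel <- random_panel(n_chrom = 8, n_sites = 6, miss_prob = 0.15,
                          seed = seed)
    pops <- with(unique(panel$meta[, c("sample_id", "population")]),
                 stats::setNames(population, sample_id))
    for (dialect in c("tsv", "vcf", "impute")) {
      path <- if (dialect == "impute") tempfile() else
        tempfile(fileext = paste0(".", dialect))
      write_panel(panel, path, dialect = dialect)
      back <- read_phased_panel(path, panel$sites, dialect = dialect,
                                populations = pops)
      expect_identical(unname(back$geno), unname(panel$geno),
                       info = paste(dialect, seed))
      expect_identical(back$meta$population, panel$meta$population,
                       info = paste(dialect, seed))
    }
  }
})

test_that("flipping the ancestral/derived annotation flips every code", {
  panel <- random_panel(n_chrom = 6, n_sites = 5, miss_prob = 0.2, seed = 9)
  path <- tempfile(fileext = ".tsv")
  write_panel(panel, path)
  flipped <- site_annotation(panel$sites$site_id, panel$sites$position,
                             ancestral = panel$sites$derived,
                             derived = panel$sites$ancestral)
  back <- read_phased_panel(path, flipped, dialect = "tsv")
  expect_identical(unname(back$geno), unname(1L - panel$geno))
})

test_that("haplotype definitions load the published derived sets", {
  defs <- core_defs()
  expect_identical(defs$entries$C1, character(0))
  expect_setequal(defs$entries$C11,
                  c("c1", "c2", "c3", "c4", "c6", "c7", "c8", "c9", "c10",
                    "c11", "c12", "c14", "c15", "c16"))
  expect_setequal(defs$entries$C10,
                  c("c2", "c3", "c4", "c6", "c7", "c8", "c9", "c10", "c12",
                    "c14", "c15", "c16"))
  expect_error(
    haplotype_definitions(list(X = "nope"), slc24a5_core_sites()),
    "unknown site nickname")
  expect_error(
    haplotype_definitions(list(X = "c1", X = "c2"), slc24a5_core_sites()),
    "duplicate haplotype name")
})

test_that("table writers are deterministic and conserve counts", {
  empty <- data.frame(sample_id = character(0), label = character(0))
  path <- tempfile(fileext = ".tsv")
  write_tables(empty, path)
  expect_identical(readLines(path), "sample_id\tlabel")

  counts <- slc24a5_hapmap_counts()
  write_tables(counts, path)
  back <- utils::read.delim(path, check.names = FALSE)
  expect_equal(sum(as.matrix(back[, -1])), sum(counts))
  expect_equal(colSums(as.matrix(back[, -1])), colSums(counts))

  one <- phased_panel(matrix(0L, 3, 2), tiny_sites(2),
                      data.frame(sample_id = c("a", "a", "b"),
                                 hap_index = c(0, 1, 0),
                                 population = "P"))
  net <- build_network(one, min_variant_freq = 0)
  dot <- tempfile(fileext = ".dot")
  write_tables(net, dot, format = "dot")
  lines <- readLines(dot)
  expect_length(grep("label=", lines), 1)  # one node, no edges
  expect_length(grep("--", lines, fixed = TRUE), 0)
})
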