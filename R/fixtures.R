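#' Shipped SLC24A5 reference tables
#'
#' Accessors for the small plain-text tables shipped with the package:
#' the published b37 LD-block coordinates around *SLC24A5*, the 16-SNP
#' core-region site annotation (with synthetic placeholder positions — see
#' the file header), the named core haplotype definitions C1-C11, the
#' HapMap per-population haplotype counts, the per-sample dating inputs for
#' the C11+D4 haplotype, and the human-chimpanzee calibration summary.
#'
#' @return `slc24a5_blocks()`: a [block_partition()];
#'   `slc24a5_core_sites()`: a [site_annotation()];
#'   `slc24a5_core_definitions()`: a [haplotype_definitions()];
#'   `slc24a5_hapmap_counts()`: integer matrix (labels x populations);
#'   `slc24a5_dating_rows()`: data.frame of per-sample dating inputs;
#'   `slc24a5_calibration()`: one-row data.frame of calibration inputs.
#' @name slc24a5_fixtures
NULL

fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "hapsweep")
  if (p == "") stop("fixture not found: ", name)
  p
}

#' @rdname slc24a5_fixtures
#' @export
slc24a5_blocks <- function() {
  df <- utils::read.delim(fixture_path("slc24a5_blocks.tsv"),
                          comment.char = "#")
  block_partition(df$name, df$start, df$end)
}

#' @rdname slc24a5_fixtures
#' @export
slc24a5_core_sites <- function() {
  read_site_annotation(fixture_path("slc24a5_core_sites.tsv"))
}

#' @rdname slc24a5_fixtures
#' @export
slc24a5_core_definitions <- function() {
  read_haplotype_definitions(fixture_path("slc24a5_core_haplotypes.tsv"),
                             slc24a5_core_sites())
}

#' @rdname slc24a5_fixtures
#' @export
slc24a5_hapmap_counts <- function() {
  df <- utils::read.delim(fixture_path("slc24a5_hapmap_counts.tsv"),
                          comment.char = "#", check.names = FALSE)
  m <- as.matrix(df[, -1])
  storage.mode(m) <- "integer"
  rownames(m) <- df$label
  m
}

#' @rdname slc24a5_fixtures
#' @export
slc24a5_dating_rows <- function() {
  utils::read.delim(fixture_path("slc24a5_dating.tsv"), comment.char = "#")
}

#' @rdname slc24a5_fixtures
#' @export
slc24a5_calibration <- function() {
  utils::read.delim(fixture_path("slc24a5_calibration.tsv"),
                    comment.char = "#")
}
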