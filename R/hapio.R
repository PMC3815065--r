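MISSING_CHAR <- "."

#' Construct a site annotation table
#'
#' A site annotation describes the biallelic polymorphisms of a panel: a
#' unique identifier (rs ID or synthetic), a 1-based genomic position, the
#' ancestral and derived alleles (ancestral inferred by outgroup comparison),
#' an optional short nickname (e.g. `"c11"` for rs1426654) and the variant
#' kind.  Ancestral state may be `NA` when outgroup comparison is
#' inconclusive (e.g. a recurrently mutating indel); such sites are carried
#' through analyses but excluded from ancestral rooting.
#'
#' @param site_id character vector of unique site identifiers.
#' @param position integer vector of 1-based positions, strictly increasing.
#' @param ancestral,derived single-character allele states; `ancestral` may
#'   contain `NA` for sites of unknown ancestral state.
#' @param nickname optional short labels (`NA` where absent).
#' @param kind `"SNP"` or `"indel"`.
#' @return A `data.frame` of class `site_annotation`.
#' @export
site_annotation <- function(site_id, position, ancestral, derived,
                            nickname = NA_character_, kind = "SNP") {
  df <- data.frame(
    site_id = as.character(site_id),
    position = as.integer(position),
    ancestral = rep_len(as.character(ancestral), length(site_id)),
    derived = rep_len(as.character(derived), length(site_id)),
    nickname = rep_len(as.character(nickname), length(site_id)),
    kind = rep_len(as.character(kind), length(site_id)),
    stringsAsFactors = FALSE
  )
  validate_site_annotation(df)
}

validate_site_annotation <- function(df) {
  if (anyDuplicated(df$site_id))
    stop("duplicate site_id: ",
         paste(unique(df$site_id[duplicated(df$site_id)]), collapse = ", "))
  if (is.unsorted(df$position, strictly = TRUE))
    stop("site positions must be strictly increasing")
  same <- !is.na(df$ancestral) & df$ancestral == df$derived
  if (any(same))
    stop("ancestral and derived alleles identical at: ",
         paste(df$site_id[same], collapse = ", "))
  bad_kind <- !df$kind %in% c("SNP", "indel")
  if (any(bad_kind)) stop("kind must be 'SNP' or 'indel'")
  class(df) <- c("site_annotation", "data.frame")
  df
}

#' Read a site annotation TSV
#'
#' Expected columns: `site_id`, `position`, `ancestral`, `derived`, and
#' optionally `nickname` and `kind`.  Lines starting with `#` are ignored.
#'
#' @param path path to a tab-separated annotation file.
#' @return A [site_annotation()] table.
#' @export
read_site_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          na.strings = c("NA", ""))
  need <- c("site_id", "position", "ancestral", "derived")
  if (!all(need %in% names(df)))
    stop("annotation file must contain columns: ", paste(need, collapse = ", "))
  site_annotation(df$site_id, df$position, df$ancestral, df$derived,
                  nickname = if ("nickname" %in% names(df)) df$nickname else NA,
                  kind = if ("kind" %in% names(df)) df$kind else "SNP")
}

#' Construct a phased panel
#'
#' A phased panel is the central container: a matrix of phased chromosomes
#' (rows) by annotated biallelic sites (columns), with alleles coded
#' 0 = ancestral, 1 = derived, `NA` = missing.  Missing data are an explicit
#' third state and are never imputed; every downstream operation documents
#' its missing-data policy.
#'
#' @param geno integer matrix (chromosomes x sites) with entries 0, 1 or `NA`.
#' @param sites a [site_annotation()] table, one row per column of `geno`.
#' @param meta `data.frame` with columns `sample_id`, `hap_index` (0 or 1)
#'   and `population`, one row per row of `geno`.
#' @return An object of class `phased_panel`.
#' @export
phased_panel <- function(geno, sites, meta) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  sites <- validate_site_annotation(as.data.frame(sites))
  if (ncol(geno) != nrow(sites))
    stop("geno has ", ncol(geno), " columns but annotation has ",
         nrow(sites), " sites")
  if (!all(c("sample_id", "hap_index", "population") %in% names(meta)))
    stop("meta must have columns sample_id, hap_index, population")
  if (nrow(meta) != nrow(geno))
    stop("meta rows must match geno rows")
  key <- paste(meta$sample_id, meta$hap_index)
  if (anyDuplicated(key))
    stop("duplicate (sample_id, hap_index) pair: ",
         key[duplicated(key)][1])
  bad <- geno[!is.na(geno)]
  if (length(bad) && !all(bad %in% c(0L, 1L)))
    stop("allele codes must be 0, 1 or NA")
  colnames(geno) <- sites$site_id
  rownames(geno) <- paste(meta$sample_id, meta$hap_index, sep = "_")
  structure(list(geno = geno, sites = sites,
                 meta = data.frame(sample_id = as.character(meta$sample_id),
                                   hap_index = as.integer(meta$hap_index),
                                   population = as.character(meta$population),
                                   stringsAsFactors = FALSE)),
            class = "phased_panel")
}

#' @export
print.phased_panel <- function(x, ...) {
  cat("phased_panel: ", nrow(x$geno), " chromosomes x ", ncol(x$geno),
      " sites; populations: ",
      paste(sort(unique(x$meta$population)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @rdname phased_panel
#' @param x a `phased_panel`.
#' @export
n_chromosomes <- function(x) nrow(x$geno)

#' @rdname phased_panel
#' @export
n_sites <- function(x) nrow(x$sites)

## map observed allele characters to 0/1/NA against the annotation
recode_alleles <- function(chars, site, anc, der) {
  out <- rep(NA_integer_, length(chars))
  out[chars == anc] <- 0L
  out[chars == der] <- 1L
  unknown <- !is.na(chars) & chars != MISSING_CHAR & is.na(out)
  if (any(unknown))
    stop("allele '", chars[unknown][1], "' at site ", site,
         " matches neither ancestral (", anc, ") nor derived (", der, ")")
  out
}

#' Read a phased haplotype panel
#'
#' Supported dialects:
#' \describe{
#'   \item{`tsv`}{plain matrix, one row per chromosome, columns `sample_id`,
#'     `hap_index`, `population`, then one nucleotide column per site
#'     (`.` for missing).}
#'   \item{`vcf`}{phased VCF (v4.x); `GT` fields must use `|` separators
#'     (haploid single-allele calls are accepted). Alleles are recoded
#'     against the annotation, so REF need not equal the ancestral state.}
#'   \item{`impute`}{IMPUTE-style triple `<prefix>.hap`, `<prefix>.legend`,
#'     `<prefix>.sample`; `path` is the prefix.}
#' }
#' Alleles are recoded to 0 (ancestral) / 1 (derived) / `NA` against
#' `sites`; any allele matching neither annotated state is an error, as are
#' unphased VCF genotypes, multiallelic records and duplicate site IDs.
#' Coordinates are 1-based inclusive throughout.
#'
#' @param path input path (or prefix for the `impute` dialect).
#' @param sites [site_annotation()] covering every site in the file.
#' @param dialect one of `"tsv"`, `"vcf"`, `"impute"`.
#' @param populations optional named character vector mapping `sample_id` to
#'   population label (used by dialects that do not carry populations).
#' @return A [phased_panel()].
#' @export
read_phased_panel <- function(path, sites,
                              dialect = c("tsv", "vcf", "impute"),
                              populations = NULL) {
  dialect <- match.arg(dialect)
  switch(dialect,
         tsv = read_panel_tsv(path, sites),
         vcf = read_panel_vcf(path, sites, populations),
         impute = read_panel_impute(path, sites, populations))
}

panel_from_chars <- function(chars, sites, meta) {
  ord <- match(sites$site_id, colnames(chars))
  if (anyNA(ord))
    stop("sites missing from input: ",
         paste(sites$site_id[is.na(ord)], collapse = ", "))
  chars <- chars[, ord, drop = FALSE]
  geno <- matrix(NA_integer_, nrow(chars), ncol(chars))
  for (j in seq_len(ncol(chars)))
    geno[, j] <- recode_alleles(chars[, j], sites$site_id[j],
                                sites$ancestral[j], sites$derived[j])
  phased_panel(geno, sites, meta)
}

read_panel_tsv <- function(path, sites) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", comment.char = "#")
  need <- c("sample_id", "hap_index", "population")
  if (!all(need %in% names(df)))
    stop("panel TSV must contain columns: ", paste(need, collapse = ", "))
  site_cols <- setdiff(names(df), need)
  if (anyDuplicated(site_cols)) stop("duplicate site_id column in panel TSV")
  chars <- as.matrix(df[, site_cols, drop = FALSE])
  chars[chars == MISSING_CHAR] <- NA_character_
  colnames(chars) <- site_cols
  panel_from_chars(chars, sites,
                   data.frame(sample_id = df$sample_id,
                              hap_index = as.integer(df$hap_index),
                              population = df$population))
}

read_panel_vcf <- function(path, sites, populations) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))  # single-record files drop to a vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ids <- fix[, "ID"]
  if (anyDuplicated(ids)) stop("duplicate site_id in VCF: ",
                               ids[duplicated(ids)][1])
  if (any(grepl(",", fix[, "ALT"], fixed = TRUE)))
    stop("multiallelic VCF records are not supported (biallelic analysis)")
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  alleles <- rbind(fix[, "REF"], fix[, "ALT"])  # index 1 = code "0", 2 = "1"
  chars_list <- list(); meta_list <- list()
  for (s in samples) {
    calls <- gt[, s]
    if (any(grepl("/", calls, fixed = TRUE))) {
      bad <- which(grepl("/", calls, fixed = TRUE))[1]
      stop("unphased genotype for sample ", s, " at site ", ids[bad])
    }
    parts <- strsplit(ifelse(is.na(calls), MISSING_CHAR, calls),
                      "|", fixed = TRUE)
    ploidy <- max(lengths(parts))
    for (h in seq_len(ploidy)) {
      code <- vapply(parts, function(p)
        if (length(p) >= h) p[h] else MISSING_CHAR, character(1))
      ch <- rep(NA_character_, length(code))
      known <- code %in% c("0", "1")
      ch[known] <- alleles[cbind(as.integer(code[known]) + 1L,
                                 which(known))]
      chars_list[[length(chars_list) + 1L]] <- ch
      meta_list[[length(meta_list) + 1L]] <-
        data.frame(sample_id = s, hap_index = h - 1L,
                   population = if (!is.null(populations) &&
                                    s %in% names(populations))
                     unname(populations[s]) else "unknown")
    }
  }
  chars <- do.call(rbind, chars_list)
  colnames(chars) <- ids
  panel_from_chars(chars, sites, do.call(rbind, meta_list))
}

read_panel_impute <- function(prefix, sites, populations) {
  leg <- utils::read.table(paste0(prefix, ".legend"), header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("id", "position", "a0", "a1") %in% names(leg)))
    stop("legend file must have columns id, position, a0, a1")
  if (anyDuplicated(leg$id)) stop("duplicate site_id in legend")
  hap <- as.matrix(utils::read.table(paste0(prefix, ".hap"),
                                     colClasses = "character"))
  if (nrow(hap) != nrow(leg))
    stop("hap file rows must match legend rows")
  smp <- utils::read.table(paste0(prefix, ".sample"), header = TRUE,
                           stringsAsFactors = FALSE)
  if (!"ID" %in% names(smp)) stop("sample file must have an ID column")
  if (ncol(hap) != 2L * nrow(smp))
    stop("hap file must have two haplotype columns per sample")
  pop <- if ("POP" %in% names(smp)) smp$POP
         else if (!is.null(populations)) unname(populations[smp$ID])
         else rep("unknown", nrow(smp))
  # transpose to chromosomes x sites; column h belongs to sample ceiling(h/2)
  chars <- matrix(NA_character_, ncol(hap), nrow(hap))
  for (i in seq_len(nrow(leg))) {
    code <- hap[i, ]
    ch <- rep(NA_character_, length(code))
    ch[code == "0"] <- leg$a0[i]
    ch[code == "1"] <- leg$a1[i]
    chars[, i] <- ch
  }
  colnames(chars) <- leg$id
  meta <- data.frame(sample_id = rep(smp$ID, each = 2L),
                     hap_index = rep(c(0L, 1L), nrow(smp)),
                     population = rep(pop, each = 2L))
  panel_from_chars(chars, sites, meta)
}

#' Write a phased panel
#'
#' Inverse of [read_phased_panel()]; round-trips are bit-exact on the allele
#' matrix for every dialect.  The VCF writer emits the annotated ancestral
#' allele as REF and the derived allele as ALT, with an `AA` INFO tag.
#'
#' @param panel a [phased_panel()].
#' @param path output path (or prefix for `impute`).
#' @param dialect one of `"tsv"`, `"vcf"`, `"impute"`.
#' @param chrom chromosome name used by the VCF dialect.
#' @return Invisibly, the path(s) written.
#' @export
write_panel <- function(panel, path, dialect = c("tsv", "vcf", "impute"),
                        chrom = "chr15") {
  dialect <- match.arg(dialect)
  switch(dialect,
         tsv = write_panel_tsv(panel, path),
         vcf = write_panel_vcf(panel, path, chrom),
         impute = write_panel_impute(panel, path))
}

allele_chars <- function(panel) {
  s <- panel$sites
  ch <- matrix(MISSING_CHAR, nrow(panel$geno), ncol(panel$geno))
  for (j in seq_len(ncol(panel$geno))) {
    g <- panel$geno[, j]
    ch[which(g == 0L), j] <- s$ancestral[j]
    ch[which(g == 1L), j] <- s$derived[j]
  }
  colnames(ch) <- s$site_id
  ch
}

write_panel_tsv <- function(panel, path) {
  ch <- allele_chars(panel)
  df <- cbind(panel$meta[, c("sample_id", "hap_index", "population")],
              as.data.frame(ch, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_panel_vcf <- function(panel, path, chrom) {
  s <- panel$sites
  m <- panel$meta
  samples <- unique(m$sample_id)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=hapsweep",
           "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  ref <- ifelse(is.na(s$ancestral), s$derived, s$ancestral)
  alt <- ifelse(is.na(s$ancestral), s$ancestral, s$derived)
  alt[is.na(alt)] <- "N"  # unknown ancestral: REF=derived, ALT placeholder
  # per-sample GT strings; code relative to REF/ALT as written
  gt_code <- function(g, j) {
    if (is.na(g)) return(MISSING_CHAR)
    if (is.na(s$ancestral[j])) as.character(1L - g) else as.character(g)
  }
  lines <- character(nrow(s))
  for (j in seq_len(nrow(s))) {
    cells <- vapply(samples, function(sm) {
      rows <- which(m$sample_id == sm)
      rows <- rows[order(m$hap_index[rows])]
      paste(vapply(rows, function(r) gt_code(panel$geno[r, j], j),
                   character(1)), collapse = "|")
    }, character(1))
    lines[j] <- paste(c(chrom, s$position[j], s$site_id[j], ref[j], alt[j],
                        ".", "PASS", paste0("AA=", ref[j]), "GT", cells),
                      collapse = "\t")
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

write_panel_impute <- function(panel, prefix) {
  s <- panel$sites
  m <- panel$meta
  samples <- unique(m$sample_id)
  idx <- lapply(samples, function(sm) {
    rows <- which(m$sample_id == sm)
    rows[order(m$hap_index[rows])]
  })
  if (any(lengths(idx) != 2L))
    stop("impute dialect requires exactly two haplotypes per sample")
  ord <- unlist(idx)
  hap <- t(panel$geno[ord, , drop = FALSE])
  hap_chr <- ifelse(is.na(hap), "?", as.character(hap))
  writeLines(apply(hap_chr, 1, paste, collapse = " "), paste0(prefix, ".hap"))
  utils::write.table(
    data.frame(id = s$site_id, position = s$position,
               a0 = ifelse(is.na(s$ancestral), "N", s$ancestral),
               a1 = s$derived),
    paste0(prefix, ".legend"), sep = " ", quote = FALSE, row.names = FALSE)
  pop <- m$population[vapply(idx, `[`, integer(1), 1L)]
  utils::write.table(data.frame(ID = samples, POP = pop),
                     paste0(prefix, ".sample"), sep = " ", quote = FALSE,
                     row.names = FALSE)
  invisible(paste0(prefix, c(".hap", ".legend", ".sample")))
}

#' Read a recombination-rate map
#'
#' TSV with columns `start`, `end`, `rate` (cM/Mb), 1-based inclusive
#' coordinates; intervals must be sorted and non-overlapping, rates
#' non-negative.
#'
#' @param path path to the map TSV.
#' @return A `data.frame` of class `recombination_map`.
#' @export
read_recombination_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  recombination_map(df$start, df$end, df$rate)
}

#' @rdname read_recombination_map
#' @param start,end,rate interval vectors (1-based inclusive; cM/Mb).
#' @export
recombination_map <- function(start, end, rate) {
  df <- data.frame(start = as.integer(start), end = as.integer(end),
                   rate = as.numeric(rate))
  if (any(df$rate < 0)) stop("recombination rates must be >= 0")
  if (any(df$end < df$start)) stop("interval end before start")
  if (is.unsorted(df$start, strictly = TRUE)) stop("intervals must be sorted")
  if (nrow(df) > 1 && any(df$start[-1] <= df$end[-nrow(df)]))
    stop("intervals overlap")
  class(df) <- c("recombination_map", "data.frame")
  df
}

#' Read a two-sequence gapped alignment from FASTA
#'
#' @param path FASTA file containing exactly two aligned (equal-length,
#'   gapped with `-`) sequences.
#' @return A list of class `pairwise_alignment` with elements `seq_a`,
#'   `seq_b` (character vectors of single residues).
#' @export
read_pairwise_alignment <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) != 2L) stop("alignment FASTA must contain exactly 2 sequences")
  pairwise_alignment(as.character(ss[[1]]), as.character(ss[[2]]))
}

#' @rdname read_pairwise_alignment
#' @param seq_a,seq_b aligned sequences as single strings or character vectors.
#' @export
pairwise_alignment <- function(seq_a, seq_b) {
  a <- toupper(unlist(strsplit(paste(seq_a, collapse = ""), "")))
  b <- toupper(unlist(strsplit(paste(seq_b, collapse = ""), "")))
  if (length(a) != length(b)) stop("aligned sequences differ in length")
  if (any(a == "-" & b == "-")) stop("column gapped in both sequences")
  structure(list(seq_a = a, seq_b = b), class = "pairwise_alignment")
}

#' Read named haplotype definitions
#'
#' TSV with columns `name` and `derived` (comma-separated site nicknames at
#' which the haplotype carries the derived allele; empty for the
#' all-ancestral haplotype).  Nicknames must exist in `sites`.
#'
#' @param path definitions TSV.
#' @param sites the companion [site_annotation()]; its nicknames form the
#'   definition site universe.
#' @param key_site nickname of the classifying functional site
#'   (default `"c11"`, rs1426654).
#' @param common_freq_threshold pooled-sample frequency above which a
#'   haplotype counts as common (default 0.005).
#' @return An object of class `haplotype_definitions`: a list with `entries`
#'   (named list of derived-nickname sets), `universe`, `key_site`,
#'   `common_freq_threshold`.
#' @export
read_haplotype_definitions <- function(path, sites, key_site = "c11",
                                       common_freq_threshold = 0.005) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          na.strings = NULL, colClasses = "character")
  if (!all(c("name", "derived") %in% names(df)))
    stop("definitions file must have columns name, derived")
  entries <- lapply(df$derived, function(x) {
    x <- trimws(strsplit(x, ",", fixed = TRUE)[[1]])
    x[nzchar(x)]
  })
  names(entries) <- df$name
  haplotype_definitions(entries, sites, key_site, common_freq_threshold)
}

#' @rdname read_haplotype_definitions
#' @param entries named list of character vectors of derived-site nicknames.
#' @export
haplotype_definitions <- function(entries, sites, key_site = "c11",
                                  common_freq_threshold = 0.005) {
  universe <- sites$nickname[!is.na(sites$nickname)]
  if (anyDuplicated(names(entries)))
    stop("duplicate haplotype name: ",
         names(entries)[duplicated(names(entries))][1])
  for (nm in names(entries)) {
    unknown <- setdiff(entries[[nm]], universe)
    if (length(unknown))
      stop("unknown site nickname in definition ", nm, ": ",
           paste(unknown, collapse = ", "))
  }
  keys <- vapply(entries, function(e) paste(sort(e), collapse = ","),
                 character(1))
  if (anyDuplicated(keys))
    stop("two haplotype names share one derived set: ",
         paste(names(entries)[keys %in% keys[duplicated(keys)]],
               collapse = ", "))
  if (!key_site %in% universe)
    stop("key_site '", key_site, "' not in the site universe")
  structure(list(entries = entries, universe = universe, key_site = key_site,
                 common_freq_threshold = common_freq_threshold,
                 sites = sites),
            class = "haplotype_definitions")
}

#' Write pipeline result tables
#'
#' Deterministic TSV export for the pipeline's tabular results and DOT
#' export for haplotype networks.  Row and column order follow the object's
#' internal (documented) ordering, so identical inputs give byte-identical
#' files.
#'
#' @param result a `data.frame`/matrix (counts, assignments, reports) or a
#'   `haplotype_network`.
#' @param path output path.
#' @param format `"tsv"` or `"dot"` (`dot` only for networks).
#' @return Invisibly, `path`.
#' @export
write_tables <- function(result, path, format = c("tsv", "dot")) {
  format <- match.arg(format)
  if (format == "dot") {
    if (!inherits(result, "haplotype_network"))
      stop("dot format is only available for haplotype networks")
    return(write_network_dot(result, path))
  }
  if (inherits(result, "haplotype_network")) {
    df <- network_edge_table(result)
  } else if (is.matrix(result)) {
    df <- data.frame(label = rownames(result), as.data.frame(result),
                     check.names = FALSE)
  } else {
    df <- as.data.frame(result)
  }
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
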