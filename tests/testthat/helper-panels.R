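# shared builders for small in-memory panels

tiny_sites <- function(n = 3, anc = "A", der = "G") {
  site_annotation(paste0("s", seq_len(n)), seq_len(n) * 100L, anc, der)
}

random_panel <- function(n_chrom = 6, n_sites = 5, miss_prob = 0,
                         seed = 1, populations = c("P1", "P2")) {
  set.seed(seed)
  geno <- matrix(sample(0:1, n_chrom * n_sites, replace = TRUE),
                 n_chrom, n_sites)
  if (miss_prob > 0)
    geno[runif(length(geno)) < miss_prob] <- NA_integer_
  stopifnot(n_chrom %% 2 == 0)  # paired for the impute dialect
  meta <- data.frame(sample_id = rep(sprintf("S%02d", seq_len(n_chrom / 2)),
                                     each = 2),
                     hap_index = rep(0:1, n_chrom / 2),
                     population = rep(rep_len(populations, n_chrom / 2),
                                      each = 2))
  phased_panel(geno, tiny_sites(n_sites), meta)
}

core_defs <- function() slc24a5_core_definitions()

# equal-count panel of the 11 published core haplotypes
table1_panel <- function(count = 1, population = "pool") {
  defs <- core_defs()
  simulate_classified_panel(
    defs, data.frame(label = names(defs$entries), population = population,
                     count = count))
}

# frequency table matching the published HapMap count matrix
counts_to_freq_table <- function(counts, populations = colnames(counts)) {
  do.call(rbind, lapply(populations, function(p) {
    data.frame(label = rownames(counts), population = p,
               count = counts[, p])
  }))
}
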