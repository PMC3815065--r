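## Per-chromosome RNG substreams: chromosome i always draws from a seed
## derived only from (master seed, i), so enlarging a panel never perturbs
## chromosomes already generated.
substream_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 16807) %% 2147483647)
}

with_preserved_rng <- function(expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  expr
}

make_sim_sites <- function(positions) {
  positions <- sort(unique(as.integer(positions)))
  site_annotation(site_id = sprintf("s%09d", positions),
                  position = positions, ancestral = "A", derived = "G")
}

sim_meta <- function(n, population) {
  data.frame(sample_id = sprintf("sim%04d", seq_len(n)),
             hap_index = 0L,
             population = rep_len(population, n))
}

#' Simulate a star genealogy under a selective sweep
#'
#' All sampled lineages coalesce in a single founder (the limit of a strong
#' sweep); each chromosome then accumulates `K ~ Poisson(mu * L * T)`
#' private derived mutations at distinct uniformly drawn positions
#' (infinite sites: no position is reused across lineages; violations are
#' redrawn, and an expected per-lineage count above `0.1 * L` is an error).
#' Chromosome `i` draws from its own RNG substream, so panels are
#' reproducible and extensible.
#'
#' The defaults mirror the dated *SLC24A5* C+D region: 127,419 nt at
#' 8.145e-10 per site per year, so an 8-ky-old founder yields a mean of
#' about 0.83 mutations per chromosome — the regime of the real data
#' (822 differences over 1013 chromosomes).
#'
#' @param n_chrom number of chromosomes (default 200).
#' @param region_length region length L in nt.
#' @param mu per-site per-year mutation rate.
#' @param tmrca founder age T in years.
#' @param seed master RNG seed.
#' @param population population label for the panel.
#' @return List with `panel` (a [phased_panel()]) and `truth`
#'   (`tmrca`, `lambda`, per-chromosome mutation counts `k`,
#'   `site_chromosome` map).
#' @export
simulate_star <- function(n_chrom = 200, region_length = 127419,
                          mu = 8.145398e-10, tmrca = 8000, seed = 1L,
                          population = "sim") {
  lambda <- mu * region_length * tmrca
  if (lambda > 0.1 * region_length)
    stop("expected mutations per chromosome exceed 0.1 * L; ",
         "infinite-sites model violated")
  with_preserved_rng({
    used <- integer(0)
    muts <- vector("list", n_chrom)
    for (i in seq_len(n_chrom)) {
      set.seed(substream_seed(seed, i))
      k <- stats::rpois(1, lambda)
      pos <- integer(0)
      while (length(pos) < k) {
        cand <- sample.int(region_length, k - length(pos))
        cand <- setdiff(cand, c(used, pos))
        pos <- c(pos, cand)
      }
      muts[[i]] <- sort(pos)
      used <- c(used, pos)
    }
    positions <- sort(used)
    sites <- make_sim_sites(positions)
    geno <- matrix(0L, n_chrom, length(positions))
    for (i in seq_len(n_chrom))
      geno[i, match(muts[[i]], positions)] <- 1L
    panel <- phased_panel(geno, sites, sim_meta(n_chrom, population))
    site_chromosome <- stats::setNames(
      rep(seq_len(n_chrom), times = lengths(muts))[order(unlist(muts))],
      sites$site_id)
    list(panel = panel,
         truth = list(tmrca = tmrca, lambda = lambda,
                      k = lengths(muts), site_chromosome = site_chromosome))
  })
}

#' Simulate an infinite-sites mutation tree with persisting ancestors
#'
#' Generates a random haplotype genealogy in which every ancestral class
#' remains present in the sample (as in standing variation, where ancestral
#' haplotypes persist alongside their mutated descendants): class 1 is the
#' all-ancestral founder and each subsequent class attaches to a uniformly
#' chosen earlier class, carrying `K ~ Poisson(mutations_per_branch)` new
#' private mutations (infinite sites).  Zero-mutation branches leave the
#' child identical to its parent, merging the two classes.  Because every
#' node of the genealogy is observed, a nearest-neighbour network built
#' from the panel recovers the true branch set exactly, making this the
#' oracle for network reconstruction.
#'
#' @param n_classes number of haplotype classes to generate.
#' @param chrom_per_class chromosomes sampled per class (scalar or vector).
#' @param region_length region length in nt.
#' @param mutations_per_branch Poisson mean of new mutations per branch.
#' @param seed RNG seed.
#' @param population population label.
#' @return List with `panel` and `truth` (`parent` vector, `branch_sites`
#'   list of site_ids per branch, `class_of_chromosome`).
#' @export
simulate_tree_panel <- function(n_classes = 8, chrom_per_class = 3,
                                region_length = 127419,
                                mutations_per_branch = 3, seed = 1L,
                                population = "sim") {
  stopifnot(n_classes >= 1)
  with_preserved_rng({
    set.seed(substream_seed(seed, 0L))
    parent <- c(NA_integer_,
                if (n_classes > 1)
                  vapply(2:n_classes, function(c)
                    sample.int(c - 1L, 1L), integer(1)))
    k <- c(0L, if (n_classes > 1) stats::rpois(n_classes - 1, mutations_per_branch))
    total <- sum(k)
    if (total > 0.1 * region_length)
      stop("too many mutations for the infinite-sites model")
    positions <- sort(sample.int(region_length, total))
    sites <- if (total > 0) make_sim_sites(positions) else
      make_sim_sites(1L)  # single monomorphic placeholder site
    shuffled <- positions[sample.int(length(positions))]
    branch_pos <- split(shuffled, rep(seq_len(n_classes), times = k))
    hap <- matrix(0L, n_classes, nrow(sites))
    for (c in seq_len(n_classes)[-1]) {
      hap[c, ] <- hap[parent[c], ]
      if (k[c] > 0)
        hap[c, match(sort(branch_pos[[as.character(c)]]),
                     sites$position)] <- 1L
    }
    counts <- rep_len(as.integer(chrom_per_class), n_classes)
    class_of <- rep(seq_len(n_classes), times = counts)
    geno <- hap[class_of, , drop = FALSE]
    panel <- phased_panel(geno, sites, sim_meta(sum(counts), population))
    branch_sites <- lapply(seq_len(n_classes), function(c)
      if (k[c] > 0) sites$site_id[match(sort(branch_pos[[as.character(c)]]),
                                        sites$position)] else character(0))
    list(panel = panel,
         truth = list(parent = parent, k = k, branch_sites = branch_sites,
                      class_of_chromosome = class_of))
  })
}

#' Simulate a panel containing single-crossover recombinants
#'
#' Copies of two parent haplotypes plus recombinants formed by a single
#' crossover at `crossover_position`: the recombinant carries `parent_a`
#' alleles at positions `<=` the crossover and `parent_b` alleles beyond it.
#'
#' @param parent_a,parent_b 0/1 vectors over `sites`.
#' @param sites a [site_annotation()].
#' @param crossover_position crossover location (nt); must lie at or after
#'   the first site and before the last site.
#' @param n_parent_a,n_parent_b,n_recombinant copy numbers (recombinants
#'   may be 0 for a parents-only panel).
#' @param population population label.
#' @return List with `panel` and `truth` (`parent_a`, `parent_b`,
#'   `crossover_position`, `recombinant`, and the recombinant chromosome
#'   row indices).
#' @export
simulate_recombinant_panel <- function(parent_a, parent_b, sites,
                                       crossover_position,
                                       n_parent_a = 5, n_parent_b = 5,
                                       n_recombinant = 2,
                                       population = "sim") {
  pos <- sites$position
  if (crossover_position < pos[1] || crossover_position >= pos[length(pos)])
    stop("crossover outside the region spanned by the sites")
  rec <- ifelse(pos <= crossover_position, parent_a, parent_b)
  geno <- rbind(
    matrix(rep(as.integer(parent_a), n_parent_a), ncol = length(pos),
           byrow = TRUE),
    matrix(rep(as.integer(parent_b), n_parent_b), ncol = length(pos),
           byrow = TRUE),
    matrix(rep(as.integer(rec), n_recombinant), ncol = length(pos),
           byrow = TRUE))
  n <- nrow(geno)
  panel <- phased_panel(geno, sites, sim_meta(n, population))
  list(panel = panel,
       truth = list(parent_a = as.integer(parent_a),
                    parent_b = as.integer(parent_b),
                    crossover_position = crossover_position,
                    recombinant = as.integer(rec),
                    recombinant_rows =
                      if (n_recombinant > 0)
                        (n_parent_a + n_parent_b + 1L):n else integer(0)))
}

#' Simulate a panel with known haplotype-class composition
#'
#' Instantiates chromosomes exactly according to a frequency table over
#' named haplotype definitions (plus the residual classes `"Other-d"` /
#' `"Other-a"`, realised as synthetic minor haplotypes matching no named
#' definition), with population labels; the classifier applied to the
#' result recovers the table exactly when no missing data are injected.
#' Optional missing-data injection at named sites creates the ambiguity
#' classes seen in real panels (e.g. missing c13 merges C6 and C7).
#'
#' @param defs a [haplotype_definitions()].
#' @param frequency_table data.frame with columns `label`, `population`,
#'   `count`.
#' @param missing_sites optional named list: label -> nicknames to blank
#'   out (`NA`) on every chromosome of that label.
#' @return A [phased_panel()] over the definitions' annotation.
#' @export
simulate_classified_panel <- function(defs, frequency_table,
                                      missing_sites = NULL) {
  ft <- frequency_table
  if (nrow(ft) == 0 || sum(ft$count) == 0) stop("empty frequency table")
  sites <- defs$sites
  universe <- defs$universe
  pattern_for <- function(label) {
    if (label %in% names(defs$entries))
      return(as.integer(universe %in% defs$entries[[label]]))
    if (label == "Other-d")
      return(residual_pattern(defs, derived_key = TRUE))
    if (label == "Other-a")
      return(residual_pattern(defs, derived_key = FALSE))
    if (label == "Other-d/Other-a") {
      # a residual pattern that stays residual with the key site blanked
      patt <- residual_pattern(defs, derived_key = FALSE)
      patt[match(defs$key_site, universe)] <- NA_integer_
      return(patt)
    }
    if (grepl("/", label, fixed = TRUE)) {
      # ambiguity class: first member's pattern with the distinguishing
      # sites blanked out, so the classifier recovers exactly this set
      parts <- strsplit(label, "/", fixed = TRUE)[[1]]
      if (!all(parts %in% names(defs$entries)))
        stop("label not in definitions: ", label)
      first <- defs$entries[[parts[1]]]
      patt <- as.integer(universe %in% first)
      distinguishing <- unique(unlist(lapply(parts[-1], function(p) {
        other <- defs$entries[[p]]
        c(setdiff(other, first), setdiff(first, other))
      })))
      patt[match(distinguishing, universe)] <- NA_integer_
      return(patt)
    }
    stop("label not in definitions: ", label)
  }
  uidx <- match(universe, sites$nickname)
  rows <- list(); meta <- list()
  counter <- 0L
  for (r in seq_len(nrow(ft))) {
    patt <- pattern_for(ft$label[r])
    g <- rep(0L, nrow(sites))
    g[uidx] <- patt
    if (!is.null(missing_sites) && ft$label[r] %in% names(missing_sites)) {
      miss <- missing_sites[[ft$label[r]]]
      bad <- setdiff(miss, sites$nickname)
      if (length(bad)) stop("unknown nickname in missing_sites: ",
                            paste(bad, collapse = ", "))
      g[match(miss, sites$nickname)] <- NA_integer_
    }
    for (cc in seq_len(ft$count[r])) {
      counter <- counter + 1L
      rows[[counter]] <- g
      meta[[counter]] <- data.frame(
        sample_id = sprintf("%s.%04d", ft$population[r], counter),
        hap_index = 0L, population = ft$population[r])
    }
  }
  phased_panel(do.call(rbind, rows), sites, do.call(rbind, meta))
}

## a minor-haplotype pattern matching no named definition, with the key
## site derived (Other-d) or ancestral (Other-a)
residual_pattern <- function(defs, derived_key) {
  universe <- defs$universe
  def_keys <- vapply(defs$entries, function(e) paste(sort(e), collapse = ","),
                     character(1))
  key <- defs$key_site
  others <- setdiff(universe, key)
  base <- if (derived_key) key else character(0)
  pieces <- c(list(character(0)), as.list(others),
              if (length(others) >= 2)
                utils::combn(others, 2, simplify = FALSE))
  for (piece in pieces) {
    set <- c(base, piece)
    if (!paste(sort(set), collapse = ",") %in% def_keys)
      return(as.integer(universe %in% set))
  }
  stop("no residual pattern available outside the named definitions")
}
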