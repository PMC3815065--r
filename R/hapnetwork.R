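#' Build a rooted nearest-neighbour haplotype network
#'
#' Chromosomes are collapsed into haplotype classes (identical allele
#' strings over the retained sites) and the classes are linked by a
#' deterministic nearest-neighbour rule: starting from singleton components,
#' the two components whose closest node pair has minimal Hamming distance
#' are joined repeatedly until the graph is connected (minimum-spanning-tree
#' behaviour on tree-like data).  Ties are broken by lexicographic order of
#' the candidate pair's allele strings, then by node counts descending.
#' Each edge is labelled with the set of sites at which its endpoints
#' differ, so the label size equals the Hamming distance.  The network is
#' rooted by ancestral alleles: at the all-ancestral string if present,
#' otherwise at the node with the fewest derived alleles (sites of unknown
#' ancestral state are excluded from root scoring but kept in edge labels).
#'
#' Sites with pooled minor-allele frequency below `min_variant_freq` are
#' removed before collapsing; chromosomes missing data at any retained site
#' are dropped with a message.  Classes rarer than `min_hap_freq` stay in
#' the graph but are flagged `displayed = FALSE` (mirroring figures that
#' draw only haplotypes above 0.5%).
#'
#' @param panel a [phased_panel()].
#' @param min_variant_freq minimum pooled minor-allele frequency for a site
#'   to be retained (default 0.01).
#' @param min_hap_freq display threshold for haplotype classes
#'   (default 0.005).
#' @return An object of class `haplotype_network`: list with `nodes`
#'   (data.frame `id`, `haplotype`, `count`, `n_derived`, `displayed`),
#'   `edges` (data.frame `from`, `to`, `n_diff`, plus list column `sites`),
#'   `root` (node id), `retained_sites` ([site_annotation()] subset),
#'   `pop_counts` (nodes x populations matrix) and `dropped_chromosomes`.
#' @export
build_network <- function(panel, min_variant_freq = 0.01,
                          min_hap_freq = 0.005) {
  if (n_chromosomes(panel) == 0) stop("empty panel")
  g <- panel$geno
  freq <- colMeans(g, na.rm = TRUE)
  freq[is.nan(freq)] <- 0
  maf <- pmin(freq, 1 - freq)
  keep_sites <- which(maf >= min_variant_freq)
  if (length(keep_sites) == 0) stop("no sites pass the frequency filter")
  g <- g[, keep_sites, drop = FALSE]
  complete <- rowSums(is.na(g)) == 0L
  dropped <- sum(!complete)
  if (dropped > 0)
    message("build_network: dropped ", dropped,
            " chromosome(s) with missing data at retained sites")
  g <- g[complete, , drop = FALSE]
  if (nrow(g) == 0) stop("no chromosomes left after filtering")
  pops <- panel$meta$population[complete]
  sites <- panel$sites[keep_sites, , drop = FALSE]

  strings <- apply(g, 1, paste, collapse = "")
  classes <- sort(unique(strings))
  n <- length(classes)
  count <- as.integer(table(factor(strings, levels = classes)))
  pop_counts <- table(factor(strings, levels = classes),
                      factor(pops, levels = unique(pops)))
  pop_counts <- matrix(as.integer(pop_counts), n, ncol(pop_counts),
                       dimnames = dimnames(pop_counts))
  names(dimnames(pop_counts)) <- NULL
  mat <- matrix(as.integer(unlist(strsplit(classes, ""))), nrow = n,
                byrow = TRUE)

  # derived counts over sites with known ancestral state (for rooting)
  known <- !is.na(sites$ancestral)
  n_derived <- as.integer(rowSums(mat[, known, drop = FALSE]))

  edges <- nearest_neighbour_edges(mat, classes, count)
  site_label <- ifelse(is.na(sites$nickname), sites$site_id, sites$nickname)
  edge_sites <- lapply(seq_len(nrow(edges)), function(k) {
    diff <- which(mat[edges$i[k], ] != mat[edges$j[k], ])
    site_label[diff]
  })

  ids <- paste0("H", seq_len(n))
  all_anc <- paste(rep("0", ncol(mat)), collapse = "")
  root <- if (all_anc %in% classes) ids[match(all_anc, classes)] else {
    cand <- which(n_derived == min(n_derived))
    ids[cand[order(classes[cand])][1]]
  }
  nodes <- data.frame(id = ids, haplotype = classes, count = count,
                      n_derived = n_derived,
                      displayed = count / sum(count) >= min_hap_freq,
                      stringsAsFactors = FALSE)
  rownames(pop_counts) <- ids
  edges_df <- if (nrow(edges)) data.frame(from = ids[edges$i],
                                          to = ids[edges$j],
                                          n_diff = edges$d,
                                          stringsAsFactors = FALSE)
              else data.frame(from = character(0), to = character(0),
                              n_diff = integer(0))
  edges_df$sites <- edge_sites
  structure(list(nodes = nodes, edges = edges_df, root = root,
                 retained_sites = sites, pop_counts = pop_counts,
                 dropped_chromosomes = dropped),
            class = "haplotype_network")
}

## deterministic component-joining on Hamming distances.
## candidate pairs ordered by (distance, lexicographic pair strings,
## total count descending); union-find keeps joins acyclic.
nearest_neighbour_edges <- function(mat, classes, count) {
  n <- nrow(mat)
  if (n == 1) return(data.frame(i = integer(0), j = integer(0),
                                d = integer(0)))
  pairs_i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  pairs_j <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n))
  d <- vapply(seq_along(pairs_i), function(k)
    sum(mat[pairs_i[k], ] != mat[pairs_j[k], ]), integer(1))
  key1 <- pmin(classes[pairs_i], classes[pairs_j])
  key2 <- pmax(classes[pairs_i], classes[pairs_j])
  tot <- count[pairs_i] + count[pairs_j]
  ord <- order(d, key1, key2, -tot)

  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  edges <- data.frame(i = integer(0), j = integer(0), d = integer(0))
  for (k in ord) {
    a <- find(pairs_i[k]); b <- find(pairs_j[k])
    if (a != b) {
      parent[a] <- b
      edges <- rbind(edges, data.frame(i = pairs_i[k], j = pairs_j[k],
                                       d = d[k]))
      if (nrow(edges) == n - 1L) break
    }
  }
  edges
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("haplotype_network: ", nrow(x$nodes), " classes (",
      sum(x$nodes$count), " chromosomes), ", nrow(x$edges),
      " edges, root ", x$root, "\n", sep = "")
  invisible(x)
}

#' Sites mutating on more than one network edge
#'
#' Under infinite sites and no recombination the network is a perfect
#' phylogeny and every polymorphic site labels exactly one edge; a site
#' appearing on two or more edges signals recurrent mutation or, far more
#' often in a recombining region, a recombinant haplotype (identified in
#' the source analysis as "polymorphisms with transitions on more than one
#' edge").
#'
#' @param network a [build_network()] result.
#' @return `data.frame` with columns `site`, `n_edges` and a list column
#'   `edges` of `"H1--H2"` descriptors; zero rows for a perfect tree.
#' @export
find_recurrent_sites <- function(network) {
  e <- network$edges
  if (is.null(e$sites) || nrow(e) == 0)
    return(data.frame(site = character(0), n_edges = integer(0),
                      edges = I(list())))
  tags <- paste0(e$from, "--", e$to)
  occ <- data.frame(site = unlist(e$sites),
                    edge = rep(tags, lengths(e$sites)),
                    stringsAsFactors = FALSE)
  tab <- table(occ$site)
  rec <- sort(names(tab)[tab >= 2])
  out <- data.frame(site = rec, n_edges = as.integer(tab[rec]),
                    stringsAsFactors = FALSE)
  out$edges <- lapply(rec, function(s) occ$edge[occ$site == s])
  out
}

network_edge_table <- function(network) {
  e <- network$edges
  data.frame(from = e$from, to = e$to, n_diff = e$n_diff,
             sites = vapply(e$sites, paste, character(1), collapse = ","),
             stringsAsFactors = FALSE)
}

#' @rdname write_tables
#' @keywords internal
write_network_dot <- function(network, path) {
  nd <- network$nodes
  lab <- ifelse(nd$id == network$root, paste0(nd$id, "*"), nd$id)
  node_lines <- sprintf(
    "  \"%s\" [label=\"%s\\n(%d)\", width=%.2f, style=%s];",
    nd$id, lab, nd$count, 0.4 + 0.6 * sqrt(nd$count / max(nd$count)),
    ifelse(nd$displayed, "solid", "dashed"))
  e <- network$edges
  edge_lines <- if (nrow(e)) sprintf(
    "  \"%s\" -- \"%s\" [label=\"%s\"];", e$from, e$to,
    vapply(e$sites, paste, character(1), collapse = ",")) else character(0)
  writeLines(c("graph haplotype_network {", "  node [shape=circle];",
               node_lines, edge_lines, "}"), path)
  invisible(path)
}
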