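test_that("a repeated haplotype collapses to a single rooted node", {
  geno <- matrix(0L, 4, 3)
  geno[, 2] <- c(1L, 1L, 1L, 1L)  # monomorphic derived column
  p <- phased_panel(geno, tiny_sites(3),
                    data.frame(sample_id = letters[1:4], hap_index = 0L,
                               population = "P"))
  net <- build_network(p, min_variant_freq = 0)
  expect_equal(nrow(net$nodes), 1)
  expect_equal(nrow(net$edges), 0)
  expect_equal(net$nodes$count, 4)
  expect_equal(net$root, net$nodes$id)
})

test_that("three haplotypes form a rooted chain with per-site edge labels", {
  geno <- rbind(c(0L, 0L), c(1L, 0L), c(1L, 1L))
  p <- phased_panel(geno, tiny_sites(2),
                    data.frame(sample_id = c("a", "b", "c"), hap_index = 0L,
                               population = "P"))
  net <- build_network(p, min_variant_freq = 0)
  expect_equal(nrow(net$edges), 2)
  expect_equal(sort(net$edges$n_diff), c(1L, 1L))
  root_hap <- net$nodes$haplotype[net$nodes$id == net$root]
  expect_equal(root_hap, "00")
  labels <- lapply(net$edges$sites, identity)
  expect_setequal(unlist(labels), c("s1", "s2"))
  expect_equal(lengths(labels), c(1L, 1L))
  expect_equal(nrow(find_recurrent_sites(net)), 0)
})

test_that("the 11 published haplotypes give the known adjacency and the c1 recurrence", {
  net <- build_network(table1_panel(), min_variant_freq = 0.01,
                       min_hap_freq = 0)
  nodes <- net$nodes
  hap_of <- function(name) {
    defs <- core_defs()
    paste(as.integer(defs$universe %in% defs$entries[[name]]),
          collapse = "")
  }
  id_of <- function(name) nodes$id[nodes$haplotype == hap_of(name)]
  e <- net$edges
  pick <- (e$from == id_of("C10") & e$to == id_of("C11")) |
          (e$from == id_of("C11") & e$to == id_of("C10"))
  expect_true(any(pick))
  expect_setequal(e$sites[[which(pick)]], c("c1", "c11"))
  rec <- find_recurrent_sites(net)
  expect_identical(rec$site, "c1")
  expect_equal(rec$n_edges, 2L)
  # rooted at the all-ancestral haplotype, C1
  expect_equal(net$root, id_of("C1"))
})

test_that("tree simulations are recovered exactly, with no recurrence", {
  for (seed in c(2, 11, 23)) {
    sim <- simulate_tree_panel(n_classes = 7, chrom_per_class = 2,
                               mutations_per_branch = 3, seed = seed)
    net <- build_network(sim$panel, min_variant_freq = 0, min_hap_freq = 0)
    expect_equal(nrow(net$edges), nrow(net$nodes) - 1)
    expect_equal(nrow(find_recurrent_sites(net)), 0)
    truth_sets <- lapply(Filter(length, sim$truth$branch_sites), sort)
    edge_sets <- lapply(net$edges$sites, sort)
    expect_true(setequal(truth_sets, edge_sets), info = paste("seed", seed))
  }
})

test_that("derived counts accumulate along root paths in a tree", {
  sim <- simulate_tree_panel(n_classes = 6, chrom_per_class = 2,
                             mutations_per_branch = 2, seed = 4)
  net <- build_network(sim$panel, min_variant_freq = 0, min_hap_freq = 0)
  # breadth-first depth-sum of edge label sizes from the root
  depth <- stats::setNames(rep(NA_integer_, nrow(net$nodes)), net$nodes$id)
  depth[net$root] <- 0L
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(net$edges))) {
      a <- net$edges$from[k]; b <- net$edges$to[k]
      w <- length(net$edges$sites[[k]])
      if (!is.na(depth[a]) && is.na(depth[b])) {
        depth[b] <- depth[a] + w; changed <- TRUE
      } else if (!is.na(depth[b]) && is.na(depth[a])) {
        depth[a] <- depth[b] + w; changed <- TRUE
      }
    }
    if (!changed) break
  }
  expect_identical(unname(depth[net$nodes$id]),
                   net$nodes$n_derived)
})

test_that("the network is invariant to chromosome order and matches an MST oracle", {
  skip_if_not_installed("igraph")
  sim <- simulate_tree_panel(n_classes = 6, chrom_per_class = 3,
                             mutations_per_branch = 2, seed = 8)
  p <- sim$panel
  net1 <- build_network(p, min_variant_freq = 0, min_hap_freq = 0)
  set.seed(1)
  perm <- sample(n_chromosomes(p))
  p2 <- phased_panel(p$geno[perm, ], p$sites, p$meta[perm, ])
  net2 <- build_network(p2, min_variant_freq = 0, min_hap_freq = 0)
  expect_identical(net1$nodes$haplotype, net2$nodes$haplotype)
  expect_identical(net1$edges[, c("from", "to", "n_diff")],
                   net2$edges[, c("from", "to", "n_diff")])

  # independent oracle: total weight of igraph's MST on the same distances
  classes <- net1$nodes$haplotype
  mat <- do.call(rbind, lapply(strsplit(classes, ""), as.integer))
  d <- as.matrix(stats::dist(mat, method = "manhattan"))
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE)
  mst_w <- sum(igraph::E(igraph::mst(g))$weight)
  expect_equal(sum(net1$edges$n_diff), mst_w)
})

test_that("chromosomes with missing data at retained sites are dropped with a message", {
  geno <- rbind(c(0L, 0L), c(1L, 0L), c(1L, NA))
  p <- phased_panel(geno, tiny_sites(2),
                    data.frame(sample_id = c("a", "b", "c"), hap_index = 0L,
                               population = "P"))
  expect_message(net <- build_network(p, min_variant_freq = 0),
                 "dropped 1")
  expect_equal(net$dropped_chromosomes, 1)
  expect_equal(sum(net$nodes$count), 2)
})

test_that("low-frequency variants are filtered before collapsing", {
  # 200 chromosomes; site s1 at 50%, site s2 a singleton (0.5% < 1%)
  geno <- matrix(0L, 200, 2)
  geno[1:100, 1] <- 1L
  geno[1, 2] <- 1L
  p <- phased_panel(geno, tiny_sites(2),
                    data.frame(sample_id = sprintf("s%03d", 1:200),
                               hap_index = 0L, population = "P"))
  net <- build_network(p, min_variant_freq = 0.01)
  expect_equal(nrow(net$retained_sites), 1)
  expect_equal(net$retained_sites$site_id, "s1")
  expect_equal(nrow(net$nodes), 2)
})
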