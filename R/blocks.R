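#' Partition a region into LD blocks at recombination hotspots
#'
#' Linkage-disequilibrium blocks are delimited by recombination hotspots:
#' maximal runs of map intervals with rate above `primary_threshold`
#' (default 5 cM/Mb) become block boundaries, placed at the midpoint of the
#' run (rounded down).  Runs exceeding only `secondary_threshold` (default
#' 0.8 cM/Mb, the modestly elevated class) are reported as candidate
#' sub-boundaries and split blocks only when `split_secondary = TRUE`.
#'
#' @param map a [recombination_map()] covering `region`.
#' @param region length-2 vector `(start, end)`, 1-based inclusive.
#' @param primary_threshold hotspot rate threshold, cM/Mb.
#' @param secondary_threshold sub-boundary rate threshold, cM/Mb; must be
#'   below `primary_threshold`.
#' @param split_secondary also split at secondary-threshold runs?
#' @param block_names names assigned to blocks in genomic order.
#' @return A `data.frame` of class `block_partition` with columns `name`,
#'   `start`, `end` (contiguous, 1-based inclusive), carrying candidate
#'   sub-boundaries in attribute `"secondary_boundaries"`.
#' @export
partition_by_hotspots <- function(map, region, primary_threshold = 5,
                                  secondary_threshold = 0.8,
                                  split_secondary = FALSE,
                                  block_names = LETTERS) {
  stopifnot(length(region) == 2, region[1] <= region[2])
  if (!(primary_threshold > secondary_threshold && secondary_threshold > 0))
    stop("need primary_threshold > secondary_threshold > 0")
  m <- map[map$end >= region[1] & map$start <= region[2], , drop = FALSE]
  if (nrow(m) == 0 || m$start[1] > region[1] || m$end[nrow(m)] < region[2] ||
      (nrow(m) > 1 && any(m$start[-1] != m$end[-nrow(m)] + 1L)))
    stop("recombination map does not cover the region contiguously")
  m$start <- pmax(m$start, region[1])
  m$end <- pmin(m$end, region[2])

  run_midpoints <- function(hot) {
    if (!any(hot)) return(integer(0))
    r <- rle(hot)
    stops <- cumsum(r$lengths)
    starts <- stops - r$lengths + 1L
    keep <- which(r$values)
    vapply(keep, function(k)
      as.integer((m$start[starts[k]] + m$end[stops[k]]) %/% 2), integer(1))
  }
  primary <- run_midpoints(m$rate > primary_threshold)
  secondary <- setdiff(run_midpoints(m$rate > secondary_threshold), primary)
  cuts <- primary
  if (split_secondary) cuts <- sort(c(cuts, secondary))
  cuts <- cuts[cuts >= region[1] & cuts < region[2]]
  bounds <- c(region[1] - 1L, sort(cuts), region[2])
  blocks <- data.frame(
    name = block_names[seq_len(length(bounds) - 1L)],
    start = bounds[-length(bounds)] + 1L,
    end = bounds[-1],
    stringsAsFactors = FALSE)
  attr(blocks, "secondary_boundaries") <- secondary
  class(blocks) <- c("block_partition", "data.frame")
  blocks
}

#' @rdname partition_by_hotspots
#' @param name,start,end explicit block coordinates (used to build a
#'   partition from published boundaries rather than from a map).
#' @export
block_partition <- function(name, start, end) {
  df <- data.frame(name = as.character(name), start = as.integer(start),
                   end = as.integer(end), stringsAsFactors = FALSE)
  if (is.unsorted(df$start, strictly = TRUE)) stop("blocks must be sorted")
  if (any(df$end < df$start)) stop("block end before start")
  if (nrow(df) > 1 && any(df$start[-1] <= df$end[-nrow(df)]))
    stop("blocks overlap")
  class(df) <- c("block_partition", "data.frame")
  df
}

#' Total length of a set of named blocks
#'
#' Lengths are nucleotide counts on 1-based inclusive coordinates,
#' `end - start + 1` summed over the selected blocks (so the published C+D
#' region of the *SLC24A5* locus measures 127,419 nt).
#'
#' @param partition a [block_partition()].
#' @param names block names to sum.
#' @return Integer nucleotide count.
#' @export
block_length <- function(partition, names) {
  missing <- setdiff(names, partition$name)
  if (length(missing))
    stop("unknown block name: ", paste(missing, collapse = ", "))
  sel <- partition[partition$name %in% names, , drop = FALSE]
  sum(sel$end - sel$start + 1L)
}
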