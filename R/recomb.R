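#' Explain a haplotype as a single crossover between two parents
#'
#' Tests whether `child` can be reconstructed, with zero mismatches, as a
#' single crossover between the two parent haplotypes (both parent orders
#' are tried).  Sites at which the parents differ are *informative*; a
#' valid single-crossover explanation requires the child's matches at
#' informative sites to be one run of left-parent matches followed by one
#' run of right-parent matches, and at every uninformative site the child
#' must carry the shared parental allele.  The crossover is localised to the
#' open interval between the last informative site matching the left parent
#' and the first matching the right parent.  When the child equals one
#' parent the match is reported as a trivial hypothesis with a degenerate
#' interval at the region edge (`position_right = NA`).
#'
#' Any residual mismatch disqualifies the pair: the model treats residual
#' differences as separate mutation events to be handled upstream (as with
#' the A111T mutation arising on the crossover product that became C11).
#'
#' @param child,parent_a,parent_b 0/1 integer vectors over the same ordered
#'   site set; no missing values.
#' @param sites a [site_annotation()] (or any data.frame with `site_id` and
#'   `position`) describing that site set.
#' @return A `crossover_hypothesis` (list with `child`, `parent_left`,
#'   `parent_right`, `breakpoint_interval`, `flank_sites`,
#'   `informative_support`, `trivial`) or `NULL` if no single crossover
#'   reproduces the child.  If both orders admit one, the narrower
#'   breakpoint interval wins.
#' @export
explain_by_crossover <- function(child, parent_a, parent_b, sites) {
  vs <- list(child = child, parent_a = parent_a, parent_b = parent_b)
  len <- lengths(vs)
  if (length(unique(len)) != 1L || len[1] != nrow(sites))
    stop("child and parents must share one site universe")
  nm <- lapply(vs, names)
  if (any(!vapply(nm, is.null, logical(1))) &&
      !all(vapply(nm, identical, logical(1), sites$site_id)))
    stop("child and parents must share one site universe")
  if (anyNA(child) || anyNA(parent_a) || anyNA(parent_b))
    stop("missing alleles are not allowed here")

  hyps <- c(try_orientation(child, parent_a, parent_b, sites),
            try_orientation(child, parent_b, parent_a, sites))
  if (length(hyps) == 0) return(NULL)
  width <- vapply(hyps, function(h) {
    iv <- h$breakpoint_interval
    if (anyNA(iv)) Inf else iv[2] - iv[1]
  }, numeric(1))
  hyps[[order(width)[1]]]
}

try_orientation <- function(child, left, right, sites) {
  info <- which(left != right)
  agree <- which(left == right)
  if (any(child[agree] != left[agree])) return(list())  # mismatch to both
  if (length(info) == 0) {
    # identical parents: child == both; degenerate pure-parent match
    return(list(new_hypothesis(child, left, right, sites,
                               cut = length(child), info_left = info,
                               info_right = integer(0))))
  }
  m_left <- child[info] == left[info]
  if (any(child[info] != left[info] & child[info] != right[info]))
    return(list())  # cannot happen for biallelic 0/1, kept for safety
  r <- rle(m_left)
  if (length(r$values) > 2L || (length(r$values) == 2L && !r$values[1]))
    return(list())  # not a single left-run then right-run
  n_left <- if (r$values[1]) r$lengths[1] else 0L
  list(new_hypothesis(child, left, right, sites,
                      cut = if (n_left > 0) info[n_left] else 0L,
                      info_left = info[seq_len(n_left)],
                      info_right = info[setdiff(seq_along(info),
                                                seq_len(n_left))]))
}

new_hypothesis <- function(child, left, right, sites, cut, info_left,
                           info_right) {
  trivial <- length(info_left) == 0L || length(info_right) == 0L
  if (length(info_left) == 0L && length(info_right) > 0L) {
    # pure right parent: crossover before the region
    interval <- c(NA_integer_, sites$position[info_right[1]])
    flanks <- c(NA_character_, sites$site_id[info_right[1]])
  } else if (length(info_right) == 0L) {
    # pure left parent (or identical parents): crossover beyond the region
    lastpos <- if (length(info_left)) sites$position[info_left[length(info_left)]]
               else sites$position[length(child)]
    lastid <- if (length(info_left)) sites$site_id[info_left[length(info_left)]]
              else NA_character_
    interval <- c(lastpos, NA_integer_)
    flanks <- c(lastid, NA_character_)
  } else {
    li <- info_left[length(info_left)]; ri <- info_right[1]
    interval <- c(sites$position[li], sites$position[ri])
    flanks <- c(sites$site_id[li], sites$site_id[ri])
  }
  structure(list(child = child, parent_left = left, parent_right = right,
                 breakpoint_interval = interval, flank_sites = flanks,
                 informative_support = c(left = length(info_left),
                                         right = length(info_right)),
                 cut = cut, sites = sites, trivial = trivial),
            class = "crossover_hypothesis")
}

#' @export
print.crossover_hypothesis <- function(x, ...) {
  iv <- x$breakpoint_interval
  cat("crossover_hypothesis:",
      if (x$trivial) "trivial (pure parent);"
      else sprintf("breakpoint in (%d, %d), width %d nt;", iv[1], iv[2],
                   iv[2] - iv[1]),
      sprintf("support %d|%d informative sites\n",
              x$informative_support["left"], x$informative_support["right"]))
  invisible(x)
}

#' Reconstruct the child from a crossover hypothesis
#'
#' @param hypothesis a `crossover_hypothesis`.
#' @return The 0/1 child vector implied by the hypothesis (always equal to
#'   the original child: the zero-mismatch guarantee).
#' @export
reconstruct_child <- function(hypothesis) {
  pos <- hypothesis$sites$position
  cutpos <- if (hypothesis$cut > 0) pos[hypothesis$cut] else -Inf
  ifelse(pos <= cutpos, hypothesis$parent_left, hypothesis$parent_right)
}

#' Reciprocal product of a crossover
#'
#' A single crossover produces two complementary products; given the
#' hypothesis for the recovered one, returns the other: the right parent's
#' left segment joined to the left parent's right segment at the same
#' breakpoint.  (In the C11 scenario this is the product "not recovered"
#' in the sampled populations.)
#'
#' @param hypothesis a `crossover_hypothesis`.
#' @return 0/1 vector of the reciprocal recombinant.
#' @export
reciprocal_product <- function(hypothesis) {
  pos <- hypothesis$sites$position
  cutpos <- if (hypothesis$cut > 0) pos[hypothesis$cut] else -Inf
  ifelse(pos <= cutpos, hypothesis$parent_right, hypothesis$parent_left)
}

#' Scan candidate parents for single-crossover explanations
#'
#' Tries every unordered pair of candidates and collects all zero-mismatch
#' single-crossover explanations of `child`, ranked by the smaller of the
#' two informative-support counts (descending: well-supported first), then
#' by breakpoint-interval width (ascending).  Trivial pure-parent matches
#' carry zero support on one side and therefore rank last.
#'
#' @param child 0/1 vector.
#' @param candidates named list (or matrix with rownames) of candidate 0/1
#'   parent vectors; at least two.
#' @param sites the shared [site_annotation()].
#' @return `data.frame` with columns `parent_left`, `parent_right`,
#'   `interval_left`, `interval_right`, `width`, `support`, `trivial`, and a
#'   list column `hypothesis`.
#' @export
scan_parent_pairs <- function(child, candidates, sites) {
  if (is.matrix(candidates))
    candidates <- stats::setNames(
      lapply(seq_len(nrow(candidates)), function(i) candidates[i, ]),
      rownames(candidates))
  if (length(candidates) < 2) stop("need at least two candidate parents")
  nms <- names(candidates)
  rows <- list()
  for (i in seq_len(length(candidates) - 1L)) {
    for (j in (i + 1L):length(candidates)) {
      h <- explain_by_crossover(child, candidates[[i]], candidates[[j]],
                                sites)
      if (is.null(h)) next
      left_name <- if (identical(h$parent_left, candidates[[i]])) nms[i]
                   else nms[j]
      right_name <- setdiff(c(nms[i], nms[j]), left_name)
      iv <- h$breakpoint_interval
      rows[[length(rows) + 1L]] <- list(
        df = data.frame(parent_left = left_name, parent_right = right_name,
                        interval_left = iv[1], interval_right = iv[2],
                        width = if (anyNA(iv)) NA_integer_ else iv[2] - iv[1],
                        support = min(h$informative_support),
                        trivial = h$trivial, stringsAsFactors = FALSE),
        h = h)
    }
  }
  if (length(rows) == 0)
    return(data.frame(parent_left = character(0), parent_right = character(0),
                      interval_left = integer(0), interval_right = integer(0),
                      width = integer(0), support = integer(0),
                      trivial = logical(0)))
  out <- do.call(rbind, lapply(rows, `[[`, "df"))
  width_key <- ifelse(is.na(out$width), Inf, out$width)
  ord <- order(-out$support, width_key, out$parent_left, out$parent_right)
  out <- out[ord, , drop = FALSE]
  out$hypothesis <- lapply(rows, `[[`, "h")[ord]
  rownames(out) <- NULL
  out
}
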