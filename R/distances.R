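# Pairwise p-distances and the per-region intra/interspecific summaries that
# make up a barcode-gap analysis. Distances are raw proportions of differing
# comparable sites; IUPAC codes whose expansions intersect count as a match,
# sites with a gap or an 'n' in either sequence are dropped from both
# numerator and denominator (switchable: gaps can instead count as
# differences, relevant where repeat-length polymorphism matters).

#' Distance policy
#'
#' @param gap_handling \code{"exclude"} (default): sites with \code{"-"} in
#'   either sequence are dropped pairwise; \code{"difference"}: a gap paired
#'   with a base counts as a difference (gap/gap sites are always dropped).
#' @param min_overlap Minimum number of comparable sites for a defined
#'   distance; fewer gives \code{NA}.
#' @return A \code{distance_policy} list.
#' @export
distance_policy <- function(gap_handling = c("exclude", "difference"),
                            min_overlap = 50L) {
  gap_handling <- match.arg(gap_handling)
  min_overlap <- as.integer(min_overlap)
  if (min_overlap < 1L) stop("min_overlap must be >= 1")
  structure(list(gap_handling = gap_handling, min_overlap = min_overlap),
            class = "distance_policy")
}

# core: p-distance between two mask vectors (already restricted to columns)
p_distance_masks <- function(a, b, policy) {
  n_mask <- 15L
  gap_a <- a == 0L
  gap_b <- b == 0L
  drop_n <- a == n_mask | b == n_mask
  if (policy$gap_handling == "exclude") {
    comparable <- !(gap_a | gap_b | drop_n)
    diffs <- sum(bitwAnd(a[comparable], b[comparable]) == 0L)
    n_comp <- sum(comparable)
  } else {
    # gap vs base is a difference; gap vs gap and any 'n' are dropped
    comparable <- !((gap_a & gap_b) | drop_n)
    diffs <- sum(bitwAnd(a[comparable], b[comparable]) == 0L |
                   xor(gap_a[comparable], gap_b[comparable]))
    n_comp <- sum(comparable)
  }
  if (n_comp < policy$min_overlap) return(NA_real_)
  diffs / n_comp
}

#' Pairwise p-distance between two aligned sequences
#'
#' Proportion of comparable sites whose symbols are incompatible (no shared
#' base in their IUPAC expansions), over a column interval.
#'
#' @param aln An \code{annotated_alignment}.
#' @param id_a,id_b Sequence ids.
#' @param columns Integer vector of alignment columns (1-based); defaults to a
#'   named region via \code{region}, or the full width.
#' @param region Optional region name, used when \code{columns} is missing.
#' @param policy A \code{\link{distance_policy}}.
#' @return A fraction in [0,1], or \code{NA} when fewer than
#'   \code{min_overlap} comparable sites remain.
#' @export
p_distance <- function(aln, id_a, id_b, columns = NULL, region = NULL,
                       policy = distance_policy()) {
  columns <- resolve_columns(aln, columns, region)
  a <- aln$enc[id_a, columns]
  b <- aln$enc[id_b, columns]
  p_distance_masks(a, b, policy)
}

resolve_columns <- function(aln, columns, region) {
  if (is.null(columns)) {
    columns <- if (is.null(region)) seq_len(aln$width)
               else region_columns(aln, region)
  }
  columns <- as.integer(columns)
  if (length(columns) == 0L) stop("empty region")
  if (any(columns < 1L) || any(columns > aln$width)) {
    stop("columns outside alignment width")
  }
  columns
}

# full pairwise matrix over a set of ids (NA where undefined)
pairwise_p_distances <- function(aln, ids, columns, policy) {
  n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2L) return(D)
  sub <- aln$enc[ids, columns, drop = FALSE]
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d <- p_distance_masks(sub[i, ], sub[j, ], policy)
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Maximum intraspecific p-distance for a taxon in a region
#'
#' @inheritParams p_distance
#' @param taxon Taxon name (any rank present in the taxonomy).
#' @param rank Optional rank of \code{taxon}; auto-detected when unique.
#' @return List with \code{taxon}, \code{region}, \code{max_intra},
#'   \code{n_pairs}, \code{single_member} (TRUE when only one member covers
#'   the region, in which case \code{max_intra} is 0).
#' @export
max_intraspecific <- function(aln, taxon, region, policy = distance_policy(),
                              rank = NULL) {
  columns <- region_columns(aln, region)
  members <- taxon_members(aln, taxon, rank)
  if (length(members) == 0L) stop("empty taxon: ", taxon)
  covered <- members[covers_region(aln, members, columns, policy)]
  if (length(covered) == 0L) stop("insufficient coverage: no member of ",
                                  taxon, " covers ", region)
  if (length(covered) == 1L) {
    return(list(taxon = taxon, region = region, max_intra = 0,
                n_pairs = 0L, single_member = TRUE))
  }
  D <- pairwise_p_distances(aln, covered, columns, policy)
  vals <- D[upper.tri(D)]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) stop("insufficient coverage: no comparable pair in ",
                               taxon, " over ", region)
  list(taxon = taxon, region = region, max_intra = max(vals),
       n_pairs = length(vals), single_member = FALSE)
}

#' Minimum interspecific p-distance for a taxon in a region
#'
#' Minimum over (member, non-member) pairs. Following the convention of
#' comparing against closely related species, the contrast set defaults to
#' non-member sequences of the same genus when the taxon is a species with an
#' annotated genus and such sequences exist; otherwise all non-members.
#'
#' @inheritParams max_intraspecific
#' @param scope \code{"genus"} (default behaviour above) or \code{"all"}.
#' @return List with \code{taxon}, \code{region}, \code{min_inter},
#'   \code{nearest_other} (species, or id when unlabelled, of the argmin
#'   non-member), \code{n_pairs}.
#' @export
min_interspecific <- function(aln, taxon, region, policy = distance_policy(),
                              rank = NULL, scope = c("genus", "all")) {
  scope <- match.arg(scope)
  columns <- region_columns(aln, region)
  members <- taxon_members(aln, taxon, rank)
  if (length(members) == 0L) stop("empty taxon: ", taxon)
  others <- contrast_set(aln, taxon, members, rank, scope)
  if (length(others) == 0L) stop("no contrast set for ", taxon)
  others <- others[covers_region(aln, others, columns, policy)]
  members <- members[covers_region(aln, members, columns, policy)]
  if (length(others) == 0L || length(members) == 0L) {
    stop("insufficient coverage for ", taxon, " over ", region)
  }
  best <- Inf
  best_id <- NA_character_
  n_pairs <- 0L
  sub_m <- aln$enc[members, columns, drop = FALSE]
  sub_o <- aln$enc[others, columns, drop = FALSE]
  for (i in seq_along(members)) {
    for (j in seq_along(others)) {
      d <- p_distance_masks(sub_m[i, ], sub_o[j, ], policy)
      if (is.na(d)) next
      n_pairs <- n_pairs + 1L
      if (d < best) {
        best <- d
        best_id <- others[j]
      }
    }
  }
  if (!is.finite(best)) stop("insufficient coverage for ", taxon,
                             " over ", region)
  sp <- aln$taxonomy$species[aln$taxonomy$id == best_id]
  nearest <- if (length(sp) && nzchar(sp)) sp else best_id
  list(taxon = taxon, region = region, min_inter = best,
       nearest_other = nearest, n_pairs = n_pairs)
}

contrast_set <- function(aln, taxon, members, rank, scope) {
  tx <- aln$taxonomy
  non_members <- setdiff(tx$id, members)
  if (scope == "all") return(non_members)
  rk <- if (is.null(rank)) taxon_rank(aln, taxon) else rank
  if (rk == "species") {
    genus <- unique(tx$genus[tx$id %in% members])
    genus <- genus[nzchar(genus)]
    if (length(genus) == 1L) {
      same_genus <- tx$id[tx$genus == genus & !(tx$id %in% members)]
      if (length(same_genus)) return(same_genus)
    }
  }
  non_members
}

covers_region <- function(aln, ids, columns, policy) {
  sub <- aln$enc[ids, columns, drop = FALSE]
  rowSums(sub != 0L & sub != 15L) >= policy$min_overlap
}

#' Barcode-gap report for a taxon over one or more regions
#'
#' Combines \code{\link{max_intraspecific}} and
#' \code{\link{min_interspecific}} into one row per region with the
#' barcode-gap verdict (\code{min_inter > max_intra}).
#'
#' @inheritParams min_interspecific
#' @param regions Character vector of region names.
#' @return Data frame with columns \code{taxon}, \code{region},
#'   \code{max_intra}, \code{min_inter}, \code{nearest_other},
#'   \code{barcode_gap}, \code{n_pairs_intra}, \code{n_pairs_inter},
#'   \code{single_member}.
#' @export
distance_report <- function(aln, taxon, regions = c("ITS2", "LSU"),
                            policy = distance_policy(), rank = NULL,
                            scope = c("genus", "all")) {
  scope <- match.arg(scope)
  rows <- lapply(regions, function(rg) {
    intra <- max_intraspecific(aln, taxon, rg, policy, rank)
    inter <- min_interspecific(aln, taxon, rg, policy, rank, scope)
    data.frame(
      taxon = taxon, region = rg,
      max_intra = intra$max_intra, min_inter = inter$min_inter,
      nearest_other = inter$nearest_other,
      barcode_gap = inter$min_inter > intra$max_intra,
      n_pairs_intra = intra$n_pairs, n_pairs_inter = inter$n_pairs,
      single_member = intra$single_member,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
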