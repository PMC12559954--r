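# Diagnostic nucleotide signatures: short, possibly IUPAC-degenerate motifs
# at fixed alignment columns that separate a target taxon from every other
# sequence within an allowed-mismatch budget m. A motif is the per-column
# degenerate consensus of the target members over a gap-free window; m is
# derived as (minimum non-target mismatch count) - 1, so that every
# non-target exceeds m. Where no single motif covers a heterogeneous target,
# an OR-disjunction of up to max_alternatives motifs is searched.

#' Signature search parameters
#'
#' @param min_len,max_len Window lengths searched (defaults 20/20; printed
#'   signatures in practice span roughly 8-33 bases).
#' @param max_ambiguous Maximum number of degenerate symbols tolerated in a
#'   motif (default 2).
#' @param region_priority Regions searched, in preference order. ITS2 leads:
#'   it combines high divergence with good read coverage and few
#'   homopolymers.
#' @param max_alternatives Maximum number of OR-alternatives in a disjunctive
#'   signature (default 3).
#' @param top_k Maximum number of ranked signatures returned
#'   (default \code{Inf}).
#' @return A \code{signature_params} list.
#' @export
signature_params <- function(min_len = 20L, max_len = 20L,
                             max_ambiguous = 2L,
                             region_priority = c("ITS2", "LSU", "5.8S",
                                                 "SSU", "ITS1"),
                             max_alternatives = 3L, top_k = Inf) {
  min_len <- as.integer(min_len)
  max_len <- as.integer(max_len)
  if (min_len > max_len) stop("min_len must be <= max_len")
  if (min_len < 1L) stop("window length must be positive")
  if (max_ambiguous < 0L) stop("max_ambiguous must be >= 0")
  structure(list(min_len = min_len, max_len = max_len,
                 max_ambiguous = as.integer(max_ambiguous),
                 region_priority = region_priority,
                 max_alternatives = as.integer(max_alternatives),
                 top_k = top_k),
            class = "signature_params")
}

#' Degenerate consensus motif of a taxon over a window
#'
#' Per column, the IUPAC code whose expansion is the union of the target
#' members' expansions. Undefined (\code{NA}) when any target member has a
#' gap inside the window: signatures are contiguous barcodes.
#'
#' @param aln An \code{annotated_alignment}.
#' @param target Taxon name.
#' @param columns Integer vector of alignment columns.
#' @param rank Optional rank of \code{target}.
#' @return A motif string, or \code{NA_character_}.
#' @export
window_consensus <- function(aln, target, columns, rank = NULL) {
  columns <- resolve_columns(aln, columns, NULL)
  members <- taxon_members(aln, target, rank)
  if (length(members) == 0L) stop("empty taxon: ", target)
  sub <- aln$enc[members, columns, drop = FALSE]
  if (any(sub == 0L)) return(NA_character_)
  u <- Reduce(bitwOr, lapply(seq_len(nrow(sub)), function(i) sub[i, ]))
  decode_seq(u)
}

#' Mismatch count of a motif against one aligned sequence
#'
#' Number of window columns whose motif symbol and sequence symbol share no
#' base in their IUPAC expansions; a gap in the sequence counts as a
#' mismatch.
#'
#' @inheritParams window_consensus
#' @param motif IUPAC motif string, same length as \code{columns}.
#' @param id Sequence id.
#' @return Integer mismatch count.
#' @export
mismatch_count <- function(motif, aln, id, columns) {
  columns <- as.integer(columns)
  m <- encode_seq(tolower(motif))
  if (length(m) != length(columns)) {
    stop("window shape: motif length != interval length")
  }
  s <- aln$enc[id, columns]
  sum(bitwAnd(m, s) == 0L)
}

#' Derive the allowed-mismatch budget for a motif
#'
#' Let d_min be the minimum mismatch count over all non-target sequences;
#' the allowed-mismatch budget is m = d_min - 1 (clamped at 0). The motif is
#' a valid signature iff d_min >= 1.
#'
#' @inheritParams mismatch_count
#' @param target Taxon name whose members are excluded from the contrast set.
#' @param rank Optional rank of \code{target}.
#' @return List with \code{m}, \code{d_min}, \code{valid},
#'   \code{nearest_nontarget} (id attaining d_min).
#' @export
allowed_mismatches <- function(motif, aln, target, columns, rank = NULL) {
  columns <- as.integer(columns)
  members <- taxon_members(aln, target, rank)
  others <- setdiff(rownames(aln$enc), members)
  if (length(others) == 0L) stop("no contrast set for ", target)
  mm <- encode_seq(tolower(motif))
  if (length(mm) != length(columns)) {
    stop("window shape: motif length != interval length")
  }
  counts <- vapply(others, function(id) {
    sum(bitwAnd(mm, aln$enc[id, columns]) == 0L)
  }, integer(1L))
  d_min <- min(counts)
  list(m = max(0L, d_min - 1L), d_min = d_min, valid = d_min >= 1L,
       nearest_nontarget = others[which.min(counts)])
}

# one signature object
new_signature <- function(target, region, alternatives, starts, len, m,
                          ambiguity, d_min) {
  structure(
    list(target = target, region = region,
         alternatives = alternatives,
         columns = lapply(starts, function(s) c(s, s + len - 1L)),
         length = len, m = as.integer(m),
         ambiguity = as.integer(ambiguity),
         d_min = as.integer(d_min), margin = as.integer(d_min - m)),
    class = "signature"
  )
}

#' @export
print.signature <- function(x, ...) {
  cat(sprintf("signature for %s in %s: %s (columns %d-%d; %s; margin %d)\n",
              x$target, x$region,
              paste(x$alternatives, collapse = " OR "),
              x$columns[[1L]][1L], x$columns[[1L]][2L],
              mismatch_phrase(x$m), x$margin))
  invisible(x)
}

#' Mine diagnostic signatures for a target taxon
#'
#' Enumerates every gap-free target window of each length in
#' \code{[min_len, max_len]} within each region (in priority order), keeps
#' windows whose consensus has at most \code{max_ambiguous} degenerate
#' symbols and whose minimum non-target mismatch count d_min is at least 1,
#' and ranks them by d_min (descending), ambiguity (ascending), region
#' priority, leftmost start column, then length. Fully deterministic.
#'
#' @inheritParams window_consensus
#' @param params A \code{\link{signature_params}}.
#' @return List of \code{signature} objects (possibly empty), best first.
#' @export
find_signatures <- function(aln, target, params = signature_params(),
                            rank = NULL) {
  members <- taxon_members(aln, target, rank)
  if (length(members) == 0L) stop("empty taxon: ", target)
  others <- setdiff(rownames(aln$enc), members)
  if (length(others) == 0L) stop("no contrast set for ", target)

  regions <- intersect(params$region_priority, aln$regions$region)
  cand <- list()
  for (ri in seq_along(regions)) {
    rg <- regions[[ri]]
    cols <- region_columns(aln, rg)
    sub_t <- aln$enc[members, cols, drop = FALSE]
    sub_o <- aln$enc[others, cols, drop = FALSE]
    w <- length(cols)

    # per-column target consensus, gap presence, ambiguity indicator
    u <- if (nrow(sub_t) == 1L) sub_t[1L, ]
         else Reduce(bitwOr, lapply(seq_len(nrow(sub_t)),
                                    function(i) sub_t[i, ]))
    has_gap <- colSums(sub_t == 0L) > 0L
    amb <- as.integer(.iupac_nbits[u + 1L] > 1L & !has_gap)

    # mismatch indicator matrix of non-targets vs consensus (gap -> mismatch)
    mm <- matrix(as.integer(bitwAnd(as.integer(sub_o),
                                    rep(u, each = nrow(sub_o))) == 0L),
                 nrow = nrow(sub_o))

    # prefix sums for O(1) window statistics
    cs_gap <- c(0L, cumsum(as.integer(has_gap)))
    cs_amb <- c(0L, cumsum(amb))
    cs_mm <- cbind(0L, t(apply(mm, 1L, cumsum)))

    for (len in seq.int(params$min_len, params$max_len)) {
      if (len > w) next
      starts <- seq_len(w - len + 1L)
      ends <- starts + len
      ok_gap <- (cs_gap[ends] - cs_gap[starts]) == 0L
      n_amb <- cs_amb[ends] - cs_amb[starts]
      ok_amb <- n_amb <= params$max_ambiguous
      keep <- which(ok_gap & ok_amb)
      if (length(keep) == 0L) next
      wm <- cs_mm[, ends[keep], drop = FALSE] -
        cs_mm[, starts[keep], drop = FALSE]
      d_min <- apply(wm, 2L, min)
      qual <- d_min >= 1L
      for (k in which(qual)) {
        s <- starts[keep[k]]
        cand[[length(cand) + 1L]] <- list(
          region = rg, region_i = ri, start = cols[s], len = len,
          motif = decode_seq(u[s:(s + len - 1L)]),
          d_min = d_min[k], ambiguity = n_amb[keep[k]])
      }
    }
  }
  if (length(cand) == 0L) return(list())
  d_min <- vapply(cand, `[[`, integer(1L), "d_min")
  ambiguity <- vapply(cand, `[[`, integer(1L), "ambiguity")
  region_i <- vapply(cand, `[[`, integer(1L), "region_i")
  start <- vapply(cand, `[[`, integer(1L), "start")
  len <- vapply(cand, `[[`, integer(1L), "len")
  o <- order(-d_min, ambiguity, region_i, start, len)
  if (is.finite(params$top_k)) o <- utils::head(o, params$top_k)
  lapply(o, function(i) {
    z <- cand[[i]]
    new_signature(target, z$region, z$motif, z$start, z$len,
                  m = z$d_min - 1L, ambiguity = z$ambiguity,
                  d_min = z$d_min)
  })
}

#' Mine a disjunctive (OR) signature for a heterogeneous target
#'
#' For targets too variable for a single low-ambiguity motif: target members
#' are partitioned into up to \code{max_alternatives} groups by
#' complete-linkage clustering of window-restricted mismatch distances, one
#' consensus motif is emitted per group, and the signature is valid when
#' every non-target exceeds m mismatches against ALL alternatives (m derived
#' from the best-alternative minimum as usual). Greedy over windows in
#' region-priority/leftmost order with the smallest feasible group count;
#' identical alternatives are deduplicated, so a homogeneous target collapses
#' to a single-motif signature.
#'
#' @inheritParams find_signatures
#' @return A \code{signature} with one or more alternatives, or \code{NULL}.
#' @export
find_disjunctive_signature <- function(aln, target,
                                       params = signature_params(),
                                       rank = NULL) {
  members <- taxon_members(aln, target, rank)
  if (length(members) == 0L) stop("empty taxon: ", target)
  others <- setdiff(rownames(aln$enc), members)
  if (length(others) == 0L) stop("no contrast set for ", target)

  regions <- intersect(params$region_priority, aln$regions$region)
  for (rg in regions) {
    cols <- region_columns(aln, rg)
    sub_t <- aln$enc[members, cols, drop = FALSE]
    sub_o <- aln$enc[others, cols, drop = FALSE]
    has_gap <- colSums(sub_t == 0L) > 0L
    cs_gap <- c(0L, cumsum(as.integer(has_gap)))
    w <- length(cols)
    for (len in seq.int(params$min_len, params$max_len)) {
      if (len > w) next
      for (s in seq_len(w - len + 1L)) {
        if ((cs_gap[s + len] - cs_gap[s]) != 0L) next
        win <- s:(s + len - 1L)
        tw <- sub_t[, win, drop = FALSE]
        ow <- sub_o[, win, drop = FALSE]
        k_max <- min(params$max_alternatives, nrow(tw))
        groups_for_k <- window_groupings(tw, k_max)
        for (groups in groups_for_k) {
          sig <- try_alternatives(tw, ow, groups, params$max_ambiguous)
          if (!is.null(sig)) {
            return(new_signature(target, rg, sig$motifs,
                                 rep(cols[s], length(sig$motifs)), len,
                                 m = sig$d_min - 1L,
                                 ambiguity = sig$ambiguity,
                                 d_min = sig$d_min))
          }
        }
      }
    }
  }
  NULL
}

# partitions of target rows into k = 1..k_max groups by complete-linkage
# clustering of within-window mismatch distances
window_groupings <- function(tw, k_max) {
  n <- nrow(tw)
  out <- list(rep(1L, n))
  if (n < 2L || k_max < 2L) return(out)
  D <- matrix(0L, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      D[i, j] <- D[j, i] <- sum(bitwAnd(tw[i, ], tw[j, ]) == 0L)
    }
  }
  hc <- stats::hclust(stats::as.dist(D), method = "complete")
  for (k in 2:k_max) {
    out[[k]] <- stats::cutree(hc, k = k)
  }
  out
}

# build per-group consensus motifs and test validity; NULL when infeasible
try_alternatives <- function(tw, ow, groups, max_ambiguous) {
  motifs_enc <- lapply(sort(unique(groups)), function(g) {
    rows <- tw[groups == g, , drop = FALSE]
    if (nrow(rows) == 1L) rows[1L, ]
    else Reduce(bitwOr, lapply(seq_len(nrow(rows)), function(i) rows[i, ]))
  })
  motifs_enc <- unique(motifs_enc)
  ambs <- vapply(motifs_enc, function(u) sum(.iupac_nbits[u + 1L] > 1L),
                 integer(1L))
  if (any(ambs > max_ambiguous)) return(NULL)
  # best (minimum over alternatives) mismatch count per non-target
  best <- rep.int(.Machine$integer.max, nrow(ow))
  for (u in motifs_enc) {
    cnt <- as.integer(rowSums(matrix(bitwAnd(as.integer(ow),
                                             rep(u, each = nrow(ow))) == 0L,
                                     nrow = nrow(ow))))
    best <- pmin(best, cnt)
  }
  d_min <- min(best)
  if (d_min < 1L) return(NULL)
  list(motifs = vapply(motifs_enc, decode_seq, character(1L)),
       d_min = d_min, ambiguity = max(ambs))
}

#' Verify a signature against an alignment
#'
#' Recomputes the membership test: every target member must be within m
#' mismatches of at least one alternative, and every non-target must exceed
#' m against all alternatives. Idempotent; usable both on mined signatures
#' and on externally stated (e.g. published) ones.
#'
#' @param aln An \code{annotated_alignment}.
#' @param sig A \code{signature} (see \code{\link{find_signatures}}), or a
#'   list with fields \code{target}, \code{alternatives}, \code{columns}
#'   (list of \code{c(start, end)} per alternative), \code{m}.
#' @param rank Optional rank of the target.
#' @return List with \code{all_targets_match},
#'   \code{min_nontarget_mismatches}, \code{valid}, \code{margin},
#'   \code{offending} (ids of target members beyond m and non-targets
#'   within m).
#' @export
verify_signature <- function(aln, sig, rank = NULL) {
  members <- taxon_members(aln, sig$target, rank)
  others <- setdiff(rownames(aln$enc), members)
  alts <- sig$alternatives
  col_list <- sig$columns
  if (length(col_list) == 1L && length(alts) > 1L) {
    col_list <- rep(col_list, length(alts))
  }
  best_of <- function(id) {
    min(vapply(seq_along(alts), function(a) {
      cols <- seq.int(col_list[[a]][1L], col_list[[a]][2L])
      mismatch_count(alts[[a]], aln, id, cols)
    }, integer(1L)))
  }
  t_cnt <- vapply(members, best_of, integer(1L))
  o_cnt <- vapply(others, best_of, integer(1L))
  all_targets_match <- all(t_cnt <= sig$m)
  min_nt <- if (length(o_cnt)) min(o_cnt) else NA_integer_
  valid <- all_targets_match && !is.na(min_nt) && min_nt > sig$m
  offending <- c(members[t_cnt > sig$m],
                 if (length(o_cnt)) others[o_cnt <= sig$m] else character(0))
  list(all_targets_match = all_targets_match,
       min_nontarget_mismatches = min_nt,
       valid = valid,
       margin = if (is.na(min_nt)) NA_integer_ else min_nt - sig$m,
       offending = offending)
}

#' Signatures as a data frame
#'
#' @param sigs List of \code{signature} objects.
#' @return Data frame, one row per signature, alternatives joined by
#'   \code{" OR "}.
#' @export
signatures_as_data_frame <- function(sigs) {
  if (length(sigs) == 0L) {
    return(data.frame(target = character(0), region = character(0),
                      motif = character(0), start = integer(0),
                      end = integer(0), m = integer(0),
                      ambiguity = integer(0), margin = integer(0)))
  }
  do.call(rbind, lapply(sigs, function(s) {
    data.frame(target = s$target, region = s$region,
               motif = paste(s$alternatives, collapse = " OR "),
               start = s$columns[[1L]][1L], end = s$columns[[1L]][2L],
               m = s$m, ambiguity = s$ambiguity, margin = s$margin,
               stringsAsFactors = FALSE)
  }))
}
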