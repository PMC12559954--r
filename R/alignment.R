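# Annotated alignment container: aligned IUPAC sequences + per-sequence
# taxonomy and roles + rRNA-operon region map. All downstream stages
# (distances, signatures, coordinates, delimitation) operate on this object.

RANKS <- c("phylum", "class", "order", "family", "genus", "species")
REGION_NAMES <- c("SSU", "ITS1", "5.8S", "ITS2", "LSU")

#' Construct an annotated alignment
#'
#' @param seqs Named character vector of equal-length aligned sequences over
#'   the IUPAC alphabet plus \code{"-"} (case-insensitive; stored lower-case).
#' @param taxonomy Data frame with columns \code{id}, the ranks
#'   \code{phylum}..\code{species} (empty strings/NA allowed above species for
#'   incertae sedis placements), and optionally \code{roles}
#'   (semicolon-separated subset of \code{legitype}, \code{nucleotype-derived},
#'   \code{reference}).
#' @param regions Data frame with columns \code{region} (names among SSU,
#'   ITS1, 5.8S, ITS2, LSU), \code{start}, \code{end}: 1-based inclusive,
#'   non-overlapping, strictly increasing alignment-column intervals.
#' @return An object of class \code{annotated_alignment} with elements
#'   \code{seqs}, \code{enc} (integer mask matrix, sequences in rows),
#'   \code{taxonomy}, \code{regions}, \code{width}.
#' @export
annotated_alignment <- function(seqs, taxonomy, regions) {
  if (length(seqs) < 1L) stop("alignment needs at least one record")
  ids <- names(seqs)
  if (is.null(ids) || anyNA(ids) || any(ids == "")) {
    stop("all sequences must be named")
  }
  if (anyDuplicated(ids)) stop("duplicate sequence id: ", ids[duplicated(ids)][1L])

  seqs <- tolower(seqs)
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) stop("unequal lengths in alignment")
  width <- widths[[1L]]

  enc <- t(vapply(seqs, encode_seq, integer(width)))
  rownames(enc) <- ids

  taxonomy <- validate_taxonomy(taxonomy, ids)
  regions <- validate_regions(regions, width)

  structure(
    list(seqs = seqs, enc = enc, taxonomy = taxonomy,
         regions = regions, width = width),
    class = "annotated_alignment"
  )
}

validate_taxonomy <- function(taxonomy, ids) {
  taxonomy <- as.data.frame(taxonomy, stringsAsFactors = FALSE)
  if (!"id" %in% names(taxonomy)) stop("taxonomy table needs an 'id' column")
  missing_ranks <- setdiff(RANKS, names(taxonomy))
  if (length(missing_ranks)) {
    stop("taxonomy table missing rank column(s): ",
         paste(missing_ranks, collapse = ", "))
  }
  if (!"roles" %in% names(taxonomy)) taxonomy$roles <- ""
  taxonomy$roles[is.na(taxonomy$roles)] <- ""
  for (r in RANKS) {
    taxonomy[[r]] <- as.character(taxonomy[[r]])
    taxonomy[[r]][is.na(taxonomy[[r]])] <- ""
  }
  absent <- setdiff(ids, taxonomy$id)
  if (length(absent)) {
    stop("unlabelled sequence: ", paste(absent, collapse = ", "))
  }
  role_tokens <- unlist(strsplit(taxonomy$roles[taxonomy$roles != ""], ";"))
  bad <- setdiff(trimws(role_tokens),
                 c("legitype", "nucleotype-derived", "reference"))
  if (length(bad)) stop("unknown role flag: ", bad[[1L]])
  taxonomy[match(ids, taxonomy$id), , drop = FALSE]
}

validate_regions <- function(regions, width) {
  regions <- as.data.frame(regions, stringsAsFactors = FALSE)
  need <- c("region", "start", "end")
  if (!all(need %in% names(regions))) {
    stop("region map needs columns region, start, end")
  }
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)
  bad <- setdiff(regions$region, REGION_NAMES)
  if (length(bad)) stop("unknown region name: ", bad[[1L]])
  if (anyDuplicated(regions$region)) stop("duplicate region in map")
  if (any(regions$start < 1L) || any(regions$end > width)) {
    stop("region interval outside alignment width")
  }
  if (any(regions$end < regions$start)) stop("region end before start")
  o <- order(regions$start)
  regions <- regions[o, , drop = FALSE]
  if (nrow(regions) > 1L &&
      any(regions$start[-1L] <= regions$end[-nrow(regions)])) {
    stop("region intervals overlap")
  }
  rownames(regions) <- NULL
  regions
}

#' @export
print.annotated_alignment <- function(x, ...) {
  cat("annotated_alignment:", nrow(x$enc), "sequences x", x$width, "columns\n")
  cat("regions:",
      paste(sprintf("%s [%d-%d]", x$regions$region, x$regions$start,
                    x$regions$end), collapse = ", "), "\n")
  sp <- unique(x$taxonomy$species)
  cat("species:", length(sp[sp != ""]), "\n")
  invisible(x)
}

# region name -> integer column vector (1-based)
region_columns <- function(aln, region) {
  i <- match(region, aln$regions$region)
  if (is.na(i)) stop("region not in region map: ", region)
  seq.int(aln$regions$start[i], aln$regions$end[i])
}

# ids of sequences whose lineage contains `taxon`; rank auto-detected unless
# given. Errors if the name is absent or appears at several ranks.
taxon_members <- function(aln, taxon, rank = NULL) {
  tx <- aln$taxonomy
  if (is.null(rank)) {
    hits <- RANKS[vapply(RANKS, function(r) taxon %in% tx[[r]], logical(1L))]
    if (length(hits) == 0L) stop("taxon not found in taxonomy: ", taxon)
    if (length(hits) > 1L) {
      stop("taxon name '", taxon, "' is ambiguous across ranks: ",
           paste(hits, collapse = ", "))
    }
    rank <- hits
  }
  if (!rank %in% RANKS) stop("bad rank: ", rank)
  tx$id[tx[[rank]] == taxon]
}

taxon_rank <- function(aln, taxon) {
  hits <- RANKS[vapply(RANKS, function(r) taxon %in% aln$taxonomy[[r]],
                       logical(1L))]
  if (length(hits) == 0L) stop("taxon not found in taxonomy: ", taxon)
  hits[[1L]]
}
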