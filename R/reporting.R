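# Taxon-ledger tallies and formal molecular Diagnosis rendering. The ledger
# is a ranked taxon table with per-rank novelty flags ("new" vs "described";
# species may additionally be "combination" for recombined names); counting
# deduplicates names shared across rows and excludes previously described
# and recombined taxa. Diagnosis blocks are rendered in the conventional
# textual format (number-words for the mismatch budget, 1-decimal percents,
# en-dash ranges) and can be re-parsed into structured fields.

LEDGER_STATUS_COLS <- paste0(RANKS, "_status")

#' Read a taxon ledger
#'
#' @param path TSV with columns \code{phylum}, \code{phylum_status},
#'   \code{class}, \code{class_status}, ..., \code{species},
#'   \code{species_status}. Status values are \code{new} or
#'   \code{described}; species rows may be \code{combination}.
#'   \code{'#'} comment lines are ignored.
#' @return A validated data frame of class \code{taxon_ledger}.
#' @export
read_taxon_ledger <- function(path) {
  df <- read_tsv_file(path)
  validate_taxon_ledger(df)
}

#' @rdname read_taxon_ledger
#' @param df A data frame with ledger columns.
#' @export
validate_taxon_ledger <- function(df) {
  need <- as.vector(rbind(RANKS, LEDGER_STATUS_COLS))
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("ledger missing column(s): ", paste(missing, collapse = ", "))
  }
  for (r in RANKS) {
    if (any(is.na(df[[r]]) | df[[r]] == "")) {
      stop("ledger row incomplete at rank ", r)
    }
  }
  ok_status <- c("new", "described", "combination")
  for (s in LEDGER_STATUS_COLS) {
    bad <- setdiff(df[[s]], ok_status)
    if (length(bad)) stop("unknown status '", bad[[1L]], "' in ", s)
  }
  class(df) <- c("taxon_ledger", "data.frame")
  df
}

#' Count distinct newly proposed taxa at a rank
#'
#' Distinct taxon names at the rank whose status flag is \code{"new"}:
#' names shared across rows count once, previously described names are
#' excluded, and recombined species are not new species.
#'
#' @param ledger A \code{taxon_ledger}.
#' @param rank One of phylum, class, order, family, genus, species.
#' @return Integer count.
#' @export
count_new_taxa <- function(ledger, rank) {
  if (!rank %in% RANKS) stop("bad rank: ", rank)
  new_names <- ledger[[rank]][ledger[[paste0(rank, "_status")]] == "new"]
  length(unique(new_names))
}

#' Count distinct highest-rank novel lineages
#'
#' For each row, take the taxon name at the highest rank (phylum first)
#' flagged \code{"new"}; count distinct names over rows. Rows with no novel
#' rank are excluded with a warning.
#'
#' @param ledger A \code{taxon_ledger}.
#' @return Integer count.
#' @export
distinct_highest_rank_lineages <- function(ledger) {
  highest <- vapply(seq_len(nrow(ledger)), function(i) {
    for (r in RANKS) {
      if (ledger[[paste0(r, "_status")]][i] == "new") return(ledger[[r]][i])
    }
    NA_character_
  }, character(1L))
  if (anyNA(highest)) {
    warning(sum(is.na(highest)), " ledger row(s) with no novel rank excluded")
  }
  length(unique(highest[!is.na(highest)]))
}

#' Per-rank summary of newly proposed taxa
#'
#' @param ledger A \code{taxon_ledger}.
#' @return Named integer vector over the six ranks plus
#'   \code{highest_rank_lineages}.
#' @export
tally_new_taxa <- function(ledger) {
  counts <- vapply(RANKS, function(r) count_new_taxa(ledger, r), integer(1L))
  c(counts, highest_rank_lineages = distinct_highest_rank_lineages(ledger))
}

# -- Diagnosis rendering ------------------------------------------------------

MISMATCH_WORDS <- c("no", "one", "two", "three")

mismatch_phrase <- function(m) {
  m <- as.integer(m)
  word <- if (m <= 3L) MISMATCH_WORDS[m + 1L] else {
    warning("mismatch budget ", m, " exceeds three; rendered as digits")
    as.character(m)
  }
  noun <- if (m <= 1L) "mismatch" else "mismatches"
  paste(word, noun, "allowed")
}

parse_mismatch_phrase <- function(txt) {
  word <- sub(" mismatch(es)? allowed$", "", txt)
  i <- match(word, MISMATCH_WORDS)
  if (!is.na(i)) return(i - 1L)
  as.integer(word)
}

pct <- function(x) sprintf("%.1f%%", 100 * x)

oxford_list <- function(x) {
  n <- length(x)
  if (n == 1L) return(x)
  if (n == 2L) return(paste(x, collapse = " and "))
  paste0(paste(x[-n], collapse = ", "), ", and ", x[n])
}

#' Render a molecular Diagnosis paragraph
#'
#' Assembles the conventional Diagnosis text: the signature clause per
#' region (positions, motif alternatives joined by \code{" OR "}, and the
#' allowed-mismatch budget as a number-word), the intraspecific-variation
#' and interspecific-distance sentences at 1-decimal percent precision
#' (flagging regions without a clear barcode gap), and the
#' least-inclusive-clade clause listing covered sequence ids.
#'
#' @param taxon Taxon (e.g. species) name.
#' @param genus Genus used in the "other species of" phrase.
#' @param signatures List of entries with \code{region}, \code{positions}
#'   (rendered position text, e.g. from \code{\link{interval_positions}}),
#'   \code{motif} (alternatives joined by \code{" OR "}), \code{m}.
#' @param distances Data frame as returned by \code{\link{distance_report}}
#'   (columns \code{region}, \code{max_intra}, \code{min_inter},
#'   \code{barcode_gap}).
#' @param clade List with \code{parent} (taxon whose phylogram the clade sits
#'   in) and \code{ids} (covered sequence ids).
#' @return A single character string; parseable by
#'   \code{\link{parse_diagnosis}}.
#' @export
render_diagnosis <- function(taxon, genus, signatures, distances, clade) {
  sig_txt <- vapply(signatures, function(s) {
    sprintf("%s (positions %s %s; %s)", s$region, s$positions, s$motif,
            mismatch_phrase(s$m))
  }, character(1L))
  intra_txt <- paste(
    sprintf("up to %s in %s", pct(distances$max_intra), distances$region),
    collapse = " and ")
  inter_txt <- paste(
    sprintf("at least %s in %s", pct(distances$min_inter), distances$region),
    collapse = " and ")
  no_gap <- distances$region[!distances$barcode_gap]
  gap_txt <- if (length(no_gap)) {
    sprintf("; i.e., there is no clear barcode gap in %s",
            paste(no_gap, collapse = " and "))
  } else ""
  paste0(
    "Separation from other species of *", genus, "* based on ",
    paste(sig_txt, collapse = " and "), ". ",
    "Intraspecific variation ", intra_txt, ". ",
    "Interspecific distance ", inter_txt, gap_txt, ". ",
    "Forms a monophyletic, least inclusive clade in ", clade$parent,
    ", covering sequences ", oxford_list(clade$ids), "."
  )
}

#' Parse a rendered Diagnosis paragraph
#'
#' Inverse of \code{\link{render_diagnosis}}: recovers genus, signatures
#' (region, position text, motif, m), per-region distances, no-gap regions,
#' and the clade clause. \code{render -> parse -> render} is a fixed point.
#'
#' @param text A Diagnosis string from \code{\link{render_diagnosis}}.
#' @return List with \code{genus}, \code{signatures}, \code{max_intra},
#'   \code{min_inter} (named numeric vectors by region),
#'   \code{no_gap_regions}, \code{clade}.
#' @export
parse_diagnosis <- function(text) {
  genus <- sub("^Separation from other species of \\*([^*]+)\\*.*$", "\\1",
               text)
  sig_block <- sub(
    "^.*?based on (.*?)\\. Intraspecific variation.*$", "\\1", text)
  sig_parts <- strsplit(sig_block, "\\) and ")[[1L]]
  sig_parts <- sub("\\)$", "", sig_parts)
  signatures <- lapply(sig_parts, function(s) {
    region <- sub("^([^ ]+) \\(positions .*$", "\\1", s)
    body <- sub("^[^ ]+ \\(positions ", "", s)
    m_txt <- sub("^.*; ", "", body)
    rest <- sub("; [^;]*$", "", body)
    # walk tokens backwards to pick up the full "x OR y OR z" motif tail
    tokens <- strsplit(rest, " ", fixed = TRUE)[[1L]]
    is_motif <- function(tok) grepl("^[acgtmrwsykvhdbn-]+$", tok)
    i <- length(tokens)
    if (!is_motif(tokens[i])) stop("cannot parse motif in: ", s)
    while (i - 2L >= 1L && tokens[i - 1L] == "OR" && is_motif(tokens[i - 2L])) {
      i <- i - 2L
    }
    motif <- paste(tokens[i:length(tokens)], collapse = " ")
    positions <- paste(tokens[seq_len(i - 1L)], collapse = " ")
    list(region = region, positions = positions, motif = motif,
         m = parse_mismatch_phrase(m_txt))
  })
  intra_block <- sub(
    "^.*Intraspecific variation (.*?)\\. Interspecific distance.*$", "\\1",
    text)
  intra_parts <- strsplit(intra_block, " and ")[[1L]]
  max_intra <- stats::setNames(
    as.numeric(sub("^up to ([0-9.]+)%.*$", "\\1", intra_parts)) / 100,
    sub("^.* in ", "", intra_parts))
  inter_block <- sub(
    "^.*Interspecific distance (.*?)\\. Forms a monophyletic.*$", "\\1",
    text)
  no_gap_regions <- character(0)
  if (grepl("; i.e., there is no clear barcode gap in ", inter_block,
            fixed = TRUE)) {
    halves <- strsplit(inter_block,
                       "; i.e., there is no clear barcode gap in ",
                       fixed = TRUE)[[1L]]
    inter_block <- halves[[1L]]
    no_gap_regions <- strsplit(halves[[2L]], " and ", fixed = TRUE)[[1L]]
  }
  inter_parts <- strsplit(inter_block, " and ")[[1L]]
  min_inter <- stats::setNames(
    as.numeric(sub("^at least ([0-9.]+)%.*$", "\\1", inter_parts)) / 100,
    sub("^.* in ", "", inter_parts))
  clade_txt <- sub(
    "^.*Forms a monophyletic, least inclusive clade in (.*)\\.$", "\\1",
    text)
  parent <- sub(", covering sequences .*$", "", clade_txt)
  ids_txt <- sub("^.*, covering sequences ", "", clade_txt)
  ids <- strsplit(ids_txt, ", and |, | and ")[[1L]]
  list(genus = genus, signatures = signatures, max_intra = max_intra,
       min_inter = min_inter, no_gap_regions = no_gap_regions,
       clade = list(parent = parent, ids = ids))
}

#' Build a Diagnosis from pipeline objects
#'
#' Convenience wrapper: takes mined signatures, a distance report, and a
#' clade test, renders position text in the supplied coordinate systems,
#' and returns the Diagnosis paragraph.
#'
#' @param aln An \code{annotated_alignment}.
#' @param sigs List of \code{signature} objects (one per region clause).
#' @param distances Output of \code{\link{distance_report}}.
#' @param clade_parent Parent taxon named in the clade clause.
#' @param clade_ids Sequence ids covered by the clade.
#' @param coord_systems Named list mapping region name to a list of
#'   \code{\link{coordinate_system}}s used for that region's positions;
#'   regions without an entry fall back to raw alignment columns.
#' @return The rendered Diagnosis string.
#' @export
diagnosis_from_results <- function(aln, sigs, distances, clade_parent,
                                   clade_ids, coord_systems = list()) {
  stopifnot(length(sigs) >= 1L)
  target <- sigs[[1L]]$target
  genus <- unique(aln$taxonomy$genus[aln$taxonomy$id %in%
                                       taxon_members(aln, target)])
  genus <- genus[nzchar(genus)][1L]
  sig_entries <- lapply(sigs, function(s) {
    cols <- seq.int(s$columns[[1L]][1L], s$columns[[1L]][2L])
    positions <- if (!is.null(coord_systems[[s$region]])) {
      interval_positions(aln, coord_systems[[s$region]], cols)$text
    } else {
      fmt_range(cols[1L], cols[length(cols)])
    }
    list(region = s$region, positions = positions,
         motif = paste(s$alternatives, collapse = " OR "), m = s$m)
  })
  render_diagnosis(target, genus, sig_entries, distances,
                   list(parent = clade_parent, ids = clade_ids))
}
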