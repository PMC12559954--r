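# Readers and writers for the three plain-text inputs: aligned FASTA,
# taxonomy TSV, region-map TSV. All readers tolerate CRLF line endings and
# '#' comment lines. '?' is normalised to 'n' and '.' to '-' (with a warning),
# a tolerance for common alignment-editor dialects.

#' Read an annotated alignment from FASTA + taxonomy + region map
#'
#' @param fasta Path to an aligned FASTA file (equal-length records, gap
#'   character \code{"-"}, IUPAC alphabet).
#' @param taxonomy Path to a TSV with columns \code{id}, \code{phylum},
#'   \code{class}, \code{order}, \code{family}, \code{genus}, \code{species},
#'   \code{roles} (semicolon-separated; may be empty).
#' @param regions Path to a TSV with columns \code{region}, \code{start},
#'   \code{end} giving 1-based inclusive alignment-column intervals.
#' @return An \code{\link{annotated_alignment}}.
#' @export
read_alignment_fasta <- function(fasta, taxonomy, regions) {
  seqs <- read_fasta_seqs(fasta)
  tx <- read_taxonomy_tsv(taxonomy)
  rg <- read_regions_tsv(regions)
  annotated_alignment(seqs, tx, rg)
}

# FASTA via Biostrings, after stripping comment lines / CRLF; returns a
# named lower-case character vector with '?'/'.' normalised.
read_fasta_seqs <- function(path) {
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  lines <- lines[!grepl("^#", lines)]
  tmp <- tempfile(fileext = ".fasta")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  set <- Biostrings::readBStringSet(tmp)
  seqs <- tolower(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (any(grepl("[?.]", seqs))) {
    warning("normalising '?' to 'n' and '.' to '-' in ", basename(path))
    seqs <- gsub("?", "n", seqs, fixed = TRUE)
    seqs <- gsub(".", "-", seqs, fixed = TRUE)
  }
  seqs
}

read_tsv_file <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' @rdname read_alignment_fasta
#' @export
read_taxonomy_tsv <- function(taxonomy) read_tsv_file(taxonomy)

#' @rdname read_alignment_fasta
#' @export
read_regions_tsv <- function(regions) read_tsv_file(regions)

#' Write an annotated alignment back to its three files
#'
#' Inverse of \code{\link{read_alignment_fasta}} up to line wrapping and case
#' canonicalisation.
#'
#' @param aln An \code{annotated_alignment}.
#' @param fasta,taxonomy,regions Output paths (any may be \code{NULL} to
#'   skip that file).
#' @param wrap Line width for sequence wrapping in the FASTA output.
#' @return \code{aln}, invisibly.
#' @export
write_alignment_fasta <- function(aln, fasta, taxonomy = NULL,
                                  regions = NULL, wrap = 80L) {
  if (!is.null(fasta)) {
    con <- file(fasta, "w")
    on.exit(close(con), add = TRUE)
    for (id in names(aln$seqs)) {
      writeLines(paste0(">", id), con)
      s <- aln$seqs[[id]]
      starts <- seq.int(1L, nchar(s), by = wrap)
      writeLines(substring(s, starts, pmin(starts + wrap - 1L, nchar(s))), con)
    }
  }
  if (!is.null(taxonomy)) {
    utils::write.table(aln$taxonomy, taxonomy, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(regions)) {
    utils::write.table(aln$regions, regions, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(aln)
}
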