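# Mapping between alignment columns and ungapped positions of a designated
# reference sequence, region-locally. Positions are 1-based on the
# reference's non-gap bases counted from the region start; positions
# upstream of the region start are negative and there is NO zero (so a
# window spanning a region boundary counts ...,-2,-1,1,2,...). Diagnosis
# coordinates use the holotype-derived legitype for ITS and an external
# reference (S. cerevisiae-style, supplied as an ordinary alignment member
# flagged role=reference) for SSU/5.8S/LSU.

#' Declare a coordinate system
#'
#' @param ref Reference sequence id (must be a member of the alignment).
#' @param region Region name whose start column is the origin.
#' @param label Human-readable label used when rendering intervals
#'   (default: the reference id).
#' @param include_zero Use a zero position at the boundary instead of the
#'   no-zero convention (default \code{FALSE}).
#' @return A \code{coordinate_system} list.
#' @export
coordinate_system <- function(ref, region, label = ref,
                              include_zero = FALSE) {
  structure(list(ref = ref, region = region, label = label,
                 include_zero = isTRUE(include_zero)),
            class = "coordinate_system")
}

# signed positions of every alignment column for a system; NA where the
# reference is gapped. Internal workhorse, vectorised once per system.
system_positions <- function(aln, system) {
  if (!system$ref %in% rownames(aln$enc)) {
    stop("unknown reference: ", system$ref)
  }
  i <- match(system$region, aln$regions$region)
  if (is.na(i)) stop("region not in region map: ", system$region)
  origin <- aln$regions$start[i]
  ref <- aln$enc[system$ref, ]
  nongap <- ref != 0L
  pos <- rep(NA_integer_, aln$width)
  after <- which(nongap & seq_len(aln$width) >= origin)
  before <- which(nongap & seq_len(aln$width) < origin)
  if (length(after)) pos[after] <- seq_along(after)
  if (length(before)) {
    p <- -rev(seq_along(before))
    if (system$include_zero) p <- p + 1L
    pos[before] <- p
  }
  pos
}

#' Alignment column to reference position
#'
#' @param aln An \code{annotated_alignment}.
#' @param system A \code{\link{coordinate_system}}.
#' @param column Integer vector of alignment columns (1-based).
#' @return Signed integer positions; \code{NA} where the reference has a gap.
#' @export
column_to_position <- function(aln, system, column) {
  column <- as.integer(column)
  if (any(column < 1L | column > aln$width)) {
    stop("column outside alignment width")
  }
  system_positions(aln, system)[column]
}

#' Reference position to alignment column
#'
#' Inverse of \code{\link{column_to_position}} on non-gap reference columns.
#'
#' @inheritParams column_to_position
#' @param position Signed integer positions (no zero unless the system uses
#'   \code{include_zero}).
#' @return Integer alignment columns.
#' @export
position_to_column <- function(aln, system, position) {
  position <- as.integer(position)
  if (!system$include_zero && any(position == 0L)) {
    stop("no zero in convention")
  }
  pos <- system_positions(aln, system)
  idx <- match(position, pos)
  if (anyNA(idx)) {
    stop("beyond reference: position ", position[is.na(idx)][1L],
         " not covered by ", system$ref)
  }
  idx
}

# "X-Y" range with en-dash; negative numbers use the minus sign
fmt_range <- function(p1, p2) {
  fmt1 <- function(p) {
    if (p < 0) paste0("−", -p) else as.character(p)
  }
  paste0(fmt1(p1), "–", fmt1(p2))
}

#' Dual-coordinate description of a column interval
#'
#' Renders the start/end positions of a window in one or more coordinate
#' systems, in the style used by molecular Diagnoses: "119–133 in
#' type species and 120–134 in S. cerevisiae"; boundary-spanning
#' windows render negative starts, e.g. "−2–18".
#'
#' @param aln An \code{annotated_alignment}.
#' @param systems A single \code{\link{coordinate_system}} or a list of them.
#' @param columns Integer vector (contiguous interval) of alignment columns.
#' @return List with \code{text} (the rendered string) and \code{positions}
#'   (per system, the \code{c(start, end)} signed positions).
#' @export
interval_positions <- function(aln, systems, columns) {
  if (inherits(systems, "coordinate_system")) systems <- list(systems)
  columns <- as.integer(columns)
  if (length(columns) == 0L) stop("empty region")
  lo <- min(columns)
  hi <- max(columns)
  per <- lapply(systems, function(sys) {
    pos <- system_positions(aln, sys)
    p1 <- pos[lo]
    p2 <- pos[hi]
    if (is.na(p1) || is.na(p2)) {
      stop("reference ", sys$ref, " is gapped at the interval boundary")
    }
    list(label = sys$label, range = c(p1, p2),
         text = fmt_range(p1, p2))
  })
  text <- paste(vapply(per, function(z) paste0(z$text, " in ", z$label),
                       character(1L)),
                collapse = " and ")
  list(text = text,
       positions = stats::setNames(lapply(per, `[[`, "range"),
                                   vapply(per, `[[`, character(1L), "label")))
}
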