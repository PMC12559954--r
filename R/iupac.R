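# IUPAC nucleotide symbol algebra on 4-bit masks: a=1, c=2, g=4, t=8.
# The gap '-' carries mask 0 and is never compatible with anything.

.iupac_mask <- c(
  "a" = 1L, "c" = 2L, "g" = 4L, "t" = 8L,
  "m" = 3L, "r" = 5L, "w" = 9L, "s" = 6L, "y" = 10L, "k" = 12L,
  "v" = 7L, "h" = 11L, "d" = 13L, "b" = 14L, "n" = 15L, "-" = 0L
)

# code for each mask value 0..15, indexed mask + 1
.iupac_code <- {
  v <- character(16L)
  v[.iupac_mask + 1L] <- names(.iupac_mask)
  v
}

# number of set bits for masks 0..15, indexed mask + 1
.iupac_nbits <- vapply(0:15, function(m) {
  sum(bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L)
}, integer(1L))

# byte-indexed lookup (1..256) for fast string encoding; NA = non-IUPAC
.iupac_lut <- {
  lut <- rep(NA_integer_, 256L)
  lut[utf8ToInt(paste(names(.iupac_mask), collapse = "")) + 1L] <- .iupac_mask
  lut[utf8ToInt(toupper(paste(names(.iupac_mask), collapse = ""))) + 1L] <-
    .iupac_mask
  lut
}

#' IUPAC symbol expansion
#'
#' Expand a (possibly degenerate) IUPAC nucleotide code into the set of
#' concrete bases it stands for. The gap character \code{"-"} expands to the
#' empty set. Input is case-insensitive.
#'
#' @param code A single IUPAC character.
#' @return Character vector, a subset of \code{c("a","c","g","t")}.
#' @examples
#' iupac_expansion("r")  # a, g
#' iupac_expansion("n")  # a, c, g, t
#' @export
iupac_expansion <- function(code) {
  m <- encode_symbols(code)
  c("a", "c", "g", "t")[bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L]
}

#' Test compatibility of two IUPAC symbols
#'
#' Two symbols are compatible when their expansions share at least one base.
#' Any comparison involving a gap is incompatible. Vectorised with recycling.
#'
#' @param a,b IUPAC characters (vectors of single characters).
#' @return Logical vector.
#' @examples
#' symbols_compatible("r", "a")  # TRUE
#' symbols_compatible("r", "t")  # FALSE
#' symbols_compatible("n", "-")  # FALSE
#' @export
symbols_compatible <- function(a, b) {
  ma <- encode_symbols(a)
  mb <- encode_symbols(b)
  bitwAnd(ma, mb) > 0L
}

#' Degenerate consensus code for a base set
#'
#' Return the unique IUPAC code whose expansion equals the given non-empty
#' set of concrete bases.
#'
#' @param bases Character vector over \code{c("a","c","g","t")}
#'   (case-insensitive; duplicates allowed).
#' @return A single IUPAC character.
#' @examples
#' union_symbol(c("a", "t"))  # "w"
#' @export
union_symbol <- function(bases) {
  bases <- tolower(as.character(bases))
  if (length(bases) == 0L) stop("no consensus: empty base set")
  if (!all(bases %in% c("a", "c", "g", "t"))) {
    stop("union_symbol expects concrete bases a/c/g/t")
  }
  m <- Reduce(bitwOr, .iupac_mask[unique(bases)])
  .iupac_code[m + 1L]
}

# -- internal encoding helpers -----------------------------------------------

# character vector of single symbols -> integer masks; errors on non-IUPAC
encode_symbols <- function(x) {
  m <- .iupac_lut[utf8ToInt(paste(x, collapse = "")) + 1L]
  if (anyNA(m)) {
    bad <- x[is.na(m)][1L]
    stop("non-IUPAC character: '", bad, "'")
  }
  m
}

# one aligned sequence string -> integer mask vector
encode_seq <- function(s) {
  b <- utf8ToInt(s)
  m <- .iupac_lut[b + 1L]
  if (anyNA(m)) {
    bad <- intToUtf8(b[which(is.na(m))[1L]])
    stop("non-IUPAC character: '", bad, "'")
  }
  m
}

# integer mask vector -> sequence string
decode_seq <- function(m) {
  paste(.iupac_code[m + 1L], collapse = "")
}
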