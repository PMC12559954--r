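# Independent oracles and toy-data builders. The oracles deliberately avoid
# the package's bitmask machinery: they work on character sets from their
# own IUPAC table, with plain per-site loops.

ORACLE_IUPAC <- list(
  a = "a", c = "c", g = "g", t = "t",
  m = c("a", "c"), r = c("a", "g"), w = c("a", "t"),
  s = c("c", "g"), y = c("c", "t"), k = c("g", "t"),
  v = c("a", "c", "g"), h = c("a", "c", "t"),
  d = c("a", "g", "t"), b = c("c", "g", "t"),
  n = c("a", "c", "g", "t"), "-" = character(0)
)

oracle_compatible <- function(x, y) {
  length(intersect(ORACLE_IUPAC[[x]], ORACLE_IUPAC[[y]])) > 0
}

oracle_code_for_set <- function(set) {
  for (code in names(ORACLE_IUPAC)) {
    if (setequal(ORACLE_IUPAC[[code]], set)) return(code)
  }
  stop("no code for set")
}

# naive per-site p-distance on two character vectors (gap/n excluded)
oracle_p_distance <- function(chars_a, chars_b, min_overlap = 1L,
                              gap_handling = "exclude") {
  diffs <- 0L
  comp <- 0L
  for (i in seq_along(chars_a)) {
    x <- chars_a[i]
    y <- chars_b[i]
    if (x == "n" || y == "n") next
    if (gap_handling == "exclude") {
      if (x == "-" || y == "-") next
      comp <- comp + 1L
      if (!oracle_compatible(x, y)) diffs <- diffs + 1L
    } else {
      if (x == "-" && y == "-") next
      comp <- comp + 1L
      if (xor(x == "-", y == "-") || (x != "-" && y != "-" &&
                                        !oracle_compatible(x, y))) {
        diffs <- diffs + 1L
      }
    }
  }
  if (comp < min_overlap) return(NA_real_)
  diffs / comp
}

aln_chars <- function(aln, id) strsplit(aln$seqs[[id]], "")[[1]]

# brute-force enumeration of all qualifying signature windows
oracle_signatures <- function(aln, target, params) {
  members <- aln$taxonomy$id[aln$taxonomy$species == target]
  others <- setdiff(aln$taxonomy$id, members)
  chars <- lapply(stats::setNames(nm = aln$taxonomy$id),
                  function(id) aln_chars(aln, id))
  out <- list()
  regions <- intersect(params$region_priority, aln$regions$region)
  for (ri in seq_along(regions)) {
    rg <- regions[ri]
    row <- aln$regions[aln$regions$region == rg, ]
    for (len in params$min_len:params$max_len) {
      if (len > row$end - row$start + 1L) next
      for (s in row$start:(row$end - len + 1L)) {
        win <- s:(s + len - 1L)
        # consensus over target members; undefined on any gap
        motif <- character(len)
        amb <- 0L
        bad <- FALSE
        for (j in seq_along(win)) {
          col_chars <- vapply(members, function(id) chars[[id]][win[j]], "")
          if (any(col_chars == "-")) {
            bad <- TRUE
            break
          }
          set <- unique(unlist(ORACLE_IUPAC[col_chars]))
          motif[j] <- oracle_code_for_set(set)
          if (length(set) > 1L) amb <- amb + 1L
        }
        if (bad || amb > params$max_ambiguous) next
        d_min <- min(vapply(others, function(id) {
          sum(vapply(seq_along(win), function(j) {
            y <- chars[[id]][win[j]]
            y == "-" || !oracle_compatible(motif[j], y)
          }, logical(1)))
        }, integer(1)))
        if (d_min >= 1L) {
          out[[length(out) + 1L]] <- data.frame(
            region = rg, start = s, len = len,
            motif = paste(motif, collapse = ""),
            d_min = d_min, ambiguity = amb, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(region = character(0), start = integer(0),
                      len = integer(0), motif = character(0),
                      d_min = integer(0), ambiguity = integer(0)))
  }
  do.call(rbind, out)
}

# monophyly / MRCA oracle by clade enumeration on a rooted tree
oracle_clade <- function(tree, tips) {
  parts <- ape::prop.part(tree)
  labels <- attr(parts, "labels")
  clades <- lapply(parts, function(p) labels[p])
  clades <- c(clades, as.list(tree$tip.label))
  containing <- Filter(function(cl) all(tips %in% cl), clades)
  sizes <- vapply(containing, length, integer(1))
  mrca_tips <- containing[[which.min(sizes)]]
  list(monophyletic = setequal(mrca_tips, tips),
       mrca_tips = sort(mrca_tips))
}

# single-linkage threshold components via hclust as independent route
oracle_components <- function(D, threshold) {
  if (nrow(D) == 1L) return(1L)
  hc <- stats::hclust(stats::as.dist(D), method = "single")
  length(unique(stats::cutree(hc, h = threshold)))
}

# -- toy builders -------------------------------------------------------------

toy_aln <- function(seqs, species = NULL, genus = NULL, regions = NULL) {
  ids <- names(seqs)
  if (is.null(species)) species <- ids
  if (is.null(genus)) genus <- rep("GenusA", length(ids))
  width <- nchar(seqs[[1]])
  if (is.null(regions)) {
    regions <- data.frame(region = "ITS2", start = 1L, end = width)
  }
  taxonomy <- data.frame(id = ids, phylum = "Phy", class = "Cls",
                         order = "Ord", family = "Fam", genus = genus,
                         species = species,
                         roles = "", stringsAsFactors = FALSE)
  annotated_alignment(seqs, taxonomy, regions)
}

random_aln <- function(n_seq, width, n_species = NULL, gap_rate = 0.05,
                       amb_rate = 0.05, regions = NULL) {
  if (is.null(n_species)) n_species <- max(2L, n_seq %/% 2L)
  alphabet <- c("a", "c", "g", "t")
  degenerate <- c("m", "r", "w", "s", "y", "k", "v", "h", "d", "b", "n")
  seqs <- vapply(seq_len(n_seq), function(i) {
    x <- sample(alphabet, width, replace = TRUE)
    gaps <- runif(width) < gap_rate
    x[gaps] <- "-"
    amb <- runif(width) < amb_rate & !gaps
    x[amb] <- sample(degenerate, sum(amb), replace = TRUE)
    paste(x, collapse = "")
  }, "")
  names(seqs) <- sprintf("seq%02d", seq_len(n_seq))
  species <- sprintf("sp%02d", rep_len(seq_len(n_species), n_seq))
  toy_aln(seqs, species = species, regions = regions)
}

write_toy_inputs <- function(aln, dir = withr::local_tempdir(
                               .local_envir = parent.frame())) {
  paths <- list(fasta = file.path(dir, "aln.fasta"),
                taxonomy = file.path(dir, "taxonomy.tsv"),
                regions = file.path(dir, "regions.tsv"))
  write_alignment_fasta(aln, paths$fasta, paths$taxonomy, paths$regions)
  paths
}
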