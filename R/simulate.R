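# Synthetic rRNA-operon alignments with known truth: nested lineages with
# controlled inter- and intraspecific divergence, IUPAC ambiguity recoding,
# indels realized as shared gap columns, homopolymer/microsatellite length
# noise, and planted diagnostic signatures. A statistical stand-in for
# environmental long reads: distances and signature structure are
# controlled, but no sequencing-platform error profile or chimera formation
# is modelled.

#' Configuration for the synthetic taxon-set generator
#'
#' Defaults emulate the divergence regime of species-level barcode-gap
#' analyses in environmental rRNA data: interspecific p-distances of at
#' least 10\% against intraspecific variation capped at 2\%, sparse IUPAC
#' ambiguities, and repeat-length polymorphism in the ITS.
#'
#' @param seed Integer RNG seed; the whole simulation is deterministic in it.
#' @param n_species Number of species.
#' @param reads_per_species Length-2 integer range; the per-species read
#'   count is drawn uniformly from it.
#' @param region_lengths Named vector of region widths in bases.
#' @param d_inter Target minimum interspecific p-distance per region.
#' @param d_intra_max Per-species maximum intraspecific p-distance cap.
#' @param ambiguity_rate Fraction of read sites recoded to a 2-base
#'   degenerate symbol containing the original base.
#' @param indel_rate Per-column probability of a shared indel (a random
#'   subset of species gapped at that column).
#' @param repeat_noise Add homopolymer (>= 6 nt) and dinucleotide-repeat
#'   (>= 4 units) loci in ITS1/ITS2 with per-read length changes of 1-3
#'   units, realized as gaps.
#' @param planted List of planted diagnostic signatures, each a list with
#'   \code{taxon} (species name, e.g. \code{"Species_01"}), \code{region},
#'   \code{len} (motif length >= 8), \code{k} (guaranteed minimum
#'   non-target mismatches).
#' @param n_genera Number of genera the species are nested into
#'   (default: about one genus per three species).
#' @return A \code{synthetic_config} list.
#' @export
synthetic_config <- function(seed = 1L, n_species = 6L,
                             reads_per_species = c(3L, 6L),
                             region_lengths = c(SSU = 1700L, ITS1 = 250L,
                                                "5.8S" = 160L, ITS2 = 300L,
                                                LSU = 1400L),
                             d_inter = 0.10, d_intra_max = 0.02,
                             ambiguity_rate = 0.005, indel_rate = 0.002,
                             repeat_noise = TRUE, planted = list(),
                             n_genera = NULL) {
  if (n_species < 1L) stop("n_species must be >= 1")
  if (length(reads_per_species) != 2L ||
      any(reads_per_species < 1L) ||
      reads_per_species[1L] > reads_per_species[2L]) {
    stop("reads_per_species must be a valid count range")
  }
  if (!(d_intra_max >= 0 && d_intra_max < d_inter && d_inter <= 1)) {
    stop("need 0 <= d_intra_max < d_inter <= 1")
  }
  for (r in c(ambiguity_rate, indel_rate)) {
    if (r < 0 || r > 1) stop("rates must be in [0,1]")
  }
  for (p in planted) {
    if (!all(c("taxon", "region", "len", "k") %in% names(p))) {
      stop("planted entries need taxon, region, len, k")
    }
    if (p$len < 8L) stop("planted motif length must be >= 8")
    if (!p$region %in% names(region_lengths)) {
      stop("planted region not in region_lengths: ", p$region)
    }
  }
  if (is.null(n_genera)) n_genera <- max(1L, ceiling(n_species / 3L))
  structure(list(seed = as.integer(seed), n_species = as.integer(n_species),
                 reads_per_species = as.integer(reads_per_species),
                 region_lengths = region_lengths, d_inter = d_inter,
                 d_intra_max = d_intra_max, ambiguity_rate = ambiguity_rate,
                 indel_rate = indel_rate, repeat_noise = isTRUE(repeat_noise),
                 planted = planted, n_genera = as.integer(n_genera)),
            class = "synthetic_config")
}

#' Jukes-Cantor-style site substitution
#'
#' Each site is independently substituted, with probability \code{p_sub}, to
#' a uniformly chosen different base. Uses the current RNG state.
#'
#' @param seq A string over \code{acgt}.
#' @param p_sub Substitution probability per site, in [0,1].
#' @return The mutated string.
#' @export
mutate_sequence <- function(seq, p_sub) {
  if (p_sub < 0 || p_sub > 1) stop("p_sub must be in [0,1]")
  codes <- encode_seq(tolower(seq))
  if (!all(codes %in% c(1L, 2L, 4L, 8L))) {
    stop("mutate_sequence expects a pure base string")
  }
  decode_seq(mutate_codes(codes, p_sub))
}

# base-code vector (1/2/4/8) mutation; vectorised
mutate_codes <- function(codes, p_sub) {
  n <- length(codes)
  hit <- which(stats::runif(n) < p_sub)
  if (length(hit)) {
    idx <- match(codes[hit], c(1L, 2L, 4L, 8L))
    new_idx <- (idx + sample.int(3L, length(hit), replace = TRUE) - 1L) %% 4L + 1L
    codes[hit] <- c(1L, 2L, 4L, 8L)[new_idx]
  }
  codes
}

# per-region mismatch proportions between two pure-base code vectors
region_mismatch <- function(a, b, reg_id, reg_len) {
  as.numeric(rowsum(as.numeric(a != b), reg_id)) / reg_len
}

#' Simulate an annotated taxon set with known truth
#'
#' Species ancestors are drawn by mutating a shared root sequence under
#' rejection until every interspecific pair differs by at least
#' \code{d_inter} (plus an intraspecific allowance) in every region; reads
#' are mutated from their species ancestor under rejection so that all
#' intraspecific pairs stay within \code{d_intra_max} per region. Ambiguity
#' recoding, shared-gap-column indels, repeat-length noise, and planted
#' signatures are then applied in that order (planting last, so target
#' reads carry the motif exactly).
#'
#' @param config A \code{\link{synthetic_config}}.
#' @return List with \code{alignment} (an
#'   \code{\link{annotated_alignment}}) and \code{truth}: the species tree
#'   (\code{ape::phylo} from average-linkage clustering of ancestor
#'   distances), planted signature locations and motifs, realized
#'   per-species/per-region maximum intraspecific distances, and realized
#'   minimum interspecific distance per region.
#' @export
simulate_taxon_set <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  rl <- config$region_lengths
  width <- sum(rl)
  reg_id <- rep(seq_along(rl), rl)
  reg_start <- cumsum(c(1L, utils::head(rl, -1L)))
  names(reg_start) <- names(rl)
  bases <- c(1L, 2L, 4L, 8L)

  if (config$d_inter + config$d_intra_max > 0.75) {
    stop("cannot achieve divergence: d_inter beyond substitution saturation")
  }

  # root, with optional repeat loci planted in ITS1/ITS2
  root <- sample(bases, width, replace = TRUE)
  repeat_loci <- list()
  if (config$repeat_noise) {
    for (rg in intersect(c("ITS1", "ITS2"), names(rl))) {
      offs <- reg_start[[rg]]
      w <- rl[[rg]]
      # two homopolymers and two dinucleotide repeats per ITS region
      spots <- offs + sort(sample.int(w - 16L, 4L)) - 1L
      for (i in seq_along(spots)) {
        if (i <= 2L) {
          len <- sample(6:9, 1L)
          unit <- 1L
          root[spots[i]:(spots[i] + len - 1L)] <- sample(bases, 1L)
        } else {
          units <- sample(4:6, 1L)
          unit <- 2L
          len <- units * 2L
          duo <- sample(bases, 2L, replace = FALSE)
          root[spots[i]:(spots[i] + len - 1L)] <- rep(duo, units)
        }
        repeat_loci[[length(repeat_loci) + 1L]] <-
          list(start = spots[i], len = len, unit = unit)
      }
    }
  }

  # species ancestors under pairwise divergence rejection
  need <- config$d_inter + config$d_intra_max
  anc <- matrix(0L, config$n_species, width)
  for (i in seq_len(config$n_species)) {
    ok <- FALSE
    for (attempt in seq_len(1000L)) {
      cand <- mutate_codes(root, config$d_inter)
      ok <- TRUE
      if (i > 1L) {
        for (j in seq_len(i - 1L)) {
          if (any(region_mismatch(cand, anc[j, ], reg_id, rl) < need)) {
            ok <- FALSE
            break
          }
        }
      }
      if (ok) break
    }
    if (!ok) stop("cannot achieve divergence: interspecific rejection failed")
    anc[i, ] <- cand
  }

  # reads per species under intraspecific cap rejection
  n_reads <- sample(seq.int(config$reads_per_species[1L],
                            config$reads_per_species[2L]),
                    config$n_species, replace = TRUE)
  total <- sum(n_reads)
  M <- matrix(0L, total, width)
  species_of <- integer(total)
  row <- 0L
  p_read <- config$d_intra_max / 4
  # each read is kept within 0.4 * d_intra_max of its ancestor per region, so
  # any read pair is within 0.8 * d_intra_max by the triangle inequality; the
  # remaining 20% headroom absorbs denominator shrinkage when gap noise later
  # removes comparable sites (at most ~15-25% in repeat-bearing ITS regions)
  read_cap <- 0.4 * config$d_intra_max
  for (i in seq_len(config$n_species)) {
    for (r in seq_len(n_reads[i])) {
      ok <- FALSE
      for (attempt in seq_len(1000L)) {
        cand <- mutate_codes(anc[i, ], p_read)
        if (all(region_mismatch(cand, anc[i, ], reg_id, rl) <= read_cap)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("cannot achieve divergence: intraspecific cap infeasible")
      row <- row + 1L
      M[row, ] <- cand
      species_of[row] <- i
    }
  }

  # ambiguity recoding: base -> 2-base degenerate code containing it
  if (config$ambiguity_rate > 0) {
    hits <- which(matrix(stats::runif(length(M)) < config$ambiguity_rate,
                         nrow(M)))
    if (length(hits)) {
      other_idx <- match(M[hits], bases)
      shift <- sample.int(3L, length(hits), replace = TRUE)
      other <- bases[(other_idx + shift - 1L) %% 4L + 1L]
      M[hits] <- bitwOr(M[hits], other)
    }
  }

  # indels: shared gap columns over a random species subset
  if (config$indel_rate > 0) {
    indel_cols <- which(stats::runif(width) < config$indel_rate)
    for (cc in indel_cols) {
      hit_sp <- which(stats::runif(config$n_species) < 0.5)
      if (length(hit_sp) == 0L || length(hit_sp) == config$n_species) next
      M[species_of %in% hit_sp, cc] <- 0L
    }
  }

  # repeat-length noise: per-read deletion of 1-3 units at each locus
  if (length(repeat_loci)) {
    for (loc in repeat_loci) {
      for (q in seq_len(total)) {
        if (stats::runif(1L) < 0.6) {
          d_units <- sample.int(3L, 1L)
          n_del <- min(d_units * loc$unit, loc$len - loc$unit)
          M[q, (loc$start + loc$len - n_del):(loc$start + loc$len - 1L)] <- 0L
        }
      }
    }
  }

  species_names <- sprintf("Species_%02d", seq_len(config$n_species))

  # planted signatures (last, so targets carry the motif exactly)
  planted_truth <- list()
  for (p in config$planted) {
    sp_i <- match(p$taxon, species_names)
    if (is.na(sp_i)) stop("planted taxon not among species: ", p$taxon)
    offs <- reg_start[[p$region]]
    w <- rl[[p$region]]
    if (p$len > w) stop("planted motif longer than region ", p$region)
    start <- offs + sample.int(w - p$len + 1L, 1L) - 1L
    win <- start:(start + p$len - 1L)
    motif_codes <- sample(bases, p$len, replace = TRUE)
    M[species_of == sp_i, win] <- rep(motif_codes, each = sum(species_of == sp_i))
    non_target <- which(species_of != sp_i)
    for (q in non_target) {
      mism <- which(bitwAnd(M[q, win], motif_codes) == 0L)
      deficit <- p$k - length(mism)
      if (deficit > 0L) {
        matchpos <- setdiff(seq_len(p$len), mism)
        force_at <- sample(matchpos, deficit)
        idx <- match(motif_codes[force_at], bases)
        M[q, win[force_at]] <-
          bases[(idx + sample.int(3L, deficit, replace = TRUE) - 1L) %% 4L + 1L]
      }
    }
    planted_truth[[length(planted_truth) + 1L]] <-
      list(taxon = p$taxon, region = p$region,
           columns = c(start, start + p$len - 1L),
           motif = decode_seq(motif_codes), k = p$k)
  }

  # assemble the annotated alignment
  read_index <- as.integer(stats::ave(species_of, species_of,
                                      FUN = seq_along))
  read_ids <- sprintf("%s_r%02d", species_names[species_of], read_index)
  seqs <- stats::setNames(apply(M, 1L, decode_seq), read_ids)
  genus_of <- sort(rep_len(seq_len(config$n_genera), config$n_species))
  taxonomy <- data.frame(
    id = read_ids,
    phylum = "Simulomycota", class = "Simulomycetes", order = "Simulales",
    family = sprintf("Simulaceae_%02d", genus_of[species_of]),
    genus = sprintf("Genus_%02d", genus_of[species_of]),
    species = species_names[species_of],
    roles = ifelse(read_index == 1L, "legitype", ""),
    stringsAsFactors = FALSE
  )
  regions <- data.frame(region = names(rl), start = reg_start,
                        end = reg_start + rl - 1L,
                        stringsAsFactors = FALSE)
  aln <- annotated_alignment(seqs, taxonomy, regions)

  # realized distance summaries and species tree
  policy <- distance_policy()
  realized_intra <- matrix(NA_real_, config$n_species, length(rl),
                           dimnames = list(species_names, names(rl)))
  for (i in seq_len(config$n_species)) {
    ids <- read_ids[species_of == i]
    for (rg in names(rl)) {
      if (length(ids) < 2L) {
        realized_intra[i, rg] <- 0
      } else {
        D <- pairwise_p_distances(aln, ids, region_columns(aln, rg), policy)
        realized_intra[i, rg] <- max(D[upper.tri(D)], na.rm = TRUE)
      }
    }
  }
  realized_min_inter <- stats::setNames(rep(NA_real_, length(rl)), names(rl))
  if (config$n_species > 1L) {
    for (rg in names(rl)) {
      cols <- region_columns(aln, rg)
      D <- pairwise_p_distances(aln, read_ids, cols, policy)
      inter <- D[outer(species_of, species_of, "!=")]
      realized_min_inter[rg] <- min(inter, na.rm = TRUE)
    }
  }
  tree <- NULL
  if (config$n_species > 1L) {
    AD <- matrix(0, config$n_species, config$n_species,
                 dimnames = list(species_names, species_names))
    for (i in seq_len(config$n_species - 1L)) {
      for (j in seq.int(i + 1L, config$n_species)) {
        AD[i, j] <- AD[j, i] <- mean(anc[i, ] != anc[j, ])
      }
    }
    tree <- ape::as.phylo(stats::hclust(stats::as.dist(AD),
                                        method = "average"))
  }

  truth <- list(config = config, tree = tree, planted = planted_truth,
                realized_max_intra = realized_intra,
                realized_min_inter = realized_min_inter,
                species = stats::setNames(species_names[species_of],
                                          read_ids))
  list(alignment = aln, truth = truth)
}
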