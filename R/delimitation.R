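# Tree-side taxon-delimitation checks ("forms a monophyletic, least
# inclusive clade") and threshold clustering for species-richness
# estimation. Trees are ape "phylo" objects with ultrafast-bootstrap-style
# supports (0-100) on internal nodes; supports supplied on a 0-1 scale are
# rescaled on read.

#' Read a support-annotated Newick tree
#'
#' Internal node labels are interpreted as bootstrap supports. Supports on a
#' 0-1 scale (all values <= 1) are rescaled to 0-100.
#'
#' @param path Path to a Newick file.
#' @return An \code{ape::phylo} with numeric \code{node.label} supports.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("parse error: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("parse error: no tree in ", path)
  if (anyDuplicated(tree$tip.label)) {
    stop("ambiguous labels: duplicate tip '",
         tree$tip.label[duplicated(tree$tip.label)][1L], "'")
  }
  normalize_supports(tree)
}

normalize_supports <- function(tree) {
  if (is.null(tree$node.label)) return(tree)
  sup <- suppressWarnings(as.numeric(tree$node.label))
  known <- sup[!is.na(sup)]
  if (length(known) && all(known <= 1) && any(known > 0)) sup <- sup * 100
  if (length(known) && (any(known < 0) || any(sup > 100, na.rm = TRUE))) {
    stop("support values outside [0,100] after normalization")
  }
  tree$node.label <- as.character(sup)
  tree
}

#' Least-inclusive-clade test for a tip set
#'
#' Finds the most recent common ancestor (MRCA) of the query tips and
#' reports the leaves under it, whether the query set is monophyletic
#' (MRCA leaf set equals the query set), and the MRCA's bootstrap support.
#' Unrooted trees must be rooted by naming an outgroup tip.
#'
#' @param tree An \code{ape::phylo} (e.g. from \code{\link{read_newick}}).
#' @param tips Character vector of query tip labels.
#' @param outgroup Outgroup tip label, required when \code{tree} is
#'   unrooted.
#' @return A \code{clade_test} list with \code{tips}, \code{monophyletic},
#'   \code{mrca_tips}, \code{support} (\code{NA} at the root or when
#'   unlabelled), \code{passes_support} (support strictly > 95).
#' @export
least_inclusive_clade <- function(tree, tips, outgroup = NULL) {
  tips <- unique(as.character(tips))
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown)) stop("tip not in tree: ", unknown[[1L]])
  if (!ape::is.rooted(tree)) {
    if (is.null(outgroup)) stop("rooting required: unrooted tree needs an outgroup")
    if (!outgroup %in% tree$tip.label) stop("tip not in tree: ", outgroup)
    tree <- normalize_supports(
      ape::root(tree, outgroup = outgroup, resolve.root = TRUE))
  }
  ntip <- length(tree$tip.label)
  if (length(tips) == ntip) {
    sup <- NA_real_
    res <- list(tips = tips, monophyletic = TRUE,
                mrca_tips = sort(tree$tip.label), support = sup,
                passes_support = FALSE)
    class(res) <- "clade_test"
    return(res)
  }
  if (length(tips) == 1L) {
    res <- list(tips = tips, monophyletic = TRUE, mrca_tips = tips,
                support = NA_real_, passes_support = FALSE)
    class(res) <- "clade_test"
    return(res)
  }
  node <- ape::getMRCA(tree, tips)
  clade <- ape::extract.clade(tree, node)$tip.label
  sup <- NA_real_
  root_node <- ntip + 1L
  if (!is.null(tree$node.label) && node != root_node) {
    sup <- suppressWarnings(as.numeric(tree$node.label[node - ntip]))
  }
  res <- list(tips = tips,
              monophyletic = setequal(clade, tips),
              mrca_tips = sort(clade),
              support = sup,
              passes_support = !is.na(sup) && sup > 95)
  class(res) <- "clade_test"
  res
}

#' @export
print.clade_test <- function(x, ...) {
  cat(sprintf("clade_test: %d query tips; monophyletic=%s; support=%s\n",
              length(x$tips), x$monophyletic,
              ifelse(is.na(x$support), "NA", format(x$support))))
  invisible(x)
}

#' Higher-taxon delimitation criteria
#'
#' A tip set passes when it is monophyletic AND its clade support strictly
#' exceeds \code{min_support} (default 95; the inequality is strict, so a
#' support of exactly 95 fails).
#'
#' @inheritParams least_inclusive_clade
#' @param min_support Support threshold (strict).
#' @return List with \code{pass}, \code{monophyletic}, \code{support},
#'   \code{failed} (character vector naming failed criteria, among
#'   \code{"monophyly"} and \code{"support"}).
#' @export
check_taxon_criteria <- function(tree, tips, min_support = 95,
                                 outgroup = NULL) {
  ct <- least_inclusive_clade(tree, tips, outgroup)
  failed <- character(0)
  if (!ct$monophyletic) failed <- c(failed, "monophyly")
  sup_ok <- !is.na(ct$support) && ct$support > min_support
  if (!sup_ok) failed <- c(failed, "support")
  list(pass = length(failed) == 0L, monophyletic = ct$monophyletic,
       support = ct$support, failed = failed)
}

#' Single-linkage threshold clustering of sequences
#'
#' Clusters are the connected components of the graph joining every pair at
#' distance <= threshold (single linkage, OTU-style); richness is the
#' component count. \code{NA} distances join nothing.
#'
#' @param D Symmetric numeric matrix with zero diagonal; dimnames give ids.
#' @param threshold Distance threshold in [0,1].
#' @return A \code{cluster_result} list with \code{threshold},
#'   \code{membership} (named integer vector, clusters numbered by first
#'   appearance), \code{clusters} (list of id vectors), \code{richness}.
#' @export
cluster_species <- function(D, threshold) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) ||
      !isTRUE(all.equal(D, t(D), tolerance = 1e-12)) ||
      any(diag(D) != 0)) {
    stop("invalid distances: matrix must be symmetric with zero diagonal")
  }
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0,1]")
  n <- nrow(D)
  ids <- rownames(D)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  # union-find over pairs within threshold
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in seq_len(max(0L, n - 1L))) {
    for (j in seq.int(i + 1L, n)) {
      if (!is.na(D[i, j]) && D[i, j] <= threshold) {
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1L))
  membership <- match(roots, unique(roots))
  names(membership) <- ids
  res <- list(threshold = threshold, membership = membership,
              clusters = split(ids, membership),
              richness = length(unique(membership)))
  class(res) <- "cluster_result"
  res
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d sequences -> %d clusters at threshold %g\n",
              length(x$membership), x$richness, x$threshold))
  invisible(x)
}

#' Species-richness estimate from an alignment region
#'
#' Computes pairwise p-distances over one region and clusters at a
#' threshold. With \code{threshold = "auto"} the threshold is the maximum
#' intraspecific distance of a designated type species — the convention of
#' calibrating clustering on the type species' observed ITS variability.
#'
#' @param aln An \code{annotated_alignment}.
#' @param region Region name (default \code{"ITS2"}).
#' @param threshold Numeric in [0,1], or \code{"auto"} (requires
#'   \code{type_species}).
#' @param type_species Species name used for the auto threshold.
#' @param policy A \code{\link{distance_policy}}.
#' @param ids Optional subset of sequence ids to cluster.
#' @return A \code{cluster_result} (see \code{\link{cluster_species}}),
#'   with the resolved threshold.
#' @export
estimate_richness <- function(aln, region = "ITS2", threshold = "auto",
                              type_species = NULL,
                              policy = distance_policy(),
                              ids = rownames(aln$enc)) {
  if (identical(threshold, "auto")) {
    if (is.null(type_species)) {
      stop("threshold='auto' needs a type_species")
    }
    threshold <- max_intraspecific(aln, type_species, region, policy,
                                   rank = "species")$max_intra
  }
  cols <- region_columns(aln, region)
  D <- pairwise_p_distances(aln, ids, cols, policy)
  cluster_species(D, threshold)
}
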