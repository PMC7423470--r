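#' Read a phylogeny from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the contract the rest
#' of the package relies on: a rooted tree with branch lengths and unique tip
#' labels.
#'
#' @param path Path to a Newick file.
#' @return An [ape::phylo] object.
#' @seealso [write_newick()]
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)),
                   error = function(e) NULL)
  if (is.null(tree)) stop("could not parse Newick in ", path)
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  validate_tree(tree)
  tree
}

#' Write a phylogeny to a Newick file
#'
#' @param tree An [ape::phylo] object with branch lengths.
#' @param path Output path.
#' @param digits Number of significant digits for branch lengths. The default
#'   preserves lengths well below the package's 1e-9 round-trip tolerance.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path, digits = 15) {
  validate_tree(tree)
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}

# Shared contract checks for every tree entering the package.
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0)) {
    stop("tree has missing or negative branch lengths")
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  invisible(tree)
}

#' Root-to-tip depths of an ultrametric tree
#'
#' @param tree An [ape::phylo] object.
#' @return Named numeric vector of root-to-tip path lengths.
#' @keywords internal
tip_depths <- function(tree) {
  nt <- ape::Ntip(tree)
  d <- ape::node.depth.edgelength(tree)[seq_len(nt)]
  names(d) <- tree$tip.label
  d
}

is_ultrametric_strict <- function(tree, tol = 1e-6) {
  d <- tip_depths(tree)
  diff(range(d)) <= tol * max(d)
}

# Genus component of a "Genus_species" label.
genus_of <- function(labels) sub("_.*$", "", labels)

#' Insert missing species next to their congeners
#'
#' Adds each species in `species` that is absent from `tree` as a new tip
#' attached within its genus, mirroring the standard congeneric-polytomy
#' approach for placing taxa that a backbone phylogeny lacks. A species with
#' two or more congeners is attached at the crown node (MRCA) of those
#' congeners, with pendant branch length equal to that node's height, so the
#' tree stays ultrametric. A species whose genus has a single member in the
#' tree is attached at the midpoint of that congener's pendant edge with a
#' matching pendant length. Species with no congeners cannot be placed; they
#' are reported, never silently dropped.
#'
#' @param tree An ultrametric [ape::phylo] with `Genus_species` tip labels.
#' @param species Character vector of `Genus_species` names to ensure present.
#' @return A list with elements `tree` (the augmented phylogeny) and
#'   `unplaced` (character vector of species that had no congener in the
#'   tree).
#' @export
congeneric_merge <- function(tree, species) {
  validate_tree(tree)
  unplaced <- character(0)
  for (sp in unique(species)) {
    if (sp %in% tree$tip.label) next
    cong <- tree$tip.label[genus_of(tree$tip.label) == genus_of(sp)]
    if (length(cong) == 0) {
      unplaced <- c(unplaced, sp)
      next
    }
    depth <- max(tip_depths(tree))
    if (length(cong) >= 2) {
      node <- ape::getMRCA(tree, cong)
      node_height <- depth - ape::node.depth.edgelength(tree)[node]
      tree <- phytools::bind.tip(tree, sp, edge.length = node_height,
                                 where = node, position = 0)
    } else {
      tip <- match(cong, tree$tip.label)
      pend <- tree$edge.length[tree$edge[, 2] == tip]
      tree <- phytools::bind.tip(tree, sp, edge.length = pend / 2,
                                 where = tip, position = pend / 2)
    }
  }
  list(tree = tree, unplaced = unplaced)
}

#' Prune a phylogeny to a species set
#'
#' Drops all tips outside `species`. Pairwise cophenetic distances among the
#' retained species are unchanged by pruning.
#'
#' @param tree An [ape::phylo] object.
#' @param species Character vector of tip labels to keep (at least 2).
#' @return The pruned [ape::phylo].
#' @export
prune_to <- function(tree, species) {
  validate_tree(tree)
  species <- unique(species)
  missing <- setdiff(species, tree$tip.label)
  if (length(missing) > 0) {
    stop("species not in tree: ", paste(missing, collapse = ", "))
  }
  if (length(species) < 2) {
    stop("cannot prune to fewer than 2 species (pairwise distances undefined)")
  }
  ape::keep.tip(tree, species)
}

#' Cophenetic (patristic) distance matrix
#'
#' Tip-to-tip path lengths on the tree, optionally element-wise
#' square-root transformed. The square-root transform puts time-calibrated
#' phylogenetic distances on a scale comparable with trait distances before
#' they are combined.
#'
#' @param tree An [ape::phylo] with at least 2 tips.
#' @param transform `"raw"` or `"sqrt"`.
#' @return A symmetric numeric matrix with species dimnames and attribute
#'   `transform` recording the state.
#' @export
cophenetic_matrix <- function(tree, transform = c("raw", "sqrt")) {
  transform <- match.arg(transform)
  validate_tree(tree)
  if (ape::Ntip(tree) < 2) stop("need >= 2 tips")
  D <- ape::cophenetic.phylo(tree)
  D <- D[order(rownames(D)), order(colnames(D)), drop = FALSE]
  if (transform == "sqrt") D <- sqrt(D)
  attr(D, "transform") <- transform
  D
}

#' Focal-species distinctiveness within a community
#'
#' Distance-based distinctiveness of one focal species relative to a set of
#' co-occurring species: mean pairwise distance (`MPD`), nearest-neighbour
#' distance (`NND`), or their abundance-weighted analogues (`AW_MPD`,
#' `AW_NND`). `AW_MPD` is the cover-weighted mean of focal-to-member
#' distances (weights normalised to sum to 1). A minimum cannot be
#' re-weighted without an arbitrary rule, so `AW_NND` is the
#' nearest-neighbour distance restricted to the members that have recorded
#' cover; this choice is exposed rather than hidden.
#'
#' @param D Distance matrix from [cophenetic_matrix()], [gower_distance()] or
#'   [combine_fpd()].
#' @param focal Focal species name (must not be in `community`).
#' @param community Character vector of co-occurring species.
#' @param weights Optional positive cover values, parallel to `community`.
#'   `NA` marks a member present without recorded cover: it is used by the
#'   unweighted metrics and skipped by the abundance-weighted ones.
#' @param metric One of `"MPD"`, `"NND"`, `"AW_MPD"`, `"AW_NND"`.
#' @return A single non-negative number.
#' @export
focal_distinctiveness <- function(D, focal, community, weights = NULL,
                                  metric = c("MPD", "NND", "AW_MPD",
                                             "AW_NND")) {
  metric <- match.arg(metric)
  if (length(community) == 0) stop("empty community")
  if (focal %in% community) stop("focal species must not be in its community")
  lab <- rownames(D)
  missing <- setdiff(c(focal, community), lab)
  if (length(missing) > 0) {
    stop("species absent from distance matrix: ",
         paste(missing, collapse = ", "))
  }
  d <- D[focal, community]
  if (metric %in% c("AW_MPD", "AW_NND")) {
    if (is.null(weights)) stop("abundance-weighted metric requires weights")
    if (length(weights) != length(community)) {
      stop("weights must align with community members")
    }
    keep <- !is.na(weights)
    if (!any(keep)) stop("no community member has recorded cover")
    if (any(weights[keep] <= 0)) stop("weights must be positive")
    d <- d[keep]
    w <- weights[keep] / sum(weights[keep])
  }
  switch(metric,
         MPD    = mean(d),
         NND    = min(d),
         AW_MPD = sum(w * d),
         AW_NND = min(d))
}

#' Richness-rarefied distinctiveness
#'
#' Removes the effect of community richness on a distinctiveness metric by
#' repeatedly subsampling the community to a fixed richness `k` and averaging
#' the metric over subsamples. The default `k = 11` matches rarefying every
#' community down to the richness of the most species-poor one.
#'
#' @inheritParams focal_distinctiveness
#' @param k Rarefied richness (subset size), default 11.
#' @param n_reps Number of subsamples, default 1000.
#' @param seed Integer seed for reproducible subsampling.
#' @return Mean of the metric over `n_reps` uniform without-replacement
#'   draws of `k` community members.
#' @export
rarefied_distinctiveness <- function(D, focal, community, k = 11,
                                     n_reps = 1000,
                                     metric = c("MPD", "NND", "AW_MPD",
                                                "AW_NND"),
                                     weights = NULL, seed = 1) {
  metric <- match.arg(metric)
  n <- length(community)
  if (n < k) stop("community has ", n, " members; need >= k = ", k)
  if (n == k) {
    return(focal_distinctiveness(D, focal, community, weights, metric))
  }
  set.seed(as.integer(seed))
  vals <- vapply(seq_len(n_reps), function(i) {
    idx <- sample.int(n, k)
    focal_distinctiveness(D, focal, community[idx], weights[idx], metric)
  }, numeric(1))
  mean(vals)
}
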