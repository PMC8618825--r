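#' Dated ladder phylogeny for gene-age dating
#'
#' A `species_ladder` indexes the branches of the focal lineage of a dated,
#' rooted phylogeny.  Walking from the root to the focal tip, every split
#' sheds one clade of non-focal species; a gene is dated onto the branch
#' (time interval) on which it originated, inferred from which of those
#' clades carry homologous sequence.  Branch `0` is older than the deepest
#' sampled split (genes shared with all sampled species); branch `B` is the
#' terminal branch of the focal species (species-specific genes).
#'
#' @param tree an [ape::phylo] object, rooted, with branch lengths in
#'   millions of years (Myr) and an ultrametric dated shape.
#' @param focal tip label of the focal species.
#' @return an object of class `species_ladder` with elements:
#'   \describe{
#'     \item{taxa}{all tip labels}
#'     \item{focal}{the focal tip label}
#'     \item{splits}{data.frame, one row per focal-path split ordered from
#'       deepest to shallowest: `age` (Myr) and `clade` (list column of the
#'       tip labels shed at that split)}
#'     \item{n_branches}{`B`, the index of the terminal focal branch; the
#'       ladder defines `B + 1` age classes `0..B`}
#'     \item{branch_duration}{numeric of length `B + 1`, Myr per branch;
#'       branch 0 predates the sampled root and has duration `NA`}
#'   }
#' @export
species_ladder <- function(tree, focal) {
  if (!inherits(tree, "phylo")) stop("'tree' must be an ape phylo object")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths (Myr)")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!focal %in% tree$tip.label) {
    stop("focal species '", focal, "' is not a tip of the tree")
  }
  ages <- ape::branching.times(tree)
  ntip <- length(tree$tip.label)
  focal_tip <- match(focal, tree$tip.label)

  ## walk root -> focal tip, collecting the clade shed at each split
  parent <- tree$edge[, 1]
  child <- tree$edge[, 2]
  path <- integer(0)
  node <- focal_tip
  while (TRUE) {
    e <- match(node, child)
    if (is.na(e)) break
    node <- parent[e]
    path <- c(node, path)           # root first
  }
  if (length(path) == 0L) stop("degenerate tree: focal tip has no ancestor")

  splits <- vector("list", length(path))
  split_age <- numeric(length(path))
  for (i in seq_along(path)) {
    nd <- path[i]
    kids <- child[parent == nd]
    if (length(kids) != 2L) {
      stop("focal path contains a polytomy at node ", nd,
           "; only strictly bifurcating (ladder) focal paths are supported")
    }
    on_path <- if (i < length(path)) path[i + 1L] else focal_tip
    off <- setdiff(kids, on_path)
    if (length(off) != 1L) stop("focal path is inconsistent at node ", nd)
    splits[[i]] <- sort(tip_labels_of(tree, off))
    split_age[i] <- unname(ages[as.character(nd)])
  }
  if (any(diff(split_age) >= 0)) {
    stop("node ages must strictly decrease toward the focal tip; ",
         "is the tree dated (ultrametric)?")
  }
  B <- length(path)
  dur <- c(NA_real_, -diff(c(split_age, 0)))
  stopifnot(length(dur) == B + 1L)
  structure(
    list(taxa = sort(tree$tip.label), focal = focal,
         splits = data.frame(age = split_age, clade = I(splits)),
         n_branches = B, branch_duration = dur, tree = tree),
    class = "species_ladder")
}

#' Read a dated ladder phylogeny from a newick file
#'
#' @param path newick file; branch lengths in Myr (dated, ultrametric).
#' @param focal focal species tip label.
#' @return a [species_ladder].
#' @export
read_ladder <- function(path, focal) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick file: ", path)
  species_ladder(tree, focal)
}

tip_labels_of <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  parent <- tree$edge[, 1]
  child <- tree$edge[, 2]
  todo <- node
  tips <- integer(0)
  while (length(todo)) {
    kids <- child[parent %in% todo]
    tips <- c(tips, kids[kids <= ntip])
    todo <- kids[kids > ntip]
  }
  tree$tip.label[tips]
}

#' @export
print.species_ladder <- function(x, ...) {
  cat("species_ladder: ", length(x$taxa), " taxa, focal = ", x$focal,
      ", branches 0-", x$n_branches, "\n", sep = "")
  for (i in seq_len(nrow(x$splits))) {
    cat(sprintf("  split %d: %.1f Myr -> {%s}\n", i, x$splits$age[i],
                paste(x$splits$clade[[i]], collapse = ", ")))
  }
  invisible(x)
}

#' Default dated ladder used throughout the package
#'
#' An 8-taxon ladder mirroring a flatfish-like sampling design: the focal
#' species and its sister split 41.8 Myr ago, two further single-species
#' splits on the focal path, then two outgroup cherries; the split to the
#' nearer outgroup cherry is 73.7 Myr.  Ages of the unconstrained nodes are
#' round values chosen between those anchors.
#'
#' @param terminal_age age (Myr) of the focal--sister split.
#' @param lineage_age age (Myr) of the split to the nearest outgroup cherry,
#'   i.e. the stem age of the focal lineage.
#' @return a [species_ladder] with `n_branches = 5`.
#' @export
default_ladder <- function(terminal_age = 41.8, lineage_age = 73.7) {
  a5 <- terminal_age
  a4 <- terminal_age + 10.2   # focal-path split 4
  a3 <- terminal_age + 23.2   # focal-path split 3
  a2 <- lineage_age
  a1 <- lineage_age + 21.3    # sampled root
  c1 <- 30; c2 <- 35          # outgroup cherry ages
  nwk <- paste0(
    "(((((focal:", a5, ",sister:", a5, "):", a4 - a5,
    ",sp3:", a4, "):", a3 - a4,
    ",sp4:", a3, "):", a2 - a3,
    ",(out1:", c1, ",out2:", c1, "):", a2 - c1,
    "):", a1 - a2,
    ",(out3:", c2, ",out4:", c2, "):", a1 - c2, ");")
  species_ladder(ape::read.tree(text = nwk), focal = "focal")
}

#' Date a presence/absence pattern onto a ladder branch (Dollo parsimony)
#'
#' Under Dollo parsimony with a single gain and no-loss interpretation of
#' absence, a character present in the focal species originated on the
#' branch leading to the most recent common ancestor of the species that
#' carry it.  Presence in either member of an off-path clade counts as
#' presence in that clade.
#'
#' @param presence named logical vector over `ladder$taxa` (or any subset
#'   naming all present species as `TRUE`).  Must include the focal species
#'   as present.
#' @param ladder a [species_ladder].
#' @return integer branch index in `0..B`.
#' @export
dollo_branch <- function(presence, ladder) {
  present <- names(presence)[as.logical(presence)]
  if (!ladder$focal %in% present) {
    stop("focal species must be present: every annotated focal gene ",
         "exists in the focal genome")
  }
  deepest <- NA_integer_
  for (i in seq_len(nrow(ladder$splits))) {
    if (any(ladder$splits$clade[[i]] %in% present)) { deepest <- i; break }
  }
  if (is.na(deepest)) ladder$n_branches else deepest - 1L
}
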