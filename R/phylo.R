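#' Read a phylogeny from a Newick file
#'
#' Thin validating wrapper around [ape::read.tree()].  The tree must carry
#' branch lengths on every edge and unique tip labels; unlabeled internal
#' nodes and polytomies are accepted.  A file lacking the terminating
#' semicolon is accepted with a warning.
#'
#' @param path path to a Newick file.
#' @return an [ape::phylo] object.
#' @export
read_newick <- function(path) {
  stopifnot(file.exists(path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  txt <- trimws(txt)
  if (!grepl(";\\s*$", txt)) {
    warning("Newick string lacks a terminating ';'; one was added", call. = FALSE)
    txt <- paste0(txt, ";")
  }
  no <- nchar(gsub("[^(]", "", txt)); nc <- nchar(gsub("[^)]", "", txt))
  if (no != nc)
    stop("malformed Newick: unbalanced parentheses (", no, " '(' vs ", nc,
         " ')') near character ", regexpr("\\)[^)]*$", txt)[1])
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) stop("Newick parse error: ",
                                            conditionMessage(e), call. = FALSE))
  if (is.null(tree)) stop("Newick parse error: unreadable tree string")
  validate_tree(tree)
  tree
}

validate_tree <- function(tree) {
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; they are required")
  if (anyNA(tree$edge.length)) {
    bad <- which(is.na(tree$edge.length))[1]
    stop("missing branch length on edge ", tree$edge[bad, 1], "->",
         tree$edge[bad, 2])
  }
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  if (!any(tree$edge.length > 0)) stop("all branch lengths are zero")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  invisible(tree)
}

#' Prune a phylogeny to a set of taxa
#'
#' Retains exactly the tips present in both the tree and `taxa`; path lengths
#' between retained tips are unchanged.  Species in `taxa` absent from the
#' tree are reported via the `dropped` attribute.
#'
#' @param tree an [ape::phylo] tree.
#' @param taxa character vector of tip names to keep.
#' @return the pruned tree, with attribute `dropped` listing requested taxa
#'   that were not in the tree.
#' @export
prune_to_taxa <- function(tree, taxa) {
  keep <- intersect(tree$tip.label, taxa)
  if (length(keep) < 2)
    stop("fewer than 2 requested taxa are present in the tree (",
         length(keep), " found)")
  dropped <- setdiff(taxa, keep)
  out <- ape::keep.tip(tree, keep)
  # keep the stem to the original root as a root edge, so root-to-tip depths
  # (hence the BM covariance) are unchanged by pruning
  mrca <- ape::getMRCA(tree, keep)
  stem <- ape::node.depth.edgelength(tree)[mrca] +
    (if (is.null(tree$root.edge)) 0 else tree$root.edge)
  if (stem > 0) out$root.edge <- stem
  attr(out, "dropped") <- dropped
  out
}

#' Brownian-motion covariance structure of a phylogeny
#'
#' Under Brownian motion the covariance of two tips is the length of their
#' shared root-to-MRCA path, and the variance of each tip is its root-to-tip
#' depth (the matrix diagonal).  The tree need not be ultrametric: unequal
#' depths are exactly what the depth-proportional GLS weights correct for.
#' Tips attached by zero-length terminal branches that duplicate another
#' tip's position receive a diagonal perturbation of 1e-8 times the maximum
#' depth so that the matrix stays invertible; the perturbation is below any
#' reported precision.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @return object of class `phylo_cov`: list with `taxa`, `V` (covariance
#'   matrix), and `depths` (root-to-tip distances).
#' @export
bm_covariance <- function(tree) {
  validate_tree(tree)
  V <- ape::vcv.phylo(tree)
  # a root edge is shared history of every tip
  if (isTRUE(tree$root.edge > 0)) V <- V + tree$root.edge
  depths <- diag(V)
  term <- match(seq_along(tree$tip.label), tree$edge[, 2])
  zero_tip <- tree$edge.length[term] == 0
  if (any(zero_tip)) {
    eps <- 1e-8 * max(depths)
    diag(V)[zero_tip] <- diag(V)[zero_tip] + eps
    depths <- diag(V)
  }
  structure(list(taxa = colnames(V), V = V, depths = depths),
            class = "phylo_cov")
}

#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies the off-diagonal elements of the Brownian-motion covariance by
#' `lambda`, leaving the diagonal untouched: `lambda = 0` removes the
#' phylogeny (independence), `lambda = 1` returns pure Brownian motion.  The
#' result is checked for positive semi-definiteness, which bounds the usable
#' `lambda` from above.
#'
#' @param cov a [bm_covariance()] result.
#' @param lambda non-negative scalar.
#' @return a transformed `phylo_cov`.
#' @export
pagel_transform <- function(cov, lambda) {
  stopifnot(inherits(cov, "phylo_cov"), length(lambda) == 1, lambda >= 0)
  V <- cov$V * lambda
  diag(V) <- diag(cov$V)
  ev_min <- min(eigen(V, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8 * sum(diag(V)))
    stop("lambda = ", lambda, " makes the covariance non-positive-semi-definite")
  structure(list(taxa = cov$taxa, V = V, depths = cov$depths),
            class = "phylo_cov")
}

# restrict a covariance to a taxon subset, preserving order of `taxa`
restrict_cov <- function(cov, taxa) {
  idx <- match(taxa, cov$taxa)
  if (anyNA(taxa) || anyNA(idx))
    stop("taxa not in covariance: ",
         paste(taxa[is.na(idx)], collapse = ", "))
  structure(list(taxa = taxa, V = cov$V[idx, idx, drop = FALSE],
                 depths = cov$depths[idx]),
            class = "phylo_cov")
}
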