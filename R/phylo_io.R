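#' Read a rooted phylogram
#'
#' Reads a newick tree whose branch lengths are expected substitutions per
#' site, and attaches the alignment length (sites) used to estimate it. Both
#' are needed downstream: branch length times alignment length gives the
#' expected substitution count per branch.
#'
#' @param path Newick file (or use `text`).
#' @param text Newick string instead of a file.
#' @param alignment_length Number of alignment sites (positive integer).
#' @return An `ape` `phylo` with attribute `alignment_length`, class
#'   `c("phylogram", "phylo")`.
#' @export
read_phylogram <- function(path = NULL, text = NULL, alignment_length) {
  stopifnot(is.numeric(alignment_length), alignment_length > 0)
  phy <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(phy)) stop("could not parse newick input", call. = FALSE)
  as_phylogram(phy, alignment_length)
}

#' Validate a phylo object as a phylogram
#' @param phy An `ape` `phylo`.
#' @inheritParams read_phylogram
#' @export
as_phylogram <- function(phy, alignment_length) {
  if (!ape::is.rooted(phy)) stop("tree must be rooted", call. = FALSE)
  if (is.null(phy$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  if (any(!is.finite(phy$edge.length)) || any(phy$edge.length < 0)) {
    stop("branch lengths must be finite and >= 0", call. = FALSE)
  }
  if (anyDuplicated(phy$tip.label)) stop("tip labels must be unique", call. = FALSE)
  attr(phy, "alignment_length") <- as.numeric(alignment_length)
  class(phy) <- unique(c("phylogram", class(phy)))
  phy
}

#' Write a phylogram to newick
#' @param phy A `phylo`/`phylogram`.
#' @param path Output newick path.
#' @export
write_phylogram <- function(phy, path) {
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Most recent common ancestor of a taxon pair
#'
#' Nodes are always addressed by an MRCA taxon pair rather than by internal
#' node index, so that re-reading a topology cannot silently shift a
#' calibration. Symmetric in its arguments.
#'
#' @param phy A `phylo`.
#' @param taxonA,taxonB Tip labels.
#' @return Internal node id (ape numbering). For `taxonA == taxonB`, the tip
#'   itself.
#' @export
mrca_node <- function(phy, taxonA, taxonB) {
  for (tx in c(taxonA, taxonB)) {
    if (!(tx %in% phy$tip.label)) {
      stop("taxon not in tree: ", tx, call. = FALSE)
    }
  }
  if (taxonA == taxonB) return(match(taxonA, phy$tip.label))
  ape::getMRCA(phy, c(taxonA, taxonB))
}

#' Node ages of an ultrametric tree
#'
#' @param phy Ultrametric `phylo` with edge lengths in MY.
#' @return Numeric vector of ages (MYA) indexed by node id (tips then
#'   internal nodes); tips are 0 up to numerical tolerance and are clamped
#'   to exactly 0.
#' @export
node_ages_from_tree <- function(phy) {
  depth <- ape::node.depth.edgelength(phy)
  root_age <- max(depth[seq_len(ape::Ntip(phy))])
  ages <- root_age - depth
  tol <- 1e-6 * max(root_age, 1)
  tip_ages <- ages[seq_len(ape::Ntip(phy))]
  if (any(abs(tip_ages) > tol)) {
    stop("tree is not ultrametric: tip age deviation ",
         signif(max(abs(tip_ages)), 3), call. = FALSE)
  }
  ages[seq_len(ape::Ntip(phy))] <- 0
  ages
}

#' Construct a chronogram object
#'
#' A chronogram couples a rooted topology with node ages in MYA (tips at 0)
#' and, optionally, per-branch substitution rates. Edge lengths of the
#' embedded tree are durations in MY.
#'
#' @param phy Rooted `phylo` (edge lengths ignored; rebuilt from `ages`).
#' @param ages Numeric vector of node ages (MYA) indexed by ape node id.
#' @param rates Optional per-edge rates (substitutions/site/MY), ordered as
#'   `phy$edge`.
#' @return Object of class `chronogram`: list with `phy` (edge lengths in
#'   MY), `ages`, `rates`.
#' @export
chronogram <- function(phy, ages, rates = NULL) {
  stopifnot(length(ages) == ape::Ntip(phy) + phy$Nnode)
  dur <- ages[phy$edge[, 1]] - ages[phy$edge[, 2]]
  if (any(dur < -1e-8 * max(ages))) {
    stop("parent younger than child: invalid ages", call. = FALSE)
  }
  phy$edge.length <- pmax(dur, 0)
  structure(list(phy = phy, ages = ages, rates = rates), class = "chronogram")
}

#' @export
print.chronogram <- function(x, ...) {
  n <- ape::Ntip(x$phy)
  cat("Chronogram:", n, "tips, root age",
      format(max(x$ages), digits = 6), "MYA\n")
  invisible(x)
}

#' Representative taxon pairs defining each internal node
#'
#' For each internal node, picks one descendant tip from each of its first
#' two child subtrees; the node is then recoverable as the MRCA of that
#' pair on any re-read of the topology.
#'
#' @param phy A rooted `phylo`.
#' @return Data frame with `node` (ape id), `node_label` (`"n<id>"`),
#'   `taxonA`, `taxonB`.
#' @export
node_definitions <- function(phy) {
  n <- ape::Ntip(phy)
  internal <- (n + 1):(n + phy$Nnode)
  first_tip <- function(node) {
    while (node > n) node <- phy$edge[which(phy$edge[, 1] == node)[1], 2]
    phy$tip.label[node]
  }
  defs <- lapply(internal, function(nd) {
    kids <- phy$edge[phy$edge[, 1] == nd, 2]
    data.frame(node = nd, node_label = paste0("n", nd),
               taxonA = first_tip(kids[1]), taxonB = first_tip(kids[2]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, defs)
}

#' Resolve node-definition rows to node ids on a tree
#'
#' @param phy A rooted `phylo`.
#' @param defs Data frame with columns `node_label`, `taxonA`, `taxonB`
#'   (e.g. read from a node-definitions CSV).
#' @return Named integer vector: node ids named by `node_label`.
#' @export
resolve_node_queries <- function(phy, defs) {
  ids <- vapply(seq_len(nrow(defs)), function(i) {
    mrca_node(phy, defs$taxonA[i], defs$taxonB[i])
  }, integer(1))
  stats::setNames(ids, defs$node_label)
}

#' Write a chronogram: newick plus a node-age sidecar table
#'
#' The newick carries node ages implicitly as edge lengths (MY); the sidecar
#' CSV makes each internal node's age explicit and addressable by an MRCA
#' taxon pair (`node_label`, `taxonA`, `taxonB`, `age`).
#'
#' @param chr A `chronogram`.
#' @param path Newick output path; the sidecar goes to `<path>.ages.csv`
#'   unless `sidecar` is given.
#' @param sidecar Optional sidecar CSV path.
#' @export
write_chronogram <- function(chr, path, sidecar = paste0(path, ".ages.csv")) {
  ape::write.tree(chr$phy, file = path)
  defs <- node_definitions(chr$phy)
  defs$age <- chr$ages[defs$node]
  utils::write.csv(defs[, c("node_label", "taxonA", "taxonB", "age")],
                   sidecar, row.names = FALSE)
  invisible(c(tree = path, sidecar = sidecar))
}

#' Read a chronogram written by [write_chronogram()]
#' @param path Newick path (edge lengths in MY, ultrametric).
#' @return A `chronogram` (rates unknown, `NULL`).
#' @export
read_chronogram <- function(path) {
  phy <- ape::read.tree(path)
  chronogram(phy, node_ages_from_tree(phy))
}
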