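# Dated host phylogeny: Newick parsing with node ages in Myr, split-age and
# monophyly queries, and the set of taxa actually surveyed for elements.

#' Read a dated host phylogeny
#'
#' Parses a Newick tree whose branch lengths are in Myr, checks that it is
#' ultrametric (all leaves at the present), and computes node ages as root
#' age minus root-to-node path length.
#'
#' @param x Newick text, a file path, or an `ape::phylo` object.
#' @param surveyed taxa screened for elements (defaults to all leaves);
#'   patchy-distribution logic is restricted to this set.
#' @param tol absolute tolerance (Myr) on leaf depth differences.
#' @return an object of class `dated_host_tree`: list with `phylo`, `ages`
#'   (Myr per node, named by node number) and `surveyed`.
#' @examples
#' h <- read_host_tree("(A:1,B:1);")
#' split_age(h, "A", "B")
#' @export
read_host_tree <- function(x, surveyed = NULL, tol = 0.05) {
  phy <- if (inherits(x, "phylo")) {
    x
  } else if (is.character(x) && length(x) == 1L && grepl("\\(", x)) {
    ape::read.tree(text = x)
  } else if (is.character(x) && length(x) == 1L && file.exists(x)) {
    ape::read.tree(x)
  } else {
    stop("cannot interpret host-tree input", call. = FALSE)
  }
  if (is.null(phy$edge.length)) stop("host tree must have branch lengths (Myr)", call. = FALSE)
  phy <- ape::collapse.singles(phy)
  depths <- ape::node.depth.edgelength(phy)
  ntip <- length(phy$tip.label)
  leaf_depth <- depths[seq_len(ntip)]
  root_age <- max(leaf_depth)
  # deviations are judged against the median leaf depth so that a single
  # perturbed leaf is the one reported
  bad <- which(abs(leaf_depth - stats::median(leaf_depth)) > tol)
  if (length(bad) > 0) {
    stop(sprintf("host tree is not ultrametric; offending leaves: %s",
                 paste(phy$tip.label[bad], collapse = ", ")), call. = FALSE)
  }
  ages <- root_age - depths
  ages[seq_len(ntip)] <- 0
  names(ages) <- as.character(seq_along(ages))
  surveyed <- surveyed %||% phy$tip.label
  missing <- setdiff(surveyed, phy$tip.label)
  if (length(missing) > 0) {
    stop("surveyed taxa not in tree: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(phylo = phy, ages = ages, surveyed = surveyed),
            class = "dated_host_tree")
}

#' @export
print.dated_host_tree <- function(x, ...) {
  ntip <- length(x$phylo$tip.label)
  cat(sprintf("dated host tree: %d taxa, root age %.1f Myr\n", ntip,
              max(x$ages)))
  cat("taxa:", paste(x$phylo$tip.label, collapse = ", "), "\n")
  invisible(x)
}

#' Split age (Myr) of two host taxa
#'
#' Age of the most recent common ancestor of two leaves; zero when the two
#' taxa are identical.
#'
#' @param host a `dated_host_tree`.
#' @param a,b leaf labels.
#' @return age in Myr.
#' @export
split_age <- function(host, a, b) {
  stopifnot(inherits(host, "dated_host_tree"))
  tips <- host$phylo$tip.label
  if (!a %in% tips || !b %in% tips) {
    stop("unknown taxon: ", paste(setdiff(c(a, b), tips), collapse = ", "), call. = FALSE)
  }
  if (a == b) return(0)
  mrca <- ape::getMRCA(host$phylo, c(a, b))
  unname(host$ages[as.character(mrca)])
}

#' Does a set of taxa form a clade on the host tree?
#'
#' TRUE iff the set equals the complete leaf set of some node (singletons
#' are trivially clades).
#'
#' @param host a `dated_host_tree` (or bare `phylo`).
#' @param taxa non-empty character vector of leaf labels.
#' @return logical flag.
#' @export
is_clade <- function(host, taxa) {
  phy <- if (inherits(host, "dated_host_tree")) host$phylo else host
  if (length(taxa) == 0) stop("empty taxon set", call. = FALSE)
  taxa <- unique(taxa)
  if (!all(taxa %in% phy$tip.label)) {
    stop("unknown taxon: ", paste(setdiff(taxa, phy$tip.label), collapse = ", "), call. = FALSE)
  }
  if (length(taxa) == 1L) return(TRUE)
  mrca <- ape::getMRCA(phy, taxa)
  clade_tips <- ape::extract.clade(phy, mrca)$tip.label
  setequal(clade_tips, taxa)
}

#' Table of internal node ages
#'
#' @param host a `dated_host_tree`.
#' @return data.frame with `node`, `age_myr` and the clade's leaf labels.
#' @export
host_ages_table <- function(host) {
  stopifnot(inherits(host, "dated_host_tree"))
  phy <- host$phylo
  ntip <- length(phy$tip.label)
  nodes <- seq.int(ntip + 1L, ntip + phy$Nnode)
  data.frame(
    node = nodes,
    age_myr = unname(host$ages[as.character(nodes)]),
    clade = vapply(nodes, function(n)
      paste(sort(ape::extract.clade(phy, n)$tip.label), collapse = "+"), "")
  )
}

#' Restrict a dated host tree to a subset of taxa
#' @noRd
restrict_host <- function(host, taxa) {
  phy <- ape::keep.tip(host$phylo, intersect(host$phylo$tip.label, taxa))
  read_host_tree(phy, surveyed = intersect(host$surveyed, phy$tip.label))
}
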