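# Element tree inference: neighbor-joining on the p-distance matrix,
# bootstrap support by alignment-column resampling, and a simple
# calibration-scaled ultrametric dating.  This is a deliberately light
# stand-in for full ML / Bayesian relaxed-clock inference: it supports
# event ordering and congruence tests, not publishable node ages.

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via `ape::nj`).  Negative branch
#' lengths, an occasional artifact of NJ on noisy distances, are clamped to
#' zero with a warning.
#'
#' @param dm a `pdist_matrix` or a symmetric numeric matrix with dimnames.
#' @return an object of class `element_tree`: list with `phylo`, `support`
#'   (`NULL` until bootstrapped), `ages` and `rate` (`NULL` until
#'   calibrated).
#' @export
neighbor_joining <- function(dm) {
  m <- if (inherits(dm, "pdist_matrix")) dm$d else as.matrix(dm)
  if (inherits(dm, "pdist_matrix") && NROW(dm$not_computed) > 0) {
    pairs <- paste(dm$not_computed[, 1], dm$not_computed[, 2], sep = "/")
    stop("distance matrix has not-computed pairs (", paste(pairs, collapse = ", "),
         "); exclude the affected elements before tree building", call. = FALSE)
  }
  if (nrow(m) < 3L) stop("need at least 3 labels for neighbor-joining", call. = FALSE)
  if (anyNA(m)) stop("distance matrix contains NA", call. = FALSE)
  phy <- ape::nj(m)
  if (any(phy$edge.length < 0)) {
    warning("negative NJ branch lengths clamped to 0")
    phy$edge.length[phy$edge.length < 0] <- 0
  }
  structure(list(phylo = phy, support = NULL, ages = NULL, rate = NULL),
            class = "element_tree")
}

#' @export
print.element_tree <- function(x, ...) {
  cat("element tree:", length(x$phylo$tip.label), "tips")
  if (!is.null(x$support)) cat(", bootstrap support attached")
  if (!is.null(x$ages)) cat(sprintf(", calibrated (rate %.3g subs/site/Myr)", x$rate))
  cat("\n")
  print(x$phylo)
  invisible(x)
}

#' Newick export of an element tree (support as internal node labels)
#'
#' @param x an `element_tree`.
#' @param file optional path; when `NULL` the Newick string is returned.
#' @return Newick string (invisibly when writing to file).
#' @export
write_element_tree <- function(x, file = NULL) {
  phy <- x$phylo
  if (!is.null(x$support)) phy$node.label <- round(x$support)
  txt <- ape::write.tree(phy)
  if (!is.null(file)) { writeLines(txt, file); return(invisible(txt)) }
  txt
}

#' Bootstrap support by alignment-column resampling
#'
#' Resamples alignment columns with replacement, rebuilds a
#' neighbor-joining tree per replicate, and scores each internal edge of
#' the reference tree by the percentage of replicates containing its
#' bipartition.  Reproducible for a fixed seed.
#'
#' @param alignment alignment accepted by [as_alignment_matrix()].
#' @param n_reps bootstrap replicates (default 100).
#' @param seed optional integer seed.
#' @param mode `"nt"` or `"aa"`.
#' @param degenerate passed to [build_distance_matrix()].
#' @return an `element_tree` with `support` (percentages per internal node,
#'   root `NA`) and support attached as node labels.
#' @export
bootstrap_supports <- function(alignment, n_reps = 100, seed = NULL,
                               mode = c("nt", "aa"), degenerate = character(0)) {
  mode <- match.arg(mode)
  if (n_reps <= 0) stop("n_reps must be positive", call. = FALSE)
  aln <- as_alignment_matrix(alignment)
  ref <- neighbor_joining(build_distance_matrix(aln, mode = mode, degenerate = degenerate))
  if (!is.null(seed)) set.seed(seed)
  L <- ncol(aln)
  reps <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    sub <- aln[, sample.int(L, L, replace = TRUE), drop = FALSE]
    reps[[b]] <- tryCatch(
      neighbor_joining(build_distance_matrix(sub, mode = mode, degenerate = degenerate))$phylo,
      error = function(e) NULL)
  }
  reps <- Filter(Negate(is.null), reps)
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(ref$phylo, reps, rooted = FALSE)
  support <- 100 * counts / length(reps)
  support[is.na(support)] <- 0
  support[1] <- NA  # root node of an unrooted NJ tree carries no bipartition
  ref$support <- support
  ref$phylo$node.label <- round(support)
  ref
}

# mean root-to-tip path length below each node of a rooted tree
.node_heights <- function(phy) {
  ntip <- length(phy$tip.label)
  depths <- ape::node.depth.edgelength(phy)
  # tip descendants per node, accumulated in post-order
  desc <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  for (e in ape::postorder(phy)) {
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  heights <- numeric(ntip + phy$Nnode)
  for (n in seq.int(ntip + 1L, ntip + phy$Nnode)) {
    heights[n] <- mean(depths[desc[[n]]] - depths[n])
  }
  heights
}

#' Calibration-scaled ultrametric node ages for an element tree
#'
#' Roots the tree (midpoint by default), takes each node's height as the
#' mean root-to-tip path below it (substitutions/site), estimates one
#' global rate as the mean over calibrations of height-at-MRCA divided by
#' calibration age, and converts heights to ages.  A strict-clock
#' simplification meant for ordering events, not for publishable dating.
#'
#' @param etree an `element_tree`.
#' @param calibrations data.frame with columns `tip_a`, `tip_b`, `age_myr`:
#'   each row dates the MRCA of the two tips.
#' @param root_method `"midpoint"` or `"outgroup"`.
#' @param outgroup tip label when `root_method = "outgroup"`.
#' @return the `element_tree` with `ages` (Myr per node, named by node
#'   number; tips 0) and `rate` (substitutions/site/Myr) filled in, and a
#'   rooted `phylo`.
#' @export
calibrate_ages <- function(etree, calibrations,
                           root_method = c("midpoint", "outgroup"), outgroup = NULL) {
  stopifnot(inherits(etree, "element_tree"))
  root_method <- match.arg(root_method)
  calibrations <- as.data.frame(calibrations)
  stopifnot(all(c("tip_a", "tip_b", "age_myr") %in% names(calibrations)))
  phy <- etree$phylo
  tips <- phy$tip.label
  miss <- setdiff(unique(c(calibrations$tip_a, calibrations$tip_b)), tips)
  if (length(miss) > 0) {
    stop("calibration tips not in tree: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  phy <- if (root_method == "midpoint") phangorn::midpoint(phy)
         else ape::root(phy, outgroup = outgroup, resolve.root = TRUE)
  heights <- .node_heights(phy)
  ntip <- length(phy$tip.label)
  rates <- mapply(function(a, b, age) {
    h <- if (a == b) stop("calibration needs two distinct tips", call. = FALSE)
         else heights[ape::getMRCA(phy, c(a, b))]
    h / age
  }, calibrations$tip_a, calibrations$tip_b, calibrations$age_myr)
  rate <- mean(rates)
  ages <- heights / rate
  ages[seq_len(ntip)] <- 0
  names(ages) <- as.character(seq_along(ages))
  etree$phylo <- phy
  etree$ages <- ages
  etree$rate <- rate
  etree
}
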