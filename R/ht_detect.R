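# Horizontal-transfer inference: divergence-versus-host-split-age points,
# the OLS regression and its exclusion refit, flagging of
# less-divergent-than-expected pairs, lineage partitioning, patchy
# distribution, element/host topology conflict, and minimal event
# reconstruction scored against the three HT criteria:
#   (i)   cross-taxon divergence lower than expected from the host split age,
#   (ii)  phylogenetic incongruence between element and host trees,
#   (iii) patchy distribution among closely related surveyed taxa.

#' Assemble divergence-versus-age points
#'
#' One point per computable cross-taxon element pair: host split age against
#' nucleotide (and optionally amino-acid) p-distance.  Elements whose median
#' distance to all others exceeds `paralog_cutoff` are excluded as ancient
#' paralogous lineages (their divergence predates the host splits and would
#' only add off-trend points), and elements flagged degenerate are excluded
#' by default since their substitution behaviour is not comparable; both
#' exclusions are recorded.  Intra-taxon pairs (age 0) enter only on
#' request.
#'
#' @param nt_dm nucleotide `pdist_matrix`.
#' @param mapping data.frame with columns `element_id`, `taxon` and
#'   optionally `degenerate`, `fragment` (logical).
#' @param host a `dated_host_tree`.
#' @param aa_dm optional amino-acid `pdist_matrix`.
#' @param include_intra_taxon include same-taxon pairs with age 0
#'   (default FALSE).
#' @param paralog_cutoff median-divergence cutoff for paralog exclusion
#'   (default 0.5).
#' @param include_degenerate keep degenerate elements in the point set
#'   (default FALSE).
#' @return object of class `age_div_points`: list with `points`
#'   (data.frame: `element_a`, `element_b`, `taxon_a`, `taxon_b`,
#'   `age_myr`, `d_nt`, `d_aa`) and `excluded` (data.frame of excluded
#'   elements with reasons).
#' @export
assemble_points <- function(nt_dm, mapping, host, aa_dm = NULL,
                            include_intra_taxon = FALSE,
                            paralog_cutoff = 0.5,
                            include_degenerate = FALSE) {
  stopifnot(inherits(nt_dm, "pdist_matrix"), inherits(host, "dated_host_tree"))
  mapping <- as.data.frame(mapping)
  stopifnot(all(c("element_id", "taxon") %in% names(mapping)))
  labels <- nt_dm$labels
  unmapped <- setdiff(labels, mapping$element_id)
  if (length(unmapped) > 0) {
    stop("elements without a host-taxon mapping: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }
  taxon_of <- stats::setNames(mapping$taxon, mapping$element_id)
  bad_tax <- setdiff(unique(taxon_of[labels]), host$phylo$tip.label)
  if (length(bad_tax) > 0) {
    stop("mapped taxa not in host tree: ", paste(bad_tax, collapse = ", "), call. = FALSE)
  }

  excluded <- data.frame(element = character(0), reason = character(0))
  med <- apply(nt_dm$d, 1L, function(r) stats::median(r[r > 0 | is.na(r)], na.rm = TRUE))
  paralogs <- labels[!is.na(med) & med > paralog_cutoff]
  if (length(paralogs) > 0) {
    message("excluding ancient paralogous lineage(s): ", paste(paralogs, collapse = ", "),
            " (median divergence > ", paralog_cutoff, ")")
    excluded <- rbind(excluded, data.frame(element = paralogs, reason = "paralog"))
  }
  degen <- character(0)
  if (!include_degenerate && "degenerate" %in% names(mapping)) {
    degen <- mapping$element_id[isTRUE_vec(mapping$degenerate)]
    degen <- setdiff(intersect(degen, labels), paralogs)
    if (length(degen) > 0) {
      excluded <- rbind(excluded, data.frame(element = degen, reason = "degenerate"))
    }
  }
  keep <- setdiff(labels, c(paralogs, degen))

  rows <- list()
  for (i in seq_along(keep)) {
    for (j in seq_len(i - 1L)) {
      a <- keep[j]; b <- keep[i]
      ta <- unname(taxon_of[a]); tb <- unname(taxon_of[b])
      if (ta == tb && !include_intra_taxon) next
      d_nt <- nt_dm$d[a, b]
      if (is.na(d_nt)) next
      d_aa <- if (!is.null(aa_dm) && a %in% aa_dm$labels && b %in% aa_dm$labels) {
        aa_dm$d[a, b]
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        element_a = a, element_b = b, taxon_a = ta, taxon_b = tb,
        age_myr = split_age(host, ta, tb), d_nt = d_nt, d_aa = d_aa)
    }
  }
  points <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(element_a = character(0), element_b = character(0),
               taxon_a = character(0), taxon_b = character(0),
               age_myr = numeric(0), d_nt = numeric(0), d_aa = numeric(0))
  structure(list(points = points, excluded = excluded, mapping = mapping, host = host),
            class = "age_div_points")
}

isTRUE_vec <- function(x) !is.na(x) & (x == TRUE | x == "TRUE" | x == "true" | x == 1)

#' @export
print.age_div_points <- function(x, ...) {
  cat(sprintf("divergence-vs-age set: %d pairs over ages {%s} Myr\n",
              nrow(x$points), paste(sort(unique(x$points$age_myr)), collapse = ", ")))
  if (nrow(x$excluded) > 0) {
    cat("excluded elements:",
        paste(sprintf("%s (%s)", x$excluded$element, x$excluded$reason), collapse = ", "), "\n")
  }
  invisible(x)
}

.points_df <- function(points) {
  if (inherits(points, "age_div_points")) points$points else as.data.frame(points)
}

#' Ordinary least squares of divergence on host split age
#'
#' Fits divergence = intercept + slope * age and reports the squared
#' Pearson correlation with its two-sided p-value.  An explicit exclusion
#' list of element pairs allows the refit to be reproduced independently of
#' any flagging heuristic.
#'
#' @param points an `age_div_points` or its data.frame.
#' @param response `"nt"` or `"aa"`.
#' @param exclude optional two-column matrix/data.frame of element pairs to
#'   drop before fitting.
#' @return object of class `div_age_fit`: `slope` (divergence/Myr),
#'   `intercept`, `r_squared`, `pearson_r`, `p_value`, `n_points`,
#'   `excluded_pairs`, plus the underlying `lm` fit.
#' @export
fit_divergence_age <- function(points, response = c("nt", "aa"), exclude = NULL) {
  response <- match.arg(response)
  df <- .points_df(points)
  df$d <- df[[paste0("d_", response)]]
  df <- df[!is.na(df$d), , drop = FALSE]
  ex <- normalize_pairs(exclude)
  if (NROW(ex) > 0) {
    keys <- pair_key(df$element_a, df$element_b)
    df <- df[!keys %in% pair_key(ex[, 1], ex[, 2]), , drop = FALSE]
  }
  if (nrow(df) < 3L) stop("need at least 3 points to fit", call. = FALSE)
  fit <- stats::lm(d ~ age_myr, data = df)
  ct <- stats::cor.test(df$age_myr, df$d, method = "pearson")
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = unname(ct$estimate)^2,
    pearson_r = unname(ct$estimate),
    p_value = ct$p.value,
    n_points = nrow(df),
    excluded_pairs = ex,
    response = response,
    model = fit
  ), class = "div_age_fit")
}

#' @export
print.div_age_fit <- function(x, ...) {
  cat(sprintf("divergence ~ age (%s): slope %.4g /Myr, intercept %.4g\n",
              x$response, x$slope, x$intercept))
  cat(sprintf("R^2 = %.3f (r = %.3f, p = %.3g, n = %d", x$r_squared, x$pearson_r,
              x$p_value, x$n_points))
  if (NROW(x$excluded_pairs) > 0) cat(",", NROW(x$excluded_pairs), "pairs excluded")
  cat(")\n")
  invisible(x)
}

#' Flag element pairs less divergent than the age trend
#'
#' Identifies the divergence-versus-age points falling significantly below
#' the regression trend, the signature of horizontal transfer (paralogy
#' pushes points above the trend and is never flagged).  Three methods:
#'
#' * `"robust"` (default): fit a robust vertical-transmission trend
#'   (M-estimation, [MASS::rlm]) constrained through the origin -- under
#'   vertical descent expected divergence vanishes as the host split age
#'   goes to zero -- scale residuals by their MAD, and flag pairs with
#'   scaled residual below `-t_flag` whose divergence also falls at least
#'   `min_rel_deficit` below the trend prediction.  Robust fitting resists
#'   the masking that a block of transferred pairs exerts on the ordinary
#'   fit, and the relative-deficit guard keeps sampling noise around a
#'   well-fitting trend from being flagged.
#' * `"iterative"`: repeatedly fit OLS, remove the most negative
#'   studentized residual while it is below `-t_iter`; removed pairs are
#'   the candidates.
#' * `"age_class"`: flag pairs below `f_age` times the median divergence of
#'   their age class.
#'
#' @param points an `age_div_points` or its data.frame.
#' @param response `"nt"` or `"aa"`.
#' @param method flagging method.
#' @param t_flag robust-residual threshold (default 1.3, calibrated on the
#'   bundled published distance matrix).
#' @param min_rel_deficit minimum relative deficit below the trend
#'   (default 0.25).
#' @param t_iter studentized-residual threshold for `"iterative"`
#'   (default 2).
#' @param f_age median fraction for `"age_class"` (default 0.5).
#' @return data.frame of flagged pairs with the statistic that flagged
#'   them, ordered from most to least extreme.
#' @export
flag_candidates <- function(points, response = c("nt", "aa"),
                            method = c("robust", "iterative", "age_class"),
                            t_flag = 1.3, min_rel_deficit = 0.25,
                            t_iter = 2, f_age = 0.5) {
  response <- match.arg(response)
  method <- match.arg(method)
  df <- .points_df(points)
  df$d <- df[[paste0("d_", response)]]
  df <- df[!is.na(df$d), , drop = FALSE]
  empty <- df[0, c("element_a", "element_b", "taxon_a", "taxon_b", "age_myr", "d")]
  empty$stat <- numeric(0)
  if (nrow(df) < 4L) return(empty)

  if (method == "robust") {
    fit <- MASS::rlm(d ~ age_myr - 1, data = df, maxit = 200)
    res <- stats::resid(fit)
    s <- stats::mad(res)
    if (s <= 0) return(empty)
    pred <- stats::fitted(fit)
    z <- res / s
    deficit <- ifelse(pred > 0, (pred - df$d) / pred, 0)
    sel <- z < -t_flag & deficit > min_rel_deficit
    out <- df[sel, c("element_a", "element_b", "taxon_a", "taxon_b", "age_myr", "d")]
    out$stat <- z[sel]
  } else if (method == "iterative") {
    cur <- df
    removed <- integer(0)
    rn <- seq_len(nrow(df))
    cur_rn <- rn
    repeat {
      if (nrow(cur) < 4L) break
      fit <- stats::lm(d ~ age_myr, data = cur)
      rs <- stats::rstudent(fit)
      i <- which.min(rs)
      # -Inf (an outlier against an otherwise exact fit) must count as extreme
      if (length(i) == 0 || is.nan(rs[i]) || rs[i] >= -t_iter) break
      removed <- c(removed, cur_rn[i])
      cur <- cur[-i, , drop = FALSE]
      cur_rn <- cur_rn[-i]
    }
    out <- df[removed, c("element_a", "element_b", "taxon_a", "taxon_b", "age_myr", "d")]
    fit <- stats::lm(d ~ age_myr, data = df)
    out$stat <- stats::rstudent(fit)[removed]
  } else {
    med <- stats::ave(df$d, df$age_myr, FUN = stats::median)
    sel <- df$d < f_age * med
    out <- df[sel, c("element_a", "element_b", "taxon_a", "taxon_b", "age_myr", "d")]
    out$stat <- (df$d / med)[sel]
  }
  out[order(out$stat), , drop = FALSE]
}

#' Expand flagged pairs to a taxon-level exclusion list
#'
#' The exclusion refit removes every element pair between the taxon pairs
#' implicated by the flagged candidates (all comparisons between the
#' putative donor and recipient taxa), not just the flagged pairs
#' themselves: once a transfer between two host lineages is suspected, no
#' element pair spanning those lineages reflects vertical descent.
#'
#' @param points an `age_div_points` or its data.frame.
#' @param flagged data.frame from [flag_candidates()] (or any data.frame
#'   with `taxon_a`, `taxon_b`).
#' @return two-column matrix of element pairs to exclude.
#' @export
ht_exclusion_pairs <- function(points, flagged) {
  df <- .points_df(points)
  if (NROW(flagged) == 0) return(normalize_pairs(NULL))
  tk <- unique(pair_key(flagged$taxon_a, flagged$taxon_b))
  sel <- pair_key(df$taxon_a, df$taxon_b) %in% tk
  normalize_pairs(df[sel, c("element_a", "element_b")])
}

#' Partition elements into lineages (divergence + shared-indel rule)
#'
#' Two elements belong to the same lineage when their nucleotide p-distance
#' is at most `threshold` (1% by default, the conventional cutoff
#' separating element lineages) AND they carry the same large-indel
#' profile; membership is closed transitively.  A large shared deletion
#' separates an element from an otherwise near-identical copy lacking it.
#'
#' @param nt_dm nucleotide `pdist_matrix`.
#' @param indel_profiles optional named list/vector: per element, a
#'   signature of its structural variants of at least `l_min` bp (e.g.
#'   `"del:1035-1460"`; empty string or `NULL` for none).
#' @param threshold lineage divergence cutoff (default 0.01).
#' @return object of class `lineage_partition`: list with `blocks` (list of
#'   element-id vectors), `threshold` and `profiles`.
#' @export
assign_lineages <- function(nt_dm, indel_profiles = NULL, threshold = 0.01) {
  stopifnot(inherits(nt_dm, "pdist_matrix"))
  labels <- nt_dm$labels
  prof <- vapply(labels, function(l) {
    p <- indel_profiles[[l]]
    if (is.null(p) || length(p) == 0 || all(is.na(p))) "" else
      paste(sort(unlist(strsplit(as.character(p), ";", fixed = TRUE))), collapse = ";")
  }, "")
  # union-find over qualifying pairs
  parent <- stats::setNames(seq_along(labels), labels)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(labels)) for (j in seq_len(i - 1L)) {
    d <- nt_dm$d[i, j]
    if (!is.na(d) && d <= threshold && prof[i] == prof[j]) {
      parent[find(i)] <- find(j)
    }
  }
  roots <- vapply(seq_along(labels), find, 0L)
  blocks <- unname(split(labels, roots))
  blocks <- blocks[order(vapply(blocks, function(b) min(b), ""))]
  structure(list(blocks = blocks, threshold = threshold, profiles = prof),
            class = "lineage_partition")
}

#' @export
print.lineage_partition <- function(x, ...) {
  cat(sprintf("lineage partition (threshold %.3g):\n", x$threshold))
  for (b in x$blocks) cat("  {", paste(b, collapse = ", "), "}\n")
  invisible(x)
}

#' Does an element lineage show a patchy distribution?
#'
#' A lineage present in two or more surveyed taxa that do not form a clade
#' on the host tree (restricted to surveyed taxa) is patchy: it occurs in
#' one lineage while absent from taxa nested inside the implied clade.
#'
#' @param block character vector of element ids (one lineage block).
#' @param mapping element-to-taxon mapping data.frame.
#' @param host a `dated_host_tree` (its `surveyed` set is honoured).
#' @return logical flag.
#' @export
patchy_distribution <- function(block, mapping, host) {
  mapping <- as.data.frame(mapping)
  taxa <- unique(mapping$taxon[mapping$element_id %in% block])
  if (length(taxa) < 2L) return(FALSE)
  sub <- restrict_host(host, host$surveyed)
  !is_clade(sub, intersect(taxa, sub$phylo$tip.label))
}

# taxon-occurrence sets on the two sides of each internal edge of a tree
.tree_splits <- function(phy, label_map = NULL, support = NULL) {
  ntip <- length(phy$tip.label)
  uphy <- ape::unroot(phy)
  parts <- ape::prop.part(uphy)   # clades of internal nodes (rooted repr.)
  labs <- attr(parts, "labels")
  splits <- list()
  nn <- length(uphy$tip.label) + seq_len(uphy$Nnode)
  for (k in seq_along(parts)) {
    if (k == 1L) next  # root pseudo-node: trivial split
    side <- labs[parts[[k]]]
    other <- setdiff(labs, side)
    if (length(side) < 2L || length(other) < 2L) next
    sup <- if (!is.null(support)) support[k] else NA_real_
    a <- if (is.null(label_map)) side else unname(label_map[side])
    b <- if (is.null(label_map)) other else unname(label_map[other])
    splits[[length(splits) + 1L]] <- list(tips_a = side, tips_b = other,
                                          taxa_a = unique(a), taxa_b = unique(b),
                                          support = sup)
  }
  splits
}

#' Conflicts between the element tree and the host phylogeny
#'
#' Maps each element-tree bipartition to the host-taxon occurrence sets of
#' its two sides and tests it against every host-tree bipartition with the
#' four-intersection rule: a host split C|D conflicts with an element split
#' whose side taxon-sets are A and B when all of A∩C, A∩D, B∩C and B∩D are
#' non-empty.  Because one taxon's elements may sit on both sides of an
#' element split (the signature of transfer), A and B may overlap.  Only
#' element splits with bootstrap support of at least `s_min` are considered
#' (all splits when no support is attached).  Also reports the
#' Robinson-Foulds distance between the host tree and the element tree
#' reduced to one representative element per taxon.
#'
#' @param etree an `element_tree`.
#' @param host a `dated_host_tree`.
#' @param mapping element-to-taxon mapping data.frame.
#' @param s_min minimum bootstrap support for an element split (default 70).
#' @param representatives optional named vector taxon -> element id for the
#'   Robinson-Foulds reduction (defaults to each taxon's first element in
#'   mapping order).
#' @return list with `conflicts` (data.frame: host split, element split,
#'   support) and `rf` (Robinson-Foulds distance on the reduced trees).
#' @export
topology_conflicts <- function(etree, host, mapping, s_min = 70,
                               representatives = NULL) {
  stopifnot(inherits(etree, "element_tree"), inherits(host, "dated_host_tree"))
  mapping <- as.data.frame(mapping)
  tax_of <- stats::setNames(mapping$taxon, mapping$element_id)
  tips <- etree$phylo$tip.label
  unmapped <- setdiff(tips, names(tax_of))
  if (length(unmapped) > 0) {
    stop("unmapped element tips: ", paste(unmapped, collapse = ", "), call. = FALSE)
  }
  support <- etree$support
  e_splits <- .tree_splits(etree$phylo, label_map = tax_of, support = support)
  if (!is.null(support)) {
    e_splits <- Filter(function(s) is.na(s$support) || s$support >= s_min, e_splits)
  }
  h_phy <- ape::keep.tip(host$phylo, intersect(host$phylo$tip.label, unique(tax_of[tips])))
  h_splits <- .tree_splits(h_phy)

  conflicts <- data.frame(host_split = character(0), element_split = character(0),
                          support = numeric(0))
  for (hs in h_splits) {
    for (es in e_splits) {
      A <- intersect(es$taxa_a, h_phy$tip.label)
      B <- intersect(es$taxa_b, h_phy$tip.label)
      C <- hs$taxa_a; D <- hs$taxa_b
      if (length(intersect(A, C)) > 0 && length(intersect(A, D)) > 0 &&
          length(intersect(B, C)) > 0 && length(intersect(B, D)) > 0) {
        conflicts <- rbind(conflicts, data.frame(
          host_split = paste(paste(sort(C), collapse = "+"),
                             paste(sort(D), collapse = "+"), sep = " | "),
          element_split = paste(paste(sort(es$tips_a), collapse = "+"),
                                paste(sort(es$tips_b), collapse = "+"), sep = " | "),
          support = es$support))
      }
    }
  }

  reps <- representatives %||% {
    first <- mapping[!duplicated(mapping$taxon), ]
    stats::setNames(first$element_id, first$taxon)
  }
  reps <- reps[names(reps) %in% h_phy$tip.label & reps %in% tips]
  rf <- NA_real_
  if (length(reps) >= 4L) {
    red <- ape::keep.tip(etree$phylo, unname(reps))
    red$tip.label <- names(reps)[match(red$tip.label, reps)]
    rf <- as.numeric(ape::dist.topo(ape::unroot(red),
                                    ape::unroot(ape::keep.tip(h_phy, names(reps)))))
  }
  list(conflicts = conflicts, rf = rf)
}

#' Reconstruct minimal horizontal-transfer events from flagged pairs
#'
#' Groups flagged low-divergence pairs into the smallest set of transfer
#' events consistent with the element tree.  Each candidate event is
#' anchored on one element: the pairs sharing that anchor support a single
#' event when their other-side elements are monophyletic in the element
#' tree restricted to the elements of the other side's taxa.  A greedy
#' minimal cover (most pairs first, ties by younger age bound then label)
#' selects the reported events.  Donor and recipient are a heuristic read
#' off tree nesting: when the anchor shares a lineage block with an element
#' of another taxon, the anchor's taxon is the recipient of that lineage;
#' otherwise the anchor's taxon is taken as donor toward the partner
#' clade's taxa.  Criterion (i) holds by construction for every event;
#' (ii) and (iii) are filled from [topology_conflicts()] and
#' [patchy_distribution()].
#'
#' @param flagged data.frame from [flag_candidates()].
#' @param lineages a `lineage_partition`.
#' @param etree an `element_tree` (calibrated ages used for bounds when
#'   present).
#' @param host a `dated_host_tree`.
#' @param mapping element-to-taxon mapping data.frame.
#' @param conflicts optional result of [topology_conflicts()] (computed
#'   when omitted).
#' @return object of class `ht_events`: list of events, each with
#'   `anchor`, `partners`, `donor_taxa`, `recipient_taxa` (heuristic),
#'   `supporting_pairs`, `age_bound_myr` and `criteria`.
#' @export
reconstruct_events <- function(flagged, lineages, etree, host, mapping,
                               conflicts = NULL) {
  if (NROW(flagged) == 0) return(structure(list(), class = "ht_events"))
  mapping <- as.data.frame(mapping)
  tax_of <- stats::setNames(mapping$taxon, mapping$element_id)
  phy <- etree$phylo
  if (is.null(conflicts)) conflicts <- topology_conflicts(etree, host, mapping)

  flagged$key <- pair_key(flagged$element_a, flagged$element_b)
  anchors <- unique(c(flagged$element_a, flagged$element_b))

  age_of_pair <- function(a, b) {
    if (!is.null(etree$ages) && a %in% phy$tip.label && b %in% phy$tip.label) {
      unname(etree$ages[as.character(ape::getMRCA(phy, c(a, b)))])
    } else {
      split_age(host, unname(tax_of[a]), unname(tax_of[b]))
    }
  }

  candidates <- list()
  for (anchor in anchors) {
    sel <- flagged$element_a == anchor | flagged$element_b == anchor
    partners <- ifelse(flagged$element_a[sel] == anchor,
                       flagged$element_b[sel], flagged$element_a[sel])
    partner_taxa <- unique(unname(tax_of[partners]))
    scope <- names(tax_of)[tax_of %in% partner_taxa]
    scope <- intersect(scope, phy$tip.label)
    ok <- if (length(partners) == 1L) TRUE else {
      red <- ape::keep.tip(phy, scope)
      ape::is.monophyletic(red, intersect(partners, red$tip.label))
    }
    if (!ok) next
    bound <- min(vapply(partners, function(p) age_of_pair(anchor, p), 0))
    candidates[[length(candidates) + 1L]] <- list(
      anchor = anchor, partners = sort(unique(partners)),
      pairs = flagged$key[sel], n = sum(sel), bound = bound)
  }
  if (length(candidates) == 0) return(structure(list(), class = "ht_events"))

  # greedy minimal cover of the flagged pairs
  ord <- order(-vapply(candidates, `[[`, 0L, "n"),
               vapply(candidates, `[[`, 0, "bound"),
               vapply(candidates, `[[`, "", "anchor"))
  candidates <- candidates[ord]
  uncovered <- unique(flagged$key)
  chosen <- list()
  for (cand in candidates) {
    newly <- intersect(cand$pairs, uncovered)
    if (length(newly) == 0) next
    cand$pairs <- newly
    chosen[[length(chosen) + 1L]] <- cand
    uncovered <- setdiff(uncovered, newly)
    if (length(uncovered) == 0) break
  }

  block_of <- function(el) {
    for (b in lineages$blocks) if (el %in% b) return(b)
    el
  }
  events <- lapply(chosen, function(cand) {
    anchor_taxon <- unname(tax_of[cand$anchor])
    partner_taxa <- sort(unique(unname(tax_of[cand$partners])))
    blk <- block_of(cand$anchor)
    mates <- setdiff(blk, cand$anchor)
    mate_taxa <- setdiff(unique(unname(tax_of[mates])), anchor_taxon)
    if (length(mate_taxa) > 0) {
      donor <- mate_taxa; recipient <- anchor_taxon
    } else {
      donor <- anchor_taxon; recipient <- partner_taxa
    }
    ev_taxa <- c(anchor_taxon, partner_taxa)
    crit_ii <- any(vapply(seq_len(NROW(conflicts$conflicts)), function(k) {
      sides <- strsplit(conflicts$conflicts$element_split[k], " | ", fixed = TRUE)[[1]]
      any(vapply(sides, function(s) {
        els <- strsplit(s, "+", fixed = TRUE)[[1]]
        tx <- unique(unname(tax_of[els]))
        anchor_taxon %in% tx && any(partner_taxa %in% tx)
      }, TRUE))
    }, TRUE))
    ev_elements <- c(cand$anchor, cand$partners)
    crit_iii <- any(vapply(lineages$blocks, function(b) {
      length(intersect(b, ev_elements)) > 0 &&
        patchy_distribution(b, mapping, host)
    }, TRUE))
    sp <- do.call(rbind, strsplit(cand$pairs, "\r", fixed = TRUE))
    list(anchor = cand$anchor, partners = cand$partners,
         donor_taxa = donor, recipient_taxa = recipient,
         supporting_pairs = data.frame(element_a = sp[, 1], element_b = sp[, 2]),
         age_bound_myr = c(0, cand$bound),
         criteria = c(low_divergence = TRUE, incongruence = crit_ii,
                      patchy = crit_iii))
  })
  structure(events, class = "ht_events")
}

#' @export
print.ht_events <- function(x, ...) {
  if (length(x) == 0) { cat("no horizontal-transfer events reconstructed\n"); return(invisible(x)) }
  cat(length(x), "horizontal-transfer event(s):\n")
  for (k in seq_along(x)) {
    e <- x[[k]]
    cat(sprintf("  %d. %s -> %s (heuristic direction); anchor %s, partners {%s}\n",
                k, paste(e$donor_taxa, collapse = "/"),
                paste(e$recipient_taxa, collapse = "/"),
                e$anchor, paste(e$partners, collapse = ", ")))
    cat(sprintf("     %d supporting pair(s); age bound <= %.2f Myr; criteria: low-divergence %s, incongruence %s, patchy %s\n",
                nrow(e$supporting_pairs), e$age_bound_myr[2],
                e$criteria["low_divergence"], e$criteria["incongruence"],
                e$criteria["patchy"]))
  }
  invisible(x)
}
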