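# Uncorrected p-distances with pairwise deletion, analytic standard errors,
# fragment-aware site counts, and the distance-matrix container used by the
# rest of the pipeline.

.valid_residues <- function(mode) {
  if (mode == "nt") NT_ALPHABET else AA_ALPHABET
}

#' Uncorrected p-distance between two aligned rows
#'
#' Proportion of differing sites among the columns comparable in both rows.
#' Columns holding a gap (`-`), missing data (`N`/`X`/`?`), an ambiguity
#' code, or falling outside either record's coverage are excluded for this
#' pair only (pairwise deletion), so partial 5'-only fragments remain
#' comparable over their covered region.
#'
#' @param a,b aligned rows of equal length (strings or character vectors).
#' @param mode `"nt"` or `"aa"`.
#' @return list with `d` (proportion, `NA` when no site is comparable) and
#'   `n_sites` (number of compared sites).
#' @examples
#' p_distance("ACGT", "ACGA")      # d = 0.25 over 4 sites
#' p_distance("AC-T", "ACGA")      # gap column excluded: d = 1/3 over 3 sites
#' @export
p_distance <- function(a, b, mode = c("nt", "aa")) {
  mode <- match.arg(mode)
  x <- toupper(seq_chars(a)); y <- toupper(seq_chars(b))
  if (length(x) != length(y)) {
    stop("aligned rows must have equal length", call. = FALSE)
  }
  ok <- x %in% .valid_residues(mode) & y %in% .valid_residues(mode)
  n <- sum(ok)
  if (n == 0L) return(list(d = NA_real_, n_sites = 0L))
  list(d = sum(x[ok] != y[ok]) / n, n_sites = n)
}

#' Analytic standard error of a p-distance
#'
#' Binomial approximation `sqrt(d (1 - d) / n_sites)`; zero whenever the
#' distance itself is zero.
#'
#' @param d p-distance in \[0, 1\].
#' @param n_sites number of compared sites (> 0).
#' @return standard error.
#' @export
p_distance_se <- function(d, n_sites) {
  stopifnot(all(n_sites[!is.na(d)] > 0))
  sqrt(d * (1 - d) / n_sites)
}

#' Build a pairwise p-distance matrix from an alignment
#'
#' Computes all pairwise uncorrected p-distances with pairwise deletion,
#' their compared-site counts and standard errors.  In amino-acid mode,
#' pairs involving an element flagged degenerate (no conceptual
#' translation) are not computed, mirroring the treatment of heavily
#' degraded ORFs; pairs with zero comparable sites are likewise marked not
#' computed rather than zero.
#'
#' @param alignment character matrix (rows = elements, rownames = labels) or
#'   a named character vector of equal-length aligned strings.
#' @param mode `"nt"` or `"aa"`.
#' @param degenerate labels whose amino-acid distances must not be computed.
#' @param se_method `"analytic"` (default, deterministic) or `"bootstrap"`
#'   (site resampling).
#' @param n_boot bootstrap replicates when `se_method = "bootstrap"`.
#' @param seed optional seed for the bootstrap.
#' @return an object of class `pdist_matrix`: list with `labels`, `d`,
#'   `n_sites`, `se` (matrices), `mode` and `not_computed` (two-column
#'   matrix of label pairs).
#' @export
build_distance_matrix <- function(alignment, mode = c("nt", "aa"),
                                  degenerate = character(0),
                                  se_method = c("analytic", "bootstrap"),
                                  n_boot = 100, seed = NULL) {
  mode <- match.arg(mode)
  se_method <- match.arg(se_method)
  aln <- as_alignment_matrix(alignment)
  labels <- rownames(aln)
  if (anyDuplicated(labels)) stop("duplicate element labels in alignment", call. = FALSE)
  if (nrow(aln) < 2L) stop("need at least two records", call. = FALSE)
  n <- length(labels)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  ns <- matrix(0L, n, n, dimnames = list(labels, labels))
  nc <- matrix(character(0), ncol = 2)
  diag(ns) <- ncol(aln)
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (mode == "aa" && (labels[i] %in% degenerate || labels[j] %in% degenerate)) {
        d[i, j] <- d[j, i] <- NA_real_
        nc <- rbind(nc, sort(c(labels[i], labels[j])))
        next
      }
      pd <- p_distance(aln[i, ], aln[j, ], mode = mode)
      if (is.na(pd$d)) nc <- rbind(nc, sort(c(labels[i], labels[j])))
      d[i, j] <- d[j, i] <- pd$d
      ns[i, j] <- ns[j, i] <- pd$n_sites
    }
  }
  se <- p_distance_se(d, pmax(ns, 1L))
  if (se_method == "bootstrap") {
    L <- ncol(aln)
    boots <- array(NA_real_, c(n, n, n_boot))
    for (b in seq_len(n_boot)) {
      cols <- sample.int(L, L, replace = TRUE)
      sub <- aln[, cols, drop = FALSE]
      for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
        if (is.na(d[i, j])) next
        boots[i, j, b] <- p_distance(sub[i, ], sub[j, ], mode = mode)$d
      }
    }
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      if (is.na(d[i, j])) next
      se[i, j] <- se[j, i] <- stats::sd(boots[i, j, ], na.rm = TRUE)
    }
  }
  diag(se) <- 0
  pdist_matrix(d, se = se, n_sites = ns, mode = mode, not_computed = nc)
}

#' Construct a `pdist_matrix` from precomputed values
#'
#' Container used both for matrices computed from alignments and for
#' published distance tables loaded from file.
#'
#' @param d symmetric numeric matrix of p-distances with dimnames.
#' @param se optional matrix of standard errors.
#' @param n_sites optional matrix of compared-site counts.
#' @param mode `"nt"` or `"aa"`.
#' @param not_computed two-column matrix of label pairs without a distance.
#' @return object of class `pdist_matrix`.
#' @export
pdist_matrix <- function(d, se = NULL, n_sites = NULL, mode = c("nt", "aa"),
                         not_computed = matrix(character(0), ncol = 2)) {
  mode <- match.arg(mode)
  labels <- rownames(d)
  stopifnot(!is.null(labels), identical(labels, colnames(d)))
  if (!isTRUE(all.equal(d, t(d), check.attributes = FALSE))) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  off <- d[upper.tri(d)]
  if (any(off < 0 | off > 1, na.rm = TRUE)) stop("p-distances must lie in [0, 1]", call. = FALSE)
  structure(list(labels = labels, d = d, se = se, n_sites = n_sites,
                 mode = mode, not_computed = not_computed),
            class = "pdist_matrix")
}

#' @export
print.pdist_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("p-distance matrix (%s), %d elements\n", x$mode, length(x$labels)))
  print(round_half_up(x$d, digits))
  if (NROW(x$not_computed) > 0) {
    cat("not computed:",
        paste(x$not_computed[, 1], x$not_computed[, 2], sep = "/", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.matrix.pdist_matrix <- function(x, ...) x$d

#' Tidy long-format view of a distance matrix
#'
#' @param x a `pdist_matrix`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame with one row per unordered pair.
#' @export
as.data.frame.pdist_matrix <- function(x, row.names = NULL, optional = FALSE, ...) {
  n <- length(x$labels)
  idx <- which(upper.tri(x$d), arr.ind = TRUE)
  data.frame(
    element_a = x$labels[idx[, 1]],
    element_b = x$labels[idx[, 2]],
    d = x$d[idx],
    se = if (is.null(x$se)) NA_real_ else x$se[idx],
    n_sites = if (is.null(x$n_sites)) NA_integer_ else x$n_sites[idx],
    mode = x$mode
  )
}

#' Coerce alignment input to an upper-case character matrix
#'
#' Accepts a character matrix, a named character vector of aligned strings,
#' or a path to an aligned FASTA file (`-` is the gap character; `N`/`X`
#' are treated as missing data downstream).
#'
#' @param x alignment input.
#' @param mode `"nt"` or `"aa"` (used when reading FASTA).
#' @return character matrix with element labels as rownames.
#' @export
as_alignment_matrix <- function(x, mode = c("nt", "aa")) {
  mode <- match.arg(mode)
  if (is.matrix(x)) {
    m <- toupper(x)
  } else if (is.character(x) && !is.null(names(x))) {
    lens <- nchar(x)
    if (length(unique(lens)) != 1L) stop("aligned sequences must have equal length", call. = FALSE)
    m <- do.call(rbind, lapply(x, seq_chars))
    m <- toupper(m)
    rownames(m) <- names(x)
  } else if (is.character(x) && length(x) == 1L && file.exists(x)) {
    bin <- ape::read.FASTA(x, type = if (mode == "nt") "DNA" else "AA")
    ch <- lapply(as.character(bin), toupper)
    lens <- lengths(ch)
    if (length(unique(lens)) != 1L) stop("FASTA records are not aligned (unequal lengths)", call. = FALSE)
    m <- do.call(rbind, ch)
    rownames(m) <- names(bin)
  } else {
    stop("cannot interpret alignment input", call. = FALSE)
  }
  if (is.null(rownames(m))) stop("alignment rows must be named", call. = FALSE)
  m
}
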