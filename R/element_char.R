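# Structural characterization of R2-like element sequences: poly-A trimming,
# ORF detection with frameshift joining, translation, zinc-finger motifs and
# large indel / duplication annotation against a reference copy.

#' Trim the 3' terminal poly-A tail of an element sequence
#'
#' R2 insertions typically end in a short poly-(A) tract.  The maximal
#' terminal run of `A` is removed when it reaches `min_run` nucleotides;
#' shorter runs are considered ordinary sequence and left in place.
#'
#' @param seq a single ungapped nucleotide string.
#' @param min_run minimum terminal A-run length for trimming (default 5).
#' @return list with `seq` (trimmed sequence) and `tail_length` (integer,
#'   0 when no tail was trimmed).
#' @examples
#' trim_poly_a(paste0("ACGTCGT", strrep("A", 9)))$tail_length
#' @export
trim_poly_a <- function(seq, min_run = 5) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq)) {
    stop("`seq` must be a single non-empty nucleotide string", call. = FALSE)
  }
  if (is_gapped(seq)) stop("`seq` must be ungapped", call. = FALSE)
  x <- toupper(seq)
  run <- attr(regexpr("A+$", x), "match.length")
  run <- if (run < 0) 0L else as.integer(run)
  if (run >= min_run) {
    list(seq = substr(x, 1L, nchar(x) - run), tail_length = run)
  } else {
    list(seq = x, tail_length = 0L)
  }
}

# Maximal stop-free codon runs of one forward reading frame.
# Each run records the nt span of its non-stop codons and, when present, the
# start of the terminating stop codon.
.orf_runs <- function(chars, frame) {
  n <- length(chars)
  starts <- seq.int(frame + 1L, n - 2L, by = 3L)
  if (length(starts) == 0L) return(list())
  codons <- paste0(chars[starts], chars[starts + 1L], chars[starts + 2L])
  is_stop <- codons %in% c("TAA", "TAG", "TGA")
  runs <- list()
  i <- 1L
  while (i <= length(codons)) {
    if (is_stop[i]) { i <- i + 1L; next }
    j <- i
    while (j < length(codons) && !is_stop[j + 1L]) j <- j + 1L
    stop_start <- if (j < length(codons)) starts[j + 1L] else NA_integer_
    runs[[length(runs) + 1L]] <- list(
      frame = frame,
      cstart = starts[i],
      open_end = starts[j] + 2L,
      stop_start = stop_start,
      full_end = if (is.na(stop_start)) starts[j] + 2L else stop_start + 2L,
      codons = codons[i:j],
      codon_starts = starts[i:j]
    )
    i <- j + 2L
  }
  runs
}

#' Find the longest open reading frame, joining frame-shifted segments
#'
#' Scans the three forward reading frames for stop-free segments and
#' assembles the longest ORF starting at an `ATG`.  Degraded elements are
#' handled by two kinds of segment joining: a shift into a different frame
#' (recorded in `frameshift_positions`) and a read-through of a premature
#' stop codon in the same frame (recorded in `internal_stop_positions`, at
#' most `max_internal_stops` per ORF).  A frameshift junction cannot be
#' located exactly from a single sequence: the causal indel may lie anywhere
#' in the window where both segments are open.  The reported position is the
#' midpoint of that window, and the window itself is kept in
#' `frameshift_windows`.
#'
#' @param seq a single ungapped nucleotide string (poly-A already trimmed).
#' @param min_segment minimum length (bp) of the primary open segment, and
#'   minimum extension (bp) a join must add; default 300.
#' @param join_gap maximum gap (bp) tolerated between the upstream segment's
#'   open end and the downstream segment's start (overlap of any size is
#'   allowed); default 30.
#' @param max_internal_stops maximum premature stop codons retained inside a
#'   joined ORF; default 2.
#' @return an object of class `orf_annotation` (list with `start`, `end`,
#'   `length_nt`, `frameshift_positions`, `frameshift_windows`,
#'   `internal_stop_positions`, `segments`, `protein`, `protein_length_aa`),
#'   or `NULL` when no open segment of at least `min_segment` bp exists.
#' @export
find_orf <- function(seq, min_segment = 300, join_gap = 30, max_internal_stops = 2) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq)) {
    stop("`seq` must be a single non-empty nucleotide string", call. = FALSE)
  }
  if (is_gapped(seq)) stop("`seq` must be ungapped", call. = FALSE)
  chars <- seq_chars(toupper(seq))
  if (length(chars) < min_segment) return(NULL)

  runs <- c(.orf_runs(chars, 0L), .orf_runs(chars, 1L), .orf_runs(chars, 2L))
  if (length(runs) == 0L) return(NULL)

  # best chain (maximal final coordinate) reachable from run `i` with a
  # budget of internal stops; memoised on (run, budget)
  memo <- new.env(parent = emptyenv())
  best_chain <- function(i, budget) {
    key <- paste(i, budget)
    if (!is.null(memo[[key]])) return(memo[[key]])
    r <- runs[[i]]
    best <- list(end = r$full_end, steps = list())
    for (j in seq_along(runs)) {
      if (j == i) next
      r2 <- runs[[j]]
      if (r2$frame == r$frame) {
        # read-through of the terminating stop codon; the continuation run
        # itself must add at least min_segment
        if (budget < 1L || is.na(r$stop_start) || r2$cstart != r$stop_start + 3L) next
        if (r2$full_end < r$full_end + min_segment) next
        sub <- best_chain(j, budget - 1L)
        step <- list(kind = "stop", at = r$stop_start, to = j)
      } else {
        # frameshift join into a different frame; the downstream run itself
        # must extend at least min_segment beyond the current open end
        if (r2$cstart > r$open_end + join_gap || r2$cstart <= r$cstart) next
        if (r2$full_end < r$open_end + min_segment) next
        sub <- best_chain(j, budget)
        step <- list(kind = "shift",
                     window = c(min(r2$cstart, r$open_end), max(r2$cstart, r$open_end)),
                     to = j)
      }
      cand <- list(end = sub$end, steps = c(list(step), sub$steps))
      if (cand$end > best$end ||
          (cand$end == best$end && length(cand$steps) < length(best$steps))) {
        best <- cand
      }
    }
    memo[[key]] <- best
    best
  }

  # candidate primary runs: must contain an in-frame ATG
  best_orf <- NULL
  for (i in seq_along(runs)) {
    r <- runs[[i]]
    atg <- which(r$codons == "ATG")
    if (length(atg) == 0L) next
    start <- r$codon_starts[atg[1L]]
    chain <- best_chain(i, max_internal_stops)
    len <- chain$end - start + 1L
    if ((r$full_end - start + 1L) < min_segment && length(chain$steps) == 0L) next
    if (len < min_segment) next
    if (is.null(best_orf) || len > best_orf$length_nt) {
      best_orf <- list(start = start, end = chain$end, length_nt = len,
                       first_run = i, steps = chain$steps)
    }
  }
  if (is.null(best_orf)) return(NULL)

  # walk the chain to collect junctions and translation segments
  fs_pos <- integer(0); fs_win <- list(); stop_pos <- integer(0)
  segs <- data.frame(frame = integer(0), from = integer(0), to = integer(0))
  cur <- runs[[best_orf$first_run]]
  seg_from <- best_orf$start
  for (step in best_orf$steps) {
    nxt <- runs[[step$to]]
    if (step$kind == "stop") {
      stop_pos <- c(stop_pos, step$at)
      # same frame: translation continues through the stop codon
    } else {
      mid <- as.integer(round(mean(step$window)))
      fs_pos <- c(fs_pos, mid)
      fs_win[[length(fs_win) + 1L]] <- step$window
      # close the upstream translation piece at the last codon boundary
      # at or before the junction estimate
      up_to <- seg_from - 1L + 3L * ((mid - seg_from + 1L) %/% 3L)
      segs <- rbind(segs, data.frame(frame = cur$frame, from = seg_from, to = up_to))
      # downstream piece restarts at the first codon boundary of the new frame
      # at or after the junction estimate
      k <- ceiling((mid - nxt$cstart) / 3)
      seg_from <- nxt$cstart + 3L * max(0L, as.integer(k))
    }
    cur <- nxt
  }
  segs <- rbind(segs, data.frame(frame = cur$frame, from = seg_from, to = cur$full_end))

  out <- structure(list(
    start = best_orf$start, end = best_orf$end,
    length_nt = best_orf$length_nt,
    frameshift_positions = fs_pos, frameshift_windows = fs_win,
    internal_stop_positions = stop_pos,
    segments = segs, protein = NULL, protein_length_aa = NA_integer_
  ), class = "orf_annotation")
  prot <- translate_orf(seq, out)
  out$protein <- prot
  out$protein_length_aa <- nchar(prot)
  out
}

#' Translate an annotated ORF
#'
#' A clean ORF (no frameshifts) is translated with the standard nuclear
#' code and must have a length divisible by three; the terminal stop is
#' excluded, so a clean ORF of `3k + 3` bp yields `k` amino acids.  A
#' frameshift-joined ORF is translated piecewise over its segments;
#' retained internal stops appear as `*`.
#'
#' @param seq the nucleotide string the annotation refers to.
#' @param orf an `orf_annotation` from [find_orf()].
#' @return the protein string (terminal stop removed).
#' @export
translate_orf <- function(seq, orf) {
  stopifnot(inherits(orf, "orf_annotation"))
  chars <- seq_chars(toupper(seq))
  if (length(orf$frameshift_positions) == 0L) {
    len <- orf$end - orf$start + 1L
    if (len %% 3L != 0L) {
      stop("ORF with no frameshift has length not divisible by 3", call. = FALSE)
    }
    starts <- seq.int(orf$start, orf$end, by = 3L)
    aa <- translate_codons(paste0(chars[starts], chars[starts + 1L], chars[starts + 2L]))
  } else {
    aa <- character(0)
    for (k in seq_len(nrow(orf$segments))) {
      s <- orf$segments[k, ]
      if (s$to - s$from + 1L < 3L) next
      to <- s$from - 1L + 3L * ((s$to - s$from + 1L) %/% 3L)
      starts <- seq.int(s$from, to, by = 3L)
      aa <- c(aa, translate_codons(paste0(chars[starts], chars[starts + 1L], chars[starts + 2L])))
    }
  }
  if (length(aa) > 0L && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}

#' Detect N-terminal zinc-finger motifs and suggest an R2 clade
#'
#' Scans the N-terminal window of a protein for CCHH- and CCHC-type
#' zinc-finger motifs.  The number and configuration of N-terminal zinc
#' fingers diagnoses the four main R2 clades; the two configurations seen in
#' this genus are mapped to a clade suggestion: a single CCHH motif is
#' characteristic of clade R2-D, a CCHC followed by a CCHH of clade R2-B.
#'
#' @param protein a single amino-acid string.
#' @param window N-terminal window scanned (aa, default 250).
#' @param patterns named character vector of motif regular expressions;
#'   defaults follow the C2H2 consensus with C-x(2,4)-C-x(8,16)-H-x(3,5)-H/C
#'   spacing.
#' @return list with `motifs` (ordered motif classes), `count`, `positions`
#'   (match starts) and `clade` (suggested clade or `NA`).
#' @export
detect_zinc_fingers <- function(protein, window = 250,
                                patterns = c(CCHH = "C.{2,4}C.{8,16}H.{3,5}H",
                                             CCHC = "C.{2,4}C.{8,16}H.{3,5}C")) {
  if (!is.character(protein) || length(protein) != 1L || !nzchar(protein)) {
    stop("`protein` must be a single non-empty amino-acid string", call. = FALSE)
  }
  region <- substr(toupper(protein), 1L, window)
  hits <- data.frame(class = character(0), start = integer(0), end = integer(0))
  for (cl in names(patterns)) {
    m <- gregexpr(patterns[[cl]], region, perl = TRUE)[[1]]
    if (m[1] != -1L) {
      hits <- rbind(hits, data.frame(class = cl, start = as.integer(m),
                                     end = as.integer(m) + attr(m, "match.length") - 1L))
    }
  }
  hits <- hits[order(hits$start, hits$end), , drop = FALSE]
  keep <- integer(0); last_end <- 0L
  for (k in seq_len(nrow(hits))) {
    if (hits$start[k] > last_end) { keep <- c(keep, k); last_end <- hits$end[k] }
  }
  hits <- hits[keep, , drop = FALSE]
  motifs <- hits$class
  clade <- if (identical(motifs, "CCHH")) "R2-D"
           else if (identical(motifs, c("CCHC", "CCHH"))) "R2-B"
           else NA_character_
  list(motifs = motifs, count = length(motifs), positions = hits$start, clade = clade)
}

#' Annotate large deletions and tandem duplications against a reference
#'
#' Takes a two-row pairwise alignment (query and reference) in which gaps
#' encode indels, and reports structural variants of at least `l_min` bp in
#' 1-based inclusive reference coordinates.  A gap run in the query is a
#' deletion.  A gap run in the reference is an insertion in the query; when
#' the inserted block repeats the immediately adjacent query sequence (at
#' `min_identity` or better) it is classified as a tandem duplication whose
#' `length_bp` is the repeated-unit length.
#'
#' @param query,reference aligned rows of equal length (strings or character
#'   vectors; `-` is the gap character).
#' @param l_min minimum variant length in bp (default 50).
#' @param min_identity minimum identity for calling a duplication (default 0.9).
#' @return data.frame with columns `kind` (`deletion`, `duplication`,
#'   `insertion`), `ref_start`, `ref_end`, `length_bp`.
#' @export
annotate_structural_variants <- function(query, reference, l_min = 50, min_identity = 0.9) {
  q <- toupper(seq_chars(query)); r <- toupper(seq_chars(reference))
  if (length(q) != length(r)) {
    stop("query and reference rows must have equal aligned length", call. = FALSE)
  }
  ref_pos <- cumsum(r != "-")          # reference coordinate at each column
  out <- data.frame(kind = character(0), ref_start = integer(0),
                    ref_end = integer(0), length_bp = integer(0))

  runs_of <- function(flag) {
    rl <- rle(flag)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    data.frame(start = starts, end = ends, len = rl$lengths, val = rl$values)
  }

  # deletions: query gap over reference bases
  del <- runs_of(q == "-" & r != "-")
  for (k in which(del$val & del$len >= l_min)) {
    out <- rbind(out, data.frame(kind = "deletion",
                                 ref_start = ref_pos[del$start[k]],
                                 ref_end = ref_pos[del$end[k]],
                                 length_bp = del$len[k]))
  }

  # insertions: reference gap over query bases; tandem-repeat check
  ins <- runs_of(r == "-" & q != "-")
  qseq <- q[q != "-"]
  q_pos <- cumsum(q != "-")
  for (k in which(ins$val & ins$len >= l_min)) {
    block <- q[ins$start[k]:ins$end[k]]
    len <- length(block)
    anchor <- ref_pos[max(ins$start[k] - 1L, 1L)]
    qs <- q_pos[ins$start[k]]            # query coordinate of block start
    ident <- function(a, b) if (length(a) != length(b) || length(a) == 0L) 0 else mean(a == b)
    before <- if (qs - len >= 1L) qseq[(qs - len):(qs - 1L)] else character(0)
    after_start <- qs + len
    after <- if (after_start + len - 1L <= length(qseq)) {
      qseq[after_start:(after_start + len - 1L)]
    } else character(0)
    is_dup <- ident(before, block) >= min_identity || ident(after, block) >= min_identity
    out <- rbind(out, data.frame(kind = if (is_dup) "duplication" else "insertion",
                                 ref_start = anchor, ref_end = anchor,
                                 length_bp = len))
  }
  out[order(out$ref_start), , drop = FALSE]
}

#' Full structural characterization of one element sequence
#'
#' Runs poly-A trimming, ORF detection with frameshift joining, translation
#' and zinc-finger motif detection, and applies a degeneracy heuristic: an
#' element is flagged degenerate (no conceptual translation) when no ORF is
#' found, when the ORF accumulates four or more disruptions (frameshifts
#' plus retained stops), or when it covers less than 45% of the trimmed
#' sequence.
#'
#' @param seq a single ungapped nucleotide string.
#' @param id optional element identifier carried into the output.
#' @param ... passed to [find_orf()].
#' @return an object of class `element_annotation`.
#' @export
characterize_element <- function(seq, id = NA_character_, ...) {
  trimmed <- trim_poly_a(seq)
  orf <- find_orf(trimmed$seq, ...)
  zf <- NULL
  degenerate <- TRUE
  if (!is.null(orf)) {
    n_disrupt <- length(orf$frameshift_positions) + length(orf$internal_stop_positions)
    degenerate <- n_disrupt >= 4L || orf$length_nt < 0.45 * nchar(trimmed$seq)
    if (nzchar(orf$protein)) zf <- detect_zinc_fingers(orf$protein)
  }
  structure(list(
    id = id,
    length_trimmed = nchar(trimmed$seq),
    poly_a_tail = trimmed$tail_length,
    orf = orf,
    zinc_fingers = zf,
    degenerate = degenerate
  ), class = "element_annotation")
}

#' @export
print.element_annotation <- function(x, ...) {
  cat("Element", x$id, "-", x$length_trimmed, "bp (poly-A tail",
      x$poly_a_tail, "nt)\n")
  if (is.null(x$orf)) {
    cat("  no ORF found\n")
  } else {
    cat(sprintf("  ORF %d-%d (%d bp), protein %d aa, %d frameshift(s), %d internal stop(s)\n",
                x$orf$start, x$orf$end, x$orf$length_nt, x$orf$protein_length_aa,
                length(x$orf$frameshift_positions), length(x$orf$internal_stop_positions)))
  }
  if (!is.null(x$zinc_fingers) && x$zinc_fingers$count > 0) {
    cat("  zinc fingers:", paste(x$zinc_fingers$motifs, collapse = " + "),
        "-> clade", x$zinc_fingers$clade, "\n")
  }
  cat("  degenerate:", x$degenerate, "\n")
  invisible(x)
}
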