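# Forward simulator of element evolution along a dated host phylogeny:
# per-site exact substitution simulation (JC or K2P), resident lineages
# splitting with their hosts, injected horizontal-transfer events (within- or
# cross-branch, with or without replacement of the resident), large
# deletions inherited as alignment gaps, tip-level degradation, and a full
# truth log.  Every pipeline stage can be validated against the truth
# without external data.

#' Simulation configuration
#'
#' @param host a `dated_host_tree` along which elements evolve.
#' @param rate substitution rate (substitutions/site/Myr, > 0).
#' @param seq_length element length in bp (>= 300).
#' @param model `"JC"` or `"K2P"`.
#' @param kappa transition/transversion rate ratio for K2P (default 2).
#' @param ht_events data.frame with columns `time` (Myr ago), `donor`,
#'   `recipient` (taxon label, or several labels joined with `+` naming a
#'   stem branch), `replace_resident` (logical) and optionally
#'   `donor_lineage` (index among the donor branch's lineages, default 1),
#'   `direction_constraint` (metadata:
#'   `paternal_to_maternal` / `maternal_to_paternal` / `unconstrained`).
#'   A donor equal to the recipient creates a new within-genome lineage
#'   (paralog birth).
#' @param lesions data.frame of inherited structural lesions: `time`,
#'   `where` (taxon/stem label as above), `lineage` (index), `kind`
#'   (currently `"deletion"`), `at`, `length`.
#' @param paralogs data.frame of ancient paralogous lineages: `taxon` (the
#'   only taxon retaining the lineage), `extra_myr` (divergence accumulated
#'   before the host root, in Myr at rate `rate`).
#' @param degradation tip-level degradation: data.frame with `element`
#'   (emitted element id), `n_frameshift`, `n_stop`, `deletions`,
#'   `duplications` (semicolon-separated lengths, may be empty),
#'   `degenerate` (flag copied to the mapping).
#' @param fragments data.frame `element`, `keep_bp` (5'-only coverage).
#' @param seed integer seed; the whole simulation is reproducible from it.
#' @return object of class `sim_config`.
#' @export
simulation_config <- function(host, rate = 0.004, seq_length = 3300,
                              model = c("JC", "K2P"), kappa = 2,
                              ht_events = NULL, lesions = NULL, paralogs = NULL,
                              degradation = NULL, fragments = NULL, seed = 1) {
  stopifnot(inherits(host, "dated_host_tree"))
  model <- match.arg(model)
  if (rate <= 0) stop("rate must be positive", call. = FALSE)
  if (seq_length < 300) stop("seq_length must be at least 300", call. = FALSE)
  norm_events <- function(ev) {
    if (is.null(ev) || NROW(ev) == 0) return(NULL)
    ev <- as.data.frame(ev)
    if (is.null(ev$donor_lineage)) ev$donor_lineage <- 1L
    if (is.null(ev$direction_constraint)) ev$direction_constraint <- "unconstrained"
    ev
  }
  cfg <- structure(list(host = host, rate = rate, seq_length = as.integer(seq_length),
                        model = model, kappa = kappa,
                        ht_events = norm_events(ht_events),
                        lesions = if (is.null(lesions)) NULL else as.data.frame(lesions),
                        paralogs = if (is.null(paralogs)) NULL else as.data.frame(paralogs),
                        degradation = if (is.null(degradation)) NULL else as.data.frame(degradation),
                        fragments = if (is.null(fragments)) NULL else as.data.frame(fragments),
                        seed = as.integer(seed)),
                   class = "sim_config")
  # validate event placement up front: each event time must fall strictly
  # inside both the donor and the recipient branch interval
  for (k in seq_len(NROW(cfg$ht_events))) {
    ev <- cfg$ht_events[k, ]
    .resolve_branch(host, ev$donor, ev$time)
    .resolve_branch(host, ev$recipient, ev$time)
  }
  for (k in seq_len(NROW(cfg$lesions))) {
    le <- cfg$lesions[k, ]
    .resolve_branch(host, le$where, le$time)
    if (le$at < 1 || le$at + le$length - 1 > seq_length) {
      stop("lesion exceeds sequence bounds", call. = FALSE)
    }
  }
  cfg
}

# branch (edge above `node`) whose subtree contains exactly/at least the given
# taxa and whose time interval contains `time`; most specific match wins
.resolve_branch <- function(host, taxa_spec, time) {
  phy <- host$phylo
  taxa <- strsplit(taxa_spec, "+", fixed = TRUE)[[1]]
  unknown <- setdiff(taxa, phy$tip.label)
  if (length(unknown) > 0) stop("unknown taxon in event: ", taxa_spec, call. = FALSE)
  ntip <- length(phy$tip.label)
  cands <- integer(0)
  for (node in phy$edge[, 2]) {
    tips <- if (node <= ntip) phy$tip.label[node] else ape::extract.clade(phy, node)$tip.label
    if (!all(taxa %in% tips)) next
    parent <- phy$edge[phy$edge[, 2] == node, 1]
    lo <- unname(host$ages[as.character(node)])
    hi <- unname(host$ages[as.character(parent)])
    if (time >= lo && time < hi) cands <- c(cands, node)
  }
  if (length(cands) == 0) {
    stop(sprintf("no branch for '%s' contains time %.3g Myr", taxa_spec, time), call. = FALSE)
  }
  sizes <- vapply(cands, function(n)
    if (n <= ntip) 1L else length(ape::extract.clade(phy, n)$tip.label), 0L)
  cands[which.min(sizes)]
}

.NT_IDX <- c(A = 1L, C = 2L, G = 3L, T = 4L)
.TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

# exact continuous-time substitution simulation on the ungapped sites;
# returns the sequence plus event and visible-change counts
.evolve <- function(chars, dt, rate, model, kappa) {
  if (dt <= 0) return(list(chars = chars, n_events = 0L, n_changes = 0L))
  sites <- which(chars %in% NT_ALPHABET)
  if (length(sites) == 0L) return(list(chars = chars, n_events = 0L, n_changes = 0L))
  k <- stats::rpois(length(sites), rate * dt)
  hit <- which(k > 0L)
  before <- chars
  for (h in hit) {
    pos <- sites[h]
    base <- chars[pos]
    for (j in seq_len(k[h])) {
      if (model == "JC") {
        base <- sample(setdiff(NT_ALPHABET, base), 1L)
      } else {
        if (stats::runif(1) < kappa / (kappa + 2)) {
          base <- unname(.TRANSITION[base])
        } else {
          base <- sample(setdiff(NT_ALPHABET, c(base, .TRANSITION[base])), 1L)
        }
      }
    }
    chars[pos] <- base
  }
  list(chars = chars, n_events = sum(k), n_changes = sum(chars != before))
}

#' Simulate element evolution along the host tree
#'
#' One resident element lineage enters at the root and splits with its
#' hosts; configured horizontal transfers copy the donor's current sequence
#' into the recipient branch at the event time (replacing the resident when
#' requested); inherited deletions become gap runs shared by all
#' descendants; tip sequences are then optionally degraded and truncated to
#' fragments.  Fully reproducible from the config seed.
#'
#' @param config a `sim_config`.
#' @param keep_sequences keep per-segment endpoint sequences in the truth
#'   log (for conservation checks; default FALSE).
#' @return list with `alignment` (character matrix, `-` for gaps/missing),
#'   `mapping` (data.frame: `element_id`, `taxon`, `lineage`, `degenerate`,
#'   `fragment`, `aligned_start`, `aligned_end`, `indel_profile`) and
#'   `truth` (list: `events`, `segments`, `degradation`, `config`).
#' @export
simulate_elements <- function(config, keep_sequences = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  host <- config$host; phy <- host$phylo
  ntip <- length(phy$tip.label)
  set.seed(config$seed)
  root <- ntip + 1L
  root_age <- unname(host$ages[as.character(root)])
  L <- config$seq_length

  lineage_n <- 0L
  new_lineage_id <- function(prefix = "L") {
    lineage_n <<- lineage_n + 1L
    paste0(prefix, lineage_n)
  }

  segments <- list()
  add_segment <- function(lineage, branch, t_from, t_to, ev, before, after) {
    segments[[length(segments) + 1L]] <<- data.frame(
      lineage = lineage, branch = branch, t_from = t_from, t_to = t_to,
      n_events = ev$n_events, n_changes = ev$n_changes,
      seq_from = if (keep_sequences) paste(before, collapse = "") else NA_character_,
      seq_to = if (keep_sequences) paste(after, collapse = "") else NA_character_)
  }
  evolve_instance <- function(inst, branch, t_to) {
    if (inst$t_last > t_to) {
      ev <- .evolve(inst$seq, inst$t_last - t_to, config$rate, config$model, config$kappa)
      add_segment(inst$id, branch, inst$t_last, t_to, ev, inst$seq, ev$chars)
      inst$seq <- ev$chars
      inst$t_last <- t_to
    }
    inst
  }

  root_seq <- sample(NT_ALPHABET, L, replace = TRUE)
  state <- new.env(parent = emptyenv())   # child-node id -> list of instances
  branch_label <- function(node) {
    if (node <= ntip) phy$tip.label[node]
    else paste(sort(ape::extract.clade(phy, node)$tip.label), collapse = "+")
  }
  subtree_tips <- function(node) {
    if (node <= ntip) phy$tip.label[node] else ape::extract.clade(phy, node)$tip.label
  }

  # founder lineage (plus any pre-diverged paralogs) enters at the root
  founders <- list(list(id = new_lineage_id(), seq = root_seq, t_last = root_age,
                        retain = NA_character_, profile = character(0)))
  for (k in seq_len(NROW(config$paralogs))) {
    pr <- config$paralogs[k, ]
    ev <- .evolve(root_seq, pr$extra_myr, config$rate, config$model, config$kappa)
    id <- new_lineage_id("P")
    add_segment(id, "stem", root_age + pr$extra_myr, root_age, ev, root_seq, ev$chars)
    founders[[length(founders) + 1L]] <- list(id = id, seq = ev$chars, t_last = root_age,
                                              retain = pr$taxon, profile = character(0))
  }
  for (child in phy$edge[phy$edge[, 1] == root, 2]) {
    inherit <- Filter(function(f) is.na(f$retain) || f$retain %in% subtree_tips(child),
                      founders)
    state[[as.character(child)]] <- inherit
  }

  agenda <- data.frame(time = numeric(0), type = character(0), idx = integer(0))
  internal <- setdiff(seq.int(ntip + 1L, ntip + phy$Nnode), root)
  if (length(internal) > 0) {
    agenda <- rbind(agenda, data.frame(time = unname(host$ages[as.character(internal)]),
                                       type = "spec", idx = internal))
  }
  for (k in seq_len(NROW(config$ht_events))) {
    agenda <- rbind(agenda, data.frame(time = config$ht_events$time[k], type = "ht", idx = k))
  }
  for (k in seq_len(NROW(config$lesions))) {
    agenda <- rbind(agenda, data.frame(time = config$lesions$time[k], type = "lesion", idx = k))
  }
  agenda <- agenda[order(-agenda$time, agenda$type, agenda$idx), , drop = FALSE]

  events_log <- list()
  for (r in seq_len(nrow(agenda))) {
    a <- agenda[r, ]
    if (a$type == "spec") {
      node <- a$idx
      key <- as.character(node)
      inst <- lapply(state[[key]], evolve_instance, branch = branch_label(node), t_to = a$time)
      for (child in phy$edge[phy$edge[, 1] == node, 2]) {
        inherit <- Filter(function(f) is.na(f$retain) || f$retain %in% subtree_tips(child), inst)
        state[[as.character(child)]] <- inherit
      }
      state[[key]] <- NULL
    } else if (a$type == "ht") {
      ev <- config$ht_events[a$idx, ]
      dnode <- .resolve_branch(host, ev$donor, ev$time)
      rnode <- .resolve_branch(host, ev$recipient, ev$time)
      dkey <- as.character(dnode); rkey <- as.character(rnode)
      dls <- state[[dkey]]
      if (is.null(dls) || length(dls) < ev$donor_lineage) {
        stop("donor branch has no lineage ", ev$donor_lineage, " at time ", ev$time,
             call. = FALSE)
      }
      dls[[ev$donor_lineage]] <- evolve_instance(dls[[ev$donor_lineage]],
                                                 branch_label(dnode), ev$time)
      state[[dkey]] <- dls
      donor_inst <- dls[[ev$donor_lineage]]
      new_id <- new_lineage_id()
      new_inst <- list(id = new_id, seq = donor_inst$seq, t_last = ev$time,
                       retain = NA_character_, profile = donor_inst$profile)
      replaced <- character(0)
      rls <- if (dkey == rkey) state[[rkey]] else state[[rkey]] %||% list()
      if (isTRUE(ev$replace_resident)) {
        rls <- lapply(rls, evolve_instance, branch = branch_label(rnode), t_to = ev$time)
        replaced <- vapply(rls, `[[`, "", "id")
        rls <- list()
      }
      rls[[length(rls) + 1L]] <- new_inst
      state[[rkey]] <- rls
      events_log[[length(events_log) + 1L]] <- data.frame(
        time = ev$time, donor = ev$donor, recipient = ev$recipient,
        donor_lineage = donor_inst$id, new_lineage = new_id,
        replace_resident = isTRUE(ev$replace_resident),
        replaced = paste(replaced, collapse = ";"),
        direction_constraint = ev$direction_constraint)
    } else {  # lesion
      le <- config$lesions[a$idx, ]
      node <- .resolve_branch(host, le$where, le$time)
      key <- as.character(node)
      ls <- state[[key]]
      if (is.null(ls) || length(ls) < le$lineage) {
        stop("lesion target lineage missing on branch ", le$where, call. = FALSE)
      }
      inst <- evolve_instance(ls[[le$lineage]], branch_label(node), le$time)
      span <- seq.int(le$at, le$at + le$length - 1L)
      inst$seq[span] <- "-"
      inst$profile <- c(inst$profile,
                        sprintf("del:%d-%d", le$at, le$at + le$length - 1L))
      ls[[le$lineage]] <- inst
      state[[key]] <- ls
    }
  }

  # reach the present on every tip branch and emit elements
  aln_rows <- list(); map_rows <- list()
  for (tip in seq_len(ntip)) {
    key <- as.character(tip)
    for (inst in state[[key]] %||% list()) {
      inst <- evolve_instance(inst, branch_label(tip), 0)
      el <- paste0(phy$tip.label[tip], ".", inst$id)
      aln_rows[[el]] <- inst$seq
      map_rows[[el]] <- data.frame(element_id = el, taxon = phy$tip.label[tip],
                                   lineage = inst$id, degenerate = FALSE,
                                   fragment = FALSE, aligned_start = 1L,
                                   aligned_end = L,
                                   indel_profile = paste(inst$profile, collapse = ";"))
    }
  }
  alignment <- do.call(rbind, aln_rows)
  mapping <- do.call(rbind, map_rows)
  rownames(mapping) <- NULL

  # tip-level degradation and fragment truncation
  degradation_log <- list()
  insertions <- list()
  for (k in seq_len(NROW(config$degradation))) {
    dg <- config$degradation[k, ]
    el <- dg$element
    if (!el %in% rownames(alignment)) stop("degradation target not emitted: ", el, call. = FALSE)
    row <- alignment[el, ]
    live <- which(row != "-")
    parse_lens <- function(x) {
      if (is.null(x) || is.na(x) || !nzchar(as.character(x))) integer(0)
      else as.integer(strsplit(as.character(x), ";", fixed = TRUE)[[1]])
    }
    for (len in parse_lens(dg$deletions)) {
      start <- sample(seq_len(length(live) - len), 1L)
      cols <- live[start:(start + len - 1L)]
      row[cols] <- "-"
      live <- which(row != "-")
      sig <- sprintf("del:%d-%d", min(cols), max(cols))
      mapping$indel_profile[mapping$element_id == el] <-
        paste(c(Filter(nzchar, mapping$indel_profile[mapping$element_id == el]), sig),
              collapse = ";")
      degradation_log[[length(degradation_log) + 1L]] <-
        data.frame(element = el, kind = "deletion", at = min(cols), length = len)
    }
    n_fs <- if (is.null(dg$n_frameshift) || is.na(dg$n_frameshift)) 0L else dg$n_frameshift
    for (j in seq_len(n_fs)) {
      pos <- live[sample(length(live), 1L)]
      row[pos] <- "-"
      live <- which(row != "-")
      degradation_log[[length(degradation_log) + 1L]] <-
        data.frame(element = el, kind = "frameshift", at = pos, length = 1L)
    }
    n_stop <- if (is.null(dg$n_stop) || is.na(dg$n_stop)) 0L else dg$n_stop
    for (j in seq_len(n_stop)) {
      start <- sample(length(live) - 2L, 1L)
      row[live[start:(start + 2L)]] <- c("T", "A", "A")
      degradation_log[[length(degradation_log) + 1L]] <-
        data.frame(element = el, kind = "stop", at = live[start], length = 3L)
    }
    for (len in parse_lens(dg$duplications)) {
      start <- sample(seq_len(length(live) - len), 1L)
      cols <- live[start:(start + len - 1L)]
      insertions[[length(insertions) + 1L]] <-
        list(element = el, after_col = max(cols), content = row[cols])
      degradation_log[[length(degradation_log) + 1L]] <-
        data.frame(element = el, kind = "duplication", at = min(cols), length = len)
    }
    alignment[el, ] <- row
    if (isTRUE_vec(dg$degenerate)) mapping$degenerate[mapping$element_id == el] <- TRUE
  }
  # expand alignment for tandem-duplication insertions (gap in other rows)
  if (length(insertions) > 0) {
    for (ins in insertions[order(-vapply(insertions, `[[`, 0, "after_col"))]) {
      block <- matrix("-", nrow(alignment), length(ins$content))
      rownames(block) <- rownames(alignment)
      block[ins$element, ] <- ins$content
      alignment <- cbind(alignment[, seq_len(ins$after_col), drop = FALSE], block,
                         alignment[, -seq_len(ins$after_col), drop = FALSE])
    }
    mapping$aligned_end <- ncol(alignment)
  }
  for (k in seq_len(NROW(config$fragments))) {
    fr <- config$fragments[k, ]
    el <- fr$element
    if (!el %in% rownames(alignment)) stop("fragment target not emitted: ", el, call. = FALSE)
    keep <- min(fr$keep_bp, ncol(alignment))
    alignment[el, seq.int(keep + 1L, ncol(alignment))] <- "-"
    mapping$fragment[mapping$element_id == el] <- TRUE
    mapping$aligned_end[mapping$element_id == el] <- keep
  }

  truth <- list(
    events = if (length(events_log) > 0) do.call(rbind, events_log) else
      data.frame(time = numeric(0), donor = character(0), recipient = character(0)),
    segments = do.call(rbind, segments),
    degradation = if (length(degradation_log) > 0) do.call(rbind, degradation_log) else
      data.frame(element = character(0), kind = character(0)),
    config = config
  )
  list(alignment = alignment, mapping = mapping, truth = truth)
}

#' Degrade an element sequence in place
#'
#' Applies, in order: large deletions, 1-bp frameshift indels, premature
#' stop codons (`TAA` written over three bases) and tandem duplications, at
#' uniformly drawn positions.  This is the ungapped single-sequence
#' counterpart of the degradation the simulator applies in alignment
#' coordinates; it is the oracle for length arithmetic (a 426-bp deletion
#' shortens the element by exactly 426 bp).
#'
#' @param seq single ungapped nucleotide string.
#' @param n_frameshift number of 1-bp deletions.
#' @param n_stop number of premature stop codons.
#' @param deletion_lengths integer vector of deletion lengths (bp).
#' @param duplication_lengths integer vector of tandem-duplication unit
#'   lengths (bp).
#' @param seed optional seed.
#' @return list with `seq` (degraded string) and `log` (data.frame `kind`,
#'   `at`, `length`; coordinates refer to the sequence state at the time
#'   each lesion is applied).
#' @export
degrade_element <- function(seq, n_frameshift = 0, n_stop = 0,
                            deletion_lengths = integer(0),
                            duplication_lengths = integer(0), seed = NULL) {
  if (is_gapped(seq)) stop("`seq` must be ungapped", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  x <- seq_chars(toupper(seq))
  log <- data.frame(kind = character(0), at = integer(0), length = integer(0))
  for (len in deletion_lengths) {
    if (len >= length(x)) stop("deletion longer than sequence", call. = FALSE)
    at <- sample(length(x) - len, 1L)
    x <- x[-seq.int(at, at + len - 1L)]
    log <- rbind(log, data.frame(kind = "deletion", at = at, length = len))
  }
  for (j in seq_len(n_frameshift)) {
    at <- sample(length(x), 1L)
    x <- x[-at]
    log <- rbind(log, data.frame(kind = "frameshift", at = at, length = 1L))
  }
  for (j in seq_len(n_stop)) {
    at <- sample(length(x) - 2L, 1L)
    x[at:(at + 2L)] <- c("T", "A", "A")
    log <- rbind(log, data.frame(kind = "stop", at = at, length = 3L))
  }
  for (len in duplication_lengths) {
    if (len > length(x)) stop("duplication unit longer than sequence", call. = FALSE)
    at <- sample(length(x) - len + 1L, 1L)
    block <- x[at:(at + len - 1L)]
    x <- append(x, block, after = at + len - 1L)
    log <- rbind(log, data.frame(kind = "duplication", at = at, length = len))
  }
  list(seq = paste(x, collapse = ""), log = log)
}

#' Synthetic data set emulating the published nine-element survey
#'
#' Simulates nine elements over the bundled five-taxon host tree with the
#' qualitative structure of the published survey: a vertical backbone, one
#' ancient within-genome paralogous lineage (median divergence > 0.5), one
#' heavily degraded (degenerate) element, two horizontal transfers (one
#' from the basal taxon into the island-subspecies stem with replacement of
#' the resident, one back from an island subspecies very recently), a large
#' deletion shared across the second transfer, and one 5'-only fragment.
#' Element names follow the published survey's naming so the synthetic set
#' can be run through the same reporting; the sequences themselves are
#' simulated, not the deposited ones.
#'
#' @param seed integer seed (default 1).
#' @param keep_sequences passed to [simulate_elements()].
#' @return list as [simulate_elements()], with renamed elements.
#' @export
paper_like_fixture <- function(seed = 1, keep_sequences = FALSE) {
  host <- read_host_tree(system.file("extdata", "bacillus_host_tree.nwk",
                                     package = "rthx"))
  cfg <- simulation_config(
    host = host, rate = 0.004, seq_length = 3300, model = "JC",
    ht_events = data.frame(
      time = c(12, 5, 1.4, 1.0),
      donor = c("rossius", "rossius", "maretimi", "maretimi"),
      recipient = c("rossius", "benazzii+maretimi", "maretimi", "rossius"),
      donor_lineage = c(1L, 1L, 1L, 2L),
      replace_resident = c(FALSE, TRUE, FALSE, FALSE)),
    lesions = data.frame(time = 1.2, where = "maretimi", lineage = 2L,
                         kind = "deletion", at = 1035, length = 426),
    paralogs = data.frame(taxon = "grandii_grandii", extra_myr = 202),
    degradation = data.frame(
      element = c("grandii_grandii.L1", "maretimi.L4", "grandii_grandii.P2",
                  "rossius.L3"),
      n_frameshift = c(1L, 1L, 1L, 3L),
      n_stop = c(0L, 0L, 2L, 3L),
      deletions = "", duplications = "",
      degenerate = c(FALSE, FALSE, FALSE, TRUE)),
    fragments = data.frame(element = "rossius.L6", keep_bp = 1720L),
    seed = seed)
  sim <- simulate_elements(cfg, keep_sequences = keep_sequences)
  name_map <- c(atticus.L1 = "R2Ba", grandii_grandii.L1 = "R2BggA",
                grandii_grandii.P2 = "R2BggB", benazzii.L4 = "R2Bgb",
                maretimi.L4 = "R2Bgm", maretimi.L5 = "R2Bgmdel",
                rossius.L1 = "R2Brfun", rossius.L3 = "R2Brdeg",
                rossius.L6 = "R2Brdel")
  old <- rownames(sim$alignment)
  if (!setequal(old, names(name_map))) {
    stop("fixture lineage layout changed; emitted: ", paste(old, collapse = ", "),
         call. = FALSE)
  }
  rownames(sim$alignment) <- unname(name_map[old])
  sim$mapping$element_id <- unname(name_map[sim$mapping$element_id])
  sim$truth$ht_pairs <- data.frame(
    element_a = c("R2Bgb", "R2Bgm", "R2Bgmdel", "R2Bgb", "R2Bgm", "R2Bgmdel"),
    element_b = c(rep("R2Brfun", 3), rep("R2Brdel", 3)))
  sim
}
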