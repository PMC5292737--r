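# Orchestration and I/O: the published-table distance format, the
# end-to-end pipeline and its report files.

#' Read a published-layout p-distance table
#'
#' Parses a CSV in the layout of the published distance table: element
#' labels as first column and header; nucleotide values below the
#' diagonal with amino-acid values in parentheses, standard errors above
#' the diagonal in the same `nt (aa)` form; `n/c` marks a distance that
#' was not computed (e.g. amino-acid comparisons with a degenerate
#' element).
#'
#' @param path CSV file path.
#' @return list with `nt` and `aa` `pdist_matrix` objects (site counts are
#'   unknown for published tables and left `NULL`).
#' @export
read_table1_fixture <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(raw[[1]])
  if (!identical(labels, names(raw)[-1])) {
    stop("asymmetric labels: rows and columns must list the same elements in order",
         call. = FALSE)
  }
  n <- length(labels)
  cell <- function(i, j) as.character(raw[i, j + 1L])
  parse_cell <- function(x) {
    x <- trimws(x)
    if (!nzchar(x)) return(c(NA_real_, NA_real_))
    m <- regmatches(x, regexec("^([0-9.]+|n/c)\\s*(?:\\(([0-9.]+|n/c)\\))?$", x))[[1]]
    if (length(m) == 0) stop("cannot parse table cell: '", x, "'", call. = FALSE)
    num <- function(v) if (v == "n/c" || !nzchar(v)) NA_real_ else as.numeric(v)
    c(num(m[2]), num(m[3]))
  }
  d_nt <- matrix(0, n, n, dimnames = list(labels, labels))
  d_aa <- d_nt; se_nt <- d_nt; se_aa <- d_nt
  nc_aa <- matrix(character(0), ncol = 2)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    v <- parse_cell(cell(i, j))
    if (i > j) {          # below diagonal: distances
      d_nt[i, j] <- d_nt[j, i] <- v[1]
      d_aa[i, j] <- d_aa[j, i] <- v[2]
      if (is.na(v[2])) nc_aa <- rbind(nc_aa, sort(c(labels[i], labels[j])))
    } else {              # above diagonal: standard errors
      se_nt[i, j] <- se_nt[j, i] <- v[1]
      se_aa[i, j] <- se_aa[j, i] <- v[2]
    }
  }
  nc_aa <- nc_aa[!duplicated(paste(nc_aa[, 1], nc_aa[, 2])), , drop = FALSE]
  list(nt = pdist_matrix(d_nt, se = se_nt, mode = "nt"),
       aa = pdist_matrix(d_aa, se = se_aa, mode = "aa", not_computed = nc_aa))
}

#' Write a pair of distance matrices in the published table layout
#'
#' Inverse of [read_table1_fixture()]: distances below the diagonal,
#' standard errors above, amino-acid values in parentheses, `n/c` for
#' not-computed pairs; values rounded to three decimals, half up.
#'
#' @param nt,aa `pdist_matrix` objects over the same labels.
#' @param path output CSV path.
#' @export
write_table1 <- function(nt, aa, path) {
  stopifnot(identical(nt$labels, aa$labels))
  labels <- nt$labels
  n <- length(labels)
  fmt <- function(x) if (is.na(x)) "n/c" else sprintf("%.3f", round_half_up(x, 3))
  out <- matrix("", n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (i > j) {
      out[i, j] <- sprintf("%s (%s)", fmt(nt$d[i, j]), fmt(aa$d[i, j]))
    } else {
      se_n <- if (is.null(nt$se)) NA_real_ else nt$se[i, j]
      se_a <- if (is.null(aa$se) || is.na(aa$d[i, j])) NA_real_ else aa$se[i, j]
      out[i, j] <- sprintf("%s (%s)", fmt(se_n), fmt(se_a))
    }
  }
  df <- data.frame(label = labels, out, check.names = FALSE)
  names(df) <- c("", labels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Paths to the bundled published-survey inputs
#'
#' The published distance table (transcribed), the dated host phylogeny and
#' the element-to-taxon mapping for the nine-element survey.
#'
#' @return named list of file paths.
#' @export
bacillus_files <- function() {
  list(
    distances = system.file("extdata", "table1_pdistances.csv", package = "rthx"),
    host_tree = system.file("extdata", "bacillus_host_tree.nwk", package = "rthx"),
    mapping = system.file("extdata", "bacillus_elements.csv", package = "rthx")
  )
}

#' Run the full horizontal-transfer detection pipeline
#'
#' Runs, in order: distance-matrix construction (or loading), the
#' divergence-versus-age regression, candidate flagging and taxon-level
#' exclusion refit, lineage partitioning with the shared-indel rule,
#' patchy-distribution tests, element-tree inference (with bootstrap when
#' an alignment is available), element/host topology conflicts, and
#' minimal event reconstruction.  Every stage error is reported with its
#' stage name.
#'
#' @param distances list with `nt` (and optionally `aa`) `pdist_matrix`
#'   objects, or a path to a published-layout CSV; ignored when
#'   `alignment` is given.
#' @param mapping data.frame or CSV path with `element_id`, `taxon` and
#'   optional `degenerate`, `fragment`, `indel_profile` columns.
#' @param host `dated_host_tree`, Newick text or file path.
#' @param alignment optional aligned FASTA path / matrix of nucleotide
#'   sequences; when given, distances and bootstrap supports are computed
#'   from it.
#' @param exclude optional explicit exclusion pairs for the refit
#'   (two-column data.frame); defaults to the taxon-level expansion of the
#'   flagged candidates.
#' @param calibrations optional data.frame (`tip_a`, `tip_b`, `age_myr`)
#'   for element-tree dating.
#' @param t_flag,min_rel_deficit,flag_method passed to [flag_candidates()].
#' @param lineage_threshold divergence cutoff for [assign_lineages()].
#' @param paralog_cutoff,include_degenerate,include_intra_taxon passed to
#'   [assemble_points()].
#' @param bootstrap_reps bootstrap replicates (0 to skip; only used with an
#'   alignment).
#' @param seed integer seed for the bootstrap.
#' @param out_dir optional output directory; when given, writes
#'   `points.csv`, `regression.json`, `events.json` and `report.md`.
#' @return object of class `ht_report` (list of all stage results).
#' @export
run_pipeline <- function(distances = NULL, mapping, host, alignment = NULL,
                         exclude = NULL, calibrations = NULL,
                         t_flag = 1.3, min_rel_deficit = 0.25,
                         flag_method = "robust",
                         lineage_threshold = 0.01, paralog_cutoff = 0.5,
                         include_degenerate = FALSE, include_intra_taxon = FALSE,
                         bootstrap_reps = 100, seed = 1, out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  host <- stage("host_model", {
    if (inherits(host, "dated_host_tree")) host else read_host_tree(host)
  })
  mapping <- stage("mapping", {
    m <- if (is.character(mapping) && length(mapping) == 1L) {
      utils::read.csv(mapping, stringsAsFactors = FALSE)
    } else as.data.frame(mapping)
    stopifnot(all(c("element_id", "taxon") %in% names(m)))
    m
  })

  dms <- stage("distances", {
    if (!is.null(alignment)) {
      aln <- as_alignment_matrix(alignment)
      list(nt = build_distance_matrix(aln, mode = "nt"), aa = NULL, alignment = aln)
    } else if (is.character(distances) && length(distances) == 1L) {
      c(read_table1_fixture(distances), list(alignment = NULL))
    } else if (is.list(distances)) {
      list(nt = distances$nt, aa = distances$aa, alignment = NULL)
    } else {
      stop("either `alignment` or `distances` must be supplied")
    }
  })

  points <- stage("assemble_points", assemble_points(
    dms$nt, mapping, host, aa_dm = dms$aa,
    include_intra_taxon = include_intra_taxon,
    paralog_cutoff = paralog_cutoff, include_degenerate = include_degenerate))

  fit_all <- stage("regression", fit_divergence_age(points, response = "nt"))
  flagged <- stage("flagging", flag_candidates(
    points, response = "nt", method = flag_method,
    t_flag = t_flag, min_rel_deficit = min_rel_deficit))
  excl <- if (!is.null(exclude)) normalize_pairs(exclude) else
    ht_exclusion_pairs(points, flagged)
  fit_excl <- stage("regression_refit", {
    if (NROW(excl) > 0) fit_divergence_age(points, response = "nt", exclude = excl)
    else fit_all
  })
  fits_aa <- NULL
  if (!is.null(dms$aa) && sum(!is.na(points$points$d_aa)) >= 3) {
    fits_aa <- stage("regression_aa", list(
      all = fit_divergence_age(points, response = "aa"),
      excluded = if (NROW(excl) > 0)
        fit_divergence_age(points, response = "aa", exclude = excl)
      else fit_divergence_age(points, response = "aa")))
  }

  profiles <- stage("lineages", {
    p <- if ("indel_profile" %in% names(mapping)) {
      stats::setNames(as.list(mapping$indel_profile), mapping$element_id)
    } else NULL
    # only ancient paralogs leave the lineage/tree analyses; degenerate
    # elements keep their nucleotide distances
    kept <- setdiff(dms$nt$labels,
                    points$excluded$element[points$excluded$reason == "paralog"])
    sub <- dms$nt$d[kept, kept, drop = FALSE]
    assign_lineages(pdist_matrix(sub, mode = "nt"), indel_profiles = p,
                    threshold = lineage_threshold)
  })
  patchy <- stage("patchiness", vapply(profiles$blocks, patchy_distribution,
                                       TRUE, mapping = mapping, host = host))

  etree <- stage("treebuild", {
    kept <- setdiff(dms$nt$labels,
                    points$excluded$element[points$excluded$reason == "paralog"])
    if (length(kept) >= 3) {
      if (!is.null(dms$alignment) && bootstrap_reps > 0) {
        bootstrap_supports(dms$alignment[kept, , drop = FALSE],
                           n_reps = bootstrap_reps, seed = seed)
      } else {
        sub <- dms$nt$d[kept, kept, drop = FALSE]
        neighbor_joining(pdist_matrix(sub, mode = "nt"))
      }
    } else NULL
  })
  dated <- stage("calibration", {
    if (!is.null(etree) && !is.null(calibrations)) {
      ok <- all(unlist(calibrations[, c("tip_a", "tip_b")]) %in% etree$phylo$tip.label)
      if (ok) calibrate_ages(etree, calibrations) else etree
    } else etree
  })
  conflicts <- stage("topology_conflicts", {
    if (!is.null(etree)) topology_conflicts(etree, host, mapping) else NULL
  })
  events <- stage("reconstruct_events", {
    if (!is.null(etree)) {
      reconstruct_events(flagged, profiles, dated %||% etree, host, mapping,
                         conflicts = conflicts)
    } else structure(list(), class = "ht_events")
  })

  report <- structure(list(
    points = points, fit_all = fit_all, fit_excluded = fit_excl,
    fits_aa = fits_aa, flagged = flagged, exclusion = excl,
    lineages = profiles, patchy = patchy, element_tree = dated,
    conflicts = conflicts, events = events,
    params = list(t_flag = t_flag, min_rel_deficit = min_rel_deficit,
                  flag_method = flag_method, lineage_threshold = lineage_threshold,
                  paralog_cutoff = paralog_cutoff, bootstrap_reps = bootstrap_reps,
                  seed = seed)
  ), class = "ht_report")
  if (!is.null(out_dir)) write_ht_report(report, out_dir)
  report
}

#' @export
print.ht_report <- function(x, ...) {
  cat("== divergence vs host split age ==\n")
  print(x$fit_all)
  cat(sprintf("after excluding %d pair(s):\n", NROW(x$exclusion)))
  print(x$fit_excluded)
  cat(sprintf("\n== %d flagged pair(s) below the trend ==\n", NROW(x$flagged)))
  if (NROW(x$flagged) > 0) print(x$flagged, row.names = FALSE)
  cat("\n== lineages ==\n")
  print(x$lineages)
  if (any(x$patchy)) {
    for (k in which(x$patchy)) {
      cat("patchy distribution: {", paste(x$lineages$blocks[[k]], collapse = ", "), "}\n")
    }
  }
  if (!is.null(x$conflicts) && NROW(x$conflicts$conflicts) > 0) {
    cat("\n== element/host topology conflicts ==\n")
    print(unique(x$conflicts$conflicts[, c("host_split", "support")]), row.names = FALSE)
  }
  cat("\n")
  print(x$events)
  invisible(x)
}

#' Write the pipeline report files
#'
#' Emits `points.csv` (the divergence-versus-age set), `regression.json`
#' (both fits and the flagging parameters), `events.json` and a Markdown
#' `report.md` summarising the run.
#'
#' @param report an `ht_report`.
#' @param out_dir directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_ht_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$points$points, file.path(out_dir, "points.csv"),
                   row.names = FALSE)
  fit_fields <- function(f) f[c("slope", "intercept", "r_squared", "pearson_r",
                                "p_value", "n_points")]
  jsonlite::write_json(list(
    all_pairs = fit_fields(report$fit_all),
    excluded = fit_fields(report$fit_excluded),
    n_excluded_pairs = NROW(report$exclusion),
    params = report$params
  ), file.path(out_dir, "regression.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(lapply(unclass(report$events), function(e) list(
    donor_taxa = e$donor_taxa, recipient_taxa = e$recipient_taxa,
    anchor = e$anchor, partners = e$partners,
    supporting_pairs = e$supporting_pairs,
    age_bound_myr = e$age_bound_myr, criteria = as.list(e$criteria)
  )), file.path(out_dir, "events.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  md <- c(
    "# Horizontal-transfer detection report", "",
    sprintf("- pairs: %d; ages (Myr): %s", nrow(report$points$points),
            paste(sort(unique(report$points$points$age_myr)), collapse = ", ")),
    sprintf("- all-pairs R^2 = %.3f (p = %.3g)", report$fit_all$r_squared,
            report$fit_all$p_value),
    sprintf("- refit R^2 after excluding %d pairs = %.3f (p = %.3g)",
            NROW(report$exclusion), report$fit_excluded$r_squared,
            report$fit_excluded$p_value),
    sprintf("- flagged pairs: %d", NROW(report$flagged)),
    if (NROW(report$flagged) > 0)
      paste0("  - ", report$flagged$element_a, " / ", report$flagged$element_b,
             " (age ", report$flagged$age_myr, " Myr, d = ", report$flagged$d, ")"),
    sprintf("- reconstructed events: %d", length(report$events)),
    unlist(lapply(seq_along(report$events), function(k) {
      e <- report$events[[k]]
      sprintf("  - event %d: %s -> %s; %d supporting pairs; criteria (i) %s, (ii) %s, (iii) %s",
              k, paste(e$donor_taxa, collapse = "/"),
              paste(e$recipient_taxa, collapse = "/"), nrow(e$supporting_pairs),
              e$criteria["low_divergence"], e$criteria["incongruence"],
              e$criteria["patchy"])
    })))
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(out_dir)
}
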