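test_that("point assembly applies the inclusion rules of the published analysis", {
  inputs <- bacillus_inputs()
  pts <- suppressMessages(assemble_points(inputs$dm$nt, inputs$mapping, inputs$host,
                                          aa_dm = inputs$dm$aa))
  # 9 elements minus the ancient paralog and the degenerate one ->
  # 7 elements, 21 pairs, minus 2 intra-taxon pairs
  expect_equal(nrow(pts$points), 19L)
  expect_setequal(unique(pts$points$age_myr), c(2, 15.4, 17, 22.8))
  expect_setequal(pts$excluded$element, c("R2BggB", "R2Brdeg"))
  # amino-acid distances ride along where computed
  expect_equal(sum(!is.na(pts$points$d_aa)), 19L)

  all24 <- suppressMessages(assemble_points(inputs$dm$nt, inputs$mapping, inputs$host,
                                            include_degenerate = TRUE))
  expect_equal(nrow(all24$points), 24L)

  intra <- suppressMessages(assemble_points(inputs$dm$nt, inputs$mapping, inputs$host,
                                            include_intra_taxon = TRUE))
  expect_equal(nrow(intra$points), 19L + 2L)
  expect_true(all(intra$points$age_myr[intra$points$taxon_a == intra$points$taxon_b] == 0))

  bad_map <- inputs$mapping[-1, ]
  expect_error(assemble_points(inputs$dm$nt, bad_map, inputs$host), "without a host-taxon")
})

test_that("the regression matches a first-principles sums-of-squares computation", {
  for (seed in 1:5) {
    set.seed(seed)
    df <- data.frame(element_a = letters[1:12], element_b = LETTERS[1:12],
                     taxon_a = "t1", taxon_b = "t2",
                     age_myr = runif(12, 1, 25))
    df$d_nt <- 0.01 * df$age_myr + rnorm(12, 0, 0.02)
    df$d_aa <- NA_real_
    fit <- fit_divergence_age(df)
    oracle <- ols_oracle(df$age_myr, df$d_nt)
    expect_equal(fit$slope, oracle$slope, tolerance = 1e-12)
    expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-12)
    expect_equal(fit$r_squared, oracle$r2, tolerance = 1e-12)
    expect_equal(fit$pearson_r, oracle$r, tolerance = 1e-12)
  }
})

test_that("collinear points give R^2 = 1 and no flags", {
  df <- data.frame(element_a = letters[1:6], element_b = LETTERS[1:6],
                   taxon_a = "t1", taxon_b = "t2",
                   age_myr = c(2, 5, 9, 14, 18, 22))
  df$d_nt <- 0.004 * df$age_myr
  df$d_aa <- NA_real_
  fit <- fit_divergence_age(df)
  expect_equal(fit$r_squared, 1)
  expect_lt(fit$p_value, 1e-6)
  expect_equal(nrow(flag_candidates(df)), 0L)
  expect_error(fit_divergence_age(df[1:2, ]), "at least 3")
})

test_that("the published matrix reproduces the printed regression contrast", {
  inputs <- bacillus_inputs()
  pts <- suppressMessages(assemble_points(inputs$dm$nt, inputs$mapping, inputs$host,
                                          aa_dm = inputs$dm$aa))
  fit_all <- fit_divergence_age(pts)
  expect_equal(fit_all$r_squared, 0.034, tolerance = 0.01)
  expect_gt(fit_all$p_value, 0.05)           # not significant

  flagged <- flag_candidates(pts)
  excl <- ht_exclusion_pairs(pts, flagged)
  fit_ex <- fit_divergence_age(pts, exclude = excl)
  expect_equal(fit_ex$r_squared, 0.796, tolerance = 0.01)
  expect_lt(fit_ex$p_value, 0.001)
  # pruning the flagged pairs never lowers the fit
  expect_gt(fit_ex$r_squared, fit_all$r_squared)

  # amino-acid analysis shows the same contrast
  fit_aa <- fit_divergence_age(pts, response = "aa")
  fit_aa_ex <- fit_divergence_age(pts, response = "aa", exclude = excl)
  expect_equal(fit_aa$r_squared, 0.041, tolerance = 0.01)
  expect_equal(fit_aa_ex$r_squared, 0.796, tolerance = 0.01)
})

test_that("exactly the six published pairs are flagged as transfer candidates", {
  inputs <- bacillus_inputs()
  pts <- suppressMessages(assemble_points(inputs$dm$nt, inputs$mapping, inputs$host))
  flagged <- flag_candidates(pts)
  got <- sort(paste(flagged$element_a, flagged$element_b, sep = "/"))
  expect_equal(got, sort(c("R2Bgb/R2Brfun", "R2Bgb/R2Brdel", "R2Bgm/R2Brfun",
                           "R2Bgm/R2Brdel", "R2Bgmdel/R2Brfun", "R2Bgmdel/R2Brdel")))
  # only pairs below the trend are ever flagged
  expect_true(all(flagged$stat < 0))
})

test_that("taxon-level exclusion covers all pairs between implicated taxa", {
  inputs <- bacillus_inputs()
  pts <- suppressMessages(assemble_points(inputs$dm$nt, inputs$mapping, inputs$host))
  flagged <- flag_candidates(pts)
  expect_equal(NROW(ht_exclusion_pairs(pts, flagged)), 6L)
  # with the degenerate element retained, its comparisons against the same
  # taxa are excluded too
  pts24 <- suppressMessages(assemble_points(inputs$dm$nt, inputs$mapping, inputs$host,
                                            include_degenerate = TRUE))
  expect_equal(NROW(ht_exclusion_pairs(pts24, flagged)), 9L)
  expect_equal(NROW(ht_exclusion_pairs(pts, flagged[0, ])), 0L)
})

test_that("alternative flagging methods expose their documented knobs", {
  set.seed(3)
  df <- data.frame(element_a = letters[1:10], element_b = LETTERS[1:10],
                   taxon_a = "t1", taxon_b = "t2",
                   age_myr = rep(c(5, 10, 15, 20, 25), each = 2))
  df$d_nt <- 0.008 * df$age_myr + rnorm(10, 0, 3e-4)
  df$d_nt[10] <- 0.01                        # far below its age class
  df$d_aa <- NA_real_
  it <- flag_candidates(df, method = "iterative", t_iter = 2)
  # the engineered outlier is by far the most extreme flagged pair
  expect_equal(paste(it$element_a[1], it$element_b[1]), "j J")
  expect_lt(it$stat[1], -100)
  ac <- flag_candidates(df, method = "age_class", f_age = 0.5)
  expect_equal(paste(ac$element_a, ac$element_b), "j J")
})

test_that("lineage partition combines the 1% rule with shared large indels", {
  inputs <- bacillus_inputs()
  kept <- setdiff(inputs$dm$nt$labels, "R2BggB")
  sub <- pdist_matrix(inputs$dm$nt$d[kept, kept], mode = "nt")
  prof <- stats::setNames(as.list(inputs$mapping$indel_profile),
                          inputs$mapping$element_id)
  lin <- assign_lineages(sub, indel_profiles = prof)
  blk <- lin$blocks[[which(vapply(lin$blocks, function(b) "R2Brdel" %in% b, TRUE))]]
  # same lineage despite crossing host taxa: d = 0.010 and shared deletion
  expect_setequal(blk, c("R2Bgmdel", "R2Brdel"))
  # d = 0.009 to R2Bgm but no shared deletion: different lineage
  expect_false("R2Bgm" %in% blk)
  # every other element is its own lineage
  expect_equal(sort(lengths(lin$blocks)), c(1, 1, 1, 1, 1, 1, 2))

  # all distances above the threshold: everyone is a singleton
  singletons <- assign_lineages(sub, indel_profiles = prof, threshold = 1e-6)
  expect_true(all(lengths(singletons$blocks) == 1))
})

test_that("patchy distribution requires two or more non-clade surveyed taxa", {
  inputs <- bacillus_inputs()
  expect_true(patchy_distribution(c("R2Bgmdel", "R2Brdel"), inputs$mapping, inputs$host))
  expect_false(patchy_distribution(c("R2Bgb", "R2Bgm"), inputs$mapping, inputs$host))
  expect_false(patchy_distribution("R2Ba", inputs$mapping, inputs$host))
})

test_that("congruent element trees raise no conflicts; incongruent ones do", {
  host <- read_host_tree(bacillus_files()$host_tree)
  # element tree mirroring the host tree, one element per taxon
  mirror <- ape::read.tree(text = paste0(
    "(e_ros:22.8,((e_ben:2,e_mar:2):15,(e_gra:15.4,e_att:15.4):1.6):5.8);"))
  mapping <- data.frame(
    element_id = c("e_ros", "e_ben", "e_mar", "e_gra", "e_att"),
    taxon = c("rossius", "benazzii", "maretimi", "grandii_grandii", "atticus"))
  et <- structure(list(phylo = mirror, support = NULL, ages = NULL, rate = NULL),
                  class = "element_tree")
  tc <- topology_conflicts(et, host, mapping)
  expect_equal(nrow(tc$conflicts), 0L)
  expect_equal(tc$rf, 0)

  # permuting the tip mapping of congruent data creates measurable conflict
  perm <- mapping
  perm$taxon <- c("benazzii", "rossius", "grandii_grandii", "maretimi", "atticus")
  tc_perm <- topology_conflicts(et, host, perm)
  expect_gt(tc_perm$rf, 0)

  # the published pattern: island-subspecies elements nested among
  # basal-taxon elements conflicts with the host sister relationship
  inputs <- bacillus_inputs()
  kept <- setdiff(inputs$dm$nt$labels, "R2BggB")
  sub <- pdist_matrix(inputs$dm$nt$d[kept, kept], mode = "nt")
  et2 <- suppressWarnings(neighbor_joining(sub))
  tc2 <- topology_conflicts(et2, inputs$host, inputs$mapping)
  expect_true(any(grepl("benazzii\\+maretimi", tc2$conflicts$host_split)))
})

test_that("minimal event reconstruction recovers the two published transfers", {
  inputs <- bacillus_inputs()
  pts <- suppressMessages(assemble_points(inputs$dm$nt, inputs$mapping, inputs$host))
  flagged <- flag_candidates(pts)
  kept <- setdiff(inputs$dm$nt$labels, "R2BggB")
  sub <- pdist_matrix(inputs$dm$nt$d[kept, kept], mode = "nt")
  et <- suppressWarnings(neighbor_joining(sub))
  et <- calibrate_ages(et, default_calibrations())
  prof <- stats::setNames(as.list(inputs$mapping$indel_profile),
                          inputs$mapping$element_id)
  lin <- assign_lineages(sub, indel_profiles = prof)
  ev <- reconstruct_events(flagged, lin, et, inputs$host, inputs$mapping)

  expect_length(ev, 2L)
  anchors <- vapply(ev, `[[`, "", "anchor")
  expect_setequal(anchors, c("R2Brfun", "R2Brdel"))
  # direction heuristics follow the published reading
  for (e in ev) {
    expect_true(e$criteria[["low_divergence"]])
    expect_true(e$criteria[["incongruence"]])
    if (e$anchor == "R2Brdel") {
      expect_equal(e$donor_taxa, "maretimi")
      expect_equal(e$recipient_taxa, "rossius")
      expect_true(e$criteria[["patchy"]])
    } else {
      expect_equal(e$donor_taxa, "rossius")
      expect_setequal(e$recipient_taxa, c("benazzii", "maretimi"))
    }
  }
  # the six flagged pairs are fully covered
  covered <- do.call(rbind, lapply(ev, `[[`, "supporting_pairs"))
  expect_equal(nrow(covered), 6L)

  expect_length(reconstruct_events(flagged[0, ], lin, et, inputs$host, inputs$mapping), 0L)
})
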