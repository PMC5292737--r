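two_taxon_host <- function(t = 10) read_host_tree(sprintf("(A:%g,B:%g);", t, t))

test_that("simulation is byte-identical for a fixed seed", {
  host <- two_taxon_host()
  cfg <- simulation_config(host, seq_length = 500, seed = 9)
  s1 <- simulate_elements(cfg, keep_sequences = TRUE)
  s2 <- simulate_elements(cfg, keep_sequences = TRUE)
  expect_identical(s1$alignment, s2$alignment)
  expect_identical(s1$truth$segments, s2$truth$segments)

  f1 <- paper_like_fixture(seed = 4)
  f2 <- paper_like_fixture(seed = 4)
  expect_identical(f1$alignment, f2$alignment)
  expect_false(identical(f1$alignment, paper_like_fixture(seed = 5)$alignment))
})

test_that("per-segment change counts equal observed mismatches along the branch", {
  host <- read_host_tree("(A:6,(B:3,C:3):3);")
  sim <- simulate_elements(simulation_config(host, rate = 0.01, seq_length = 800,
                                             seed = 13), keep_sequences = TRUE)
  seg <- sim$truth$segments
  expect_gt(nrow(seg), 0)
  for (k in seq_len(nrow(seg))) {
    a <- strsplit(seg$seq_from[k], "")[[1]]
    b <- strsplit(seg$seq_to[k], "")[[1]]
    ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
    expect_equal(sum(a[ok] != b[ok]), seg$n_changes[k])
    expect_lte(seg$n_changes[k], seg$n_events[k])
  }
})

test_that("no-transfer divergence matches the Jukes-Cantor closed form", {
  host <- two_taxon_host(10)
  r <- 0.004
  ps <- vapply(1:50, function(seed) {
    sim <- simulate_elements(simulation_config(host, rate = r, seq_length = 1000,
                                               seed = seed))
    p_distance(sim$alignment[1, ], sim$alignment[2, ])$d
  }, 0)
  expected <- jc_expected_p(r, 2 * 10)
  se_mean <- sd(ps) / sqrt(length(ps))
  expect_lt(abs(mean(ps) - expected), 3 * se_mean)
})

test_that("K2P simulation biases changes toward transitions", {
  host <- two_taxon_host(20)
  sim <- simulate_elements(simulation_config(host, rate = 0.004, seq_length = 4000,
                                             model = "K2P", kappa = 8, seed = 2),
                           keep_sequences = TRUE)
  a <- sim$alignment[1, ]; b <- sim$alignment[2, ]
  diff <- which(a != b)
  is_transition <- (a[diff] %in% c("A", "G") & b[diff] %in% c("A", "G")) |
    (a[diff] %in% c("C", "T") & b[diff] %in% c("C", "T"))
  # under JC only a third of changes are transitions; kappa = 8 pushes the
  # proportion far above a half
  expect_gt(mean(is_transition), 0.5)
})

test_that("a transfer at the present leaves donor and recipient identical", {
  host <- two_taxon_host(10)
  cfg <- simulation_config(host, seq_length = 500,
                           ht_events = data.frame(time = 0, donor = "A",
                                                  recipient = "B",
                                                  replace_resident = TRUE),
                           seed = 3)
  sim <- simulate_elements(cfg)
  expect_equal(p_distance(sim$alignment[1, ], sim$alignment[2, ])$d, 0)
  expect_equal(sim$truth$events$donor, "A")

  # events outside the named branch interval are rejected
  expect_error(simulation_config(host, ht_events = data.frame(
    time = 15, donor = "A", recipient = "B", replace_resident = TRUE)),
    "no branch")
})

test_that("degradation follows exact length arithmetic and round-trips", {
  s <- random_orf(1162, seed = 8)                    # 3486 bp
  s <- substr(s, 1, 3485)
  out <- degrade_element(s, deletion_lengths = 426, seed = 1)
  expect_equal(nchar(out$seq), 3485L - 426L)
  expect_equal(out$log$kind, "deletion")

  none <- degrade_element(s, seed = 1)
  expect_equal(none$seq, toupper(s))
  expect_equal(nrow(none$log), 0L)

  dup <- degrade_element(s, duplication_lengths = c(333, 68, 57), seed = 2)
  expect_equal(nchar(dup$seq), 3485L + 333L + 68L + 57L)

  expect_error(degrade_element("ACGT", deletion_lengths = 10), "longer than")

  # a single 1-bp deletion inside a clean ORF surfaces as one frameshift
  orf <- random_orf(700, seed = 12)                  # 2100 bp
  fs <- degrade_element(orf, n_frameshift = 1, seed = 6)
  ann <- find_orf(fs$seq)
  expect_length(ann$frameshift_positions, 1)
})

test_that("the synthetic nine-element survey reproduces the published structure", {
  sim <- paper_like_fixture(seed = 1)
  host <- read_host_tree(bacillus_files()$host_tree)
  expect_setequal(rownames(sim$alignment),
                  c("R2Ba", "R2BggA", "R2BggB", "R2Bgb", "R2Bgm", "R2Bgmdel",
                    "R2Brfun", "R2Brdeg", "R2Brdel"))
  dm <- build_distance_matrix(sim$alignment, mode = "nt")

  # the ancient paralog is the most divergent element (beyond the cutoff)
  others <- setdiff(dm$labels, "R2BggB")
  expect_gt(min(dm$d["R2BggB", others]), 0.5)

  # the shared deletion is inherited across the transfer
  prof <- sim$mapping$indel_profile[match(c("R2Bgmdel", "R2Brdel"),
                                          sim$mapping$element_id)]
  expect_equal(prof[1], prof[2])
  expect_match(prof[1], "del:1035-1460")

  # the 5'-only fragment has fewer compared sites than full-length pairs
  expect_lt(dm$n_sites["R2Brdel", "R2Brfun"], ncol(sim$alignment))
  expect_lte(dm$n_sites["R2Brdel", "R2Brfun"], 1720L)

  # the configured transfer pairs are exactly the flagged ones
  pts <- suppressMessages(assemble_points(dm, sim$mapping, host))
  flagged <- flag_candidates(pts)
  key <- function(a, b) sort(paste(pmin(a, b), pmax(a, b)))
  expect_equal(key(flagged$element_a, flagged$element_b),
               key(sim$truth$ht_pairs$element_a, sim$truth$ht_pairs$element_b))
})

test_that("regressing no-transfer divergence on age recovers twice the rate", {
  # in the nearly linear regime of the JC curve the vertical-descent slope
  # is 2r (both lineages accumulate r per Myr)
  host <- read_host_tree(bacillus_files()$host_tree)
  r <- 0.001
  slopes <- vapply(1:20, function(seed) {
    sim <- simulate_elements(simulation_config(host, rate = r, seq_length = 3000,
                                               seed = seed))
    pts <- assemble_points(build_distance_matrix(sim$alignment, mode = "nt"),
                           sim$mapping, host)
    fit_divergence_age(pts)$slope
  }, 0)
  expect_lt(abs(mean(slopes) - 2 * r) / (2 * r), 0.10)
})
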