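test_that("poly-A trimming removes the maximal terminal run, with a minimum-run rule", {
  nine <- paste0("ACGTCGTCG", strrep("A", 9))
  out <- trim_poly_a(nine)
  expect_equal(out$tail_length, 9L)
  expect_equal(out$seq, "ACGTCGTCG")

  expect_equal(trim_poly_a("ACGTACGT")$tail_length, 0L)
  expect_equal(trim_poly_a("ACGTACGT")$seq, "ACGTACGT")

  body <- rand_seq(1000, seed = 11)
  body <- sub("A+$", "G", body)           # make sure the body itself ends in non-A
  out <- trim_poly_a(paste0(body, strrep("A", 7)))
  expect_equal(out$tail_length, 7L)
  expect_equal(out$seq, body)

  # runs below the minimum are ordinary sequence
  expect_equal(trim_poly_a("ACGTCGAAAA")$tail_length, 0L)

  expect_error(trim_poly_a("ACG-T"), "ungapped")
  expect_error(trim_poly_a(""), "non-empty")
})

test_that("poly-A trimming is idempotent", {
  for (seed in 1:10) {
    s <- paste0(sub("A+$", "C", rand_seq(300, seed = seed)),
                strrep("A", sample(0:12, 1)))
    once <- trim_poly_a(s)
    twice <- trim_poly_a(once$seq)
    expect_equal(twice$seq, once$seq)
    expect_equal(twice$tail_length, 0L)
  }
})

test_that("a clean single-frame ORF is found with exact coordinates", {
  set.seed(42)
  s <- random_orf(1060)                    # ATG + 1058 sense codons + stop
  expect_equal(nchar(s), 3180L)
  o <- find_orf(s)
  expect_equal(o$start, 1L)
  expect_equal(o$end, 3180L)
  expect_equal(o$length_nt, 3180L)
  expect_length(o$frameshift_positions, 0)
  expect_equal(o$protein_length_aa, 1059L)  # 3180/3 - 1
})

test_that("translation arithmetic excludes the terminal stop", {
  o <- find_orf(random_orf(1059, seed = 1))   # 3177 bp
  expect_equal(o$length_nt, 3177L)
  expect_equal(o$protein_length_aa, 1058L)

  o <- find_orf(random_orf(913, seed = 2))    # 2739 bp
  expect_equal(o$length_nt, 2739L)
  expect_equal(o$protein_length_aa, 912L)

  # minimal ORF: translated with an explicit annotation (below find_orf's
  # minimum segment length)
  orf <- structure(list(start = 1L, end = 6L, length_nt = 6L,
                        frameshift_positions = integer(0),
                        frameshift_windows = list(),
                        internal_stop_positions = integer(0),
                        segments = NULL), class = "orf_annotation")
  expect_equal(translate_orf("ATGTAA", orf), "M")

  orf$end <- 5L; orf$length_nt <- 5L
  expect_error(translate_orf("ATGTA", orf), "divisible by 3")
})

test_that("a 1-bp deletion inside a long ORF is recovered as one frameshift join", {
  set.seed(42)
  s <- random_orf(1060)
  mut <- paste(strsplit(s, "")[[1]][-1726], collapse = "")
  o <- find_orf(mut)
  expect_length(o$frameshift_positions, 1)
  w <- o$frameshift_windows[[1]]
  expect_true(1726 >= w[1] - 6 && 1726 <= w[2] + 6)
  # joined ORF spans essentially the whole construct
  expect_gt(o$length_nt, 3000)
  expect_equal(o$end, 3179L)
})

test_that("frameshift joins localize an engineered indel within the reported window", {
  # the causal indel cannot be pinpointed from one sequence: both reading
  # frames are open throughout the junction window; assert the window
  # contains the engineered site in nearly all replicates
  hits <- 0L; contained <- 0L
  n_rep <- 60L
  for (k in seq_len(n_rep)) {
    s <- random_orf(800, seed = k)
    pos <- 200 + ((k * 37) %% 2000)
    mut <- paste(strsplit(s, "")[[1]][-pos], collapse = "")
    o <- find_orf(mut)
    if (!is.null(o) && length(o$frameshift_positions) == 1L) {
      hits <- hits + 1L
      w <- o$frameshift_windows[[1]]
      if (pos >= w[1] - 6 && pos <= w[2] + 6) contained <- contained + 1L
    }
  }
  expect_gte(hits / n_rep, 0.85)
  expect_equal(contained, hits)
})

test_that("premature stops are read through and recorded, up to the budget", {
  s <- random_orf(1400, seed = 7)            # 4200 bp
  ch <- strsplit(s, "")[[1]]
  ch[901:903] <- c("T", "A", "A")
  ch[2401:2403] <- c("T", "G", "A")
  o <- find_orf(paste(ch, collapse = ""))
  expect_equal(o$internal_stop_positions, c(901L, 2401L))
  expect_equal(o$length_nt, 4200L)
  expect_length(o$frameshift_positions, 0)
  # retained stops appear as * in the protein
  expect_equal(nchar(gsub("[^*]", "", o$protein)), 2L)
})

test_that("no-ORF input yields a no-ORF result, not an error", {
  # short sequence, and a stop-saturated sequence
  expect_null(find_orf(strrep("TAA", 150)))
  expect_null(find_orf("ATGAAATAA"))
})

test_that("zinc-finger motifs are detected in order and mapped to clades", {
  cchh <- "CAACAAAAAAAAAAHAAAH"
  cchc <- "CAACAAAAAAAAAAHAAAC"
  one <- detect_zinc_fingers(paste0(strrep("M", 10), cchh, strrep("A", 50)))
  expect_equal(one$motifs, "CCHH")
  expect_equal(one$count, 1L)
  expect_equal(one$clade, "R2-D")

  two <- detect_zinc_fingers(paste0("MA", cchc, strrep("A", 10), cchh, strrep("A", 30)))
  expect_equal(two$motifs, c("CCHC", "CCHH"))
  expect_equal(two$clade, "R2-B")

  none <- detect_zinc_fingers(strrep("A", 100))
  expect_equal(none$count, 0L)
  expect_true(is.na(none$clade))

  # motifs outside the N-terminal window are ignored
  far <- detect_zinc_fingers(paste0(strrep("A", 300), cchh))
  expect_equal(far$count, 0L)
})

test_that("structural variants are annotated with 1-based inclusive reference coordinates", {
  ref <- rand_seq(3485, seed = 5)
  rc <- strsplit(ref, "")[[1]]

  q <- rc; q[1035:1460] <- "-"
  v <- annotate_structural_variants(paste(q, collapse = ""), ref)
  expect_equal(nrow(v), 1L)
  expect_equal(v$kind, "deletion")
  expect_equal(v$ref_start, 1035L)
  expect_equal(v$ref_end, 1460L)
  expect_equal(v$length_bp, 426L)
  expect_equal(v$length_bp, v$ref_end - v$ref_start + 1L)

  expect_equal(nrow(annotate_structural_variants(ref, ref)), 0L)

  # tandem duplication of a 333-bp block
  block <- rc[500:832]
  qdup <- paste(c(rc[1:832], block, rc[833:3485]), collapse = "")
  refal <- paste(c(rc[1:832], rep("-", 333), rc[833:3485]), collapse = "")
  vd <- annotate_structural_variants(qdup, refal)
  expect_equal(vd$kind, "duplication")
  expect_equal(vd$length_bp, 333L)

  expect_error(annotate_structural_variants("AC-", "ACGT"), "equal aligned length")
})

test_that("variant annotation is symmetric under role swap", {
  ref <- rand_seq(800, seed = 9)
  rc <- strsplit(ref, "")[[1]]
  q <- rc; q[201:300] <- "-"
  fwd <- annotate_structural_variants(paste(q, collapse = ""), ref)
  rev <- annotate_structural_variants(ref, paste(q, collapse = ""))
  expect_equal(fwd$kind, "deletion")
  expect_true(rev$kind %in% c("insertion", "duplication"))
  expect_equal(fwd$length_bp, rev$length_bp)
})

test_that("characterize_element summarises structure and flags degeneracy", {
  s <- paste0("GG", random_orf(500, seed = 3), "CC", strrep("A", 8))
  ann <- characterize_element(s, id = "el1")
  expect_equal(ann$poly_a_tail, 8L)
  expect_false(ann$degenerate)
  expect_equal(ann$orf$length_nt, 1500L)

  # a non-coding sequence has no ORF and is degenerate
  junk <- characterize_element(strrep("TAACGTAA", 100))
  expect_true(junk$degenerate)
})
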