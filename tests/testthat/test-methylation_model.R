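test_that("mtase_specificity validates cores, weights and efficiency", {
  expect_error(mtase_specificity("GG"), "CG/CA/CC/CT")
  expect_error(mtase_specificity("CG", efficiency = 1.5), "efficiency")
  expect_error(mtase_specificity("CG", flank3_weights = c(A = 2, C = 1,
                                                          G = 1, T = 1)),
               "\\[0, 1\\]")
  s <- mtase_specificity(c("CC", "CG", "CG"))
  expect_equal(s$core, c("CC", "CG"))
  expect_equal(s$name, "CC+CG")
})

test_that("CG targets are listed symmetrically on both strands", {
  s <- duplex_seq("ACGA", "linear")
  sites <- list_target_sites(s, flat_spec("CG"))
  expect_equal(nrow(sites), 2L)
  expect_setequal(sites$strand, c("top", "bottom"))
  expect_equal(sites$position[sites$strand == "top"], 2L)
  expect_equal(sites$position[sites$strand == "bottom"], 3L)
})

test_that("cytosines inside recognition sites are listed like any other", {
  # inner C of Eco47I's GGWCC is followed by C -> a CC target
  s <- duplex_seq("TTAGGACCATT", "linear")
  sites <- list_target_sites(s, flat_spec("CC"))
  expect_true(any(sites$strand == "top" & sites$position == 7))
  # concrete Alw44I site: the internal C (motif position 4) is followed by A
  a <- duplex_seq("TTGTGCACTT", "circular")
  ca <- list_target_sites(a, flat_spec("CA"))
  expect_true(any(ca$strand == "top" & ca$position == 6))
  expect_true(any(ca$strand == "bottom"))
})

test_that("flank weights gate deterministic methylation", {
  spec <- mtase_specificity("CC",
                            flank3_weights = c(A = 1, C = 1, G = 0, T = 0))
  s <- duplex_seq("TATTCCGTTAT", "linear")   # CC followed by G
  meth <- apply_methylation(s, spec, "deterministic")
  expect_false(any(meth$marks$strand == "top" & meth$marks$position == 5))
  s2 <- duplex_seq("TATTCCATTAT", "linear")  # CC followed by A
  meth2 <- apply_methylation(s2, spec, "deterministic")
  expect_true(any(meth2$marks$strand == "top" & meth2$marks$position == 5))
})

test_that("deterministic CG methylation marks every CG locus twice", {
  s <- random_duplex(600, "circular", seed = 4)
  meth <- apply_methylation(s, flat_spec("CG"), "deterministic")
  n_loci <- nrow(scan_motif(s, "CG"))
  expect_equal(nrow(meth$marks), 2L * n_loci)
  # strand-symmetric: bottom marks are top marks shifted by +1
  tops <- sort(meth$marks$position[meth$marks$strand == "top"])
  bots <- sort(meth$marks$position[meth$marks$strand == "bottom"])
  expect_equal(sort(wrap_pos(tops + 1L, s$length)), bots)
})

test_that("stochastic mode honours efficiency and requires a seed", {
  s <- random_duplex(300, "circular", seed = 2)
  spec <- mtase_specificity("CG", efficiency = 0)
  expect_error(apply_methylation(s, spec, "stochastic"), "seed")
  meth <- apply_methylation(s, spec, "stochastic", seed = 1)
  expect_equal(nrow(meth$marks), 0L)
  full <- apply_methylation(s, mtase_specificity("CG", efficiency = 1),
                            "stochastic", seed = 1)
  expect_equal(nrow(full$marks),
               nrow(apply_methylation(s, flat_spec("CG"),
                                      "deterministic")$marks))
})

test_that("raising a flank weight never removes a deterministic mark", {
  s <- random_duplex(500, "circular", seed = 9)
  w <- c(A = 0.6, C = 0.3, G = 0.9, T = 0.1)
  lo <- apply_methylation(s, mtase_specificity("CC", flank3_weights = w),
                          "deterministic")
  w2 <- w
  w2["C"] <- 0.8
  hi <- apply_methylation(s, mtase_specificity("CC", flank3_weights = w2),
                          "deterministic")
  expect_true(all(mark_keys(lo) %in% mark_keys(hi)))
})

test_that("flat weights reproduce a brute-force dinucleotide scan", {
  s <- random_duplex(400, "circular", seed = 11)
  ch <- strsplit(s$residues, "")[[1]]
  L <- length(ch)
  nxt <- ch[c(2:L, 1)]
  for (core in c("CA", "CG", "CT")) {
    sites <- list_target_sites(s, flat_spec(core))
    # oracle: top-strand dinucleotides + the motif's reverse complement on top
    top_oracle <- which(ch == "C" & nxt == substr(core, 2, 2))
    rc <- reverse_complement(core)
    bot_oracle <- wrap_pos(which(ch == substr(rc, 1, 1) &
                                   nxt == substr(rc, 2, 2)) + 1L, L)
    expect_setequal(sites$position[sites$strand == "top"], top_oracle)
    expect_setequal(sites$position[sites$strand == "bottom"], bot_oracle)
    expect_true(all(sites$weight == 1))
  }
})

test_that("asymmetric cores mark the two strands at unrelated positions", {
  s <- random_duplex(500, "circular", seed = 5)
  meth <- apply_methylation(s, flat_spec("CA"), "deterministic")
  tops <- meth$marks$position[meth$marks$strand == "top"]
  bots <- meth$marks$position[meth$marks$strand == "bottom"]
  # unlike CG, there is no +1 shift pairing
  expect_false(isTRUE(all.equal(sort(wrap_pos(tops + 1L, s$length)),
                                sort(bots))))
})

test_that("marks on non-cytosines are rejected", {
  s <- duplex_seq("ACGT", "linear")
  expect_error(methylation_state(s, "top", 1L), "non-cytosine")
  expect_silent(methylation_state(s, "top", 2L))
  expect_silent(methylation_state(s, "bottom", 3L))
})

test_that("build_oligo_duplex centres the cassette on an A/T backbone", {
  od <- build_oligo_duplex("A", "CC", "A")
  expect_equal(length(od$seq), 23L)
  expect_equal(od$seq$topology, "linear")
  # only cassette bases are C/G
  expect_equal(sum(strsplit(od$seq$residues, "")[[1]] %in% c("C", "G")), 2L)
  expect_error(build_oligo_duplex("A", "CC", "A", length = 5),
               "core length")

  hemi <- build_oligo_duplex("A", "CG", "A", premeth = "bottom")
  expect_equal(nrow(hemi$meth$marks), 1L)
  expect_equal(hemi$meth$marks$strand, "bottom")
  # the top-strand target C remains unmarked
  expect_false(any(hemi$meth$marks$strand == "top"))
  expect_error(build_oligo_duplex("A", "CA", "A", premeth = "bottom"),
               "no bottom-strand C")
})
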