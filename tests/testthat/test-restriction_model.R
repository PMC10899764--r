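test_that("the shipped table holds the nine documented enzymes", {
  tab <- load_enzyme_table()
  expect_setequal(names(tab), c("Alw44I", "XmiI", "BsuRI", "Bsh1236I",
                                "Hin6I", "Eco47I", "MspI", "BamHI", "NcoI"))
  expect_equal(tab$Alw44I$motif, "GTGCAC")
  expect_equal(tab$XmiI$rules[[1]]$mode, "blocked_if_both_strands")
  expect_equal(length(tab$Eco47I$rules), 2L)
})

test_that("enzyme tables round-trip bit-exactly and reject bad rows", {
  tab <- load_enzyme_table()
  tmp <- tempfile(fileext = ".tsv")
  write_enzyme_table(tab, tmp)
  tab2 <- load_enzyme_table(tmp)
  tmp2 <- tempfile(fileext = ".tsv")
  write_enzyme_table(tab2, tmp2)
  expect_identical(readLines(tmp), readLines(tmp2))
  expect_equal(tab2$Bsh1236I$rules[[1]]$positions, c(1L, 3L))

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("name\tmotif\tcut_offset\trules",
               "FooI\tGGCC\t2\t3|blocked_sometimes"), bad)
  expect_error(load_enzyme_table(bad), "blocked_sometimes")

  empty <- tempfile(fileext = ".tsv")
  writeLines("name\tmotif\tcut_offset\trules", empty)
  expect_warning(res <- load_enzyme_table(empty), "empty")
  expect_length(res, 0L)
})

test_that("rule constructors validate watched positions", {
  expect_error(restriction_enzyme("X", "GTGCAC", 7), "cut_offset")
  # position 2 of GTGCAC (T) can never be a C
  expect_error(restriction_enzyme("X", "GTGCAC", 1,
                                  list(sensitivity_rule(2, "blocked_if_any_strand"))),
               "never a C")
  # degenerate positions that admit C are accepted (M = A/C)
  expect_silent(restriction_enzyme("X", "GTMKAC", 2,
                                   list(sensitivity_rule(3, "blocked_if_any_strand"))))
})

test_that("Alw44I is blocked by hemimethylation of the 3' cytosine", {
  s <- duplex_seq("TTGTGCACATT", "circular")
  site <- scan_motif(s, "GTGCAC")
  enz <- mpei_enzymes()$Alw44I
  none <- methylation_state(s)
  expect_false(is_blocked(s, none, site, enz)$blocked)
  top_only <- methylation_state(s, "top", 8L)   # 3'-C on the top strand
  expect_true(is_blocked(s, top_only, site, enz)$blocked)
  bottom_only <- methylation_state(s, "bottom", 3L) # 3'-C on the bottom strand
  expect_true(is_blocked(s, bottom_only, site, enz)$blocked)
  # methylation at the internal CA (position 6) is not watched
  internal <- methylation_state(s, "top", 6L)
  expect_false(is_blocked(s, internal, site, enz)$blocked)
})

test_that("XmiI requires the 3' cytosine marked on both strands", {
  s <- duplex_seq("TTGTAGACATT", "circular")
  site <- scan_motif(s, "GTMKAC")
  enz <- mpei_enzymes()$XmiI
  one <- methylation_state(s, "top", 8L)
  expect_false(is_blocked(s, one, site, enz)$blocked)
  both <- methylation_state(s, c("top", "bottom"), c(8L, 3L))
  expect_true(is_blocked(s, both, site, enz)$blocked)
})

test_that("Eco47I is blocked by either the terminal or the inner cytosine", {
  s <- duplex_seq("TTGGACCATT", "circular")
  site <- scan_motif(s, "GGWCC")
  enz <- mpei_enzymes()$Eco47I
  terminal <- methylation_state(s, "top", 7L)
  inner <- methylation_state(s, "top", 6L)
  expect_true(is_blocked(s, terminal, site, enz)$blocked)
  v <- is_blocked(s, inner, site, enz)
  expect_true(v$blocked)
  expect_true(2L %in% v$firing_rules)
  # bottom-strand terminal C (complement of the leading G)
  expect_true(is_blocked(s, methylation_state(s, "bottom", 3L), site,
                         enz)$blocked)
})

test_that("mismatched site and enzyme motifs are rejected", {
  s <- duplex_seq("TTGGACCATT", "circular")
  site <- scan_motif(s, "GGWCC")
  expect_error(is_blocked(s, methylation_state(s), site,
                          mpei_enzymes()$Alw44I), "motif")
})

test_that("adding marks never unblocks a site", {
  s <- random_duplex(800, "circular", seed = 3)
  enzymes <- mpei_enzymes()
  meth_small <- apply_methylation(s, flat_spec("CG"), "deterministic")
  meth_big <- apply_methylation(s, flat_spec(c("CG", "CC", "CA")),
                                "deterministic")
  expect_true(all(mark_keys(meth_small) %in% mark_keys(meth_big)))
  for (enz in enzymes) {
    sites <- scan_motif(s, enz$motif, enz$name)
    for (i in seq_len(nrow(sites))) {
      small <- is_blocked(s, meth_small, sites[i, ], enz)$blocked
      big <- is_blocked(s, meth_big, sites[i, ], enz)$blocked
      expect_true(!small || big)
    }
  }
})

test_that("strand swap of the duplex leaves blocking unchanged", {
  s <- random_duplex(600, "circular", seed = 8)
  L <- s$length
  rc <- duplex_seq(reverse_complement(s$residues), "circular")
  meth <- apply_methylation(s, flat_spec(c("CG", "CC")), "deterministic")
  # mirror the marks: strand flips, position maps to L - pos + 1
  mirr <- methylation_state(
    rc,
    ifelse(meth$marks$strand == "top", "bottom", "top"),
    L - meth$marks$position + 1L
  )
  for (enz in mpei_enzymes()[c("Alw44I", "BsuRI", "Eco47I", "Hin6I")]) {
    a <- digest(s, meth, enz)
    b <- digest(rc, mirr, enz)
    expect_equal(sort(a$fragments), sort(b$fragments), info = enz$name)
    expect_equal(a$status, b$status, info = enz$name)
  }
})
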