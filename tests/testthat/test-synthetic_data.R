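test_that("generators are byte-stable for a fixed seed", {
  expect_identical(make_alw44i_fixture(seed = 1)$residues,
                   make_alw44i_fixture(seed = 1)$residues)
  expect_false(identical(make_alw44i_fixture(seed = 1)$residues,
                         make_alw44i_fixture(seed = 2)$residues))
  expect_identical(make_selection_fixture(seed = 3)$residues,
                   make_selection_fixture(seed = 3)$residues)
})

test_that("the three-site plasmid reproduces the printed digest arithmetic", {
  for (seed in 1:3) {
    fx <- make_alw44i_fixture(seed = seed)
    expect_equal(length(fx), 6421L)
    sites <- scan_motif(fx, "GTGCAC")
    expect_equal(nrow(sites), 3L)
    frags <- digest(fx, methylation_state(fx), "Alw44I")$fragments
    expect_equal(sort(frags), c(500L, 1935L, 3986L))
    # fused-fragment arithmetic: 4486 = 3986 + 500, 5921 = 1935 + 3986,
    # 2435 = 500 + 1935, 6421 = total
    expect_equal(sum(frags), 6421L)
    ctx <- table(context_coverage(fx, "Alw44I")$context)
    expect_equal(as.integer(ctx[c("CA", "CG", "CC", "CT")]),
                 c(1L, 1L, 3L, 1L))
    # no stray XmiI or Eco47I sites in the background
    expect_equal(nrow(scan_motif(fx, "GTMKAC")), 0L)
    expect_equal(nrow(scan_motif(fx, "GGWCC")), 0L)
  }
})

test_that("CT-specific methylation fuses the 500|1935 junction", {
  fx <- make_alw44i_fixture(seed = 1)
  ct <- predict_pattern(fx, flat_spec("CT"), "Alw44I")
  expect_equal(sort(ct$fragments), c(2435L, 3986L))
})

test_that("planted flanks are recovered by the context analyser", {
  p <- make_random_plasmid(
    2500,
    planted = list(
      planted_site("GTGCAC", 300, flank3_top = "G", flank3_bottom = "T"),
      planted_site("GGWCC", 1400, concrete = "GGTCC",
                   flank3_top = "A", flank3_bottom = "A")
    ),
    seed = 21)
  a <- scan_motif(p, "GTGCAC")
  expect_equal(a$flank3_top, "G")
  expect_equal(a$flank3_bottom, "T")
  ctx <- context_coverage(p, "Eco47I")
  expect_setequal(ctx$context, "CA")
})

test_that("infeasible layouts are rejected with an explanation", {
  expect_error(
    make_random_plasmid(100, list(planted_site("GTGCAC", 10),
                                  planted_site("GTGCAC", 12)), seed = 1),
    "overlap")
  expect_error(planted_site("GTGCAC", 5, concrete = "GTGCAA"),
               "not a concretisation")
})

test_that("selection fixture covers CA/CC/CT, lacks CG, and has an A/A XmiI site", {
  sel <- make_selection_fixture(seed = 1)
  ctx <- context_coverage(sel, "Eco47I")$context
  expect_setequal(unique(ctx), c("CA", "CC", "CT"))
  expect_false("CG" %in% ctx)
  expect_equal(nrow(scan_motif(sel, "GTGCAC")), 0L)
  xmii <- scan_motif(sel, "GTMKAC")
  expect_equal(nrow(xmii), 1L)
  expect_equal(xmii$flank3_top, "A")
  expect_equal(xmii$flank3_bottom, "A")
  # one site is T/A-flanked
  e <- scan_motif(sel, "GGWCC")
  expect_true(any(e$flank3_top == "T" & e$flank3_bottom == "A"))

  # all three Eco47I sites cut without methylation, all blocked under CC
  expect_equal(length(digest(sel, methylation_state(sel),
                             "Eco47I")$cut_positions), 3L)
  cc <- predict_pattern(sel, flat_spec("CC"), "Eco47I")
  expect_equal(cc$status, "uncut_circular")
  expect_equal(nrow(cc$blocked_sites), 3L)
})

test_that("oligo panels enumerate the stated cassettes", {
  core <- make_oligo_panel("AXXA_core_panel")
  expect_length(core, 4L)
  expect_true(all(vapply(core, function(o) length(o$seq) == 23L,
                         logical(1))))
  # members share the backbone and differ only in the cassette
  expect_equal(substr(core$ACGA$seq$residues, 1, 9),
               substr(core$ACTA$seq$residues, 1, 9))
  expect_equal(nrow(core$ACGA$meth$marks), 1L)   # hemimethylated CG control
  expect_equal(core$ACGA$meth$marks$strand, "bottom")
  expect_equal(nrow(core$ACCA$meth$marks), 0L)

  f3 <- make_oligo_panel("flank3_panel")
  marked <- vapply(f3, function(o) {
    nrow(apply_methylation(o$seq, quadruple_mutant_cc_profile(),
                           "deterministic")$marks) > 0
  }, logical(1))
  expect_equal(unname(marked), c(TRUE, TRUE, FALSE, FALSE)) # ccA ccC ccG ccT

  f5 <- make_oligo_panel("flank5_panel")
  marked5 <- vapply(f5, function(o) {
    nrow(apply_methylation(o$seq, quadruple_mutant_cc_profile(),
                           "deterministic")$marks) > 0
  }, logical(1))
  expect_equal(marked5[["Acc"]], FALSE)
  expect_true(all(marked5[c("Ccc", "Gcc", "Tcc")]))

  expect_length(make_oligo_panel("NNccNN_panel"), 16L)
})

test_that("ANccCT members contain a ccC target and no ccA target", {
  panel <- make_oligo_panel("ANccCT_panel")
  expect_length(panel, 4L)
  for (o in panel) {
    sites <- list_target_sites(o$seq, flat_spec("CC"))
    expect_true(any(sites$flank3 == "C", na.rm = TRUE), info = o$seq$name)
    expect_false(any(sites$flank3 == "A", na.rm = TRUE), info = o$seq$name)
  }
})
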