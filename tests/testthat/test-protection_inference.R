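fx <- make_alw44i_fixture(seed = 1)

test_that("predicted patterns reproduce the fixture protection arithmetic", {
  expect_true(2435 %in% predict_pattern(fx, flat_spec("CT"),
                                        "Alw44I")$fragments)
  cc <- predict_pattern(fx, flat_spec("CC"), "Alw44I")
  expect_equal(cc$fragments, 6421L)  # single full-length linear product
  ca <- predict_pattern(fx, flat_spec("CA"), "Alw44I")
  expect_equal(sort(ca$fragments), c(1935L, 4486L))
})

test_that("band matching is bijective within relative tolerance", {
  pred <- predict_pattern(fx, flat_spec("CG"), "Alw44I")  # {4486, 1935}
  ok <- patterns_consistent(pred, observed_pattern("Alw44I", c(4500, 1900)),
                            rel_tol = 0.05)
  expect_true(ok$consistent)
  expect_equal(nrow(ok$matching), 2L)
  bad <- patterns_consistent(pred, observed_pattern("Alw44I", 5921),
                             rel_tol = 0.05)
  expect_false(bad$consistent)
  exact <- patterns_consistent(pred,
                               observed_pattern("Alw44I", c(4486, 1935)),
                               rel_tol = 0)
  expect_true(exact$consistent)
  expect_error(patterns_consistent(pred, observed_pattern("Alw44I", 100),
                                   rel_tol = 0.5), "rel_tol")
})

test_that("uncut and full-length-linear flags match the right outcomes", {
  uncut_pred <- predict_pattern(fx, flat_spec(c("CA", "CC", "CG", "CT")),
                                "Alw44I")
  expect_true(patterns_consistent(uncut_pred,
                                  observed_pattern("Alw44I",
                                                   uncut = TRUE))$consistent)
  single <- predict_pattern(fx, flat_spec("CC"), "Alw44I")
  obs_lin <- observed_pattern("Alw44I", full_length_linear = TRUE)
  expect_true(patterns_consistent(single, obs_lin)$consistent)
  expect_false(patterns_consistent(uncut_pred, obs_lin)$consistent)
})

test_that("the 4486 bp pattern alone leaves CG and CA ambiguous", {
  res <- infer_specificities(fx, list(observed_pattern("Alw44I",
                                                       c(4486, 1935))))
  singles <- res$hypothesis[res$n_core == 1]
  expect_setequal(singles, c("CG", "CA"))
  expect_false("CC" %in% res$hypothesis)
  expect_false("CT" %in% res$hypothesis)
  # parsimony ranking puts the single-dinucleotide readings first
  expect_true(all(which(res$n_core == 1) < which(res$n_core > 1)))
})

test_that("a fully cut both-A-flanked XmiI-like site eliminates CA", {
  p <- make_random_plasmid(
    3000,
    planted = list(
      planted_site("GTGCAC", 500, flank3_top = "A", flank3_bottom = "G"),
      planted_site("GTMKAC", 1800, concrete = "GTAGAC",
                   flank3_top = "A", flank3_bottom = "A")
    ),
    seed = 12, scrub_motifs = c("GTGCAC", "GTMKAC"))
  obs <- list(
    observed_pattern("Alw44I", uncut = TRUE),               # site protected
    observed_pattern("XmiI", full_length_linear = TRUE)     # site cut
  )
  res <- infer_specificities(p, obs, rel_tol = 0)
  expect_true("CG" %in% res$hypothesis)
  expect_false("CA" %in% res$hypothesis)
})

test_that("unmethylated observations yield only the inactive baseline", {
  obs <- lapply(c("Alw44I", "BsuRI"), function(e) {
    un <- digest(fx, methylation_state(fx), e)
    if (un$status == "uncut_circular") {
      observed_pattern(e, uncut = TRUE)
    } else {
      observed_pattern(e, un$fragments)
    }
  })
  expect_message(res <- infer_specificities(fx, obs, rel_tol = 0),
                 "no methylation detected")
  expect_equal(res$hypothesis, "none")
})

test_that("the true specificity is always among the consistent set", {
  space <- hypothesis_space()
  enzymes <- c("Alw44I", "XmiI", "BsuRI", "Bsh1236I", "Eco47I")
  for (seed in 1:3) {
    plasmid <- if (seed %% 2 == 0) make_alw44i_fixture(seed) else
      make_selection_fixture(seed)
    for (truth in c("CG", "CC", "CA", "CT")) {
      obs <- lapply(enzymes, function(e) {
        pred <- predict_pattern(plasmid, flat_spec(truth), e)
        if (pred$status == "uncut_circular") {
          observed_pattern(e, uncut = TRUE)
        } else {
          observed_pattern(e, pred$fragments)
        }
      })
      res <- infer_specificities(plasmid, obs, space = space, rel_tol = 0)
      expect_true(truth %in% res$hypothesis,
                  info = paste("seed", seed, "truth", truth))
    }
  }
})

test_that("adding observations never enlarges the consistent set", {
  obs1 <- list(observed_pattern("Alw44I", c(4486, 1935)))
  obs2 <- c(obs1, list(observed_pattern("XmiI",
                                        digest(fx, methylation_state(fx),
                                               "XmiI")$fragments)))
  r1 <- infer_specificities(fx, obs1, rel_tol = 0)
  r2 <- infer_specificities(fx, obs2, rel_tol = 0)
  expect_true(all(r2$hypothesis %in% r1$hypothesis))
})

test_that("context coverage enumerates two contexts per palindromic site", {
  cov <- context_coverage(fx, "Alw44I")
  expect_equal(nrow(cov), 6L)
  expect_equal(as.list(table(cov$context)),
               list(CA = 1L, CC = 3L, CG = 1L, CT = 1L))
  one <- make_random_plasmid(2000, list(planted_site("GTGCAC", 700)),
                             seed = 9)
  expect_equal(nrow(context_coverage(one, "Alw44I")), 2L)
})

test_that("selection suitability verdicts follow context coverage", {
  sel <- make_selection_fixture(seed = 1)
  fit <- selection_suitability(sel, "Eco47I", desired = c("CA", "CC", "CT"),
                               forbidden = "CG")
  expect_true(fit$suitable)
  expect_length(fit$missing_desired, 0L)
  # the internal GGWCC CC protection route is reported
  expect_true(length(fit$secondary_routes) > 0L)
  expect_match(fit$secondary_routes, "CC")

  unfit <- selection_suitability(fx, "Alw44I", desired = character(0),
                                 forbidden = "CG")
  expect_false(unfit$suitable)
  expect_equal(unfit$present_forbidden, "CG")
  expect_error(selection_suitability(fx, "Alw44I", desired = "CG",
                                     forbidden = "CG"), "disjoint")
})
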