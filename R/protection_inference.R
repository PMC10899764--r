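# The central reasoning engine: predict protection patterns under specificity
# hypotheses, test them against observed band sizes, enumerate consistent
# hypotheses, and evaluate restriction-based selection designs.

#' An observed digestion band pattern
#'
#' @param enzyme Enzyme label.
#' @param bands Numeric vector of fragment sizes read off a gel (bp);
#'   duplicates allowed.
#' @param uncut `TRUE` if the digest left the plasmid circular.
#' @param full_length_linear `TRUE` if the dominant product is the
#'   full-length linear plasmid (a single cut); counted as one band of the
#'   plasmid length during matching.
#' @return Object of class `observed_pattern`.
#' @export
observed_pattern <- function(enzyme, bands = numeric(0), uncut = FALSE,
                             full_length_linear = FALSE) {
  bands <- as.numeric(bands)
  if (any(bands <= 0)) stop("band sizes must be positive")
  if (uncut && (length(bands) > 0L || full_length_linear)) {
    stop("'uncut' excludes bands and the full-length-linear flag")
  }
  structure(list(enzyme = enzyme, bands = sort(bands, decreasing = TRUE),
                 uncut = uncut, full_length_linear = full_length_linear),
            class = "observed_pattern")
}

#' Predict the band pattern of a plasmid under a specificity hypothesis
#'
#' Deterministic (threshold-semantics) methylation composed with [digest()].
#'
#' @param plasmid A [duplex_seq()].
#' @param spec An [mtase_specificity()].
#' @param enzyme As for [digest()].
#' @param threshold Deterministic methylation threshold.
#' @return A `fragment_set`.
#' @examples
#' fx <- make_alw44i_fixture(seed = 1)
#' predict_pattern(fx, mtase_specificity("CG"), "Alw44I")$fragments
#' @export
predict_pattern <- function(plasmid, spec, enzyme, threshold = 0.5) {
  meth <- apply_methylation(plasmid, spec, "deterministic", threshold)
  digest(plasmid, meth, enzyme)
}

#' Test whether a predicted pattern is consistent with an observed one
#'
#' Matching is bijective and greedy on size-sorted lists: the k-th largest
#' observed band must agree with the k-th largest predicted fragment within
#' relative tolerance (`|obs - pred| <= rel_tol * pred`), and the band counts
#' must agree. An observed `uncut` flag matches only a zero-cut prediction;
#' `full_length_linear` matches any single-cut outcome.
#'
#' @param predicted A `fragment_set` from [digest()]/[predict_pattern()].
#' @param observed An [observed_pattern()].
#' @param rel_tol Relative size tolerance in `[0, 0.2]`; default 0.05.
#' @return List with `consistent` (logical) and `matching` (data frame of
#'   paired sizes and their relative errors), plus a `reason` on failure.
#' @export
patterns_consistent <- function(predicted, observed, rel_tol = 0.05) {
  stopifnot(inherits(predicted, "fragment_set"),
            inherits(observed, "observed_pattern"))
  if (rel_tol < 0 || rel_tol > 0.2) stop("rel_tol must be in [0, 0.2]")
  empty <- data.frame(observed = numeric(0), predicted = numeric(0),
                      rel_error = numeric(0))
  if (observed$uncut) {
    ok <- predicted$status == "uncut_circular"
    return(list(consistent = ok, matching = empty,
                reason = if (ok) NA_character_ else "plasmid was cut"))
  }
  if (predicted$status == "uncut_circular") {
    return(list(consistent = FALSE, matching = empty,
                reason = "predicted uncut circular, bands observed"))
  }
  obs <- observed$bands
  if (observed$full_length_linear) obs <- c(predicted$seq_length, obs)
  obs <- sort(obs, decreasing = TRUE)
  pred <- sort(predicted$fragments, decreasing = TRUE)
  if (length(obs) != length(pred)) {
    return(list(consistent = FALSE, matching = empty,
                reason = sprintf("band count mismatch (%d observed, %d predicted)",
                                 length(obs), length(pred))))
  }
  rel <- abs(obs - pred) / pred
  matching <- data.frame(observed = obs, predicted = pred, rel_error = rel)
  bad <- which(rel > rel_tol)
  list(consistent = length(bad) == 0L, matching = matching,
       reason = if (length(bad) == 0L) NA_character_ else
         sprintf("band %g does not match predicted %g", obs[bad[1]],
                 pred[bad[1]]))
}

#' Default hypothesis space of specificity candidates
#'
#' All 15 non-empty subsets of \{CG, CA, CC, CT\} with flat flank weights,
#' preceded by the inactive baseline `"none"` (no methylation). Flank-weighted
#' profiles can be appended explicitly.
#'
#' @param extra Optional list of additional [mtase_specificity()] candidates.
#' @return List of `mtase_specificity` objects with unique names.
#' @export
hypothesis_space <- function(extra = list()) {
  subsets <- unlist(lapply(1:4, function(k) {
    utils::combn(CORE_DINUCLEOTIDES, k, simplify = FALSE)
  }), recursive = FALSE)
  space <- c(list(mtase_specificity(character(0), name = "none")),
             lapply(subsets, mtase_specificity),
             extra)
  nm <- vapply(space, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("candidate names must be unique")
  stats::setNames(space, nm)
}

#' Enumerate specificity hypotheses consistent with observed digests
#'
#' Exhaustively tests every candidate specificity against every observation
#' (via [predict_pattern()] and [patterns_consistent()]) and returns the
#' candidates consistent with ALL observations, ranked by parsimony (fewest
#' core dinucleotides first, then name). An empty result is a valid outcome.
#'
#' @param plasmid A [duplex_seq()].
#' @param observations List of [observed_pattern()]s (at least one).
#' @param space Candidate list; default [hypothesis_space()].
#' @param rel_tol Band-size tolerance passed to [patterns_consistent()].
#' @param enzymes Named list of enzymes to resolve observation labels
#'   against; default the shipped table.
#' @return Data frame `hypothesis`, `core`, `n_core`, `consistent`; the
#'   consistent subset is returned ranked, with the full evaluation grid in
#'   `attr(, "grid")`. If the inactive baseline is the only consistent
#'   candidate a "no methylation detected" message is emitted.
#' @export
infer_specificities <- function(plasmid, observations,
                                space = hypothesis_space(), rel_tol = 0.05,
                                enzymes = mpei_enzymes()) {
  if (length(observations) < 1L) stop("at least one observation is required")
  grid <- list()
  keep <- logical(length(space))
  for (i in seq_along(space)) {
    spec <- space[[i]]
    ok <- TRUE
    for (obs in observations) {
      if (!obs$enzyme %in% names(enzymes)) {
        stop("observation names unknown enzyme: ", obs$enzyme)
      }
      pred <- predict_pattern(plasmid, spec, enzymes[[obs$enzyme]])
      res <- patterns_consistent(pred, obs, rel_tol)
      grid[[length(grid) + 1L]] <- data.frame(
        hypothesis = spec$name, enzyme = obs$enzyme,
        consistent = res$consistent,
        violation = if (res$consistent) NA_character_ else res$reason,
        stringsAsFactors = FALSE)
      if (!res$consistent) {
        ok <- FALSE
        break
      }
    }
    keep[i] <- ok
  }
  consistent <- space[keep]
  out <- data.frame(
    hypothesis = vapply(consistent, `[[`, character(1), "name"),
    core = vapply(consistent, function(s) paste(s$core, collapse = "+"),
                  character(1)),
    n_core = vapply(consistent, function(s) length(s$core), integer(1)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$n_core, out$hypothesis), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) > 0L && all(out$hypothesis == "none")) {
    message("no methylation detected: only the inactive baseline is consistent")
  }
  attr(out, "grid") <- do.call(rbind, grid)
  out
}

# default anchor: the 3'-most literal C of the motif
default_anchor <- function(motif) {
  pos <- which(strsplit(motif, "")[[1]] == "C")
  if (length(pos) == 0L) stop("motif ", motif, " has no literal C to anchor")
  max(pos)
}

#' Dinucleotide contexts created by a motif cytosine across all sites
#'
#' For each site of the enzyme on the plasmid and each strand of the duplex,
#' returns the dinucleotide formed by the anchored cytosine and its 3'
#' neighbour (a multiset of size 2 x number of palindromic sites).
#'
#' @param plasmid A [duplex_seq()].
#' @param enzyme As for [digest()].
#' @param anchor Motif position of the anchored C; default the 3'-most
#'   literal C of the motif.
#' @return Data frame `start`, `strand`, `context`.
#' @examples
#' fx <- make_alw44i_fixture(seed = 1)
#' table(context_coverage(fx, "Alw44I")$context)
#' @export
context_coverage <- function(plasmid, enzyme, anchor = NULL) {
  enz <- resolve_enzymes(enzyme)[[1]]
  if (is.null(anchor)) anchor <- default_anchor(enz$motif)
  sites <- scan_motif(plasmid, enz$motif, motif_id = enz$name)
  if (nrow(sites) == 0L) {
    return(data.frame(start = integer(0), strand = character(0),
                      context = character(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    site <- sites[i, ]
    strands <- if (site$palindromic) c("top", "bottom") else site$strand
    data.frame(start = site$start, strand = strands,
               context = vapply(strands, function(s) {
                 dinucleotide_context(plasmid, site, anchor, s)
               }, character(1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Evaluate a plasmid/enzyme pair as a selection substrate
#'
#' A selection design is suitable when every desired dinucleotide context
#' appears at least once among the enzyme's anchored-cytosine site contexts
#' and no forbidden context appears. The report also flags secondary
#' protection routes: watched internal cytosines that sit in a CC
#' dinucleotide inside the motif itself, which protect the site under
#' CC-specific methylation regardless of the flanking base.
#'
#' @param plasmid A [duplex_seq()].
#' @param enzyme As for [digest()].
#' @param desired,forbidden Disjoint character vectors of contexts
#'   (e.g. `c("CA","CC","CT")` and `"CG"`).
#' @param anchor Passed to [context_coverage()].
#' @return List with `suitable` (logical), `contexts` (per-site data frame),
#'   `missing_desired`, `present_forbidden`, and `secondary_routes`
#'   (character description of flank-independent protection paths).
#' @export
selection_suitability <- function(plasmid, enzyme, desired,
                                  forbidden = character(0), anchor = NULL) {
  if (length(intersect(desired, forbidden)) > 0L) {
    stop("desired and forbidden context sets must be disjoint")
  }
  enz <- resolve_enzymes(enzyme)[[1]]
  cov <- context_coverage(plasmid, enz, anchor)
  missing_desired <- setdiff(desired, cov$context)
  present_forbidden <- intersect(forbidden, unique(cov$context))

  motif_ch <- strsplit(enz$motif, "")[[1]]
  watched <- sort(unique(unlist(lapply(enz$rules, `[[`, "positions"))))
  internal_cc <- watched[watched < length(motif_ch) &
                           motif_ch[watched] == "C" &
                           motif_ch[pmin(watched + 1L,
                                         length(motif_ch))] == "C"]
  secondary <- if (length(internal_cc) > 0L) {
    sprintf(paste0("motif position %d cytosine lies in an internal CC of ",
                   "%s; CC-specific methylation can protect every site ",
                   "independent of its flanking base"),
            internal_cc, enz$motif)
  } else {
    character(0)
  }
  list(
    suitable = length(missing_desired) == 0L &&
      length(present_forbidden) == 0L,
    contexts = cov,
    missing_desired = missing_desired,
    present_forbidden = present_forbidden,
    secondary_routes = secondary
  )
}
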