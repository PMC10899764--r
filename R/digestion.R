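# Complete in silico digestion of a (sequence, methylation state) pair.
# Deterministic digestion is always complete: every unblocked site is cut.
# Partial bands are modelled exclusively as molecule-to-molecule methylation
# heterogeneity in population mode, never as stochastic enzyme failure.

resolve_enzymes <- function(enzymes) {
  if (inherits(enzymes, "restriction_enzyme")) enzymes <- list(enzymes)
  lapply(enzymes, function(e) {
    if (is.character(e)) {
      tab <- mpei_enzymes()
      if (!e %in% names(tab)) stop("unknown enzyme: ", e)
      tab[[e]]
    } else {
      stopifnot(inherits(e, "restriction_enzyme"))
      e
    }
  })
}

# top-strand coordinate of the base immediately 5' of the duplex break
cut_coordinate <- function(site, enz, L, circular) {
  m <- nchar(enz$motif)
  raw <- if (site$strand == "top") {
    site$start - 1L + enz$cut_offset
  } else {
    site$start + m - enz$cut_offset - 1L
  }
  if (circular) {
    w <- raw %% L
    if (w == 0L) L else w
  } else {
    raw
  }
}

#' Digest a duplex sequence with one or more restriction enzymes
#'
#' Cuts at every enzyme site that is not blocked by the methylation state
#' (see [is_blocked()]). Fragment lengths are computed from the top-strand
#' cut coordinates with circular wraparound; the result is deterministic and
#' independent of the circular origin. Coincident cuts count once.
#'
#' @param seq A [duplex_seq()].
#' @param meth A [methylation_state()]; use `methylation_state(seq)` for
#'   unmethylated DNA.
#' @param enzymes A [restriction_enzyme()], enzyme name from the shipped
#'   table, or a list of either.
#' @return Object of class `fragment_set`: `status` (`"cut"` or
#'   `"uncut_circular"`), `fragments` (lengths in bp, sorted decreasing),
#'   `cut_positions`, `blocked_sites` (data frame of blocked site loci), and
#'   bookkeeping fields.
#' @examples
#' fx <- make_alw44i_fixture(seed = 1)
#' digest(fx, methylation_state(fx), "Alw44I")$fragments
#' @export
digest <- function(seq, meth, enzymes) {
  stopifnot(inherits(seq, "duplex_seq"), inherits(meth, "meth_state"))
  enzymes <- resolve_enzymes(enzymes)
  L <- seq$length
  circ <- seq$topology == "circular"
  cuts <- integer(0)
  blocked <- list()
  for (enz in enzymes) {
    sites <- scan_motif(seq, enz$motif, motif_id = enz$name)
    for (i in seq_len(nrow(sites))) {
      site <- sites[i, ]
      verdict <- is_blocked(seq, meth, site, enz)
      if (verdict$blocked) {
        blocked[[length(blocked) + 1L]] <-
          data.frame(enzyme = enz$name, start = site$start,
                     firing_rules = paste(verdict$firing_rules,
                                          collapse = ","),
                     stringsAsFactors = FALSE)
      } else {
        cuts <- c(cuts, cut_coordinate(site, enz, L, circ))
      }
    }
  }
  if (!circ) cuts <- cuts[cuts >= 1L & cuts < L]
  cuts <- sort(unique(cuts))
  blocked <- if (length(blocked) > 0L) do.call(rbind, blocked) else
    data.frame(enzyme = character(0), start = integer(0),
               firing_rules = character(0), stringsAsFactors = FALSE)

  if (circ) {
    if (length(cuts) == 0L) {
      frags <- integer(0)
      status <- "uncut_circular"
    } else {
      frags <- if (length(cuts) == 1L) L else
        as.integer(c(diff(cuts), L - cuts[length(cuts)] + cuts[1]))
      status <- "cut"
    }
  } else {
    frags <- as.integer(diff(c(0L, cuts, L)))
    status <- "cut"
  }
  structure(
    list(status = status, fragments = sort(frags, decreasing = TRUE),
         cut_positions = cuts, blocked_sites = blocked,
         seq_name = seq$name, seq_length = L,
         enzymes = vapply(enzymes, `[[`, character(1), "name")),
    class = "fragment_set"
  )
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("<fragment_set of '%s' (%d bp) by %s>\n", x$seq_name,
              x$seq_length, paste(x$enzymes, collapse = "+")))
  if (x$status == "uncut_circular") {
    cat("  uncut circular\n")
  } else {
    cat("  fragments (bp):", paste(x$fragments, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Population-level digestion under stochastic methylation
#'
#' Simulates `n_molecules` independent stochastic methylation states (each
#' strand of each target site marked with probability
#' `efficiency * site_weight`), digests each molecule, and aggregates band
#' intensities. Reproducible for a fixed seed.
#'
#' @param seq A [duplex_seq()].
#' @param spec An [mtase_specificity()].
#' @param enzymes As for [digest()].
#' @param n_molecules Number of molecules to simulate.
#' @param seed Integer seed.
#' @return Object of class `band_profile`: data frame `bands` (`length`,
#'   `fraction`) over linear fragments, plus `uncut_fraction` (mass remaining
#'   as uncut circle) and `n_molecules`.
#' @export
digest_population <- function(seq, spec, enzymes, n_molecules = 1000L,
                              seed = 1L) {
  stopifnot(n_molecules >= 1L)
  enzymes <- resolve_enzymes(enzymes)
  sites <- list_target_sites(seq, spec)
  p <- spec$efficiency * sites$weight

  tallies <- new.env(parent = emptyenv())
  uncut <- 0L
  withr::with_seed(seed, {
    for (k in seq_len(n_molecules)) {
      keep <- stats::runif(nrow(sites)) < p
      meth <- methylation_state(seq, sites$strand[keep],
                                sites$position[keep])
      fs <- digest(seq, meth, enzymes)
      if (fs$status == "uncut_circular") {
        uncut <- uncut + 1L
      } else {
        for (f in fs$fragments) {
          key <- as.character(f)
          tallies[[key]] <- (if (is.null(tallies[[key]])) 0L
                             else tallies[[key]]) + 1L
        }
      }
    }
  })
  lens <- as.integer(ls(tallies))
  counts <- vapply(as.character(lens), function(k) tallies[[k]], integer(1))
  ord <- order(lens, decreasing = TRUE)
  structure(
    list(bands = data.frame(length = lens[ord],
                            fraction = unname(counts[ord]) / n_molecules),
         uncut_fraction = uncut / n_molecules,
         n_molecules = n_molecules, seq_name = seq$name,
         enzymes = vapply(enzymes, `[[`, character(1), "name")),
    class = "band_profile"
  )
}

#' @export
print.band_profile <- function(x, ...) {
  cat(sprintf("<band_profile of '%s' by %s over %d molecules>\n",
              x$seq_name, paste(x$enzymes, collapse = "+"), x$n_molecules))
  if (x$uncut_fraction > 0) {
    cat(sprintf("  uncut circular: %.3f\n", x$uncut_fraction))
  }
  if (nrow(x$bands) > 0L) {
    cat(sprintf("  %6d bp  %.3f\n", x$bands$length, x$bands$fraction),
        sep = "")
  }
  invisible(x)
}
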