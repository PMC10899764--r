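# Synthetic substrates: random plasmids with planted restriction sites and
# exact flanking contexts, the three-site Alw44I test plasmid whose digest
# arithmetic matches the published fragment sizes, the Eco47I selection
# fixture, and defined-context oligonucleotide panels. All generators are
# seeded and byte-stable, and scrub their random backgrounds of accidental
# motif hits so that planted sites are the only sites.

#' Describe a site to plant in a random plasmid
#'
#' @param motif IUPAC recognition pattern.
#' @param start 1-based top-strand position of the site's first base.
#' @param concrete Concrete realisation of the motif to write (defaults to
#'   the first concretisation, degenerate letters replaced by their first
#'   allowed base).
#' @param flank3_top Base to place immediately 3' of the site on the top
#'   strand (`NA` = leave random).
#' @param flank3_bottom Base the bottom strand must show 3' of the site; the
#'   generator writes its complement immediately 5' of the site on the top
#'   strand (`NA` = leave random).
#' @return Object of class `planted_site`.
#' @export
planted_site <- function(motif, start, concrete = NULL,
                         flank3_top = NA_character_,
                         flank3_bottom = NA_character_) {
  motif <- check_iupac(motif)
  if (is.null(concrete)) {
    concrete <- paste(vapply(strsplit(motif, "")[[1]],
                             function(ch) IUPAC_SETS[[ch]][1], character(1)),
                      collapse = "")
  }
  concrete <- toupper(concrete)
  if (!grepl(paste0("^", iupac_to_regex(motif), "$"), concrete)) {
    stop("'", concrete, "' is not a concretisation of motif ", motif)
  }
  structure(list(motif = motif, start = as.integer(start),
                 concrete = concrete, flank3_top = flank3_top,
                 flank3_bottom = flank3_bottom),
            class = "planted_site")
}

#' Random circular plasmid with planted sites and exact flanks
#'
#' Generates a seeded random background, writes each planted site (and its
#' requested flanking bases), then resamples background bases until no motif
#' in `union(planted motifs, scrub_motifs)` matches anywhere outside the
#' planted loci, on either strand. Fails with an explanation if the layout is
#' infeasible (overlapping plants or unscrubbable hits).
#'
#' @param length Plasmid length (bp).
#' @param planted List of [planted_site()]s.
#' @param seed Integer seed; output is byte-identical for a fixed seed.
#' @param scrub_motifs Additional IUPAC motifs to scrub from the background.
#' @param topology `"circular"` (default) or `"linear"`.
#' @param name Sequence label.
#' @return A [duplex_seq()] whose only matches of the scrubbed motifs are the
#'   planted ones.
#' @export
make_random_plasmid <- function(length, planted = list(), seed = 1L,
                                scrub_motifs = character(0),
                                topology = "circular",
                                name = "synthetic_plasmid") {
  length <- as.integer(length)
  withr::with_seed(seed, {
    ch <- sample(BASES, length, replace = TRUE)

    protected <- integer(0)
    for (ps in planted) {
      stopifnot(inherits(ps, "planted_site"))
      m <- nchar(ps$concrete)
      win <- wrap_pos(seq.int(ps$start, ps$start + m - 1L), length)
      full <- wrap_pos(seq.int(ps$start - 1L, ps$start + m), length)
      if (any(full %in% protected)) {
        stop("infeasible layout: planted sites (including flanks) overlap")
      }
      ch[win] <- strsplit(ps$concrete, "")[[1]]
      if (!is.na(ps$flank3_top)) {
        ch[wrap_pos(ps$start + m, length)] <- toupper(ps$flank3_top)
      }
      if (!is.na(ps$flank3_bottom)) {
        ch[wrap_pos(ps$start - 1L, length)] <-
          complement_base(toupper(ps$flank3_bottom))
      }
      protected <- c(protected, full)
    }

    motifs <- unique(c(vapply(planted, `[[`, character(1), "motif"),
                       toupper(scrub_motifs)))
    allowed <- lapply(motifs, function(mo) {
      starts <- vapply(planted, function(ps) {
        if (ps$motif == mo) ps$start else NA_integer_
      }, integer(1))
      starts[!is.na(starts)]
    })
    names(allowed) <- motifs

    for (iter in seq_len(500L)) {
      seq <- duplex_seq(paste(ch, collapse = ""), topology, name = name)
      dirty <- FALSE
      for (mo in motifs) {
        hits <- scan_motif(seq, mo)
        extra <- unique(hits$start[!(hits$start %in% allowed[[mo]])])
        for (s in extra) {
          win <- wrap_pos(seq.int(s, s + nchar(mo) - 1L), length)
          editable <- setdiff(win, protected)
          if (length(editable) == 0L) {
            stop("infeasible layout: accidental ", mo, " hit at ", s,
                 " lies entirely within protected windows")
          }
          p <- editable[1]
          ch[p] <- sample(setdiff(BASES, ch[p]), 1)
          dirty <- TRUE
        }
      }
      if (!dirty) break
      if (iter == 500L) stop("background scrubbing did not converge")
    }
    duplex_seq(paste(ch, collapse = ""), topology, name = name)
  })
}

#' The three-site Alw44I test plasmid
#'
#' A circular 6421 bp plasmid carrying exactly three GTGCAC sites whose
#' complete digest yields fragments of 1935, 3986 and 500 bp. The 3'-flank
#' contexts of the sites (top/bottom) are planted as A/G at the site fusing
#' the 3986 and 500 bp fragments, C/C at the 1935|3986 junction and C/T at
#' the 500|1935 junction, so the four CN dinucleotide contexts created by the
#' sites' 3' cytosines are CA, CG, CC (three times) and CT. The background is
#' scrubbed of further GTGCAC, GTMKAC and GGWCC matches. Consequences:
#' CG- or CA-specific methylation protects only the A/G site (fused 4486 bp
#' fragment), CC-specific methylation protects both C-flanked sites (single
#' 6421 bp linear product), and CT-specific methylation protects only the
#' C/T site (fused 2435 bp fragment).
#'
#' @param seed Integer seed; the fixture is byte-identical per seed.
#' @return A circular 6421 bp [duplex_seq()].
#' @examples
#' fx <- make_alw44i_fixture(seed = 1)
#' sort(digest(fx, methylation_state(fx), "Alw44I")$fragments)
#' @export
make_alw44i_fixture <- function(seed = 1L) {
  # Alw44I cuts G^TGCAC (offset 1); a site starting at s cuts after base s,
  # so sites at 500/1000/2935 cut after 500/1000/2935: fragments 500
  # (500->1000), 1935 (1000->2935) and 3986 (2935->500 around the origin).
  make_random_plasmid(
    6421L,
    planted = list(
      planted_site("GTGCAC", 500L, flank3_top = "A", flank3_bottom = "G"),
      planted_site("GTGCAC", 1000L, flank3_top = "C", flank3_bottom = "T"),
      planted_site("GTGCAC", 2935L, flank3_top = "C", flank3_bottom = "C")
    ),
    seed = seed,
    scrub_motifs = c("GTMKAC", "GGWCC"),
    name = "alw44i_fixture"
  )
}

#' The Eco47I selection fixture
#'
#' A circular plasmid with three GGWCC sites whose six 3'-cytosine contexts
#' cover CA, CC and CT but contain no CG (the third site is T/A-flanked), and
#' one GTMKAC site flanked by adenine on both sides, so that full Eco47I
#' digestion selects for non-CG (CH) methylation specificity while the XmiI
#' site reports CA activity. No GTGCAC sites are present.
#'
#' @param seed Integer seed.
#' @param length Plasmid length; default 4000 bp.
#' @return A circular [duplex_seq()].
#' @export
make_selection_fixture <- function(seed = 1L, length = 4000L) {
  make_random_plasmid(
    length,
    planted = list(
      planted_site("GGWCC", 600L, concrete = "GGACC",
                   flank3_top = "A", flank3_bottom = "C"),
      planted_site("GGWCC", 1600L, concrete = "GGTCC",
                   flank3_top = "C", flank3_bottom = "C"),
      planted_site("GGWCC", 2600L, concrete = "GGACC",
                   flank3_top = "T", flank3_bottom = "A"),
      planted_site("GTMKAC", 3400L, concrete = "GTAGAC",
                   flank3_top = "A", flank3_bottom = "A")
    ),
    seed = seed,
    scrub_motifs = "GTGCAC",
    name = "eco47i_selection_fixture"
  )
}

#' Defined-context oligonucleotide substrate panels
#'
#' All members are 23-mer linear duplexes on a shared A/T backbone and differ
#' only in the central cassette.
#'
#' * `AXXA_core_panel`: the four cores CG/CA/CC/CT in AXXA context; the CG
#'   member carries a single 5mC mark on the bottom strand (hemimethylated
#'   control, leaving the top-strand target C unmarked).
#' * `flank3_panel`: TccX cassettes, X in A/C/G/T (5' flank fixed to T).
#' * `flank5_panel`: XccA cassettes, X in A/C/G/T.
#' * `ANccCT_panel`: ANccCT cassettes, N in A/C/G/T, in which the ccC target
#'   is followed by T so that no ccA site is created.
#' * `NNccNN_panel`: the 16-member enumeration of both single flanks
#'   (XccY for all X, Y).
#'
#' @param kind Panel name.
#' @return Named list of `list(seq, meth)` pairs as returned by
#'   [build_oligo_duplex()].
#' @export
make_oligo_panel <- function(kind = c("AXXA_core_panel", "flank3_panel",
                                      "flank5_panel", "ANccCT_panel",
                                      "NNccNN_panel")) {
  kind <- match.arg(kind)
  panel <- switch(kind,
    AXXA_core_panel = {
      out <- lapply(CORE_DINUCLEOTIDES, function(xx) {
        build_oligo_duplex("A", xx, "A",
                           premeth = if (xx == "CG") "bottom" else NULL,
                           name = paste0("A", tolower(xx), "A"))
      })
      stats::setNames(out, paste0("A", CORE_DINUCLEOTIDES, "A"))
    },
    flank3_panel = {
      out <- lapply(BASES, function(x) {
        build_oligo_duplex("T", "CC", x, name = paste0("Tcc", x))
      })
      stats::setNames(out, paste0("cc", BASES))
    },
    flank5_panel = {
      out <- lapply(BASES, function(x) {
        build_oligo_duplex(x, "CC", "A", name = paste0(x, "ccA"))
      })
      stats::setNames(out, paste0(BASES, "cc"))
    },
    ANccCT_panel = {
      out <- lapply(BASES, function(n) {
        build_oligo_duplex("A", paste0(n, "CCC"), "T",
                           name = paste0("A", n, "ccCT"))
      })
      stats::setNames(out, paste0("A", BASES, "ccCT"))
    },
    NNccNN_panel = {
      combos <- expand.grid(f5 = BASES, f3 = BASES,
                            stringsAsFactors = FALSE)
      out <- lapply(seq_len(nrow(combos)), function(i) {
        build_oligo_duplex(combos$f5[i], "CC", combos$f3[i],
                           name = paste0(combos$f5[i], "cc", combos$f3[i]))
      })
      stats::setNames(out, paste0(combos$f5, "cc", combos$f3))
    }
  )
  panel
}
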