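# Independent oracles used by the property tests.

random_duplex <- function(n, topology = "circular", seed = 1) {
  withr::with_seed(seed, duplex_seq(
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
    topology, name = paste0("rand", n, "_", seed)
  ))
}

# Brute-force motif scan via Biostrings on the (doubled, for circular)
# sequence: an implementation completely independent of scan_motif().
oracle_scan_starts <- function(seq, motif) {
  L <- seq$length
  m <- nchar(motif)
  circ <- seq$topology == "circular"
  s <- if (circ) paste0(seq$residues, substr(seq$residues, 1, m - 1)) else
    seq$residues
  subj <- Biostrings::DNAString(s)
  tops <- BiocGenerics::start(
    Biostrings::matchPattern(motif, subj, fixed = FALSE))
  bots <- BiocGenerics::start(
    Biostrings::matchPattern(reverse_complement(motif), subj, fixed = FALSE))
  if (circ) {
    tops <- tops[tops <= L]
    bots <- bots[bots <= L]
  }
  if (identical(motif, reverse_complement(motif))) {
    list(top = sort(unique(c(tops, bots))), bottom = integer(0))
  } else {
    list(top = sort(tops), bottom = sort(bots))
  }
}

# Brute-force fragment lengths: physically split the rotated residue string
# at the cut coordinates and measure the pieces.
oracle_fragments <- function(seq, cuts) {
  L <- seq$length
  cuts <- sort(unique(cuts))
  if (seq$topology == "circular") {
    if (length(cuts) == 0L) return(integer(0))
    rot <- paste0(substr(seq$residues, cuts[1] + 1, L),
                  substr(seq$residues, 1, cuts[1]))
    bounds <- c(0L, sort((cuts - cuts[1]) %% L)[-1], L)
    nchar(substring(rot, bounds[-length(bounds)] + 1L, bounds[-1]))
  } else {
    bounds <- c(0L, cuts[cuts >= 1 & cuts < L], L)
    nchar(substring(seq$residues, bounds[-length(bounds)] + 1L, bounds[-1]))
  }
}

# rotate a circular duplex so that old position k+1 becomes position 1
rotate_duplex <- function(seq, k) {
  duplex_seq(paste0(substr(seq$residues, k + 1, seq$length),
                    substr(seq$residues, 1, k)),
             seq$topology, name = seq$name)
}

flat_spec <- function(core) mtase_specificity(core)

# test enzyme with a single watched cytosine sitting in a palindromic CG
# (TCGA), used for exact binomial checks in population mode
tcga_enzyme <- function() {
  restriction_enzyme("TCGAtest", "TCGA", 2,
                     list(sensitivity_rule(2, "blocked_if_any_strand")))
}
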