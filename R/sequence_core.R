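# Duplex DNA with explicit topology, IUPAC motif scanning on both strands,
# and flanking-context extraction. Coordinates are 1-based, inclusive, on the
# top strand; bottom-strand features are reported in top-strand coordinates.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  W = c("A", "T"), S = c("C", "G"), M = c("A", "C"), K = c("G", "T"),
  R = c("A", "G"), Y = c("C", "T"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  W = "W", S = "S", M = "K", K = "M", R = "Y", Y = "R",
  B = "V", V = "B", D = "H", H = "D", N = "N"
)

#' Duplex DNA sequence
#'
#' Construct a double-stranded DNA sequence. Only the top strand (5'->3') is
#' stored; the bottom strand is implied by Watson-Crick complementarity.
#' Circular sequences use modular position arithmetic (position `length + 1`
#' is position 1).
#'
#' @param residues Character scalar over `A`, `C`, `G`, `T` (the top strand).
#' @param topology `"circular"` or `"linear"`.
#' @param name Optional label.
#' @return An object of class `duplex_seq` with fields `residues`,
#'   `topology`, `name` and `length`.
#' @examples
#' duplex_seq("AAGTGCACTT", topology = "circular")
#' @export
duplex_seq <- function(residues, topology = c("circular", "linear"),
                       name = "seq") {
  topology <- match.arg(topology)
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (nchar(residues) < 1L) {
    stop("duplex sequence must have length >= 1")
  }
  bad <- setdiff(unique(strsplit(residues, "")[[1]]), c("A", "C", "G", "T"))
  if (length(bad) > 0L) {
    stop("invalid residue(s) in concrete sequence: ",
         paste(bad, collapse = ", "),
         " (degenerate letters are allowed in motifs only)")
  }
  structure(
    list(residues = residues, topology = topology, name = name,
         length = nchar(residues)),
    class = "duplex_seq"
  )
}

#' @export
print.duplex_seq <- function(x, ...) {
  preview <- if (x$length > 60L) {
    paste0(substr(x$residues, 1, 57), "...")
  } else {
    x$residues
  }
  cat(sprintf("<duplex_seq '%s': %d bp, %s>\n  %s\n",
              x$name, x$length, x$topology, preview))
  invisible(x)
}

#' @export
length.duplex_seq <- function(x) x$length

# modular 1-based position on a circle; identity beyond-range handling for
# linear sequences is the caller's job
wrap_pos <- function(i, L) ((i - 1L) %% L) + 1L

seq_chars <- function(seq) strsplit(seq$residues, "")[[1]]

# base at position i honouring topology; NA outside a linear sequence
base_at <- function(seq, i) {
  if (seq$topology == "circular") {
    substr(seq$residues, wrap_pos(i, seq$length), wrap_pos(i, seq$length))
  } else if (i >= 1L && i <= seq$length) {
    substr(seq$residues, i, i)
  } else {
    NA_character_
  }
}

check_iupac <- function(pattern) {
  letters <- unique(strsplit(toupper(pattern), "")[[1]])
  bad <- setdiff(letters, names(IUPAC_SETS))
  if (length(bad) > 0L) {
    stop("invalid IUPAC letter(s): ", paste(bad, collapse = ", "))
  }
  toupper(pattern)
}

#' Reverse complement of a (possibly degenerate) base string
#'
#' Degenerate IUPAC letters map to their complements (`W`<->`W`, `M`<->`K`,
#' `S`<->`S`, ...).
#'
#' @param s Character scalar of IUPAC letters.
#' @return Character scalar.
#' @examples
#' reverse_complement("GTGCAC") # palindrome
#' reverse_complement("GGWCC")  # degenerate palindrome
#' @export
reverse_complement <- function(s) {
  s <- check_iupac(s)
  paste(rev(unname(IUPAC_COMPLEMENT[strsplit(s, "")[[1]]])), collapse = "")
}

complement_base <- function(b) {
  ifelse(is.na(b), NA_character_, unname(IUPAC_COMPLEMENT[b]))
}

iupac_to_regex <- function(pattern) {
  paste(vapply(strsplit(pattern, "")[[1]], function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (length(set) == 1L) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1)), collapse = "")
}

is_palindromic_motif <- function(motif) {
  identical(check_iupac(motif), reverse_complement(motif))
}

# all (overlapping) start positions of an IUPAC pattern in a plain string
regex_starts <- function(string, pattern) {
  m <- gregexpr(paste0("(?=", iupac_to_regex(pattern), ")"), string,
                perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Scan a duplex sequence for an IUPAC motif on both strands
#'
#' Matches are reported in top-strand coordinates (`start` is the top-strand
#' position of the leftmost base of the duplex site). Self-complementary
#' motifs are reported once per locus with `strand = "top"` and
#' `palindromic = TRUE`; both-strand flank annotations are always supplied.
#' Circular sequences report matches spanning the origin.
#'
#' @param seq A [duplex_seq()].
#' @param motif Non-empty IUPAC pattern (supports A,C,G,T,W,S,M,K,R,Y,B,D,H,V,N).
#' @param motif_id Label stored with each match; defaults to the motif.
#' @return A data frame of site matches with columns `motif_id`, `start`,
#'   `strand`, `matched` (motif-oriented concrete sequence), `palindromic`,
#'   and single-base flanks `flank5_top`, `flank3_top`, `flank5_bottom`,
#'   `flank3_bottom` (`NA` beyond a linear end). `flank3_bottom` is the
#'   complement of the top-strand base immediately 5' of `start`.
#' @examples
#' scan_motif(duplex_seq("AAGTGCACTT", "circular"), "GTGCAC")
#' @export
scan_motif <- function(seq, motif, motif_id = motif) {
  stopifnot(inherits(seq, "duplex_seq"))
  motif <- check_iupac(motif)
  m <- nchar(motif)
  if (m < 1L) stop("motif must be non-empty")
  L <- seq$length
  circ <- seq$topology == "circular"
  if (m > L) {
    return(empty_sitematch(motif_id))
  }

  search_str <- if (circ) {
    paste0(seq$residues, substr(seq$residues, 1L, m - 1L))
  } else {
    seq$residues
  }

  palin <- is_palindromic_motif(motif)
  top_starts <- regex_starts(search_str, motif)
  if (circ) top_starts <- top_starts[top_starts <= L]

  if (palin) {
    starts <- sort(unique(top_starts))
    strands <- rep("top", length(starts))
  } else {
    bot_starts <- regex_starts(search_str, reverse_complement(motif))
    if (circ) bot_starts <- bot_starts[bot_starts <= L]
    starts <- c(top_starts, bot_starts)
    strands <- c(rep("top", length(top_starts)),
                 rep("bottom", length(bot_starts)))
    ord <- order(starts, strands)
    starts <- starts[ord]
    strands <- strands[ord]
  }
  if (length(starts) == 0L) {
    return(empty_sitematch(motif_id))
  }

  window <- substring(search_str, starts, starts + m - 1L)
  matched <- ifelse(strands == "top", window,
                    vapply(window, reverse_complement, character(1)))
  f5t <- vapply(starts, function(s) base_at(seq, s - 1L), character(1))
  f3t <- vapply(starts, function(s) base_at(seq, s + m), character(1))
  data.frame(
    motif_id = motif_id, start = as.integer(starts), strand = strands,
    matched = unname(matched), palindromic = palin,
    flank5_top = f5t, flank3_top = f3t,
    flank5_bottom = complement_base(f3t),
    flank3_bottom = complement_base(f5t),
    motif = motif,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

empty_sitematch <- function(motif_id) {
  data.frame(
    motif_id = character(0), start = integer(0), strand = character(0),
    matched = character(0), palindromic = logical(0),
    flank5_top = character(0), flank3_top = character(0),
    flank5_bottom = character(0), flank3_bottom = character(0),
    motif = character(0), stringsAsFactors = FALSE
  )
}

#' Dinucleotide context of a cytosine within a matched site
#'
#' Returns the 2-mer formed by a cytosine inside the matched motif and its
#' immediate 3' neighbour on the same strand, crossing the site boundary when
#' the cytosine is terminal. `anchor` indexes the position within the motif
#' *as read on the given strand* (for palindromic sites, the bottom-strand
#' reading runs right-to-left in top coordinates).
#'
#' @param seq A [duplex_seq()].
#' @param site One row of a [scan_motif()] result (data frame or list).
#' @param anchor Position within the motif (1-based) that must be a C on the
#'   requested strand.
#' @param strand `"top"` or `"bottom"`.
#' @return Character scalar, e.g. `"CA"`.
#' @export
dinucleotide_context <- function(seq, site, anchor,
                                 strand = c("top", "bottom")) {
  strand <- match.arg(strand)
  start <- as.integer(site$start)
  m <- nchar(site$matched[[1]])
  if (anchor < 1L || anchor > m) stop("anchor outside motif")
  if (strand == "top") {
    b <- base_at(seq, start + anchor - 1L)
    if (!identical(b, "C")) {
      stop("anchor base is not C on the top strand (found ", b, ")")
    }
    nxt <- base_at(seq, start + anchor)
    if (is.na(nxt)) stop("no 3' neighbour beyond the linear sequence end")
    paste0("C", nxt)
  } else {
    pos <- start + m - anchor
    b <- complement_base(base_at(seq, pos))
    if (!identical(b, "C")) {
      stop("anchor base is not C on the bottom strand (found ", b, ")")
    }
    nxt <- complement_base(base_at(seq, pos - 1L))
    if (is.na(nxt)) stop("no 3' neighbour beyond the linear sequence end")
    paste0("C", nxt)
  }
}
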