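# MTase specificity hypotheses (core dinucleotides + flanking-preference
# weights) and their application to duplex DNA. The methylated base of a core
# dinucleotide is its 5' C; the 5' flank is the base preceding that C and the
# 3' flank is the base following the dinucleotide (the NNccNN reading). The
# two strands are methylated independently.

CORE_DINUCLEOTIDES <- c("CG", "CA", "CC", "CT")

flat_weights <- function() c(A = 1, C = 1, G = 1, T = 1)

check_weights <- function(w, what) {
  if (is.null(w)) return(flat_weights())
  if (!all(c("A", "C", "G", "T") %in% names(w))) {
    stop(what, " must name weights for all of A, C, G, T")
  }
  w <- w[c("A", "C", "G", "T")]
  if (any(w < 0 | w > 1)) stop(what, " must lie in [0, 1]")
  w
}

#' DNA methyltransferase specificity model
#'
#' A specificity hypothesis: the set of core dinucleotides whose 5' cytosine
#' the enzyme methylates, multiplicative flanking-preference weights, and a
#' per-strand methylation efficiency. All-1 weights reproduce pure
#' dinucleotide specificity. An empty `core` is permitted only as the
#' inactive ("no methylation") baseline used in hypothesis testing.
#'
#' @param core Character vector drawn from `CG`, `CA`, `CC`, `CT`.
#' @param flank5_weights,flank3_weights Named numeric weights in `[0, 1]` for
#'   `A`, `C`, `G`, `T`; default all 1.
#' @param efficiency Probability in `[0, 1]` that an eligible site is
#'   methylated per strand (stochastic mode).
#' @param name Label.
#' @return Object of class `mtase_specificity`.
#' @examples
#' mtase_specificity("CG")
#' mtase_specificity("CC", flank3_weights = c(A = 1, C = 0.6, G = 0.05, T = 0.05))
#' @export
mtase_specificity <- function(core, flank5_weights = NULL,
                              flank3_weights = NULL, efficiency = 1,
                              name = NULL) {
  core <- toupper(core)
  if (length(core) > 0L) {
    bad <- setdiff(core, CORE_DINUCLEOTIDES)
    if (length(bad) > 0L) {
      stop("core dinucleotides must be among CG/CA/CC/CT; got: ",
           paste(bad, collapse = ", "))
    }
  }
  if (efficiency < 0 || efficiency > 1) stop("efficiency must be in [0, 1]")
  core <- sort(unique(core))
  if (is.null(name)) {
    name <- if (length(core) == 0L) "none" else paste(core, collapse = "+")
  }
  structure(
    list(name = name, core = core,
         flank5_weights = check_weights(flank5_weights, "flank5_weights"),
         flank3_weights = check_weights(flank3_weights, "flank3_weights"),
         efficiency = efficiency),
    class = "mtase_specificity"
  )
}

#' @export
print.mtase_specificity <- function(x, ...) {
  fmt_w <- function(w) paste(sprintf("%s=%g", names(w), w), collapse = " ")
  cat(sprintf("<mtase_specificity '%s'> core: {%s}, efficiency %g\n",
              x$name, paste(x$core, collapse = ","), x$efficiency))
  cat("  flank5:", fmt_w(x$flank5_weights), "\n")
  cat("  flank3:", fmt_w(x$flank3_weights), "\n")
  invisible(x)
}

#' Shipped specificity profile of the evolved CC-preferring enzyme
#'
#' Encodes the qualitative flanking-nucleotide preference of the quadruple
#' mutant (strong preference for A and C following the CC site; A disfavoured
#' before it) as configurable weights. The numbers are a tunable stand-in for
#' a graphically reported ordering, not ground truth.
#'
#' @return An `mtase_specificity`.
#' @export
quadruple_mutant_cc_profile <- function() {
  mtase_specificity(
    "CC",
    flank5_weights = c(A = 0.4, C = 1, G = 1, T = 1),
    flank3_weights = c(A = 1, C = 0.6, G = 0.05, T = 0.05),
    efficiency = 1,
    name = "quadruple_mutant_CC"
  )
}

#' Per-strand 5-methylcytosine marks
#'
#' A set of `(strand, position)` pairs carrying 5mC, in top-strand
#' coordinates. Every marked position must be a C on the indicated strand
#' (a C on top, or a G on top when `strand = "bottom"`).
#'
#' @param seq The [duplex_seq()] the marks refer to.
#' @param strand Character vector of `"top"`/`"bottom"`.
#' @param position Integer vector of 1-based top-strand positions.
#' @return Object of class `meth_state` (data frame of marks plus metadata).
#' @export
methylation_state <- function(seq, strand = character(0),
                              position = integer(0)) {
  stopifnot(inherits(seq, "duplex_seq"), length(strand) == length(position))
  if (length(position) > 0L) {
    if (seq$topology == "circular") {
      position <- wrap_pos(as.integer(position), seq$length)
    } else if (any(position < 1L | position > seq$length)) {
      stop("mark position outside linear sequence")
    }
    bases <- seq_chars(seq)[position]
    ok <- ifelse(strand == "top", bases == "C", bases == "G")
    if (!all(ok)) {
      stop("mark at a non-cytosine: position(s) ",
           paste(position[!ok], collapse = ", "))
    }
  }
  marks <- unique(data.frame(strand = as.character(strand),
                             position = as.integer(position),
                             stringsAsFactors = FALSE))
  structure(list(marks = marks, seq_name = seq$name, seq_length = seq$length),
            class = "meth_state")
}

#' @export
print.meth_state <- function(x, ...) {
  cat(sprintf("<meth_state on '%s': %d mark(s)>\n", x$seq_name,
              nrow(x$marks)))
  invisible(x)
}

mark_keys <- function(meth) {
  if (nrow(meth$marks) == 0L) character(0)
  else paste(meth$marks$strand, meth$marks$position)
}

#' List candidate methylation target sites on both strands
#'
#' Every cytosine (on either strand) whose immediate 3' neighbour completes a
#' core dinucleotide is listed, with its flanks and multiplicative site
#' weight `flank5_weight[5' base] * flank3_weight[3' base]`. Cytosines inside
#' restriction recognition sequences are listed like any other; flanks beyond
#' a linear sequence end contribute weight 1.
#'
#' @param seq A [duplex_seq()].
#' @param spec An [mtase_specificity()].
#' @return Data frame with columns `strand`, `position` (of the target C, in
#'   top-strand coordinates), `core`, `flank5`, `flank3`, `weight`.
#' @export
list_target_sites <- function(seq, spec) {
  stopifnot(inherits(seq, "duplex_seq"), inherits(spec, "mtase_specificity"))
  if (length(spec$core) == 0L) {
    return(data.frame(strand = character(0), position = integer(0),
                      core = character(0), flank5 = character(0),
                      flank3 = character(0), weight = numeric(0),
                      stringsAsFactors = FALSE))
  }
  ch <- seq_chars(seq)
  L <- seq$length
  circ <- seq$topology == "circular"
  at <- function(i) {
    if (circ) return(ch[wrap_pos(i, L)])
    out <- rep(NA_character_, length(i))
    ok <- i >= 1L & i <= L
    out[ok] <- ch[i[ok]]
    out
  }
  idx <- seq_len(L)

  # top strand: C at p, partner at p+1, flank5 at p-1, flank3 at p+2
  top_core <- paste0(ch, at(idx + 1L))
  top_keep <- ch == "C" & top_core %in% spec$core
  top <- data.frame(strand = rep("top", sum(top_keep)),
                    position = idx[top_keep],
                    core = top_core[top_keep],
                    flank5 = at(idx - 1L)[top_keep],
                    flank3 = at(idx + 2L)[top_keep],
                    stringsAsFactors = FALSE)

  # bottom strand: C where top is G at p; 3' neighbour is complement(p-1)
  bot_core <- paste0("C", complement_base(at(idx - 1L)))
  bot_keep <- ch == "G" & !is.na(at(idx - 1L)) & bot_core %in% spec$core
  bot <- data.frame(strand = rep("bottom", sum(bot_keep)),
                    position = idx[bot_keep],
                    core = bot_core[bot_keep],
                    flank5 = complement_base(at(idx + 1L))[bot_keep],
                    flank3 = complement_base(at(idx - 2L))[bot_keep],
                    stringsAsFactors = FALSE)

  out <- rbind(top, bot)
  out <- out[order(out$position, out$strand), , drop = FALSE]
  w5 <- ifelse(is.na(out$flank5), 1, spec$flank5_weights[out$flank5])
  w3 <- ifelse(is.na(out$flank3), 1, spec$flank3_weights[out$flank3])
  out$weight <- unname(w5 * w3)
  rownames(out) <- NULL
  out
}

#' Apply methylation to a duplex sequence
#'
#' Deterministic mode marks every target site whose weight reaches the
#' threshold (efficiency is ignored); stochastic mode marks each site
#' independently with probability `efficiency * weight`. Strand events are
#' independent; hemimethylation of a site never alters the other strand's
#' eligibility.
#'
#' @param seq A [duplex_seq()].
#' @param spec An [mtase_specificity()].
#' @param mode `"deterministic"` or `"stochastic"`.
#' @param threshold Weight cutoff for deterministic mode, in `[0, 1]`.
#' @param seed Integer seed, required for stochastic mode.
#' @return A [methylation_state()].
#' @export
apply_methylation <- function(seq, spec,
                              mode = c("deterministic", "stochastic"),
                              threshold = 0.5, seed = NULL) {
  mode <- match.arg(mode)
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  sites <- list_target_sites(seq, spec)
  if (mode == "deterministic") {
    keep <- sites$weight >= threshold
  } else {
    if (is.null(seed)) stop("stochastic mode requires a seed")
    p <- spec$efficiency * sites$weight
    keep <- withr::with_seed(seed,
      stats::runif(nrow(sites)) < p)
  }
  methylation_state(seq, sites$strand[keep], sites$position[keep])
}

#' Build a defined-context oligonucleotide duplex
#'
#' Places a variable cassette `flank5 + core + flank3` at the centre of a
#' fixed A/T-only backbone (so the backbone itself contains no CG/CA/CC/CT
#' target on either strand). `premeth` plants a single 5mC mark on the core's
#' cytosine of the given strand, emulating a hemimethylated CG control.
#'
#' @param flank5,flank3 Single bases.
#' @param core Dinucleotide or 4-mer cassette core (concrete bases).
#' @param length Total duplex length; default 23.
#' @param premeth `NULL`, `"top"` or `"bottom"`.
#' @param name Label.
#' @return List with elements `seq` (a linear [duplex_seq()]) and `meth`
#'   (a [methylation_state()]).
#' @export
build_oligo_duplex <- function(flank5 = "A", core = "CG", flank3 = "A",
                               length = 23L, premeth = NULL, name = NULL) {
  core <- toupper(core)
  cassette <- paste0(toupper(flank5), core, toupper(flank3))
  if (length < nchar(core) + 4L) stop("length must be >= core length + 4")
  if (nchar(cassette) > length) stop("cassette does not fit")
  backbone <- substr(paste(rep("TA", ceiling(length / 2)), collapse = ""),
                     1L, length)
  off <- (length - nchar(cassette)) %/% 2L   # cassette start - 1
  res <- paste0(substr(backbone, 1L, off), cassette,
                substr(backbone, off + nchar(cassette) + 1L, length))
  if (is.null(name)) name <- paste0("oligo_", cassette)
  seq <- duplex_seq(res, "linear", name = name)

  meth <- methylation_state(seq)
  if (!is.null(premeth)) {
    core_start <- off + 1L + nchar(flank5)
    core_ch <- strsplit(core, "")[[1]]
    if (premeth == "top") {
      p <- which(core_ch == "C")[1]
      if (is.na(p)) stop("core has no top-strand C to premethylate")
      meth <- methylation_state(seq, "top", core_start + p - 1L)
    } else if (premeth == "bottom") {
      p <- which(core_ch == "G")[1]
      if (is.na(p)) stop("core has no bottom-strand C to premethylate")
      meth <- methylation_state(seq, "bottom", core_start + p - 1L)
    } else {
      stop("premeth must be NULL, 'top' or 'bottom'")
    }
  }
  list(seq = seq, meth = meth)
}
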