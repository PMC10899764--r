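# Directed-evolution loop: error-prone PCR library generation with a biased
# substitution spectrum, genotype -> specificity phenotypes, restriction-based
# uncut-survival selection, and library statistics estimation. Substitutions
# only; codon-level deletion variants are constructed explicitly with
# make_deletion_variant(), never sampled.

BASES <- c("A", "C", "G", "T")

#' Default error-prone PCR substitution spectrum
#'
#' Joint probabilities over the 12 substitution types (rows = from-base on
#' the top strand, columns = to-base; diagonal zero; sums to 1). The default
#' puts 0.8 of the mass on A:T -> G:C transitions (0.4 on A->G and 0.4 on its
#' strand mirror T->C) and spreads the remaining 0.2 uniformly.
#'
#' @return 4x4 numeric matrix.
#' @export
default_substitution_spectrum <- function() {
  s <- matrix(0.02, 4, 4, dimnames = list(BASES, BASES))
  diag(s) <- 0
  s["A", "G"] <- 0.4
  s["T", "C"] <- 0.4
  s / sum(s)
}

#' Error-prone PCR mutagenesis model
#'
#' @param mean_mutations_per_gene Non-negative Poisson rate of substitutions
#'   per clone.
#' @param substitution_bias 4x4 joint probability matrix over substitution
#'   types as recorded on the top strand (rows from-base, columns to-base,
#'   zero diagonal); normalised to sum 1. Strand symmetry is the caller's
#'   choice: a bottom-strand A->G event is recorded as T->C on the top
#'   strand, so a strand-symmetric spectrum has mirrored entries.
#' @param gene_length Gene length in bases (bookkeeping; checked at use).
#' @return Object of class `mutagenesis_model`.
#' @export
mutagenesis_model <- function(mean_mutations_per_gene = 2.5,
                              substitution_bias = default_substitution_spectrum(),
                              gene_length = NA_integer_) {
  if (mean_mutations_per_gene < 0) stop("mean mutation rate must be >= 0")
  b <- substitution_bias
  if (!is.matrix(b) || !identical(dim(b), c(4L, 4L))) {
    stop("substitution_bias must be a 4x4 matrix")
  }
  dimnames(b) <- list(BASES, BASES)
  if (any(diag(b) != 0)) stop("self-substitutions are not allowed")
  if (any(b < 0) || sum(b) <= 0) stop("substitution_bias must be non-negative")
  structure(list(mean_mutations_per_gene = mean_mutations_per_gene,
                 substitution_bias = b / sum(b),
                 gene_length = as.integer(gene_length)),
            class = "mutagenesis_model")
}

#' Simulate an error-prone PCR library
#'
#' Per clone, the substitution count is Poisson with the model mean; each
#' substitution draws a (from, to) type from the spectrum and a uniformly
#' chosen not-yet-mutated position carrying the from-base.
#'
#' @param gene Character scalar over A/C/G/T (top strand of the gene).
#' @param model A [mutagenesis_model()].
#' @param n Number of clones.
#' @param seed Integer seed.
#' @return Character vector of `n` mutant sequences.
#' @export
mutagenize_library <- function(gene, model, n, seed) {
  stopifnot(inherits(model, "mutagenesis_model"), n >= 1L)
  gene <- toupper(gene)
  ref <- strsplit(gene, "")[[1]]
  L <- length(ref)
  spec <- model$substitution_bias
  types <- which(spec > 0, arr.ind = TRUE)
  type_p <- spec[types]
  pos_by_base <- lapply(BASES, function(b) which(ref == b))
  names(pos_by_base) <- BASES

  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      k <- stats::rpois(1, model$mean_mutations_per_gene)
      if (k == 0L) return(gene)
      mut <- ref
      used <- integer(0)
      for (j in seq_len(k)) {
        # redraw the type if every position of that from-base is taken
        for (attempt in 1:100) {
          t <- types[sample.int(nrow(types), 1, prob = type_p), ]
          from <- BASES[t[1]]
          to <- BASES[t[2]]
          avail <- setdiff(pos_by_base[[from]], used)
          if (length(avail) > 0L) break
        }
        if (length(avail) == 0L) break
        p <- avail[sample.int(length(avail), 1)]
        mut[p] <- to
        used <- c(used, p)
      }
      paste(mut, collapse = "")
    }, character(1))
  })
}

#' Estimate mutation statistics of a library
#'
#' Per-clone Hamming differences against the reference and the substitution
#' spectrum tabulated by (reference base -> observed base).
#'
#' @param library Character vector of clone sequences (same length as
#'   `reference`; indels are out of scope).
#' @param reference Character scalar.
#' @return List with `mean_per_gene`, `per_clone` (integer vector),
#'   `spectrum` (4x4 count matrix) and `n_substitutions`.
#' @export
estimate_mutation_stats <- function(library, reference) {
  reference <- toupper(reference)
  ref <- strsplit(reference, "")[[1]]
  if (any(nchar(library) != length(ref))) {
    stop("all library sequences must match the reference length")
  }
  spectrum <- matrix(0L, 4, 4, dimnames = list(BASES, BASES))
  per_clone <- vapply(library, function(s) {
    ch <- strsplit(toupper(s), "")[[1]]
    d <- which(ch != ref)
    for (p in d) spectrum[ref[p], ch[p]] <<- spectrum[ref[p], ch[p]] + 1L
    length(d)
  }, integer(1), USE.NAMES = FALSE)
  list(mean_per_gene = mean(per_clone), per_clone = per_clone,
       spectrum = spectrum, n_substitutions = sum(spectrum))
}

#' A single round of restriction-based selection
#'
#' @param selection_enzyme Enzyme label or [restriction_enzyme()].
#' @param survival_rule Only `"survive_if_uncut"` is modelled: a clone
#'   survives iff its self-methylated plasmid is not cut at all.
#' @return Object of class `selection_round`.
#' @export
selection_round <- function(selection_enzyme,
                            survival_rule = "survive_if_uncut") {
  survival_rule <- match.arg(survival_rule, "survive_if_uncut")
  structure(list(selection_enzyme = selection_enzyme,
                 survival_rule = survival_rule),
            class = "selection_round")
}

#' Simulate one uncut-survival selection round
#'
#' Each clone's plasmid is methylated deterministically according to its
#' phenotype and digested with the selection enzyme; clones whose plasmid
#' stays circular survive. Enrichment per phenotype class is the survivor
#' frequency divided by the input frequency.
#'
#' @param library Character vector of genotype sequences.
#' @param phenotype_map Function mapping a genotype to an
#'   [mtase_specificity()] or `NULL` (inactive).
#' @param plasmid A circular [duplex_seq()] carrying the selection sites.
#' @param round A [selection_round()].
#' @param threshold Deterministic methylation threshold.
#' @return List with `survivors` (indices into `library`), `survived`
#'   (logical vector) and `enrichment` (data frame per phenotype class:
#'   input count, survivor count, enrichment factor).
#' @export
simulate_selection <- function(library, phenotype_map, plasmid, round,
                               threshold = 0.5) {
  stopifnot(inherits(round, "selection_round"),
            inherits(plasmid, "duplex_seq"))
  enz <- resolve_enzymes(round$selection_enzyme)[[1]]
  phenos <- lapply(library, phenotype_map)
  classes <- vapply(phenos, function(p) {
    if (is.null(p)) "inactive" else p$name
  }, character(1))

  # one digest per distinct phenotype class
  survives <- vapply(unique(classes), function(cl) {
    p <- phenos[[match(cl, classes)]]
    meth <- if (is.null(p)) methylation_state(plasmid) else
      apply_methylation(plasmid, p, "deterministic", threshold)
    digest(plasmid, meth, enz)$status == "uncut_circular"
  }, logical(1))
  survived <- unname(survives[classes])

  input <- table(classes)
  surv <- table(factor(classes[survived], levels = names(input)))
  n_surv <- sum(survived)
  enrich <- data.frame(
    phenotype = names(input),
    input = as.integer(input),
    survivors = as.integer(surv),
    input_freq = as.numeric(input) / length(classes),
    survivor_freq = if (n_surv > 0) as.numeric(surv) / n_surv else NA_real_,
    stringsAsFactors = FALSE
  )
  enrich$enrichment <- enrich$survivor_freq / enrich$input_freq
  list(survivors = which(survived), survived = survived, enrichment = enrich)
}

#' Construct an in-frame deletion variant
#'
#' Removes a window (default one codon, 3 bp) from a plasmid or gene; refuses
#' deletions overlapping any site of the given motifs.
#'
#' @param plasmid A [duplex_seq()].
#' @param start 1-based first deleted position.
#' @param length Number of bases to delete (0 returns the input unchanged).
#' @param protected_motifs Character vector of IUPAC motifs whose sites must
#'   not be disrupted (default Alw44I's).
#' @return A [duplex_seq()] shortened by `length` bases.
#' @export
make_deletion_variant <- function(plasmid, start, length = 3L,
                                  protected_motifs = "GTGCAC") {
  stopifnot(inherits(plasmid, "duplex_seq"))
  length <- as.integer(length)
  if (length == 0L) return(plasmid)
  if (start < 1L || start + length - 1L > plasmid$length) {
    stop("deletion window outside the sequence")
  }
  del <- seq.int(start, start + length - 1L)
  for (motif in protected_motifs) {
    sites <- scan_motif(plasmid, motif)
    m <- nchar(motif)
    for (s in sites$start) {
      win <- wrap_pos(seq.int(s, s + m - 1L), plasmid$length)
      if (any(del %in% win)) {
        stop("deletion overlaps a planted ", motif, " site at ", s)
      }
    }
  }
  res <- paste0(substr(plasmid$residues, 1L, start - 1L),
                substr(plasmid$residues, start + length, plasmid$length))
  duplex_seq(res, plasmid$topology,
             name = paste0(plasmid$name, "_del", start, "_", length))
}
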