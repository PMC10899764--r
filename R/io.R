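# File formats: FASTA (via Biostrings), a minimal GenBank flat-file reader
# (LOCUS topology + ORIGIN sequence), YAML specificity profiles, and
# observation documents.

#' Read a duplex sequence from FASTA
#'
#' @param path FASTA file with at least one record; the first is used.
#' @param topology Topology to assign (FASTA does not record it).
#' @return A [duplex_seq()].
#' @export
read_fasta_duplex <- function(path, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) < 1L) stop("no sequences in ", path)
  duplex_seq(as.character(set[[1]]), topology, name = names(set)[1])
}

#' Write a duplex sequence to FASTA
#'
#' @param seq A [duplex_seq()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_duplex <- function(seq, path) {
  set <- Biostrings::DNAStringSet(seq$residues)
  names(set) <- paste0(seq$name, " [topology=", seq$topology, "]")
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read a duplex sequence from a GenBank flat file
#'
#' Minimal reader: takes the topology (circular/linear) from the LOCUS line
#' and the sequence from the ORIGIN block. Features are ignored.
#'
#' @param path GenBank flat file.
#' @param topology Optional override of the LOCUS topology.
#' @return A [duplex_seq()].
#' @export
read_genbank_duplex <- function(path, topology = NULL) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0L) stop("no LOCUS line in ", path)
  fields <- strsplit(trimws(locus[1]), "\\s+")[[1]]
  name <- if (length(fields) >= 2L) fields[2] else "genbank_seq"
  if (is.null(topology)) {
    topology <- if (any(grepl("circular", locus[1], ignore.case = TRUE))) {
      "circular"
    } else {
      "linear"
    }
  }
  o <- grep("^ORIGIN", lines)
  if (length(o) == 0L) stop("no ORIGIN block in ", path)
  end <- grep("^//", lines)
  end <- if (length(end) > 0L) min(end[end > o[1]]) else length(lines) + 1L
  body <- lines[(o[1] + 1L):(end - 1L)]
  residues <- toupper(gsub("[^acgtACGT]", "", paste(body, collapse = "")))
  duplex_seq(residues, topology, name = name)
}

#' Write a duplex sequence as a minimal GenBank flat file
#'
#' @param seq A [duplex_seq()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank_duplex <- function(seq, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s   SYN",
                     seq$name, seq$length, seq$topology), con)
  writeLines(sprintf("DEFINITION  %s.", seq$name), con)
  writeLines("ORIGIN", con)
  res <- tolower(seq$residues)
  for (i in seq(1L, seq$length, by = 60L)) {
    chunk <- substr(res, i, min(i + 59L, seq$length))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", i, paste(blocks, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Read a specificity profile from YAML
#'
#' Expected keys: `name`, `core` (list of dinucleotides), optional
#' `flank5_weights`/`flank3_weights` (maps base -> weight) and `efficiency`.
#'
#' @param path YAML file.
#' @return An [mtase_specificity()].
#' @export
read_specificity_profile <- function(path) {
  doc <- yaml::read_yaml(path)
  mtase_specificity(
    core = unlist(doc$core),
    flank5_weights = if (!is.null(doc$flank5_weights))
      unlist(doc$flank5_weights),
    flank3_weights = if (!is.null(doc$flank3_weights))
      unlist(doc$flank3_weights),
    efficiency = doc$efficiency %||% 1,
    name = doc$name
  )
}

#' Write a specificity profile to YAML
#'
#' @param spec An [mtase_specificity()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_specificity_profile <- function(spec, path) {
  yaml::write_yaml(list(
    name = spec$name,
    core = as.list(spec$core),
    flank5_weights = as.list(spec$flank5_weights),
    flank3_weights = as.list(spec$flank3_weights),
    efficiency = spec$efficiency
  ), path)
  invisible(path)
}

#' Resolve a specificity argument
#'
#' Accepts an [mtase_specificity()], the name of a shipped profile
#' (`"quadruple_mutant_CC"`), a plain core string like `"CG"` or `"CA+CC"`,
#' or a path to a YAML profile.
#'
#' @param x Specification (see Details).
#' @return An [mtase_specificity()].
#' @export
resolve_specificity <- function(x) {
  if (inherits(x, "mtase_specificity")) return(x)
  stopifnot(is.character(x), length(x) == 1L)
  if (identical(x, "quadruple_mutant_CC")) return(quadruple_mutant_cc_profile())
  if (file.exists(x)) return(read_specificity_profile(x))
  mtase_specificity(strsplit(x, "+", fixed = TRUE)[[1]])
}

#' Read observed band patterns from YAML
#'
#' A list of documents with keys `enzyme`, `bands` (bp), and optional flags
#' `uncut` and `full_length_linear`.
#'
#' @param path YAML file.
#' @return List of [observed_pattern()]s.
#' @export
read_observations <- function(path) {
  doc <- yaml::read_yaml(path)
  lapply(doc, function(d) {
    observed_pattern(d$enzyme, unlist(d$bands) %||% numeric(0),
                     uncut = isTRUE(d$uncut),
                     full_length_linear = isTRUE(d$full_length_linear))
  })
}
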