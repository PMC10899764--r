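# Restriction enzymes with explicit methylation-sensitivity semantics.
# A sensitivity rule watches specific cytosines of the recognition motif;
# for self-complementary motifs the watched positions are expanded to both
# orientations of the duplex site. Only the cytosines a rule names are
# watched: 5mC elsewhere inside a site never blocks by default.

#' Methylation-sensitivity rule
#'
#' @param positions Integer vector of motif positions (1-based, as read
#'   5'->3' on the matching strand) whose cytosines the rule watches.
#' @param mode `"blocked_if_any_strand"` (fires when at least one watched
#'   cytosine carries 5mC on either strand of the duplex site) or
#'   `"blocked_if_both_strands"` (fires only when some watched position's
#'   cytosine is marked on both strands, i.e. the symmetric pair of a
#'   palindromic site).
#' @param note Free-text provenance of the rule.
#' @return Object of class `sensitivity_rule`.
#' @export
sensitivity_rule <- function(positions,
                             mode = c("blocked_if_any_strand",
                                      "blocked_if_both_strands"),
                             note = "") {
  mode <- match.arg(mode)
  positions <- as.integer(positions)
  if (length(positions) < 1L || any(positions < 1L)) {
    stop("rule must watch at least one positive motif position")
  }
  structure(list(positions = positions, mode = mode, note = note),
            class = "sensitivity_rule")
}

#' Restriction enzyme definition
#'
#' @param name Enzyme label.
#' @param motif IUPAC recognition pattern.
#' @param cut_offset Bases from the motif start to the top-strand cut point
#'   (`0 <= cut_offset <= nchar(motif)`); the duplex break is reported at the
#'   top-strand coordinate.
#' @param rules List of [sensitivity_rule()]s; the site is blocked if ANY
#'   rule fires.
#' @return Object of class `restriction_enzyme`.
#' @export
restriction_enzyme <- function(name, motif, cut_offset, rules = list()) {
  motif <- check_iupac(motif)
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0L || cut_offset > nchar(motif)) {
    stop("cut_offset must be between 0 and the motif length")
  }
  for (r in rules) {
    stopifnot(inherits(r, "sensitivity_rule"))
    for (p in r$positions) {
      if (p > nchar(motif)) stop("watched position beyond motif: ", p)
      set <- IUPAC_SETS[[substr(motif, p, p)]]
      if (!("C" %in% set)) {
        stop("watched position ", p, " is never a C in motif ", motif)
      }
    }
  }
  structure(list(name = name, motif = motif, cut_offset = cut_offset,
                 rules = rules, palindromic = is_palindromic_motif(motif)),
            class = "restriction_enzyme")
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  cat(sprintf("<restriction_enzyme %s: %s, cut offset %d, %d rule(s)>\n",
              x$name, x$motif, x$cut_offset, length(x$rules)))
  invisible(x)
}

# Watched duplex coordinates for one rule at one site. Returns a list of
# "position groups": each group is the set of (strand, abs-position) keys
# that realise one watched motif position in one orientation, paired across
# orientations for both-strand semantics. Coordinates whose actual base is
# not a cytosine on that strand are dropped (degenerate motif positions).
watched_coords <- function(seq, site, enz, rule) {
  start <- as.integer(site$start)
  m <- nchar(enz$motif)
  L <- seq$length
  circ <- seq$topology == "circular"
  norm <- function(p) if (circ) wrap_pos(p, L) else p
  orientations <- if (enz$palindromic) c("top", "bottom") else site$strand

  lapply(rule$positions, function(p) {
    coords <- list()
    for (ori in orientations) {
      if (ori == "top") {
        pos <- norm(start + p - 1L)
        strand <- "top"
        is_c <- identical(base_at(seq, pos), "C")
      } else {
        pos <- norm(start + m - p)
        strand <- "bottom"
        is_c <- identical(complement_base(base_at(seq, pos)), "C")
      }
      if (isTRUE(is_c)) coords[[ori]] <- paste(strand, pos)
    }
    coords
  })
}

#' Decide whether methylation blocks cleavage at a site
#'
#' Maps each rule's motif-relative watched cytosines to absolute duplex
#' coordinates (both orientations for palindromic motifs) and evaluates the
#' rule against the methylation state. The site is blocked if any rule fires.
#'
#' @param seq A [duplex_seq()].
#' @param meth A [methylation_state()].
#' @param site One row of [scan_motif()] output for `enz$motif`.
#' @param enz A [restriction_enzyme()].
#' @return List with `blocked` (logical) and `firing_rules` (integer indices
#'   into `enz$rules`).
#' @export
is_blocked <- function(seq, meth, site, enz) {
  stopifnot(inherits(enz, "restriction_enzyme"))
  site_motif <- if (!is.null(site$motif)) site$motif[[1]] else NULL
  if (!is.null(site_motif) && !identical(site_motif, enz$motif)) {
    stop("site was matched with motif ", site_motif,
         ", not the enzyme's motif ", enz$motif)
  }
  marked <- mark_keys(meth)
  firing <- integer(0)
  for (i in seq_along(enz$rules)) {
    rule <- enz$rules[[i]]
    groups <- watched_coords(seq, site, enz, rule)
    fired <- if (rule$mode == "blocked_if_any_strand") {
      any(unlist(groups) %in% marked)
    } else {
      any(vapply(groups, function(g) {
        length(g) == 2L && all(unlist(g) %in% marked)
      }, logical(1)))
    }
    if (fired) firing <- c(firing, i)
  }
  list(blocked = length(firing) > 0L, firing_rules = firing)
}

parse_rule_string <- function(s, row = NA) {
  parts <- strsplit(trimws(s), "|", fixed = TRUE)[[1]]
  if (length(parts) < 2L) {
    stop("malformed rule '", s, "' in row ", row,
         " (expected 'pos1,pos2|any' or '...|both')")
  }
  mode <- switch(trimws(parts[2]),
    any = "blocked_if_any_strand",
    both = "blocked_if_both_strands",
    stop("unknown blocking mode '", trimws(parts[2]), "' in row ", row)
  )
  note <- if (length(parts) >= 3L) trimws(parts[3]) else ""
  positions <- as.integer(strsplit(parts[1], ",")[[1]])
  if (any(is.na(positions))) {
    stop("malformed watched positions in rule '", s, "' in row ", row)
  }
  sensitivity_rule(positions, mode, note)
}

format_rule_string <- function(rule) {
  mode <- if (rule$mode == "blocked_if_any_strand") "any" else "both"
  base <- paste0(paste(rule$positions, collapse = ","), "|", mode)
  if (nzchar(rule$note)) paste0(base, "|", rule$note) else base
}

#' Load a restriction-enzyme table
#'
#' Tab-separated table with columns `name`, `motif`, `cut_offset`, `rules`.
#' Rules are semicolon-separated `positions|mode[|note]` strings, e.g.
#' `"6|any"` or `"1,3|any"`; mode is `any` (blocked if any watched cytosine
#' is marked on either strand) or `both` (blocked only when marked on both
#' strands). Round-trips bit-exactly through [write_enzyme_table()].
#'
#' @param path File path; default is the table of the nine
#'   methylation-sensitive enzymes shipped with the package.
#' @return Named list of [restriction_enzyme()] objects.
#' @export
load_enzyme_table <- function(path = system.file("extdata", "enzymes.tsv",
                                                 package = "methdigest")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(tab) == 0L) {
    warning("enzyme table '", path, "' is empty")
    return(list())
  }
  need <- c("name", "motif", "cut_offset", "rules")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    stop("enzyme table lacks column(s): ", paste(miss, collapse = ", "))
  }
  enzymes <- lapply(seq_len(nrow(tab)), function(i) {
    rules <- lapply(strsplit(tab$rules[i], ";", fixed = TRUE)[[1]],
                    parse_rule_string, row = i)
    restriction_enzyme(tab$name[i], tab$motif[i],
                       as.integer(tab$cut_offset[i]), rules)
  })
  stats::setNames(enzymes, tab$name)
}

#' Write a restriction-enzyme table
#'
#' @param enzymes Named list of [restriction_enzyme()]s.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_enzyme_table <- function(enzymes, path) {
  rows <- lapply(enzymes, function(e) {
    data.frame(name = e$name, motif = e$motif, cut_offset = e$cut_offset,
               rules = paste(vapply(e$rules, format_rule_string,
                                    character(1)), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The nine methylation-sensitive enzymes shipped with the package
#'
#' @return Named list of [restriction_enzyme()]s (Alw44I, XmiI, BsuRI,
#'   Bsh1236I, Hin6I, Eco47I, MspI, BamHI, NcoI) with their documented
#'   C5-methylation blocking rules.
#' @export
mpei_enzymes <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_enzyme_table()
    cache
  }
})
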