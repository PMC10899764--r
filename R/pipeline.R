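# Pipeline surface tying the stages together: a validated run configuration,
# stage dispatch, and machine-readable JSON reports embedding the seed and
# input checksums. The thin command-line wrapper in inst/cli/methdigest
# forwards to run_pipeline().

#' Run configuration for the analysis pipeline
#'
#' @param stage One of `fixtures`, `digest`, `predict`, `infer`, `coverage`,
#'   `select-sim`, `epcr-sim`, `mm-fit`.
#' @param input Path to the input sequence (FASTA or GenBank; extension
#'   `.gb`/`.gbk` selects the GenBank reader) or data file, where the stage
#'   needs one. `NULL` for `fixtures`.
#' @param out_dir Output directory for reports (created if missing).
#' @param enzymes Character vector of enzyme names, or a path to an enzyme
#'   table for non-shipped enzymes.
#' @param mtase Specificity: profile name, core string, YAML path or
#'   [mtase_specificity()] (see [resolve_specificity()]).
#' @param observations Path to a YAML observations document (`infer` stage).
#' @param mode `"deterministic"` or `"stochastic"` methylation.
#' @param seed Integer seed, recorded in every report.
#' @param rel_tol Band-matching tolerance.
#' @param topology Topology override for FASTA inputs.
#' @param n Stage-specific count (molecules, clones).
#' @param E Enzyme concentration for `mm-fit` (nM).
#' @param verbose Print per-site blocking decisions.
#' @return Object of class `run_config`.
#' @export
run_config <- function(stage, input = NULL, out_dir = "methdigest_out",
                       enzymes = "Alw44I", mtase = "CG",
                       observations = NULL,
                       mode = c("deterministic", "stochastic"), seed = 1L,
                       rel_tol = 0.05, topology = "circular", n = 1000L,
                       E = 5, verbose = FALSE) {
  stage <- match.arg(stage, c("fixtures", "digest", "predict", "infer",
                              "coverage", "select-sim", "epcr-sim", "mm-fit"))
  mode <- match.arg(mode)
  if (!is.null(input) && !file.exists(input)) {
    stop("input file not found: ", input)
  }
  if (!is.null(observations) && !file.exists(observations)) {
    stop("observations file not found: ", observations)
  }
  structure(list(stage = stage, input = input, out_dir = out_dir,
                 enzymes = enzymes, mtase = mtase,
                 observations = observations, mode = mode,
                 seed = as.integer(seed), rel_tol = rel_tol,
                 topology = topology, n = as.integer(n), E = E,
                 verbose = verbose),
            class = "run_config")
}

read_any_duplex <- function(path, topology) {
  if (grepl("\\.(gb|gbk|genbank)$", path, ignore.case = TRUE)) {
    read_genbank_duplex(path)
  } else {
    read_fasta_duplex(path, topology)
  }
}

file_checksum <- function(path) {
  if (is.null(path)) NA_character_ else unname(tools::md5sum(path))
}

report_header <- function(config, ...) {
  list(package = "methdigest",
       version = as.character(utils::packageVersion("methdigest")),
       stage = config$stage, seed = config$seed,
       input = config$input, input_md5 = file_checksum(config$input), ...)
}

write_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

fragment_report <- function(fs) {
  list(status = fs$status,
       fragments = sort(fs$fragments, decreasing = TRUE),
       cut_positions = fs$cut_positions,
       blocked_sites = fs$blocked_sites,
       enzymes = fs$enzymes, sequence = fs$seq_name,
       sequence_length = fs$seq_length)
}

#' Execute one pipeline stage and write its reports
#'
#' Stages: `fixtures` writes the Alw44I and selection fixtures as FASTA and
#' GenBank plus a manifest; `digest` methylates the input and digests it;
#' `predict` reports the pattern expected under a specificity; `infer`
#' enumerates specificities consistent with observed bands; `coverage`
#' reports site contexts; `select-sim` runs a demonstration selection round;
#' `epcr-sim` simulates a mutant library and its recovered statistics;
#' `mm-fit` fits Michaelis-Menten parameters to a two-column `S, v` table.
#' Every report embeds the seed and input checksum.
#'
#' @param config A [run_config()].
#' @return Named list of report objects (also written as JSON under
#'   `config$out_dir`), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(config$out_dir, paste0(name, ".json"))
  reports <- list()

  if (config$stage == "fixtures") {
    fx <- make_alw44i_fixture(seed = config$seed)
    sel <- make_selection_fixture(seed = config$seed)
    write_fasta_duplex(fx, file.path(config$out_dir, "alw44i_fixture.fasta"))
    write_genbank_duplex(fx, file.path(config$out_dir, "alw44i_fixture.gb"))
    write_fasta_duplex(sel, file.path(config$out_dir,
                                      "selection_fixture.fasta"))
    write_genbank_duplex(sel, file.path(config$out_dir,
                                        "selection_fixture.gb"))
    manifest <- c(report_header(config),
      list(alw44i_fixture = list(
             length = fx$length,
             sites = scan_motif(fx, "GTGCAC", "Alw44I")$start,
             complete_digest =
               digest(fx, methylation_state(fx), "Alw44I")$fragments,
             contexts = table_to_list(context_coverage(fx, "Alw44I")$context)),
           selection_fixture = list(
             length = sel$length,
             eco47i_sites = scan_motif(sel, "GGWCC", "Eco47I")$start,
             xmii_sites = scan_motif(sel, "GTMKAC", "XmiI")$start,
             eco47i_contexts =
               table_to_list(context_coverage(sel, "Eco47I")$context))))
    reports$manifest <- manifest
    write_report(manifest, out("fixtures_manifest"))
  } else if (config$stage %in% c("digest", "predict")) {
    seq <- read_any_duplex(config$input, config$topology)
    spec <- resolve_specificity(config$mtase)
    meth <- if (config$mode == "deterministic") {
      apply_methylation(seq, spec, "deterministic")
    } else {
      apply_methylation(seq, spec, "stochastic", seed = config$seed)
    }
    fs <- digest(seq, meth, as.list(config$enzymes))
    if (config$verbose) {
      print(fs$blocked_sites)
    }
    rep <- c(report_header(config),
             list(mtase = spec$name, mode = config$mode,
                  mark_count = nrow(meth$marks)),
             fragment_report(fs))
    reports$digest <- rep
    write_report(rep, out(config$stage))
  } else if (config$stage == "infer") {
    seq <- read_any_duplex(config$input, config$topology)
    obs <- read_observations(config$observations)
    res <- infer_specificities(seq, obs, rel_tol = config$rel_tol)
    rep <- c(report_header(config),
             list(observations_md5 = file_checksum(config$observations),
                  consistent = res, grid = attr(res, "grid")))
    reports$infer <- rep
    write_report(rep, out("infer"))
  } else if (config$stage == "coverage") {
    seq <- read_any_duplex(config$input, config$topology)
    rep_list <- lapply(config$enzymes, function(e) {
      cov <- context_coverage(seq, e)
      list(enzyme = e, contexts = cov,
           context_counts = table_to_list(cov$context))
    })
    rep <- c(report_header(config), list(coverage = rep_list))
    reports$coverage <- rep
    write_report(rep, out("coverage"))
  } else if (config$stage == "epcr-sim") {
    gene <- if (!is.null(config$input)) {
      read_any_duplex(config$input, "linear")$residues
    } else {
      withr::with_seed(config$seed,
        paste(sample(BASES, 1185L, replace = TRUE), collapse = ""))
    }
    model <- mutagenesis_model(gene_length = nchar(gene))
    lib <- mutagenize_library(gene, model, n = config$n, seed = config$seed)
    stats_ <- estimate_mutation_stats(lib, gene)
    rep <- c(report_header(config),
             list(n_clones = config$n, gene_length = nchar(gene),
                  mean_mutations_per_gene = stats_$mean_per_gene,
                  spectrum = as.data.frame(as.table(stats_$spectrum))))
    reports$epcr <- rep
    write_report(rep, out("epcr-sim"))
  } else if (config$stage == "select-sim") {
    plasmid <- if (!is.null(config$input)) {
      read_any_duplex(config$input, config$topology)
    } else {
      make_selection_fixture(seed = config$seed)
    }
    # demonstration phenotype map: CG for the reference genotype, the
    # CC-preferring mutant profile for anything mutated
    gene <- withr::with_seed(config$seed,
      paste(sample(BASES, 300L, replace = TRUE), collapse = ""))
    lib <- mutagenize_library(gene, mutagenesis_model(), n = config$n,
                              seed = config$seed + 1L)
    pmap <- function(g) {
      if (identical(g, gene)) mtase_specificity("CG")
      else quadruple_mutant_cc_profile()
    }
    res <- simulate_selection(lib, pmap, plasmid,
                              selection_round(config$enzymes[[1]]))
    rep <- c(report_header(config),
             list(selection_enzyme = config$enzymes[[1]],
                  enrichment = res$enrichment,
                  n_survivors = length(res$survivors)))
    reports$selection <- rep
    write_report(rep, out("select-sim"))
  } else if (config$stage == "mm-fit") {
    tab <- utils::read.delim(config$input)
    names(tab)[1:2] <- c("S", "v")
    fit <- fit_mm(tab, E = config$E)
    rep <- c(report_header(config),
             list(KM = fit$KM, kcat = fit$kcat, KM_se = fit$KM_se,
                  kcat_se = fit$kcat_se, E = fit$E,
                  converged = fit$converged,
                  residuals = unname(fit$residuals)))
    reports$mm_fit <- rep
    write_report(rep, out("mm-fit"))
  }
  invisible(reports)
}

table_to_list <- function(x) {
  tb <- table(x)
  stats::setNames(as.list(as.integer(tb)), names(tb))
}
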