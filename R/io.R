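# SMILES file I/O, TSV writers and the command-line front end.

#' Read a SMILES file
#'
#' One molecule per line, `SMILES<TAB>ID`; the identifier is optional
#' (`MOL<line>` is assigned when missing). Lines that fail to parse or
#' contain more than one component (salt-like records) are skipped with
#' a per-line diagnostic; the diagnostics are attached as attribute
#' `"problems"` and reported via a warning.
#'
#' @param path path to a `.smi` file.
#' @return A tibble with columns `compound_id`, `smiles`.
#' @export
read_smiles <- function(path) {
  if (!file.exists(path)) stop("SMILES file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0) stop("no molecule records in ", path)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  smiles <- trimws(purrr::map_chr(fields, 1))
  ids <- purrr::map2_chr(fields, keep, function(f, ln) {
    if (length(f) >= 2 && nzchar(trimws(f[2]))) trimws(f[2]) else
      paste0("MOL", ln)
  })
  res <- chem_canonical(smiles)
  probs <- list()
  ok <- logical(length(keep))
  for (i in seq_along(keep)) {
    r <- res[[i]]
    if (!isTRUE(r$ok)) {
      probs[[length(probs) + 1]] <- tibble::tibble(
        line = keep[i], message = paste0("SMILES failed to parse: ", smiles[i]))
    } else if (r$n_components > 1) {
      probs[[length(probs) + 1]] <- tibble::tibble(
        line = keep[i],
        message = paste0("multi-component SMILES (salt?); skipped: ", smiles[i]))
    } else {
      ok[i] <- TRUE
    }
  }
  if (!any(ok)) stop("no parseable single-component molecules in ", path)
  out <- tibble::tibble(compound_id = ids[ok], smiles = smiles[ok])
  probs <- if (length(probs)) dplyr::bind_rows(probs) else
    tibble::tibble(line = integer(), message = character())
  if (nrow(probs)) {
    warning(nrow(probs), " line(s) skipped while reading ", path, call. = FALSE)
  }
  attr(out, "problems") <- probs
  out
}

#' Write molecules as a SMILES file
#' @param molecules data frame with `compound_id`, `smiles`.
#' @param path output path.
#' @export
write_smiles <- function(molecules, path) {
  writeLines(paste(molecules$smiles, molecules$compound_id, sep = "\t"), path)
  invisible(path)
}

#' Write per-compound fragment lists as TSV
#'
#' One line per compound: `ID<TAB>frag1 frag2 ...` (space-separated
#' canonical SMILES; empty field when no fragment survived).
#'
#' @param fragments output of [fragment_molecules()].
#' @param path output path (`"-"` for standard output).
#' @param compound_ids compounds to report, in order; defaults to the
#'   compounds present in `fragments`.
#' @export
write_fragments_tsv <- function(fragments, path, compound_ids = NULL) {
  if (is.null(compound_ids)) compound_ids <- unique(fragments$compound_id)
  by_id <- split(fragments$smiles, fragments$compound_id)
  lines <- vapply(compound_ids, function(id) {
    paste0(id, "\t", paste(by_id[[id]], collapse = " "))
  }, character(1))
  write_lines_or_stdout(lines, path)
}

#' Write a fragment frequency table as TSV
#' @param lib a `fragment_library`.
#' @param path output path (`"-"` for standard output).
#' @export
write_frequency_tsv <- function(lib, path) {
  lines <- c("canonical_smiles\tfrequency",
             paste(lib$freq$smiles, lib$freq$n_compounds, sep = "\t"))
  write_lines_or_stdout(lines, path)
}

#' Write a one-line run summary as TSV
#' @param lib a `fragment_library`.
#' @param params the [fragmentation_params()] of the run.
#' @param ruleset_label rule-set name used.
#' @param path output path (`"-"` for standard output).
#' @export
write_summary_tsv <- function(lib, params, ruleset_label, path) {
  dist <- if (lib$n_fragmented > 0) count_distribution(lib) else
    tibble::tibble(min = NA, q1 = NA, median = NA, q3 = NA, max = NA)
  header <- paste(c("ruleset", "k", "n_min", "m_max", "s_rel", "w_max", "x",
                    "n_fragmented", "n_unique_fragments",
                    "min", "q1", "median", "q3", "max"), collapse = "\t")
  fmt <- function(v) if (is.null(v)) "NA" else as.character(v)
  row <- paste(c(ruleset_label, fmt(params$k), fmt(params$n_min),
                 fmt(params$m_max), fmt(params$s_rel), fmt(params$w_max),
                 fmt(params$x), lib$n_fragmented, nrow(lib$freq),
                 unlist(lapply(dist, fmt))), collapse = "\t")
  write_lines_or_stdout(c(header, row), path)
}

write_lines_or_stdout <- function(lines, path) {
  if (identical(path, "-")) cat(lines, sep = "\n") else writeLines(lines, path)
  invisible(path)
}

cli_options <- function() {
  list(
    optparse::make_option(c("-i", "--input"), type = "character",
      help = "input SMILES file (SMILES<TAB>ID per line)"),
    optparse::make_option(c("-o", "--output"), type = "character", default = "-",
      help = "output file ['-' = stdout]"),
    optparse::make_option(c("-r", "--rules"), type = "character",
      default = "RECAP",
      help = "rule set: RECAP, BRICS, CCQ, extendedRECAP, or a rule-file path"),
    optparse::make_option(c("-k", "--combine"), type = "integer", default = 1L,
      help = "max smallest fragments combined; <= 0 = unlimited [default %default]"),
    optparse::make_option(c("-n", "--min-atoms"), type = "integer", default = 5L,
      dest = "n_min", help = "minimal heavy atoms per fragment [default %default]"),
    optparse::make_option(c("-m", "--max-atoms"), type = "integer", default = NA,
      dest = "m_max", help = "maximal heavy atoms per fragment [default none]"),
    optparse::make_option(c("-s", "--rel-size"), type = "double", default = 0.99,
      dest = "s_rel",
      help = "maximal size relative to parent (0,1]; <= 0 disables [default %default]"),
    optparse::make_option(c("-w", "--max-weight"), type = "double", default = NA,
      dest = "w_max", help = "maximal molecular weight in Da [default none]"),
    optparse::make_option(c("-x", "--dummy-atoms"), action = "store_true",
      default = FALSE, dest = "x",
      help = "cap cut points with dummy atoms (*) instead of hydrogens"),
    optparse::make_option(c("-e", "--extensive"), action = "store_true",
      default = FALSE,
      help = "smallest-fragment mode (alias for -k 1)"),
    optparse::make_option("--ro3", type = "character", default = "none",
      help = "rule-of-three filters: comma list of weight,xlogp,hbd,hba,rotb, or all/none"),
    optparse::make_option("--mode", type = "character", default = "per-compound",
      help = "output mode: per-compound | frequency | summary [default %default]"),
    optparse::make_option("--guard", type = "double", default = 1e5,
      help = "max connected subsets per molecule [default %default]"),
    optparse::make_option(c("-q", "--quiet"), action = "store_true",
      default = FALSE, help = "suppress log messages")
  )
}

#' Command-line entry point
#'
#' Thin front end used by the installed `molfrag` script: reads a
#' SMILES file, fragments every molecule, and writes the selected
#' output (per-compound fragment lists, a frequency table, or a run
#' summary). Flags mirror the fragmentation parameters: `-k` combine
#' cap, `-n` minimal atoms, `-m` maximal atoms, `-s` relative size,
#' `-w` maximal weight, `-x` dummy atoms, `-r` rule set, `-e`
#' smallest-fragment alias for `-k 1`. Logs go to standard error.
#'
#' @param args character vector of command-line arguments.
#' @return Exit status, invisibly: 0 on success (with a warning when no
#'   molecule was fragmented), 2 on fatal error.
#' @export
molfrag_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  parser <- optparse::OptionParser(
    usage = "molfrag -i molecules.smi [options]",
    option_list = cli_options(),
    prog = "molfrag")
  status <- tryCatch({
    opt <- optparse::parse_args(parser, args = args)
    if (is.null(opt$input)) stop("an input SMILES file is required (-i)")
    say <- function(...) if (!opt$quiet) message("[molfrag] ", ...)

    ruleset <- if (opt$rules %in% builtin_names) builtin_ruleset(opt$rules)
      else read_rules(opt$rules)
    mode <- match.arg(opt$mode, c("per-compound", "frequency", "summary"))
    if (opt$extensive) opt$combine <- 1L

    mols <- withCallingHandlers(
      read_smiles(opt$input),
      warning = function(w) {
        say(conditionMessage(w)); invokeRestart("muffleWarning")
      })
    rprob <- attr(mols, "problems")
    for (ln in seq_len(nrow(rprob))) say(rprob$message[ln])
    say(nrow(mols), " molecule(s) read from ", opt$input)

    params <- fragmentation_params(
      k = opt$combine, n_min = opt$n_min,
      m_max = if (is.na(opt$m_max)) NULL else opt$m_max,
      s_rel = if (is.na(opt$s_rel) || opt$s_rel <= 0) NULL else opt$s_rel,
      w_max = if (is.na(opt$w_max)) NULL else opt$w_max,
      x = opt$x, guard = opt$guard)
    frags <- withCallingHandlers(
      fragment_molecules(mols, ruleset, params = params),
      warning = function(w) {
        say(conditionMessage(w)); invokeRestart("muffleWarning")
      })
    for (msg in fragmentation_problems(frags)$message) say(msg)

    if (!identical(opt$ro3, "none")) {
      filters <- if (identical(opt$ro3, "all")) "all" else
        strsplit(opt$ro3, ",", fixed = TRUE)[[1]]
      unique_frags <- dplyr::distinct(frags, .data$smiles)
      filtered <- apply_ro3(unique_frags, filters = filters)
      counts <- ro3_counts(filtered)
      for (r in seq_len(nrow(counts))) {
        say("rule-of-three [", counts$filter[r], "]: ", counts$survivors[r],
            " of ", nrow(unique_frags), " unique fragments survive")
      }
      frags <- frags[frags$smiles %in% filtered$smiles, , drop = FALSE]
    }

    lib <- fragment_library(frags)
    say(lib$n_fragmented, " of ", nrow(mols), " molecule(s) fragmented; ",
        nrow(lib$freq), " unique fragment(s)")
    switch(mode,
      "per-compound" = write_fragments_tsv(frags, opt$output, mols$compound_id),
      "frequency" = write_frequency_tsv(lib, opt$output),
      "summary" = write_summary_tsv(lib, params, ruleset_name(ruleset),
                                    opt$output))
    if (lib$n_fragmented == 0) {
      warning("no molecule produced any surviving fragment", call. = FALSE)
    }
    0L
  }, error = function(e) {
    message("[molfrag] error: ", conditionMessage(e))
    2L
  })
  invisible(status)
}
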