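# All input and output files are plain tab-delimited text with a mandatory
# header row; the missing-value code is configurable (default "NA").

.read_tsv <- function(path, what) {
  if (!file.exists(path))
    stop(what, " file not found: ", path, call. = FALSE)
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    na.strings = character(0), check.names = FALSE,
                    strip.white = TRUE)
}

.require_columns <- function(df, cols, path, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " file '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
}

#' Read a parameter file
#'
#' Parameter files are `KEY = value` lines; `;` or `#` starts a comment and
#' keys are case-insensitive. Mandatory keys: `PLOIDY` (2 or 4),
#' `MAPFUNCTION` (`HALDANE` or `KOSAMBI`), `CHROMFILE`, `MAPFILE`,
#' `PEDFILE`, `FOUNDERFILE`, `OUTPUT` (output path prefix). Optional:
#' `MISSING` (missing-value code, default `NA`), `SEED` (integer),
#' `TEST` (0/1), `TESTMEIOSES` (meioses per chromosome in test mode,
#' default 10000). Relative file paths are resolved against the parameter
#' file's directory. Unknown keys are reported as warnings, not errors.
#'
#' @param path Path to the parameter file.
#' @return An object of class `run_parameters`.
#' @export
read_parameter_file <- function(path) {
  if (!file.exists(path))
    stop("parameter file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("[;#].*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad))
    stop("parameter file '", path, "': cannot parse line '",
         lines[bad][1L], "'", call. = FALSE)
  keys <- toupper(trimws(vapply(kv, `[`, character(1), 2L)))
  vals <- trimws(vapply(kv, `[`, character(1), 3L))
  names(vals) <- keys
  known <- c("PLOIDY", "MAPFUNCTION", "MISSING", "CHROMFILE", "MAPFILE",
             "PEDFILE", "FOUNDERFILE", "OUTPUT", "SEED", "TEST",
             "TESTMEIOSES")
  unknown <- setdiff(keys, known)
  if (length(unknown))
    warning("parameter file '", path, "': ignoring unknown key(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  need <- function(key) {
    if (!key %in% keys)
      stop("parameter file '", path, "': mandatory key ", key, " is missing",
           call. = FALSE)
    vals[[key]]
  }
  ploidy <- suppressWarnings(as.integer(need("PLOIDY")))
  if (is.na(ploidy) || !ploidy %in% c(2L, 4L))
    stop("PLOIDY must be 2 or 4, got '", need("PLOIDY"), "'", call. = FALSE)
  mapfunction <- toupper(need("MAPFUNCTION"))
  if (!mapfunction %in% c("HALDANE", "KOSAMBI"))
    stop("MAPFUNCTION must be one of HALDANE, KOSAMBI; got '",
         mapfunction, "'", call. = FALSE)
  dir <- dirname(path)
  resolve <- function(f)
    if (grepl("^(/|[A-Za-z]:)", f)) f else file.path(dir, f)
  files <- c(chromfile = resolve(need("CHROMFILE")),
             mapfile = resolve(need("MAPFILE")),
             pedfile = resolve(need("PEDFILE")),
             founderfile = resolve(need("FOUNDERFILE")))
  for (f in files)
    if (!file.exists(f))
      stop("referenced file not found: ", f, call. = FALSE)
  seed <- if ("SEED" %in% keys) suppressWarnings(as.integer(vals[["SEED"]]))
          else NA_integer_
  structure(list(ploidy = ploidy,
                 mapfunction = mapfunction,
                 missing_code = if ("MISSING" %in% keys) vals[["MISSING"]]
                                else "NA",
                 chromfile = unname(files[["chromfile"]]),
                 mapfile = unname(files[["mapfile"]]),
                 pedfile = unname(files[["pedfile"]]),
                 founderfile = unname(files[["founderfile"]]),
                 output_prefix = resolve(need("OUTPUT")),
                 seed = seed,
                 test_mode = "TEST" %in% keys &&
                   vals[["TEST"]] %in% c("1", "TRUE", "true", "yes"),
                 test_meioses = if ("TESTMEIOSES" %in% keys)
                   as.integer(vals[["TESTMEIOSES"]]) else 10000L),
            class = "run_parameters")
}

#' Write a parameter file
#'
#' Inverse of [read_parameter_file()]: writes the `KEY = value` lines.
#'
#' @param params A `run_parameters` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parameter_file <- function(params, path) {
  lines <- c(
    paste("PLOIDY =", params$ploidy),
    paste("MAPFUNCTION =", params$mapfunction),
    paste("MISSING =", params$missing_code),
    paste("CHROMFILE =", params$chromfile),
    paste("MAPFILE =", params$mapfile),
    paste("PEDFILE =", params$pedfile),
    paste("FOUNDERFILE =", params$founderfile),
    paste("OUTPUT =", params$output_prefix))
  if (!is.na(params$seed)) lines <- c(lines, paste("SEED =", params$seed))
  if (params$test_mode) lines <- c(lines, "TEST = 1",
                                   paste("TESTMEIOSES =", params$test_meioses))
  writeLines(lines, path)
  invisible(path)
}

#' Read a chromosome file
#'
#' Tab-delimited with header
#' `chromosome length centromere prefPairing quadrivalents`; lengths and
#' centromere positions in cM, `prefPairing` the preferential pairing
#' fraction, and `quadrivalents` either a forced quadrivalent fraction or
#' the missing code for the natural pairing model. Optional extra columns
#' `parallel` (fraction of quadrivalents that are parallel-type) and
#' `pairedCentromeres` (0/1).
#'
#' @param path Path to the chromosome file.
#' @param missing_code Missing-value code (default `"NA"`).
#' @return A list of [chromosome_spec()]s.
#' @export
read_chromosome_file <- function(path, missing_code = "NA") {
  df <- .read_tsv(path, "chromosome")
  .require_columns(df, c("chromosome", "length", "centromere", "prefPairing",
                         "quadrivalents"), path, "chromosome")
  if (nrow(df) == 0L)
    stop("chromosome file '", path, "' defines no chromosomes (empty genome)",
         call. = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    qv <- as.character(df$quadrivalents[i])
    qf <- if (qv == missing_code) "natural" else suppressWarnings(as.numeric(qv))
    if (!identical(qf, "natural") && is.na(qf))
      stop("chromosome file '", path, "' row ", i,
           ": quadrivalents must be a fraction or '", missing_code, "'",
           call. = FALSE)
    tryCatch(
      chromosome_spec(
        name = as.character(df$chromosome[i]),
        length = as.numeric(df$length[i]),
        centromere = as.numeric(df$centromere[i]),
        pref_pairing = as.numeric(df$prefPairing[i]),
        quadrivalent_fraction = qf,
        parallel_fraction = if ("parallel" %in% names(df))
          as.numeric(df$parallel[i]) else 0,
        paired_centromeres = if ("pairedCentromeres" %in% names(df))
          as.integer(df$pairedCentromeres[i]) > 0L else FALSE),
      error = function(e)
        stop("chromosome file '", path, "' row ", i, ": ",
             conditionMessage(e), call. = FALSE))
  })
}

#' Read a marker map file
#'
#' Tab-delimited with header `marker chromosome position` (position in
#' cM). Marker names must be unique, chromosomes known, and positions
#' within their chromosome.
#'
#' @param path Path to the map file.
#' @param specs List of [chromosome_spec()]s for cross-validation.
#' @return A data frame with columns `marker`, `chromosome`, `position`.
#' @export
read_map_file <- function(path, specs) {
  df <- .read_tsv(path, "map")
  .require_columns(df, c("marker", "chromosome", "position"), path, "map")
  df$marker <- as.character(df$marker)
  df$chromosome <- as.character(df$chromosome)
  df$position <- as.numeric(df$position)
  if (anyDuplicated(df$marker))
    stop("map file '", path, "': duplicate marker '",
         df$marker[duplicated(df$marker)][1L], "'", call. = FALSE)
  lens <- stats::setNames(vapply(specs, `[[`, numeric(1), "length"),
                          vapply(specs, `[[`, character(1), "name"))
  for (i in seq_len(nrow(df))) {
    if (!df$chromosome[i] %in% names(lens))
      stop("map file '", path, "': marker '", df$marker[i],
           "' is on unknown chromosome '", df$chromosome[i], "'",
           call. = FALSE)
    if (df$position[i] < 0 || df$position[i] > lens[[df$chromosome[i]]])
      stop("map file '", path, "': marker '", df$marker[i], "' at ",
           df$position[i], " cM is outside chromosome '", df$chromosome[i],
           "' (0-", lens[[df$chromosome[i]]], " cM)", call. = FALSE)
  }
  df
}

#' Read a pedigree file
#'
#' Tab-delimited with header `name parent1 parent2`; founders carry the
#' missing code in both parent columns. Parents must be defined before
#' their offspring (file order is processing order).
#'
#' @param path Path to the pedigree file.
#' @param missing_code Missing-value code (default `"NA"`).
#' @return A data frame with columns `name`, `parent1`, `parent2`
#'   (`NA` for founders).
#' @export
read_pedigree_file <- function(path, missing_code = "NA") {
  df <- .read_tsv(path, "pedigree")
  .require_columns(df, c("name", "parent1", "parent2"), path, "pedigree")
  df$name <- as.character(df$name)
  df$parent1 <- as.character(df$parent1)
  df$parent2 <- as.character(df$parent2)
  df$parent1[df$parent1 == missing_code] <- NA_character_
  df$parent2[df$parent2 == missing_code] <- NA_character_
  if (anyDuplicated(df$name))
    stop("pedigree file '", path, "': duplicate individual '",
         df$name[duplicated(df$name)][1L], "'", call. = FALSE)
  seen <- character(0)
  for (i in seq_len(nrow(df))) {
    f1 <- is.na(df$parent1[i]); f2 <- is.na(df$parent2[i])
    if (f1 != f2)
      stop("pedigree file '", path, "': individual '", df$name[i],
           "' lists one parent only", call. = FALSE)
    if (!f1)
      for (pp in c(df$parent1[i], df$parent2[i]))
        if (!pp %in% seen)
          stop("pedigree file '", path, "': individual '", df$name[i],
               "' has undefined parent '", pp, "'", call. = FALSE)
    seen <- c(seen, df$name[i])
  }
  df
}

#' Read a founder allele file
#'
#' Tab-delimited with header `marker` followed by one column per founder
#' homolog named `<founder>_<slot>` with slot 1..ploidy, for each founder
#' of the pedigree in order. Column `<founder i>_<k>` defines the observed
#' allele of founder allele ID `(i-1)*ploidy + (k-1)` at every marker.
#' The reference allele for dosage counting is the observed allele of
#' founder allele ID 0 at each locus.
#'
#' @param path Path to the founder file.
#' @param pedigree Pedigree data frame (see [read_pedigree_file()]).
#' @param ploidy 2 or 4.
#' @param map Optional map data frame; if given, every mapped marker must
#'   be present.
#' @return An [allele_assignment()].
#' @export
read_founder_file <- function(path, pedigree, ploidy, map = NULL) {
  df <- .read_tsv(path, "founder")
  .require_columns(df, "marker", path, "founder")
  founders <- pedigree$name[is.na(pedigree$parent1)]
  want <- as.vector(t(outer(founders, seq_len(ploidy), paste, sep = "_")))
  .require_columns(df, want, path, "founder")
  markers <- as.character(df$marker)
  if (anyDuplicated(markers))
    stop("founder file '", path, "': duplicate marker '",
         markers[duplicated(markers)][1L], "'", call. = FALSE)
  if (!is.null(map)) {
    miss <- setdiff(map$marker, markers)
    if (length(miss))
      stop("founder file '", path, "': no founder alleles for mapped ",
           "marker(s): ", paste(utils::head(miss, 5L), collapse = ", "),
           call. = FALSE)
  }
  alleles <- as.matrix(df[, want, drop = FALSE])
  mode(alleles) <- "character"
  rownames(alleles) <- markers
  colnames(alleles) <- as.character(seq_along(want) - 1L)  # founder allele IDs
  allele_assignment(alleles)
}

#' Write simulation output files
#'
#' Writes the four tab-delimited result files:
#' * `<prefix>_founderalleles.dat` — founder allele ID per marker (rows)
#'   and individual homolog slot (columns `<ind>_<slot>`),
#' * `<prefix>_genotypes.dat` — observed alleles, same layout,
#' * `<prefix>_alleledose.dat` — reference-allele dosage per marker and
#'   individual,
#' * `<prefix>_haplostruct.dat` — long-format segment table (`individual
#'   chromosome homolog start allele`; starts printed with full precision
#'   so the file reads back bit-exact).
#'
#' @param population Named list of `individual_genome`s.
#' @param realized A `realized_genotypes` object.
#' @param prefix Output path prefix.
#' @return Character vector of the four file paths, invisibly.
#' @export
write_outputs <- function(population, realized, prefix) {
  out_dir <- dirname(prefix)
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  paths <- paste0(prefix, "_", c("founderalleles", "genotypes", "alleledose",
                                 "haplostruct"), ".dat")
  write_mat <- function(m, path) {
    df <- data.frame(marker = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  write_mat(realized$founder, paths[1L])
  write_mat(realized$obs, paths[2L])
  write_mat(realized$dosage, paths[3L])
  con <- file(paths[4L], "w")
  on.exit(close(con))
  writeLines("individual\tchromosome\thomolog\tstart\tallele", con)
  for (ind in population) {
    for (chrom in names(ind$homologs)) {
      hs <- ind$homologs[[chrom]]
      for (k in seq_along(hs)) {
        h <- hs[[k]]
        writeLines(sprintf("%s\t%s\t%d\t%.17g\t%d",
                           ind$name, chrom, k, h$start, h$allele), con)
      }
    }
  }
  invisible(paths)
}

#' Read back a haplostruct file
#'
#' Reconstructs the per-individual homolog [haplostruct()]s written by
#' [write_outputs()].
#'
#' @param path Path to a `*_haplostruct.dat` file.
#' @return Nested list: individual -> chromosome -> homolog haplostructs.
#' @export
read_haplostruct_file <- function(path) {
  df <- .read_tsv(path, "haplostruct")
  .require_columns(df, c("individual", "chromosome", "homolog", "start",
                         "allele"), path, "haplostruct")
  df$individual <- as.character(df$individual)
  df$chromosome <- as.character(df$chromosome)
  out <- list()
  for (ind in unique(df$individual)) {
    di <- df[df$individual == ind, ]
    out[[ind]] <- list()
    for (chrom in unique(di$chromosome)) {
      dc <- di[di$chromosome == chrom, ]
      out[[ind]][[chrom]] <- lapply(sort(unique(dc$homolog)), function(k) {
        dk <- dc[dc$homolog == k, ]
        haplostruct(dk$start, dk$allele, chromosome = chrom)
      })
    }
  }
  out
}

#' Run a full simulation from a parameter set
#'
#' Reads all input files, seeds the global random number generator once,
#' gene-drops the pedigree, realizes the marker genotypes and writes the
#' four output files. With `params$test_mode` (or the CLI `--test` flag)
#' it instead runs the replicated-meiosis test harness per chromosome and
#' writes `<prefix>_testreport.dat`.
#'
#' @param params A `run_parameters` object or the path to a parameter
#'   file.
#' @param seed Optional integer overriding the parameter-file seed.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the loaded inputs and output file paths.
#' @export
run_simulation <- function(params, seed = NULL, quiet = FALSE) {
  if (is.character(params)) params <- read_parameter_file(params)
  specs <- read_chromosome_file(params$chromfile, params$missing_code)
  map <- read_map_file(params$mapfile, specs)
  pedigree <- read_pedigree_file(params$pedfile, params$missing_code)
  assignment <- read_founder_file(params$founderfile, pedigree,
                                  params$ploidy, map)
  if (is.null(seed)) seed <- if (!is.na(params$seed)) params$seed else
    sample.int(.Machine$integer.max, 1L)
  set.seed(seed)
  if (!quiet) message("seed: ", seed)
  cfg <- chiasma_config(interference = params$mapfunction == "KOSAMBI")
  population <- build_population(pedigree, specs, cfg, params$ploidy)
  realized <- realize_genotypes(population, map, assignment)
  paths <- write_outputs(population, realized, params$output_prefix)
  if (!quiet) message("wrote: ", paste(paths, collapse = ", "))
  invisible(list(params = params, seed = seed, specs = specs, map = map,
                 pedigree = pedigree, population = population,
                 realized = realized, paths = paths))
}

#' Run the test mode from a parameter set
#'
#' For every chromosome, runs `params$test_meioses` replicated meioses of
#' a single founder, with test loci on a regular grid plus the centromere,
#' and writes the summary table (estimates, standard errors, closed-form
#' references and z-scores) to `<prefix>_testreport.dat`.
#'
#' @inheritParams run_simulation
#' @param n_loci Number of grid loci per chromosome (default 9).
#' @return Invisibly, a list with per-chromosome `gamete_stats` and the
#'   combined report data frame.
#' @export
run_test_mode <- function(params, seed = NULL, quiet = FALSE, n_loci = 9) {
  if (is.character(params)) params <- read_parameter_file(params)
  specs <- read_chromosome_file(params$chromfile, params$missing_code)
  if (is.null(seed)) seed <- if (!is.na(params$seed)) params$seed else
    sample.int(.Machine$integer.max, 1L)
  set.seed(seed)
  if (!quiet) message("seed: ", seed, " (test mode, ", params$test_meioses,
                      " meioses per chromosome)")
  cfg <- chiasma_config(interference = params$mapfunction == "KOSAMBI")
  all_stats <- list()
  reports <- list()
  for (spec in specs) {
    loci <- sort(unique(c(seq(0, spec$length, length.out = n_loci),
                          spec$centromere)))
    stats <- run_test_meioses(spec, cfg, params$test_meioses, loci,
                              ploidy = params$ploidy)
    rep_df <- summarize_gamete_stats(stats)
    rep_df <- cbind(chromosome = spec$name, rep_df)
    all_stats[[spec$name]] <- stats
    reports[[spec$name]] <- rep_df
    if (!quiet) {
      message("chromosome ", spec$name, " configurations:")
      tb <- table(stats$config)
      message(paste(sprintf("  %s: %d", names(tb), as.integer(tb)),
                    collapse = "\n"))
    }
  }
  report <- do.call(rbind, reports)
  rownames(report) <- NULL
  out_dir <- dirname(params$output_prefix)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  path <- paste0(params$output_prefix, "_testreport.dat")
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!quiet) message("wrote: ", path)
  invisible(list(stats = all_stats, report = report, path = path,
                 seed = seed))
}

#' Command-line entry point
#'
#' Implements `polymeiosis <paramfile> [--seed N] [--test]` (see
#' `inst/cli/polymeiosis.R`): runs the simulation or, with `--test`, the
#' test-mode harness. Validation failures print a one-line diagnostic to
#' stderr and return a nonzero status before any output is written.
#'
#' @param argv Character vector of command-line arguments.
#' @return Integer exit status (0 on success).
#' @export
cli_main <- function(argv) {
  seed <- NULL
  test <- FALSE
  positional <- character(0)
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (a == "--seed") {
      if (i == length(argv)) {
        message("polymeiosis: --seed requires a value")
        return(2L)
      }
      seed <- suppressWarnings(as.integer(argv[i + 1L]))
      if (is.na(seed)) {
        message("polymeiosis: --seed requires an integer")
        return(2L)
      }
      i <- i + 2L
    } else if (a == "--test") {
      test <- TRUE
      i <- i + 1L
    } else {
      positional <- c(positional, a)
      i <- i + 1L
    }
  }
  if (length(positional) != 1L) {
    message("usage: polymeiosis <paramfile> [--seed N] [--test]")
    return(2L)
  }
  tryCatch({
    params <- read_parameter_file(positional)
    if (test || params$test_mode)
      run_test_mode(params, seed = seed)
    else
      run_simulation(params, seed = seed)
    0L
  }, error = function(e) {
    message("polymeiosis: ", conditionMessage(e))
    1L
  })
}
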