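#' Map functions
#'
#' Closed-form recombination fraction for a map distance: Haldane
#' (`r = (1 - exp(-2d))/2`, no chiasma interference) or Kosambi
#' (`r = tanh(2d)/2`, moderate interference).
#'
#' @param d Map distance(s) in Morgan, >= 0.
#' @param kind `"HALDANE"` or `"KOSAMBI"` (case-insensitive).
#' @return Recombination fraction(s).
#' @examples
#' map_function_r(0.10, "HALDANE")  # 0.0906
#' map_function_r(1.00, "KOSAMBI")  # 0.4820
#' @export
map_function_r <- function(d, kind = c("HALDANE", "KOSAMBI")) {
  if (any(d < 0))
    stop("map distance must be >= 0", call. = FALSE)
  kind <- match.arg(toupper(kind), c("HALDANE", "KOSAMBI"))
  switch(kind,
         HALDANE = (1 - exp(-2 * d)) / 2,
         KOSAMBI = tanh(2 * d) / 2)
}

#' Accumulate gamete statistics over replicated meioses
#'
#' Test-mode harness: simulates `n` independent meioses of a single
#' founder individual, samples one gamete per meiosis, and records the
#' founder allele of every gamete chromatid at each test locus, together
#' with the pairing configuration drawn in each meiosis (and the exchange
#' point for cross-type quadrivalents). These raw observations feed
#' [estimate_recombination()], [estimate_double_reduction()] and
#' [summarize_gamete_stats()].
#'
#' @param spec A [chromosome_spec()] (its `pref_pairing`,
#'   `quadrivalent_fraction` and `parallel_fraction` define the model
#'   under test).
#' @param cfg A [chiasma_config()].
#' @param n Number of meioses (>= 1).
#' @param loci Numeric vector of test locus positions in cM.
#' @param ploidy 2 or 4.
#' @return An object of class `gamete_stats`: list with `n`, `ploidy`,
#'   `loci`, `alleles` (a list of `ploidy/2` integer matrices, `n` rows x
#'   `length(loci)` columns), `config` (factor: bivalents / cross /
#'   parallel per meiosis) and `exchange` (cM, `NA` unless cross-type).
#' @export
run_test_meioses <- function(spec, cfg, n, loci, ploidy = 4) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (any(loci < 0) || any(loci > spec$length))
    stop("test loci must lie within the chromosome", call. = FALSE)
  if (!ploidy %in% c(2L, 4L))
    stop("unsupported ploidy: ", ploidy, call. = FALSE)
  founder <- founder_genome(0L, ploidy, list(spec))
  homologs <- founder$homologs[[spec$name]]
  nl <- length(loci)
  nchr <- ploidy %/% 2L
  alleles <- lapply(seq_len(nchr), function(i)
    matrix(NA_integer_, n, nl))
  config <- integer(n)
  exchange <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    rs <- .recombine_chromosome(homologs, spec, cfg, ploidy)
    config[i] <- switch(rs$variant, bivalent = 1L, two_bivalents = 1L,
                        cross = 2L, parallel = 3L)
    if (rs$variant == "cross") exchange[i] <- rs$exchange_point
    pc <- isTRUE(spec$paired_centromeres) && rs$variant == "cross"
    poles <- first_division(rs, paired_centromeres = pc)
    pole <- poles[[sample.int(2L, 1L)]]
    halves <- second_division(pole)
    gam <- halves[[sample.int(2L, 1L)]]
    for (k in seq_len(nchr)) {
      h <- gam[[k]]
      alleles[[k]][i, ] <- h$allele[findInterval(loci, h$start)]
    }
  }
  structure(list(n = n, ploidy = as.integer(ploidy), loci = loci,
                 alleles = alleles,
                 config = factor(c("bivalents", "cross", "parallel")[config],
                                 levels = c("bivalents", "cross", "parallel")),
                 exchange = exchange,
                 spec = spec, cfg = cfg),
            class = "gamete_stats")
}

#' @export
print.gamete_stats <- function(x, ...) {
  cat(sprintf("<gamete_stats: %d meioses, ploidy %d, %d test loci on '%s'>\n",
              x$n, x$ploidy, length(x$loci), x$spec$name))
  print(table(x$config))
  invisible(x)
}

.locus_index <- function(stats, pos) {
  i <- match(pos, stats$loci)
  if (is.na(i))
    stop("locus at ", pos, " cM was not recorded", call. = FALSE)
  i
}

#' Estimate a recombination fraction from gamete statistics
#'
#' The fraction of recorded chromatids whose founder alleles differ
#' between the two loci. A double crossover restoring the same founder
#' allele scores as non-recombinant, matching the observational definition
#' underlying map functions.
#'
#' @param stats A `gamete_stats` object.
#' @param locusA,locusB Test locus positions (cM) present in `stats$loci`.
#' @return List with `r` (estimate), `se` (binomial standard error) and
#'   `n` (number of chromatids scored).
#' @export
estimate_recombination <- function(stats, locusA, locusB) {
  iA <- .locus_index(stats, locusA)
  iB <- .locus_index(stats, locusB)
  rec <- unlist(lapply(stats$alleles, function(a) a[, iA] != a[, iB]),
                use.names = FALSE)
  n <- length(rec)
  r <- mean(rec)
  list(r = r, se = sqrt(r * (1 - r) / n), n = n)
}

#' Estimate the double-reduction frequency at a locus
#'
#' Double reduction: a gamete whose two chromatids carry the same founder
#' allele at the locus, i.e. two copies of (part of) the same parental
#' homolog. Only multivalents can produce it; it is 0 at the centromere
#' and approaches 1/7 far from it under random centromere assortment.
#'
#' @param stats A tetraploid `gamete_stats` object.
#' @param locus Test locus position (cM).
#' @return List with `dr` (estimate), `se` and `n` (gametes scored).
#' @export
estimate_double_reduction <- function(stats, locus) {
  if (stats$ploidy != 4L)
    stop("double reduction is undefined for diploid gametes", call. = FALSE)
  i <- .locus_index(stats, locus)
  dr <- mean(stats$alleles[[1L]][, i] == stats$alleles[[2L]][, i])
  list(dr = dr, se = sqrt(dr * (1 - dr) / stats$n), n = stats$n)
}

#' Count quadrivalent configurations over many pairing draws
#'
#' Draws the top and bottom telomere pairings independently `n` times at
#' preferential pairing `p` (matching pairing probability `p + (1-p)/3`,
#' each other pairing `(1-p)/3`) and counts the draws in which the two
#' ends pair differently, i.e. form a quadrivalent.
#'
#' @param n Number of pairing draws (meioses).
#' @param p Preferential pairing fraction in `[0, 1]`.
#' @return Integer count of quadrivalent configurations.
#' @export
count_quadrivalent_draws <- function(n, p) {
  top <- pair_telomere(p, n)
  bottom <- pair_telomere(p, n)
  sum(top != bottom)
}

#' Summarize test-mode statistics against closed-form references
#'
#' Builds a report table with one row per locus interval (recombination
#' fraction), per locus (double reduction) and one row for the
#' quadrivalent configuration frequency, each with its estimate, binomial
#' standard error, the closed-form reference where one is defined, and the
#' z-score of the deviation. References: the Haldane (no interference) or
#' Kosambi (interference) map function for bivalent-only runs; the
#' telomere-pairing closed form for natural-mode configuration
#' frequencies, or the forced fraction.
#'
#' @param stats A `gamete_stats` object.
#' @param intervals Two-column matrix/data frame of locus position pairs;
#'   defaults to all ordered pairs of recorded loci.
#' @return A data frame with columns `statistic`, `locusA`, `locusB`,
#'   `estimate`, `se`, `expected`, `z`.
#' @export
summarize_gamete_stats <- function(stats, intervals = NULL) {
  loci <- stats$loci
  if (is.null(intervals) && length(loci) >= 2L) {
    cmb <- utils::combn(sort(loci), 2L)
    intervals <- data.frame(locusA = cmb[1L, ], locusB = cmb[2L, ])
  }
  spec <- stats$spec
  cfg <- stats$cfg
  bivalent_only <- stats$ploidy == 2L ||
    identical(spec$quadrivalent_fraction, 0) ||
    identical(spec$quadrivalent_fraction, 0L) ||
    (identical(spec$quadrivalent_fraction, "natural") &&
       spec$pref_pairing == 1)
  kind <- if (cfg$interference) "KOSAMBI" else "HALDANE"
  rows <- list()
  if (!is.null(intervals)) {
    for (i in seq_len(nrow(intervals))) {
      a <- intervals[i, 1L]; b <- intervals[i, 2L]
      est <- estimate_recombination(stats, a, b)
      expd <- if (bivalent_only)
        map_function_r(.cm2m(abs(b - a)), kind) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        statistic = "recombination", locusA = a, locusB = b,
        estimate = est$r, se = est$se, expected = expd,
        z = if (!is.na(expd) && est$se > 0) (est$r - expd) / est$se
            else NA_real_)
    }
  }
  if (stats$ploidy == 4L) {
    for (l in loci) {
      est <- estimate_double_reduction(stats, l)
      expd <- if (bivalent_only) 0 else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        statistic = "double_reduction", locusA = l, locusB = NA_real_,
        estimate = est$dr, se = est$se, expected = expd,
        z = if (!is.na(expd) && est$se > 0) (est$dr - expd) / est$se
            else NA_real_)
    }
    qf <- mean(stats$config != "bivalents")
    se <- sqrt(qf * (1 - qf) / stats$n)
    expd <- if (identical(spec$quadrivalent_fraction, "natural"))
      expected_quadrivalent_fraction(spec$pref_pairing)
    else as.numeric(spec$quadrivalent_fraction)
    rows[[length(rows) + 1L]] <- data.frame(
      statistic = "quadrivalent_fraction", locusA = NA_real_,
      locusB = NA_real_, estimate = qf, se = se, expected = expd,
      z = if (se > 0) (qf - expd) / se else NA_real_)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
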