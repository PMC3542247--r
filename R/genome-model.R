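#' Define a chromosome for simulation
#'
#' A chromosome is described entirely on the genetic (centiMorgan) scale:
#' its map length, the centromere position, and the tetraploid pairing
#' parameters that govern bivalent versus quadrivalent formation.
#'
#' @param name Chromosome identifier (character scalar).
#' @param length Map length in centiMorgan, > 0.
#' @param centromere Centromere position in cM, within `[0, length]`.
#' @param pref_pairing Preferential pairing fraction `p` in `[0, 1]`:
#'   0 means fully random pairing of the four homologues (autotetraploid),
#'   1 means exclusive pairing within subgenomes (allotetraploid).
#' @param quadrivalent_fraction Either the string `"natural"` (the
#'   bivalent/quadrivalent ratio emerges from independent telomere pairing)
#'   or a fraction in `[0, 1]` forcing that proportion of quadrivalents.
#' @param parallel_fraction Fraction of quadrivalents that are
#'   parallel-type rather than cross-type, in `[0, 1]`.
#' @param paired_centromeres Logical; alternative first-division model for
#'   cross-type quadrivalents in which the two centromeres paired on the
#'   centromere side of the exchange point always move to opposite poles.
#' @return An object of class `chromosome_spec`.
#' @examples
#' chromosome_spec("1", length = 100, centromere = 20)
#' @export
chromosome_spec <- function(name, length, centromere,
                            pref_pairing = 0,
                            quadrivalent_fraction = "natural",
                            parallel_fraction = 0,
                            paired_centromeres = FALSE) {
  stopifnot(is.character(name) || is.factor(name), length(name) == 1L)
  name <- as.character(name)
  if (!is.numeric(length) || length <= 0)
    stop("chromosome '", name, "': length must be > 0 cM", call. = FALSE)
  if (!is.numeric(centromere) || centromere < 0 || centromere > length)
    stop("chromosome '", name, "': centromere must lie in [0, length]",
         call. = FALSE)
  if (!is.numeric(pref_pairing) || pref_pairing < 0 || pref_pairing > 1)
    stop("chromosome '", name, "': pref_pairing must lie in [0, 1]",
         call. = FALSE)
  if (!(identical(quadrivalent_fraction, "natural") ||
        (is.numeric(quadrivalent_fraction) &&
         quadrivalent_fraction >= 0 && quadrivalent_fraction <= 1)))
    stop("chromosome '", name,
         "': quadrivalent_fraction must be 'natural' or in [0, 1]",
         call. = FALSE)
  if (!is.numeric(parallel_fraction) ||
      parallel_fraction < 0 || parallel_fraction > 1)
    stop("chromosome '", name, "': parallel_fraction must lie in [0, 1]",
         call. = FALSE)
  structure(
    list(name = name,
         length = as.numeric(length),
         centromere = as.numeric(centromere),
         pref_pairing = as.numeric(pref_pairing),
         quadrivalent_fraction = quadrivalent_fraction,
         parallel_fraction = as.numeric(parallel_fraction),
         paired_centromeres = isTRUE(paired_centromeres)),
    class = "chromosome_spec")
}

#' @export
print.chromosome_spec <- function(x, ...) {
  qf <- if (identical(x$quadrivalent_fraction, "natural")) "natural"
        else format(x$quadrivalent_fraction)
  cat(sprintf(
    "<chromosome_spec '%s': %g cM, centromere %g cM, p = %g, quadrivalents %s>\n",
    x$name, x$length, x$centromere, x$pref_pairing, qf))
  invisible(x)
}

#' Construct a haplotype structure
#'
#' A `haplostruct` represents one chromatid (or homolog) as an ordered
#' sequence of segments, each carrying a founder allele from a start
#' position to the start of the next segment (half-open `[start, next)`
#' convention). It is the universal recombination product: every
#' chromosome in a simulated population is a mosaic of founder segments.
#'
#' @param starts Numeric vector of ascending segment start positions in cM;
#'   the first must be 0.
#' @param alleles Integer vector of founder allele IDs, same length as
#'   `starts`.
#' @param chromosome Optional chromosome name.
#' @param length Optional chromosome length in cM (enables bounds checks
#'   in [allele_at()]).
#' @return An object of class `haplostruct` with fields `start` and
#'   `allele`.
#' @examples
#' h <- haplostruct(c(0, 30, 70), c(2L, 3L, 2L))
#' allele_at(h, 50)
#' @export
haplostruct <- function(starts, alleles, chromosome = NULL, length = NULL) {
  starts <- as.numeric(starts)
  alleles <- as.integer(alleles)
  n <- base::length(starts)
  if (n == 0L || base::length(alleles) != n)
    stop("haplostruct: starts and alleles must be non-empty and equal length",
         call. = FALSE)
  if (starts[1L] != 0)
    stop("haplostruct: first segment must start at 0", call. = FALSE)
  if (n > 1L && any(diff(starts) <= 0))
    stop("haplostruct: segment starts must be strictly increasing",
         call. = FALSE)
  if (any(alleles < 0L))
    stop("haplostruct: founder alleles must be non-negative", call. = FALSE)
  if (!is.null(length) && any(starts >= length))
    stop("haplostruct: segment starts must lie in [0, length)", call. = FALSE)
  structure(list(start = starts, allele = alleles),
            chromosome = chromosome, length = length,
            class = "haplostruct")
}

#' @export
print.haplostruct <- function(x, ...) {
  cat("<haplostruct: ",
      paste(sprintf("(%g, %d)", x$start, x$allele), collapse = " "),
      ">\n", sep = "")
  invisible(x)
}

#' @export
format.haplostruct <- function(x, ...) {
  paste(sprintf("%g:%d", x$start, x$allele), collapse = " ")
}

#' Founder allele at a position
#'
#' Looks up the founder allele carried by a haplotype structure at a map
#' position, using the half-open segment convention: a position exactly at
#' a segment start belongs to that (right-hand) segment.
#'
#' @param h A [haplostruct()].
#' @param pos Position(s) in cM, within the chromosome.
#' @return Integer founder allele ID(s).
#' @export
allele_at <- function(h, pos) {
  len <- attr(h, "length")
  if (any(pos < 0) || (!is.null(len) && any(pos > len)))
    stop("allele_at: position outside chromosome", call. = FALSE)
  h$allele[findInterval(pos, h$start)]
}

#' Canonicalize a haplotype structure
#'
#' Merges adjacent segments that carry the same founder allele. The
#' position-to-allele map is unchanged.
#'
#' @param h A [haplostruct()] (or a bare list with `start`/`allele`).
#' @return A canonical `haplostruct`.
#' @export
canonicalize <- function(h) {
  st <- h$start
  al <- h$allele
  n <- length(st)
  if (n > 1L && any(diff(st) <= 0))
    stop("canonicalize: malformed haplostruct (starts not increasing)",
         call. = FALSE)
  if (n > 1L) {
    keep <- c(TRUE, al[-1L] != al[-n])
    if (!all(keep)) {
      st <- st[keep]
      al <- al[keep]
    }
  }
  structure(list(start = st, allele = al),
            chromosome = attr(h, "chromosome"),
            length = attr(h, "length"),
            class = "haplostruct")
}

#' Create a founder genome
#'
#' Every homolog of a founder carries a single, unique founder allele over
#' its full length: founder `i` (counted from 0) of ploidy `P` receives
#' allele IDs `i*P + 0 .. i*P + (P-1)`, extending the conventional diploid
#' numbering (founder 0 has alleles 0 and 1, founder 1 has 2 and 3, ...).
#'
#' @param founder_index Zero-based founder index.
#' @param ploidy 2 or 4.
#' @param chromosomes List of [chromosome_spec()] objects.
#' @param name Individual name (default `"F<index>"`).
#' @return An `individual_genome`: a named list of per-chromosome homolog
#'   lists, each homolog a single-segment [haplostruct()].
#' @export
founder_genome <- function(founder_index, ploidy, chromosomes,
                           name = paste0("F", founder_index)) {
  if (!ploidy %in% c(2L, 4L))
    stop("unsupported ploidy: ", ploidy, " (only 2 and 4 are supported)",
         call. = FALSE)
  if (founder_index < 0)
    stop("founder_index must be >= 0", call. = FALSE)
  if (inherits(chromosomes, "chromosome_spec")) chromosomes <- list(chromosomes)
  homologs <- lapply(chromosomes, function(spec) {
    lapply(seq_len(ploidy) - 1L, function(k) {
      haplostruct(0, founder_index * ploidy + k,
                  chromosome = spec$name, length = spec$length)
    })
  })
  names(homologs) <- vapply(chromosomes, `[[`, character(1), "name")
  structure(list(name = name, ploidy = as.integer(ploidy),
                 homologs = homologs),
            class = "individual_genome")
}

#' @export
print.individual_genome <- function(x, ...) {
  cat(sprintf("<individual_genome '%s': ploidy %d, %d chromosome(s)>\n",
              x$name, x$ploidy, length(x$homologs)))
  invisible(x)
}

# Internal fast constructor: no validation, used in the meiosis hot path.
.hs <- function(st, al, chromosome = NULL, length = NULL) {
  structure(list(start = st, allele = al),
            chromosome = chromosome, length = length,
            class = "haplostruct")
}
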