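# The three possible telomere pairings of homolog slots 1..4.
# Code 1 is the "matching" pairing between true homologues: slots 1,2 are
# one subgenome, slots 3,4 the other.
.PAIRINGS <- list(list(c(1L, 2L), c(3L, 4L)),
                  list(c(1L, 3L), c(2L, 4L)),
                  list(c(1L, 4L), c(2L, 3L)))

#' Draw a telomere pairing
#'
#' Pairing of the four homologous chromosome ends starts independently at
#' each telomere. With preferential pairing fraction `p`, the matching
#' pairing (each chromosome with its true homologue) has probability
#' `p + (1-p)/3` and each of the other two pairings `(1-p)/3`.
#'
#' @param p Preferential pairing fraction in `[0, 1]`.
#' @param n Number of draws.
#' @return Integer pairing code(s) in 1..3; code 1 is the matching pairing
#'   `{(1,2),(3,4)}`, codes 2 and 3 are `{(1,3),(2,4)}` and
#'   `{(1,4),(2,3)}`.
#' @export
pair_telomere <- function(p, n = 1) {
  if (!is.numeric(p) || p < 0 || p > 1)
    stop("pref_pairing p must lie in [0, 1]", call. = FALSE)
  q <- (1 - p) / 3
  sample.int(3L, n, replace = TRUE, prob = c(p + q, q, q))
}

#' Expected fraction of quadrivalents
#'
#' Under independent pairing at the two telomeres, two bivalents form when
#' both telomeres pair identically, so
#' `P(bivalents) = (p + (1-p)/3)^2 + 2 ((1-p)/3)^2` and the expected
#' quadrivalent fraction is its complement: 2/3 at `p = 0` (fully random
#' pairing), 0 at `p = 1` (exclusive preferential pairing).
#'
#' @param p Preferential pairing fraction in `[0, 1]`.
#' @return Expected fraction of meioses forming a quadrivalent.
#' @examples
#' expected_quadrivalent_fraction(0)     # 2/3
#' expected_quadrivalent_fraction(0.75)  # 0.292
#' @export
expected_quadrivalent_fraction <- function(p) {
  if (any(!is.numeric(p)) || any(p < 0) || any(p > 1))
    stop("pref_pairing p must lie in [0, 1]", call. = FALSE)
  q <- (1 - p) / 3
  1 - ((p + q)^2 + 2 * q^2)
}

#' Decide the pairing configuration of one chromosome set
#'
#' For a tetraploid chromosome set, resolves whether the four homologues
#' form two bivalents or one quadrivalent in this meiosis, and for
#' quadrivalents whether it is cross-type or parallel. In natural mode
#' (`quadrivalent_fraction = "natural"`) the two telomeres pair
#' independently and a quadrivalent results whenever they pair
#' differently. In forced mode the bivalent/quadrivalent ratio is a direct
#' Bernoulli draw, and the pairing is performed within the constraints of
#' the drawn configuration (for two bivalents a single telomere pairing is
#' used at both ends; for a quadrivalent the bottom pairing is drawn from
#' the preferential distribution renormalized over the two pairings that
#' differ from the top).
#'
#' @param spec A [chromosome_spec()].
#' @param ploidy 2 or 4; diploids always form a single bivalent.
#' @return An object of class `meiotic_config`: a list with `variant`
#'   (`"bivalent"`, `"two_bivalents"`, `"cross"` or `"parallel"`) and,
#'   where applicable, pairing codes `pairing`, `top`, `bottom`.
#' @export
decide_configuration <- function(spec, ploidy = 4) {
  if (ploidy == 2L)
    return(structure(list(variant = "bivalent"), class = "meiotic_config"))
  p <- spec$pref_pairing
  qf <- spec$quadrivalent_fraction
  if (identical(qf, "natural")) {
    ends <- pair_telomere(p, 2L)
    if (ends[1L] == ends[2L])
      return(structure(list(variant = "two_bivalents", pairing = ends[1L]),
                       class = "meiotic_config"))
    top <- ends[1L]
    bottom <- ends[2L]
  } else {
    if (stats::runif(1L) >= qf)
      return(structure(list(variant = "two_bivalents",
                            pairing = pair_telomere(p)),
                       class = "meiotic_config"))
    top <- pair_telomere(p)
    others <- setdiff(1:3, top)
    q <- (1 - p) / 3
    w <- c(p + q, q, q)[others]
    bottom <- others[sample.int(2L, 1L, prob = w)]
  }
  variant <- if (stats::runif(1L) < spec$parallel_fraction) "parallel"
             else "cross"
  structure(list(variant = variant, top = top, bottom = bottom),
            class = "meiotic_config")
}

# Apply a set of chiasmata to the chromatids of one pairing structure.
#
# Physical bookkeeping: the template DNA of each chromosome stays on its
# own axis; the recombinant molecules are paths across the axes. At any
# position exactly two molecules are copying each chromosome's template
# (they are sisters there, identical by construction), so a chiasma at x
# between chromosomes qa and qb picks one of the two molecules currently
# on qa's axis and one of the two on qb's -- uniformly and independently,
# i.e. without chromatid interference -- swaps their tails, and the two
# molecules exchange axes from x onward. A molecule is attached to the
# centromere of the axis it occupies at the centromere position, which is
# frozen once the ascending sweep passes the centromere.
#
# mols: list of 2*P molecule haplostructs; axis_of: current axis (chromosome
# index) per molecule, two molecules per axis; xs ascending chiasma
# positions; qa, qb: chromosome pair per chiasma; cpos: centromere (cM).
# Returns list(mols, attach) with attach the centromere axis per molecule.
.apply_chiasmata <- function(mols, axis_of, xs, qa, qb, cpos) {
  attach <- NULL
  k <- length(xs)
  if (k) {
    sis <- matrix(sample.int(2L, 2L * k, replace = TRUE), ncol = 2L)
    for (i in seq_len(k)) {
      x <- xs[i]
      if (is.null(attach) && x > cpos) attach <- axis_of
      mi <- which(axis_of == qa[i])[sis[i, 1L]]
      mj <- which(axis_of == qb[i])[sis[i, 2L]]
      res <- .swap_tail(mols[[mi]], mols[[mj]], x)
      mols[[mi]] <- res[[1L]]
      mols[[mj]] <- res[[2L]]
      axis_of[c(mi, mj)] <- axis_of[c(mj, mi)]
    }
  }
  if (is.null(attach)) attach <- axis_of
  list(mols = mols, attach = attach)
}

# Group recombined molecules into centromere units (one unit per
# chromosome axis, two attached chromatids each).
.centromere_units <- function(mols, attach, axes) {
  lapply(axes, function(q) mols[attach == q])
}

#' Recombine a bivalent
#'
#' Generates chiasmata over the full chromosome (mean gap
#' `cfg$mean_distance`, 0.5 Morgan by default, i.e. two chiasmata per
#' Morgan per bivalent) and applies each to a uniformly chosen pair of
#' non-sister chromatids in ascending position order (non-sister at the
#' crossover position: one molecule copying each chromosome's template).
#' Each recombined chromatid is attached to the centromere of the
#' chromosome whose axis it occupies at the centromere position.
#'
#' @param chromA,chromB Lists of the two sister chromatid
#'   [haplostruct()]s of each homologous chromosome.
#' @param spec The [chromosome_spec()].
#' @param cfg A [chiasma_config()].
#' @return A `recombined_set` with two centromeres, each carrying two
#'   (possibly recombined) chromatids.
#' @export
do_bivalent <- function(chromA, chromB, spec, cfg) {
  xs <- generate_chiasma_positions(0, spec$length, cfg)
  k <- length(xs)
  res <- .apply_chiasmata(c(chromA, chromB), c(1L, 1L, 2L, 2L), xs,
                          rep.int(1L, k), rep.int(2L, k), spec$centromere)
  structure(list(variant = "bivalent",
                 cents = .centromere_units(res$mols, res$attach, 1:2),
                 centromere = spec$centromere,
                 n_chiasmata = k),
            class = "recombined_set")
}

#' Recombine a cross-type quadrivalent
#'
#' A cross-type quadrivalent has four branches: two in which the "top"
#' ends of two chromosomes are paired, and two pairing the "bottom" ends
#' of the complementary combinations. Chiasmata are generated inward from
#' each of the four telomeres with the bivalent chiasma frequency (mean
#' gap 0.5 Morgan per branch). The chromosome exchange point is realized
#' first: pairing fronts advance inward from the two ends as renewal walks
#' with the inter-chiasma step distribution (the side whose front lags
#' advances next), and pairing ends when the two sides' pending steps
#' would cross each other; the exchange point is the midpoint of the final
#' gap between the fronts, which gives it a unimodal distribution peaking
#' at the chromosome center. Each branch then forms chiasmata by the
#' standard renewal process from its own telomere, truncated at the
#' exchange point, so every position is paired -- and recombines -- in
#' exactly one side. Each chiasma involves uniform non-sister chromatids
#' of its branch's chromosome pair; all chiasmata are applied in ascending
#' order.
#'
#' @param cents List of four homologous chromosomes, each a list of two
#'   sister chromatid [haplostruct()]s (slot order 1..4).
#' @param top,bottom Pairing codes (1..3, see [pair_telomere()]) of the
#'   top and bottom telomeres; they must differ.
#' @param spec The [chromosome_spec()].
#' @param cfg A [chiasma_config()].
#' @return A `recombined_set` with four centromeres and the realized
#'   `exchange_point` (cM).
#' @export
build_cross_quadrivalent <- function(cents, top, bottom, spec, cfg) {
  if (top == bottom)
    stop("cross-type quadrivalent requires different top and bottom pairings",
         call. = FALSE)
  L <- spec$length
  len_m <- .cm2m(L)
  # branch chromosome pairs: 1,2 = top branches; 3,4 = bottom branches
  bpairs <- c(.PAIRINGS[[top]], .PAIRINGS[[bottom]])
  # Stage 1: realize the exchange point. Pairing fronts advance inward
  # from the two ends as renewal walks with the inter-chiasma step
  # distribution, one walk per branch, superposed per side; the side whose
  # front lags advances next, and pairing ends when the two sides' pending
  # steps would cross each other. The exchange point is the midpoint of
  # the final gap between the fronts.
  tops <- sort(c(.chiasma_stream(len_m, cfg), .chiasma_stream(len_m, cfg)))
  bots <- sort(c(.chiasma_stream(len_m, cfg), .chiasma_stream(len_m, cfg)))
  tops <- .m2cm(tops); bots <- .m2cm(bots)   # distances from own telomere
  iT <- 1L; iB <- 1L
  RT <- 0; RB <- 0                           # front distances
  top_first <- stats::runif(1L) < 0.5        # unbiased tie-break at the start
  repeat {
    cT <- if (iT <= length(tops)) tops[iT] else Inf
    cB <- if (iB <= length(bots)) L - bots[iB] else -Inf
    if (cT >= cB) break                      # pending steps cross: done
    adv_top <- if (RT == RB) top_first else RT < RB
    if (adv_top) { RT <- cT; iT <- iT + 1L }
    else         { RB <- L - cB; iB <- iB + 1L }
  }
  exchange <- (RT + (L - RB)) / 2
  # Stage 2: chiasma formation within the realized branch regions. Each
  # top branch runs the renewal process from the top telomere truncated at
  # the exchange point, each bottom branch from the bottom telomere
  # truncated there, so every position recombines in exactly one side.
  acc_x <- numeric(0); acc_b <- integer(0)
  for (br in 1:2) {
    xs <- .m2cm(.chiasma_stream(.cm2m(exchange), cfg))
    acc_x <- c(acc_x, xs); acc_b <- c(acc_b, rep.int(br, length(xs)))
  }
  for (br in 3:4) {
    xs <- L - .m2cm(.chiasma_stream(.cm2m(L - exchange), cfg))
    acc_x <- c(acc_x, xs); acc_b <- c(acc_b, rep.int(br, length(xs)))
  }
  k <- length(acc_x)
  ord <- order(acc_x)
  acc_x <- acc_x[ord]; acc_b <- acc_b[ord]
  qa <- vapply(bpairs, `[`, integer(1), 1L)[acc_b]
  qb <- vapply(bpairs, `[`, integer(1), 2L)[acc_b]
  mols <- c(cents[[1L]], cents[[2L]], cents[[3L]], cents[[4L]])
  res <- .apply_chiasmata(mols, rep(1:4, each = 2L), acc_x, qa, qb,
                          spec$centromere)
  structure(list(variant = "cross",
                 cents = .centromere_units(res$mols, res$attach, 1:4),
                 top = top, bottom = bottom,
                 exchange_point = exchange,
                 centromere = spec$centromere,
                 n_chiasmata = k),
            class = "recombined_set")
}

#' Recombine a parallel quadrivalent
#'
#' All four chromosomes are arranged in parallel, so at any point a
#' chiasma can involve any chromosome pair. A single chiasma stream runs
#' over the chromosome with mean gap 0.25 Morgan (four chiasmata per
#' Morgan, preserving the per-chromatid recombination frequency); each
#' chiasma picks a uniform pair among the six chromosome pairs, then
#' uniform non-sister chromatids.
#'
#' @inheritParams build_cross_quadrivalent
#' @return A `recombined_set` with four centromeres.
#' @export
build_parallel_quadrivalent <- function(cents, spec, cfg) {
  xs <- generate_chiasma_positions(0, spec$length, cfg)
  k <- length(xs)
  pairs6 <- list(c(1L, 2L), c(1L, 3L), c(1L, 4L),
                 c(2L, 3L), c(2L, 4L), c(3L, 4L))
  pidx <- sample.int(6L, k, replace = TRUE)
  qa <- vapply(pairs6, `[`, integer(1), 1L)[pidx]
  qb <- vapply(pairs6, `[`, integer(1), 2L)[pidx]
  mols <- c(cents[[1L]], cents[[2L]], cents[[3L]], cents[[4L]])
  res <- .apply_chiasmata(mols, rep(1:4, each = 2L), xs, qa, qb,
                          spec$centromere)
  structure(list(variant = "parallel",
                 cents = .centromere_units(res$mols, res$attach, 1:4),
                 centromere = spec$centromere,
                 n_chiasmata = k),
            class = "recombined_set")
}

#' First meiotic division
#'
#' Separates the centromeres (each carrying its two chromatids) to the two
#' spindle poles. A bivalent sends one centromere to each pole; two
#' bivalents split independently. In a quadrivalent the four centromeres
#' are partitioned into two pairs uniformly over the three possible
#' partitions (random centromere assortment). For cross-type
#' quadrivalents, `paired_centromeres = TRUE` selects the alternative
#' model in which the two chromosomes paired at the centromere position
#' (the pairing on the centromere side of the exchange point) always move
#' to opposite poles; the two compatible partitions are equally likely.
#'
#' @param rs A `recombined_set` from [do_bivalent()],
#'   [build_cross_quadrivalent()], [build_parallel_quadrivalent()], or a
#'   combined two-bivalent set from [do_meiosis()].
#' @param paired_centromeres Logical; see above (cross-type only).
#' @return A list of two poles; each pole is a list of `ploidy/2`
#'   centromere units (each a list of two chromatids).
#' @export
first_division <- function(rs, paired_centromeres = FALSE) {
  cents <- rs$cents
  switch(rs$variant,
    bivalent = {
      o <- sample.int(2L, 1L)
      list(cents[o], cents[-o])
    },
    two_bivalents = {
      p1 <- rs$pairs[[1L]]; p2 <- rs$pairs[[2L]]
      o1 <- sample.int(2L, 1L); o2 <- sample.int(2L, 1L)
      list(list(cents[[p1[o1]]], cents[[p2[o2]]]),
           list(cents[[p1[3L - o1]]], cents[[p2[3L - o2]]]))
    },
    cross = ,
    parallel = {
      if (paired_centromeres) {
        if (rs$variant == "parallel")
          stop("paired_centromeres model is defined for cross-type ",
               "quadrivalents only", call. = FALSE)
        cent_pairing <- if (rs$centromere <= rs$exchange_point) rs$top
                        else rs$bottom
        part <- setdiff(1:3, cent_pairing)[sample.int(2L, 1L)]
      } else {
        part <- sample.int(3L, 1L)
      }
      pr <- .PAIRINGS[[part]]
      list(cents[pr[[1L]]], cents[pr[[2L]]])
    },
    stop("unknown recombined_set variant: ", rs$variant, call. = FALSE))
}

#' Second meiotic division
#'
#' Splits every centromere at a pole in half; the two chromatids are
#' distributed to the two daughter gametes with independent random
#' orientation, so each daughter receives exactly one chromatid per
#' centromere.
#'
#' @param pole A pole from [first_division()]: a list of centromere units.
#' @return A list of two gamete halves, each a list with one chromatid per
#'   centromere.
#' @export
second_division <- function(pole) {
  n <- length(pole)
  o <- 1L + (stats::runif(n) < 0.5)
  g1 <- vector("list", n)
  g2 <- vector("list", n)
  for (i in seq_len(n)) {
    g1[[i]] <- pole[[i]][[o[i]]]
    g2[[i]] <- pole[[i]][[3L - o[i]]]
  }
  list(g1, g2)
}

# Recombination for one chromosome set: duplicate homologs into sister
# chromatids, resolve the configuration, recombine. Returns a recombined_set.
.recombine_chromosome <- function(homologs, spec, cfg, ploidy) {
  cents <- lapply(homologs, function(h) list(h, h))
  if (ploidy == 2L)
    return(do_bivalent(cents[[1L]], cents[[2L]], spec, cfg))
  config <- decide_configuration(spec, ploidy)
  if (config$variant == "two_bivalents") {
    prs <- .PAIRINGS[[config$pairing]]
    for (pr in prs) {
      rs <- do_bivalent(cents[[pr[1L]]], cents[[pr[2L]]], spec, cfg)
      cents[[pr[1L]]] <- rs$cents[[1L]]
      cents[[pr[2L]]] <- rs$cents[[2L]]
    }
    structure(list(variant = "two_bivalents", cents = cents,
                   pairs = prs, pairing = config$pairing,
                   centromere = spec$centromere),
              class = "recombined_set")
  } else if (config$variant == "parallel") {
    cfg4 <- cfg
    cfg4$mean_distance <- cfg$mean_distance / 2
    build_parallel_quadrivalent(cents, spec, cfg4)
  } else {
    build_cross_quadrivalent(cents, config$top, config$bottom, spec, cfg)
  }
}

#' Simulate one meiosis
#'
#' Runs the full meiotic pipeline for every chromosome set independently:
#' pairing configuration, chiasma formation and recombination, first and
#' second meiotic divisions, and assembles the four resulting gametes.
#' Each gamete carries `ploidy/2` chromatids per chromosome, with
#' centromeres originating from different parental chromosomes.
#'
#' @param parent An `individual_genome` (see [founder_genome()]).
#' @param specs List of [chromosome_spec()]s matching the parent's
#'   chromosomes.
#' @param cfg A [chiasma_config()] (bivalent/cross-branch mean gap; the
#'   parallel-quadrivalent stream automatically uses half the mean gap).
#' @return A list of four `gamete` objects, each a named list (by
#'   chromosome) of chromatid [haplostruct()] lists.
#' @export
do_meiosis <- function(parent, specs, cfg) {
  if (inherits(specs, "chromosome_spec")) specs <- list(specs)
  ploidy <- parent$ploidy
  gametes <- rep(list(list()), 4L)
  for (spec in specs) {
    homologs <- parent$homologs[[spec$name]]
    if (is.null(homologs))
      stop("parent '", parent$name, "' has no chromosome '", spec$name, "'",
           call. = FALSE)
    rs <- .recombine_chromosome(homologs, spec, cfg, ploidy)
    pc <- isTRUE(spec$paired_centromeres) && rs$variant == "cross"
    poles <- first_division(rs, paired_centromeres = pc)
    h1 <- second_division(poles[[1L]])
    h2 <- second_division(poles[[2L]])
    dress <- function(hs) lapply(hs, function(h)
      .hs(h$start, h$allele, chromosome = spec$name, length = spec$length))
    gametes[[1L]][[spec$name]] <- dress(h1[[1L]])
    gametes[[2L]][[spec$name]] <- dress(h1[[2L]])
    gametes[[3L]][[spec$name]] <- dress(h2[[1L]])
    gametes[[4L]][[spec$name]] <- dress(h2[[2L]])
  }
  lapply(gametes, function(g)
    structure(list(chromatids = g, ploidy = ploidy %/% 2L),
              class = "gamete"))
}

#' Sample one gamete from a meiosis
#'
#' @param gametes The list of four gametes from [do_meiosis()].
#' @return One gamete, chosen uniformly.
#' @export
sample_gamete <- function(gametes) {
  if (length(gametes) != 4L)
    stop("sample_gamete expects the four gametes of one meiosis",
         call. = FALSE)
  gametes[[sample.int(4L, 1L)]]
}
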