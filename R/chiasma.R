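#' Configure the chiasma renewal process
#'
#' Chiasma positions along a paired region are generated by a renewal
#' process read from one telomere to the other. Without chiasma
#' interference the gaps between successive chiasmata are exponential;
#' with interference they follow a gamma distribution (shape > 1
#' suppresses nearby crossovers), and the process is burnt in by starting
#' several Morgan before the region so that it is stationary at entry.
#'
#' @param interference Logical; model chiasma interference?
#' @param mean_distance Mean inter-chiasma distance in Morgan: 0.5 for
#'   bivalents and cross-type quadrivalent branches (two chiasmata per
#'   Morgan), 0.25 for parallel quadrivalents (four per Morgan).
#' @param gamma_shape Gamma shape parameter used when interference is on;
#'   2.63 reproduces the Kosambi map function in bivalents.
#' @param burnin_length Burn-in length in Morgan (>= 5) before the region
#'   entry point when interference is on.
#' @return An object of class `chiasma_config`.
#' @export
chiasma_config <- function(interference = FALSE,
                           mean_distance = 0.5,
                           gamma_shape = 2.63,
                           burnin_length = 10) {
  if (!is.numeric(mean_distance) || mean_distance <= 0)
    stop("mean_distance must be > 0 Morgan", call. = FALSE)
  if (!is.numeric(gamma_shape) || gamma_shape <= 0)
    stop("gamma_shape must be > 0", call. = FALSE)
  if (!is.numeric(burnin_length) || burnin_length < 5)
    stop("burnin_length must be >= 5 Morgan", call. = FALSE)
  structure(list(interference = isTRUE(interference),
                 mean_distance = as.numeric(mean_distance),
                 gamma_shape = as.numeric(gamma_shape),
                 burnin_length = as.numeric(burnin_length)),
            class = "chiasma_config")
}

#' @export
print.chiasma_config <- function(x, ...) {
  cat(sprintf("<chiasma_config: %s, mean gap %g M%s>\n",
              if (x$interference) "gamma interference" else "no interference",
              x$mean_distance,
              if (x$interference)
                sprintf(", shape %g, burn-in %g M", x$gamma_shape,
                        x$burnin_length) else ""))
  invisible(x)
}

# cM <-> Morgan conversion, centralized.
.cm2m <- function(x) x / 100
.m2cm <- function(x) x * 100

#' Sample inter-chiasma distances
#'
#' Draws gaps between successive chiasmata: exponential with mean
#' `mean_distance` without interference, gamma with shape `gamma_shape`
#' and the same mean with interference.
#'
#' @param cfg A [chiasma_config()].
#' @param n Number of draws.
#' @return Numeric vector of distances in Morgan.
#' @export
sample_interchiasma_distance <- function(cfg, n = 1) {
  if (cfg$interference)
    stats::rgamma(n, shape = cfg$gamma_shape,
                  rate = cfg$gamma_shape / cfg$mean_distance)
  else
    stats::rexp(n, rate = 1 / cfg$mean_distance)
}

# Internal: ascending chiasma distances (Morgan) from the entry telomere of
# a paired region of len_m Morgan. Without interference the first position
# is a plain exponential draw from the entry point; with interference the
# process starts burnin_length Morgan before entry with one exponential
# (virtual first chiasma) followed by gamma gaps, and only positions inside
# [0, len_m] are returned.
.chiasma_stream <- function(len_m, cfg) {
  m <- cfg$mean_distance
  if (!cfg$interference) {
    pos <- stats::rexp(1L, rate = 1 / m)
    if (pos > len_m) return(numeric(0))
    out <- pos
    repeat {
      k <- max(8L, as.integer(2 * (len_m - pos) / m))
      pos <- pos + cumsum(stats::rexp(k, rate = 1 / m))
      out <- c(out, pos)
      pos <- pos[k]
      if (pos > len_m) break
    }
    out[out <= len_m]
  } else {
    shape <- cfg$gamma_shape
    rate <- shape / m
    pos <- -cfg$burnin_length + stats::rexp(1L, rate = 1 / m)
    out <- pos
    repeat {
      k <- max(8L, as.integer(2 * (len_m - pos[length(pos)]) / m))
      pos <- pos[length(pos)] + cumsum(stats::rgamma(k, shape = shape,
                                                     rate = rate))
      out <- c(out, pos)
      if (pos[k] > len_m) break
    }
    out[out >= 0 & out <= len_m]
  }
}

#' Generate chiasma positions over a paired region
#'
#' Runs the chiasma renewal process over `[region_start, region_end]` (cM)
#' from one end to the other and returns the chiasma positions that fall
#' inside the region, in ascending order.
#'
#' @param region_start,region_end Region bounds in cM,
#'   `region_start < region_end` (a zero-length region returns no
#'   chiasmata).
#' @param cfg A [chiasma_config()].
#' @param direction `+1` to read from `region_start` towards `region_end`,
#'   `-1` to mirror the process from `region_end` back; positions are
#'   returned ascending either way.
#' @return Numeric vector of chiasma positions in cM (possibly empty).
#' @export
generate_chiasma_positions <- function(region_start, region_end, cfg,
                                       direction = 1) {
  len_m <- .cm2m(region_end - region_start)
  if (len_m <= 0) return(numeric(0))
  d <- .m2cm(.chiasma_stream(len_m, cfg))
  if (direction >= 0) region_start + d else sort(region_end - d)
}

#' Choose the chromatids participating in a chiasma
#'
#' Each chiasma involves one of the two sister chromatids of each of the
#' two paired chromosomes, with all four combinations equally likely and
#' independent across chiasmata (no chromatid interference).
#'
#' @param n Number of chiasmata to draw for.
#' @return An `n x 2` integer matrix of sister indices (1 or 2): column 1
#'   for the first chromosome, column 2 for the second.
#' @export
choose_chromatids <- function(n = 1) {
  matrix(sample.int(2L, 2L * n, replace = TRUE), ncol = 2L)
}

# Internal tail-swap without validation. Returns list(u', v') as bare
# start/allele lists (the engine hot path skips attribute bookkeeping;
# the exported apply_chiasma() restores full haplostruct objects).
.swap_tail <- function(u, v, x) {
  us <- u[["start"]]; vs <- v[["start"]]
  ua <- u[["allele"]]; va <- v[["allele"]]
  hu <- us < x; hv <- vs < x
  ju <- sum(us <= x); jv <- sum(vs <= x)
  n_st <- c(us[hu], x, vs[vs > x])
  n_al <- c(ua[hu], va[jv], va[vs > x])
  m_st <- c(vs[hv], x, us[us > x])
  m_al <- c(va[hv], ua[ju], ua[us > x])
  k <- length(n_al)
  keep <- c(TRUE, n_al[-1L] != n_al[-k])
  if (!all(keep)) { n_st <- n_st[keep]; n_al <- n_al[keep] }
  k <- length(m_al)
  keep <- c(TRUE, m_al[-1L] != m_al[-k])
  if (!all(keep)) { m_st <- m_st[keep]; m_al <- m_al[keep] }
  list(list(start = n_st, allele = n_al),
       list(start = m_st, allele = m_al))
}

#' Apply a chiasma to two chromatids
#'
#' Exchanges the contents of the two chromatids distal to the crossover
#' position `x` (positions `>= x`, half-open convention), producing two
#' recombinant mosaics. Content is conserved: at every position the
#' multiset of alleles on the pair is unchanged.
#'
#' @param u,v Canonical [haplostruct()] chromatids of the same chromosome.
#' @param x Crossover position in cM, strictly inside the chromosome.
#' @return A list of the two recombined `haplostruct`s.
#' @examples
#' u <- haplostruct(0, 0L); v <- haplostruct(0, 1L)
#' apply_chiasma(u, v, 30)
#' @export
apply_chiasma <- function(u, v, x) {
  len <- attr(u, "length")
  if (is.null(len)) len <- attr(v, "length")
  if (x <= 0 || (!is.null(len) && x >= len))
    stop("apply_chiasma: crossover position must lie strictly inside the ",
         "chromosome", call. = FALSE)
  res <- .swap_tail(u, v, x)
  list(.hs(res[[1L]]$start, res[[1L]]$allele,
           chromosome = attr(u, "chromosome"), length = attr(u, "length")),
       .hs(res[[2L]]$start, res[[2L]]$allele,
           chromosome = attr(v, "chromosome"), length = attr(v, "length")))
}
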