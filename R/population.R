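#' Mate two individuals
#'
#' Simulates one meiosis in each parent, samples one gamete from each, and
#' combines them into an offspring genome. The maternal (first parent)
#' gamete chromatids fill the first `ploidy/2` homolog slots in their
#' original order, the paternal gamete the remaining slots; this
#' positional convention is what downstream preferential pairing acts on.
#' Selfing (`parent1` identical to `parent2`) runs two independent
#' meioses.
#'
#' @param parent1,parent2 `individual_genome` objects of equal ploidy.
#' @param specs List of [chromosome_spec()]s.
#' @param cfg A [chiasma_config()].
#' @param name Offspring name.
#' @return The offspring `individual_genome`.
#' @export
mate <- function(parent1, parent2, specs, cfg, name = "offspring") {
  if (parent1$ploidy != parent2$ploidy)
    stop("cannot mate individuals of different ploidy (",
         parent1$ploidy, " vs ", parent2$ploidy, ")", call. = FALSE)
  g1 <- sample_gamete(do_meiosis(parent1, specs, cfg))
  g2 <- sample_gamete(do_meiosis(parent2, specs, cfg))
  if (inherits(specs, "chromosome_spec")) specs <- list(specs)
  homologs <- lapply(specs, function(spec)
    c(g1$chromatids[[spec$name]], g2$chromatids[[spec$name]]))
  names(homologs) <- vapply(specs, `[[`, character(1), "name")
  structure(list(name = name, ploidy = parent1$ploidy, homologs = homologs),
            class = "individual_genome")
}

#' Gene-drop a pedigree
#'
#' Creates founder genomes for pedigree entries without parents (in file
#' order, so the first founder gets founder alleles `0..ploidy-1`, the
#' second `ploidy..2*ploidy-1`, and so on) and generates every offspring
#' by mating its two parents. Entries must list both parents or neither,
#' and parents must be defined before their offspring.
#'
#' @param pedigree A data frame with columns `name`, `parent1`, `parent2`
#'   (`NA` for founders), e.g. from [read_pedigree_file()].
#' @param specs List of [chromosome_spec()]s.
#' @param cfg A [chiasma_config()].
#' @param ploidy 2 or 4.
#' @return A named list of `individual_genome`s, in pedigree order.
#' @export
build_population <- function(pedigree, specs, cfg, ploidy) {
  if (!ploidy %in% c(2L, 4L))
    stop("unsupported ploidy: ", ploidy, call. = FALSE)
  nm <- as.character(pedigree$name)
  p1 <- as.character(pedigree$parent1)
  p2 <- as.character(pedigree$parent2)
  if (anyDuplicated(nm))
    stop("duplicate individual in pedigree: ",
         nm[duplicated(nm)][1L], call. = FALSE)
  pop <- vector("list", length(nm))
  names(pop) <- nm
  founder_i <- 0L
  for (i in seq_along(nm)) {
    f1 <- is.na(p1[i]); f2 <- is.na(p2[i])
    if (f1 != f2)
      stop("pedigree entry '", nm[i],
           "' lists one parent only; founders must have neither",
           call. = FALSE)
    if (f1) {
      pop[[i]] <- founder_genome(founder_i, ploidy, specs, name = nm[i])
      founder_i <- founder_i + 1L
    } else {
      for (pp in c(p1[i], p2[i]))
        if (is.null(pop[[pp]]))
          stop("pedigree entry '", nm[i], "': parent '", pp,
               "' is not defined before use", call. = FALSE)
      pop[[i]] <- mate(pop[[p1[i]]], pop[[p2[i]]], specs, cfg, name = nm[i])
    }
  }
  pop
}

#' Define the observable alleles of the founder haplotypes
#'
#' Maps every founder allele ID to an observable allele (a SNP nucleotide,
#' an SSR fragment length, a dominant/recessive symbol, ...) at every
#' locus, plus a reference allele per locus for dosage counting.
#'
#' @param alleles Character matrix: rows = loci (rownames = marker names),
#'   columns = founder allele IDs `0..F*ploidy-1` in order.
#' @param reference Character vector of per-locus reference alleles;
#'   defaults to the observed allele of founder allele ID 0.
#' @return An object of class `allele_assignment`.
#' @export
allele_assignment <- function(alleles, reference = alleles[, 1L]) {
  alleles <- as.matrix(alleles)
  if (is.null(rownames(alleles)))
    stop("allele_assignment: allele matrix must have marker rownames",
         call. = FALSE)
  if (any(is.na(alleles)))
    stop("allele_assignment: every founder allele needs an observed allele ",
         "at every locus", call. = FALSE)
  if (length(reference) != nrow(alleles))
    stop("allele_assignment: one reference allele per locus required",
         call. = FALSE)
  reference <- stats::setNames(as.character(reference), rownames(alleles))
  structure(list(alleles = alleles, reference = reference),
            class = "allele_assignment")
}

#' Realize marker genotypes and allele dosages
#'
#' For each individual and locus, looks up the founder allele of every
#' homolog slot at the locus position, translates it to the observed
#' allele, and counts the dosage of the locus's reference allele
#' (0..ploidy). Distinct founder haplotypes may yield a homozygous
#' observed genotype if the same observable allele is assigned to both.
#'
#' @param population Named list of `individual_genome`s (see
#'   [build_population()]).
#' @param map Data frame with columns `marker`, `chromosome`, `position`
#'   (cM), e.g. from [read_map_file()].
#' @param assignment An [allele_assignment()] covering every founder
#'   allele present in the population at every mapped locus.
#' @return An object of class `realized_genotypes`: a list with
#'   * `founder`: integer matrix (loci x individual-slots) of founder
#'     allele IDs,
#'   * `obs`: character matrix of the same shape with observed alleles,
#'   * `dosage`: integer matrix (loci x individuals) of reference-allele
#'     dosages,
#'   plus `markers`, `individuals` and `ploidy`.
#' @export
realize_genotypes <- function(population, map, assignment) {
  ploidy <- population[[1L]]$ploidy
  inds <- names(population)
  markers <- as.character(map$marker)
  n_loc <- length(markers)
  n_ind <- length(inds)
  slot_names <- as.vector(t(outer(inds, seq_len(ploidy), paste, sep = "_")))
  fmat <- matrix(NA_integer_, n_loc, n_ind * ploidy,
                 dimnames = list(markers, slot_names))
  for (j in seq_len(n_ind)) {
    ind <- population[[j]]
    for (k in seq_len(ploidy)) {
      col <- (j - 1L) * ploidy + k
      for (chrom in names(ind$homologs)) {
        rows <- which(map$chromosome == chrom)
        if (!length(rows)) next
        h <- ind$homologs[[chrom]][[k]]
        fmat[rows, col] <- h$allele[findInterval(map$position[rows], h$start)]
      }
    }
  }
  if (anyNA(fmat))
    stop("realize_genotypes: map refers to chromosomes absent from the ",
         "population", call. = FALSE)
  amat <- assignment$alleles[markers, , drop = FALSE]
  max_id <- max(fmat)
  if (max_id + 1L > ncol(amat))
    stop("assignment gap: no observed allele for founder allele ", max_id,
         " (have ", ncol(amat), " columns) at locus '",
         markers[which(fmat == max_id, arr.ind = TRUE)[1L, 1L]], "'",
         call. = FALSE)
  obs <- matrix(amat[cbind(rep(seq_len(n_loc), n_ind * ploidy),
                           as.vector(fmat) + 1L)],
                n_loc, n_ind * ploidy, dimnames = dimnames(fmat))
  ref <- assignment$reference[match(markers, rownames(assignment$alleles))]
  dosage <- matrix(0L, n_loc, n_ind, dimnames = list(markers, inds))
  for (j in seq_len(n_ind)) {
    cols <- (j - 1L) * ploidy + seq_len(ploidy)
    dosage[, j] <- as.integer(rowSums(obs[, cols, drop = FALSE] == ref))
  }
  structure(list(founder = fmat, obs = obs, dosage = dosage,
                 markers = markers, individuals = inds,
                 ploidy = as.integer(ploidy)),
            class = "realized_genotypes")
}

#' @export
print.realized_genotypes <- function(x, ...) {
  cat(sprintf("<realized_genotypes: %d loci x %d individuals (ploidy %d)>\n",
              length(x$markers), length(x$individuals), x$ploidy))
  invisible(x)
}
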