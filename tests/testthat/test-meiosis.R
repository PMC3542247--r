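founder_cents <- function(spec, ploidy = 4) {
  f <- founder_genome(0, ploidy, list(spec))
  lapply(f$homologs[[spec$name]], function(h) list(h, h))
}

test_that("telomere pairing follows the preferential-pairing distribution", {
  set.seed(301)
  expect_true(all(pair_telomere(1, 200) == 1L))
  n <- 2e4
  fr0 <- tabulate(pair_telomere(0, n), 3) / n
  expect_true(all(abs(fr0 - 1 / 3) < 3 * sqrt((1 / 3) * (2 / 3) / n)))
  fr5 <- mean(pair_telomere(0.5, n) == 1L)
  expect_within_3se(fr5, 0.5 + 0.5 / 3, n)
  expect_error(pair_telomere(1.5), "\\[0, 1\\]")
})

test_that("expected quadrivalent fraction matches the pairing closed form", {
  expect_equal(expected_quadrivalent_fraction(0), 2 / 3)
  expect_equal(expected_quadrivalent_fraction(1), 0)
  expect_equal(round(expected_quadrivalent_fraction(0.75), 3), 0.292)
  expect_equal(expected_quadrivalent_fraction(0.25), 0.625)
  expect_equal(expected_quadrivalent_fraction(0.5), 0.5)
  expect_error(expected_quadrivalent_fraction(-0.1), "\\[0, 1\\]")
})

test_that("configuration decisions reproduce natural and forced ratios", {
  set.seed(302)
  n <- 2e4
  quad <- function(spec) mean(vapply(seq_len(n), function(i)
    decide_configuration(spec)$variant != "two_bivalents", logical(1)))
  expect_within_3se(quad(chrom100(pref_pairing = 0)), 2 / 3, n)
  expect_equal(quad(chrom100(pref_pairing = 1)), 0)
  expect_within_3se(quad(chrom100(quadrivalent_fraction = 0.4)), 0.4, n)
  # parallel fraction splits quadrivalents
  sp <- chrom100(quadrivalent_fraction = 1, parallel_fraction = 0.3)
  vs <- vapply(seq_len(n), function(i) decide_configuration(sp)$variant,
               character(1))
  expect_within_3se(mean(vs == "parallel"), 0.3, n)
  # diploid path always a single bivalent
  expect_equal(decide_configuration(chrom100(), ploidy = 2)$variant,
               "bivalent")
  # cross configurations always carry different top/bottom pairings
  cr <- Filter(function(cc) cc$variant %in% c("cross", "parallel"),
               lapply(1:200, function(i)
                 decide_configuration(chrom100(pref_pairing = 0))))
  expect_true(all(vapply(cr, function(cc) cc$top != cc$bottom, logical(1))))
})

test_that("bivalent recombination matches Haldane and conserves content", {
  set.seed(303)
  spec <- chrom100()
  # zero chiasmata leave all chromatids unrecombined
  cents <- founder_cents(spec)
  rs0 <- do_bivalent(cents[[1]], cents[[2]], spec, cfg_none())
  expect_equal(rs0$n_chiasmata, 0)
  expect_true(all(vapply(unlist(rs0$cents, recursive = FALSE),
                         function(h) length(h$start) == 1L, logical(1))))
  # conservation: each parental allele appears exactly twice at any point
  n <- 3000
  grid <- c(0, 10, 20, 50, 99.9)
  cfg <- cfg_haldane()
  for (i in seq_len(n)) {
    cents <- founder_cents(spec)
    rs <- do_bivalent(cents[[1]], cents[[2]], spec, cfg)
    mols <- unlist(rs$cents, recursive = FALSE)
    al <- vapply(mols, function(h)
      h$allele[findInterval(grid, h$start)], numeric(length(grid)))
    expect_true(all(apply(al, 1, function(r)
      sum(r == 0) == 2 && sum(r == 1) == 2)))
  }
  # recombination over 10-50 cM (40 cM interval): Haldane expectation
  set.seed(304)
  rec <- 0; m <- 0
  for (i in seq_len(8000)) {
    cents <- founder_cents(spec)
    rs <- do_bivalent(cents[[1]], cents[[2]], spec, cfg)
    for (h in unlist(rs$cents, recursive = FALSE)) {
      al <- h$allele[findInterval(c(10, 50), h$start)]
      rec <- rec + (al[1] != al[2]); m <- m + 1
    }
  }
  expect_within_3se(rec / m, map_function_r(0.4, "HALDANE"), m)
})

test_that("cross-type quadrivalents have a central unimodal exchange point", {
  set.seed(305)
  spec <- chrom100(quadrivalent_fraction = 1)
  cfg <- cfg_haldane()
  n <- 5000
  ex <- numeric(n); three <- FALSE
  for (i in seq_len(n)) {
    rs <- build_cross_quadrivalent(founder_cents(spec), 1L, 2L, spec, cfg)
    ex[i] <- rs$exchange_point
    if (!three)
      three <- any(vapply(unlist(rs$cents, recursive = FALSE),
                          function(h) length(unique(h$allele)) >= 3,
                          logical(1)))
  }
  expect_true(all(ex > 0 & ex < 100))
  expect_lt(abs(mean(ex) - 50), 3 * sd(ex) / sqrt(n))
  cnt <- hist(ex, breaks = seq(0, 100, 10), plot = FALSE)$counts
  expect_true(which.max(cnt) %in% 5:6)          # mode at the centre
  expect_true(all(cnt[c(1, 10)] < cnt[5:6]))    # tails below the mode
  # chromatids mosaicking three founders occur
  expect_true(three)
  expect_error(build_cross_quadrivalent(founder_cents(spec), 2L, 2L, spec,
                                        cfg),
               "different top and bottom")
  # degenerate: no chiasmata anywhere puts the exchange point at the centre
  rs0 <- build_cross_quadrivalent(founder_cents(spec), 1L, 3L, spec,
                                  cfg_none())
  expect_equal(rs0$exchange_point, 50)
  expect_equal(rs0$n_chiasmata, 0)
})

test_that("parallel quadrivalents mix all four founders", {
  set.seed(306)
  spec <- chrom100(quadrivalent_fraction = 1, parallel_fraction = 1)
  cfg4 <- chiasma_config(mean_distance = 0.25)
  four <- FALSE
  for (i in 1:2000) {
    rs <- build_parallel_quadrivalent(founder_cents(spec), spec, cfg4)
    if (any(vapply(unlist(rs$cents, recursive = FALSE),
                   function(h) length(unique(h$allele)) == 4, logical(1)))) {
      four <- TRUE
      break
    }
  }
  expect_true(four)
})

test_that("first division assorts centromeres correctly", {
  set.seed(307)
  spec <- chrom100(quadrivalent_fraction = 1)
  # quadrivalent default: the 3 pole partitions are equally likely
  rs <- build_cross_quadrivalent(founder_cents(spec), 1L, 2L, spec,
                                 cfg_none())
  n <- 6000
  part <- vapply(seq_len(n), function(i) {
    poles <- first_division(rs)
    mate_of_1 <- sort(vapply(poles[[1]], function(cc) cc[[1]]$allele[1],
                             integer(1)))[2]
    mate_of_1
  }, integer(1))
  fr <- tabulate(part, 3)[2:3] / n
  fr <- c(fr, 1 - sum(fr))
  expect_true(all(abs(fr - 1 / 3) < 3 * sqrt((1 / 3) * (2 / 3) / n)))
  # two bivalents: paired centromeres never share a pole
  f <- founder_genome(0, 4, list(spec))
  rs2 <- structure(list(variant = "two_bivalents",
                        cents = founder_cents(spec),
                        pairs = list(c(1L, 2L), c(3L, 4L)),
                        centromere = 20),
                   class = "recombined_set")
  for (i in 1:50) {
    poles <- first_division(rs2)
    a <- sort(vapply(poles[[1]], function(cc) cc[[1]]$allele[1], integer(1)))
    expect_true(a[1] %in% 0:1 && a[2] %in% 2:3)
  }
  # paired-centromeres model: centromere-side partners at opposite poles
  rs3 <- structure(list(variant = "cross", cents = founder_cents(spec),
                        top = 1L, bottom = 2L, exchange_point = 60,
                        centromere = 20),
                   class = "recombined_set")
  for (i in 1:50) {
    poles <- first_division(rs3, paired_centromeres = TRUE)
    a <- sort(vapply(poles[[1]], function(cc) cc[[1]]$allele[1], integer(1)))
    # top pairing {(0,1),(2,3)} split across poles
    expect_false(identical(a, c(0L, 1L)) || identical(a, c(2L, 3L)))
  }
  rs4 <- structure(list(variant = "parallel", cents = founder_cents(spec),
                        centromere = 20),
                   class = "recombined_set")
  expect_error(first_division(rs4, paired_centromeres = TRUE), "cross-type")
})

test_that("second division splits centromeres with independent orientation", {
  set.seed(308)
  spec <- chrom100()
  pole <- founder_cents(spec)[1:2]   # two centromeres, two chromatids each
  n <- 5000
  halves <- lapply(seq_len(n), function(i) second_division(pole))
  for (h in halves[1:20]) {
    expect_length(h[[1]], 2)
    expect_length(h[[2]], 2)
  }
  # per-centromere orientation 0.5/0.5 with distinct sister labels
  pole2 <- list(list(haplostruct(0, 0L), haplostruct(0, 1L)),
                list(haplostruct(0, 2L), haplostruct(0, 3L)))
  o <- vapply(seq_len(n), function(i) {
    h <- second_division(pole2)
    c(h[[1]][[1]]$allele[1], h[[1]][[2]]$allele[1])
  }, integer(2))
  expect_within_3se(mean(o[1, ] == 0L), 0.5, n)
  expect_within_3se(mean(o[2, ] == 2L), 0.5, n)
  # independence between the two centromeres at a pole
  joint <- table(o[1, ], o[2, ])
  expect_gt(suppressWarnings(chisq.test(joint))$p.value, 1e-4)
})

test_that("do_meiosis yields balanced gametes obeying the centromere rule", {
  set.seed(309)
  specs <- list(chrom100(pref_pairing = 0.3, parallel_fraction = 0.4),
                chromosome_spec("2", 60, 30))
  cfg <- cfg_haldane()
  f2 <- founder_genome(0, 2, specs)
  g2 <- do_meiosis(f2, specs, cfg)
  expect_length(g2, 4)
  expect_true(all(vapply(g2, function(g)
    all(lengths(g$chromatids) == 1L), logical(1))))
  f4 <- founder_genome(0, 4, specs)
  g4 <- do_meiosis(f4, specs, cfg)
  expect_true(all(vapply(g4, function(g)
    all(lengths(g$chromatids) == 2L), logical(1))))
  # conservation + centromere rule across random meioses (mixed configs)
  grid <- c(0, 10, 20, 50, 99.9)
  for (i in 1:500) {
    g <- do_meiosis(f4, specs[1], cfg)
    al <- sapply(g, function(gm) sapply(gm$chromatids[["1"]], function(h)
      h$allele[findInterval(grid, h$start)]))
    al <- matrix(al, nrow = length(grid))
    expect_true(all(apply(al, 1, function(r)
      all(tabulate(r + 1, 4) == 2))))
    for (gm in g) {
      cen <- vapply(gm$chromatids[["1"]], function(h)
        h$allele[findInterval(20, h$start)], integer(1))
      expect_false(cen[1] == cen[2])
    }
  }
})

test_that("bivalent-only tetraploid meiosis shows no double reduction", {
  set.seed(310)
  spec <- chrom100(quadrivalent_fraction = 0)
  st <- run_test_meioses(spec, cfg_haldane(), 3000,
                         loci = c(0, 20, 50, 100), ploidy = 4)
  for (l in c(0, 20, 50, 100))
    expect_equal(estimate_double_reduction(st, l)$dr, 0)
})

test_that("cross-type far-locus double reduction approaches 4/27", {
  # With a single exchange point and uniform centromere partition the
  # far-locus DR limit for cross-type quadrivalents is 4/27 (partner in
  # the same top branch: (1/3)(1/3); partner in another branch: (1/2)(1/3);
  # averaged over the three pole partitions: (1/9 + 1/6 + 1/6)/3).
  set.seed(311)
  spec <- chromosome_spec("1", 400, 80, quadrivalent_fraction = 1)
  st <- run_test_meioses(spec, cfg_haldane(), 2e4, loci = c(80, 400),
                         ploidy = 4)
  expect_equal(estimate_double_reduction(st, 80)$dr, 0)
  expect_within_3se(estimate_double_reduction(st, 400)$dr, 4 / 27, 2e4)
})

test_that("gamete sampling is uniform and seed-reproducible", {
  set.seed(312)
  spec <- chrom100()
  f <- founder_genome(0, 2, list(spec))
  g <- do_meiosis(f, list(spec), cfg_none())
  n <- 2e4
  pick <- vapply(seq_len(n), function(i)
    sample_gamete(g)$chromatids[["1"]][[1]]$allele[1], integer(1))
  fr <- tabulate(pick + 1, 2) / n
  expect_true(all(abs(fr - 0.5) < 3 * sqrt(0.25 / n)))
  expect_error(sample_gamete(g[1:3]), "four gametes")
  set.seed(99); a <- sample_gamete(g)
  set.seed(99); b <- sample_gamete(g)
  expect_identical(a, b)
})
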