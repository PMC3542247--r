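test_that("inter-chiasma distances have the configured mean and variance", {
  set.seed(201)
  n <- 2e4
  d <- sample_interchiasma_distance(cfg_haldane(), n)
  expect_lt(abs(mean(d) - 0.5), 3 * 0.5 / sqrt(n))       # exp: sd = mean
  dk <- sample_interchiasma_distance(cfg_kosambi(), n)
  sd_g <- 0.5 / sqrt(2.63)
  expect_lt(abs(mean(dk) - 0.5), 3 * sd_g / sqrt(n))
  # gamma variance mean^2/shape; 3-sigma band for a sample variance
  expect_lt(abs(var(dk) - 0.5^2 / 2.63), 0.005)
})

test_that("chiasma counts are Poisson without interference", {
  set.seed(202)
  n <- 2e4
  cfg <- cfg_haldane()
  cnt <- vapply(seq_len(n),
                function(i) length(generate_chiasma_positions(0, 100, cfg)),
                numeric(1))
  expect_lt(abs(mean(cnt) - 2), 3 * sqrt(2 / n))
  expect_lt(abs(var(cnt) / mean(cnt) - 1), 0.05)
  # chi-square against Poisson(2) on binned counts
  obs <- table(factor(pmin(cnt, 6), levels = 0:6))
  p <- dpois(0:5, 2); p <- c(p, 1 - sum(p))
  expect_gt(suppressWarnings(chisq.test(obs, p = p))$p.value, 1e-4)
  # four chiasmata per Morgan at the parallel-quadrivalent mean distance
  cfg4 <- chiasma_config(mean_distance = 0.25)
  cnt4 <- vapply(seq_len(n),
                 function(i) length(generate_chiasma_positions(0, 100, cfg4)),
                 numeric(1))
  expect_lt(abs(mean(cnt4) - 4), 3 * sqrt(4 / n))
})

test_that("interference under-disperses counts and is stationary after burn-in", {
  set.seed(203)
  n <- 2e4
  cfg <- cfg_kosambi()
  pos <- lapply(seq_len(n), function(i) generate_chiasma_positions(0, 100, cfg))
  cnt <- lengths(pos)
  expect_lt(abs(mean(cnt) - 2), 3 * sqrt(1 / n))  # var < mean = 2
  expect_lt(var(cnt), 0.7 * mean(cnt))            # under-dispersion
  # rate near the start telomere equals the rate at the region centre
  all_pos <- unlist(pos)
  n_start <- sum(all_pos <= 10)
  n_mid <- sum(all_pos > 45 & all_pos <= 55)
  expect_lt(abs(n_start - n_mid), 3 * sqrt(n_start + n_mid))
})

test_that("zero-length regions and mirrored generation behave", {
  set.seed(204)
  expect_length(generate_chiasma_positions(50, 50, cfg_haldane()), 0)
  p <- generate_chiasma_positions(0, 100, cfg_haldane(), direction = -1)
  expect_true(all(diff(p) > 0))
  expect_true(all(p >= 0 & p <= 100))
})

test_that("chromatid choice is uniform and independent across chiasmata", {
  set.seed(205)
  n <- 2e4
  ch <- choose_chromatids(n)
  combo <- (ch[, 1] - 1L) * 2L + ch[, 2]
  fr <- tabulate(combo, 4) / n
  expect_true(all(abs(fr - 0.25) < 3 * sqrt(0.25 * 0.75 / n)))
  # consecutive draws independent: 16-cell contingency uniform
  joint <- table(combo[-n], combo[-1])
  expect_gt(suppressWarnings(chisq.test(joint))$p.value, 1e-4)
  one <- choose_chromatids(1)
  expect_equal(dim(one), c(1L, 2L))
  expect_true(all(one %in% 1:2))
})

test_that("apply_chiasma performs a conservative tail swap", {
  u <- haplostruct(0, 0L, length = 100)
  v <- haplostruct(0, 1L, length = 100)
  r <- apply_chiasma(u, v, 30)
  expect_equal(r[[1]]$start, c(0, 30)); expect_equal(r[[1]]$allele, c(0L, 1L))
  expect_equal(r[[2]]$start, c(0, 30)); expect_equal(r[[2]]$allele, c(1L, 0L))
  # involution: same swap twice restores the inputs
  r2 <- apply_chiasma(r[[1]], r[[2]], 30)
  expect_equal(r2[[1]]$start, u$start); expect_equal(r2[[1]]$allele, u$allele)
  # mid-segment swap
  u3 <- haplostruct(c(0, 20), c(0L, 2L), length = 100)
  r3 <- apply_chiasma(u3, v, 50)
  expect_equal(r3[[1]]$start, c(0, 20, 50))
  expect_equal(r3[[1]]$allele, c(0L, 2L, 1L))
  expect_equal(r3[[2]]$start, c(0, 50))
  expect_equal(r3[[2]]$allele, c(1L, 2L))
  expect_error(apply_chiasma(u, v, 0), "strictly inside")
  expect_error(apply_chiasma(u, v, 100), "strictly inside")
})

test_that("apply_chiasma conserves the allele multiset at every position", {
  set.seed(206)
  grid <- seq(0, 99.5, by = 0.5)
  for (i in 1:200) {
    ku <- sample(1:6, 1); kv <- sample(1:6, 1)
    u <- haplostruct(sort(c(0, runif(ku - 1, 1, 99))),
                     sample(0:3, ku, replace = TRUE), length = 100)
    v <- haplostruct(sort(c(0, runif(kv - 1, 1, 99))),
                     sample(0:3, kv, replace = TRUE), length = 100)
    x <- runif(1, 1, 99)
    r <- apply_chiasma(u, v, x)
    before <- pmin(allele_at(u, grid), allele_at(v, grid)) * 10 +
      pmax(allele_at(u, grid), allele_at(v, grid))
    after <- pmin(allele_at(r[[1]], grid), allele_at(r[[2]], grid)) * 10 +
      pmax(allele_at(r[[1]], grid), allele_at(r[[2]], grid))
    expect_equal(after, before)
    # swap semantics: below x unchanged, at/above x exchanged
    expect_equal(allele_at(r[[1]], grid[grid < x]),
                 allele_at(u, grid[grid < x]))
    expect_equal(allele_at(r[[1]], grid[grid >= x]),
                 allele_at(v, grid[grid >= x]))
  }
})

test_that("chiasma_config validates parameters", {
  expect_error(chiasma_config(mean_distance = 0), "mean_distance")
  expect_error(chiasma_config(gamma_shape = -1), "gamma_shape")
  expect_error(chiasma_config(burnin_length = 2), "burnin")
})
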