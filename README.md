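# polymeiosis

Forward simulation of meiosis in diploid and tetraploid organisms.

Tetraploid crops — potato, rose, leek, alfalfa — inherit each chromosome
in four copies, and their meiosis involves phenomena without any diploid
counterpart: the four homologues may pair as two bivalents or as one
quadrivalent (cross-type with a variable chromosome exchange point, or
parallel), homoeologues may pair preferentially within their own
subgenome, and quadrivalents produce *double reduction* — gametes carrying
two copies of part of the same parental homologue. Software for linkage
mapping, haplotyping and QTL analysis in tetraploids has to be developed
and validated against data whose generating model is known exactly;
`polymeiosis` produces such data.

## The model in brief

Per chromosome set, each meiosis runs four steps:

1. **Pairing.** Telomeres pair independently; with preferential-pairing
   fraction *p*, the matching pairing has probability *p* + (1−*p*)/3 and
   each other pairing (1−*p*)/3. Two bivalents form when both telomeres
   pair alike, so the expected quadrivalent fraction is
   1 − [(*p*+(1−*p*)/3)² + 2((1−*p*)/3)²] — 2/3 for *p* = 0, 0 for
   *p* = 1. The ratio can also be forced per chromosome, and quadrivalents
   are cross-type or parallel in a configurable ratio.
2. **Chiasmata.** Crossover positions follow a renewal process from one
   telomere to the other: exponential gaps (mean 0.5 Morgan per bivalent
   or cross-type branch, 0.25 Morgan in parallel quadrivalents) without
   interference — the Haldane regime, r = (1 − e^(−2d))/2 — or gamma gaps
   (shape 2.63, same mean, 10-Morgan burn-in) with interference, which
   reproduces the Kosambi map function r = tanh(2d)/2. Each chiasma
   involves a uniform pair of non-sister chromatids (no chromatid
   interference) and exchanges their distal segments.
3. **Division I.** Bivalents split across poles; quadrivalent centromeres
   are partitioned into two pairs uniformly over the three partitions (or,
   optionally for cross-type, with centromere-side partners forced to
   opposite poles).
4. **Division II.** Every centromere splits with independent random
   orientation; each of the four gametes receives one chromatid per
   centromere, the two centromeres of a tetraploid gamete always coming
   from different parental chromosomes (hence double reduction is zero at
   the centromere and rises with distance, to 1/7 in parallel
   quadrivalents).

Founder homologues carry unique integer *founder alleles* (founder *i* of
ploidy *P* carries *iP*..*iP*+*P*−1), so every simulated chromosome is a
mosaic of founder segments. Gene-dropping a pedigree and translating
founder alleles to observable marker alleles yields ordered genotypes and
allele dosages (0..ploidy) on any genetic map. See the methods vignette
(`vignettes/meiosis-models.Rmd`) for the full model, parameter meanings
and design decisions.

## Worked example

Input files are plain tab-delimited text. A tetraploid cross of two
founders with three SNP markers on one 100 cM chromosome (centromere at
20 cM, natural pairing):

`params.txt`
```
PLOIDY = 4
MAPFUNCTION = HALDANE
CHROMFILE = chrom.txt
MAPFILE = map.txt
PEDFILE = ped.txt
FOUNDERFILE = founder.txt
OUTPUT = out/demo
SEED = 42
```

with `chrom.txt` (`chromosome length centromere prefPairing
quadrivalents`; `NA` = natural ratio), `map.txt` (`marker chromosome
position`), `ped.txt` (`name parent1 parent2`, founders have `NA`
parents: here `P1`, `P2` and two offspring `F1`, `F2`), and `founder.txt`
assigning observed alleles to the eight founder haplotypes per marker.
Then either

```sh
Rscript inst/cli/polymeiosis.R params.txt          # or cli_main("params.txt")
```

or `run_simulation("params.txt")` from R. The run prints the seed and
writes four files; with the inputs above, `out/demo_alleledose.dat` is

```
marker  P1  P2  F1  F2
M10     2   0   1   1
M40     1   2   1   1
M90     4   1   3   2
```

the dosage of each marker's reference allele (the allele of founder
haplotype 0: `A`/`C`/`G`) in each individual, 0..4 per tetraploid. P1 was
given dosage 2 at M10 (`A A a a`) and both offspring inherited exactly one
`A` copy — consistent with one `A`-bearing chromatid transmitted through
the P1 gamete. `out/demo_genotypes.dat` holds the ordered observable
genotypes per homolog slot, `out/demo_founderalleles.dat` the underlying
founder-allele IDs, and `out/demo_haplostruct.dat` the full segment
mosaics (round-trippable with `read_haplostruct_file()`).

The test mode validates the engine against closed forms. For a
bivalent-only tetraploid without interference, recombination over 50 cM
should be Haldane's r(0.5 M) = 0.3161:

```r
sp <- chromosome_spec("chr1", 100, 20, quadrivalent_fraction = 0)
st <- run_test_meioses(sp, chiasma_config(), 20000, loci = c(25, 75),
                       ploidy = 4)
estimate_recombination(st, 25, 75)
#> $r
#> [1] 0.318025
#> $se
#> [1] 0.002328546
#> $n
#> [1] 40000
```

0.3180 ± 0.0023: within two standard errors of 0.3161.
`summarize_gamete_stats(st)` tabulates every interval against its
reference with z-scores, and `cli_main(c("params.txt", "--test"))` writes
the same table as `<prefix>_testreport.dat`.

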