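test_that("FASTA loading enforces the population map and round-trips", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "locus1.fasta")
  seqs <- c(a1 = "ACGTAC-GTA", a2 = "ACGTACCGTA", b1 = "ACTTACCGTA",
            b2 = "ACTTACCGNA")
  writeLines(paste0(">", names(seqs), "\n", seqs), fa)
  map <- c(a1 = "popA", a2 = "popA", b1 = "popB", b2 = "popB")

  aln <- loadLocusFasta(fa, map)
  expect_s4_class(aln, "LocusAlignment")
  expect_length(aln, 4L)
  expect_equal(as.character(popLabels(aln)), unname(map))

  expect_error(loadLocusFasta(fa, map[-2]), "a2")

  out <- file.path(dir, "roundtrip.fasta")
  writeLocusFasta(aln, out)
  back <- loadLocusFasta(out, map)
  expect_identical(as.character(back@sequences), as.character(aln@sequences))

  ragged <- file.path(dir, "ragged.fasta")
  writeLines(c(">a1", "ACGT", ">a2", "ACG"), ragged)
  expect_error(loadLocusFasta(ragged, map), "ragged")
})

test_that("nucleotide diversity matches definition and brute force", {
  same <- LocusAlignment("m", rep(strrep("ACGT", 25), 10), rep("p", 10))
  expect_equal(as.numeric(nucleotideDiversity(same)), 0)

  two <- LocusAlignment("t", c(strrep("A", 100),
                               paste0(strrep("A", 99), "T")),
                        c("p", "p"))
  expect_equal(as.numeric(nucleotideDiversity(two)), 0.01)

  toy <- toyAlignment()
  expect_equal(as.numeric(nucleotideDiversity(toy)), 10 / 6 / 3,
               tolerance = 1e-12)

  # property: exact agreement with the O(n^2 L) oracle on random alignments,
  # including gap/N columns which must be deleted completely
  set.seed(42)
  for (rep in 1:15) {
    n <- sample(4:12, 1)
    L <- sample(20:60, 1)
    m <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE,
                       prob = c(.4, .3, .2, .1)), n, L)
    m[sample(length(m), 5)] <- "-"
    m[sample(length(m), 3)] <- "N"
    seqs <- apply(m, 1, paste, collapse = "")
    aln <- LocusAlignment("r", seqs, rep(c("x", "y"), length.out = n))
    orc <- oraclePi(seqs)
    got <- nucleotideDiversity(aln)
    expect_equal(as.numeric(got), orc$pi, tolerance = 1e-12)
    expect_equal(attr(got, "nSitesUsed"), orc$nSites)
  }
})

test_that("an all-gap column changes no statistic (complete deletion)", {
  toy <- toyAlignment()
  gapped <- LocusAlignment("toy", c("AA-A", "AA-T", "AT-T", "TT-T"),
                           toy@popLabels, fragmentLength = 3L)
  expect_equal(as.numeric(nucleotideDiversity(gapped)),
               as.numeric(nucleotideDiversity(toy)))
  expect_equal(as.numeric(tajimasD(gapped)), as.numeric(tajimasD(toy)))
  expect_equal(phiSt(gapped, 0)$phiSt, phiSt(toy, 0)$phiSt)
})

test_that("Tajima's D follows the 1989 formulas and undefined rules", {
  mono <- LocusAlignment("m", rep("ACGT", 5), rep("p", 5))
  expect_true(is.na(tajimasD(mono)))

  three <- LocusAlignment("t3", c("AAAA", "AATA", "ATTA"), rep("p", 3))
  expect_true(is.na(tajimasD(three)))

  toy <- toyAlignment()
  d <- tajimasD(toy)
  expect_equal(as.numeric(d), oracleTajimaD(3, 10 / 6, 4),
               tolerance = 1e-12)
  # per-population values undefined at n = 2 < 4
  expect_true(all(is.na(attr(d, "perPop"))))
})

test_that("Phi-ST matches direct AMOVA arithmetic and handles extremes", {
  fixed <- LocusAlignment("f",
    c("AAAA", "AAAA", "TTTT", "TTTT"), c("x", "x", "y", "y"))
  expect_equal(phiSt(fixed, 0)$phiSt, 1)

  # identical haplotype composition in the two populations: Phi-ST near 0
  # (slightly negative by construction), permutation test non-significant
  same <- LocusAlignment("s",
    rep(c("AAAA", "TTTT"), 50), rep(c("x", "y"), each = 50))
  set.seed(1)
  res <- phiSt(same, 199)
  expect_lt(abs(res$phiSt), 0.05)
  expect_gt(res$pValue, 0.05)

  # one shared and one private variant: compare to the arithmetic oracle
  seqs <- c("AAAA", "AATA", "TATA", "TAAA")
  labs <- c("x", "x", "y", "y")
  aln <- LocusAlignment("o", seqs, labs)
  expect_equal(phiSt(aln, 0)$phiSt, oraclePhiSt(seqs, labs),
               tolerance = 1e-12)

  one <- LocusAlignment("e", c("AAAA", "AATA", "TATA"), c("x", "x", "y"))
  expect_error(phiSt(one), "at least 2 sequences")

  # random labels give a roughly uniform permutation p
  set.seed(7)
  ps <- replicate(40, {
    m <- matrix(sample(c("A", "T"), 8 * 30, replace = TRUE), 8, 30)
    aln <- LocusAlignment("u", apply(m, 1, paste, collapse = ""),
                          sample(rep(c("x", "y"), 4)))
    phiSt(aln, 99)$pValue
  })
  expect_gt(mean(ps), 0.30)
  expect_lt(mean(ps), 0.72)
})

test_that("locusStats bundles components and is order-invariant", {
  mono <- LocusAlignment("m", rep("ACGTACGT", 6),
                         rep(c("x", "y"), each = 3))
  st <- locusStats(mono)
  expect_equal(st$pi, 0)
  expect_equal(st$S, 0L)
  expect_true(is.na(st$tajd))

  set.seed(11)
  m <- matrix(sample(c("A", "C", "G", "T"), 8 * 40, replace = TRUE), 8, 40)
  seqs <- apply(m, 1, paste, collapse = "")
  labs <- rep(c("x", "y"), each = 4)
  a1 <- LocusAlignment("z", seqs, labs)
  perm <- sample(8)
  a2 <- LocusAlignment("z", seqs[perm], labs[perm])
  s1 <- locusStats(a1)
  s2 <- locusStats(a2)
  for (col in c("pi", "phi_st", "tajd", "tajd_mean", "S", "n_sites_used"))
    expect_equal(s1[[col]], s2[[col]], info = col)
  # internal consistency of the (pi, S, D) triple with the oracles
  orc <- oraclePi(seqs)
  expect_equal(s1$pi, orc$pi, tolerance = 1e-12)
  expect_equal(s1$tajd, oracleTajimaD(s1$S, orc$meanDiffs, 8),
               tolerance = 1e-12)
})

test_that("multilocusSummary uses n-1 SD, CV = sd/|mean|, skips NA", {
  stats <- data.frame(pi = c(0.01, 0.01, 0.01), phi_st = c(0, 0.1, 0.2),
                      tajd = c(-1, NA, 1))
  s <- multilocusSummary(stats)
  expect_equal(s$sd[s$statistic == "pi"], 0)
  expect_equal(s$cv[s$statistic == "pi"], 0)
  expect_equal(s$sd[s$statistic == "phi_st"], sd(c(0, .1, .2)))
  expect_equal(s$n_loci[s$statistic == "tajd"], 2L)
  expect_equal(s$n_undefined[s$statistic == "tajd"], 1L)

  bad <- data.frame(pi = c(0.1, 0.2), phi_st = c(0.1, 0.2),
                    tajd = c(NA_real_, NA_real_))
  expect_error(multilocusSummary(bad), "fewer than 2")
})

test_that("the summary-table reader validates its dialect", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "t.tsv")
  writeLines(c("locus\tlength_bp\tpi\tphi_st\ttajd",
               "A\t300\t0.01\t0.05\t-0.2"), f)
  tab <- readTable1(f)
  expect_equal(tab$pi, 0.01)
  writeLines(c("locus\tpi", "A\t0.01"), f)
  expect_error(readTable1(f), "length_bp")
})
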