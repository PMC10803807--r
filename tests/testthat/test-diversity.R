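test_that("heterozygosities, F-statistics and allelic richness behave at
          the analytic extremes", {
  L <- 4; n <- 20
  panel <- tinyPanel(L)
  ## two groups fixed for alternate alleles: H_S = 0, H_T = 0.5, FST = 1
  gm <- makeGm(rbind(matrix("AA", n, L), matrix("BB", n, L)), panel,
               line = rep(c("LL", "LC"), each = n),
               ids = sprintf("i%02d", 1:(2 * n)))
  dv <- molecularDiversity(gm, loci = panel$marker_id)
  expect_equal(dv$perLocus$hS, rep(0, L))
  expect_equal(dv$perLocus$hT, rep(0.5, L))
  expect_equal(dv$fstats$perLocusMean[dv$fstats$statistic == "F_ST"], 1)
  expect_equal(dv$fstats$fromMeanH[dv$fstats$statistic == "F_ST"], 1)
  ## monomorphic-within-group rarefaction floor: AR = 1
  expect_true(all(dv$allelicRichness == 1))

  ## all-heterozygote group: H_O = 1 > H_S -> F_IS < 0
  gm2 <- makeGm(rbind(matrix("AB", n, L), matrix("AB", n, L)), panel,
                line = rep(c("LL", "LC"), each = n),
                ids = sprintf("j%02d", 1:(2 * n)))
  dv2 <- molecularDiversity(gm2, loci = panel$marker_id)
  expect_lt(dv2$fstats$fromMeanH[dv2$fstats$statistic == "F_IS"], 0)
})

test_that("the (1-FIT) = (1-FIS)(1-FST) identity is exact in mean-H mode
          and estimates are allele-label invariant", {
  gm <- simTwoPop(13, n = 40, L = 20)
  dv <- molecularDiversity(gm, loci = markerInfo(gm)$marker_id)
  fs <- dv$fstats$fromMeanH
  names(fs) <- dv$fstats$statistic
  expect_equal(unname(1 - fs["F_IT"]),
               unname((1 - fs["F_IS"]) * (1 - fs["F_ST"])),
               tolerance = 1e-12)
  ## relabel alleles (swap AA <-> BB) at every locus
  calls <- genoCalls(gm)
  swapped <- calls
  swapped[calls == "AA"] <- "BB"
  swapped[calls == "BB"] <- "AA"
  gmSw <- makeGenotypeCalls(swapped, markerInfo(gm),
                            individuals = individualInfo(gm))
  dvSw <- molecularDiversity(gmSw, loci = markerInfo(gm)$marker_id)
  expect_equal(dvSw$fstats, dv$fstats)
  expect_equal(dvSw$groupStats$uhE, dv$groupStats$uhE)
  ## jackknife SEs are non-negative
  expect_true(all(dv$fstats$perLocusSE >= 0))
})

test_that("a random-mating population shows no systematic F_IS", {
  set.seed(61)
  L <- 800; n <- 80
  p <- runif(L, 0.1, 0.9)
  draw <- function() matrix(
    c("AA", "AB", "BB")[rbinom(n * L, 2, rep(p, each = n)) + 1L], n, L)
  gm <- makeGm(rbind(draw(), draw()), tinyPanel(L),
               line = rep(c("LL", "LC"), each = n),
               ids = sprintf("i%03d", 1:(2 * n)))
  dv <- molecularDiversity(gm, loci = markerInfo(gm)$marker_id)
  fis <- dv$fstats$perLocusMean[dv$fstats$statistic == "F_IS"]
  se <- dv$fstats$perLocusSE[dv$fstats$statistic == "F_IS"]
  expect_lt(abs(fis), 3 * se)
})

test_that("tabular kinship reproduces textbook coancestries", {
  ## full-sib mating: offspring inbreeding 0.25
  ped <- pedFromTable(
    id = c("A", "B", "S1", "S2", "K"),
    sire = c("", "", "A", "A", "S1"),
    dam = c("", "", "B", "B", "S2"),
    sex = c("M", "F", "M", "F", "M"),
    line = "LL", alive = 1)
  kin <- pedigreeKinship(ped)
  expect_equal(unname(kin$inbreeding["K"]), 0.25)
  ## parent-offspring coancestry 0.25, full sibs 0.25, self 0.5
  expect_equal(unname(kin$kinship["A", "S1"]), 0.25)
  expect_equal(unname(kin$kinship["S1", "S2"]), 0.25)
  expect_equal(unname(kin$kinship["A", "A"]), 0.5)
  expect_equal(unname(kin$kinship["A", "B"]), 0)
})

test_that("kinship agrees with a brute-force gene-drop estimate on a
          random pedigree", {
  ts <- simulatePopulation(simConfig(seed = 37, nGenerations = 3))
  kin <- pedigreeKinship(ts$pedigree)
  rec <- pedRecords(ts$pedigree)
  ## independent oracle: identity-by-descent sharing of dropped alleles
  set.seed(2)
  iters <- 20000
  ids <- rec$id
  sireIx <- match(rec$sire, ids); damIx <- match(rec$dam, ids)
  ord <- order(is.na(sireIx) + is.na(damIx), decreasing = TRUE)
  a1 <- matrix(0L, length(ids), iters); a2 <- a1; nxt <- 0L
  for (i in ord) {
    if (is.na(sireIx[i])) { nxt <- nxt + 1L; a1[i, ] <- nxt }
    else a1[i, ] <- ifelse(runif(iters) < 0.5, a1[sireIx[i], ],
                           a2[sireIx[i], ])
    if (is.na(damIx[i])) { nxt <- nxt + 1L; a2[i, ] <- nxt }
    else a2[i, ] <- ifelse(runif(iters) < 0.5, a1[damIx[i], ],
                           a2[damIx[i], ])
  }
  pairs <- cbind(sample(seq_along(ids), 12), sample(seq_along(ids), 12))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    ## coancestry = P(random allele of i IBD to random allele of j)
    f <- mean((a1[i, ] == a1[j, ]) + (a1[i, ] == a2[j, ]) +
                (a2[i, ] == a1[j, ]) + (a2[i, ] == a2[j, ])) / 4
    se <- sqrt(f * (1 - f) / iters) + 1e-6
    expect_lt(abs(f - kin$kinship[ids[i], ids[j]]), 5 * se + 0.01)
  }
})

test_that("gene diversity: closed forms for tiny pools, and the two
          estimators target the same quantity", {
  ped <- pedFromTable(id = c("A", "B"), sire = c("", ""),
                      dam = c("", ""), sex = c("M", "F"),
                      line = "LL", alive = 1)
  gd <- geneDiversity(ped, iterations = 50, seed = 3)
  expect_equal(gd$gdKinship, 0.75)
  expect_equal(gd$gdGeneDrop, 0.75)     # 4 equifrequent founder alleles
  gd1 <- geneDiversity(ped, living = "A", iterations = 10, seed = 3)
  expect_equal(gd1$gdKinship, 0.5)
  expect_error(geneDiversity(ped, living = "ZZ"), "absent")

  ts <- simulatePopulation(simConfig(seed = 41, nGenerations = 3))
  gd2 <- geneDiversity(ts$pedigree, iterations = 4000, seed = 9)
  expect_lt(abs(gd2$gdGeneDrop - gd2$gdKinship),
            4 * gd2$gdGeneDropSE + 1e-4)
  ## founder contributions are a probability distribution
  expect_equal(sum(gd2$founderContributions$contribution), 1,
               tolerance = 1e-9)
})

test_that("pedigree F-statistics: null case, separated-lines sign, and the
          Wright identity", {
  ## two lines of mutually unrelated non-inbred individuals
  ped0 <- pedFromTable(id = sprintf("u%d", 1:6), sire = "", dam = "",
                       sex = rep(c("M", "F"), 3),
                       line = rep(c("LL", "LC"), each = 3), alive = 1)
  f0 <- pedigreeFStats(ped0)
  expect_equal(unname(f0["fis"]), 0)
  expect_equal(unname(f0["fst"]), 0)
  ## two inbred, mutually unrelated lines -> FST > 0
  ped1 <- pedFromTable(
    id = c("A", "B", "s1", "d1", "k1", "C", "D", "s2", "d2", "k2"),
    sire = c("", "", "A", "A", "s1", "", "", "C", "C", "s2"),
    dam = c("", "", "B", "B", "d1", "", "", "D", "D", "d2"),
    sex = c("M", "F", "M", "F", "M", "M", "F", "M", "F", "F"),
    line = rep(c("LL", "LC"), each = 5), alive = 1)
  f1 <- pedigreeFStats(ped1)
  expect_gt(unname(f1["fst"]), 0)
  expect_equal(unname(1 - f1["fit"]),
               unname((1 - f1["fis"]) * (1 - f1["fst"])),
               tolerance = 1e-12)
  ## single line -> hard error
  pedS <- pedFromTable(id = c("A", "B"), sire = "", dam = "",
                       sex = c("M", "F"), line = "LL", alive = 1)
  expect_error(pedigreeFStats(pedS), "F_ST undefined")
})

test_that("molecular and pedigree F_ST agree on the synthetic two-line
          population", {
  ts <- simulatePopulation(simConfig(seed = 47, nGenerations = 4,
                                     migration = 0.02))
  dv <- molecularDiversity(ts$genotypes)
  molFst <- dv$fstats$fromMeanH[dv$fstats$statistic == "F_ST"]
  seFst <- dv$fstats$fromMeanHSE[dv$fstats$statistic == "F_ST"]
  pedFst <- unname(pedigreeFStats(ts$pedigree)["fst"])
  expect_lt(abs(molFst - pedFst), 4 * seFst + 0.02)
})
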