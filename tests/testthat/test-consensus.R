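consensusOf <- function(reps, panel = tinyPanel(1)) {
  rc <- makeRc(matrix(reps, ncol = 1), panel)
  unname(buildConsensus(rc, markers = panel,
                        minReplicates = 1L)$genotype[1])
}

test_that("worked consensus examples follow the scoring rules", {
  ## equal homo/het split is heterozygous
  expect_identical(consensusOf(c("AA", "AB")), "AB")
  ## opposing homozygotes 50:50 -> no zygosity assigned
  expect_identical(consensusOf(c("AA", "BB")), NA_character_)
  ## strict majority once the het-forcing rules fail
  expect_identical(consensusOf(c("AA", "AA", "AB")), "AA")
  ## both opposite homozygotes at least twice + a het -> heterozygous
  expect_identical(consensusOf(c("AA", "AA", "BB", "BB", "AB")), "AB")
  ## every zygosity present -> heterozygous
  expect_identical(consensusOf(c("AA", "AB", "BB")), "AB")
  ## all missing -> No Call
  expect_identical(consensusOf(c(NA, NA, NA)), NA_character_)
})

test_that("consensus is invariant under replicate permutation", {
  set.seed(7)
  for (i in 1:25) {
    reps <- sample(c("AA", "AB", "BB", NA), sample(2:6, 1),
                   replace = TRUE)
    expect_identical(consensusOf(reps), consensusOf(sample(reps)))
  }
})

test_that("adding an error-free replicate never corrupts a correct consensus", {
  ## enumerate all tallies up to 5 replicates; whenever the consensus
  ## equals some truth g, appending one replicate equal to g keeps it
  tallies <- expand.grid(nAA = 0:5, nAB = 0:5, nBB = 0:5)
  tallies <- tallies[rowSums(tallies) >= 1 & rowSums(tallies) <= 5, ]
  for (k in seq_len(nrow(tallies))) {
    tl <- tallies[k, ]
    cons <- wisentpanel:::.consensusFromTally(tl$nAA, tl$nAB, tl$nBB)
    if (is.na(cons)) next
    tl2 <- tl
    tl2[[paste0("n", cons)]] <- tl2[[paste0("n", cons)]] + 1L
    expect_identical(
      wisentpanel:::.consensusFromTally(tl2$nAA, tl2$nAB, tl2$nBB), cons)
  }
})

test_that("with zero simulated error, consensus equals truth and GE = 0", {
  cfg <- simConfig(seed = 13, nGenerations = 2, pAdo = 0, pFa = 0,
                   pMissNoninvasive = 0.05)
  ts <- simulatePopulation(cfg)
  rcs <- observeReplicates(ts, cfg)
  cons <- lapply(rcs, buildConsensus)
  truth <- genoCalls(ts$genotypes)
  for (i in seq_along(cons)) {
    g <- cons[[i]]$genotype
    called <- !is.na(g)
    expect_identical(unname(g[called]), unname(truth[i, called]))
  }
  er <- estimateErrorRates(rcs, cons)
  expect_equal(unname(er$overall["geRate"]), 0)
})

test_that("error classification matches the definitions and the generator log", {
  panel <- tinyPanel(2)
  rc <- makeRc(rbind(c("AB", "AA"), c("AA", "AB"), c("AB", "AA")), panel)
  cons <- buildConsensus(rc, markers = panel, minReplicates = 3L)
  expect_identical(unname(cons$genotype), c("AB", "AA"))
  er <- estimateErrorRates(list(rc), list(cons), markers = panel)
  pl <- er$perLocus[match(c("M01", "M02"), er$perLocus$marker), ]
  expect_equal(pl$nAdo, c(1L, 0L))   # consensus AB, replicate AA
  expect_equal(pl$nFa, c(0L, 1L))    # consensus AA, replicate AB
  expect_equal(unname(er$overall["geRate"]),
               sum(pl$nAdo + pl$nFa) / sum(pl$comparisons))

  ## on simulated data the classified events equal the generator's log
  ## at loci where the consensus equals truth
  cfg <- simConfig(seed = 17, nGenerations = 3)
  ts <- simulatePopulation(cfg)
  rcs <- observeReplicates(ts, cfg)
  cons <- lapply(rcs, buildConsensus)
  er2 <- estimateErrorRates(rcs, cons)
  log <- attr(rcs, "eventLog")
  truth <- genoCalls(ts$genotypes)
  ids <- individualInfo(ts$genotypes)$id
  consMat <- do.call(rbind, lapply(cons, `[[`, "genotype"))
  rownames(consMat) <- ids
  okCell <- function(s, m) !is.na(consMat[s, m]) &&
    consMat[s, m] == truth[s, m]
  trueEv <- log[log$event != "miss" &
                  mapply(okCell, log$sample, log$marker), ]
  estEv <- er2$events[mapply(okCell, er2$events$sample,
                             er2$events$marker), ]
  keyOf <- function(d) sort(paste(d$sample, d$replicate, d$marker,
                                  d$event))
  expect_identical(keyOf(estEv), keyOf(trueEv))
})

test_that("ADO and FA are mutually exclusive per biallelic comparison and
          GE = ADO + FA", {
  cfg <- simConfig(seed = 23, nGenerations = 3)
  ts <- simulatePopulation(cfg)
  rcs <- observeReplicates(ts, cfg)
  er <- estimateErrorRates(rcs)
  expect_false(any(duplicated(
    er$events[, c("sample", "replicate", "marker")])))
  expect_equal(unname(er$overall["geRate"]),
               unname(er$overall["adoRate"] + er$overall["faRate"]))
  with(er$perLocus, expect_equal(geRate[comparisons > 0],
                                 adoRate[comparisons > 0] +
                                   faRate[comparisons > 0]))
})

test_that("under-replicated non-invasive samples are withheld, loci above
          the GE threshold flagged", {
  panel <- tinyPanel(2)
  rc <- makeRc(rbind(c("AA", "AB")), panel)   # single replicate
  cons <- buildConsensus(rc, markers = panel, minReplicates = 3L)
  expect_true(cons$flagged)
  expect_true(all(is.na(cons$genotype)))
  rcInv <- makeRc(rbind(c("AA", "AB")), panel, type = "invasive")
  expect_false(buildConsensus(rcInv, markers = panel)$flagged)

  ## a locus with heavy disagreement gets flagged at the 5% GE threshold
  bad <- lapply(1:6, function(i)
    makeRc(rbind(c("AB", "AA"), c("AA", "AA"), c("AB", "AA")), panel,
           sampleId = paste0("s", i)))
  er <- estimateErrorRates(bad, markers = panel)
  expect_true(er$perLocus$flagged[er$perLocus$marker == "M01"])
  expect_false(er$perLocus$flagged[er$perLocus$marker == "M02"])
})

test_that("sex determination reproduces the majority-vote failure taxonomy", {
  panel <- tinyPanel(1, withSex = TRUE)
  sexRc <- function(calls) makeRc(cbind("AA", calls), panel)
  s <- determineSex(sexRc(rep("XY", 6)), markers = panel)
  expect_identical(s$sex, "male")
  expect_equal(s$yFraction, 1)
  ## a female with 4 of 6 spurious Y calls is a false-positive male
  expect_identical(determineSex(sexRc(c("XY", "XY", "XY", "XY", "X", "X")),
                                markers = panel)$sex, "male")
  ## 3 of 6 is a tie: not determinable
  expect_identical(determineSex(sexRc(c("XY", "XY", "XY", "X", "X", "X")),
                                markers = panel)$sex, "undetermined")
  expect_identical(determineSex(sexRc(c("X", "X", "X", "XY", NA, NA)),
                                markers = panel)$sex, "female")
  nodata <- determineSex(sexRc(rep(NA_character_, 6)), markers = panel)
  expect_identical(nodata$sex, "undetermined")
  expect_identical(nodata$reason, "no data")
})

test_that("consensusGenotypes assembles one row per individual with sexes", {
  cfg <- simConfig(seed = 31, nGenerations = 2)
  ts <- simulatePopulation(cfg)
  rcs <- observeReplicates(ts, cfg)
  gm <- consensusGenotypes(rcs)
  expect_equal(nrow(genoCalls(gm)), length(rcs))
  rec <- pedRecords(ts$pedigree)
  sexes <- individualInfo(gm)$sex
  trueSex <- rec$sex[match(individualInfo(gm)$id, rec$id)]
  expect_gt(mean(sexes == trueSex), 0.9)
  expect_equal(length(gm@provenance$callRate), length(rcs))
})
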