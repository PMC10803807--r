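freqTable <- function(pB, panel = tinyPanel(length(pB))) {
  data.frame(marker = panel$marker_id, pA = 1 - pB, pB = pB,
             nGenes = 100L, hExp = 2 * pB * (1 - pB),
             stringsAsFactors = FALSE)
}

test_that("PID and PIDsib match the closed forms and their ordering", {
  pc <- pidCurves(freqTable(0.5), threshold = 1e-4)
  expect_equal(pc$pid, 0.375)
  expect_equal(pc$pidsib, 0.59375)
  ## monomorphic locus discriminates nothing
  pcMono <- suppressWarnings(pidCurves(freqTable(c(1, 1))))
  expect_equal(pcMono$pid, c(1, 1))
  expect_equal(pcMono$cumPidsib, c(1, 1))
  ## PIDsib >= PID on a frequency grid (siblings are harder)
  grid <- seq(0.01, 0.99, by = 0.02)
  per <- t(vapply(grid, wisentpanel:::.pidLocus, c(pid = 0, pidsib = 0)))
  expect_true(all(per[, "pidsib"] >= per[, "pid"]))
})

test_that("cumulative PID curves are non-increasing, ranked by H_E, and
          report the locus count to threshold", {
  set.seed(5)
  pB <- runif(40, 0.05, 0.95)
  pc <- pidCurves(freqTable(pB), threshold = 1e-4)
  expect_true(all(diff(pc$cumPid) <= 0))
  expect_true(all(diff(pc$cumPidsib) <= 0))
  expect_true(all(diff(pc$hExp) <= 0))
  hit <- attr(pc, "lociToThreshold")
  expect_true(pc$cumPid[hit["pid"]] < 1e-4)
  expect_true(hit["pid"] == 1 || pc$cumPid[hit["pid"] - 1] >= 1e-4)
  expect_gte(hit["pidsib"], hit["pid"])
})

test_that("mismatch counts follow the definition and ignore missing loci", {
  gm <- makeGm(rbind(c("AA", "AB", "BB"),
                     c("AA", "BB", "BB"),
                     c("AA", NA, "BB")), tinyPanel(3))
  mm <- matchIndividuals(gm, maxMismatch = 0)
  expect_equal(unname(mm$mismatch["ind01", "ind02"]), 1)
  expect_equal(unname(mm$compared["ind01", "ind02"]), 3)
  ## identical where both called, disjoint missingness -> 0 mismatches
  expect_equal(unname(mm$mismatch["ind01", "ind03"]), 0)
  expect_equal(unname(mm$compared["ind01", "ind03"]), 2)
  expect_true(isSymmetric(mm$mismatch))
  expect_true(all(diag(mm$mismatch) == 0))
  expect_true(all(mm$mismatch <= mm$compared))
})

test_that("duplicate observations of one individual are grouped, distinct
          individuals are not", {
  cfg <- simConfig(seed = 19, nGenerations = 3)
  ts <- simulatePopulation(cfg)
  gm <- ts$genotypes
  n <- nrow(genoCalls(gm))
  ## re-observe 5 individuals through the noisy replicate model twice
  dup <- observeReplicates(ts, cfg, seed = 99)[1:5]
  dupCons <- lapply(dup, function(rc) buildConsensus(rc)$genotype)
  calls <- rbind(genoCalls(gm), do.call(rbind, dupCons))
  ids <- c(individualInfo(gm)$id, paste0("dup_", individualInfo(gm)$id[1:5]))
  gm2 <- makeGenotypeCalls(calls, markerInfo(gm),
    individuals = data.frame(id = ids, species = "B. bonasus",
                             line = "U", sex = "U"))
  mm <- matchIndividuals(gm2, maxMismatch = 3)
  grp <- mm$groups$group
  names(grp) <- mm$groups$id
  for (i in 1:5)
    expect_equal(unname(grp[paste0("dup_", ids[i])]), unname(grp[ids[i]]))
  ## duplicates only pair with their source
  expect_equal(max(table(grp)), 2L)
  ## noisy duplicates sit far below the between-individual minimum
  dupMism <- sapply(1:5, function(i)
    mm$mismatch[ids[i], paste0("dup_", ids[i])])
  between <- mm$mismatch[seq_len(n), seq_len(n)]
  minBetween <- min(between[upper.tri(between)])
  expect_lt(max(dupMism), minBetween)
})

test_that("exclusions and LOD contributions match hand computations", {
  ## opposing homozygotes are exclusions
  gm <- makeGm(rbind(c("AA"), c("BB")), tinyPanel(1))
  po <- assignParents(gm, freqs = freqTable(0.5, tinyPanel(1)),
                      loci = "M01")
  expect_equal(po$exclusions[1], 1L)
  ## offspring AB vs candidate AA at p_B = 0.5: T = 0.5 = P_HW -> LOD 0
  gm2 <- makeGm(rbind(c("AB"), c("AA")), tinyPanel(1))
  po2 <- assignParents(gm2, freqs = freqTable(0.5, tinyPanel(1)),
                       loci = "M01", epsilon = 0)
  expect_equal(po2$lod[1], 0)
  ## transition probabilities sum to one over offspring genotypes for
  ## every parent genotype and frequency (brute-force grid)
  for (p in seq(0.05, 0.95, by = 0.09)) {
    tr <- wisentpanel:::.transitionMatrix(p)
    expect_equal(unname(rowSums(tr)), c(1, 1, 1))
    expect_equal(sum(wisentpanel:::.hwProbs(p)), 1)
  }
})

test_that("with epsilon = 0 the likelihood reduces to pure exclusion", {
  ## enumerate all 3 x 3 genotype pairs at a few frequencies
  panel <- tinyPanel(1)
  gcodes <- c("AA", "AB", "BB")
  for (p in c(0.2, 0.5, 0.8)) {
    for (go in gcodes) for (gc in gcodes) {
      gm <- makeGm(rbind(go, gc), panel)
      po <- assignParents(gm, freqs = freqTable(p, panel),
                          loci = "M01", epsilon = 0)
      opposing <- (go == "AA" && gc == "BB") || (go == "BB" && gc == "AA")
      if (opposing) expect_equal(po$lod[1], -Inf)
      else expect_true(is.finite(po$lod[1]))
    }
  }
})

test_that("an error-free pedigree yields exclusion-free, positive-LOD
          parent-offspring pairs", {
  ts <- simulatePopulation(simConfig(seed = 29, nGenerations = 3,
                                     founderFreqBeta = c(5, 5)))
  po <- assignParents(ts$genotypes)
  rec <- pedRecords(ts$pedigree)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  poKey <- key(po$focal, po$candidate)
  for (col in c("sire", "dam")) {
    links <- rec[!is.na(rec[[col]]), ]
    idx <- match(key(links$id, links[[col]]), poKey)
    expect_false(anyNA(idx))
    expect_true(all(po$exclusions[idx] == 0L))
  }
})

test_that("family network concordance labels the four categories", {
  ## genotyped trio with strongly informative loci
  set.seed(1)
  L <- 30
  panel <- tinyPanel(L)
  sireA <- sample(0:1, L, replace = TRUE)
  sireB <- sample(0:1, L, replace = TRUE)
  damA <- sample(0:1, L, replace = TRUE)
  damB <- sample(0:1, L, replace = TRUE)
  kidA <- ifelse(runif(L) < 0.5, sireA, sireB)
  kidB <- ifelse(runif(L) < 0.5, damA, damB)
  code <- function(a, b) c("AA", "AB", "BB")[a + b + 1L]
  others <- matrix(c("AA", "AB", "BB")[stats::rbinom(5 * L, 2, 0.5) + 1L],
                   5, L)
  calls <- rbind(code(sireA, sireB), code(damA, damB), code(kidA, kidB),
                 others)
  gm <- makeGm(calls, panel, sex = c("M", "F", "M", rep("U", 5)),
               ids = c("sire", "dam", "kid", paste0("x", 1:5)))
  ped <- pedFromTable(id = c("sire", "dam", "kid"),
                      sire = c("", "", "sire"), dam = c("", "", "dam"),
                      sex = c("M", "F", "M"), line = "LL", alive = 1)
  trueFreqs <- freqTable(rep(0.5, L), panel)  # the generating frequencies
  po <- assignParents(gm, freqs = trueFreqs, loci = panel$marker_id)
  net <- buildFamilyNetwork(po, gm, pedigree = ped)
  expect_equal(unname(net$counts["verified"]), 2)
  expect_equal(unname(net$counts["not_testable"]), 0)

  ## withholding the dam's genotype makes her links not testable
  gm2 <- makeGm(calls[-2, , drop = FALSE], panel,
                sex = c("M", "M", rep("U", 5)),
                ids = c("sire", "kid", paste0("x", 1:5)))
  po2 <- assignParents(gm2, freqs = trueFreqs, loci = panel$marker_id)
  net2 <- buildFamilyNetwork(po2, gm2, pedigree = ped)
  links2 <- net2$pedigreeLinks
  expect_identical(links2$category[links2$parent == "dam"],
                   "not_testable")
})
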