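#' Configuration for the synthetic two-breeding-line population
#'
#' The defaults emulate the study system: a 12-founder bottleneck with a
#' nested 7-founder subset seeding breeding line A (the "lowland"-like
#' line), one-directional gene flow from line A into line B, biallelic
#' genotypes dropped through the pedigree, and a replicate observation
#' model with per-event allelic-dropout (ADO), false-allele (FA) and
#' missingness probabilities (ADO 1.6%, FA 0.3%; missingness tuned to an
#' expected call rate of about 92.4% for non-invasive and 98% for
#' invasive samples).
#'
#' @param nFoundersTotal total founder count (default 12).
#' @param nFoundersLineA founders assigned to line A (default 7; must not
#'   exceed `nFoundersTotal`).
#' @param nGenerations discrete non-overlapping generations bred after
#'   the founders (default 6).
#' @param offspringMean Poisson mean number of offspring per breeding
#'   female (default 3, roughly the post-bottleneck growth of a managed
#'   herd).
#' @param migration probability that a line-B female is mated to a
#'   line-A sire (gene flow A -> B only; default 0.05).
#' @param founderFreqBeta length-2 Beta(shape1, shape2) parameters for
#'   per-marker founder allele frequencies (default c(2, 2), favouring
#'   the intermediate frequencies a panel selected for polymorphism has).
#' @param pAdo per-replicate probability that one allele of a
#'   heterozygote drops out (default 0.016).
#' @param pFa per-replicate probability that a homozygote gains a
#'   spurious second allele (default 0.003).
#' @param pMissNoninvasive,pMissInvasive per-call No Call probability by
#'   sample type (defaults 0.076 and 0.02).
#' @param replicatesNoninvasive,replicatesInvasive replicate counts by
#'   sample type (defaults 3 and 1).
#' @param seed integer seed; all generator functions are bit-reproducible
#'   under a fixed seed.
#' @return A list of class `SimConfig`.
#' @export
simConfig <- function(nFoundersTotal = 12L, nFoundersLineA = 7L,
                      nGenerations = 6L, offspringMean = 3,
                      migration = 0.05, founderFreqBeta = c(2, 2),
                      pAdo = 0.016, pFa = 0.003,
                      pMissNoninvasive = 0.076, pMissInvasive = 0.02,
                      replicatesNoninvasive = 3L, replicatesInvasive = 1L,
                      seed = 1L) {
  cfg <- list(nFoundersTotal = as.integer(nFoundersTotal),
              nFoundersLineA = as.integer(nFoundersLineA),
              nGenerations = as.integer(nGenerations),
              offspringMean = offspringMean, migration = migration,
              founderFreqBeta = founderFreqBeta, pAdo = pAdo, pFa = pFa,
              pMissNoninvasive = pMissNoninvasive,
              pMissInvasive = pMissInvasive,
              replicatesNoninvasive = as.integer(replicatesNoninvasive),
              replicatesInvasive = as.integer(replicatesInvasive),
              seed = as.integer(seed))
  probs <- c(cfg$migration, cfg$pAdo, cfg$pFa, cfg$pMissNoninvasive,
             cfg$pMissInvasive)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]")
  if (cfg$nFoundersLineA > cfg$nFoundersTotal)
    stop("nFoundersLineA must not exceed nFoundersTotal")
  if (cfg$nFoundersTotal < 2L) stop("need at least two founders")
  class(cfg) <- "SimConfig"
  cfg
}

#' Simulate a two-line pedigree population with true genotypes
#'
#' Founder genotypes are drawn from Hardy-Weinberg proportions at
#' Beta-sampled per-marker allele frequencies; descendants are produced
#' by Mendelian gene dropping through a randomly mated pedigree with
#' discrete generations.  Gene flow is one-directional: with probability
#' `migration` a line-B female is sired by a line-A male (offspring keep
#' the dam's line label).  Sexes are assigned 1:1.  Cross-species
#' markers are fixed for allele A (monomorphic in the focal species);
#' the sex marker is `XY` in males and `X` in females.
#'
#' @param cfg a [simConfig()] object.
#' @param markers marker definition table (default [defaultPanel()]).
#' @return A list of class `TruthSet` with elements `pedigree`
#'   ([Pedigree-class]), `genotypes` ([GenotypeCalls-class] of true
#'   genotypes), `founderFreqs` (per-marker allele-b frequency) and
#'   `alleles` (the underlying per-individual allele pair matrices, used
#'   by downstream oracles).
#' @export
simulatePopulation <- function(cfg, markers = defaultPanel()) {
  stopifnot(inherits(cfg, "SimConfig"))
  if (nrow(markers) == 0L) stop("zero markers")
  set.seed(cfg$seed)
  L <- nrow(markers)
  auto <- markers$is_autosomal & !markers$cross_species
  sexm <- which(!is.na(markers$sex) & markers$sex)
  freq <- stats::rbeta(L, cfg$founderFreqBeta[1], cfg$founderFreqBeta[2])
  freq[markers$cross_species] <- 0          # monomorphic in focal species
  freq[sexm] <- NA

  nf <- cfg$nFoundersTotal
  id <- sprintf("F%02d", seq_len(nf))
  line <- rep(c("LL", "LC"), c(cfg$nFoundersLineA, nf - cfg$nFoundersLineA))
  ## alternate sexes within each line so both lines can breed
  sex <- unlist(lapply(unique(line), function(l)
    rep_len(c("M", "F"), sum(line == l))))
  rec <- data.frame(id = id, sire = NA_character_, dam = NA_character_,
                    sex = sex, line = line, alive = TRUE, founder = TRUE,
                    stringsAsFactors = FALSE)
  ## allele matrices: 0 = allele_a, 1 = allele_b
  a1 <- matrix(0L, nf, L); a2 <- matrix(0L, nf, L)
  a1[, auto] <- matrix(stats::rbinom(nf * sum(auto), 1L, rep(freq[auto],
                       each = nf)), nf)
  a2[, auto] <- matrix(stats::rbinom(nf * sum(auto), 1L, rep(freq[auto],
                       each = nf)), nf)

  genIdx <- rep(0L, nf)
  prevGen <- seq_len(nf)
  counter <- nf
  if (cfg$nGenerations > 0L) for (g in seq_len(cfg$nGenerations)) {
    newRows <- list(); newA1 <- list(); newA2 <- list()
    for (l in c("LL", "LC")) {
      moms <- prevGen[rec$line[prevGen] == l & rec$sex[prevGen] == "F"]
      dadsOwn <- prevGen[rec$line[prevGen] == l & rec$sex[prevGen] == "M"]
      dadsA <- prevGen[rec$line[prevGen] == "LL" & rec$sex[prevGen] == "M"]
      if (!length(moms) || (!length(dadsOwn) && !length(dadsA))) next
      for (m in moms) {
        useMigrant <- l == "LC" && length(dadsA) &&
          stats::runif(1) < cfg$migration
        pool <- if (useMigrant) dadsA else dadsOwn
        if (!length(pool)) pool <- dadsOwn
        if (!length(pool)) next
        dad <- pool[sample.int(length(pool), 1L)]
        nOff <- stats::rpois(1L, cfg$offspringMean)
        if (nOff == 0L) next
        for (o in seq_len(nOff)) {
          counter <- counter + 1L
          kid <- sprintf("I%04d", counter)
          ksex <- c("M", "F")[counter %% 2L + 1L]   # exact 1:1 sex ratio
          newRows[[length(newRows) + 1L]] <- data.frame(
            id = kid, sire = rec$id[dad], dam = rec$id[m], sex = ksex,
            line = l, alive = TRUE, founder = FALSE,
            stringsAsFactors = FALSE)
          fromSire <- ifelse(stats::runif(L) < 0.5, a1[dad, ], a2[dad, ])
          fromDam <- ifelse(stats::runif(L) < 0.5, a1[m, ], a2[m, ])
          newA1[[length(newA1) + 1L]] <- fromSire
          newA2[[length(newA2) + 1L]] <- fromDam
        }
      }
    }
    if (!length(newRows)) break
    rec <- rbind(rec, do.call(rbind, newRows))
    a1 <- rbind(a1, do.call(rbind, newA1))
    a2 <- rbind(a2, do.call(rbind, newA2))
    genIdx <- c(genIdx, rep(g, length(newRows)))
    prevGen <- which(genIdx == g)
  }

  n <- nrow(rec)
  calls <- matrix(NA_character_, n, L,
                  dimnames = list(rec$id, markers$marker_id))
  code <- c("AA", "AB", "BB")
  dose <- a1 + a2
  calls[, auto | markers$cross_species] <-
    code[dose[, auto | markers$cross_species, drop = FALSE] + 1L]
  if (length(sexm))
    calls[, sexm] <- ifelse(rec$sex == "M", "XY", "X")
  ped <- new("Pedigree", records = rec)
  gm <- makeGenotypeCalls(calls, markers,
    individuals = data.frame(id = rec$id, species = "B. bonasus",
                             line = rec$line, sex = rec$sex,
                             stringsAsFactors = FALSE))
  structure(list(pedigree = ped, genotypes = gm, founderFreqs = freq,
                 generation = genIdx,
                 alleles = list(a1 = a1, a2 = a2), config = cfg),
            class = "TruthSet")
}

#' Observe noisy replicate calls from a truth set
#'
#' Each sample x replicate x marker call is, independently: missing with
#' the sample type's No Call probability; otherwise a true heterozygote
#' loses one allele with probability `pAdo` (yielding a false homozygous
#' call) and a true homozygote gains the marker's other allele with
#' probability `pFa` (yielding a false heterozygous call).  At the sex
#' marker the FA mechanism produces spurious Y calls in females and the
#' ADO mechanism drops the Y in males.  The exact event log (which calls
#' were ADO / FA / missing) is attached so estimator accuracy can be
#' scored against truth.
#'
#' @param truth a `TruthSet` from [simulatePopulation()].
#' @param cfg the [simConfig()] used (defaults to the one in `truth`).
#' @param sampleTypes optional character vector (`"invasive"` /
#'   `"noninvasive"`) per individual; default all non-invasive.
#' @param seed RNG seed (default `cfg$seed + 1`).
#' @return list of [ReplicateCalls-class] with attribute `eventLog`, a
#'   data.frame (sample, replicate, marker, event).
#' @export
observeReplicates <- function(truth, cfg = truth$config,
                              sampleTypes = NULL, seed = cfg$seed + 1L) {
  stopifnot(inherits(truth, "TruthSet"))
  set.seed(seed)
  gm <- truth$genotypes
  mk <- gm@markers
  n <- nrow(gm@calls); L <- ncol(gm@calls)
  if (is.null(sampleTypes)) sampleTypes <- rep("noninvasive", n)
  stopifnot(length(sampleTypes) == n)
  logs <- vector("list", n)
  out <- vector("list", n)
  other <- c(AA = "BB", BB = "AA")
  for (i in seq_len(n)) {
    type <- sampleTypes[i]
    r <- if (type == "invasive") cfg$replicatesInvasive
         else cfg$replicatesNoninvasive
    pm <- if (type == "invasive") cfg$pMissInvasive
          else cfg$pMissNoninvasive
    g <- gm@calls[i, ]
    m <- matrix(rep(g, each = r), r, L,
                dimnames = list(paste0("rep", seq_len(r)),
                                mk$marker_id))
    u <- matrix(stats::runif(r * L), r, L)
    ev <- matrix("", r, L)
    missMask <- u < pm
    u2 <- matrix(stats::runif(r * L), r, L)
    het <- !missMask & !is.na(m) & m == "AB"
    ado <- het & u2 < cfg$pAdo
    if (any(ado))
      m[ado] <- ifelse(stats::runif(sum(ado)) < 0.5, "AA", "BB")
    hom <- !missMask & !is.na(m) & (m == "AA" | m == "BB") & !ado
    fa <- hom & u2 < cfg$pFa
    m[fa] <- "AB"
    maleSex <- !missMask & !is.na(m) & m == "XY"
    adoY <- maleSex & u2 < cfg$pAdo
    m[adoY] <- "X"
    femSex <- !missMask & !is.na(m) & m == "X" & !adoY
    faY <- femSex & u2 < cfg$pFa
    m[faY] <- "XY"
    m[missMask] <- NA_character_
    ev[ado | adoY] <- "ado"
    ev[fa | faY] <- "fa"
    ev[missMask] <- "miss"
    hit <- which(ev != "", arr.ind = TRUE)
    logs[[i]] <- if (nrow(hit)) data.frame(
      sample = gm@individuals$id[i],
      replicate = rownames(m)[hit[, 1]],
      marker = mk$marker_id[hit[, 2]],
      event = ev[hit], stringsAsFactors = FALSE) else NULL
    out[[i]] <- new("ReplicateCalls", sampleId = gm@individuals$id[i],
                    individualId = gm@individuals$id[i],
                    sampleType = type, calls = m)
  }
  eventLog <- do.call(rbind, logs[!vapply(logs, is.null, logical(1))])
  if (is.null(eventLog))
    eventLog <- data.frame(sample = character(), replicate = character(),
                           marker = character(), event = character())
  attr(out, "eventLog") <- eventLog
  out
}

#' Simulate genotypes for non-target taxa
#'
#' Generates Hardy-Weinberg genotypes for non-target evolutionarily
#' significant units (ESUs) with per-ESU allele-frequency offsets from
#' the focal founder frequencies (emulating divergence) and per-ESU
#' baseline call rates (emulating phylogenetic amplification dropout).
#' Cross-species markers, monomorphic in the focal species, are made
#' polymorphic (frequency 0.5) in ESUs with `cross_polymorphic = TRUE`.
#'
#' @param cfg a [simConfig()] (its seed anchors the RNG).
#' @param divergence data.frame with columns `esu`, `n`, `call_rate`,
#'   `shift` (per-marker absolute frequency offset, applied with a
#'   seeded random sign per ESU and marker) and optionally
#'   `cross_polymorphic` (default TRUE).
#' @param founderFreqs per-marker focal allele-b frequencies (e.g. from a
#'   `TruthSet`); drawn fresh from the config's Beta prior if omitted.
#' @param markers marker definition table.
#' @param seed RNG seed (default `cfg$seed + 2`).
#' @return A [GenotypeCalls-class] with `species` set to the ESU labels.
#' @export
makeNontargetGenotypes <- function(cfg, divergence,
                                   founderFreqs = NULL,
                                   markers = defaultPanel(),
                                   seed = cfg$seed + 2L) {
  stopifnot(inherits(cfg, "SimConfig"), is.data.frame(divergence))
  if (any(divergence$call_rate < 0))
    stop("negative call rate in divergence spec")
  if (is.null(divergence$cross_polymorphic))
    divergence$cross_polymorphic <- TRUE
  set.seed(seed)
  L <- nrow(markers)
  if (is.null(founderFreqs)) {
    founderFreqs <- stats::rbeta(L, cfg$founderFreqBeta[1],
                                 cfg$founderFreqBeta[2])
    founderFreqs[markers$cross_species] <- 0
  }
  sexm <- markers$sex
  rows <- list(); ids <- list(); esus <- list()
  for (k in seq_len(nrow(divergence))) {
    d <- divergence[k, ]
    sgn <- sample(c(-1, 1), L, replace = TRUE)
    q <- pmin(pmax(founderFreqs + sgn * d$shift, 0), 1)
    if (d$cross_polymorphic) q[markers$cross_species] <- 0.5
    q[sexm] <- 0           # placeholder; sex-marker calls overwritten below
    n <- d$n
    dose <- matrix(stats::rbinom(n * L, 2L, rep(q, each = n)), n, L)
    calls <- matrix(c("AA", "AB", "BB")[dose + 1L], n, L)
    sx <- sample(c("M", "F"), n, replace = TRUE)
    if (any(sexm)) calls[, sexm] <- ifelse(sx == "M", "XY", "X")
    nc <- matrix(stats::runif(n * L) > d$call_rate, n, L)
    calls[nc] <- NA_character_
    rows[[k]] <- calls
    ids[[k]] <- sprintf("%s_%02d", gsub("[^A-Za-z0-9]+", "", d$esu),
                        seq_len(n))
    esus[[k]] <- data.frame(id = ids[[k]], species = d$esu, line = "U",
                            sex = sx, stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, rows)
  colnames(calls) <- markers$marker_id
  makeGenotypeCalls(calls, markers, individuals = do.call(rbind, esus))
}
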