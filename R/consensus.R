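## Consensus genotype calling from replicated SNP runs, genotyping-error
## decomposition (allelic dropout vs false alleles) and Y-marker sexing.

## Tally-based autosomal consensus rule, applied in fixed precedence:
##   1. all replicates missing                     -> No Call
##   2. het seen and both opposite homozygotes >=2 -> AB
##   3. all three genotype classes present         -> AB
##   4. het count >= max(homozygote counts) (>0)   -> AB
##   5. strict majority                            -> majority genotype
##   6. homozygotes only, exact tie                -> No Call
## The het-forcing rules (2-4) come first; they are the most specific
## statements of the scoring protocol and any other order breaks one of
## them on some tally.
.consensusFromTally <- function(nAA, nAB, nBB) {
  if (nAA + nAB + nBB == 0L) return(NA_character_)
  if (nAB >= 1L && nAA >= 2L && nBB >= 2L) return("AB")
  if (nAA >= 1L && nAB >= 1L && nBB >= 1L) return("AB")
  if (nAB > 0L && nAB >= max(nAA, nBB)) return("AB")
  counts <- c(AA = nAA, AB = nAB, BB = nBB)
  top <- which(counts == max(counts))
  if (length(top) == 1L) return(names(top))
  NA_character_   # opposing homozygotes scored 50:50
}

#' Build the consensus genotype of one sample
#'
#' Applies the replicate majority / heterozygote-forcing rules per
#' autosomal marker and majority voting over Y-bearing calls at the sex
#' marker.  Non-invasive samples with fewer replicates than
#' `minReplicates` are flagged and their consensus withheld (all
#' No Call); invasive samples may be single runs.
#'
#' @param rc a [ReplicateCalls-class].
#' @param markers marker definition table matching the call columns.
#' @param minReplicates minimum replicate count for non-invasive
#'   consensus (default 3).
#' @param minReplicatesInvasive minimum for invasive samples (default 1).
#' @return list of class `ConsensusResult`: `genotype` (named code
#'   vector), `tally` (marker x {nAA, nAB, nBB, nMiss}), `callRate`,
#'   `sex` (the [determineSex()] result), `flagged`.
#' @export
buildConsensus <- function(rc, markers = defaultPanel(),
                           minReplicates = 3L, minReplicatesInvasive = 1L) {
  stopifnot(is(rc, "ReplicateCalls"))
  m <- rc@calls
  mk <- markers[match(colnames(m), markers$marker_id), , drop = FALSE]
  r <- nrow(m)
  need <- if (rc@sampleType == "invasive") minReplicatesInvasive
          else minReplicates
  tally <- cbind(nAA = colSums(m == "AA", na.rm = TRUE),
                 nAB = colSums(m == "AB", na.rm = TRUE),
                 nBB = colSums(m == "BB", na.rm = TRUE),
                 nMiss = colSums(is.na(m)))
  rownames(tally) <- colnames(m)
  flagged <- r < need
  sexCall <- determineSex(rc, markers = markers)
  geno <- rep(NA_character_, ncol(m))
  names(geno) <- colnames(m)
  if (!flagged) {
    isAuto <- mk$is_autosomal
    geno[isAuto] <- vapply(which(isAuto), function(j)
      .consensusFromTally(tally[j, 1L], tally[j, 2L], tally[j, 3L]),
      character(1))
    sexIdx <- which(!is.na(mk$sex) & mk$sex)
    if (length(sexIdx))
      geno[sexIdx] <- switch(sexCall$sex, male = "XY", female = "X",
                             NA_character_)
  }
  structure(list(sampleId = rc@sampleId, individualId = rc@individualId,
                 genotype = geno, tally = tally,
                 callRate = mean(!is.na(geno)), replicates = r,
                 sex = sexCall, flagged = flagged),
            class = "ConsensusResult")
}

#' Consensus genotypes for a set of samples
#'
#' Runs [buildConsensus()] over a list of samples and assembles one
#' [GenotypeCalls-class] row per individual (samples without an
#' individual assignment keep their sample id).  Sexes come from the
#' Y-marker caller; line/species labels can be supplied.
#'
#' @inheritParams buildConsensus
#' @param rcs list of [ReplicateCalls-class].
#' @param lines optional named character vector of breeding-line labels
#'   (names = individual ids).
#' @param species species label for all samples (default `"B. bonasus"`).
#' @return A [GenotypeCalls-class] whose `provenance` holds the
#'   per-sample replicate counts, call rates and flags.
#' @export
consensusGenotypes <- function(rcs, markers = defaultPanel(),
                               minReplicates = 3L,
                               minReplicatesInvasive = 1L,
                               lines = NULL, species = "B. bonasus") {
  cons <- lapply(rcs, buildConsensus, markers = markers,
                 minReplicates = minReplicates,
                 minReplicatesInvasive = minReplicatesInvasive)
  ids <- vapply(cons, function(cc)
    if (!is.na(cc$individualId)) cc$individualId else cc$sampleId,
    character(1))
  if (anyDuplicated(ids))
    stop("multiple samples map to one individual; merge or rename first: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  calls <- do.call(rbind, lapply(cons, `[[`, "genotype"))
  rownames(calls) <- ids
  sexes <- vapply(cons, function(cc)
    switch(cc$sex$sex, male = "M", female = "F", "U"), character(1))
  ind <- data.frame(id = ids, species = species,
                    line = if (is.null(lines)) "U"
                           else unname(lines[ids]),
                    sex = sexes, stringsAsFactors = FALSE)
  ind$line[is.na(ind$line)] <- "U"
  makeGenotypeCalls(calls, markers[match(colnames(calls),
                                         markers$marker_id), ],
                    individuals = ind,
                    provenance = list(
                      sampleId = vapply(cons, `[[`, character(1), "sampleId"),
                      replicates = vapply(cons, `[[`, integer(1),
                                          "replicates"),
                      callRate = vapply(cons, `[[`, numeric(1), "callRate"),
                      flagged = vapply(cons, `[[`, logical(1), "flagged"),
                      consensus = cons))
}

#' Decompose genotyping error into allelic dropout and false alleles
#'
#' Compares every replicate call against the sample's consensus genotype
#' (both non-missing).  An allelic dropout (ADO) is a homozygous
#' replicate at a heterozygous consensus; a false allele (FA) is a
#' replicate carrying an allele absent from the consensus.  With
#' biallelic markers the two are mutually exclusive and genotyping-error
#' (GE) events = ADO + FA events.  Rates are reported per locus (across
#' samples), per sample (across loci) and overall, both marginally
#' (events / all comparisons, so GE rate = ADO rate + FA rate) and
#' conditionally (ADO events / heterozygous-consensus comparisons, FA
#' events / homozygous-consensus comparisons, matching the per-event
#' probabilities of the error model).  Loci with GE rate above
#' `geThreshold` are flagged for exclusion.
#'
#' @param rcs list of [ReplicateCalls-class].
#' @param consensuses matching list of `ConsensusResult` (computed if
#'   omitted).
#' @param markers marker definition table.
#' @param geThreshold per-locus GE-rate exclusion threshold (default
#'   0.05).
#' @return list of class `ErrorReport`: `perLocus`, `perSample` data
#'   frames, `overall` named vector, `events` (the classified event
#'   table).
#' @export
estimateErrorRates <- function(rcs, consensuses = NULL,
                               markers = defaultPanel(),
                               geThreshold = 0.05) {
  if (is.null(consensuses))
    consensuses <- lapply(rcs, buildConsensus, markers = markers)
  stopifnot(length(rcs) == length(consensuses))
  evs <- list()
  locTot <- locHet <- locHom <- locAdo <- locFa <-
    stats::setNames(rep(0, nrow(markers)), markers$marker_id)
  sampRows <- list()
  for (i in seq_along(rcs)) {
    rc <- rcs[[i]]; cc <- consensuses[[i]]
    if (cc$flagged || all(is.na(cc$genotype))) {
      warning("consensus missing for sample ", rc@sampleId, "; skipped")
      next
    }
    m <- rc@calls
    cons <- cc$genotype[colnames(m)]
    consM <- matrix(rep(cons, each = nrow(m)), nrow(m))
    ok <- !is.na(m) & !is.na(consM)
    hetC <- ok & consM == "AB"
    homC <- ok & (consM == "AA" | consM == "BB")
    sexC <- ok & (consM == "X" | consM == "XY")
    ado <- (hetC & (m == "AA" | m == "BB")) |
           (ok & consM == "XY" & m == "X")
    fa <- (homC & m != consM) |            # replicate shows a novel allele
          (ok & consM == "X" & m == "XY")
    idx <- match(colnames(m), names(locTot))
    locTot[idx] <- locTot[idx] + colSums(ok)
    locHet[idx] <- locHet[idx] + colSums(hetC | (ok & consM == "XY"))
    locHom[idx] <- locHom[idx] + colSums(homC | (ok & consM == "X"))
    locAdo[idx] <- locAdo[idx] + colSums(ado)
    locFa[idx] <- locFa[idx] + colSums(fa)
    sampRows[[length(sampRows) + 1L]] <- data.frame(
      sample = rc@sampleId, comparisons = sum(ok),
      nAdo = sum(ado), nFa = sum(fa),
      adoRate = sum(ado) / max(sum(ok), 1L),
      faRate = sum(fa) / max(sum(ok), 1L),
      geRate = (sum(ado) + sum(fa)) / max(sum(ok), 1L),
      stringsAsFactors = FALSE)
    hit <- which(ado | fa, arr.ind = TRUE)
    if (nrow(hit))
      evs[[length(evs) + 1L]] <- data.frame(
        sample = rc@sampleId,
        replicate = rownames(m)[hit[, 1]],
        marker = colnames(m)[hit[, 2]],
        event = ifelse(ado[hit], "ado", "fa"),
        stringsAsFactors = FALSE)
  }
  perLocus <- data.frame(
    marker = names(locTot), comparisons = locTot,
    hetComparisons = locHet, homComparisons = locHom,
    nAdo = locAdo, nFa = locFa,
    adoRate = ifelse(locTot > 0, locAdo / locTot, NA_real_),
    faRate = ifelse(locTot > 0, locFa / locTot, NA_real_),
    geRate = ifelse(locTot > 0, (locAdo + locFa) / locTot, NA_real_),
    adoRateHet = ifelse(locHet > 0, locAdo / locHet, NA_real_),
    faRateHom = ifelse(locHom > 0, locFa / locHom, NA_real_),
    row.names = NULL, stringsAsFactors = FALSE)
  perLocus$flagged <- !is.na(perLocus$geRate) &
    perLocus$geRate > geThreshold
  tot <- sum(locTot); hets <- sum(locHet); homs <- sum(locHom)
  overall <- c(comparisons = tot,
               adoRate = sum(locAdo) / max(tot, 1),
               faRate = sum(locFa) / max(tot, 1),
               geRate = (sum(locAdo) + sum(locFa)) / max(tot, 1),
               adoRateHet = if (hets > 0) sum(locAdo) / hets else NA_real_,
               faRateHom = if (homs > 0) sum(locFa) / homs else NA_real_)
  events <- if (length(evs)) do.call(rbind, evs)
            else data.frame(sample = character(), replicate = character(),
                            marker = character(), event = character())
  structure(list(perLocus = perLocus,
                 perSample = do.call(rbind, sampRows),
                 overall = overall, events = events,
                 geThreshold = geThreshold),
            class = "ErrorReport")
}

#' Determine sex from the Y-associated marker
#'
#' Majority voting over called replicates of the gonosomal marker:
#' male if more than half of the called replicates carry the Y cluster,
#' female if fewer than half, undetermined on an exact tie or when no
#' replicate is called.
#'
#' @param rc a [ReplicateCalls-class].
#' @param markers marker definition table (the marker with `sex = TRUE`
#'   is used).
#' @return list of class `SexCall`: `sex` (`"male"`, `"female"`,
#'   `"undetermined"`), `yFraction`, `nCalled`, `reason`.
#' @export
determineSex <- function(rc, markers = defaultPanel()) {
  sexIds <- markers$marker_id[!is.na(markers$sex) & markers$sex]
  sexIds <- intersect(sexIds, colnames(rc@calls))
  if (!length(sexIds))
    return(structure(list(sex = "undetermined", yFraction = NA_real_,
                          nCalled = 0L, reason = "no sex marker"),
                     class = "SexCall"))
  v <- rc@calls[, sexIds[1L]]
  called <- v[!is.na(v)]
  if (!length(called))
    return(structure(list(sex = "undetermined", yFraction = NA_real_,
                          nCalled = 0L, reason = "no data"),
                     class = "SexCall"))
  yf <- mean(called == "XY")
  sex <- if (yf > 0.5) "male" else if (yf < 0.5) "female" else
    "undetermined"
  structure(list(sex = sex, yFraction = yf, nCalled = length(called),
                 reason = if (sex == "undetermined") "tie" else "ok"),
            class = "SexCall")
}
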