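## Molecular genetic diversity (heterozygosities, F-statistics in two
## averaging modes, rarefied allelic richness) and pedigree analytics
## (tabular kinship, gene-drop gene diversity, founder contributions,
## pedigree F-statistics).

#' Molecular diversity table
#'
#' Per breeding line and overall: observed heterozygosity H_O, Nei
#' unbiased within-group expected heterozygosity (h-hat =
#' 2n/(2n-1) (1 - sum p^2)), total heterozygosity H_T from unweighted
#' mean allele frequencies, rarefied allelic richness, and the
#' F-statistics F_IS = 1 - H_O/H_S, F_ST = (H_T - H_S)/H_T,
#' F_IT = 1 - H_O/H_T computed in two averaging modes: the arithmetic
#' mean of per-locus F values, and F from the locus-averaged H's (in the
#' latter mode (1-F_IT) = (1-F_IS)(1-F_ST) holds exactly).  Standard
#' errors are jackknife-over-loci.
#'
#' @param gm a [GenotypeCalls-class] with line labels.
#' @param loci marker ids (default: parentage/diversity subset).
#' @param groups line labels to use (default: the labeled lines
#'   present).
#' @param neiChesser apply the Nei & Chesser small-sample correction to
#'   H_T (default FALSE, matching the plain definitions).
#' @return list of class `DiversityTable`: `groupStats` (per group and
#'   pooled: n, loci, H_O, uH_E, allelic richness), `fstats` (both
#'   modes with jackknife SEs), `perLocus`.
#' @export
molecularDiversity <- function(gm, loci = NULL, groups = NULL,
                               neiChesser = FALSE) {
  loci <- .resolveLoci(gm, loci, "parentage_diversity")
  if (is.null(groups))
    groups <- sort(setdiff(unique(gm@individuals$line), "U"))
  if (length(groups) < 2L)
    stop("need at least two labeled groups for F-statistics")
  for (gname in groups)
    if (sum(gm@individuals$line == gname) < 2L)
      stop("group ", gname, " has fewer than 2 individuals")
  g <- .genoIndex(gm@calls[, loci, drop = FALSE])
  L <- length(loci)
  nG <- length(groups)
  ## per locus per group: n, pB, H_O, unbiased h
  arr <- array(NA_real_, c(L, nG, 4),
               dimnames = list(loci, groups, c("n", "pB", "hO", "uh")))
  for (k in seq_len(nG)) {
    gk <- g[gm@individuals$line == groups[k], , drop = FALSE]
    n <- colSums(!is.na(gk))
    het <- colSums(gk == 2, na.rm = TRUE)
    pB <- ifelse(n > 0, (het + 2 * colSums(gk == 3, na.rm = TRUE)) /
                   (2 * n), NA_real_)
    hexp <- 2 * pB * (1 - pB)
    arr[, k, "n"] <- n
    arr[, k, "pB"] <- pB
    arr[, k, "hO"] <- ifelse(n > 0, het / n, NA_real_)
    arr[, k, "uh"] <- ifelse(n > 1, 2 * n / (2 * n - 1) * hexp, NA_real_)
  }
  hO <- rowMeans(arr[, , "hO"])                 # unweighted group means
  hS <- rowMeans(arr[, , "uh"])
  pbar <- rowMeans(arr[, , "pB"])
  hT <- 2 * pbar * (1 - pbar)
  if (neiChesser) {
    nharm <- nG / rowSums(1 / arr[, , "n"])
    hT <- hT + hS / (2 * nharm * nG)
  }
  usable <- !is.na(hS) & !is.na(hT) & hT > 0
  perLocus <- data.frame(
    marker = loci, hO = hO, hS = hS, hT = hT,
    fis = ifelse(usable & hS > 0, 1 - hO / hS, NA_real_),
    fst = ifelse(usable, (hT - hS) / hT, NA_real_),
    fit = ifelse(usable, 1 - hO / hT, NA_real_),
    usable = usable, row.names = NULL, stringsAsFactors = FALSE)
  fFrom <- function(idx) {
    ## both averaging modes on the locus subset idx
    u <- idx[perLocus$usable[idx]]
    mH <- c(hO = mean(hO[u]), hS = mean(hS[u]), hT = mean(hT[u]))
    c(fis_perlocus = mean(perLocus$fis[u], na.rm = TRUE),
      fst_perlocus = mean(perLocus$fst[u], na.rm = TRUE),
      fit_perlocus = mean(perLocus$fit[u], na.rm = TRUE),
      fis_meanH = 1 - mH["hO"] / mH["hS"],
      fst_meanH = (mH["hT"] - mH["hS"]) / mH["hT"],
      fit_meanH = 1 - mH["hO"] / mH["hT"])
  }
  est <- fFrom(seq_len(L))
  ## jackknife over loci
  uIdx <- which(perLocus$usable)
  if (length(uIdx) > 1L) {
    jk <- vapply(uIdx, function(drop) fFrom(setdiff(seq_len(L), drop)),
                 est)
    m <- length(uIdx)
    se <- sqrt((m - 1) / m * rowSums((jk - rowMeans(jk))^2))
  } else se <- rep(NA_real_, length(est))
  fstats <- data.frame(
    statistic = c("F_IS", "F_ST", "F_IT"),
    perLocusMean = unname(est[1:3]), perLocusSE = unname(se[1:3]),
    fromMeanH = unname(est[4:6]), fromMeanHSE = unname(se[4:6]),
    stringsAsFactors = FALSE)
  ## allelic richness rarefied to the smallest group's gene copies
  gCopies <- 2 * arr[, , "n"]
  gMin <- apply(gCopies, 1, min)
  arOne <- function(pB, N2, gg) {
    ## N2 gene copies, allele-b count nb
    nb <- round(pB * N2)
    counts <- c(N2 - nb, nb)
    sum(vapply(counts, function(Ni)
      1 - exp(lchoose(N2 - Ni, gg) - lchoose(N2, gg)), numeric(1)))
  }
  ar <- matrix(NA_real_, L, nG, dimnames = list(loci, groups))
  for (k in seq_len(nG)) for (l in seq_len(L)) {
    if (!is.na(arr[l, k, "pB"]) && gMin[l] >= 2)
      ar[l, k] <- arOne(arr[l, k, "pB"], gCopies[l, k], gMin[l])
  }
  pooled <- {
    nAll <- colSums(!is.na(g))
    het <- colSums(g == 2, na.rm = TRUE)
    pB <- ifelse(nAll > 0, (het + 2 * colSums(g == 3, na.rm = TRUE)) /
                   (2 * nAll), NA_real_)
    data.frame(group = "total", n = nrow(g), lociUsed = sum(nAll > 0),
               hO = mean(ifelse(nAll > 0, het / nAll, NA_real_),
                         na.rm = TRUE),
               uhE = mean(ifelse(nAll > 1,
                                 2 * nAll / (2 * nAll - 1) *
                                   2 * pB * (1 - pB), NA_real_),
                          na.rm = TRUE),
               allelicRichness = NA_real_, stringsAsFactors = FALSE)
  }
  groupStats <- rbind(pooled, do.call(rbind, lapply(seq_len(nG),
    function(k) data.frame(
      group = groups[k],
      n = sum(gm@individuals$line == groups[k]),
      lociUsed = sum(!is.na(arr[, k, "pB"])),
      hO = mean(arr[, k, "hO"], na.rm = TRUE),
      uhE = mean(arr[, k, "uh"], na.rm = TRUE),
      allelicRichness = mean(ar[, k], na.rm = TRUE),
      stringsAsFactors = FALSE))))
  structure(list(groupStats = groupStats, fstats = fstats,
                 perLocus = perLocus, allelicRichness = ar,
                 rarefactionG = gMin),
            class = "DiversityTable")
}

#' Pedigree kinship matrix (tabular method)
#'
#' Coancestries f(i, j) by the tabular recursion in topological order:
#' f(i, j) = 1/2 [f(sire_i, j) + f(dam_i, j)] and
#' f(i, i) = 1/2 (1 + f(sire_i, dam_i)); an unknown parent contributes
#' as a unique non-inbred founder.  Individual inbreeding F_i is the
#' coancestry of the parents.
#'
#' @param ped a [Pedigree-class].
#' @return list of class `KinshipMatrix`: `kinship` (named symmetric
#'   matrix), `inbreeding` (named vector).
#' @export
pedigreeKinship <- function(ped) {
  rec <- ped@records
  n <- nrow(rec)
  ## topological order (parents before offspring)
  ord <- integer(0)
  placed <- logical(n)
  sireIx <- match(rec$sire, rec$id)
  damIx <- match(rec$dam, rec$id)
  remaining <- seq_len(n)
  while (length(remaining)) {
    ready <- remaining[
      (is.na(sireIx[remaining]) | placed[sireIx[remaining]]) &
      (is.na(damIx[remaining]) | placed[damIx[remaining]])]
    if (!length(ready)) stop("pedigree is cyclic")   # guarded upstream
    ord <- c(ord, ready)
    placed[ready] <- TRUE
    remaining <- setdiff(remaining, ready)
  }
  K <- matrix(0, n, n, dimnames = list(rec$id, rec$id))
  for (i in ord) {
    s <- sireIx[i]; d <- damIx[i]
    prev <- ord[seq_len(match(i, ord) - 1L)]
    if (length(prev)) {
      row <- 0.5 * ((if (!is.na(s)) K[s, prev] else 0) +
                    (if (!is.na(d)) K[d, prev] else 0))
      K[i, prev] <- row
      K[prev, i] <- row
    }
    fPar <- if (!is.na(s) && !is.na(d)) K[s, d] else 0
    K[i, i] <- 0.5 * (1 + fPar)
  }
  structure(list(kinship = K,
                 inbreeding = stats::setNames(2 * diag(K) - 1, rec$id)),
            class = "KinshipMatrix")
}

#' Pedigree gene diversity: kinship closed form and gene drop
#'
#' GD from the kinship matrix is 1 minus the mean coancestry over all
#' ordered pairs of living individuals (self-pairs included — the
#' convention under which the kinship and gene-drop estimators agree in
#' expectation).  The gene-drop estimate labels each founder's two
#' alleles uniquely, transmits them through the pedigree by Mendelian
#' sampling, and averages 1 - sum q_a^2 over iterations; an unknown
#' parent contributes its own unique allele pair.  Founder contributions
#' are the expected share of the living gene pool descending from each
#' founder.
#'
#' @param ped a [Pedigree-class].
#' @param living ids forming the living gene pool (default: records with
#'   `alive = TRUE`).
#' @param iterations gene-drop iterations (default 1000).
#' @param seed RNG seed.
#' @param kin optional precomputed [pedigreeKinship()] result.
#' @return list of class `GeneDiversity`: `gdKinship`, `gdGeneDrop`,
#'   `gdGeneDropSE` (Monte-Carlo SE), `founderContributions`.
#' @export
geneDiversity <- function(ped, living = NULL, iterations = 1000L,
                          seed = 1L, kin = NULL) {
  rec <- ped@records
  if (is.null(living)) living <- rec$id[rec$alive]
  bad <- setdiff(living, rec$id)
  if (length(bad))
    stop("living individual(s) absent from pedigree: ",
         paste(bad, collapse = ", "))
  stopifnot(iterations >= 1L)
  if (is.null(kin)) kin <- pedigreeKinship(ped)
  K <- kin$kinship[living, living, drop = FALSE]
  gdKin <- 1 - mean(K)
  ## gene drop
  set.seed(seed)
  n <- nrow(rec)
  sireIx <- match(rec$sire, rec$id)
  damIx <- match(rec$dam, rec$id)
  ord <- order(.pedDepth(rec))
  a1 <- matrix(0L, n, iterations)
  a2 <- matrix(0L, n, iterations)
  nextAllele <- 0L
  for (i in ord) {
    s <- sireIx[i]; d <- damIx[i]
    if (is.na(s)) {
      a1[i, ] <- nextAllele + 1L
      nextAllele <- nextAllele + 1L
    } else {
      pick <- stats::runif(iterations) < 0.5
      a1[i, ] <- ifelse(pick, a1[s, ], a2[s, ])
    }
    if (is.na(d)) {
      a2[i, ] <- nextAllele + 1L
      nextAllele <- nextAllele + 1L
    } else {
      pick <- stats::runif(iterations) < 0.5
      a2[i, ] <- ifelse(pick, a1[d, ], a2[d, ])
    }
  }
  liv <- match(living, rec$id)
  gdIter <- vapply(seq_len(iterations), function(it) {
    al <- c(a1[liv, it], a2[liv, it])
    q <- tabulate(al, nextAllele) / length(al)
    1 - sum(q^2)
  }, numeric(1))
  ## founder contributions (expected share of the living gene pool)
  contrib <- matrix(0, n, sum(rec$founder),
                    dimnames = list(rec$id, rec$id[rec$founder]))
  fIdx <- which(rec$founder)
  for (j in seq_along(fIdx)) contrib[fIdx[j], j] <- 1
  for (i in ord) {
    s <- sireIx[i]; d <- damIx[i]
    if (is.na(s) && is.na(d)) next
    contrib[i, ] <- 0.5 * ((if (!is.na(s)) contrib[s, ] else 0) +
                           (if (!is.na(d)) contrib[d, ] else 0))
  }
  fc <- colMeans(contrib[liv, , drop = FALSE])
  structure(list(gdKinship = gdKin, gdGeneDrop = mean(gdIter),
                 gdGeneDropSE = stats::sd(gdIter) / sqrt(iterations),
                 gdIterations = gdIter,
                 founderContributions =
                   data.frame(founder = names(fc), contribution = fc,
                              row.names = NULL, stringsAsFactors = FALSE),
                 living = living), class = "GeneDiversity")
}

## generation depth (founders 0), used to get a topological order fast
.pedDepth <- function(rec) {
  n <- nrow(rec)
  sireIx <- match(rec$sire, rec$id)
  damIx <- match(rec$dam, rec$id)
  depth <- rep(NA_integer_, n)
  depth[is.na(sireIx) & is.na(damIx)] <- 0L
  while (anyNA(depth)) {
    todo <- which(is.na(depth))
    prog <- FALSE
    for (i in todo) {
      ds <- if (is.na(sireIx[i])) -1L else depth[sireIx[i]]
      dd <- if (is.na(damIx[i])) -1L else depth[damIx[i]]
      if (!anyNA(c(ds, dd))) {
        depth[i] <- max(ds, dd) + 1L
        prog <- TRUE
      }
    }
    if (!prog) stop("pedigree is cyclic")
  }
  depth
}

#' Pedigree-based F-statistics
#'
#' From the kinship matrix over living individuals grouped by breeding
#' line: with F-tilde the mean inbreeding, f-tilde the unweighted mean
#' of within-group mean pairwise coancestries (self-pairs excluded) and
#' f-bar the overall mean pairwise coancestry,
#' F_IS = (F-tilde - f-tilde) / (1 - f-tilde),
#' F_ST = (f-tilde - f-bar) / (1 - f-bar) and
#' (1 - F_IT) = (1 - F_IS)(1 - F_ST).
#'
#' @param ped a [Pedigree-class].
#' @param living ids of the living gene pool (default `alive` records).
#' @param kin optional precomputed [pedigreeKinship()].
#' @return named vector: `fis`, `fst`, `fit`, `meanInbreeding`,
#'   `meanWithinCoancestry`, `meanCoancestry`, plus attribute `groups`.
#' @export
pedigreeFStats <- function(ped, living = NULL, kin = NULL) {
  rec <- ped@records
  if (is.null(living)) living <- rec$id[rec$alive]
  grp <- rec$line[match(living, rec$id)]
  groups <- sort(setdiff(unique(grp), "U"))
  if (length(groups) < 2L)
    stop("F_ST undefined: need living individuals in >= 2 lines")
  if (is.null(kin)) kin <- pedigreeKinship(ped)
  K <- kin$kinship[living, living, drop = FALSE]
  Fbar <- mean(kin$inbreeding[living])
  offMean <- function(M) {
    if (nrow(M) < 2L) return(NA_real_)
    (sum(M) - sum(diag(M))) / (nrow(M) * (nrow(M) - 1))
  }
  fWithin <- mean(vapply(groups, function(gname)
    offMean(K[grp == gname, grp == gname, drop = FALSE]), numeric(1)),
    na.rm = TRUE)
  fAll <- offMean(K)
  fis <- (Fbar - fWithin) / (1 - fWithin)
  fst <- (fWithin - fAll) / (1 - fAll)
  out <- c(fis = fis, fst = fst, fit = 1 - (1 - fis) * (1 - fst),
           meanInbreeding = Fbar, meanWithinCoancestry = fWithin,
           meanCoancestry = fAll)
  attr(out, "groups") <- groups
  out
}
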