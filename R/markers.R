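## Marker-subset selection: Hardy-Weinberg testing, composite LD (R^2),
## per-locus FST ranking, private alleles and the relative-filtered
## selection workflow.

#' Drop offspring of fully genotyped pairs
#'
#' Removes, once, every individual whose sire and dam are both present
#' in the genotype set — the standard relatedness filter applied before
#' allele-frequency based marker ranking, which keeps the maximum allele
#' variation while removing first-degree redundancy.
#'
#' @param gm a [GenotypeCalls-class].
#' @param pedigree a [Pedigree-class].
#' @return The filtered [GenotypeCalls-class].
#' @export
dropFirstDegreeOffspring <- function(gm, pedigree) {
  rec <- pedigree@records
  ids <- gm@individuals$id
  rec <- rec[match(ids, rec$id), , drop = FALSE]
  drop <- !is.na(rec$sire) & !is.na(rec$dam) &
    rec$sire %in% ids & rec$dam %in% ids
  drop[is.na(drop)] <- FALSE
  keep <- which(!drop)
  makeGenotypeCalls(gm@calls[keep, , drop = FALSE], gm@markers,
                    individuals = gm@individuals[keep, , drop = FALSE])
}

#' Hardy-Weinberg equilibrium test per locus
#'
#' Chi-square goodness-of-fit (1 df) of observed genotype counts against
#' expectations from the observed allele frequencies, with an exact
#' mid-p alternative (Levene-Haldane conditional distribution of the
#' heterozygote count).
#'
#' @param gm a [GenotypeCalls-class].
#' @param loci marker ids (default: all autosomal markers).
#' @param group optional line label restriction.
#' @param minCalled minimum called individuals per locus (default 5);
#'   loci under it are returned with NA statistics.
#' @param method `"chisq"` (default) or `"exact-midp"`.
#' @return data.frame: `marker`, `nAA`, `nAB`, `nBB`, `pB`, `chisq`,
#'   `p`, `monomorphic`.
#' @export
hweTest <- function(gm, loci = NULL, group = NULL, minCalled = 5L,
                    method = c("chisq", "exact-midp")) {
  method <- match.arg(method)
  loci <- .resolveLoci(gm, loci)
  keep <- rep(TRUE, nrow(gm@calls))
  if (!is.null(group)) keep <- gm@individuals$line == group
  g <- .genoIndex(gm@calls[keep, loci, drop = FALSE])
  out <- data.frame(marker = loci, nAA = NA_integer_, nAB = NA_integer_,
                    nBB = NA_integer_, pB = NA_real_, chisq = NA_real_,
                    p = NA_real_, monomorphic = NA,
                    stringsAsFactors = FALSE)
  for (j in seq_along(loci)) {
    cnt <- tabulate(g[, j], 3L)
    n <- sum(cnt)
    out[j, c("nAA", "nAB", "nBB")] <- cnt
    if (n == 0L) next
    pB <- (cnt[2] + 2 * cnt[3]) / (2 * n)
    out$pB[j] <- pB
    out$monomorphic[j] <- pB == 0 || pB == 1
    if (n < minCalled || out$monomorphic[j]) next
    if (method == "chisq") {
      expd <- n * c((1 - pB)^2, 2 * pB * (1 - pB), pB^2)
      out$chisq[j] <- sum((cnt - expd)^2 / expd)
      out$p[j] <- stats::pchisq(out$chisq[j], df = 1, lower.tail = FALSE)
    } else {
      out$p[j] <- .hweExactMidP(cnt[1], cnt[2], cnt[3])
    }
  }
  out
}

## Exact HWE mid-p: conditional distribution of the heterozygote count
## given allele counts (Levene-Haldane), two-sided by probability mass.
.hweExactMidP <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  nB <- nAB + 2 * nBB
  nA <- 2 * n - nB
  rare <- min(nA, nB)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    homR <- (rare - h) / 2
    homC <- n - h - homR
    ## constant-in-h terms are dropped; they cancel in the normalization
    -lfactorial(homR) - lfactorial(h) - lfactorial(homC) + h * log(2)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[hets == nAB]
  min(1, sum(pr[pr < obs]) + 0.5 * sum(pr[pr == obs]))
}

#' Composite linkage disequilibrium (R^2) matrix
#'
#' Squared Pearson correlation of allele-dosage vectors (0/1/2) across
#' individuals called at both loci (composite LD; no phasing).  Pairs
#' with fewer than `minShared` shared complete individuals or with a
#' zero-variance dosage at either locus are returned as NA and flagged.
#'
#' @param gm a [GenotypeCalls-class].
#' @param loci marker ids (default: all autosomal markers).
#' @param minShared minimum shared complete individuals (default 20).
#' @return list of class `LdMatrix`: `r2`, `n` (shared counts),
#'   `undefined` (data.frame of flagged pairs).
#' @export
ldR2 <- function(gm, loci = NULL, minShared = 20L) {
  loci <- .resolveLoci(gm, loci)
  d <- .dosage(gm@calls[, loci, drop = FALSE])
  nMat <- crossprod(!is.na(d) * 1)
  suppressWarnings(r <- stats::cor(d, use = "pairwise.complete.obs"))
  r2 <- r^2
  vzero <- apply(d, 2, function(x) stats::var(x, na.rm = TRUE)) %in%
    c(0, NA)
  r2[vzero, ] <- NA; r2[, vzero] <- NA
  r2[nMat < minShared] <- NA
  diag(r2) <- ifelse(vzero, NA, 1)
  und <- which(is.na(r2) & upper.tri(r2), arr.ind = TRUE)
  structure(list(r2 = r2, n = nMat,
                 undefined = data.frame(
                   locus1 = loci[und[, 1]], locus2 = loci[und[, 2]],
                   stringsAsFactors = FALSE),
                 minShared = minShared), class = "LdMatrix")
}

## Per-locus Nei-style FST from two groups' allele frequencies
## (unweighted group means): (H_T - H_S) / H_T.
.neiFstLocus <- function(p1, p2) {
  hS <- mean(c(2 * p1 * (1 - p1), 2 * p2 * (1 - p2)))
  pbar <- mean(c(p1, p2))
  hT <- 2 * pbar * (1 - pbar)
  if (hT == 0) return(NA_real_)
  (hT - hS) / hT
}

## Weir & Cockerham (1984) theta per locus for two groups, from genotype
## counts; offered as an alternative estimator for the line ranking.
.wcThetaLocus <- function(cnt1, cnt2) {
  n <- c(sum(cnt1), sum(cnt2))
  if (any(n < 2)) return(NA_real_)
  p <- c((cnt1[2] + 2 * cnt1[3]) / (2 * n[1]),
         (cnt2[2] + 2 * cnt2[3]) / (2 * n[2]))
  h <- c(cnt1[2] / n[1], cnt2[2] / n[2])
  r <- 2
  nbar <- mean(n)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  if (a + b + cc == 0) return(NA_real_)
  a / (a + b + cc)
}

#' Rank markers and select the analysis subsets
#'
#' Reproduces the subset-selection workflow: on a relatedness-filtered
#' individual set (offspring of fully genotyped pairs removed), (a) the
#' diversity subset keeps polymorphic autosomal loci passing the HWE
#' test at `hweAlpha` (Bonferroni-corrected across loci) after greedy LD
#' pruning (of each pair with R^2 > `ldMax` the locus with the higher
#' mean R^2 is removed); (b) the line-discrimination subset keeps loci
#' with per-locus Nei FST between the two breeding lines at or above
#' `fstMin`; (c) alleles with nonzero count in exactly one line are
#' reported as private.
#'
#' @param gm a [GenotypeCalls-class] with line labels on >= 2 lines.
#' @param pedigree optional [Pedigree-class] used for the relatedness
#'   filter.
#' @param fstMin line-subset FST threshold (default 0.075).
#' @param hweAlpha HWE familywise alpha (default 0.05, Bonferroni).
#' @param ldMax LD pruning threshold on R^2 (default 0.8).
#' @param loci candidate marker ids (default: all autosomal,
#'   non-cross-species markers).
#' @param fstMethod `"nei"` (default) or `"wc"` (Weir-Cockerham theta).
#' @return list of class `MarkerSelection`: `stats` (per-locus table),
#'   `diversitySubset`, `lineSubset`, `privateAlleles`, `ld`,
#'   `individualsUsed`.
#' @export
rankAndSelect <- function(gm, pedigree = NULL, fstMin = 0.075,
                          hweAlpha = 0.05, ldMax = 0.8, loci = NULL,
                          fstMethod = c("nei", "wc")) {
  fstMethod <- match.arg(fstMethod)
  mk <- gm@markers
  if (is.null(loci))
    loci <- mk$marker_id[mk$is_autosomal & !mk$cross_species]
  gmF <- if (!is.null(pedigree)) dropFirstDegreeOffspring(gm, pedigree)
         else gm
  lines <- sort(setdiff(unique(gmF@individuals$line), "U"))
  if (length(lines) != 2L)
    stop("exactly two labeled breeding lines required, found: ",
         paste(lines, collapse = ", "))
  for (l in lines)
    if (sum(gmF@individuals$line == l) < 2L)
      stop("group ", l, " has fewer than 2 individuals")
  g <- .genoIndex(gmF@calls[, loci, drop = FALSE])
  grp <- gmF@individuals$line
  cnt <- function(l) apply(g[grp == l, , drop = FALSE], 2, tabulate,
                           nbins = 3L)
  c1 <- cnt(lines[1]); c2 <- cnt(lines[2])
  pOf <- function(cc) {
    n <- colSums(cc)
    ifelse(n > 0, (cc[2, ] + 2 * cc[3, ]) / (2 * n), NA_real_)
  }
  p1 <- pOf(c1); p2 <- pOf(c2)
  hwe <- hweTest(gmF, loci = loci)
  fst <- if (fstMethod == "nei")
    vapply(seq_along(loci), function(j) .neiFstLocus(p1[j], p2[j]),
           numeric(1))
  else
    vapply(seq_along(loci), function(j) .wcThetaLocus(c1[, j], c2[, j]),
           numeric(1))
  ## private alleles: nonzero count in exactly one line
  privRows <- list()
  for (j in seq_along(loci)) for (al in c("A", "B")) {
    n1 <- if (al == "A") 2 * c1[1, j] + c1[2, j] else 2 * c1[3, j] + c1[2, j]
    n2 <- if (al == "A") 2 * c2[1, j] + c2[2, j] else 2 * c2[3, j] + c2[2, j]
    if (xor(n1 > 0, n2 > 0) && (n1 + n2) > 0)
      privRows[[length(privRows) + 1L]] <- data.frame(
        marker = loci[j], allele = al,
        group = if (n1 > 0) lines[1] else lines[2],
        count = max(n1, n2), stringsAsFactors = FALSE)
  }
  privateAlleles <- if (length(privRows)) do.call(rbind, privRows)
    else data.frame(marker = character(), allele = character(),
                    group = character(), count = integer())
  stats <- data.frame(
    marker = loci, pB1 = p1, pB2 = p2,
    hweP = hwe$p, monomorphic = hwe$monomorphic, fst = fst,
    private = loci %in% privateAlleles$marker,
    row.names = NULL, stringsAsFactors = FALSE)
  ## diversity subset: polymorphic, HWE pass, then greedy LD pruning
  polym <- !is.na(stats$monomorphic) & !stats$monomorphic
  nTested <- sum(!is.na(hwe$p))
  hwePass <- polym & (is.na(hwe$p) | hwe$p >= hweAlpha / max(nTested, 1L))
  cand <- loci[polym & hwePass]
  ld <- ldR2(gmF, loci = loci)
  keep <- cand
  repeat {
    r2 <- ld$r2[keep, keep, drop = FALSE]
    diag(r2) <- NA
    worst <- which(r2 > ldMax, arr.ind = TRUE)
    if (!nrow(worst)) break
    meanR2 <- rowMeans(r2, na.rm = TRUE)
    inPair <- unique(as.vector(worst))
    drop <- inPair[which.max(meanR2[inPair])]
    keep <- keep[-drop]
  }
  lineSubset <- loci[!is.na(stats$fst) & stats$fst >= fstMin]
  structure(list(stats = stats, diversitySubset = keep,
                 lineSubset = lineSubset,
                 privateAlleles = privateAlleles, ld = ld,
                 individualsUsed = gmF@individuals$id,
                 params = list(fstMin = fstMin, hweAlpha = hweAlpha,
                               ldMax = ldMax, fstMethod = fstMethod)),
            class = "MarkerSelection")
}
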