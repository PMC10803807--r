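## Individual discrimination (PID / PIDsib curves, pairwise allele
## mismatches) and pairwise parent-offspring assignment (Mendelian
## exclusion + error-tolerant likelihood).

#' Per-marker allele frequencies
#'
#' Frequencies are estimated from called genotypes only; gene copy
#' counts (2n) are reported alongside.
#'
#' @param gm a [GenotypeCalls-class].
#' @param loci marker ids (default: all autosomal markers).
#' @param group optional breeding-line label to restrict individuals.
#' @return data.frame with `marker`, `pA`, `pB`, `nGenes`, `hExp`
#'   (expected heterozygosity 1 - pA^2 - pB^2).
#' @export
alleleFreqTable <- function(gm, loci = NULL, group = NULL) {
  loci <- .resolveLoci(gm, loci)
  keep <- rep(TRUE, nrow(gm@calls))
  if (!is.null(group)) keep <- gm@individuals$line == group
  d <- .dosage(gm@calls[keep, loci, drop = FALSE])
  nGenes <- 2 * colSums(!is.na(d))
  pB <- ifelse(nGenes > 0, colSums(d, na.rm = TRUE) / nGenes, NA_real_)
  data.frame(marker = loci, pA = 1 - pB, pB = pB, nGenes = nGenes,
             hExp = 2 * pB * (1 - pB), row.names = NULL,
             stringsAsFactors = FALSE)
}

## Per-locus PID / PIDsib for a biallelic locus with frequencies p, q.
.pidLocus <- function(p) {
  q <- 1 - p
  sum2 <- p^2 + q^2
  sum4 <- p^4 + q^4
  pid <- sum4 + (2 * p * q)^2
  pidsib <- 0.25 + 0.5 * sum2 + 0.5 * sum2^2 - 0.25 * sum4
  c(pid = pid, pidsib = pidsib)
}

#' Probability-of-identity curves
#'
#' Computes per-locus PID (probability two random individuals share a
#' genotype) and PIDsib (same for full siblings), sorts loci by
#' descending expected heterozygosity and accumulates the products in
#' log space.  Reports the locus count at which each curve first drops
#' below `threshold` (the conventional 0.0001 bound for natural
#' populations).
#'
#' @param freqs an [alleleFreqTable()] result (or a `GenotypeCalls`, in
#'   which case frequencies are computed over the individualisation
#'   subset).
#' @param threshold PID threshold (default 1e-4).
#' @return data.frame of class `PidCurve` with one row per locus in
#'   ranked order (`marker`, `hExp`, `pid`, `pidsib`, `cumPid`,
#'   `cumPidsib`) and attribute `lociToThreshold` (named vector, NA if
#'   never reached).
#' @export
pidCurves <- function(freqs, threshold = 1e-4) {
  if (is(freqs, "GenotypeCalls"))
    freqs <- alleleFreqTable(freqs,
      loci = .resolveLoci(freqs, NULL, "individualisation"))
  f <- freqs[!is.na(freqs$pB), , drop = FALSE]
  if (all(f$hExp == 0))
    warning("all loci monomorphic; PID curves are constant at 1")
  per <- t(vapply(f$pB, .pidLocus, c(pid = 0, pidsib = 0)))
  ord <- order(f$hExp, decreasing = TRUE)
  out <- data.frame(marker = f$marker[ord], hExp = f$hExp[ord],
                    pid = per[ord, "pid"], pidsib = per[ord, "pidsib"],
                    row.names = NULL, stringsAsFactors = FALSE)
  out$cumPid <- exp(cumsum(log(out$pid)))
  out$cumPidsib <- exp(cumsum(log(out$pidsib)))
  hit <- function(x) {
    w <- which(x < threshold)
    if (length(w)) w[1L] else NA_integer_
  }
  attr(out, "lociToThreshold") <- c(pid = hit(out$cumPid),
                                    pidsib = hit(out$cumPidsib))
  attr(out, "threshold") <- threshold
  class(out) <- c("PidCurve", "data.frame")
  out
}

#' Pairwise allele-mismatch matrix and same-individual grouping
#'
#' Counts, for every pair of individuals, the loci where both are called
#' and the genotypes differ.  Pairs at or below `maxMismatch` (and with
#' at least one comparable locus) are grouped as candidate observations
#' of the same individual via connected components.
#'
#' @param gm a [GenotypeCalls-class].
#' @param maxMismatch same-individual threshold (default 3, well under
#'   the minimum between-individual mismatch observed on real panels).
#' @param loci marker ids (default: individualisation subset).
#' @return list of class `MismatchResult`: `mismatch` and `compared`
#'   (symmetric matrices), `groups` (data.frame id/group), `incomparable`
#'   (pairs with zero shared loci), `summary` (mean and minimum pairwise
#'   mismatch among distinct individuals).
#' @export
matchIndividuals <- function(gm, maxMismatch = 3L, loci = NULL) {
  loci <- .resolveLoci(gm, loci, "individualisation")
  g <- .genoIndex(gm@calls[, loci, drop = FALSE])
  n <- nrow(g)
  called <- !is.na(g)
  cmp <- tcrossprod(called * 1)           # loci where both called
  same <- matrix(0, n, n)
  for (k in 1:3) {
    ik <- (g == k) & called
    ik[is.na(ik)] <- FALSE
    same <- same + tcrossprod(ik * 1)
  }
  mism <- cmp - same
  diag(mism) <- 0
  ids <- gm@individuals$id
  dimnames(mism) <- dimnames(cmp) <- list(ids, ids)
  adj <- mism <= maxMismatch & cmp > 0
  diag(adj) <- TRUE
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(gr)$membership
  up <- which(upper.tri(cmp), arr.ind = TRUE)
  incomp <- up[cmp[up] == 0, , drop = FALSE]
  off <- mism[upper.tri(mism)]
  offc <- cmp[upper.tri(cmp)]
  structure(list(
    mismatch = mism, compared = cmp,
    groups = data.frame(id = ids, group = unname(comp),
                        stringsAsFactors = FALSE),
    incomparable = data.frame(id1 = ids[incomp[, 1]],
                              id2 = ids[incomp[, 2]],
                              stringsAsFactors = FALSE),
    summary = c(meanMismatch = mean(off[offc > 0]),
                minMismatch = if (any(offc > 0)) min(off[offc > 0])
                              else NA_real_),
    maxMismatch = maxMismatch), class = "MismatchResult")
}

## Single-parent Mendelian transition probabilities: row = candidate
## parent genotype (AA/AB/BB), col = offspring genotype; the unknown
## parent contributes a Hardy-Weinberg allele (pB = frequency of B).
.transitionMatrix <- function(pB) {
  pA <- 1 - pB
  rbind(AA = c(pA, pB, 0),
        AB = c(pA / 2, 0.5, pB / 2),
        BB = c(0, pA, pB))
}

.hwProbs <- function(pB) {
  pA <- 1 - pB
  c(AA = pA^2, AB = 2 * pA * pB, BB = pB^2)
}

#' Pairwise parent-offspring assignment
#'
#' For every pair of genotyped individuals, counts Mendelian exclusions
#' (opposing homozygotes) and computes a LOD score comparing "candidate
#' is a parent, the other parent drawn from Hardy-Weinberg" against
#' "unrelated", with per-locus genotyping error rate `epsilon` mixed in:
#' `P(g_o | parent) = (1 - e) T(g_o | g_c) + e P_HW(g_o)`.  A candidate
#' passes when exclusions <= `maxExclusions` and LOD > `lodMin`.  The
#' likelihood is direction-dependent; both orientations are evaluated and
#' the better one kept, with the orientation reported as undetermined
#' (molecular data alone cannot tell parent from offspring).  Candidates
#' are every other genotyped individual, split into sire/dam pools by
#' sex; if several candidates in a pool pass with an exactly tied top
#' LOD they are reported as `ambiguous`.
#'
#' @param gm a [GenotypeCalls-class] of consensus genotypes.
#' @param freqs optional [alleleFreqTable()] over the parentage loci.
#' @param epsilon per-locus genotyping error rate (default 1e-4, the
#'   rate appropriate for consensus genotypes built from triplicates).
#' @param maxExclusions maximum tolerated exclusions (default 1, so a
#'   single mis-scored locus cannot veto a true parent).
#' @param lodMin LOD acceptance threshold (default 0).
#' @param loci marker ids (default: parentage/diversity subset).
#' @return data.frame of class `PoAssignment`: `focal`, `candidate`,
#'   `candidateSex`, `compared`, `exclusions`, `lod`, `decision`
#'   (`assigned` / `ambiguous` / `rejected`), `orientation`.
#' @export
assignParents <- function(gm, freqs = NULL, epsilon = 1e-4,
                          maxExclusions = 1L, lodMin = 0, loci = NULL) {
  stopifnot(epsilon >= 0, epsilon < 0.5)
  loci <- .resolveLoci(gm, loci, "parentage_diversity")
  if (is.null(freqs)) freqs <- alleleFreqTable(gm, loci = loci)
  freqs <- freqs[match(loci, freqs$marker), , drop = FALSE]
  g <- .genoIndex(gm@calls[, loci, drop = FALSE])
  n <- nrow(g); L <- length(loci)
  ids <- gm@individuals$id
  sexes <- gm@individuals$sex
  ## per-locus 4x4 tables (4th state = missing, contributes zero)
  lodPC <- matrix(0, n, n)    # LOD with row = offspring, col = parent
  excl <- matrix(0L, n, n)
  cmp <- matrix(0L, n, n)
  for (l in seq_len(L)) {
    pB <- freqs$pB[l]
    if (is.na(pB)) next
    tr <- .transitionMatrix(pB)
    hw <- .hwProbs(pB)
    num <- (1 - epsilon) * tr + epsilon * rep(hw, each = 3)
    lt <- log10(num) - rep(log10(hw), each = 3)   # [parent, offspring]
    lt[!is.finite(lt)] <- -Inf
    M <- matrix(0, 4, 4); M[1:3, 1:3] <- t(lt)    # [offspring, parent]
    E <- matrix(0L, 4, 4); E[1, 3] <- E[3, 1] <- 1L
    Cm <- matrix(0L, 4, 4); Cm[1:3, 1:3] <- 1L
    gl <- g[, l]; gl[is.na(gl)] <- 4L
    lodPC <- lodPC + M[gl, gl]
    excl <- excl + E[gl, gl]
    cmp <- cmp + Cm[gl, gl]
  }
  ## best orientation per unordered pair
  lodBest <- pmax(lodPC, t(lodPC))
  up <- which(upper.tri(lodBest), arr.ind = TRUE)
  res <- data.frame(
    focal = ids[up[, 1]], candidate = ids[up[, 2]],
    candidateSex = sexes[up[, 2]],
    compared = cmp[up], exclusions = excl[up], lod = lodBest[up],
    stringsAsFactors = FALSE)
  ## mirror so every individual appears as focal with all candidates
  res <- rbind(res, data.frame(
    focal = ids[up[, 2]], candidate = ids[up[, 1]],
    candidateSex = sexes[up[, 1]],
    compared = cmp[up], exclusions = excl[up], lod = lodBest[up],
    stringsAsFactors = FALSE))
  res <- res[res$compared > 0, , drop = FALSE]
  pass <- res$exclusions <= maxExclusions & res$lod > lodMin
  res$decision <- ifelse(pass, "assigned", "rejected")
  ## exact-tie ambiguity within each focal's sire (M/U) and dam (F/U) pool
  for (f in unique(res$focal[pass])) {
    sub <- which(res$focal == f & pass)
    for (pool in list(c("M", "U"), c("F", "U"))) {
      ps <- sub[res$candidateSex[sub] %in% pool]
      if (length(ps) > 1L) {
        top <- max(res$lod[ps])
        tied <- ps[res$lod[ps] == top]
        if (length(tied) > 1L) res$decision[tied] <- "ambiguous"
      }
    }
  }
  res$orientation <- "undetermined"
  res <- res[order(res$focal, -res$lod), ]
  rownames(res) <- NULL
  class(res) <- c("PoAssignment", "data.frame")
  res
}

#' Assemble the family network and compare it with a pedigree
#'
#' Builds a graph of accepted parent-offspring edges and, when a
#' pedigree is supplied, labels every expected pedigree link as
#' `verified` (the pair passes the PO test), `not_verified` (both
#' genotyped but the pair fails it) or `not_testable` (a member
#' ungenotyped), and every edge of the assignment graph absent from the
#' pedigree as `novel`.  Verification is judged against all passing
#' pairs; the graph itself keeps only the best candidate per pool when
#' `bestPerPool` is set, because with undetermined orientation an
#' individual's own offspring compete in its parent pools.
#'
#' @param po a [assignParents()] result.
#' @param gm the [GenotypeCalls-class] the assignments came from.
#' @param pedigree optional [Pedigree-class].
#' @param bestPerPool keep only the top-LOD accepted candidate within
#'   each focal individual's sire and dam pool (default TRUE); with
#'   FALSE every passing candidate contributes an edge.
#' @return list of class `FamilyNetwork`: `graph` (igraph), `edges`
#'   (accepted unordered pairs), `pedigreeLinks` (expected links with
#'   category), `novel`, `counts`.
#' @export
buildFamilyNetwork <- function(po, gm, pedigree = NULL,
                               bestPerPool = TRUE) {
  accAll <- po[po$decision %in% c("assigned", "ambiguous"), , drop = FALSE]
  acc <- accAll
  if (bestPerPool && nrow(acc)) {
    pool <- ifelse(acc$candidateSex == "F", "dam", "sire")
    keep <- unlist(lapply(split(seq_len(nrow(acc)),
                                paste(acc$focal, pool)), function(ix) {
      top <- max(acc$lod[ix])
      ix[acc$lod[ix] == top]
    }))
    acc <- acc[sort(keep), , drop = FALSE]
  }
  pairKey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  edges <- unique(data.frame(
    id1 = pmin(acc$focal, acc$candidate),
    id2 = pmax(acc$focal, acc$candidate), stringsAsFactors = FALSE))
  gr <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = gm@individuals$id))
  pedLinks <- NULL; novel <- edges; counts <- NULL
  if (!is.null(pedigree)) {
    rec <- pedigree@records
    genotyped <- gm@individuals$id
    links <- rbind(
      data.frame(child = rec$id, parent = rec$sire,
                 stringsAsFactors = FALSE),
      data.frame(child = rec$id, parent = rec$dam,
                 stringsAsFactors = FALSE))
    links <- links[!is.na(links$parent), , drop = FALSE]
    accKeys <- pairKey(edges$id1, edges$id2)
    passKeys <- pairKey(accAll$focal, accAll$candidate)
    linkKeys <- pairKey(links$child, links$parent)
    testable <- links$child %in% genotyped & links$parent %in% genotyped
    links$category <- ifelse(!testable, "not_testable",
                             ifelse(linkKeys %in% passKeys, "verified",
                                    "not_verified"))
    novel <- edges[!accKeys %in% linkKeys[testable], , drop = FALSE]
    counts <- c(verified = sum(links$category == "verified"),
                not_verified = sum(links$category == "not_verified"),
                not_testable = sum(links$category == "not_testable"),
                novel = nrow(novel))
    pedLinks <- links
  }
  structure(list(graph = gr, edges = edges, pedigreeLinks = pedLinks,
                 novel = novel, counts = counts),
            class = "FamilyNetwork")
}
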