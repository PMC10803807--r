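## Breeding-line assignment (classification-EM maximum-likelihood
## clustering and supervised Dirichlet allele-frequency assignment, with
## the dual 60% decision rule) and cross-species detection (call-rate
## gating plus principal coordinates analysis).

## log P(genotype | allele-b frequency f) for codes 1/2/3, columns of f.
.genoLogLik <- function(g, f) {
  ## g: n x L integer matrix (NA = missing), f: length-L frequencies
  lp <- rbind(2 * log(1 - f), log(2) + log(f) + log(1 - f), 2 * log(f))
  ll <- matrix(0, nrow(g), 1)
  out <- numeric(nrow(g))
  for (l in seq_len(ncol(g))) {
    gl <- g[, l]
    ok <- !is.na(gl)
    out[ok] <- out[ok] + lp[gl[ok], l]
  }
  out
}

#' Maximum-likelihood genetic clustering (classification EM)
#'
#' Hard-assignment EM under a Hardy-Weinberg-within-cluster likelihood:
#' the E-step assigns each individual to the cluster maximizing its
#' genotype likelihood, the M-step re-estimates cluster allele
#' frequencies from the assignments.  Membership probabilities are the
#' normalized per-cluster likelihoods at convergence and the model score
#' is BIC = -2 logL + K L log(n).  Multi-start (k-means-on-dosage plus
#' random restarts) under a deterministic seed schedule; the best
#' likelihood is kept.  The classification log-likelihood is
#' non-decreasing over iterations; this is checked at run time.
#'
#' @param gm a [GenotypeCalls-class].
#' @param K number of clusters (>= 1).
#' @param loci marker ids (default: line-discrimination subset).
#' @param nStarts number of starts (default 20).
#' @param maxIter maximum EM iterations per start (default 100).
#' @param seed RNG seed for the start schedule.
#' @return list of class `MembershipResult`: `Q` (n x K), `assignment`,
#'   `freqs` (K x L allele-b frequencies), `logLik`, `bic`, `converged`,
#'   `K`, `method = "ml_em"`.
#' @export
mlCluster <- function(gm, K, loci = NULL, nStarts = 20L, maxIter = 100L,
                      seed = 1L) {
  stopifnot(K >= 1L)
  loci <- .resolveLoci(gm, loci, "line_discrimination")
  g <- .genoIndex(gm@calls[, loci, drop = FALSE])
  n <- nrow(g); L <- ncol(g)
  d <- .dosage(gm@calls[, loci, drop = FALSE])
  dImp <- apply(d, 2, function(x) {
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    x
  })
  dImp[is.na(dImp)] <- 1
  mstep <- function(assign) {
    f <- matrix(NA_real_, K, L)
    for (k in seq_len(K)) {
      rows <- which(assign == k)
      if (!length(rows)) next
      dk <- d[rows, , drop = FALSE]
      m2 <- 2 * colSums(!is.na(dk))
      f[k, ] <- ifelse(m2 > 0, colSums(dk, na.rm = TRUE) / m2, 0.5)
    }
    f
  }
  clusterLogLik <- function(f) {
    ## n x K matrix of log P(genotypes | cluster k)
    ll <- matrix(0, n, K)
    for (k in seq_len(K)) ll[, k] <- .genoLogLik(g, f[k, ])
    ll
  }
  runOne <- function(assign0) {
    assign <- assign0
    f <- mstep(assign)
    prev <- -Inf
    converged <- FALSE
    monotone <- TRUE
    for (it in seq_len(maxIter)) {
      ## keep previous frequencies for clusters that lost all members
      ll <- clusterLogLik(f)
      newAssign <- max.col(ll, ties.method = "first")
      cur <- sum(ll[cbind(seq_len(n), newAssign)])
      if (cur < prev - 1e-9) monotone <- FALSE
      if (is.finite(prev) && cur - prev < 1e-10) {
        converged <- TRUE
        assign <- newAssign
        break
      }
      prev <- cur
      assign <- newAssign
      fNew <- mstep(assign)
      f[!is.na(fNew[, 1]), ] <- fNew[!is.na(fNew[, 1]), , drop = FALSE]
    }
    ll <- clusterLogLik(f)
    assign <- max.col(ll, ties.method = "first")
    logL <- sum(ll[cbind(seq_len(n), assign)])
    list(assign = assign, f = f, ll = ll, logL = logL,
         converged = converged, monotone = monotone)
  }
  set.seed(seed)
  starts <- list()
  if (K == 1L) {
    starts[[1L]] <- rep(1L, n)
  } else {
    km <- tryCatch(stats::kmeans(dImp, centers = K, nstart = 2),
                   error = function(e) NULL)
    if (!is.null(km)) starts[[1L]] <- km$cluster
    while (length(starts) < nStarts)
      starts[[length(starts) + 1L]] <-
        sample(rep_len(seq_len(K), n))   # every cluster seeded non-empty
  }
  best <- NULL
  for (s in starts) {
    fit <- runOne(s)
    if (is.null(best) || fit$logL > best$logL) best <- fit
  }
  if (!best$monotone)
    warning("classification log-likelihood decreased during EM")
  ## membership probabilities: normalized per-cluster likelihoods
  mx <- apply(best$ll, 1, max)
  Q <- exp(best$ll - mx)
  Q <- Q / rowSums(Q)
  colnames(Q) <- paste0("cluster", seq_len(K))
  rownames(Q) <- gm@individuals$id
  ## BIC uses the equal-proportion mixture log-likelihood at the fitted
  ## frequencies: the classification log-likelihood (sum of per-individual
  ## maxima) is optimistically biased and systematically overfits K
  logLikMix <- sum(mx + log(rowMeans(exp(best$ll - mx))))
  structure(list(Q = Q, assignment = best$assign, freqs = best$f,
                 logLik = best$logL, logLikMix = logLikMix,
                 bic = -2 * logLikMix + K * L * log(n),
                 converged = best$converged, monotone = best$monotone,
                 K = K, loci = loci, method = "ml_em"),
            class = "MembershipResult")
}

#' Choose the number of clusters by BIC
#'
#' Fits [mlCluster()] over a K range and returns the fits with the
#' BIC-minimizing K.
#'
#' @inheritParams mlCluster
#' @param Krange candidate cluster counts (default 1:10).
#' @return list: `bestK`, `bic` (named vector), `fits`.
#' @export
selectK <- function(gm, Krange = 1:10, loci = NULL, nStarts = 20L,
                    maxIter = 100L, seed = 1L) {
  fits <- lapply(Krange, function(K)
    mlCluster(gm, K, loci = loci, nStarts = nStarts, maxIter = maxIter,
              seed = seed + K))
  bic <- vapply(fits, `[[`, numeric(1), "bic")
  names(bic) <- Krange
  list(bestK = Krange[which.min(bic)], bic = bic, fits = fits)
}

#' Supervised Bayesian allele-frequency assignment
#'
#' Leave-one-out assignment to labeled reference lines: per line,
#' posterior-predictive genotype probabilities under a symmetric
#' Dirichlet(1) (Beta(1,1)) prior on allele frequencies estimated from
#' that line's reference genotypes excluding the focal individual;
#' membership probabilities are the normalized marginal likelihoods.
#' Loci where a line has no reference gene copies are skipped for that
#' line.
#'
#' @param gm a [GenotypeCalls-class]; individuals with a line label in
#'   `lines` form the reference panels, all individuals are assigned.
#' @param loci marker ids (default: line-discrimination subset).
#' @param lines the two reference labels (default `c("LL", "LC")`).
#' @return list of class `MembershipResult` (`method = "bayes_af"`,
#'   `Q` columns named by line).
#' @export
bayesAssign <- function(gm, loci = NULL, lines = c("LL", "LC")) {
  loci <- .resolveLoci(gm, loci, "line_discrimination")
  d <- .dosage(gm@calls[, loci, drop = FALSE])
  n <- nrow(d); L <- ncol(d)
  grp <- gm@individuals$line
  logQ <- matrix(0, n, length(lines))
  for (li in seq_along(lines)) {
    ref <- which(grp == lines[li])
    if (!length(ref)) stop("line ", lines[li], " has no reference genotypes")
    dr <- d[ref, , drop = FALSE]
    totB <- colSums(dr, na.rm = TRUE)
    totN <- 2 * colSums(!is.na(dr))
    for (i in seq_len(n)) {
      nB <- totB; nN <- totN
      r <- match(i, ref)
      if (!is.na(r)) {          # leave the focal individual out
        ok <- !is.na(dr[r, ])
        nB[ok] <- nB[ok] - dr[r, ok]
        nN[ok] <- nN[ok] - 2
      }
      gi <- d[i, ]
      use <- !is.na(gi) & nN > 0
      a <- nB[use] + 1; b <- (nN[use] - nB[use]) + 1  # Beta posterior
      tot <- nN[use]
      ## posterior predictive of an ordered pair of draws
      pAA <- b * (b + 1) / ((tot + 2) * (tot + 3))
      pAB <- 2 * a * b / ((tot + 2) * (tot + 3))
      pBB <- a * (a + 1) / ((tot + 2) * (tot + 3))
      pg <- ifelse(gi[use] == 0, pAA, ifelse(gi[use] == 1, pAB, pBB))
      logQ[i, li] <- sum(log(pg))
    }
  }
  mx <- apply(logQ, 1, max)
  Q <- exp(logQ - mx)
  Q <- Q / rowSums(Q)
  colnames(Q) <- lines
  rownames(Q) <- gm@individuals$id
  structure(list(Q = Q, assignment = max.col(Q, ties.method = "first"),
                 logLik = NA_real_, bic = NA_real_, K = length(lines),
                 loci = loci, method = "bayes_af"),
            class = "MembershipResult")
}

#' Dual-threshold breeding-line decision
#'
#' An individual is assigned to a breeding line only if *both* clustering
#' methods give that line a membership probability of at least
#' `threshold` (default 0.6); otherwise it is unassigned, with flags for
#' a below-threshold probability or a between-method conflict.  Cluster
#' labels of the unsupervised method are aligned to lines through the
#' labeled anchor individuals.
#'
#' @param m1,m2 `MembershipResult`s over the same individuals with
#'   K = 2.
#' @param gm the [GenotypeCalls-class] (provides anchor labels and
#'   expected lines).
#' @param threshold dual assignment threshold (default 0.6).
#' @param lines the two line labels.
#' @return data.frame of class `LineDecision`: per individual the two
#'   per-line probabilities, `decision`, flags, and `expectedComparison`
#'   (`match` / `false_positive` / `unassigned` / `n/a`).
#' @export
decideLines <- function(m1, m2, gm, threshold = 0.6,
                        lines = c("LL", "LC")) {
  alignQ <- function(m) {
    Q <- m$Q
    if (all(lines %in% colnames(Q))) return(Q[, lines, drop = FALSE])
    if (ncol(Q) != 2L) stop("line decision requires K = 2")
    anchors <- gm@individuals$line %in% lines
    if (!any(anchors))
      stop("no labeled anchor individuals; cannot align clusters to lines")
    perm <- list(1:2, 2:1)
    lineIdx <- match(gm@individuals$line[anchors], lines)
    score <- vapply(perm, function(p) {
      sum(Q[cbind(which(anchors), p[lineIdx])])
    }, numeric(1))
    Qa <- Q[, perm[[which.max(score)]], drop = FALSE]
    colnames(Qa) <- lines
    Qa
  }
  Q1 <- alignQ(m1); Q2 <- alignQ(m2)
  stopifnot(identical(rownames(Q1), rownames(Q2)))
  n <- nrow(Q1)
  decision <- character(n); conflict <- below <- logical(n)
  for (i in seq_len(n)) {
    l1 <- lines[which.max(Q1[i, ])]
    l2 <- lines[which.max(Q2[i, ])]
    p1 <- max(Q1[i, ]); p2 <- max(Q2[i, ])
    if (l1 == l2 && p1 >= threshold && p2 >= threshold) {
      decision[i] <- l1
    } else {
      decision[i] <- "unassigned"
      conflict[i] <- l1 != l2 && p1 >= threshold && p2 >= threshold
      below[i] <- min(p1, p2) < threshold
    }
  }
  expected <- gm@individuals$line
  cmpr <- ifelse(!expected %in% lines, "n/a",
                 ifelse(decision == "unassigned", "unassigned",
                        ifelse(decision == expected, "match",
                               "false_positive")))
  out <- data.frame(id = rownames(Q1),
                    q1 = Q1[, 1], q2 = Q1[, 2],
                    q1b = Q2[, 1], q2b = Q2[, 2],
                    decision = decision,
                    methodConflict = conflict, belowThreshold = below,
                    expected = expected, expectedComparison = cmpr,
                    stringsAsFactors = FALSE)
  names(out)[2:5] <- c(paste0(lines, "_m1"), paste0(lines, "_m2"))
  rownames(out) <- NULL
  class(out) <- c("LineDecision", "data.frame")
  out
}

#' Cross-species principal coordinates analysis
#'
#' Gates individuals at a minimum SNP call rate (default 80%) over the
#' analysis loci, computes pairwise squared codominant genetic distances
#' (per locus 0 for identical genotypes, 1 for homozygote-heterozygote,
#' 4 for opposite homozygotes, i.e. squared dosage differences) summed
#' over shared called loci and rescaled by total/shared locus counts,
#' and eigendecomposes the double-centered matrix.  Negative eigenvalues
#' are reported, not dropped.
#'
#' @param gm a [GenotypeCalls-class] (typically focal plus non-target
#'   taxa via [bindIndividuals()]).
#' @param callRateMin inclusion threshold (default 0.8).
#' @param loci marker ids (default: the autosomal individualisation +
#'   cross-species loci).
#' @param nAxes number of coordinate axes to return (default 2).
#' @return list of class `PcoaResult`: `coordinates`, `eigenvalues`,
#'   `pctVar` (share of the positive eigenvalue mass), `included`,
#'   `excluded` (data.frame with call rates), `dist2` (the scaled
#'   squared-distance matrix).
#' @export
speciesPcoa <- function(gm, callRateMin = 0.8, loci = NULL, nAxes = 2L) {
  if (is.null(loci)) {
    mk <- gm@markers
    loci <- mk$marker_id[mk$is_autosomal]
  }
  d <- .dosage(gm@calls[, loci, drop = FALSE])
  callRate <- rowMeans(!is.na(d))
  excluded <- data.frame(id = gm@individuals$id[callRate < callRateMin],
                         species =
                           gm@individuals$species[callRate < callRateMin],
                         callRate = callRate[callRate < callRateMin],
                         stringsAsFactors = FALSE)
  keep <- which(callRate >= callRateMin)
  if (length(keep) < 3L)
    stop("fewer than 3 individuals pass the call-rate gate")
  d <- d[keep, , drop = FALSE]
  L <- ncol(d)
  x <- d; x[is.na(x)] <- 0
  called <- (!is.na(d)) * 1
  shared <- tcrossprod(called)
  sq <- tcrossprod(x^2, called) + tcrossprod(called, x^2) -
    2 * tcrossprod(x)
  d2 <- ifelse(shared > 0, sq * (L / shared), NA)
  if (anyNA(d2)) stop("individual pair with zero shared called loci")
  n <- nrow(d2)
  Jc <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * Jc %*% d2 %*% Jc
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  pos <- e$values > 1e-9
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), nrow = sum(pos))
  nAxes <- min(nAxes, ncol(coords))
  rownames(coords) <- gm@individuals$id[keep]
  structure(list(
    coordinates = coords[, seq_len(nAxes), drop = FALSE],
    allCoordinates = coords,
    eigenvalues = e$values,
    pctVar = 100 * e$values[pos][seq_len(nAxes)] / sum(e$values[pos]),
    included = data.frame(id = gm@individuals$id[keep],
                          species = gm@individuals$species[keep],
                          callRate = callRate[keep],
                          stringsAsFactors = FALSE),
    excluded = excluded, dist2 = d2, callRateMin = callRateMin),
    class = "PcoaResult")
}
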