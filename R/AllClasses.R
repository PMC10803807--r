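#' @import methods
NULL

## Internal genotype vocabulary.  Autosomal calls are stored as one of
## "AA", "AB", "BB" (unordered allele pairs relative to the marker's
## allele_a / allele_b, canonicalized at parse time); the gonosomal sex
## marker uses "X" (no Y detected) and "XY".  NA encodes "No Call".
.GENO_CODES <- c("AA", "AB", "BB")
.SEX_CODES <- c("X", "XY")

.SUBSET_FLAGS <- c("individualisation", "parentage_diversity",
                   "line_discrimination", "sex", "cross_species",
                   "posthitis_meta")

.LINE_LEVELS <- c("LL", "LC", "U")
.SEX_LEVELS <- c("M", "F", "U")

#' ReplicateCalls: replicated SNP calls for one sample
#'
#' Holds the replicate-by-marker call table for a single DNA sample
#' (typically a non-invasive sample genotyped in >= 3 replicates).
#' Calls are stored as canonical genotype codes (`"AA"`, `"AB"`, `"BB"`,
#' `"X"`, `"XY"`) with `NA` for "No Call".
#'
#' @slot sampleId single sample identifier.
#' @slot individualId identifier of the individual the sample is assigned
#'   to, or `NA` if the sample was not individually assignable in the field.
#' @slot sampleType `"invasive"` or `"noninvasive"`.
#' @slot calls character matrix, replicates in rows, markers in columns
#'   (column names are marker ids).
#' @exportClass ReplicateCalls
setClass("ReplicateCalls",
  slots = c(sampleId = "character",
            individualId = "character",
            sampleType = "character",
            calls = "matrix"))

setValidity("ReplicateCalls", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L)
    msg <- c(msg, "sampleId must be a single string")
  if (!object@sampleType %in% c("invasive", "noninvasive"))
    msg <- c(msg, "sampleType must be 'invasive' or 'noninvasive'")
  if (nrow(object@calls) < 1L)
    msg <- c(msg, "at least one replicate is required")
  if (is.null(colnames(object@calls)))
    msg <- c(msg, "calls must have marker ids as column names")
  bad <- !(object@calls %in% c(.GENO_CODES, .SEX_CODES) | is.na(object@calls))
  if (any(bad))
    msg <- c(msg, "calls contain codes outside {AA, AB, BB, X, XY, NA}")
  if (length(msg)) msg else TRUE
})

#' GenotypeCalls: consensus genotypes for a set of individuals
#'
#' One row per individual (not per sample), one column per marker.
#' Individual metadata (species/ESU, breeding line, sex) travels with the
#' matrix, as does the marker definition table and, where applicable,
#' consensus provenance (replicate counts and per-sample call rates).
#'
#' @slot calls character matrix of canonical genotype codes, individuals
#'   in rows (row names are individual ids), markers in columns.
#' @slot individuals data.frame with columns `id`, `species`, `line`, `sex`.
#' @slot markers marker definition data.frame (see [defaultPanel()]).
#' @slot provenance list of consensus metadata (may be empty).
#' @exportClass GenotypeCalls
setClass("GenotypeCalls",
  slots = c(calls = "matrix",
            individuals = "data.frame",
            markers = "data.frame",
            provenance = "list"))

setValidity("GenotypeCalls", function(object) {
  msg <- character()
  ind <- object@individuals
  if (!all(c("id", "species", "line", "sex") %in% names(ind)))
    msg <- c(msg, "individuals needs columns id, species, line, sex")
  else {
    if (nrow(object@calls) != nrow(ind))
      msg <- c(msg, "one calls row per individual required")
    if (anyDuplicated(ind$id))
      msg <- c(msg, "individual ids must be unique (one row per individual)")
    if (!all(ind$line %in% .LINE_LEVELS))
      msg <- c(msg, "line labels must be one of LL, LC, U")
    if (!all(ind$sex %in% .SEX_LEVELS))
      msg <- c(msg, "sex labels must be one of M, F, U")
  }
  if (!identical(colnames(object@calls), object@markers$marker_id))
    msg <- c(msg, "calls columns must match markers$marker_id (same order)")
  bad <- !(object@calls %in% c(.GENO_CODES, .SEX_CODES) | is.na(object@calls))
  if (any(bad))
    msg <- c(msg, "calls contain codes outside {AA, AB, BB, X, XY, NA}")
  if (length(msg)) msg else TRUE
})

#' Pedigree: studbook-style sire/dam genealogy
#'
#' A validated directed acyclic sire/dam pedigree with sex, breeding line
#' and alive flags.  Founders are individuals with both parents unknown.
#'
#' @slot records data.frame with columns `id`, `sire`, `dam` (NA =
#'   unknown), `sex` (M/F/U), `line` (LL/LC/U), `alive` (logical),
#'   `founder` (logical).
#' @exportClass Pedigree
setClass("Pedigree", slots = c(records = "data.frame"))

setValidity("Pedigree", function(object) {
  rec <- object@records
  need <- c("id", "sire", "dam", "sex", "line", "alive", "founder")
  if (!all(need %in% names(rec)))
    return(paste("records needs columns", paste(need, collapse = ", ")))
  msg <- character()
  if (anyDuplicated(rec$id))
    msg <- c(msg, "duplicated individual ids")
  miss <- setdiff(c(rec$sire, rec$dam), c(rec$id, NA))
  if (length(miss))
    msg <- c(msg, paste("parents absent from pedigree:",
                        paste(miss, collapse = ", ")))
  ## sires male, dams female (when sex known)
  sx <- rec$sex[match(rec$sire, rec$id)]
  if (any(sx == "F", na.rm = TRUE))
    msg <- c(msg, "individual with recorded female sex used as sire")
  dx <- rec$sex[match(rec$dam, rec$id)]
  if (any(dx == "M", na.rm = TRUE))
    msg <- c(msg, "individual with recorded male sex used as dam")
  if (any(rec$founder & (!is.na(rec$sire) | !is.na(rec$dam))))
    msg <- c(msg, "founders must have no recorded parents")
  cyc <- .findPedigreeCycle(rec)
  if (!is.null(cyc))
    msg <- c(msg, paste("pedigree contains a cycle:",
                        paste(cyc, collapse = " -> ")))
  if (length(msg)) msg else TRUE
})

## Kahn topological check; returns one offending cycle path or NULL.
.findPedigreeCycle <- function(rec) {
  id <- rec$id
  parent <- cbind(match(rec$sire, id), match(rec$dam, id))
  ndep <- rowSums(!is.na(parent))
  kids <- lapply(seq_along(id), function(i)
    which(parent[, 1] == i | parent[, 2] == i))
  queue <- which(ndep == 0L)
  seen <- 0L
  ndep2 <- ndep
  while (length(queue)) {
    i <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (k in kids[[i]]) {
      ndep2[k] <- ndep2[k] - 1L
      if (ndep2[k] == 0L) queue <- c(queue, k)
    }
  }
  if (seen == length(id)) return(NULL)
  ## walk parents from an unresolved node until a repeat closes the cycle
  start <- which(ndep2 > 0L)[1L]
  path <- start
  cur <- start
  repeat {
    nxt <- parent[cur, ]
    nxt <- nxt[!is.na(nxt) & ndep2[nxt] > 0L][1L]
    if (is.na(nxt)) break
    if (nxt %in% path) {
      cyc <- c(path[which(path == nxt):length(path)], nxt)
      return(id[cyc])
    }
    path <- c(path, nxt)
    cur <- nxt
  }
  id[path]
}

setMethod("show", "ReplicateCalls", function(object) {
  cat(sprintf("ReplicateCalls '%s' (%s): %d replicates x %d markers\n",
              object@sampleId, object@sampleType,
              nrow(object@calls), ncol(object@calls)))
  cat(sprintf("  called: %.1f%%\n",
              100 * mean(!is.na(object@calls))))
})

setMethod("show", "GenotypeCalls", function(object) {
  cat(sprintf("GenotypeCalls: %d individuals x %d markers\n",
              nrow(object@calls), ncol(object@calls)))
  sp <- table(object@individuals$species)
  cat("  species:", paste(sprintf("%s (%d)", names(sp), sp), collapse = ", "),
      "\n")
  cat(sprintf("  called: %.1f%%\n", 100 * mean(!is.na(object@calls))))
})

setMethod("show", "Pedigree", function(object) {
  rec <- object@records
  cat(sprintf("Pedigree: %d individuals (%d founders, %d alive)\n",
              nrow(rec), sum(rec$founder), sum(rec$alive)))
})
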