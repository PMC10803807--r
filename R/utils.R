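## Shared internal helpers: call-string parsing, dosage conversion,
## marker-subset lookup and a convenience constructor.

## Parse one textual call ("A:G", "G", "AG", "NoCall", "", "X", "XY",
## "X:Y") into a canonical code relative to a marker's alleles.
## Returns NA for No Call; stops with a contextual error on bad alleles.
.parseCall <- function(txt, alleleA, alleleB, marker = "?", sample = "?") {
  if (is.na(txt)) return(NA_character_)
  txt <- trimws(txt)
  if (txt == "" || tolower(txt) %in% c("nocall", "no call", "na", "-"))
    return(NA_character_)
  parts <- toupper(unlist(strsplit(txt, ":", fixed = TRUE)))
  if (length(parts) == 1L && nchar(parts) == 2L)
    parts <- strsplit(parts, "")[[1L]]
  if (length(parts) == 1L) parts <- rep(parts, 2L)
  if (length(parts) != 2L)
    stop(sprintf("malformed call '%s' (sample %s, marker %s)",
                 txt, sample, marker), call. = FALSE)
  ## gonosomal sex marker: X-only vs XY
  if (identical(sort(c(alleleA, alleleB)), c("X", "Y"))) {
    if (setequal(parts, c("X", "Y")) || identical(parts, c("Y", "Y")))
      return("XY")
    if (identical(parts, c("X", "X"))) return("X")
    stop(sprintf("call '%s' not valid for sex marker %s (sample %s)",
                 txt, marker, sample), call. = FALSE)
  }
  bad <- setdiff(parts, c(alleleA, alleleB))
  if (length(bad))
    stop(sprintf(
      "call '%s' uses allele(s) %s not defined for marker %s (%s/%s) [sample %s]",
      txt, paste(bad, collapse = ","), marker, alleleA, alleleB, sample),
      call. = FALSE)
  n_b <- sum(parts == alleleB)
  c("AA", "AB", "BB")[n_b + 1L]
}

## Canonical code -> textual call for the writers.
.formatCall <- function(code, alleleA, alleleB) {
  if (is.na(code)) return("NoCall")
  switch(code,
         AA = paste(alleleA, alleleA, sep = ":"),
         AB = paste(alleleA, alleleB, sep = ":"),
         BB = paste(alleleB, alleleB, sep = ":"),
         X = "X:X",
         XY = "X:Y",
         stop("unknown genotype code ", code))
}

## Allele-b dosage (0/1/2, NA for No Call / sex codes).
.dosage <- function(calls) {
  d <- matrix(NA_real_, nrow(calls), ncol(calls),
              dimnames = dimnames(calls))
  d[calls == "AA"] <- 0
  d[calls == "AB"] <- 1
  d[calls == "BB"] <- 2
  d
}

## Genotype code as integer index 1/2/3 (AA/AB/BB), NA otherwise.
.genoIndex <- function(calls) {
  g <- match(calls, .GENO_CODES)
  dim(g) <- dim(calls)
  dimnames(g) <- dimnames(calls)
  g
}

## Marker ids carrying a given subset flag.
.subsetMarkers <- function(markers, flag) {
  stopifnot(flag %in% .SUBSET_FLAGS)
  markers$marker_id[markers[[flag]]]
}

## Resolve a `loci` argument: NULL -> markers with `defaultFlag` if that
## flag selects anything, else all autosomal markers.
.resolveLoci <- function(gm, loci, defaultFlag = NULL) {
  mk <- gm@markers
  if (is.null(loci)) {
    if (!is.null(defaultFlag) && any(mk[[defaultFlag]]))
      return(.subsetMarkers(mk, defaultFlag))
    return(mk$marker_id[mk$is_autosomal])
  }
  missing <- setdiff(loci, mk$marker_id)
  if (length(missing))
    stop("unknown marker id(s): ", paste(missing, collapse = ", "))
  loci
}

#' Assemble a GenotypeCalls object
#'
#' Low-level constructor used by the readers, the consensus builder and
#' the simulator.
#'
#' @param calls character matrix of canonical genotype codes
#'   (individuals x markers; `NA` = No Call).
#' @param markers marker definition table, e.g. [defaultPanel()]; order
#'   must match the call matrix columns.
#' @param individuals optional data.frame with columns `id`, `species`,
#'   `line`, `sex`; defaults are filled in from the call matrix row names.
#' @param provenance optional list of consensus metadata.
#' @return A [GenotypeCalls-class] object.
#' @export
makeGenotypeCalls <- function(calls, markers, individuals = NULL,
                              provenance = list()) {
  if (is.null(colnames(calls))) colnames(calls) <- markers$marker_id
  if (is.null(individuals)) {
    ids <- rownames(calls)
    if (is.null(ids)) ids <- sprintf("ind%03d", seq_len(nrow(calls)))
    individuals <- data.frame(id = ids, species = "B. bonasus",
                              line = "U", sex = "U",
                              stringsAsFactors = FALSE)
  }
  individuals$species <- as.character(individuals$species)
  individuals$line <- toupper(as.character(individuals$line))
  individuals$line[!individuals$line %in% .LINE_LEVELS] <- "U"
  individuals$sex <- toupper(substr(as.character(individuals$sex), 1, 1))
  individuals$sex[!individuals$sex %in% .SEX_LEVELS] <- "U"
  rownames(calls) <- individuals$id
  new("GenotypeCalls", calls = calls, individuals = individuals,
      markers = markers, provenance = provenance)
}

#' Combine two genotype sets over the same marker panel
#'
#' Row-binds individuals of two [GenotypeCalls-class] objects sharing an
#' identical marker table (e.g. the focal species plus simulated
#' non-target taxa before a cross-species PCoA).
#'
#' @param x,y [GenotypeCalls-class] objects with identical markers.
#' @return A [GenotypeCalls-class] holding all individuals of `x` and `y`.
#' @export
bindIndividuals <- function(x, y) {
  stopifnot(is(x, "GenotypeCalls"), is(y, "GenotypeCalls"))
  if (!identical(x@markers$marker_id, y@markers$marker_id))
    stop("marker panels differ; cannot combine")
  if (any(y@individuals$id %in% x@individuals$id))
    stop("duplicated individual ids across the two sets")
  makeGenotypeCalls(rbind(x@calls, y@calls), x@markers,
                    rbind(x@individuals, y@individuals))
}
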