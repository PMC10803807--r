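#' The default 96-SNP European bison marker panel
#'
#' Returns the shipped marker definition table: 90 autosomal markers for
#' individual discrimination (of which 63 are flagged for parentage and
#' genetic-diversity work, 18 for breeding-line discrimination and 12 as
#' posthitis-associated metadata), one gonosomal amelogenin-type sex
#' marker with a Y-diagnostic allele cluster, and 5 markers monomorphic
#' in the European bison that are used for cross-species detection only.
#'
#' Marker ids, chromosome placement (all Bos taurus autosomes except 25)
#' and allele pairs are synthetic stand-ins with the panel's published
#' structure; real assay tables can be supplied in the same format.
#'
#' @return data.frame with columns `marker_id`, `chromosome`, `allele_a`,
#'   `allele_b`, `is_autosomal` and logical subset flags
#'   `individualisation`, `parentage_diversity`, `line_discrimination`,
#'   `sex`, `cross_species`, `posthitis_meta`.
#' @examples
#' panel <- defaultPanel()
#' colSums(panel[, c("individualisation", "parentage_diversity",
#'                   "line_discrimination", "sex", "cross_species")])
#' @export
defaultPanel <- function() {
  autosomes <- setdiff(1:29, 25)   # chromosome 25 is not represented
  pairs <- matrix(c("A", "G", "C", "T", "A", "C", "G", "T"),
                  ncol = 2, byrow = TRUE)
  n_auto <- 90L
  auto <- data.frame(
    marker_id = sprintf("EBS%03d", seq_len(n_auto)),
    chromosome = as.character(rep_len(autosomes, n_auto)),
    allele_a = pairs[rep_len(seq_len(4), n_auto), 1],
    allele_b = pairs[rep_len(seq_len(4), n_auto), 2],
    is_autosomal = TRUE,
    stringsAsFactors = FALSE)
  auto$individualisation <- TRUE
  auto$parentage_diversity <- seq_len(n_auto) <= 63L
  auto$line_discrimination <- seq_len(n_auto) > 72L
  auto$sex <- FALSE
  auto$cross_species <- FALSE
  auto$posthitis_meta <- seq_len(n_auto) %in% 52:63
  sexm <- data.frame(
    marker_id = "AMELY1", chromosome = "XY-homolog",
    allele_a = "X", allele_b = "Y", is_autosomal = FALSE,
    individualisation = FALSE, parentage_diversity = FALSE,
    line_discrimination = FALSE, sex = TRUE, cross_species = FALSE,
    posthitis_meta = FALSE, stringsAsFactors = FALSE)
  xsp <- data.frame(
    marker_id = sprintf("XSP%02d", 1:5),
    chromosome = as.character(c(3, 8, 14, 19, 26)),
    allele_a = c("A", "C", "A", "G", "C"),
    allele_b = c("G", "T", "C", "T", "A"),
    is_autosomal = TRUE,
    individualisation = FALSE, parentage_diversity = FALSE,
    line_discrimination = FALSE, sex = FALSE, cross_species = TRUE,
    posthitis_meta = FALSE, stringsAsFactors = FALSE)
  rbind(auto, sexm, xsp)
}

.sniffSep <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty file: ", path, call. = FALSE)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a replicate-level SNP call table
#'
#' Accepts the long dialect (columns `sample_id`, `replicate_id`,
#' `marker_id`, `call`, plus optional `individual_id` and `sample_type`)
#' or the wide dialect (`sample_id`, `replicate_id`, then one column per
#' marker).  Calls may be allele pairs (`"A:G"`, `"AG"`), single letters
#' for homozygotes, `"X"`/`"X:Y"` for the sex marker, or `"NoCall"`.
#'
#' Unknown marker ids and alleles outside the marker definition are hard
#' errors naming the offenders; nothing is silently dropped.
#'
#' @param path delimited text file (comma or tab separated).
#' @param markers marker definition table (see [defaultPanel()]).
#' @return list of [ReplicateCalls-class], one per sample.
#' @export
readCallTable <- function(path, markers = defaultPanel()) {
  sep <- .sniffSep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0L) stop("no records in call table ", path, call. = FALSE)
  long <- all(c("sample_id", "marker_id", "call") %in% names(df))
  if (!long) {
    if (!"sample_id" %in% names(df))
      stop("call table needs a sample_id column", call. = FALSE)
    idcols <- intersect(c("sample_id", "individual_id", "sample_type",
                          "replicate_id"), names(df))
    mcols <- setdiff(names(df), idcols)
    unknown <- setdiff(mcols, markers$marker_id)
    if (length(unknown))
      stop("unknown marker id(s) in call table: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    df <- cbind(
      df[rep(seq_len(nrow(df)), each = length(mcols)), idcols, drop = FALSE],
      data.frame(marker_id = rep(mcols, nrow(df)),
                 call = as.character(t(as.matrix(df[, mcols]))),
                 stringsAsFactors = FALSE))
  }
  unknown <- setdiff(unique(df$marker_id), markers$marker_id)
  if (length(unknown))
    stop("unknown marker id(s) in call table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (!"replicate_id" %in% names(df)) df$replicate_id <- "1"
  if (!"individual_id" %in% names(df)) df$individual_id <- NA_character_
  if (!"sample_type" %in% names(df)) df$sample_type <- "noninvasive"
  mrow <- match(df$marker_id, markers$marker_id)
  df$code <- vapply(seq_len(nrow(df)), function(i)
    .parseCall(df$call[i], markers$allele_a[mrow[i]],
               markers$allele_b[mrow[i]],
               marker = df$marker_id[i], sample = df$sample_id[i]),
    character(1))
  out <- lapply(split(df, df$sample_id), function(d) {
    reps <- unique(d$replicate_id)
    m <- matrix(NA_character_, length(reps), nrow(markers),
                dimnames = list(reps, markers$marker_id))
    m[cbind(match(d$replicate_id, reps), match(d$marker_id,
                                               markers$marker_id))] <- d$code
    new("ReplicateCalls",
        sampleId = d$sample_id[1L],
        individualId = as.character(d$individual_id[1L]),
        sampleType = if (d$sample_type[1L] %in% c("invasive", "noninvasive"))
          d$sample_type[1L] else "noninvasive",
        calls = m)
  })
  unname(out[unique(df$sample_id)])
}

#' Write replicate calls as a long-format table
#'
#' Emits the long dialect read back by [readCallTable()] (one row per
#' sample x replicate x marker).
#'
#' @param rcs list of [ReplicateCalls-class].
#' @param markers marker definition table matching the call columns.
#' @param path output file; comma separated.
#' @export
writeCallTable <- function(rcs, path, markers = defaultPanel()) {
  rows <- lapply(rcs, function(rc) {
    m <- rc@calls
    mi <- match(colnames(m), markers$marker_id)
    data.frame(
      sample_id = rc@sampleId,
      individual_id = ifelse(is.na(rc@individualId), "", rc@individualId),
      sample_type = rc@sampleType,
      replicate_id = rep(rownames(m) %||% as.character(seq_len(nrow(m))),
                         times = ncol(m)),
      marker_id = rep(colnames(m), each = nrow(m)),
      call = vapply(seq_along(m), function(k) {
        j <- ((k - 1L) %/% nrow(m)) + 1L
        .formatCall(m[k], markers$allele_a[mi[j]], markers$allele_b[mi[j]])
      }, character(1)),
      stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a studbook-style pedigree file
#'
#' Expects delimited text with columns `id`, `sire`, `dam` and optionally
#' `sex`, `line`, `alive` (case-insensitive; missing parents encoded as
#' empty, `"0"` or `NA`).  Parents referenced but not listed are created
#' as unknown-sex founders with a warning.  Cycles and sex-inconsistent
#' parent records are hard errors.
#'
#' @param path delimited text file.
#' @return A [Pedigree-class].
#' @export
readPedigree <- function(path) {
  sep <- .sniffSep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  names(df) <- tolower(names(df))
  if (nrow(df) == 0L) stop("no records in pedigree file", call. = FALSE)
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(df)))
    stop("pedigree file needs columns id, sire, dam", call. = FALSE)
  blank <- function(x) is.na(x) | trimws(x) %in% c("", "0", "NA")
  rec <- data.frame(
    id = trimws(df$id),
    sire = ifelse(blank(df$sire), NA_character_, trimws(df$sire)),
    dam = ifelse(blank(df$dam), NA_character_, trimws(df$dam)),
    sex = if ("sex" %in% names(df))
      toupper(substr(trimws(df$sex), 1, 1)) else "U",
    line = if ("line" %in% names(df)) toupper(trimws(df$line)) else "U",
    alive = if ("alive" %in% names(df))
      !tolower(trimws(df$alive)) %in% c("0", "false", "f", "no", "dead")
    else TRUE,
    stringsAsFactors = FALSE)
  rec$sex[!rec$sex %in% .SEX_LEVELS] <- "U"
  rec$line[!rec$line %in% .LINE_LEVELS] <- "U"
  missing <- setdiff(c(rec$sire, rec$dam), c(rec$id, NA))
  if (length(missing)) {
    warning("parent(s) not listed in file created as unknown-sex founders: ",
            paste(missing, collapse = ", "))
    sx <- ifelse(missing %in% rec$sire & !missing %in% rec$dam, "M",
                 ifelse(missing %in% rec$dam & !missing %in% rec$sire,
                        "F", "U"))
    rec <- rbind(rec, data.frame(id = missing, sire = NA_character_,
                                 dam = NA_character_, sex = sx,
                                 line = "U", alive = FALSE,
                                 stringsAsFactors = FALSE))
  }
  rec$founder <- is.na(rec$sire) & is.na(rec$dam)
  new("Pedigree", records = rec)
}

#' Write a pedigree file
#'
#' @param ped a [Pedigree-class].
#' @param path output file; comma separated with empty missing parents.
#' @export
writePedigree <- function(ped, path) {
  rec <- ped@records
  out <- data.frame(id = rec$id,
                    sire = ifelse(is.na(rec$sire), "", rec$sire),
                    dam = ifelse(is.na(rec$dam), "", rec$dam),
                    sex = rec$sex, line = rec$line,
                    alive = as.integer(rec$alive),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export consensus genotypes
#'
#' `"csv"` writes the native table that [readGenotypeMatrix()] reads back
#' losslessly.  `"ped"` writes PLINK PED/MAP text files (missing call =
#' `0 0`).  `"vcf"` writes VCF v4.2 via the vcfR package (missing call =
#' `./.`; REF/ALT are the marker's two alleles, positions are placeholder
#' indices); non-autosomal pseudo-allele markers (the X/Y sex marker) are
#' excluded from VCF output because REF/ALT must be nucleotides.
#'
#' @param gm a [GenotypeCalls-class].
#' @param path output file (for `"ped"` the `.map` file is written next
#'   to it).
#' @param format one of `"csv"`, `"ped"`, `"vcf"`.
#' @importClassesFrom vcfR vcfR
#' @export
writeGenotypeMatrix <- function(gm, path, format = c("csv", "ped", "vcf")) {
  format <- match.arg(format)
  if (nrow(gm@calls) == 0L) stop("empty genotype matrix", call. = FALSE)
  mk <- gm@markers
  if (format == "csv") {
    txt <- vapply(seq_len(ncol(gm@calls)), function(j)
      vapply(gm@calls[, j], .formatCall, character(1),
             alleleA = mk$allele_a[j], alleleB = mk$allele_b[j]),
      character(nrow(gm@calls)))
    if (nrow(gm@calls) == 1L) txt <- matrix(txt, nrow = 1L)
    colnames(txt) <- mk$marker_id
    out <- cbind(gm@individuals[, c("id", "species", "line", "sex")], txt)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else if (format == "ped") {
    alle <- function(code, a, b) switch(code,
      AA = c(a, a), AB = c(a, b), BB = c(b, b), X = c("X", "X"),
      XY = c("X", "Y"))
    lines <- vapply(seq_len(nrow(gm@calls)), function(i) {
      al <- unlist(lapply(seq_len(ncol(gm@calls)), function(j) {
        code <- gm@calls[i, j]
        if (is.na(code)) c("0", "0")
        else alle(code, mk$allele_a[j], mk$allele_b[j])
      }))
      sex <- c(M = "1", F = "2", U = "0")[gm@individuals$sex[i]]
      paste(c("FAM", gm@individuals$id[i], "0", "0", sex, "-9", al),
            collapse = " ")
    }, character(1))
    writeLines(lines, path)
    map <- data.frame(chr = ifelse(mk$is_autosomal, mk$chromosome, "XY"),
                      id = mk$marker_id, cm = 0,
                      pos = seq_len(nrow(mk)))
    mapPath <- if (grepl("\\.ped$", path)) sub("\\.ped$", ".map", path)
               else paste0(path, ".map")
    utils::write.table(map, mapPath, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  } else {
    keep <- mk$is_autosomal
    mkv <- mk[keep, , drop = FALSE]
    gt <- t(apply(gm@calls[, keep, drop = FALSE], 1, function(row)
      c(AA = "0/0", AB = "0/1", BB = "1/1")[row]))
    gt[is.na(gt)] <- "./."
    if (nrow(gm@calls) == 1L) gt <- matrix(gt, nrow = 1L)
    fix <- cbind(CHROM = mkv$chromosome, POS = as.character(seq_len(nrow(mkv))),
                 ID = mkv$marker_id, REF = mkv$allele_a, ALT = mkv$allele_b,
                 QUAL = ".", FILTER = ".", INFO = ".")
    gtm <- cbind(FORMAT = "GT", t(gt))
    colnames(gtm) <- c("FORMAT", gm@individuals$id)
    rownames(gtm) <- NULL
    v <- new("vcfR",
             meta = c("##fileformat=VCFv4.2",
                      "##source=wisentpanel",
                      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
             fix = fix, gt = gtm)
    if (!grepl("\\.gz$", path)) path <- paste0(path, ".gz")
    vcfR::write.vcf(v, file = path)   # gzip-compressed VCF
  }
  invisible(path)
}

#' Read the native genotype-matrix CSV
#'
#' @param path file written by [writeGenotypeMatrix()] with
#'   `format = "csv"`.
#' @param markers marker definition table used when writing.
#' @return A [GenotypeCalls-class].
#' @export
readGenotypeMatrix <- function(path, markers = defaultPanel()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE, colClasses = "character")
  if (nrow(df) == 0L) stop("no records in genotype matrix", call. = FALSE)
  mcols <- setdiff(names(df), c("id", "species", "line", "sex"))
  unknown <- setdiff(mcols, markers$marker_id)
  if (length(unknown))
    stop("unknown marker id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  markers <- markers[match(mcols, markers$marker_id), , drop = FALSE]
  calls <- vapply(seq_along(mcols), function(j)
    vapply(seq_len(nrow(df)), function(i)
      .parseCall(df[[mcols[j]]][i], markers$allele_a[j],
                 markers$allele_b[j], marker = mcols[j],
                 sample = df$id[i]), character(1)),
    character(nrow(df)))
  if (nrow(df) == 1L) calls <- matrix(calls, nrow = 1L)
  colnames(calls) <- mcols
  makeGenotypeCalls(calls, markers,
                    individuals = df[, c("id", "species", "line", "sex")])
}
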