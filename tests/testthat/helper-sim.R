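# Shared fixtures: a tiny marker table, quick constructors for genotype
# and replicate objects, and a direct two-population genotype sampler.

tinyPanel <- function(nAuto = 4, withSex = FALSE) {
  pairs <- matrix(c("A", "G", "C", "T", "A", "C", "G", "T"),
                  ncol = 2, byrow = TRUE)
  p <- data.frame(
    marker_id = sprintf("M%02d", seq_len(nAuto)),
    chromosome = as.character(rep_len(1:29, nAuto)),
    allele_a = pairs[rep_len(1:4, nAuto), 1],
    allele_b = pairs[rep_len(1:4, nAuto), 2],
    is_autosomal = TRUE,
    individualisation = TRUE, parentage_diversity = TRUE,
    line_discrimination = FALSE, sex = FALSE, cross_species = FALSE,
    posthitis_meta = FALSE, stringsAsFactors = FALSE)
  if (withSex)
    p <- rbind(p, data.frame(
      marker_id = "SEXM", chromosome = "XY-homolog", allele_a = "X",
      allele_b = "Y", is_autosomal = FALSE, individualisation = FALSE,
      parentage_diversity = FALSE, line_discrimination = FALSE,
      sex = TRUE, cross_species = FALSE, posthitis_meta = FALSE,
      stringsAsFactors = FALSE))
  p
}

# genotype matrix from a character matrix of codes
makeGm <- function(codes, panel = tinyPanel(ncol(codes)), line = "U",
                   sex = "U", species = "B. bonasus", ids = NULL) {
  if (is.null(ids)) ids <- sprintf("ind%02d", seq_len(nrow(codes)))
  colnames(codes) <- panel$marker_id
  makeGenotypeCalls(codes, panel,
    individuals = data.frame(id = ids, species = species,
                             line = rep_len(line, nrow(codes)),
                             sex = rep_len(sex, nrow(codes)),
                             stringsAsFactors = FALSE))
}

# replicate calls from a replicate x marker matrix of codes
makeRc <- function(codes, panel = tinyPanel(ncol(codes)),
                   sampleId = "s1", type = "noninvasive",
                   individualId = NA_character_) {
  colnames(codes) <- panel$marker_id
  rownames(codes) <- paste0("rep", seq_len(nrow(codes)))
  new("ReplicateCalls", sampleId = sampleId, individualId = individualId,
      sampleType = type, calls = codes)
}

# direct two-group Hardy-Weinberg sampler with per-locus Nei FST ~ fst;
# used where the clustering / FST machinery needs clean, unpedigreed data
simTwoPop <- function(seed, n = 60, L = 18, fst = 0.1, hybrids = 0) {
  set.seed(seed)
  pbar <- pmin(pmax(stats::rbeta(L, 2, 2), 0.15), 0.85)
  d <- sqrt(fst * pbar * (1 - pbar))
  p1 <- pmin(pmax(pbar - d, 0.01), 0.99)
  p2 <- pmin(pmax(pbar + d, 0.01), 0.99)
  draw <- function(p, n) matrix(
    c("AA", "AB", "BB")[stats::rbinom(n * L, 2, rep(p, each = n)) + 1L],
    n, L)
  calls <- rbind(draw(p1, n), draw(p2, n))
  lines <- rep(c("LL", "LC"), each = n)
  if (hybrids > 0) {
    a1 <- matrix(stats::rbinom(hybrids * L, 1, rep(p1, each = hybrids)),
                 hybrids, L)
    a2 <- matrix(stats::rbinom(hybrids * L, 1, rep(p2, each = hybrids)),
                 hybrids, L)
    calls <- rbind(calls, matrix(c("AA", "AB", "BB")[a1 + a2 + 1L],
                                 hybrids, L))
    lines <- c(lines, rep("U", hybrids))
  }
  panel <- tinyPanel(L)
  panel$line_discrimination <- TRUE
  makeGm(calls, panel, line = lines,
         ids = sprintf("i%03d", seq_len(nrow(calls))))
}

# small deterministic pedigree table builder
pedFromTable <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE)
  on.exit(unlink(f))
  readPedigree(f)
}
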