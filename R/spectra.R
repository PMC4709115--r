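# SFS construction: SNP orientation and filtering, hypergeometric
# projection, folding, diversity summaries, flat-file I/O.

.amkLog <- function(...) {
  if (isTRUE(getOption("adaptiveMK.verbose", FALSE))) message(sprintf(...))
  invisible(NULL)
}

#' Orient SNPs with the outgroup and filter unusable sites
#'
#' Keeps bi-allelic SNPs whose outgroup state is a single nucleotide equal
#' to one of the two focal alleles; the derived allele is the focal allele
#' not matching the outgroup. Tri-/tetra-allelic SNPs and SNPs with a
#' missing, polymorphic, or third-state outgroup are discarded. Per-reason
#' discard counts are attached as the \code{"filtered"} attribute and
#' logged when \code{options(adaptiveMK.verbose = TRUE)}.
#'
#' @param snps a data.frame (or list of rows) with columns
#'   \code{site_class} (\code{"synonymous"} or \code{"non-synonymous"}),
#'   \code{alleles} (character like \code{"A:3,G:5"}) and
#'   \code{outgroup_state} (a nucleotide, \code{"polymorphic"} or
#'   \code{"missing"}). See [readSNPRecords()].
#' @return A data.frame with columns \code{derived_count},
#'   \code{genotyped_chrom} and \code{site_class}, one row per retained
#'   SNP, plus attribute \code{"filtered"} (named integer vector of
#'   discard counts by reason).
#' @examples
#' snps <- data.frame(
#'   site_class = c("synonymous", "non-synonymous", "synonymous"),
#'   alleles = c("A:3,G:5", "A:3,G:5", "A:2,G:3,T:3"),
#'   outgroup_state = c("G", "C", "A"))
#' orientAndFilter(snps)  # only the first SNP survives (derived count 3)
#' @export
orientAndFilter <- function(snps) {
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  stopifnot(all(c("site_class", "alleles", "outgroup_state") %in% names(snps)))
  reasons <- c(outgroup_missing = 0L, outgroup_polymorphic = 0L,
               multi_allelic = 0L, outgroup_third_state = 0L,
               monomorphic = 0L)
  out <- vector("list", nrow(snps))
  for (k in seq_len(nrow(snps))) {
    spec <- strsplit(strsplit(snps$alleles[k], ",", fixed = TRUE)[[1]], ":",
                     fixed = TRUE)
    states <- vapply(spec, `[`, "", 1L)
    counts <- as.numeric(vapply(spec, `[`, "", 2L))
    og <- snps$outgroup_state[k]
    if (length(states) < 2L) { reasons["monomorphic"] <- reasons["monomorphic"] + 1L; next }
    if (length(states) > 2L) { reasons["multi_allelic"] <- reasons["multi_allelic"] + 1L; next }
    if (og == "missing") { reasons["outgroup_missing"] <- reasons["outgroup_missing"] + 1L; next }
    if (og == "polymorphic") { reasons["outgroup_polymorphic"] <- reasons["outgroup_polymorphic"] + 1L; next }
    hit <- match(og, states)
    if (is.na(hit)) { reasons["outgroup_third_state"] <- reasons["outgroup_third_state"] + 1L; next }
    derived <- counts[-hit]
    out[[k]] <- data.frame(derived_count = as.integer(derived),
                           genotyped_chrom = as.integer(sum(counts)),
                           site_class = snps$site_class[k],
                           stringsAsFactors = FALSE)
  }
  kept <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(kept))
    kept <- data.frame(derived_count = integer(), genotyped_chrom = integer(),
                       site_class = character(), stringsAsFactors = FALSE)
  .amkLog("orientAndFilter: kept %d of %d SNPs (%s)", nrow(kept), nrow(snps),
          paste(sprintf("%s: %d", names(reasons), reasons), collapse = ", "))
  attr(kept, "filtered") <- reasons
  kept
}

#' Hypergeometric projection of SNPs onto a common sample size
#'
#' Each SNP observed at derived count i among 2n genotyped chromosomes
#' contributes to class j of the target spectrum (2m chromosomes) the
#' hypergeometric weight \eqn{C(i,j) C(2n-i, 2m-j) / C(2n, 2m)}, i.e. the
#' probability that a random subsample of 2m chromosomes contains j copies
#' of the derived allele. Weight landing on j = 0 or j = 2m (monomorphic
#' subsamples) is dropped, not renormalized, mirroring the loss of
#' observable polymorphism. SNPs genotyped in fewer than \code{targetChrom}
#' chromosomes are discarded (counted in the \code{"dropped_snps"}
#' attribute). Projected counts are real-valued.
#'
#' @param snps data.frame with columns \code{derived_count} and
#'   \code{genotyped_chrom} (e.g. one site class of [orientAndFilter()]
#'   output).
#' @param targetChrom even target number of chromosomes (2m >= 2).
#' @return An unfolded [Spectrum-class] at \code{nChrom = targetChrom},
#'   with attributes \code{"dropped_snps"} (SNPs below the target size) and
#'   \code{"monomorphic_weight"} (total weight projected onto classes 0 and
#'   2m).
#' @examples
#' snp <- data.frame(derived_count = 2, genotyped_chrom = 8)
#' sfsCounts(projectSFS(snp, 4))  # 40/70, 15/70, 0
#' @export
projectSFS <- function(snps, targetChrom) {
  targetChrom <- as.integer(targetChrom)
  if (targetChrom < 2L) stop("targetChrom must be >= 2")
  counts <- numeric(targetChrom - 1L)
  dropped <- 0L
  mono <- 0
  for (k in seq_len(nrow(snps))) {
    i <- snps$derived_count[k]
    n2 <- snps$genotyped_chrom[k]
    if (n2 < targetChrom) { dropped <- dropped + 1L; next }
    j <- 0:targetChrom
    w <- dhyper(j, i, n2 - i, targetChrom)
    counts <- counts + w[2:targetChrom]
    mono <- mono + w[1L] + w[targetChrom + 1L]
  }
  .amkLog("projectSFS: projected %d SNPs to 2m = %d (%d dropped below target)",
          nrow(snps) - dropped, targetChrom, dropped)
  out <- Spectrum(counts, nChrom = targetChrom, folded = FALSE)
  attr(out, "dropped_snps") <- dropped
  attr(out, "monomorphic_weight") <- mono
  out
}

#' Default diploid subsample size for projection
#'
#' Rule mapping the number of sampled diploid individuals to the projection
#' subsample size n (so the target chromosome number is 2n): n = 4 for 4-5
#' individuals, 5 for 6, 6 for 7-8, and 7 for more than 8.
#'
#' @param totalIndividuals number of sampled diploid individuals (>= 4).
#' @return Integer n; use \code{2 * n} as \code{targetChrom} in
#'   [projectSFS()].
#' @examples
#' defaultTargetSize(5)  # 4
#' defaultTargetSize(8)  # 6
#' defaultTargetSize(9)  # 7
#' @export
defaultTargetSize <- function(totalIndividuals) {
  totalIndividuals <- as.integer(totalIndividuals)
  if (totalIndividuals < 4L) stop("at least 4 individuals are required")
  if (totalIndividuals <= 5L) 4L
  else if (totalIndividuals == 6L) 5L
  else if (totalIndividuals <= 8L) 6L
  else 7L
}

#' Fold an unfolded site frequency spectrum
#'
#' Merges mirror derived-allele classes: folded class k holds
#' unfolded[k] + unfolded[2n-k] for k < n, and folded class n holds
#' unfolded[n]. Folding removes all dependence on ancestral-state
#' orientation.
#'
#' @param sfs an unfolded [Spectrum-class].
#' @return A folded [Spectrum-class] with n = nChrom/2 classes.
#' @examples
#' sfsCounts(foldSFS(Spectrum(c(3, 2, 1), 4)))  # 4, 2
#' @export
foldSFS <- function(sfs) {
  stopifnot(is(sfs, "Spectrum"))
  if (sfs@folded) stop("spectrum is already folded")
  n2 <- sfs@nChrom
  n <- n2 %/% 2L
  u <- sfs@counts
  f <- numeric(n)
  for (k in seq_len(n - 1L)) f[k] <- u[k] + u[n2 - k]
  f[n] <- u[n]
  Spectrum(f, nChrom = n2, folded = TRUE)
}

#' Per-site nucleotide diversity from an SFS
#'
#' Unbiased pairwise-difference estimator: each SNP in class i contributes
#' \eqn{2 i (2n - i) / (2n (2n - 1))} heterozygosity. The formula applies
#' unchanged to folded spectra because i(2n - i) is symmetric under
#' i -> 2n - i.
#'
#' @param sfs a [Spectrum-class] (folded or unfolded).
#' @param nSites positive number of sites surveyed.
#' @return Non-negative per-site diversity (pi).
#' @examples
#' piFromSFS(Spectrum(c(1, 0, 0), 4), 100)  # 0.005
#' @export
piFromSFS <- function(sfs, nSites) {
  stopifnot(is(sfs, "Spectrum"))
  if (nSites <= 0) stop("nSites must be positive")
  n2 <- as.numeric(sfs@nChrom)
  i <- seq_along(sfs@counts)
  sum(sfs@counts * 2 * i * (n2 - i) / (n2 * (n2 - 1))) / nSites
}

# --- flat-file I/O -----------------------------------------------------

#' Read polymorphism/divergence datasets from a flat file
#'
#' Tab-separated format, one dataset per data line:
#' \preformatted{#sfs_format v1 <unfolded|folded>
#' label  2n  L_N  PN_1..PN_k  L_S  PS_1..PS_k  Ldiv_N  D_N  Ldiv_S  D_S}
#' with k = 2n-1 (unfolded) or n (folded). Fields may be real-valued
#' (projection produces fractional counts).
#'
#' @param path file path.
#' @return A list of [PolyDivData-class] objects.
#' @seealso [writeDataset()]
#' @export
readDataset <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty dataset file: ", path)
  hdr <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  if (length(hdr) != 3L || hdr[1] != "#sfs_format" || hdr[2] != "v1" ||
      !hdr[3] %in% c("unfolded", "folded"))
    stop("line 1: malformed header (expected '#sfs_format v1 <unfolded|folded>')")
  folded <- hdr[3] == "folded"
  out <- list()
  for (ln in seq_along(lines)[-1]) {
    txt <- trimws(lines[ln])
    if (!nzchar(txt) || startsWith(txt, "#")) next
    f <- strsplit(txt, "\t", fixed = TRUE)[[1]]
    label <- f[1]
    num <- suppressWarnings(as.numeric(f[-1]))
    if (any(is.na(num)))
      stop(sprintf("line %d: non-numeric field", ln))
    n2 <- as.integer(num[1])
    if (n2 < 2L || n2 %% 2L != 0L)
      stop(sprintf("line %d: 2n must be a positive even integer", ln))
    k <- if (folded) n2 %/% 2L else n2 - 1L
    if (length(num) != 1L + 2L * (k + 1L) + 4L)
      stop(sprintf("line %d: expected %d fields after the label for 2n = %d (%s), got %d",
                   ln, 1L + 2L * (k + 1L) + 4L, n2, hdr[3], length(num)))
    LN <- num[2]; PN <- num[3:(2L + k)]
    LS <- num[3L + k]; PS <- num[(4L + k):(3L + 2L * k)]
    rest <- num[(4L + 2L * k):(7L + 2L * k)]
    if (any(c(PN, PS, rest[2], rest[4]) < 0))
      stop(sprintf("line %d: negative counts", ln))
    out[[length(out) + 1L]] <- PolyDivData(
      label = label,
      sfsNonsyn = Spectrum(PN, n2, folded),
      sfsSyn = Spectrum(PS, n2, folded),
      DN = rest[2], DS = rest[4], LN = LN, LS = LS,
      LdivN = rest[1], LdivS = rest[3])
  }
  out
}

#' Write polymorphism/divergence datasets to a flat file
#'
#' @param datasets a [PolyDivData-class] or list thereof (all sharing the
#'   folded flag).
#' @param path file path.
#' @return Invisibly, the path.
#' @seealso [readDataset()]
#' @export
writeDataset <- function(datasets, path) {
  if (is(datasets, "PolyDivData")) datasets <- list(datasets)
  folded <- vapply(datasets, isFolded, TRUE)
  if (length(unique(folded)) != 1L)
    stop("all datasets in one file must share the folded flag")
  fmt <- function(x) sprintf("%.12g", x)
  lines <- c(sprintf("#sfs_format v1 %s", if (folded[1]) "folded" else "unfolded"),
             vapply(datasets, function(d) {
               paste(c(d@label, fmt(nChrom(d)), fmt(d@LN),
                       fmt(d@sfsNonsyn@counts), fmt(d@LS),
                       fmt(d@sfsSyn@counts), fmt(d@LdivN), fmt(d@DN),
                       fmt(d@LdivS), fmt(d@DS)), collapse = "\t")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read SNP records
#'
#' Tab-separated, one SNP per line:
#' \code{site_class  allele:count[,allele:count...]  outgroup_state}.
#' Lines starting with \code{#} are skipped.
#'
#' @param path file path.
#' @return A data.frame with columns \code{site_class}, \code{alleles},
#'   \code{outgroup_state}, suitable for [orientAndFilter()].
#' @export
readSNPRecords <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) != 3L)
  if (length(bad))
    stop(sprintf("malformed SNP record (expected 3 tab-separated fields) at record %d",
                 bad[1]))
  data.frame(site_class = vapply(f, `[`, "", 1L),
             alleles = vapply(f, `[`, "", 2L),
             outgroup_state = vapply(f, `[`, "", 3L),
             stringsAsFactors = FALSE)
}
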