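test_that("orientation keeps bi-allelic SNPs matching the outgroup and counts discards", {
  snps <- data.frame(
    site_class = c("synonymous", "non-synonymous", "synonymous",
                   "synonymous", "non-synonymous", "synonymous"),
    alleles = c("A:3,G:5",        # outgroup G -> derived A, count 3
                "A:3,G:5",        # outgroup C (third state) -> discard
                "A:2,G:3,T:3",    # tri-allelic -> discard
                "C:1,T:7",        # outgroup polymorphic -> discard
                "C:4,T:4",        # outgroup missing -> discard
                "A:2,C:6"),       # outgroup A -> derived C, count 6
    outgroup_state = c("G", "C", "A", "polymorphic", "missing", "A"))
  out <- orientAndFilter(snps)
  expect_equal(nrow(out), 2L)
  expect_equal(out$derived_count, c(3L, 6L))
  expect_equal(out$genotyped_chrom, c(8L, 8L))
  filt <- attr(out, "filtered")
  expect_equal(unname(filt[c("outgroup_third_state", "multi_allelic",
                             "outgroup_polymorphic", "outgroup_missing")]),
               c(1L, 1L, 1L, 1L))
})

test_that("hypergeometric projection weights match direct enumeration", {
  # one SNP, i = 2 of 2n = 8, projected to 2m = 4
  w <- sfsCounts(projectSFS(data.frame(derived_count = 2,
                                       genotyped_chrom = 8), 4))
  oracle <- sapply(1:3, function(j)
    choose(2, j) * choose(6, 4 - j) / choose(8, 4))
  expect_equal(w, oracle, tolerance = 1e-12)
  expect_equal(w, c(40, 15, 0) / 70, tolerance = 1e-12)
  # dropped monomorphic weight is C(6,4)/C(8,4)
  expect_equal(attr(projectSFS(data.frame(derived_count = 2,
                                          genotyped_chrom = 8), 4),
                    "monomorphic_weight"), 15 / 70, tolerance = 1e-12)
})

test_that("projection to a SNP's own sample size is the identity", {
  s <- projectSFS(data.frame(derived_count = 5, genotyped_chrom = 10), 10)
  expect_equal(sfsCounts(s), as.numeric(seq_len(9) == 5))
})

test_that("SNPs genotyped below the target size are discarded, target < 2 errors", {
  s <- projectSFS(data.frame(derived_count = c(2, 3),
                             genotyped_chrom = c(6, 8)), 8)
  expect_equal(attr(s, "dropped_snps"), 1L)
  expect_equal(sum(sfsCounts(s)), 1)     # only the 2n = 8 SNP, no mass lost
  expect_error(projectSFS(data.frame(derived_count = 1,
                                     genotyped_chrom = 4), 1),
               "targetChrom")
})

test_that("projection conserves mass per SNP up to the dropped monomorphic classes", {
  set.seed(5)
  for (k in 1:25) {
    n2 <- 2L * sample(3:12, 1)
    i <- sample(seq_len(n2 - 1L), 1)
    m2 <- 2L * sample(2:(n2 %/% 2L), 1)
    s <- projectSFS(data.frame(derived_count = i, genotyped_chrom = n2), m2)
    expect_equal(sum(sfsCounts(s)) + attr(s, "monomorphic_weight"), 1,
                 tolerance = 1e-12)
  }
})

test_that("projection commutes with the neutral 1/i expectation", {
  n2 <- 20L; m2 <- 8L
  proj <- rowsum(do.call(rbind, lapply(seq_len(n2 - 1L), function(i)
    (1 / i) * sfsCounts(projectSFS(data.frame(derived_count = i,
                                              genotyped_chrom = n2), m2)))),
    rep(1, n2 - 1L))
  expect_equal(as.numeric(proj) / proj[1],
               (1 / seq_len(m2 - 1L)) / 1, tolerance = 1e-9)
})

test_that("default projection size follows the sample-size rule", {
  expect_equal(sapply(4:10, defaultTargetSize), c(4, 4, 5, 6, 6, 7, 7))
  expect_error(defaultTargetSize(3), "at least 4")
})

test_that("folding merges mirror classes and conserves totals", {
  expect_equal(sfsCounts(foldSFS(Spectrum(c(3, 2, 1), 4))), c(4, 2))
  expect_equal(sfsCounts(foldSFS(Spectrum(c(5, 0, 0, 0, 5), 6))),
               c(10, 0, 0))
  set.seed(8)
  u <- Spectrum(rpois(9, 20), 10)
  expect_equal(sum(sfsCounts(foldSFS(u))), sum(sfsCounts(u)))
  expect_error(foldSFS(foldSFS(u)), "already folded")
})

test_that("pi matches the pairwise-difference closed form and the pairing identity", {
  expect_equal(piFromSFS(Spectrum(c(1, 0, 0), 4), 100), 0.005)
  expect_equal(piFromSFS(Spectrum(numeric(7), 8), 50), 0)
  u <- Spectrum(c(1, 0, 0), 4)
  expect_equal(piFromSFS(u, 100), piFromSFS(foldSFS(u), 100))
  set.seed(3)
  u2 <- Spectrum(rpois(11, 7), 12)
  expect_equal(piFromSFS(u2, 1e3), piFromSFS(foldSFS(u2), 1e3))
  expect_error(piFromSFS(u, 0), "positive")
})

test_that("dataset files round-trip and malformed input is rejected with line numbers", {
  sc <- refScenario("gamma", LN = 1e4, LS = 5e3)
  ds <- lapply(1:3, function(r) sampleDataset(sc, r, seed = 9))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeDataset(ds, path)
  back <- readDataset(path)
  expect_length(back, 3)
  for (k in 1:3) {
    expect_equal(sfsCounts(back[[k]]@sfsNonsyn), sfsCounts(ds[[k]]@sfsNonsyn))
    expect_equal(sfsCounts(back[[k]]@sfsSyn), sfsCounts(ds[[k]]@sfsSyn))
    expect_equal(back[[k]]@DN, ds[[k]]@DN)
    expect_equal(back[[k]]@LdivS, ds[[k]]@LdivS)
    expect_false(isFolded(back[[k]]))
  }
  # folded flag honoured on read
  fd <- lapply(ds, function(d) PolyDivData(d@label, foldSFS(d@sfsNonsyn),
                                           foldSFS(d@sfsSyn), d@DN, d@DS,
                                           d@LN, d@LS, d@LdivN, d@LdivS))
  writeDataset(fd, path)
  expect_true(isFolded(readDataset(path)[[1]]))
  # wrong SFS length
  lines <- readLines(path)
  bad <- strsplit(lines[2], "\t")[[1]]
  writeLines(c(lines[1], paste(bad[-3], collapse = "\t")), path)
  expect_error(readDataset(path), "line 2")
  writeLines(c("#sfs_format v2 unfolded", lines[2]), path)
  expect_error(readDataset(path), "header")
})

test_that("SNP record files are parsed and validated", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment",
               "synonymous\tA:3,G:5\tG",
               "non-synonymous\tC:1,T:7\tmissing"), path)
  rec <- readSNPRecords(path)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$outgroup_state, c("G", "missing"))
  writeLines("synonymous\tA:3,G:5", path)
  expect_error(readSNPRecords(path), "malformed")
})
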