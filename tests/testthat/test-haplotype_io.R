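test_that("bundled haplotype table loads with the documented dimensions", {
  ds <- fixture_ds()
  expect_equal(nrow(ds$alleles), 24)
  expect_equal(nrow(ds$sites), 37)
  expect_equal(length(unique(ds$sites$label)), 36)  # 1-2 is one event
  expect_equal(sum(ds$counts), 160)
  expect_equal(ds$segment_length_bp, 11024L)
  afr <- match(AFR(), ds$populations$name)
  expect_equal(sum(ds$counts[, afr]), 111)
  expect_equal(sum(ds$counts[, -afr]), 49)
  # Ethiopian column: n = 15 with 8 copies of H12
  eth <- ds$counts[, "Ethiopian"]
  expect_equal(sum(eth), 15)
  expect_equal(unname(eth["H12"]), 8)
  # 21 haplotypes observed in sub-Saharan Africa, 4 outside
  expect_equal(sum(rowSums(ds$counts[, afr]) > 0), 21)
  expect_equal(sum(ds$counts[, -afr] > 0), 4)
})

test_that("write/read round trip is lossless", {
  ds <- fixture_ds()
  f <- tempfile(fileext = ".tsv")
  write_haplotype_table(ds, f)
  ds2 <- read_haplotype_table(f)
  expect_equal(ds2$sites, ds$sites)
  expect_equal(ds2$alleles, ds$alleles)
  expect_equal(ds2$counts, ds$counts)
  expect_equal(ds2$populations, ds$populations)
  expect_equal(ds2$segment_length_bp, ds$segment_length_bp)
  expect_equal(ds2$outgroups, ds$outgroups)
  expect_equal(ds2$archaics, ds$archaics)
})

test_that("reader rejects malformed tables with informative errors", {
  ds <- fixture_ds()
  f <- tempfile(fileext = ".tsv")
  write_haplotype_table(ds, f)
  lines <- readLines(f)
  # duplicated position
  bad <- lines
  pos <- strsplit(bad[2], "\t")[[1]]
  pos[3] <- pos[2]
  bad[2] <- paste(pos, collapse = "\t")
  writeLines(bad, f)
  expect_error(read_haplotype_table(f), "duplicated")
  # invalid allele symbol
  bad <- lines
  h1 <- strsplit(bad[grep("^H1\t", bad)[1]], "\t")[[1]]
  h1[2] <- "X"
  bad[grep("^H1\t", bad)[1]] <- paste(h1, collapse = "\t")
  writeLines(bad, f)
  expect_error(read_haplotype_table(f), "allele")
  # negative count
  bad <- lines
  h1 <- strsplit(bad[grep("^H1\t", bad)[1]], "\t")[[1]]
  h1[length(h1)] <- "-1"
  bad[grep("^H1\t", bad)[1]] <- paste(h1, collapse = "\t")
  writeLines(bad, f)
  expect_error(read_haplotype_table(f), "count")
})

test_that("ancestral-allele rule follows chimp, then two-outgroup agreement", {
  # chimp match wins
  expect_equal(ancestral_rule(c("G", "A"), chimp = "G"), "G")
  # chimp missing: two other outgroups agreeing on a human allele
  expect_equal(ancestral_rule(c("C", "T"), chimp = NA,
                              others = c("T", "T")), "T")
  # one agreeing outgroup is not enough
  expect_true(is.na(ancestral_rule(c("C", "T"), chimp = NA,
                                   others = c("T", NA))))
  # chimp allele absent from humans falls through to the others
  expect_equal(ancestral_rule(c("C", "T"), chimp = "G",
                              others = c("T", "T")), "T")
  # all outgroups missing: unresolved, no error
  expect_true(is.na(ancestral_rule(c("C", "T"), chimp = NA,
                                   others = c(NA, NA))))
  # monomorphic human site
  expect_equal(ancestral_rule("C", chimp = "C"), "C")
})

test_that("polarization is idempotent and row-order independent", {
  ds <- fixture_ds()
  pol1 <- infer_ancestral_alleles(ds)
  expect_equal(pol1$sites$ancestral, ds$sites$ancestral)
  expect_length(attr(pol1, "unresolved"), 0)
  perm <- sample(nrow(ds$alleles))
  ds2 <- ds
  ds2$alleles <- ds$alleles[perm, , drop = FALSE]
  ds2$counts <- ds$counts[perm, , drop = FALSE]
  pol2 <- infer_ancestral_alleles(ds2)
  expect_equal(pol2$sites$ancestral, pol1$sites$ancestral)
  expect_equal(infer_ancestral_alleles(pol1)$sites$ancestral,
               pol1$sites$ancestral)
})

test_that("binary encoding has the documented segregating-site counts", {
  ds <- fixture_ds()
  ba <- as_binary_matrix(ds, AFR())
  expect_equal(ba$n, 111)
  expect_equal(sum(ba$segregating), 34)
  bn <- as_binary_matrix(ds, "NonAfrican")
  expect_equal(bn$n, 49)
  expect_equal(sum(bn$segregating), 3)
  expect_error(as_binary_matrix(ds, character(0)), "empty sample")
  expect_error(as_binary_matrix(ds, "Atlantis"), "unknown")
})

test_that("unpolarized sites block binary encoding with a site list", {
  ds <- fixture_ds()
  ds$sites$ancestral[5] <- NA
  expect_error(as_binary_matrix(ds),
               as.character(ds$sites$position[5]))
})

test_that("expanding to chromosomes and re-collapsing recovers the counts", {
  ds <- fixture_ds()
  bm <- as_binary_matrix(ds)
  m <- expand_binary_matrix(bm)
  expect_equal(nrow(m), 160)
  key <- apply(m, 1, paste, collapse = "")
  key0 <- apply(bm$x, 1, paste, collapse = "")
  expect_equal(sort(as.integer(table(key))),
               sort(bm$counts))
  expect_setequal(unique(key), key0)
})

test_that("VCF export is readable and faithful", {
  skip_if_not_installed("vcfR")
  ds <- fixture_ds()
  f <- tempfile(fileext = ".vcf")
  write_vcf(ds, f)
  v <- suppressWarnings(vcfR::read.vcfR(f, verbose = FALSE))
  expect_equal(nrow(v@fix), 37)
  expect_equal(as.integer(v@fix[, "POS"]), ds$sites$position)
  expect_equal(unname(v@fix[, "REF"]), ds$sites$ancestral)
  # derived-allele counts at the three non-African segregating sites
  gt <- v@gt[, -1]
  expect_equal(ncol(gt), 160)
  dc <- rowSums(gt == "1")
  bm <- as_binary_matrix(ds)
  # position 63569727 (mutation 19): carried by 61 chromosomes worldwide
  # (H12 x55, H13, H14, H15, H16 x2, H24)
  expect_equal(unname(dc[ds$sites$position == 63569727]), 61)
})

test_that("FASTA export round-trips sequences over polymorphic positions", {
  ds <- fixture_ds()
  f <- tempfile(fileext = ".fa")
  write_fasta(ds, f)
  dna <- ape::read.FASTA(f)
  expect_length(dna, 24)
  m <- toupper(do.call(rbind, lapply(as.character(dna), identity)))
  expect_equal(unname(m), unname(ds$alleles))
})
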