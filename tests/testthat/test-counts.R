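test_that("amino-acid counting excludes ambiguous residues and stops", {
  r <- count_amino_acids("KKR")
  expect_equal(r$counts[["K"]], 2L)
  expect_equal(r$counts[["R"]], 1L)
  expect_equal(r$total, 3L)

  r <- count_amino_acids("XXXX")
  expect_true(all(r$counts == 0L))
  expect_equal(r$total, 0L)

  r <- count_amino_acids("ACDEFGHIKLMNPQRSTVWY")
  expect_true(all(r$counts == 1L))
  expect_equal(r$total, 20L)

  err <- tryCatch(count_amino_acids("MKB"), error = identity)
  expect_s3_class(err, "cogbias_parse_error")
  expect_match(conditionMessage(err), "position 3")
})

test_that("nucleotide counting excludes N from counts and total", {
  r <- count_nucleotides("ATGC")
  expect_equal(unname(r$counts[c("A", "T", "G", "C")]), c(1L, 1L, 1L, 1L))
  expect_equal(r$total, 4L)
  r <- count_nucleotides("AANN")
  expect_equal(r$counts[["A"]], 2L)
  expect_equal(r$total, 2L)
  r <- count_nucleotides("")
  expect_equal(r$total, 0L)
  expect_error(count_nucleotides("ACGU"), class = "cogbias_parse_error")
})

test_that("codon counting reads frame-0 triplets with the exclusion rules", {
  r <- count_codons("ATGAAACGA")
  expect_equal(r$counts[["ATG"]], 1L)
  expect_equal(r$counts[["AAA"]], 1L)
  expect_equal(r$counts[["CGA"]], 1L)
  expect_equal(r$total, 3L)

  r <- count_codons("ATGAA")                  # trailing 'AA' dropped
  expect_equal(r$counts[["ATG"]], 1L)
  expect_equal(r$total, 1L)

  r <- count_codons("ATGNNNAAA")              # N-triplet excluded
  expect_equal(r$total, 2L)
  expect_equal(r$counts[["ATG"]] + r$counts[["AAA"]], 2L)

  r <- count_codons("ATGTAA")                 # stop counted, sense total not
  expect_equal(r$counts[["TAA"]], 1L)
  expect_equal(r$total, 2L)
  expect_equal(r$total_sense, 1L)
})

test_that("GC percentage follows 100*(G+C)/(A+C+G+T)", {
  expect_equal(gc_fraction(c(A = 1, T = 1, G = 1, C = 1)), 50)
  expect_equal(gc_fraction(c(A = 0, T = 0, G = 3, C = 1)), 100)
  expect_equal(gc_fraction(c(A = 7, T = 1, G = 1, C = 1)), 20)
  expect_equal(gc_fraction(count_nucleotides("ATGC")), 50)
  expect_error(gc_fraction(c(A = 0, T = 0, G = 0, C = 0)),
               class = "cogbias_undefined_error")
})

test_that("counting is concatenation-additive", {
  set.seed(7)
  for (i in 1:20) {
    s1 <- paste(sample(c(AA20, "X"), sample(5:40, 1), TRUE), collapse = "")
    s2 <- paste(sample(c(AA20, "X"), sample(5:40, 1), TRUE), collapse = "")
    a <- count_amino_acids(s1); b <- count_amino_acids(s2)
    ab <- count_amino_acids(paste0(s1, s2))
    expect_identical(ab$counts, a$counts + b$counts)

    n1 <- paste(sample(c("A", "C", "G", "T", "N"), 3 * sample(2:20, 1), TRUE),
                collapse = "")
    n2 <- paste(sample(c("A", "C", "G", "T", "N"), 3 * sample(2:20, 1), TRUE),
                collapse = "")
    x <- count_nucleotides(n1); y <- count_nucleotides(n2)
    xy <- count_nucleotides(paste0(n1, n2))
    expect_identical(xy$counts, x$counts + y$counts)
    # codon additivity holds because nchar(n1) is a multiple of 3
    cx <- count_codons(n1); cy <- count_codons(n2)
    cxy <- count_codons(paste0(n1, n2))
    expect_identical(cxy$counts, cx$counts + cy$counts)
  }
})

test_that("3*codon_total equals nt_total on N-free CDS", {
  set.seed(8)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 3 * sample(5:50, 1), TRUE),
               collapse = "")
    expect_equal(3L * count_codons(s)$total, count_nucleotides(s)$total)
  }
})

test_that("codon counts map through the genetic code to amino-acid counts", {
  ds <- shared_sim()$ds
  code <- Biostrings::GENETIC_CODE
  cn <- ds$counts
  for (i in sample(nrow(ds$sequences), 10)) {
    codon_implied <- vapply(AA20, function(a) {
      sum(cn$codon[i, names(code)[code == a]])
    }, numeric(1))
    expect_equal(codon_implied, cn$aa[i, AA20], ignore_attr = TRUE)
  }
})

test_that("CDS/protein consistency checking flags mismatches only", {
  rec <- data.frame(organism_id = "o", protein_gi = "p",
                    aa_seq = "MK", nt_seq = "ATGAAATAA",
                    stringsAsFactors = FALSE)
  expect_equal(verify_cds_consistency(rec)$status, "consistent")

  rec$nt_seq <- "ATGGGG"
  expect_warning(rep <- verify_cds_consistency(rec), "mismatch")
  expect_equal(rep$status, "mismatch")
  expect_equal(rep$n_mismatch, 1L)
  expect_equal(rep$first_mismatch, 2L)

  rec$nt_seq <- ""
  expect_equal(verify_cds_consistency(rec)$status, "skipped")

  # ambiguous codons are not counted as mismatches
  rec$nt_seq <- "ATGNNN"
  expect_equal(verify_cds_consistency(rec)$status, "consistent")
})

test_that("count sidecar TSV round-trips the cached matrices", {
  ds <- load_toy()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts_tsv(ds, path)
  ds2 <- parse_nucocog_xml(toy_file("toy.xml"))
  ds2 <- read_counts_tsv(ds2, path)
  expect_equal(ds2$counts$aa, ds$counts$aa, ignore_attr = TRUE)
  expect_equal(ds2$counts$nt, ds$counts$nt, ignore_attr = TRUE)
  expect_equal(ds2$counts$codon, ds$counts$codon, ignore_attr = TRUE)
  expect_equal(ds2$counts$codon_total_sense, ds$counts$codon_total_sense)
})
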