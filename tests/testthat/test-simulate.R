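test_that("invalid bias specs are rejected", {
  expect_error(bias_spec(seq_len_codons = 5), class = "cogbias_usage_error")
  expect_error(bias_spec(enriched = list(list(cog_ids = "COG0001",
                                              features = "K", factor = 0))),
               class = "cogbias_usage_error")
  expect_error(bias_spec(enriched = list(list(cog_ids = "COG0001",
                                              features = "L", factor = 12))),
               class = "cogbias_usage_error")   # L mass would exceed 1
  expect_error(bias_spec(per_organism_gc = 1.2), class = "cogbias_usage_error")
  expect_error(bias_spec(per_organism_agr = 0.5,
                         ogt_model = list(slope = 1, intercept = 0, sigma = 0)),
               class = "cogbias_usage_error")
  # an extreme GC target is infeasible by synonymous-codon choice alone
  expect_error(generate_dataset(bias_spec(n_organisms = 2, n_cogs = 2,
                                          per_organism_gc = 0.05, seed = 1)),
               "infeasible", class = "cogbias_usage_error")
})

test_that("generation is deterministic: same seed, byte-identical bundle", {
  spec <- bias_spec(n_organisms = 3, n_cogs = 4, seq_len_codons = 30, seed = 77)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  g1 <- generate_dataset(spec)
  p1 <- write_fixture_bundle(g1$dataset, g1$ground_truth, d1)
  g2 <- generate_dataset(spec)
  p2 <- write_fixture_bundle(g2$dataset, g2$ground_truth, d2)
  expect_length(p1, 4L)                         # xml + taxonomy + traits + truth
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  # a different seed changes the sequences
  g3 <- generate_dataset(bias_spec(n_organisms = 3, n_cogs = 4,
                                   seq_len_codons = 30, seed = 78))
  expect_false(identical(g1$dataset$sequences$aa_seq,
                         g3$dataset$sequences$aa_seq))
})

test_that("every generated CDS translates exactly to its protein", {
  ds <- shared_sim()$ds
  rep <- verify_cds_consistency(ds)
  expect_true(all(rep$status == "consistent"))
})

test_that("generated bundle round-trips through the XML/TSV loaders", {
  gen <- shared_sim()
  dir <- withr::local_tempdir()
  paths <- write_fixture_bundle(gen$ds, gen$gt, dir)
  ds <- parse_nucocog_xml(paths["xml"])
  ds <- attach_taxonomy(ds, load_taxonomy(paths["taxonomy"]))
  ds <- attach_traits(ds, load_traits(paths["traits"]))
  expect_equal(nrow(ds$sequences), nrow(gen$ds$sequences))
  expect_true(ds$has_taxonomy && ds$has_traits)
  expect_setequal(ds$organisms$species, gen$ds$organisms$species)
  expect_equal(sort(ds$organisms$oxygen_class),
               sort(gen$ds$organisms$oxygen_class))
})

test_that("realized enrichment matches the requested factor within noise", {
  gen <- generate_dataset(bias_spec(
    n_organisms = 10, n_cogs = 20, seq_len_codons = 100,
    enriched = list(list(cog_ids = "COG0001", features = "K", factor = 2)),
    seed = 909))
  ds <- precompute_counts(gen$dataset)
  in_cog <- apsf(ds, which(ds$sequences$cog_id == "COG0001"),
                 "amino_acid", "K")$apsf / 100
  bg <- BACKGROUND_AA_FREQS[["K"]]
  n_res <- 10 * 100
  se <- sqrt(2 * bg * (1 - 2 * bg) / n_res)
  expect_lt(abs(in_cog - 2 * bg), 4 * se)
  # unenriched COGs stay at background
  out_cog <- apsf(ds, which(ds$sequences$cog_id == "COG0011"),
                  "amino_acid", "K")$apsf / 100
  expect_lt(abs(out_cog - bg), 4 * sqrt(bg * (1 - bg) / n_res))
})

test_that("realized pooled GC hits the per-organism target within 3 SD", {
  gen <- generate_dataset(bias_spec(n_organisms = 6, n_cogs = 15,
                                    seq_len_codons = 100,
                                    per_organism_gc = c(0.45, 0.45, 0.45,
                                                        0.54, 0.54, 0.54),
                                    seed = 31))
  ds <- precompute_counts(gen$dataset)
  for (i in seq_len(6)) {
    oid <- ds$organisms$organism_id[i]
    idx <- which(ds$sequences$organism_id == oid)
    n_nt <- sum(ds$counts$nt_total[idx])
    gc <- sum(ds$counts$nt[idx, c("G", "C")]) / n_nt
    target <- gen$ground_truth$organisms$gc_target[i]
    expect_lt(abs(gc - target), 3 * sqrt(target * (1 - target) / n_nt))
  }
})

test_that("noise-free OGT model puts AGR targets exactly on the line", {
  gen <- generate_dataset(bias_spec(
    n_organisms = 10, n_cogs = 10, seq_len_codons = 100,
    ogt_model = list(slope = 0.02, intercept = -0.2, sigma = 0), seed = 55))
  gt <- gen$ground_truth$organisms
  expect_equal(gt$agr_target, 0.02 * gt$ogt_celsius - 0.2, tolerance = 1e-12)
  # and realized AGR tracks the target within binomial sampling noise
  ds <- precompute_counts(gen$dataset)
  agr <- agr_fraction(ds) / 100
  expect_gt(cor(agr, gt$agr_target), 0.8)
})

test_that("fixture bundle writing fails cleanly on uncreatable directories", {
  blocker <- withr::local_tempfile()
  writeLines("x", blocker)                      # a file where a dir is needed
  gen <- shared_sim()
  expect_error(write_fixture_bundle(gen$ds, gen$gt, file.path(blocker, "sub")),
               class = "cogbias_io_error")
})
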