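test_that("APSF pools counts over the scope (length-weighted)", {
  ds <- make_aa_dataset(c("KKR", "KA"))
  r <- apsf(ds, feature_type = "amino_acid", features = "K")
  expect_equal(r$selected_feature_count, 3)
  expect_equal(r$total_feature_count, 5)
  expect_equal(r$apsf, 60)                       # pooled 3/5, not mean(2/3, 1/2)
  m <- apsf(ds, feature_type = "amino_acid", features = "K",
            mean_of_sequences = TRUE)
  expect_equal(m$apsf, 100 * mean(c(2 / 3, 1 / 2)))
})

test_that("APSF of the full residue alphabet is 100 on X-free scopes", {
  ds <- shared_sim()$ds
  r <- apsf(ds, feature_type = "amino_acid", features = AA20)
  expect_equal(r$apsf, 100)
  # and the 20 single-feature APSFs sum to 100
  total <- sum(vapply(AA20, function(a) {
    apsf(ds, feature_type = "amino_acid", features = a)$apsf
  }, numeric(1)))
  expect_equal(total, 100, tolerance = 1e-12)
})

test_that("protein-only scopes make nucleotide/codon queries undefined", {
  ds <- make_aa_dataset(c("MKR", "MQH"))        # no CDS at all
  err <- tryCatch(apsf(ds, feature_type = "codon", features = "AAA"),
                  error = identity)
  expect_s3_class(err, "cogbias_undefined_error")
  expect_equal(err$n_skipped, 2L)
})

test_that("stop codons are rejected from sense-codon queries unless opted in", {
  ds <- shared_sim()$ds
  expect_error(apsf(ds, feature_type = "codon", features = "TAA"),
               class = "cogbias_usage_error")
  r <- apsf(ds, feature_type = "codon", features = "TAA", include_stops = TRUE)
  expect_gt(r$apsf, 0)
})

test_that("APSF equals the brute-force concatenate-and-count oracle exactly", {
  ds <- shared_sim()$ds
  set.seed(99)
  for (i in 1:30) {
    type <- sample(c("amino_acid", "nucleotide", "codon"), 1)
    feats <- switch(type,
                    amino_acid = sample(AA20, sample(1:4, 1)),
                    nucleotide = sample(c("A", "C", "G", "T"), sample(1:2, 1)),
                    codon = sample(setdiff(colnames(ds$counts$codon), STOPS),
                                   sample(1:5, 1)))
    idx <- sort(sample(nrow(ds$sequences), sample(2:15, 1)))
    got <- apsf(ds, idx, type, feats)
    want <- oracle_apsf(
      if (type == "amino_acid") ds$sequences$aa_seq[idx] else ds$sequences$nt_seq[idx],
      feats, type)
    expect_identical(got$selected_feature_count, as.numeric(want$selected))
    expect_identical(got$total_feature_count, as.numeric(want$total))
    expect_identical(got$apsf, want$apsf)
  }
})

test_that("reference APSF modes coincide at full selection", {
  ds <- shared_sim()$ds
  whole <- reference_apsf(ds, "amino_acid", "K", "whole_database")
  sel_all <- reference_apsf(ds, "amino_acid", "K", "selected_organisms",
                            selection = select_all(ds))
  expect_identical(whole, sel_all)
  one <- select_ids(ds, "org001")
  ref1 <- reference_apsf(ds, "amino_acid", "K", "selected_organisms",
                         selection = one)
  idx <- which(ds$sequences$organism_id == "org001")
  expect_identical(ref1, oracle_apsf(ds$sequences$aa_seq[idx], "K", "amino_acid")$apsf)
})

test_that("normalized all-feature scores are exactly 1 and rankings are deterministic", {
  ds <- shared_sim()$ds
  r <- score_cogs(ds, "amino_acid", AA20, normalization = "whole_database")
  expect_true(all(r$score == 1))
  # tie-break: equal scores sorted by cog id ascending
  expect_identical(r$group_label, sort(r$group_label))
})

test_that("enriched COG tops the K ranking in biased synthetic data", {
  ds <- shared_sim()$ds                          # COG0001 has K enriched 2x
  r <- score_cogs(ds, "amino_acid", "K", normalization = "whole_database")
  expect_equal(r$group_label[1], "COG0001")
  expect_gt(r$score[1], 1.4)
})

test_that("subgrouping yields one row per COG and taxon", {
  ds <- shared_sim()$ds
  r <- score_cogs(ds, "amino_acid", "K", subgroup_rank = "species")
  expect_equal(nrow(r), nrow(ds$cogs) * nrow(ds$organisms))  # 1 species/organism
  expect_false(anyNA(r$subgroup))
  r2 <- score_cogs(ds, "amino_acid", "K", subgroup_rank = "superkingdom")
  expect_equal(nrow(r2), nrow(ds$cogs) * 2L)
})

test_that("scores are invariant under input sequence order", {
  ds <- shared_sim()$ds
  set.seed(5)
  perm <- sample(nrow(ds$sequences))
  ds2 <- cog_dataset(ds$source, ds$organisms, ds$cogs, ds$sequences[perm, ])
  ds2$has_taxonomy <- TRUE
  r1 <- score_cogs(ds, "amino_acid", c("K", "R"), normalization = "whole_database")
  r2 <- score_cogs(ds2, "amino_acid", c("K", "R"), normalization = "whole_database")
  expect_equal(as.data.frame(r1), as.data.frame(r2))
})

test_that("adding features never decreases counts or APSF", {
  ds <- shared_sim()$ds
  set.seed(17)
  for (i in 1:10) {
    f1 <- sample(AA20, sample(1:5, 1))
    f2 <- union(f1, sample(AA20, sample(1:5, 1)))
    idx <- sort(sample(nrow(ds$sequences), 10))
    a1 <- apsf(ds, idx, "amino_acid", f1)
    a2 <- apsf(ds, idx, "amino_acid", f2)
    expect_gte(a2$selected_feature_count, a1$selected_feature_count)
    expect_gte(a2$apsf, a1$apsf)
  }
})

test_that("batch grammar parses names, features and COG lists", {
  g <- parse_batch("ArgPath:R:COG0001,COG0002")
  expect_length(g, 1L)
  expect_equal(g[[1]]$name, "ArgPath")
  expect_equal(g[[1]]$features, "R")
  expect_equal(g[[1]]$cog_ids, c("COG0001", "COG0002"))

  g2 <- parse_batch(c("# comment", "", "A : K,R : COG0001 COG0002", "B:H:COG0003"))
  expect_length(g2, 2L)
  expect_equal(g2[[1]]$features, c("K", "R"))
  expect_equal(g2[[1]]$cog_ids, c("COG0001", "COG0002"))

  expect_error(parse_batch("X::"), "line 1", class = "cogbias_parse_error")
  expect_error(parse_batch(c("A:K:COG0001", "oops")), "line 2",
               class = "cogbias_parse_error")
  ds <- shared_sim()$ds
  expect_error(parse_batch("A:K:COG9999", ds = ds), "COG9999",
               class = "cogbias_usage_error")
})

test_that("batch scores pool over all sequences of the listed COGs", {
  ds <- make_aa_dataset(c("KKKKK", "KAAAA", "AAAAA", "MMMMM"),
                        org = c("a", "b", "a", "b"),
                        cog = c("COG0001", "COG0001", "COG0002", "COG0003"))
  g <- parse_batch("grp : K : COG0001, COG0002")
  r <- score_batch(ds, g, "amino_acid")
  expect_equal(r$selected_feature_count, 6)
  expect_equal(r$total_feature_count, 15)
  expect_equal(r$apsf, 40)                       # pooled 6/15

  # singleton group equals the score_cogs row for that COG
  g1 <- parse_batch("solo : K : COG0001")
  rb <- score_batch(ds, g1, "amino_acid", normalization = "whole_database")
  rc <- score_cogs(ds, "amino_acid", "K", normalization = "whole_database",
                   cog_scope = "COG0001")
  expect_equal(rb$apsf, rc$apsf)
  expect_equal(rb$score, rc$score)

  # group with empty scope is omitted with a warning
  sel <- select_ids(ds, "a")
  g3 <- parse_batch(c("hasA : K : COG0001", "onlyB : M : COG0003"))
  expect_warning(r3 <- score_batch(ds, g3, "amino_acid", selection = sel),
                 "onlyB")
  expect_equal(r3$group_label, "hasA")
})

test_that("subgrouped batch scoring gives one row per species present", {
  ds <- shared_sim()$ds
  g <- parse_batch("grp : K : COG0002, COG0003")
  r <- score_batch(ds, g, "amino_acid", normalization = "whole_database",
                   subgroup_rank = "species")
  expect_equal(nrow(r), nrow(ds$organisms))
  expect_setequal(r$subgroup, ds$organisms$species)
})
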