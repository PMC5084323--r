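test_that("two-row score pairs decode to the four call states", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "locus_id\tallele\tsequence\ts1\ts2\ts3\ts4",
    "L1\tREF\t\t1\t1\t0\t0",
    "L1\tSNP\t\t0\t1\t1\t"), tmp)
  d <- read_genotype_table(tmp, format = "two_row_dart")
  expect_equal(unname(d$calls[1, ]), c("REF_HOM", "HET", "ALT_HOM", NA))
  expect_equal(d$marker_type, "SNP")
  # (0,0) is missing, like a blank
  writeLines(c("locus_id\tallele\tsequence\ts1",
               "L1\tREF\t\t0", "L1\tSNP\t\t0"), tmp)
  expect_true(is.na(read_genotype_table(tmp, "two_row_dart")$calls[1, 1]))
})

test_that("malformed genotype tables are rejected with distinct errors", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("locus_id\tallele\tsequence\ts1",
               "L1\tREF\t\t2", "L1\tSNP\t\t0"), tmp)
  expect_error(read_genotype_table(tmp, "two_row_dart"), "unknown score")
  writeLines(c("locus_id\tallele\tsequence\ts1",
               "L1\tREF\t\t1", "L1\tSNP\t\t0",
               "L1\tREF\t\t1", "L1\tSNP\t\t0"), tmp)
  expect_error(read_genotype_table(tmp, "two_row_dart"), "duplicated locus_id")
  writeLines(c("locus_id\tsample_id\tcall", "L1\ts1\tWEIRD"), tmp)
  expect_error(read_genotype_table(tmp, "long"), "unknown call token")
  writeLines(c("locus_id\tallele\tsequence\ts1",
               "L1\tREF\t\t1", "L1\tSNP\t\t0"), tmp)
  expect_error(
    read_genotype_table(tmp, "two_row_dart",
                        sample_table = data.frame(sample_id = "other",
                                                  sex = "MALE")),
    "unresolvable sample_id")
})

test_that("round trips are identity for all dialects, including edge cases", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  # dataset with missing calls and sequences
  d <- genotype_dataset(
    matrix(c("REF_HOM", "HET", NA, "ALT_HOM", NA, "REF_HOM"), nrow = 2,
           dimnames = list(c("L1", "L2"), c("a", "b", "c"))),
    loci = data.frame(locus_id = c("L1", "L2"), marker_type = "SNP",
                      ref_sequence = c("ACGT", NA),
                      alt_sequence = c("ACTT", NA)),
    samples = data.frame(sample_id = c("a", "b", "c"),
                         sex = c("FEMALE", "MALE", "MALE")))
  for (fmt in c("two_row_dart", "long")) {
    write_genotype_table(d, tmp, fmt)
    d2 <- read_genotype_table(tmp, fmt, sample_table = d$samples)
    expect_equal(d2$calls, d$calls, info = fmt)
    expect_equal(d2$samples, d$samples, info = fmt)
    if (fmt == "two_row_dart") expect_equal(d2$loci, d$loci)
  }
  # empty dataset -> header-only file that still round-trips
  empty <- genotype_dataset(matrix(character(0), 0, 0),
                            loci = data.frame(locus_id = character(0),
                                              marker_type = character(0)),
                            samples = data.frame(sample_id = character(0),
                                                 sex = character(0)))
  write_genotype_table(empty, tmp, "two_row_dart")
  expect_equal(nrow(read_genotype_table(tmp, "two_row_dart")$loci), 0)
  # PA matrix round trip
  pa <- pa_dataset(matrix(c("PRESENT", NA, "ABSENT", "PRESENT"), 2),
                   sexes = c("FEMALE", "MALE"))
  write_genotype_table(pa, tmp, "pa_matrix")
  pa2 <- read_genotype_table(tmp, "pa_matrix", sample_table = pa$samples)
  expect_equal(pa2$calls, pa$calls)
})

test_that("a simulated dataset round-trips field-by-field", {
  cfg <- sim_config(n_females = 10, n_males = 10,
                    loci = list(locus_sim_spec("SL1", q_x = 0.1,
                                               y_fidelity = 0.9)),
                    n_autosomal = 99, missing_rate = 0.05, seed = 11)
  d <- simulate_dataset(cfg)$dataset
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_genotype_table(d, tmp, "long")
  d2 <- read_genotype_table(tmp, "long", sample_table = d$samples)
  expect_equal(d2$calls, d$calls)
  expect_equal(d2$loci$locus_id, d$loci$locus_id)
  expect_equal(d2$samples, d$samples)
})

test_that("tag-pair validation finds the single mismatch position", {
  tab <- racl_markers("snp")
  i <- match("RaclCT002", tab$locus_id)
  pos <- snp_position_from_sequences(tab$ref_sequence[i], tab$alt_sequence[i])
  expect_equal(pos, 17L)
  # every bundled locus has exactly one mismatch, so validation passes
  d <- genotype_dataset(
    matrix(NA_character_, nrow(tab), 0,
           dimnames = list(tab$locus_id, NULL)),
    loci = data.frame(locus_id = tab$locus_id, marker_type = "SNP",
                      ref_sequence = tab$ref_sequence,
                      alt_sequence = tab$alt_sequence),
    samples = data.frame(sample_id = character(0), sex = character(0)))
  expect_true(all(!is.na(d$loci$snp_position)))
  expect_error(snp_position_from_sequences("AAAA", "ATTA"), "exactly one")
  expect_error(snp_position_from_sequences("AAA", "AAAA"), "equal length")
})

test_that("dataset construction rejects inconsistent inputs", {
  expect_error(snp_dataset(matrix("BAD", 1, 1), sexes = "MALE"),
               "unknown call token")
  expect_error(genotype_dataset(
    matrix("REF_HOM", 2, 1),
    loci = data.frame(locus_id = c("L1", "L1"), marker_type = "SNP"),
    samples = data.frame(sample_id = "s", sex = "MALE")),
    "duplicated locus_id")
  expect_error(genotype_dataset(
    matrix("REF_HOM", 1, 2),
    loci = data.frame(locus_id = "L1", marker_type = "SNP"),
    samples = data.frame(sample_id = c("s", "s"), sex = "MALE")),
    "duplicated sample_id")
  expect_error(genotype_dataset(
    matrix("REF_HOM", 2, 1),
    loci = data.frame(locus_id = "L1", marker_type = "SNP"),
    samples = data.frame(sample_id = "s", sex = "MALE")),
    "dimension mismatch")
})

test_that("replicate collapsing keeps agreements and blanks disagreements", {
  # two identical replicates -> consensus equals either, concordance 1
  calls <- matrix(c("REF_HOM", "HET", "REF_HOM", "HET"), nrow = 2,
                  dimnames = list(NULL, c("r1", "r2")))
  d <- snp_dataset(calls, sexes = c("MALE", "MALE"),
                   replicate_group = c("g1", "g1"))
  out <- collapse_replicates(d)
  expect_equal(unname(out$dataset$calls[, 1]), c("REF_HOM", "HET"))
  expect_equal(out$dataset$samples$sample_id, "g1")
  expect_equal(out$concordance$concordance[out$concordance$group == "g1"], 1)

  # disagreement -> missing consensus, concordance 0 at that locus
  calls <- matrix(c("REF_HOM", "HET"), nrow = 1,
                  dimnames = list("L1", c("r1", "r2")))
  d <- snp_dataset(calls, sexes = c("MALE", "MALE"),
                   replicate_group = c("g1", "g1"))
  out <- collapse_replicates(d)
  expect_true(is.na(out$dataset$calls[1, 1]))
  expect_equal(out$concordance$concordance[1], 0)
})

test_that("three-replicate concordance counts agreements over compared loci", {
  # 10 loci, 3 replicates; loci 4 and 9 discordant, locus 10 has only one
  # non-missing replicate (not compared)
  base <- c(rep("REF_HOM", 5), rep("HET", 5))
  r1 <- r2 <- r3 <- base
  r2[4] <- "ALT_HOM"
  r3[9] <- "REF_HOM"
  r1[10] <- NA; r2[10] <- NA
  calls <- cbind(r1 = r1, r2 = r2, r3 = r3, s4 = base)
  d <- snp_dataset(calls, sexes = rep("MALE", 4),
                   replicate_group = c("g1", "g1", "g1", NA))
  out <- collapse_replicates(d)
  g <- out$concordance[out$concordance$group == "g1", ]
  expect_equal(g$n_compared, 9L)
  expect_equal(g$n_agree, 7L)
  expect_equal(g$concordance, 7 / 9)
  # non-replicated sample passes through untouched
  expect_equal(unname(out$dataset$calls[, "s4"]), base)
  # locus 10: single non-missing replicate passes through
  expect_equal(unname(out$dataset$calls[10, "g1"]), "HET")
})

test_that("consensus never invents a call", {
  set.seed(42)
  for (rep in 1:20) {
    calls <- matrix(sample(c("REF_HOM", "HET", "ALT_HOM", NA), 30,
                           replace = TRUE), nrow = 10)
    colnames(calls) <- c("r1", "r2", "r3")
    d <- snp_dataset(calls, sexes = rep("FEMALE", 3),
                     replicate_group = rep("g", 3))
    cons <- collapse_replicates(d)$dataset$calls[, 1]
    for (l in 1:10) {
      seen <- calls[l, ][!is.na(calls[l, ])]
      expect_true(is.na(cons[l]) || cons[l] %in% seen)
      if (!is.na(cons[l])) expect_true(all(seen == cons[l]))
    }
  }
})
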