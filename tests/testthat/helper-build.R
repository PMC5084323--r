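# Small in-code builders shared across the suite.

snp_dataset <- function(calls, sexes, populations = NULL,
                        life_stage = "OTHER", replicate_group = NULL) {
  calls <- as.matrix(calls)
  n <- ncol(calls)
  if (is.null(rownames(calls))) {
    rownames(calls) <- sprintf("L%03d", seq_len(nrow(calls)))
  }
  if (is.null(colnames(calls))) colnames(calls) <- sprintf("s%02d", seq_len(n))
  genotype_dataset(
    calls,
    loci = data.frame(locus_id = rownames(calls), marker_type = "SNP"),
    samples = data.frame(
      sample_id = colnames(calls), sex = sexes,
      population = if (is.null(populations)) "p1" else populations,
      life_stage = life_stage,
      replicate_group = if (is.null(replicate_group)) NA_character_
                        else replicate_group))
}

pa_dataset <- function(calls, sexes) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls))) {
    rownames(calls) <- sprintf("P%03d", seq_len(nrow(calls)))
  }
  if (is.null(colnames(calls))) {
    colnames(calls) <- sprintf("s%02d", seq_len(ncol(calls)))
  }
  genotype_dataset(
    calls,
    loci = data.frame(locus_id = rownames(calls), marker_type = "PA"),
    samples = data.frame(sample_id = colnames(calls), sex = sexes))
}

# One proportions row in the compute_proportions() layout, for criteria tests.
props_row <- function(f = c(1, 0, 0), m = c(0, 0, 1),
                      f_call_rate = 1, m_call_rate = 1,
                      locus_id = "L1", cohort = "all", evaluable = TRUE) {
  data.frame(locus_id = locus_id, cohort = cohort, marker_type = "SNP",
             f_n = 20, f_n_called = 20, f_call_rate = f_call_rate,
             f_ref_hom = f[1], f_alt_hom = f[2], f_het = f[3],
             m_n = 20, m_n_called = 20, m_call_rate = m_call_rate,
             m_ref_hom = m[1], m_alt_hom = m[2], m_het = m[3],
             evaluable = evaluable, stringsAsFactors = FALSE)
}
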