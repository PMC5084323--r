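# Bundled reference tables for the published Rana clamitans sex-linked
# markers (dbSNP accession PRJNA326426, ss# 2019323440-2019323452): the 13
# candidate SNP loci with REF/SNP tag sequences and the 8 presence-absence
# markers, with the per-sex genotype proportions reported for the tadpole and
# adult cohorts. These are worked-example data: the printed proportions (two
# decimals) stand in for the unavailable individual-level genotype matrix.

#' Published green frog sex-linked marker tables
#'
#' Returns the bundled marker tables for *Rana clamitans*: tag sequences and
#' per-cohort, per-sex genotype proportions for the 13 candidate sex-linked
#' SNP loci, or presence proportions for the 8 PA markers, together with
#' discovery annotations (`discovered_in`: cohort(s) in which the locus was
#' originally identified; `forest5_affected`: loci at which male tadpoles
#' from the Forest5 pond lose sex-linkage, a geographic-variation signature).
#'
#' @param type `"snp"` or `"pa"`.
#' @return Data frame, one row per locus.
#' @seealso [racl_marker_proportions()]
#' @export
racl_markers <- function(type = c("snp", "pa")) {
  type <- match.arg(type)
  path <- system.file("extdata", paste0("racl_", type, "_markers.tsv"),
                      package = "sexlinkr", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Marker tables as sex-genotype proportion records
#'
#' Reshapes [racl_markers()] into the `sex_genotype_proportions` layout of
#' [compute_proportions()], one row per (locus, cohort), so the filter
#' criteria can be applied to the published proportions directly. Cohort
#' sample sizes are 12 female / 13 male tadpoles and 23 female / 54 male
#' adults (the sizes the printed two-decimal proportions are consistent
#' with); call rates are set to 1 because the published loci all passed the
#' 90\% per-sex call-rate rule before tabulation.
#'
#' @param type `"snp"` or `"pa"`.
#' @return Data frame of class `sex_genotype_proportions` with extra columns
#'   `discovered_in` and `forest5_affected`.
#' @export
racl_marker_proportions <- function(type = c("snp", "pa")) {
  type <- match.arg(type)
  tab <- racl_markers(type)
  sizes <- list(TADPOLE = c(f = 12L, m = 13L), ADULT = c(f = 23L, m = 54L))
  rows <- list()
  for (cohort in names(sizes)) {
    pre <- if (cohort == "TADPOLE") "t_" else "a_"
    nf <- sizes[[cohort]][["f"]]; nm <- sizes[[cohort]][["m"]]
    base <- data.frame(locus_id = tab$locus_id, cohort = cohort,
                       marker_type = toupper(type),
                       f_n = nf, f_n_called = nf, f_call_rate = 1,
                       stringsAsFactors = FALSE)
    if (type == "snp") {
      base$f_ref_hom <- tab[[paste0(pre, "f_ref_hom")]]
      base$f_alt_hom <- tab[[paste0(pre, "f_alt_hom")]]
      base$f_het <- tab[[paste0(pre, "f_het")]]
    } else {
      base$f_present <- tab[[paste0(pre, "f_present")]]
    }
    base$m_n <- nm; base$m_n_called <- nm; base$m_call_rate <- 1
    if (type == "snp") {
      base$m_ref_hom <- tab[[paste0(pre, "m_ref_hom")]]
      base$m_alt_hom <- tab[[paste0(pre, "m_alt_hom")]]
      base$m_het <- tab[[paste0(pre, "m_het")]]
    } else {
      base$m_present <- tab[[paste0(pre, "m_present")]]
    }
    base$evaluable <- TRUE
    base$discovered_in <- tab$discovered_in
    base$forest5_affected <- tab$forest5_affected
    rows[[cohort]] <- base
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "marker_type") <- toupper(type)
  class(res) <- c("sex_genotype_proportions", "data.frame")
  res
}
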