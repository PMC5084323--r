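#' Sex-linkage filter thresholds
#'
#' Thresholds of the sex-stratified genotype-proportion filter. Defaults
#' encode the standard criteria for an XX-XY scan: homogametic (female)
#' reference-allele homozygosity at least 0.80, SNP-allele homozygosity at
#' most 0.10, heterozygosity at most 0.20; heterogametic (male)
#' reference-allele homozygosity at most 0.10 and heterozygosity at least
#' 0.75; each sex called at 90\% of samples or more. PA markers are kept when
#' the fragment is sequenced in at least 90\% of one sex and at most 10\% of
#' the other. All comparisons are inclusive and made on exact fractions.
#' A ZZ-ZW scan applies the same rules with the sex roles exchanged.
#'
#' @param female_ref_hom_min,female_alt_hom_max,female_het_max rules on the
#'   homogametic sex's genotype proportions (fractions of non-missing calls).
#' @param male_ref_hom_max,male_het_min rules on the heterogametic sex.
#' @param call_rate_min minimum per-sex call rate for SNP loci.
#' @param pa_present_min,pa_present_max_other PA presence thresholds for the
#'   linked and the opposite sex.
#' @return An object of class `filter_criteria`.
#' @export
filter_criteria <- function(female_ref_hom_min = 0.80,
                            female_alt_hom_max = 0.10,
                            female_het_max = 0.20,
                            male_ref_hom_max = 0.10,
                            male_het_min = 0.75,
                            call_rate_min = 0.90,
                            pa_present_min = 0.90,
                            pa_present_max_other = 0.10) {
  x <- list(female_ref_hom_min = female_ref_hom_min,
            female_alt_hom_max = female_alt_hom_max,
            female_het_max = female_het_max,
            male_ref_hom_max = male_ref_hom_max,
            male_het_min = male_het_min,
            call_rate_min = call_rate_min,
            pa_present_min = pa_present_min,
            pa_present_max_other = pa_present_max_other)
  bad <- names(x)[!vapply(x, function(v) is.numeric(v) && length(v) == 1 &&
                            v >= 0 && v <= 1, logical(1))]
  if (length(bad)) stop("thresholds must be single values in [0,1]: ",
                        paste(bad, collapse = ", "))
  structure(x, class = "filter_criteria")
}

#' Per-locus, per-sex genotype proportions
#'
#' Tabulates, for every locus and cohort, each sex's genotype class
#' proportions and call rate. SNP proportions (`f_ref_hom`, `f_alt_hom`,
#' `f_het` and male counterparts) are fractions of that sex's *non-missing*
#' calls; call rate is the fraction of the sex's samples called. PA presence
#' (`f_present`, `m_present`) uses all samples of the sex as denominator — an
#' unsequenced restriction fragment is the absent state.
#'
#' @param dataset a [genotype_dataset()].
#' @param cohort_by name of a sample-table column to stratify by (e.g.
#'   `"life_stage"` or `"population"`), or `NULL` for a single `"all"` cohort.
#' @return Data frame of class `sex_genotype_proportions`, one row per
#'   (locus, cohort), with counts, call rates, proportions and an `evaluable`
#'   flag (`FALSE` where a cohort lacks samples of either sex). Samples of
#'   unknown sex are dropped with a warning.
#' @export
compute_proportions <- function(dataset, cohort_by = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  samples <- dataset$samples
  unknown <- samples$sex == "UNKNOWN"
  if (any(unknown)) {
    warning(sum(unknown), " sample(s) of unknown sex excluded from proportions")
  }
  cohort <- if (is.null(cohort_by)) {
    rep("all", nrow(samples))
  } else {
    if (!cohort_by %in% names(samples)) {
      stop("no sample column called ", cohort_by)
    }
    as.character(samples[[cohort_by]])
  }
  out <- list()
  for (co in unique(cohort)) {
    fi <- which(cohort == co & samples$sex == "FEMALE")
    mi <- which(cohort == co & samples$sex == "MALE")
    out[[co]] <- .props_one_cohort(dataset, co, fi, mi)
  }
  if (!length(out)) out <- list(.props_one_cohort(dataset, character(0),
                                                  integer(0), integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "marker_type") <- dataset$marker_type
  class(res) <- c("sex_genotype_proportions", "data.frame")
  res
}

.props_one_cohort <- function(dataset, cohort, fi, mi) {
  mt <- dataset$marker_type
  sex_block <- function(idx) {
    m <- dataset$calls[, idx, drop = FALSE]
    n <- length(idx)
    nl <- nrow(m)
    n_called <- rowSums(!is.na(m))
    if (mt == "SNP") {
      data.frame(n = rep(n, nl), n_called = n_called,
                 call_rate = if (n > 0) n_called / n else rep(NA_real_, nl),
                 ref_hom = rowSums(m == "REF_HOM", na.rm = TRUE) / n_called,
                 alt_hom = rowSums(m == "ALT_HOM", na.rm = TRUE) / n_called,
                 het = rowSums(m == "HET", na.rm = TRUE) / n_called)
    } else {
      data.frame(n = rep(n, nl), n_called = n_called,
                 call_rate = if (n > 0) n_called / n else rep(NA_real_, nl),
                 present = if (n > 0) {
                   rowSums(m == "PRESENT", na.rm = TRUE) / n
                 } else rep(NA_real_, nl))
    }
  }
  f <- sex_block(fi)
  m <- sex_block(mi)
  names(f) <- paste0("f_", names(f))
  names(m) <- paste0("m_", names(m))
  nl <- nrow(dataset$loci)
  cbind(data.frame(locus_id = dataset$loci$locus_id,
                   cohort = rep_len(if (length(cohort)) cohort else "all", nl),
                   marker_type = rep_len(mt, nl), stringsAsFactors = FALSE),
        f, m,
        data.frame(evaluable = rep_len(length(fi) > 0 & length(mi) > 0, nl)))
}

#' Apply the SNP sex-linkage criteria
#'
#' Evaluates each proportion row against the filter. For an XY system the
#' homogametic sex is the female and the heterogametic sex the male; a ZW
#' system exchanges the roles. Rows that are not evaluable get `NA` verdicts
#' (distinct from a fail).
#'
#' @param props a `sex_genotype_proportions` data frame (SNP loci).
#' @param criteria a [filter_criteria()].
#' @param system `"XY"` or `"ZW"`.
#' @return `props` with per-rule logical columns (`hom_ref_hom_ok`,
#'   `hom_alt_hom_ok`, `hom_het_ok`, `het_ref_hom_ok`, `het_het_ok`,
#'   `call_rate_ok`), a `system` column and an overall `pass`.
#' @export
apply_snp_criteria <- function(props, criteria = filter_criteria(),
                               system = c("XY", "ZW")) {
  system <- match.arg(system)
  stopifnot(is.data.frame(props))
  if (!all(c("f_ref_hom", "m_ref_hom") %in% names(props))) {
    stop("`props` must be SNP proportions from compute_proportions()")
  }
  # homogametic sex: XX under XY, ZZ (male) under ZW
  hom <- if (system == "XY") "f" else "m"
  het <- if (system == "XY") "m" else "f"
  g <- function(sex, what) props[[paste0(sex, "_", what)]]
  res <- props
  res$system <- rep_len(system, nrow(props))
  res$hom_ref_hom_ok <- g(hom, "ref_hom") >= criteria$female_ref_hom_min
  res$hom_alt_hom_ok <- g(hom, "alt_hom") <= criteria$female_alt_hom_max
  res$hom_het_ok <- g(hom, "het") <= criteria$female_het_max
  res$het_ref_hom_ok <- g(het, "ref_hom") <= criteria$male_ref_hom_max
  res$het_het_ok <- g(het, "het") >= criteria$male_het_min
  res$call_rate_ok <- props$f_call_rate >= criteria$call_rate_min &
    props$m_call_rate >= criteria$call_rate_min
  rule_cols <- c("hom_ref_hom_ok", "hom_alt_hom_ok", "hom_het_ok",
                 "het_ref_hom_ok", "het_het_ok", "call_rate_ok")
  res$pass <- Reduce(`&`, res[rule_cols])
  for (col in c(rule_cols, "pass")) res[[col]][!props$evaluable] <- NA
  res
}

#' Apply the presence-absence sex-linkage criteria
#'
#' @param props a `sex_genotype_proportions` data frame (PA loci).
#' @param criteria a [filter_criteria()].
#' @return `props` with an `outcome` column: `MALE_LINKED` when the fragment
#'   is sequenced in at least `pa_present_min` of males and at most
#'   `pa_present_max_other` of females, `FEMALE_LINKED` by the mirror rule,
#'   else `NOT_LINKED`; `NOT_EVALUABLE` where a sex is absent.
#' @export
apply_pa_criteria <- function(props, criteria = filter_criteria()) {
  stopifnot(is.data.frame(props))
  if (!all(c("f_present", "m_present") %in% names(props))) {
    stop("`props` must be PA proportions from compute_proportions()")
  }
  male_linked <- props$m_present >= criteria$pa_present_min &
    props$f_present <= criteria$pa_present_max_other
  female_linked <- props$f_present >= criteria$pa_present_min &
    props$m_present <= criteria$pa_present_max_other
  res <- props
  res$outcome <- ifelse(male_linked, "MALE_LINKED",
                        ifelse(female_linked, "FEMALE_LINKED", "NOT_LINKED"))
  res$outcome[!props$evaluable] <- "NOT_EVALUABLE"
  res
}

#' Scan a dataset for candidate sex-linked loci
#'
#' Computes per-cohort sex-stratified proportions, applies the SNP criteria
#' under both the XY and ZW hypotheses (or the PA criteria), and annotates
#' each locus with its cross-cohort consistency: `"all"` if it passes in
#' every evaluable cohort, `"some"` if only in part of them, `"none"`
#' otherwise. Cohorts (e.g. life stages) are analyzed separately and compared
#' afterwards.
#'
#' @param dataset a [genotype_dataset()].
#' @param cohort_by sample-table column to stratify by, or `NULL`.
#' @param criteria a [filter_criteria()].
#' @return Data frame of class `sexlink_candidates`, one row per
#'   (locus, cohort). SNP datasets gain `xy_pass`, `zw_pass`, `xy_cross`,
#'   `zw_cross`; PA datasets gain `outcome`, `male_cross`, `female_cross`.
#' @export
discover_candidates <- function(dataset, cohort_by = NULL,
                                criteria = filter_criteria()) {
  props <- compute_proportions(dataset, cohort_by = cohort_by)
  cross <- function(pass) {
    # pass: logical per cohort row (NA = not evaluable), grouped by locus
    vapply(split(pass, props$locus_id)[unique(props$locus_id)], function(p) {
      p <- p[!is.na(p)]
      if (!length(p)) "none" else if (all(p)) "all"
      else if (any(p)) "some" else "none"
    }, character(1))
  }
  if (dataset$marker_type == "SNP") {
    xy <- apply_snp_criteria(props, criteria, "XY")
    zw <- apply_snp_criteria(props, criteria, "ZW")
    res <- xy
    names(res)[names(res) == "pass"] <- "xy_pass"
    res$system <- NULL
    res$zw_pass <- zw$pass
    res$xy_cross <- cross(res$xy_pass)[res$locus_id]
    res$zw_cross <- cross(res$zw_pass)[res$locus_id]
  } else {
    res <- apply_pa_criteria(props, criteria)
    ml <- res$outcome == "MALE_LINKED"
    fl <- res$outcome == "FEMALE_LINKED"
    ml[res$outcome == "NOT_EVALUABLE"] <- NA
    fl[res$outcome == "NOT_EVALUABLE"] <- NA
    res$male_cross <- cross(ml)[res$locus_id]
    res$female_cross <- cross(fl)[res$locus_id]
  }
  attr(res, "criteria") <- criteria
  attr(res, "marker_type") <- dataset$marker_type
  class(res) <- c("sexlink_candidates", "data.frame")
  res
}
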