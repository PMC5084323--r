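#' Simulation parameters for one sex-linked locus
#'
#' Population-level parameterization of imperfect sex-linkage. For a SNP
#' locus under an XY system, `q_x` is the standing frequency of the SNP
#' allele on X chromosomes (historical X-Y recombination leakage: produces
#' heterozygous females and SNP-homozygous males) and `y_fidelity` the
#' probability that a Y chromosome carries the SNP allele (1 = tight
#' linkage). For a PA marker, `y_fidelity` is the probability the Y carries
#' the restriction fragment and `pa_leak` the probability the autosomal/X
#' background yields the fragment anyway. Any parameter can be overridden per
#' population (e.g. a pond where the locus is not sex-linked).
#'
#' @param locus_id locus label.
#' @param marker_type `"SNP"` or `"PA"`.
#' @param q_x SNP-allele frequency on X chromosomes, in \[0,1\].
#' @param y_fidelity probability the Y carries the SNP allele / fragment.
#' @param pa_leak background fragment probability (PA only).
#' @param overrides named list: population -> list of parameter overrides,
#'   e.g. `list(Forest5 = list(q_x = 0.5, y_fidelity = 0.5))`.
#' @return Object of class `locus_sim_spec`.
#' @export
locus_sim_spec <- function(locus_id, marker_type = c("SNP", "PA"),
                           q_x = 0, y_fidelity = 1, pa_leak = 0,
                           overrides = NULL) {
  marker_type <- match.arg(marker_type)
  for (v in c(q_x, y_fidelity, pa_leak)) {
    if (!is.numeric(v) || v < 0 || v > 1) stop("probabilities must be in [0,1]")
  }
  structure(list(locus_id = locus_id, marker_type = marker_type, q_x = q_x,
                 y_fidelity = y_fidelity, pa_leak = pa_leak,
                 overrides = overrides),
            class = "locus_sim_spec")
}

.spec_for_pop <- function(spec, pop) {
  ov <- spec$overrides[[pop]]
  if (!is.null(ov)) for (nm in names(ov)) spec[[nm]] <- ov[[nm]]
  spec
}

#' Simulation configuration
#'
#' Defines a synthetic marker-discovery study: per-population sample sizes,
#' sex-linked loci ([locus_sim_spec()]), an unlinked autosomal background,
#' sex reversal and missing data. The default sample sizes mirror a
#' wild-adult survey of 23 females and 54 males.
#'
#' @param n_females,n_males samples per population (scalar, or one value per
#'   population).
#' @param populations population labels.
#' @param sex_reversal_rate probability that an individual's phenotypic sex
#'   contradicts its genotypic (chromosomal) sex.
#' @param missing_rate per-call missing probability.
#' @param loci list of [locus_sim_spec()] (all the same marker type).
#' @param n_autosomal number of unlinked background SNP loci (SNP configs
#'   only; a dataset is homogeneous in marker type).
#' @param autosomal_freq fixed minor-allele frequency for autosomal loci, or
#'   `NULL` to draw each locus's frequency uniformly on (0.05, 0.95).
#' @param system `"XY"` (heterogametic males) or `"ZW"` (heterogametic
#'   females; same generative model with the sex roles relabeled).
#' @param life_stage life stage recorded for the simulated samples.
#' @param seed mandatory integer seed; identical configs give byte-identical
#'   output.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_females = 23, n_males = 54, populations = "pond1",
                       sex_reversal_rate = 0, missing_rate = 0,
                       loci = list(), n_autosomal = 0, autosomal_freq = NULL,
                       system = c("XY", "ZW"), life_stage = "ADULT", seed) {
  system <- match.arg(system)
  if (missing(seed) || is.null(seed)) stop("`seed` is mandatory")
  npop <- length(populations)
  n_females <- rep_len(n_females, npop)
  n_males <- rep_len(n_males, npop)
  if (any(n_females < 0) || any(n_males < 0)) stop("sample counts must be >= 0")
  for (r in c(sex_reversal_rate, missing_rate)) {
    if (r < 0 || r > 1) stop("rates must be in [0,1]")
  }
  if (length(loci) && !all(vapply(loci, inherits, logical(1), "locus_sim_spec"))) {
    stop("`loci` must be a list of locus_sim_spec objects")
  }
  types <- unique(vapply(loci, `[[`, character(1), "marker_type"))
  if (length(types) > 1) stop("all simulated loci must share one marker_type")
  if (n_autosomal > 0 && identical(types, "PA")) {
    stop("autosomal SNP background cannot be mixed into a PA dataset")
  }
  structure(list(n_females = n_females, n_males = n_males,
                 populations = populations,
                 sex_reversal_rate = sex_reversal_rate,
                 missing_rate = missing_rate, loci = loci,
                 n_autosomal = n_autosomal, autosomal_freq = autosomal_freq,
                 system = system, life_stage = life_stage, seed = seed),
            class = "sim_config")
}

#' Simulate a genotype dataset with known truth
#'
#' Generative model per individual and sex-linked SNP locus: a genotypic
#' female (XX) draws two X alleles, each carrying the SNP allele with
#' probability `q_x`; a genotypic male (XY) draws one X allele
#' (`Bernoulli(q_x)`) and one Y allele (`Bernoulli(y_fidelity)`); the
#' genotype call is REF_HOM / HET / ALT_HOM by SNP-allele count. A PA marker
#' is PRESENT in a male if the Y carries the fragment or the background leak
#' fires, and in a female if the leak fires. Phenotypic sex flips with
#' probability `sex_reversal_rate` (genotype and marker pattern follow the
#' chromosomes — exactly the discordance sex-reversal surveys look for).
#' Autosomal loci draw Hardy-Weinberg genotypes independent of sex. Each
#' call is finally masked missing with probability `missing_rate`. Under
#' `system = "ZW"` the heterogametic sex is the female and labels swap.
#'
#' @param config a [sim_config()].
#' @return List with `dataset` (a [genotype_dataset()], phenotypic sex in the
#'   sample table) and `truth` (data frame: `sample_id`, `population`,
#'   `genotypic_sex`, `phenotypic_sex`, `sex_reversed`; attributes
#'   `allele_counts` — the loci x samples matrix of latent SNP-allele copies
#'   or fragment indicators before masking — and `locus_params`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, .simulate_impl(config))
}

.simulate_impl <- function(config) {
  het_genotypic <- if (config$system == "XY") "MALE" else "FEMALE"
  hom_genotypic <- if (config$system == "XY") "FEMALE" else "MALE"

  pops <- character(0); gsex <- character(0)
  for (p in seq_along(config$populations)) {
    nf <- config$n_females[p]; nm <- config$n_males[p]
    pops <- c(pops, rep(config$populations[p], nf + nm))
    gsex <- c(gsex, rep("FEMALE", nf), rep("MALE", nm))
  }
  n <- length(pops)
  sample_id <- if (n) sprintf("%s_%03d", pops, stats::ave(seq_len(n), pops,
                                                          FUN = seq_along))
               else character(0)
  reversed <- if (n) stats::runif(n) < config$sex_reversal_rate else logical(0)
  psex <- ifelse(reversed, ifelse(gsex == "FEMALE", "MALE", "FEMALE"), gsex)
  heterogam <- gsex == het_genotypic

  sex_loci <- config$loci
  n_sex <- length(sex_loci)
  n_auto <- config$n_autosomal
  marker_type <- if (n_sex) sex_loci[[1]]$marker_type else "SNP"
  n_loci <- n_sex + n_auto
  latent <- matrix(0L, n_loci, n)
  calls <- matrix(NA_character_, n_loci, n)
  params <- list()

  for (i in seq_len(n_sex)) {
    spec <- sex_loci[[i]]
    for (pop in unique(pops)) {
      sp <- .spec_for_pop(spec, pop)
      jh <- which(pops == pop & heterogam)   # one X + one Y (or Z + W)
      jo <- which(pops == pop & !heterogam)  # two X (or two Z)
      if (marker_type == "SNP") {
        latent[i, jo] <- stats::rbinom(length(jo), 2L, sp$q_x)
        latent[i, jh] <- stats::rbinom(length(jh), 1L, sp$q_x) +
          stats::rbinom(length(jh), 1L, sp$y_fidelity)
        calls[i, c(jo, jh)] <- .SNP_CALLS[latent[i, c(jo, jh)] + 1L]
      } else {
        pres_o <- stats::runif(length(jo)) < sp$pa_leak
        pres_h <- (stats::runif(length(jh)) < sp$y_fidelity) |
          (stats::runif(length(jh)) < sp$pa_leak)
        latent[i, jo] <- as.integer(pres_o)
        latent[i, jh] <- as.integer(pres_h)
        calls[i, c(jo, jh)] <- ifelse(latent[i, c(jo, jh)] == 1L,
                                      "PRESENT", "ABSENT")
      }
      params[[length(params) + 1L]] <- data.frame(
        locus_id = spec$locus_id, population = pop, marker_type = marker_type,
        q_x = sp$q_x, y_fidelity = sp$y_fidelity, pa_leak = sp$pa_leak,
        stringsAsFactors = FALSE)
    }
  }

  auto_freq <- numeric(0)
  if (n_auto > 0) {
    auto_freq <- if (is.null(config$autosomal_freq)) {
      stats::runif(n_auto, 0.05, 0.95)
    } else rep_len(config$autosomal_freq, n_auto)
    for (i in seq_len(n_auto)) {
      row <- n_sex + i
      latent[row, ] <- stats::rbinom(n, 2L, auto_freq[i])
      calls[row, ] <- .SNP_CALLS[latent[row, ] + 1L]
    }
  }

  if (config$missing_rate > 0 && length(calls)) {
    calls[stats::runif(length(calls)) < config$missing_rate] <- NA_character_
  }

  locus_ids <- c(vapply(sex_loci, `[[`, character(1), "locus_id"),
                 if (n_auto > 0) sprintf("AUTO%05d", seq_len(n_auto)))
  loci <- data.frame(locus_id = locus_ids,
                     marker_type = rep_len(marker_type, length(locus_ids)),
                     stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = sample_id, sex = as.character(psex),
                        population = pops,
                        life_stage = rep_len(config$life_stage, n),
                        replicate_group = rep_len(NA_character_, n),
                        stringsAsFactors = FALSE)
  dimnames(latent) <- list(locus_ids, sample_id)
  truth <- data.frame(sample_id = sample_id, population = pops,
                      genotypic_sex = gsex, phenotypic_sex = as.character(psex),
                      sex_reversed = reversed, stringsAsFactors = FALSE)
  attr(truth, "allele_counts") <- latent
  attr(truth, "locus_params") <- if (length(params)) {
    do.call(rbind, params)
  } else {
    data.frame(locus_id = character(0), population = character(0),
               marker_type = character(0), q_x = numeric(0),
               y_fidelity = numeric(0), pa_leak = numeric(0))
  }
  attr(truth, "autosomal_freq") <- auto_freq
  attr(truth, "heterogametic_sex") <- het_genotypic
  rownames(calls) <- locus_ids
  colnames(calls) <- sample_id
  list(dataset = genotype_dataset(calls, loci, samples), truth = truth)
}

#' Expected per-sex genotype class probabilities for a simulated locus
#'
#' Closed forms implied by the generative model (XY labeling; under ZW swap
#' the sexes). SNP: a female is `(1-q_x)^2` REF_HOM, `2 q_x (1-q_x)` HET and
#' `q_x^2` ALT_HOM; a male is `(1-q_x)(1-y)` REF_HOM,
#' `(1-q_x) y + q_x (1-y)` HET and `q_x y` ALT_HOM where `y = y_fidelity`.
#' PA: female presence `pa_leak`; male presence
#' `1 - (1-y_fidelity)(1-pa_leak)`.
#'
#' @param spec a [locus_sim_spec()].
#' @param population optional population label whose overrides to apply.
#' @return For SNP: list of named vectors `female`, `male` with entries
#'   `ref_hom`, `het`, `alt_hom`. For PA: list with `female`, `male`
#'   presence probabilities.
#' @export
expected_proportions <- function(spec, population = NULL) {
  stopifnot(inherits(spec, "locus_sim_spec"))
  if (!is.null(population)) spec <- .spec_for_pop(spec, population)
  q <- spec$q_x; y <- spec$y_fidelity
  if (spec$marker_type == "SNP") {
    list(female = c(ref_hom = (1 - q)^2, het = 2 * q * (1 - q),
                    alt_hom = q^2),
         male = c(ref_hom = (1 - q) * (1 - y),
                  het = (1 - q) * y + q * (1 - y),
                  alt_hom = q * y))
  } else {
    list(female = c(present = spec$pa_leak),
         male = c(present = 1 - (1 - y) * (1 - spec$pa_leak)))
  }
}

#' Recover simulation parameters from a genotyped SNP locus
#'
#' Method-of-moments recovery harness: the SNP-allele frequency on X is
#' estimated from female calls (each called female contributes two X draws),
#' and the Y fidelity from the male REF_HOM fraction given the female
#' estimate: `y_hat = 1 - m_ref_hom / (1 - q_hat)`, clipped to \[0,1\].
#' The pattern "males SNP-homozygous while no female carries the SNP allele"
#' is impossible under the model with `q_x = 0` and is flagged.
#'
#' @param dataset a [genotype_dataset()] (SNP, sexed samples).
#' @param locus_id the locus to fit.
#' @return List: `q_x`, `y_fidelity`, `n_female_called`, `n_male_called`,
#'   `consistent` (`FALSE` when male ALT_HOM calls occur with `q_x`
#'   estimated at 0).
#' @export
fit_locus_params <- function(dataset, locus_id) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (dataset$marker_type != "SNP") stop("parameter recovery is for SNP loci")
  i <- match(locus_id, dataset$loci$locus_id)
  if (is.na(i)) stop("unknown locus: ", locus_id)
  calls <- dataset$calls[i, ]
  sex <- dataset$samples$sex
  f <- calls[sex == "FEMALE" & !is.na(calls)]
  m <- calls[sex == "MALE" & !is.na(calls)]
  if (!length(f)) stop("no called females at locus ", locus_id)
  q_hat <- (2 * sum(f == "ALT_HOM") + sum(f == "HET")) / (2 * length(f))
  m_ref <- if (length(m)) mean(m == "REF_HOM") else NA_real_
  y_hat <- if (!length(m)) {
    NA_real_
  } else if (q_hat >= 1) {
    1
  } else {
    min(1, max(0, 1 - m_ref / (1 - q_hat)))
  }
  consistent <- !(q_hat == 0 && length(m) && any(m == "ALT_HOM"))
  list(q_x = q_hat, y_fidelity = y_hat,
       n_female_called = length(f), n_male_called = length(m),
       consistent = consistent)
}
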