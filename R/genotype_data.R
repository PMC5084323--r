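#' Construct a genotype dataset
#'
#' The universal currency of the package: an individuals x loci call matrix
#' (stored loci-in-rows) together with per-locus and per-sample metadata.
#' A dataset is homogeneous in marker type: either biallelic SNP loci with
#' calls in `REF_HOM`, `HET`, `ALT_HOM` (plus `NA` for missing), or
#' presence-absence (PA / SilicoDArT) restriction-fragment markers with calls
#' in `PRESENT`, `ABSENT` (plus `NA`).
#'
#' @param calls character matrix, rows = loci, columns = samples. Valid
#'   entries depend on the marker type; `NA` marks a missing call.
#' @param loci data frame with columns `locus_id`, `marker_type` (all equal,
#'   `"SNP"` or `"PA"`), and optionally `ref_sequence`, `alt_sequence`,
#'   `snp_position` (1-based index of the variant site in the tag sequence).
#' @param samples data frame with columns `sample_id`,
#'   `sex` (`FEMALE`/`MALE`/`UNKNOWN`), `population`, `life_stage`
#'   (`TADPOLE`/`ADULT`/`OTHER`) and `replicate_group` (`NA` except for
#'   technical replicates, which share a group label).
#'
#' @details For SNP loci that carry tag sequences, `ref_sequence` and
#'   `alt_sequence` must be equal-length A/C/G/T strings differing at exactly
#'   one position, and `snp_position` must be that (1-based) position; use
#'   [snp_position_from_sequences()] to locate it. Sequence fields may be `NA`
#'   (e.g. simulated data).
#'
#' @return An object of class `genotype_dataset`: a list with elements
#'   `calls`, `loci`, `samples`, `marker_type`.
#' @seealso [read_genotype_table()], [simulate_dataset()]
#' @examples
#' calls <- matrix(c("REF_HOM", "HET", NA, "ALT_HOM"), nrow = 2,
#'                 dimnames = list(c("L1", "L2"), c("s1", "s2")))
#' d <- genotype_dataset(calls,
#'                       loci = data.frame(locus_id = c("L1", "L2"),
#'                                         marker_type = "SNP"),
#'                       samples = data.frame(sample_id = c("s1", "s2"),
#'                                            sex = c("FEMALE", "MALE")))
#' d
#' @export
genotype_dataset <- function(calls, loci, samples) {
  if (!is.matrix(calls) || !(is.character(calls) || all(is.na(calls)))) {
    stop("`calls` must be a character matrix (loci x samples)")
  }
  mode(calls) <- "character"
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!"locus_id" %in% names(loci)) stop("`loci` needs a locus_id column")
  if (!"marker_type" %in% names(loci)) loci$marker_type <- rep("SNP", nrow(loci))
  for (col in c("ref_sequence", "alt_sequence")) {
    if (!col %in% names(loci)) loci[[col]] <- rep(NA_character_, nrow(loci))
  }
  if (!"snp_position" %in% names(loci)) loci$snp_position <- rep(NA_integer_, nrow(loci))
  if (!"sample_id" %in% names(samples)) stop("`samples` needs a sample_id column")
  if (!"sex" %in% names(samples)) samples$sex <- rep("UNKNOWN", nrow(samples))
  if (!"population" %in% names(samples)) samples$population <- rep(NA_character_, nrow(samples))
  if (!"life_stage" %in% names(samples)) samples$life_stage <- rep("OTHER", nrow(samples))
  if (!"replicate_group" %in% names(samples)) samples$replicate_group <- rep(NA_character_, nrow(samples))
  samples$replicate_group[!is.na(samples$replicate_group) &
                            samples$replicate_group == ""] <- NA_character_

  if (nrow(calls) != nrow(loci) || ncol(calls) != nrow(samples)) {
    stop(sprintf("dimension mismatch: calls is %d x %d but %d loci, %d samples",
                 nrow(calls), ncol(calls), nrow(loci), nrow(samples)))
  }
  if (anyDuplicated(loci$locus_id)) {
    stop("duplicated locus_id: ",
         paste(unique(loci$locus_id[duplicated(loci$locus_id)]), collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicated sample_id: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]), collapse = ", "))
  }
  marker_type <- unique(loci$marker_type)
  if (length(marker_type) > 1) {
    stop("all loci in a dataset must share one marker_type; got: ",
         paste(marker_type, collapse = ", "))
  }
  if (length(marker_type) == 0) marker_type <- "SNP"
  if (!marker_type %in% c("SNP", "PA")) stop("marker_type must be 'SNP' or 'PA'")
  valid <- if (marker_type == "SNP") .SNP_CALLS else .PA_CALLS
  bad <- setdiff(unique(calls[!is.na(calls)]), valid)
  if (length(bad)) {
    stop("unknown call token(s) for ", marker_type, " data: ",
         paste(bad, collapse = ", "))
  }
  if (!all(samples$sex %in% .SEXES)) {
    stop("sample sex must be one of ", paste(.SEXES, collapse = ", "))
  }

  # sequence metadata checks (SNP loci with sequences present)
  if (marker_type == "SNP") {
    has_seq <- !is.na(loci$ref_sequence) & !is.na(loci$alt_sequence)
    for (i in which(has_seq)) {
      pos <- snp_position_from_sequences(loci$ref_sequence[i], loci$alt_sequence[i])
      if (is.na(loci$snp_position[i])) {
        loci$snp_position[i] <- pos
      } else if (loci$snp_position[i] != pos) {
        stop(sprintf("locus %s: snp_position %d does not match sequence mismatch at %d",
                     loci$locus_id[i], loci$snp_position[i], pos))
      }
    }
  }

  rownames(calls) <- loci$locus_id
  colnames(calls) <- samples$sample_id
  structure(list(calls = calls, loci = loci, samples = samples,
                 marker_type = marker_type),
            class = "genotype_dataset")
}

#' Locate the variant site shared by a REF/SNP allele tag pair
#'
#' Scans two equal-length DNA tag sequences and returns the 1-based position
#' at which they differ; errors unless they differ at exactly one position and
#' contain only A/C/G/T.
#'
#' @param ref,alt DNA strings (reference and SNP allele tag sequences).
#' @return Integer 1-based position of the single mismatch.
#' @examples
#' snp_position_from_sequences("TGCAGCGAGAACATTTCGGCATG",
#'                             "TGCAGCGAGAACATTTTGGCATG")
#' @export
snp_position_from_sequences <- function(ref, alt) {
  if (nchar(ref) != nchar(alt)) {
    stop("ref and alt tag sequences must have equal length")
  }
  r <- strsplit(toupper(ref), "")[[1]]
  a <- strsplit(toupper(alt), "")[[1]]
  if (!all(c(r, a) %in% c("A", "C", "G", "T"))) {
    stop("tag sequences may contain only A/C/G/T")
  }
  pos <- which(r != a)
  if (length(pos) != 1) {
    stop("sequences must differ at exactly one position; found ", length(pos))
  }
  as.integer(pos)
}

#' @export
print.genotype_dataset <- function(x, ...) {
  n_missing <- sum(is.na(x$calls))
  cat(sprintf("genotype_dataset: %d %s loci x %d samples (%.1f%% missing)\n",
              nrow(x$loci), x$marker_type, nrow(x$samples),
              if (length(x$calls)) 100 * n_missing / length(x$calls) else 0))
  sx <- table(factor(x$samples$sex, levels = .SEXES))
  cat(sprintf("samples: %d female, %d male, %d unknown sex; %d population(s)\n",
              sx[["FEMALE"]], sx[["MALE"]], sx[["UNKNOWN"]],
              length(unique(x$samples$population))))
  invisible(x)
}

#' Subset a genotype dataset
#'
#' @param x a [genotype_dataset()].
#' @param loci,samples locus ids / sample ids (character) or index vectors;
#'   `NULL` keeps all.
#' @param ... unused.
#' @return A `genotype_dataset` restricted to the requested loci and samples.
#' @export
subset_dataset <- function(x, loci = NULL, samples = NULL, ...) {
  stopifnot(inherits(x, "genotype_dataset"))
  li <- if (is.null(loci)) seq_len(nrow(x$loci)) else {
    if (is.character(loci)) match(loci, x$loci$locus_id) else loci
  }
  si <- if (is.null(samples)) seq_len(nrow(x$samples)) else {
    if (is.character(samples)) match(samples, x$samples$sample_id) else samples
  }
  if (anyNA(li)) stop("unknown locus id(s)")
  if (anyNA(si)) stop("unknown sample id(s)")
  genotype_dataset(x$calls[li, si, drop = FALSE],
                   x$loci[li, , drop = FALSE],
                   x$samples[si, , drop = FALSE])
}
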