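# Mutation calling, arm-level deletion, 1p/19q codeletion and 2016 WHO class
# from MAF-like variant tables and SEG-like copy-number segment tables.

# Closed vocabulary of variant classifications. Only the first three call a
# mutation; frameshift covers insertion- and deletion-type frameshifts.
VARIANT_CLASSES <- c("missense", "frameshift", "nonsense", "silent", "other")
QUALIFYING_CLASSES <- c("missense", "frameshift", "nonsense")

#' Read a MAF-like variant table
#'
#' Tab-separated with columns `patient_id`, `gene`, `variant_classification`.
#' Classifications must come from the closed vocabulary
#' missense/frameshift/nonsense/silent/other.
#'
#' @param path TSV path.
#' @return data.frame of variant records.
#' @export
read_maf <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "gene", "variant_classification")
  if (!all(need %in% names(df))) {
    stop_data("variant table must have columns: ", paste(need, collapse = ", "))
  }
  validate_variants(df)
  df
}

validate_variants <- function(variants) {
  bad <- setdiff(unique(variants$variant_classification), VARIANT_CLASSES)
  if (length(bad)) {
    stop_data("unknown variant classification(s): ", paste(bad, collapse = ", "))
  }
  invisible(variants)
}

#' Read a SEG-like copy-number segment table
#'
#' Tab-separated with columns `patient_id`, `chrom`, `arm`, `start`, `end`,
#' `seg_mean`. Coordinates are 1-based inclusive on disk; [seg_to_internal()]
#' converts to the half-open 0-based representation used internally.
#'
#' @param path TSV path.
#' @return data.frame of segments (1-based inclusive coordinates).
#' @export
read_seg <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "chrom", "arm", "start", "end", "seg_mean")
  if (!all(need %in% names(df))) {
    stop_data("segment table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(df$start > df$end)) stop_data("segment start > end")
  df
}

#' Convert segment coordinates between on-disk and internal conventions
#'
#' On disk: 1-based, inclusive `[start, end]`. Internal: 0-based, half-open
#' `[start0, end0)`. The pair of converters round-trips exactly.
#'
#' @param seg segment data.frame.
#' @return the data.frame with converted `start`/`end`.
#' @export
seg_to_internal <- function(seg) {
  seg$start <- seg$start - 1L
  seg
}

#' @rdname seg_to_internal
#' @export
seg_to_disk <- function(seg) {
  seg$start <- seg$start + 1L
  seg
}

#' Call mutation status for one patient and gene
#'
#' Status is 1 iff at least one record for the (patient, gene) pair has a
#' qualifying classification (missense, frameshift or nonsense); silent and
#' other records never trigger a call. Idempotent and order-independent.
#'
#' @param variants variant records (data.frame as from [read_maf()]).
#' @param patient patient identifier.
#' @param gene gene symbol.
#' @return integer 0/1.
#' @export
call_mutation <- function(variants, patient, gene) {
  validate_variants(variants)
  hit <- variants$patient_id == patient & variants$gene == gene &
    variants$variant_classification %in% QUALIFYING_CLASSES
  as.integer(any(hit))
}

#' Call arm-level deletion from copy-number segments
#'
#' An arm is called deleted when the length-weighted fraction of its covered
#' bases lying in segments with `seg_mean` below the threshold exceeds 0.5.
#' The threshold comparison is strict (a segment mean exactly at the
#' threshold does not count as deleted), and so is the majority comparison.
#'
#' @param segments segment data.frame (1-based inclusive coordinates).
#' @param arm arm label to call (e.g. `"1p"`, `"19q"`).
#' @param threshold deletion threshold on the segment mean (default -0.2).
#' @return 0/1, or `NA` (with class signalled by [arm_coverage_missing()])
#'   when no segment covers the arm.
#' @export
call_arm_deletion <- function(segments, arm, threshold = -0.2) {
  seg <- segments[segments$arm == arm, , drop = FALSE]
  if (nrow(seg) == 0L) return(NA_integer_)
  len <- as.numeric(seg$end) - as.numeric(seg$start) + 1
  if (any(len <= 0)) stop_data("non-positive segment length on arm ", arm)
  deleted <- seg$seg_mean < threshold
  frac <- sum(len[deleted]) / sum(len)
  as.integer(frac > 0.5)
}

#' Is an arm status missing (no coverage)?
#' @param status result of [call_arm_deletion()].
#' @return logical.
#' @export
arm_coverage_missing <- function(status) is.na(status)

#' Call 1p/19q codeletion
#'
#' Codeletion requires both 1p and 19q to be called deleted. If either arm is
#' uncovered the status is `NA`.
#'
#' @inheritParams call_arm_deletion
#' @return 0/1 or `NA`.
#' @export
call_1p19q_codeletion <- function(segments, threshold = -0.2) {
  d1p <- call_arm_deletion(segments, "1p", threshold)
  d19q <- call_arm_deletion(segments, "19q", threshold)
  if (is.na(d1p) || is.na(d19q)) return(NA_integer_)
  as.integer(d1p == 1L && d19q == 1L)
}

#' 2016 WHO histological class from molecular markers
#'
#' Oligodendroglioma is glioma with IDH mutation and 1p/19q codeletion;
#' everything else (IDH mutant without codeletion, or IDH wild-type) is
#' diffuse astrocytoma.
#'
#' @param idh 0/1 IDH mutation status.
#' @param codel 0/1 1p/19q codeletion status.
#' @return `"Oligodendroglioma"` or `"DiffuseAstrocytoma"` (`NA` in, `NA` out).
#' @export
classify_2016 <- function(idh, codel) {
  ifelse(is.na(idh) | is.na(codel), NA_character_,
         ifelse(idh == 1L & codel == 1L,
                "Oligodendroglioma", "DiffuseAstrocytoma"))
}

#' Screen genes by cohort mutation frequency
#'
#' Returns genes whose mutation-call rate across the cohort is at least
#' `min_fraction`, sorted by rate descending with ties broken alphabetically.
#'
#' @param variants variant records.
#' @param patients character vector of cohort patient ids (the denominator).
#' @param min_fraction minimum mutation rate in (0, 1].
#' @return data.frame with columns `gene`, `n_mutated`, `rate`.
#' @export
mutation_frequency_screen <- function(variants, patients, min_fraction = 0.05) {
  if (length(patients) == 0L) stop_data("empty cohort")
  if (!is.numeric(min_fraction) || min_fraction <= 0 || min_fraction > 1) {
    stop_cfg("min_fraction must be in (0, 1]")
  }
  validate_variants(variants)
  qual <- variants[variants$variant_classification %in% QUALIFYING_CLASSES &
                     variants$patient_id %in% patients, , drop = FALSE]
  if (nrow(qual) == 0L) {
    return(data.frame(gene = character(), n_mutated = integer(),
                      rate = numeric()))
  }
  tab <- stats::aggregate(patient_id ~ gene, data = qual,
                          FUN = function(p) length(unique(p)))
  names(tab)[2] <- "n_mutated"
  tab$rate <- tab$n_mutated / length(patients)
  tab <- tab[tab$rate >= min_fraction, , drop = FALSE]
  tab <- tab[order(-tab$rate, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Derive per-patient genomic status table
#'
#' Convenience wrapper calling CIC/IDH/FUBP1 mutation status, 1p/19q
#' codeletion and the 2016 WHO class for every patient.
#'
#' @param variants variant records.
#' @param segments segment records for all patients.
#' @param patients patient ids.
#' @param idh_genes gene symbols counted as IDH (default IDH1/IDH2).
#' @return data.frame with one row per patient.
#' @export
genomic_status_table <- function(variants, segments, patients,
                                 idh_genes = c("IDH1", "IDH2")) {
  res <- lapply(patients, function(p) {
    seg_p <- segments[segments$patient_id == p, , drop = FALSE]
    idh <- as.integer(any(vapply(idh_genes, function(g) {
      call_mutation(variants, p, g) == 1L
    }, logical(1))))
    codel <- call_1p19q_codeletion(seg_p)
    data.frame(patient_id = p,
               cic = call_mutation(variants, p, "CIC"),
               idh = idh,
               fubp1 = call_mutation(variants, p, "FUBP1"),
               codel = codel,
               histology_2016 = classify_2016(idh, codel),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
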