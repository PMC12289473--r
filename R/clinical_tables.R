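#' Integer floor percent of a feature frequency
#'
#' Cohort phenotype tables report each feature as `numerator/denominator`
#' with the percent truncated to an integer (floor), e.g. 5/12 prints as
#' 41 and 8/12 as 66.
#'
#' @param numerator Count of patients positive for the feature.
#' @param denominator Count of patients with a recorded +/- value.
#' @return Integer percent, `floor(100 * numerator / denominator)`.
#' @export
feature_frequency <- function(numerator, denominator) {
  stopifnot(length(numerator) == length(denominator))
  if (any(denominator < 1L)) stop("denominator must be >= 1", call. = FALSE)
  if (any(numerator < 0L) || any(numerator > denominator)) {
    stop("need 0 <= numerator <= denominator", call. = FALSE)
  }
  as.integer(floor(100 * numerator / denominator))
}

#' Summarize a per-patient feature table into cohort frequencies
#'
#' Rows are patients, columns are clinical features, cells are `+`
#' (present), `-` (absent) or `n.a.` (not assessed). Patients with
#' `n.a.` are excluded from a feature's denominator, following the
#' `x/y (z n.a.)` convention of clinical cohort tables.
#'
#' @param tab A data.frame of `+`/`-`/`n.a.` cells; an optional
#'   `patient_id` column is used for row labels.
#' @return A data.frame with one row per feature: `feature`, `numerator`,
#'   `denominator`, `n_na`, `percent` (`NA` if no patient was assessed).
#' @export
summarize_cohort <- function(tab) {
  stopifnot(is.data.frame(tab), nrow(tab) >= 1L)
  pid <- if ("patient_id" %in% names(tab)) {
    as.character(tab$patient_id)
  } else if (!is.null(rownames(tab))) {
    rownames(tab)
  } else {
    as.character(seq_len(nrow(tab)))
  }
  feats <- setdiff(names(tab), "patient_id")
  out <- lapply(feats, function(f) {
    v <- trimws(as.character(tab[[f]]))
    bad <- which(!v %in% c("+", "-", "n.a."))
    if (length(bad) > 0L) {
      stop(sprintf("unknown symbol '%s' for patient '%s', feature '%s'",
                   v[bad[1L]], pid[bad[1L]], f), call. = FALSE)
    }
    num <- sum(v == "+")
    den <- num + sum(v == "-")
    data.frame(feature = f, numerator = num, denominator = den,
               n_na = sum(v == "n.a."),
               percent = if (den > 0L) feature_frequency(num, den)
                         else NA_integer_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a per-patient phenotype table (TSV)
#'
#' @param path TSV with a `patient_id` column and one column per feature,
#'   cells in `+`/`-`/`n.a.`.
#' @return A data.frame suitable for [summarize_cohort()].
#' @export
read_phenotype_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character")
}

#' Read a variant table (TSV)
#'
#' Expected columns: `patient_id`, `cdna`, `protein`, `zygosity`
#' (`het`/`hom`), `criteria` (ACMG codes joined by `+`),
#' `classification`.
#'
#' @param path TSV file path.
#' @return A data.frame of variant records.
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("patient_id", "cdna", "protein", "zygosity", "criteria",
            "classification")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    stop(sprintf("variant table missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (!all(tab$zygosity %in% c("het", "hom"))) {
    stop("zygosity must be 'het' or 'hom'", call. = FALSE)
  }
  tab
}

#' Count distinct patients carrying a variant
#'
#' Homozygous carriers count once; the variant is matched by exact cDNA
#' notation (HGVS-style `c.` string).
#'
#' @param records Variant data.frame (see [read_variant_table()]).
#' @param cdna cDNA string, e.g. `"c.1199_1201del"`.
#' @return Integer count of distinct carrier patient ids.
#' @export
count_variant_carriers <- function(records, cdna) {
  stopifnot(is.data.frame(records))
  if (length(cdna) != 1L || !is.character(cdna) ||
      !grepl("^c\\.", cdna)) {
    stop("'cdna' must be a single HGVS cDNA string starting with 'c.'",
         call. = FALSE)
  }
  length(unique(records$patient_id[records$cdna == cdna]))
}

acmg_vocabulary <- c(
  "PVS1",
  paste0("PS", 1:4),
  paste0("PM", 1:6),
  paste0("PP", 1:5)
)

#' Combine pathogenic-side ACMG evidence codes into a classification
#'
#' Applies the standard evidence-combining rules over very strong
#' (PVS1), strong (PS1-4), moderate (PM1-6) and supporting (PP1-5)
#' pathogenicity criteria. Duplicate codes are collapsed and order is
#' irrelevant. Benign-side codes are out of scope.
#'
#' Pathogenic: PVS1 with (>=1 PS, or >=2 PM, or 1 PM + 1 PP, or >=2 PP);
#' or >=2 PS; or 1 PS with (>=3 PM, or 2 PM + >=2 PP, or 1 PM + >=4 PP).
#' Likely pathogenic: PVS1 + 1 PM; 1 PS + 1-2 PM; 1 PS + >=2 PP;
#' >=3 PM; 2 PM + >=2 PP; 1 PM + >=4 PP. Anything less: VUS.
#'
#' @param criteria Character vector of ACMG codes (e.g.
#'   `c("PVS1", "PM2")`) or a single `+`-joined string (`"PVS1+PM2"`).
#' @return `"Pathogenic"`, `"Likely pathogenic"` or `"VUS"`.
#' @export
acmg_classify <- function(criteria) {
  if (length(criteria) == 1L && grepl("[+]", criteria)) {
    criteria <- strsplit(criteria, "+", fixed = TRUE)[[1L]]
  }
  criteria <- unique(trimws(criteria))
  criteria <- criteria[nzchar(criteria)]
  unknown <- setdiff(criteria, acmg_vocabulary)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown ACMG code(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  pvs <- "PVS1" %in% criteria
  ns <- sum(grepl("^PS", criteria))
  nm <- sum(grepl("^PM", criteria))
  np <- sum(grepl("^PP", criteria))

  pathogenic <-
    (pvs && (ns >= 1 || nm >= 2 || (nm >= 1 && np >= 1) || np >= 2)) ||
    ns >= 2 ||
    (ns >= 1 && (nm >= 3 || (nm >= 2 && np >= 2) || (nm >= 1 && np >= 4)))
  if (pathogenic) return("Pathogenic")

  likely <-
    (pvs && nm >= 1) ||
    (ns >= 1 && nm >= 1) ||
    (ns >= 1 && np >= 2) ||
    nm >= 3 ||
    (nm >= 2 && np >= 2) ||
    (nm >= 1 && np >= 4)
  if (likely) return("Likely pathogenic")
  "VUS"
}

#' Classify every row of a variant table and flag concordance
#'
#' @param records Variant data.frame with a `criteria` column
#'   (`+`-joined codes) and optionally a reported `classification`.
#' @return The input with columns `computed_classification` and (if a
#'   reported classification exists) logical `concordant`.
#' @export
classify_variants <- function(records) {
  stopifnot(is.data.frame(records), "criteria" %in% names(records))
  records$computed_classification <-
    vapply(records$criteria, acmg_classify, character(1), USE.NAMES = FALSE)
  if ("classification" %in% names(records)) {
    records$concordant <-
      records$computed_classification == records$classification
  }
  records
}
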