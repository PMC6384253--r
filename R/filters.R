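#' Site quality-control thresholds
#'
#' Constructor for the hard-filter thresholds applied by [qc_filter()].
#' Defaults are the standard exome hard-filter values: a site is removed
#' when its RMS mapping quality falls below 30, it has more than 4 reads
#' with mapping quality zero, its approximate depth is below 5, its QUAL is
#' below 50, or its phred-scaled strand-bias score exceeds 10. All
#' boundaries are inclusive on the passing side (MQ = 30 passes).
#'
#' @param min_mapping_quality Minimum RMS mapping quality (MQ).
#' @param max_mq0_reads Maximum count of mapping-quality-zero reads (MQ0).
#' @param min_site_depth Minimum approximate site read depth (DP).
#' @param min_qual Minimum variant quality (QUAL).
#' @param max_strand_bias_phred Maximum phred-scaled strand-bias score (FS).
#' @param mq0_literal If `TRUE`, invert the MQ0 rule to remove sites with
#'   *fewer* than `max_mq0_reads` MQ0 reads. This literal reading of the
#'   rule discards the cleanest sites and exists only for comparison; the
#'   default removes sites with an excess of MQ0 reads.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_mapping_quality = 30,
                          max_mq0_reads = 4,
                          min_site_depth = 5,
                          min_qual = 50.0,
                          max_strand_bias_phred = 10.0,
                          mq0_literal = FALSE) {
  stopifnot(is.numeric(min_mapping_quality), is.numeric(max_mq0_reads),
            is.numeric(min_site_depth), is.numeric(min_qual),
            is.numeric(max_strand_bias_phred), is.logical(mq0_literal))
  structure(
    list(min_mapping_quality = min_mapping_quality,
         max_mq0_reads = max_mq0_reads,
         min_site_depth = min_site_depth,
         min_qual = min_qual,
         max_strand_bias_phred = max_strand_bias_phred,
         mq0_literal = mq0_literal),
    class = "qc_thresholds"
  )
}

#' Functional and prevalence filter thresholds
#'
#' Constructor for the thresholds applied by [functional_filter()]:
#' synonymous variants are dropped, as are variants with allele frequency
#' above 5% in any population database, carrier-sample depth of coverage
#' below 6, or carrier-sample variant allele fraction ("mutation ratio")
#' below 30%.
#'
#' @param max_db_frequency Maximum allele frequency tolerated in any
#'   population database; absent frequencies are treated as 0.
#' @param min_carrier_depth Minimum depth of coverage across carrier
#'   samples (reads).
#' @param min_alt_fraction Minimum variant allele fraction across carrier
#'   samples, in `[0, 1]`.
#' @param drop_synonymous Drop synonymous variants?
#' @param aggregate How depth and allele fraction are summarized across
#'   carrier samples: `"mean"` (default) or `"min"` (every carrier must
#'   individually pass).
#' @return A list of class `functional_thresholds`.
#' @export
functional_thresholds <- function(max_db_frequency = 0.05,
                                  min_carrier_depth = 6,
                                  min_alt_fraction = 0.30,
                                  drop_synonymous = TRUE,
                                  aggregate = c("mean", "min")) {
  stopifnot(max_db_frequency >= 0, max_db_frequency <= 1 ||
              is.infinite(max_db_frequency),
            min_alt_fraction >= 0, min_alt_fraction <= 1)
  structure(
    list(max_db_frequency = max_db_frequency,
         min_carrier_depth = min_carrier_depth,
         min_alt_fraction = min_alt_fraction,
         drop_synonymous = drop_synonymous,
         aggregate = match.arg(aggregate)),
    class = "functional_thresholds"
  )
}

new_filter_report <- function(stage, input, output, reasons,
                              rejections = NULL, extra = list()) {
  stopifnot(output + sum(reasons) == input)
  structure(
    c(list(stage = stage, input = as.integer(input),
           output = as.integer(output), reasons = reasons,
           rejections = rejections), extra),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report: %s>  %d -> %d variants\n",
              x$stage, x$input, x$output))
  if (length(x$reasons) > 0L && sum(x$reasons) > 0L) {
    for (r in names(x$reasons)) {
      if (x$reasons[[r]] > 0L) cat(sprintf("  rejected %-24s %d\n", r,
                                           x$reasons[[r]]))
    }
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a filter report into one row per rejection reason
#' @param x A `filter_report`.
#' @param ... Unused.
#' @method tidy filter_report
#' @export
tidy.filter_report <- function(x, ...) {
  tibble::tibble(
    stage = x$stage,
    reason = c("passed", names(x$reasons)),
    n = c(x$output, unname(unlist(x$reasons)))
  )
}

#' One-row summary of a filter report
#' @param x A `filter_report`.
#' @param ... Unused.
#' @method glance filter_report
#' @export
glance.filter_report <- function(x, ...) {
  tibble::tibble(stage = x$stage, input = x$input, output = x$output,
                 rejected = x$input - x$output)
}

append_report <- function(variants, report) {
  reports <- c(attr(variants, "filter_reports"), list(report))
  names(reports)[length(reports)] <- report$stage
  attr(variants, "filter_reports") <- reports
  variants
}

#' Retrieve accumulated filter reports
#'
#' Each filter stage attaches its [tidy()]-able report to the returned
#' variant tibble, so a piped cascade carries its own counts ledger.
#'
#' @param variants Variant tibble that has passed through filter stages.
#' @return Named list of `filter_report` objects (possibly empty).
#' @export
filter_reports <- function(variants) {
  attr(variants, "filter_reports") %||% list()
}

first_reason <- function(fail_mat, reason_order) {
  # fail_mat: logical matrix n x k, columns in documented order
  idx <- apply(fail_mat, 1L, function(z) {
    w <- which(z %in% TRUE)
    if (length(w) == 0L) NA_integer_ else w[1]
  })
  reason_order[idx]
}

#' Stage 1: site quality-control filter
#'
#' Removes variants failing any of five site-level hard-filter criteria,
#' checked in a fixed order (mapping quality, MQ0 excess, site depth,
#' QUAL, strand bias); the rejection reason recorded for a variant is the
#' first criterion it fails, making reports deterministic. Variants with a
#' missing QC field are rejected with reason `missing_qc_field` unless
#' `missing = "pass"`.
#'
#' @param variants Variant tibble from [read_vcf()].
#' @param thresholds A [qc_thresholds()] object.
#' @param missing Policy for records with a missing QC field: `"reject"`
#'   (default) or `"pass"` the criterion that cannot be evaluated.
#' @return The passing subset of `variants`, with a `filter_report`
#'   appended (see [filter_reports()]).
#' @export
qc_filter <- function(variants, thresholds = qc_thresholds(),
                      missing = c("reject", "pass")) {
  missing <- match.arg(missing)
  th <- thresholds
  mq0_fail <- if (th$mq0_literal) {
    variants$mq0 < th$max_mq0_reads
  } else {
    variants$mq0 > th$max_mq0_reads
  }
  fail <- cbind(
    low_mapping_quality = variants$mq < th$min_mapping_quality,
    excess_mq0_reads    = mq0_fail,
    low_site_depth      = variants$dp < th$min_site_depth,
    low_site_quality    = variants$qual < th$min_qual,
    strand_bias         = variants$fs > th$max_strand_bias_phred
  )
  any_missing <- apply(fail, 1L, anyNA)
  if (missing == "pass") fail[is.na(fail)] <- FALSE
  reason <- first_reason(fail, colnames(fail))
  reason[is.na(reason) & any_missing & missing == "reject"] <-
    "missing_qc_field"
  finish_stage(variants, reason, "qc",
               c(colnames(fail), "missing_qc_field"))
}

max_db_frequency <- function(variants) {
  af_cols <- grep("^af_", names(variants), value = TRUE)
  if (length(af_cols) == 0L) return(rep(0, nrow(variants)))
  af <- as.matrix(variants[af_cols])
  af[is.na(af)] <- 0
  apply(af, 1L, max)
}

carrier_coverage <- function(calls, aggregate) {
  carriers <- dplyr::filter(calls, .data$carrier %in% TRUE)
  if (nrow(carriers) == 0L) {
    return(c(depth = NA_real_, vaf = NA_real_, n = 0))
  }
  vaf <- carriers$alt_reads / carriers$depth
  agg <- if (aggregate == "mean") {
    function(x) mean(x, na.rm = TRUE)
  } else {
    function(x) suppressWarnings(min(x, na.rm = TRUE))
  }
  c(depth = agg(carriers$depth), vaf = agg(vaf), n = nrow(carriers))
}

#' Stage 2: functional and prevalence filter
#'
#' Removes variants that are synonymous, common in any population database
#' (frequency above `max_db_frequency`; absent frequencies count as 0),
#' carried by no sample, or poorly supported in the carrier samples (depth
#' of coverage or variant allele fraction below threshold, summarized
#' across carriers per `thresholds$aggregate`). Rejection reasons are
#' recorded in that order.
#'
#' @inheritParams qc_filter
#' @param thresholds A [functional_thresholds()] object.
#' @return The passing subset with a `filter_report` appended.
#' @export
functional_filter <- function(variants, thresholds = functional_thresholds()) {
  th <- thresholds
  cov <- purrr::map(variants$calls, carrier_coverage,
                    aggregate = th$aggregate)
  depth <- purrr::map_dbl(cov, "depth")
  vaf <- purrr::map_dbl(cov, "vaf")
  n_carriers <- purrr::map_dbl(cov, "n")
  fail <- cbind(
    synonymous         = th$drop_synonymous &
                           variants$csq_class == "synonymous",
    common_in_database = max_db_frequency(variants) > th$max_db_frequency,
    no_carrier         = n_carriers == 0,
    low_carrier_depth  = depth < th$min_carrier_depth,
    low_alt_fraction   = vaf < th$min_alt_fraction
  )
  # depth/vaf are NA only when there is no carrier, which is caught first
  reason <- first_reason(fail, colnames(fail))
  finish_stage(variants, reason, "functional", colnames(fail))
}

#' Stage 3: segregation filter under a dominant model
#'
#' Applies the two within-family predicates in sequence:
#'
#' 1. *sharing* — every affected member and every obligate carrier is a
#'    called carrier of the variant;
#' 2. *marry-in exclusion* — no marry-in is a called carrier.
#'
#' By default a missing genotype fails predicate 1 (an uncalled required
#' sample cannot be confirmed to share) and is ignored by predicate 2
#' (only a confirmed carrier excludes); `missing_as_compatible = TRUE`
#' makes predicate 1 treat missing calls as compatible as well. The report
#' records the count after each predicate separately.
#'
#' @inheritParams qc_filter
#' @param ped Pedigree tibble; roles are computed if absent.
#' @param obligate_carriers Character vector of obligate-carrier ids;
#'   defaults to [infer_obligate_carriers()] on `ped`.
#' @param missing_as_compatible Treat missing genotypes in required
#'   samples as compatible with sharing?
#' @return The passing subset with a `filter_report` appended; the report
#'   carries `after_sharing`, the count after predicate 1 alone.
#' @export
segregation_filter <- function(variants, ped, obligate_carriers = NULL,
                               missing_as_compatible = FALSE) {
  if (!"role" %in% names(ped)) ped <- classify_roles(ped)
  if (is.null(obligate_carriers)) {
    obligate_carriers <- infer_obligate_carriers(ped)
  }
  required <- union(ped$id[ped$role == "affected"], obligate_carriers)
  excluded <- ped$id[ped$role == "marry_in"]

  shared <- purrr::map_lgl(variants$calls, function(calls) {
    st <- calls$carrier[match(required, calls$sample_id)]
    if (missing_as_compatible) st[is.na(st)] <- TRUE
    all(st %in% TRUE)
  })
  in_marry_in <- purrr::map_lgl(variants$calls, function(calls) {
    any(calls$carrier[match(excluded, calls$sample_id)] %in% TRUE)
  })

  reason <- dplyr::case_when(
    !shared              ~ "not_shared_by_required",
    in_marry_in          ~ "carried_by_marry_in",
    TRUE                 ~ NA_character_
  )
  finish_stage(variants, reason, "segregation",
               c("not_shared_by_required", "carried_by_marry_in"),
               extra = list(after_sharing = sum(shared)))
}

finish_stage <- function(variants, reason, stage, reason_levels,
                         extra = list()) {
  keep <- is.na(reason)
  reasons <- table(factor(reason, levels = reason_levels))
  reasons <- stats::setNames(as.integer(reasons), names(reasons))
  rejections <- tibble::tibble(
    variant_id = variants$variant_id[!keep],
    reason = reason[!keep]
  )
  report <- new_filter_report(stage, nrow(variants), sum(keep), reasons,
                              rejections = rejections, extra = extra)
  prior <- attr(variants, "filter_reports")  # `[` drops attributes
  out <- variants[keep, , drop = FALSE]
  attr(out, "filter_reports") <- prior
  append_report(out, report)
}
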