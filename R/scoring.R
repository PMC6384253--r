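#' Prioritization scoring configuration
#'
#' Parameters of the multiplicative variant-prioritization score. The
#' three components — annotation, population, and dominant-model
#' segregation — are each in `(0, 1]` and are combined by product.
#'
#' Segregation penalties: each affected member not carrying the variant
#' multiplies the score by `affected_noncarrier_penalty`; each unaffected
#' blood member carrying it (obligate carriers exempt) multiplies it by
#' `unaffected_carrier_penalty`. The defaults 0.1 and 0.8 are calibrated
#' so that fully consistent dominant segregation scores 1 and observed
#' score spectra factorize as `0.8^u * 0.1^a`.
#'
#' Population tiers (first match wins, frequency = maximum across
#' databases): not in dbSNP -> 1.0; in dbSNP with no recorded frequency ->
#' 0.6; frequency below `rare_frequency` -> 0.2; otherwise -> 0.02. The
#' tier boundaries (0.001 and the 0.05 prevalence cut upstream) are
#' configurable.
#'
#' @param affected_noncarrier_penalty Penalty per affected non-carrier.
#' @param unaffected_carrier_penalty Penalty per unaffected blood-member
#'   carrier.
#' @param rare_frequency Boundary between the 0.2 and 0.02 tiers.
#' @param tier_scores Named numeric vector with entries `novel`,
#'   `no_frequency`, `rare`, `common`.
#' @param annotation_scores Named numeric vector mapping consequence
#'   classes to scores.
#' @return A list of class `scoring_config`.
#' @export
scoring_config <- function(affected_noncarrier_penalty = 0.1,
                           unaffected_carrier_penalty = 0.8,
                           rare_frequency = 0.001,
                           tier_scores = c(novel = 1.0, no_frequency = 0.6,
                                           rare = 0.2, common = 0.02),
                           annotation_scores = c(lof_or_damaging = 1.0,
                                                 nonsynonymous = 0.8,
                                                 synonymous = 0.01,
                                                 noncoding = 0.01)) {
  stopifnot(
    affected_noncarrier_penalty > 0, affected_noncarrier_penalty <= 1,
    unaffected_carrier_penalty > 0, unaffected_carrier_penalty <= 1,
    all(tier_scores > 0), all(tier_scores <= 1),
    all(annotation_scores > 0), all(annotation_scores <= 1),
    all(c("novel", "no_frequency", "rare", "common") %in% names(tier_scores))
  )
  structure(
    list(affected_noncarrier_penalty = affected_noncarrier_penalty,
         unaffected_carrier_penalty = unaffected_carrier_penalty,
         rare_frequency = rare_frequency,
         tier_scores = tier_scores,
         annotation_scores = annotation_scores),
    class = "scoring_config"
  )
}

#' Dominant-model segregation score
#'
#' For each variant, counts affected members not called as carriers and
#' unaffected blood members called as carriers (obligate carriers exempt:
#' under incomplete penetrance an unaffected obligate carrier is expected
#' to carry the allele), and returns
#' `pi_a^(affected non-carriers) * pi_u^(unaffected carriers)`.
#' Missing genotypes contribute no penalty. A variant whose genotypes are
#' fully consistent with dominant segregation scores 1.
#'
#' @param variants Variant tibble with a `calls` list-column.
#' @param ped Pedigree tibble; roles computed if absent.
#' @param config A [scoring_config()].
#' @param obligate_carriers Obligate-carrier ids; defaults to
#'   [infer_obligate_carriers()].
#' @return Numeric vector of scores in `(0, 1]`.
#' @export
segregation_score_dominant <- function(variants, ped,
                                       config = scoring_config(),
                                       obligate_carriers = NULL) {
  if (!"role" %in% names(ped)) ped <- classify_roles(ped)
  if (is.null(obligate_carriers)) {
    obligate_carriers <- infer_obligate_carriers(ped)
  }
  affected <- ped$id[ped$role == "affected"]
  unaffected_blood <- setdiff(ped$id[ped$role == "unaffected_blood"],
                              obligate_carriers)
  purrr::map_dbl(variants$calls, function(calls) {
    carrier <- stats::setNames(calls$carrier, calls$sample_id)
    a <- sum(carrier[affected] %in% FALSE)
    u <- sum(carrier[unaffected_blood] %in% TRUE)
    config$affected_noncarrier_penalty^a *
      config$unaffected_carrier_penalty^u
  })
}

#' Population rarity score
#'
#' Tiered score of a variant's prevalence in reference populations. The
#' frequency used is the maximum across all `af_*` database columns;
#' tiers, first match wins: no dbSNP identifier -> `novel` (1.0); dbSNP
#' identifier but no recorded frequency -> `no_frequency` (0.6); maximum
#' frequency below `rare_frequency` -> `rare` (0.2); otherwise ->
#' `common` (0.02). Frequencies above the upstream prevalence cut still
#' receive the lowest tier (tiering is independent of filtering).
#'
#' @param variants Variant tibble with `dbsnp` and `af_*` columns.
#' @param config A [scoring_config()].
#' @return Numeric vector of tier scores.
#' @export
population_score <- function(variants, config = scoring_config()) {
  freq <- max_db_frequency(variants)
  has_freq <- freq > 0
  ts <- config$tier_scores
  dplyr::case_when(
    is.na(variants$dbsnp)                 ~ ts[["novel"]],
    !has_freq                             ~ ts[["no_frequency"]],
    freq < config$rare_frequency          ~ ts[["rare"]],
    TRUE                                  ~ ts[["common"]]
  )
}

#' Functional annotation score
#'
#' Maps each variant's consequence class to its score (defaults:
#' loss-of-function or predicted-damaging 1.0, other nonsynonymous 0.8,
#' synonymous and noncoding 0.01). An unrecognized class receives the
#' lowest configured score, with a warning.
#'
#' @param variants Variant tibble with a `csq_class` column.
#' @param config A [scoring_config()].
#' @return Numeric vector of annotation scores.
#' @export
annotation_score <- function(variants, config = scoring_config()) {
  scores <- config$annotation_scores
  out <- unname(scores[variants$csq_class])
  unknown <- is.na(out)
  if (any(unknown)) {
    warning("unknown consequence class: ",
            paste(unique(variants$csq_class[unknown]), collapse = ", "),
            "; assigned lowest annotation score", call. = FALSE)
    out[unknown] <- min(scores)
  }
  out
}

#' Null-sharing statistic
#'
#' The probability `(1/2)^m` that `m` informative transmissions would all
#' carry the same allele under random Mendelian segregation, where `m` is
#' the number of blood-member carriers among non-founders. Small values
#' indicate sharing far beyond chance expectation.
#'
#' @param variants Variant tibble with a `calls` list-column.
#' @param ped Pedigree tibble; roles computed if absent.
#' @return Numeric vector of `(1/2)^m` values.
#' @export
null_sharing_score <- function(variants, ped) {
  if (!"role" %in% names(ped)) ped <- classify_roles(ped)
  non_founder_blood <- ped$id[!is_founder(ped) &
                                ped$role %in% c("affected",
                                                "unaffected_blood")]
  purrr::map_dbl(variants$calls, function(calls) {
    m <- sum(calls$carrier[match(non_founder_blood,
                                 calls$sample_id)] %in% TRUE)
    0.5^m
  })
}

#' Score and rank candidate variants
#'
#' Computes the three component scores for every variant, combines them
#' multiplicatively (`overall = ann_score * popu_score * seg_score_dom`),
#' and ranks candidates by decreasing overall score. Ties are broken by
#' higher population score, then chromosome and position, so the ranking
#' is deterministic.
#'
#' @param variants Variant tibble (typically the filter-cascade
#'   survivors).
#' @param ped Pedigree tibble.
#' @param config A [scoring_config()].
#' @param obligate_carriers Obligate-carrier ids; defaults to
#'   [infer_obligate_carriers()].
#' @return `variants` with columns `ann_score`, `popu_score`,
#'   `seg_score_dom`, `seg_score` (null-sharing statistic), `overall`,
#'   and `rank`, ordered by rank.
#' @examples
#' sim <- simulate_pedigree_dataset(sim_spec(seed = 1))
#' ranked <- prioritize_variants(
#'   segregation_filter(sim$variants, sim$ped), sim$ped)
#' head(ranked[, c("variant_id", "overall", "rank")])
#' @export
prioritize_variants <- function(variants, ped, config = scoring_config(),
                                obligate_carriers = NULL) {
  reports <- attr(variants, "filter_reports")
  out <- variants |>
    dplyr::mutate(
      ann_score = annotation_score(variants, config),
      popu_score = population_score(variants, config),
      seg_score_dom = segregation_score_dominant(variants, ped, config,
                                                 obligate_carriers),
      seg_score = null_sharing_score(variants, ped),
      overall = .data$ann_score * .data$popu_score * .data$seg_score_dom
    ) |>
    dplyr::arrange(dplyr::desc(.data$overall), dplyr::desc(.data$popu_score),
                   .data$chrom, .data$pos) |>
    dplyr::mutate(rank = dplyr::row_number())
  attr(out, "filter_reports") <- reports
  out
}

#' Combine component scores into an overall priority score
#'
#' The multiplicative combination rule used by [prioritize_variants()],
#' exposed for scoring components obtained elsewhere (e.g. a published
#' score table).
#'
#' @param ann_score,popu_score,seg_score_dom Component score vectors.
#' @return `ann_score * popu_score * seg_score_dom`.
#' @examples
#' combine_scores(0.01, 0.02, 1)
#' @export
combine_scores <- function(ann_score, popu_score, seg_score_dom) {
  stopifnot(all(ann_score > 0 & ann_score <= 1, na.rm = TRUE),
            all(popu_score > 0 & popu_score <= 1, na.rm = TRUE),
            all(seg_score_dom > 0 & seg_score_dom <= 1, na.rm = TRUE))
  ann_score * popu_score * seg_score_dom
}
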