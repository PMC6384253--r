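#' Published reference candidate score table
#'
#' The 26-row ranked candidate table from the familial mood-disorder
#' exome study the package's scoring defaults are calibrated against:
#' per-variant overall, annotation, population and dominant-segregation
#' scores plus the null-sharing statistic, region class, dbSNP id,
#' variant type and reference-population allele frequency. Shipped as a
#' regression fixture: the multiplicative combination rule and the score
#' vocabularies can be checked against every row.
#'
#' @return Tibble with one row per ranked candidate variant.
#' @examples
#' ref <- reference_candidate_scores()
#' all.equal(ref$overall_score,
#'           combine_scores(ref$ann_score, ref$popu_score,
#'                          ref$seg_score_dom),
#'           tolerance = 0.005)
#' @export
reference_candidate_scores <- function() {
  path <- system.file("extdata", "candidate_scores_reference.tsv",
                      package = "pedscreen", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, na = "NA",
                  col_types = readr::cols(
                    rank = readr::col_integer(),
                    locus = readr::col_character(),
                    gene = readr::col_character(),
                    overall_score = readr::col_double(),
                    ann_score = readr::col_double(),
                    popu_score = readr::col_double(),
                    seg_score_dom = readr::col_double(),
                    seg_score = readr::col_double(),
                    region = readr::col_character(),
                    dbsnp = readr::col_character(),
                    variant_type = readr::col_character(),
                    af_1000g = readr::col_double()
                  ))
}
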