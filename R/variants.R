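#' Region-class vocabulary
#'
#' The closed vocabulary of genomic region classes used by the annotation
#' model and by [tabulate_regions()]. These are the region labels emitted
#' by exome annotation pipelines (exonic, intronic, splicing, non-coding
#' RNA variants thereof, UTRs, upstream/downstream, intergenic and the
#' compound classes).
#'
#' @return Character vector of valid `region` values.
#' @export
region_classes <- function() {
  c("exonic", "intronic", "splicing", "ncRNA_exonic", "ncRNA_intronic",
    "ncRNA_splicing", "UTR5", "UTR3", "upstream", "downstream",
    "intergenic", "exonic_splicing", "upstream_downstream", "UTR5_UTR3")
}

#' Functional consequence classes
#'
#' @return Character vector of valid `csq_class` values, ordered from most
#'   to least severe.
#' @export
consequence_classes <- function() {
  c("lof_or_damaging", "nonsynonymous", "synonymous", "noncoding")
}

# INFO keys the variant model retains; AF_* keys are discovered dynamically
info_keys <- c("MQ", "MQ0", "DP", "FS", "GENE", "REGION", "CSQCLASS")

# dose of a given ALT allele index within GT strings such as "0/1", "1|2"
parse_gt_dose <- function(gt, allele_index) {
  alleles <- stringr::str_split(gt, "[/|]")
  purrr::map_int(alleles, function(a) {
    if (length(a) == 0L || anyNA(a) || any(a == ".")) return(NA_integer_)
    as.integer(sum(a == as.character(allele_index)))
  })
}

#' Read an annotated multi-sample VCF
#'
#' Reads a VCF v4.x file into the package's variant model: a tibble with
#' one row per (site, ALT allele) — multi-allelic sites are split — and a
#' nested `calls` list-column holding one genotype tibble per variant
#' (`sample_id`, `gt` = alt-allele dose 0/1/2 or `NA`, `depth`,
#' `alt_reads`, `carrier`). A sample is a carrier when it holds at least
#' one copy of the ALT allele.
#'
#' Site-level quality fields are taken from QUAL and the INFO keys `MQ`,
#' `MQ0`, `DP`, `FS`; annotation from `GENE`, `REGION`, `CSQCLASS`, the ID
#' column (dbSNP identifier) and every `AF_<database>` INFO key, which
#' become lower-case `af_<database>` columns.
#'
#' @param file Path to a VCF file (plain text).
#' @param ped Optional pedigree tibble; when supplied the VCF sample set is
#'   reconciled against the pedigree.
#' @param on_missing_sample What to do when a pedigree member has no VCF
#'   column: `"warn"` (default) or `"error"`.
#' @return Tibble with columns `variant_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `variant_type` (`"SNV"`/`"indel"`), `qual`, `mq`, `mq0`, `dp`, `fs`,
#'   `gene`, `region`, `csq_class`, `dbsnp`, `af_*` columns, and `calls`.
#' @export
read_vcf <- function(file, ped = NULL,
                     on_missing_sample = c("warn", "error")) {
  on_missing_sample <- match.arg(on_missing_sample)
  vcf <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- vcf@fix
  if (nrow(fix) == 0L) {
    return(empty_variants())
  }
  samples <- colnames(vcf@gt)[-1]
  if (!is.null(ped)) {
    absent <- setdiff(ped$id, samples)
    if (length(absent) > 0L) {
      msg <- paste("pedigree samples absent from VCF:",
                   paste(absent, collapse = ", "))
      if (on_missing_sample == "error") stop(msg, call. = FALSE)
      warning(msg, call. = FALSE)
    }
    extra <- setdiff(samples, ped$id)
    if (length(extra) > 0L) {
      warning("VCF samples not in pedigree: ",
              paste(extra, collapse = ", "), call. = FALSE)
    }
  }

  gt_mat <- vcfR::extract.gt(vcf)
  dp_mat <- suppressWarnings(
    vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  ad_mat <- vcfR::extract.gt(vcf, element = "AD")

  info_num <- function(key) {
    suppressWarnings(vcfR::extract.info(vcf, element = key, as.numeric = TRUE))
  }
  info_chr <- function(key) vcfR::extract.info(vcf, element = key)

  af_keys <- unique(unlist(
    stringr::str_extract_all(fix[, "INFO"], "AF_[A-Za-z0-9]+")))
  af_keys <- sort(af_keys)

  base <- tibble::tibble(
    site      = seq_len(nrow(fix)),
    chrom     = fix[, "CHROM"],
    pos       = as.integer(fix[, "POS"]),
    ref       = fix[, "REF"],
    alt_field = fix[, "ALT"],
    qual      = as.numeric(fix[, "QUAL"]),
    mq        = info_num("MQ"),
    mq0       = info_num("MQ0"),
    dp        = info_num("DP"),
    fs        = info_num("FS"),
    gene      = info_chr("GENE"),
    region    = info_chr("REGION"),
    csq_class = info_chr("CSQCLASS"),
    dbsnp     = dplyr::na_if(fix[, "ID"], ".")
  )
  for (k in af_keys) {
    base[[tolower(k)]] <- info_num(k)
  }

  # split multi-allelic sites: one record per ALT allele
  split <- base |>
    dplyr::mutate(alt = stringr::str_split(.data$alt_field, ",")) |>
    tidyr::unnest_longer(col = "alt", indices_to = "allele_index") |>
    dplyr::select(-"alt_field")

  split$calls <- purrr::map2(split$site, split$allele_index, function(i, k) {
    gt <- gt_mat[i, samples]
    ad <- ad_mat[i, samples]
    dose <- parse_gt_dose(gt, k)
    alt_reads <- purrr::map_int(ad, function(a) {
      if (is.na(a)) return(NA_integer_)
      parts <- suppressWarnings(as.integer(strsplit(a, ",")[[1]]))
      if (length(parts) < k + 1L) NA_integer_ else parts[k + 1L]
    })
    tibble::tibble(
      sample_id = samples,
      gt        = dose,
      depth     = as.integer(dp_mat[i, samples]),
      alt_reads = unname(alt_reads),
      carrier   = dose >= 1L
    )
  })

  split |>
    dplyr::mutate(
      variant_id   = paste(.data$chrom, .data$pos, .data$ref, .data$alt,
                           sep = ":"),
      variant_type = ifelse(nchar(.data$ref) != nchar(.data$alt),
                            "indel", "SNV")
    ) |>
    dplyr::select("variant_id", "chrom", "pos", "ref", "alt", "variant_type",
                  "qual", "mq", "mq0", "dp", "fs", "gene", "region",
                  "csq_class", "dbsnp", dplyr::starts_with("af_"), "calls")
}

empty_variants <- function() {
  tibble::tibble(
    variant_id = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), variant_type = character(),
    qual = numeric(), mq = numeric(), mq0 = numeric(), dp = numeric(),
    fs = numeric(), gene = character(), region = character(),
    csq_class = character(), dbsnp = character(), calls = list()
  )
}

fmt_num <- function(x) {
  ifelse(is.na(x), NA_character_,
         sub("e([+-])0*(\\d)", "e\\1\\2", sprintf("%.10g", x)))
}

#' Write variants to VCF
#'
#' Serializes a variant tibble (as produced by [read_vcf()] or
#' [simulate_pedigree_dataset()]) back to VCF v4.2 text with the package's
#' INFO/FORMAT schema. Records already split per ALT allele are written as
#' biallelic lines, so `read_vcf(write_vcf(x))` is the identity on the
#' retained fields.
#'
#' @param variants Variant tibble.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_vcf <- function(variants, file) {
  af_cols <- grep("^af_", names(variants), value = TRUE)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=pedscreen",
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">',
    '##INFO=<ID=MQ0,Number=1,Type=Integer,Description="Mapping quality zero reads">',
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Approximate site read depth">',
    '##INFO=<ID=FS,Number=1,Type=Float,Description="Phred-scaled strand-bias p-value">',
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=REGION,Number=1,Type=String,Description="Genomic region class">',
    '##INFO=<ID=CSQCLASS,Number=1,Type=String,Description="Consequence class">',
    purrr::map_chr(af_cols, ~ sprintf(
      '##INFO=<ID=%s,Number=1,Type=Float,Description="Allele frequency (%s)">',
      toupper(.x), sub("^af_", "", .x))),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths (ref,alt)">'
  )
  samples <- if (nrow(variants) > 0L) variants$calls[[1]]$sample_id else character()
  header <- c(header, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                              "FILTER", "INFO", "FORMAT", samples),
                            collapse = "\t"))
  body <- character(nrow(variants))
  if (nrow(variants) > 0L) {
    info_of <- function(row) {
      kv <- c(
        MQ = fmt_num(row$mq), MQ0 = fmt_num(row$mq0), DP = fmt_num(row$dp),
        FS = fmt_num(row$fs), GENE = row$gene, REGION = row$region,
        CSQCLASS = row$csq_class
      )
      for (a in af_cols) kv[[toupper(a)]] <- fmt_num(row[[a]])
      kv <- kv[!is.na(kv)]
      if (length(kv) == 0L) "." else paste(names(kv), kv, sep = "=",
                                           collapse = ";")
    }
    for (i in seq_len(nrow(variants))) {
      row <- variants[i, ]
      calls <- row$calls[[1]]
      gt_str <- dplyr::case_match(calls$gt, 0L ~ "0/0", 1L ~ "0/1",
                                  2L ~ "1/1", .default = "./.")
      sample_fields <- paste(
        gt_str,
        ifelse(is.na(calls$depth), ".", calls$depth),
        ifelse(is.na(calls$alt_reads) | is.na(calls$depth), ".",
               paste(calls$depth - calls$alt_reads, calls$alt_reads,
                     sep = ",")),
        sep = ":"
      )
      body[i] <- paste(c(row$chrom, row$pos,
                         ifelse(is.na(row$dbsnp), ".", row$dbsnp),
                         row$ref, row$alt, fmt_num(row$qual), ".",
                         info_of(row), "GT:DP:AD", sample_fields),
                       collapse = "\t")
    }
  }
  writeLines(c(header, body), file)
  invisible(file)
}

#' Tabulate variants by genomic region class
#'
#' Counts records in each region class and expresses each as a percentage
#' of the total, the standard summary of an exome call set's composition.
#'
#' @param variants Variant tibble with a `region` column.
#' @return Tibble with columns `region`, `n`, `percent`, ordered by
#'   decreasing count; zero rows for empty input.
#' @examples
#' v <- tibble::tibble(region = c("exonic", "exonic", "intronic"))
#' tabulate_regions(v)
#' @export
tabulate_regions <- function(variants) {
  if (nrow(variants) == 0L) {
    return(tibble::tibble(region = character(), n = integer(),
                          percent = numeric()))
  }
  variants |>
    dplyr::count(.data$region, name = "n") |>
    dplyr::mutate(percent = 100 * .data$n / sum(.data$n)) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$region)
}
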