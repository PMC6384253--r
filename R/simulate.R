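#' Three-generation study pedigree template
#'
#' A 22-member, three-generation pedigree with the structure the
#' segregation model assumes: a founding couple (the founder affected),
#' five of their children of whom three daughters are affected, five
#' unaffected spouses who married into the family, and ten grandchildren
#' of whom five are affected. Nine members are affected in total (5
#' males, 4 females) and one unaffected blood member (A03) is the father
#' of two affected sons by a marry-in wife, making him an obligate
#' carrier under a dominant model with incomplete penetrance.
#'
#' The full parent-child structure of the study family this mirrors is
#' not public; this template is one consistent realization of its
#' described role structure and is intended for simulation and testing,
#' not as a genealogical record.
#'
#' @return Pedigree tibble in the [read_ped()] layout.
#' @examples
#' dplyr::count(classify_roles(pedigree_template()), role)
#' @export
pedigree_template <- function() {
  ped <- tibble::tribble(
    ~id,    ~father_id, ~mother_id, ~sex,     ~affected,
    # generation I: founding couple
    "A06",  NA,         NA,         "male",   "affected",
    "A07",  NA,         NA,         "female", "unaffected",
    # generation II: blood children
    "A03",  "A06",      "A07",      "male",   "unaffected",
    "A08",  "A06",      "A07",      "female", "affected",
    "A12",  "A06",      "A07",      "female", "affected",
    "A15",  "A06",      "A07",      "female", "affected",
    "A10",  "A06",      "A07",      "male",   "unaffected",
    # generation II: marry-ins
    "A09",  NA,         NA,         "female", "unaffected",
    "A11",  NA,         NA,         "male",   "unaffected",
    "A13",  NA,         NA,         "male",   "unaffected",
    "A16",  NA,         NA,         "male",   "unaffected",
    "A14",  NA,         NA,         "female", "unaffected",
    # generation III
    "A17",  "A03",      "A09",      "male",   "affected",
    "A18",  "A03",      "A09",      "male",   "affected",
    "A20",  "A03",      "A09",      "female", "unaffected",
    "A21",  "A11",      "A08",      "male",   "affected",
    "A22",  "A11",      "A08",      "female", "unaffected",
    "A23",  "A13",      "A12",      "female", "affected",
    "A28",  "A13",      "A12",      "male",   "unaffected",
    "A25",  "A16",      "A15",      "male",   "affected",
    "A29",  "A16",      "A15",      "female", "unaffected",
    "A30",  "A10",      "A14",      "male",   "unaffected"
  )
  validate_ped(dplyr::mutate(ped, family_id = "FAM1", .before = 1))
}

# region-class composition typical of a whole-exome call set (percent)
exome_region_composition <- c(
  exonic = 48.63, intronic = 30.20, intergenic = 8.12, ncRNA_exonic = 3.18,
  ncRNA_intronic = 2.64, UTR3 = 2.32, splicing = 2.08, UTR5 = 1.81,
  upstream = 0.51, downstream = 0.32, ncRNA_splicing = 0.08,
  exonic_splicing = 0.07, upstream_downstream = 0.03, UTR5_UTR3 = 0.01
)

#' Simulation specification
#'
#' Parameters of the gene-dropping pedigree simulator
#' ([simulate_pedigree_dataset()]). Defaults emulate the study regime the
#' package targets: the 22-member [pedigree_template()], a planted
#' dominant causal variant private to the family under high but
#' incomplete penetrance (f = 0.9), background variants at
#' Hardy-Weinberg founder frequencies, and per-sample sequencing depth
#' around 70x (the 46-80x whole-exome range).
#'
#' @param ped Pedigree template tibble.
#' @param n_background_variants Number of background variants.
#' @param background_af Founder allele frequencies for background
#'   variants: a single value, a vector of length
#'   `n_background_variants`, or a function of `n` returning frequencies
#'   in `[0, 0.5]`. Default draws Uniform(0.01, 0.5).
#' @param region_probs Named probability weights over [region_classes()]
#'   used to assign background region classes; defaults to a typical
#'   whole-exome call-set composition.
#' @param causal List describing the planted variant: `founder` (id of
#'   the lineal founder carrying one copy), `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, `region`, `csq_class`, `dbsnp` (`NA` for novel), `af`
#'   (frequency recorded in the annotation databases; the allele is
#'   still treated as absent from all other founders).
#' @param penetrance Probability a causal carrier is affected.
#' @param phenocopy Probability a non-carrier is affected.
#' @param mean_depth Mean per-call sequencing depth (Poisson lambda).
#' @param seq_error Per-read sequencing error used for allele-balance
#'   draws (hom calls show alt fraction `seq_error` / `1 - seq_error`).
#' @param genotype_error Probability a called genotype is replaced by one
#'   of the other two genotypes.
#' @param missing_rate Probability a genotype call is missing.
#' @param qc_violation_rate Fraction of background variants given one
#'   failing site-QC field (to exercise the QC stage).
#' @param seed Integer seed; fully determines the simulated dataset.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(ped = pedigree_template(),
                     n_background_variants = 200,
                     background_af = function(n) stats::runif(n, 0.01, 0.5),
                     region_probs = exome_region_composition,
                     causal = list(founder = "A06", chrom = "chr9",
                                   pos = 128305252L, ref = "C", alt = "G",
                                   gene = "MAPKAP1", region = "intronic",
                                   csq_class = "noncoding",
                                   dbsnp = "rs78809014", af = 0.008786),
                     penetrance = 0.9,
                     phenocopy = 0.0,
                     mean_depth = 70,
                     seq_error = 0.005,
                     genotype_error = 0.0,
                     missing_rate = 0.0,
                     qc_violation_rate = 0.1,
                     seed = 1L) {
  stopifnot(
    penetrance >= 0, penetrance <= 1, phenocopy >= 0, phenocopy <= 1,
    genotype_error >= 0, genotype_error <= 1,
    missing_rate >= 0, missing_rate <= 1,
    qc_violation_rate >= 0, qc_violation_rate <= 1,
    seq_error >= 0, seq_error < 0.5, mean_depth > 0,
    n_background_variants >= 0,
    all(names(region_probs) %in% region_classes())
  )
  founders <- ped$id[is_founder(ped)]
  if (!is.null(causal) && !causal$founder %in% founders) {
    stop("causal founder must be a founder of the pedigree", call. = FALSE)
  }
  if (!is.null(causal)) {
    ped_roles <- classify_roles(ped)
    if (ped_roles$role[ped_roles$id == causal$founder] == "marry_in") {
      stop("causal founder must be a lineal founder, not a marry-in",
           call. = FALSE)
    }
  }
  structure(
    list(ped = ped, n_background_variants = n_background_variants,
         background_af = background_af, region_probs = region_probs,
         causal = causal, penetrance = penetrance, phenocopy = phenocopy,
         mean_depth = mean_depth, seq_error = seq_error,
         genotype_error = genotype_error, missing_rate = missing_rate,
         qc_violation_rate = qc_violation_rate, seed = as.integer(seed)),
    class = "sim_spec"
  )
}

topo_order <- function(ped) {
  placed <- character()
  remaining <- ped$id
  up <- stats::setNames(
    purrr::map2(ped$father_id, ped$mother_id, ~ stats::na.omit(c(.x, .y))),
    ped$id
  )
  while (length(remaining) > 0L) {
    ready <- remaining[purrr::map_lgl(up[remaining],
                                      ~ all(.x %in% placed))]
    if (length(ready) == 0L) {
      stop("pedigree is not acyclic", call. = FALSE)
    }
    placed <- c(placed, ready)
    remaining <- setdiff(remaining, ready)
  }
  placed
}

# Mendelian gene-dropping of one set of variants down the pedigree.
# af: founder allele frequency per variant; origin_dose: named list giving
# fixed genotypes for specific founders (used to plant the causal allele).
gene_drop <- function(ped, af, origin = NULL) {
  n_var <- length(af)
  order_ids <- topo_order(ped)
  geno <- matrix(0L, nrow = n_var, ncol = nrow(ped),
                 dimnames = list(NULL, ped$id))
  father <- stats::setNames(ped$father_id, ped$id)
  mother <- stats::setNames(ped$mother_id, ped$id)
  for (who in order_ids) {
    if (is.na(father[[who]]) && is.na(mother[[who]])) {
      geno[, who] <- if (!is.null(origin)) {
        rep(if (who == origin) 1L else 0L, n_var)
      } else {
        stats::rbinom(n_var, 2L, af)
      }
    } else {
      gf <- if (is.na(father[[who]])) rep(0L, n_var) else geno[, father[[who]]]
      gm <- if (is.na(mother[[who]])) rep(0L, n_var) else geno[, mother[[who]]]
      geno[, who] <- stats::rbinom(n_var, 1L, gf / 2) +
        stats::rbinom(n_var, 1L, gm / 2)
    }
  }
  geno
}

draw_alt_reads <- function(true_geno, depth, seq_error) {
  p <- c(seq_error, 0.5, 1 - seq_error)[true_geno + 1L]
  stats::rbinom(length(depth), depth, p)
}

#' Simulate a pedigree exome dataset with a planted causal variant
#'
#' Generates a multi-sample variant call set by gene-dropping: founder
#' genotypes for background variants are drawn under Hardy-Weinberg
#' equilibrium at each variant's frequency and transmitted down the
#' pedigree by Mendelian rules; the causal allele is planted heterozygous
#' in one lineal founder and is absent from all other founders, so it can
#' never enter through a marry-in. Affection status is then assigned
#' Bernoulli(penetrance) to causal carriers and Bernoulli(phenocopy) to
#' non-carriers. Per-call read depth is Poisson, alt-allele reads are
#' binomial given the true genotype, and genotype calls are corrupted at
#' the configured error and missingness rates. Everything is determined
#' by `spec$seed`.
#'
#' @param spec A [sim_spec()].
#' @return List with elements
#'   * `variants` — variant tibble in the [read_vcf()] schema;
#'   * `ped` — the pedigree with simulated affection status;
#'   * `truth` — list recording the causal variant id, true genotype
#'     matrix, true carrier ids, realized affected ids, and the injected
#'     error/missingness masks, sufficient to recompute any downstream
#'     expectation by brute force.
#' @examples
#' sim <- simulate_pedigree_dataset(sim_spec(n_background_variants = 20,
#'                                           seed = 7))
#' sim$truth$causal_id
#' @export
simulate_pedigree_dataset <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  withr::with_seed(spec$seed, simulate_pedigree_dataset_impl(spec))
}

simulate_pedigree_dataset_impl <- function(spec) {
  ped <- spec$ped
  n_bg <- spec$n_background_variants
  samples <- ped$id
  n_s <- length(samples)

  af <- if (is.function(spec$background_af)) {
    spec$background_af(n_bg)
  } else {
    rep_len(spec$background_af, n_bg)
  }
  stopifnot(all(af >= 0 & af <= 0.5))
  af <- round(af, 6)

  geno_bg <- gene_drop(ped, af)
  has_causal <- !is.null(spec$causal)
  if (has_causal) {
    geno_causal <- gene_drop(ped, spec$causal$af, origin = spec$causal$founder)
    true_geno <- rbind(geno_bg, geno_causal)
  } else {
    true_geno <- geno_bg
  }
  n_var <- nrow(true_geno)

  # affection follows true causal carrier status
  carrier <- if (has_causal) true_geno[n_var, ] >= 1L else
    stats::setNames(rep(FALSE, n_s), samples)
  p_aff <- ifelse(carrier, spec$penetrance, spec$phenocopy)
  affected <- stats::rbinom(n_s, 1L, p_aff) == 1L
  ped_out <- ped
  ped_out$affected <- ifelse(affected, "affected", "unaffected")

  # reads reflect the true genotype; the call is what gets corrupted
  depth <- matrix(stats::rpois(n_var * n_s, spec$mean_depth),
                  nrow = n_var, dimnames = list(NULL, samples))
  alt_reads <- matrix(
    draw_alt_reads(as.vector(true_geno), as.vector(depth), spec$seq_error),
    nrow = n_var, dimnames = list(NULL, samples))

  called <- true_geno
  err_mask <- matrix(stats::runif(n_var * n_s) < spec$genotype_error,
                     nrow = n_var)
  if (any(err_mask)) {
    shift <- 1L + (stats::runif(sum(err_mask)) < 0.5)   # +1 or +2 mod 3
    called[err_mask] <- (called[err_mask] + shift) %% 3L
  }
  miss_mask <- matrix(stats::runif(n_var * n_s) < spec$missing_rate,
                      nrow = n_var)
  called[miss_mask] <- NA_integer_

  ann <- simulate_annotation(spec, af, n_bg)
  site <- simulate_site_qc(spec, n_bg, depth)

  variants <- dplyr::bind_cols(ann, site)
  variants$calls <- purrr::map(seq_len(n_var), function(i) {
    tibble::tibble(
      sample_id = samples,
      gt = as.integer(called[i, ]),
      depth = as.integer(depth[i, ]),
      alt_reads = as.integer(alt_reads[i, ]),
      carrier = unname(called[i, ] >= 1L)
    )
  })
  variants <- variants |>
    dplyr::mutate(
      variant_id = paste(.data$chrom, .data$pos, .data$ref, .data$alt,
                         sep = ":"),
      variant_type = ifelse(nchar(.data$ref) != nchar(.data$alt),
                            "indel", "SNV"),
      .before = 1
    ) |>
    dplyr::arrange(.data$chrom, .data$pos) |>
    dplyr::select("variant_id", "chrom", "pos", "ref", "alt",
                  "variant_type", "qual", "mq", "mq0", "dp", "fs", "gene",
                  "region", "csq_class", "dbsnp", "af_1000g", "calls")

  truth <- list(
    causal_id = if (has_causal) {
      paste(spec$causal$chrom, spec$causal$pos, spec$causal$ref,
            spec$causal$alt, sep = ":")
    } else NA_character_,
    origin_founder = if (has_causal) spec$causal$founder else NA_character_,
    true_genotypes = true_geno,
    causal_carriers = samples[carrier],
    affected = samples[affected],
    genotype_errors = err_mask,
    missing_calls = miss_mask,
    background_af = af
  )
  list(variants = variants, ped = ped_out, truth = truth)
}

simulate_annotation <- function(spec, af, n_bg) {
  regions <- sample(names(spec$region_probs), n_bg, replace = TRUE,
                    prob = spec$region_probs)
  csq <- dplyr::case_when(
    regions %in% c("exonic", "exonic_splicing") ~
      sample(c("synonymous", "nonsynonymous", "lof_or_damaging"), n_bg,
             replace = TRUE, prob = c(0.55, 0.40, 0.05)),
    regions == "splicing" ~ "lof_or_damaging",
    TRUE ~ "noncoding"
  )
  coding_like <- !regions %in% "intergenic"
  idx <- seq_len(n_bg)
  # ~90% of background sites are known (dbSNP id); known sites with a
  # database record carry their founder frequency as the annotated AF
  known <- stats::runif(n_bg) < 0.9
  recorded <- known & stats::runif(n_bg) < 0.85
  ann <- tibble::tibble(
    chrom = paste0("chr", sample(1:22, n_bg, replace = TRUE)),
    pos = 1000000L + sample.int(199000000L, n_bg),
    ref = sample(c("A", "C", "G", "T"), n_bg, replace = TRUE),
    gene = as.character(ifelse(coding_like, paste0("GENE", idx),
                               NA_character_)),
    region = regions,
    csq_class = csq,
    dbsnp = as.character(ifelse(known, paste0("rs9", sprintf("%06d", idx)),
                                NA_character_)),
    af_1000g = as.numeric(ifelse(recorded, af, NA_real_))
  )
  ann$alt <- purrr::map_chr(ann$ref,
                            ~ sample(setdiff(c("A", "C", "G", "T"), .x), 1))
  if (!is.null(spec$causal)) {
    ann <- dplyr::bind_rows(ann, tibble::tibble(
      chrom = spec$causal$chrom, pos = as.integer(spec$causal$pos),
      ref = spec$causal$ref, alt = spec$causal$alt,
      gene = spec$causal$gene, region = spec$causal$region,
      csq_class = spec$causal$csq_class,
      dbsnp = spec$causal$dbsnp %||% NA_character_,
      af_1000g = spec$causal$af %||% NA_real_
    ))
  }
  ann
}

simulate_site_qc <- function(spec, n_bg, depth) {
  n_var <- nrow(depth)
  site <- tibble::tibble(
    qual = round(stats::runif(n_var, 100, 3000), 2),
    mq = round(stats::runif(n_var, 40, 60), 2),
    mq0 = stats::rbinom(n_var, 4, 0.2),
    dp = as.integer(round(rowMeans(depth))),
    fs = round(stats::runif(n_var, 0, 8), 2)
  )
  # plant one failing QC field in a fraction of background variants
  # (never in the causal variant, which is the last row when present)
  violate <- stats::runif(n_bg) < spec$qc_violation_rate
  which_field <- sample(5L, n_bg, replace = TRUE)
  for (i in which(violate)) {
    switch(which_field[i],
           site$mq[i] <- round(stats::runif(1, 5, 29.5), 2),
           site$mq0[i] <- sample(5:20, 1),
           site$dp[i] <- sample(0:4, 1),
           site$qual[i] <- round(stats::runif(1, 1, 49.5), 2),
           site$fs[i] <- round(stats::runif(1, 10.5, 60), 2))
  }
  site
}

#' Simulate two-group (or multi-group) expression data
#'
#' Draws independent normal measurements per group, optionally rescaled so
#' each group's sample mean and SD equal the specification exactly
#' (useful for reconstructing raw-value datasets consistent with
#' published summary statistics).
#'
#' @param groups Tibble with columns `group`, `mean`, `sd`, `n`.
#' @param seed Integer seed.
#' @param exact_moments Affinely rescale each group so its sample moments
#'   match `mean`/`sd` exactly?
#' @return Tibble with columns `sample_id`, `group`, `value`.
#' @examples
#' simulate_expression(
#'   tibble::tibble(group = c("a", "b"), mean = c(0, 1), sd = c(1, 1),
#'                  n = c(5, 5)), seed = 1)
#' @export
simulate_expression <- function(groups, seed = 1L, exact_moments = FALSE) {
  stopifnot(all(c("group", "mean", "sd", "n") %in% names(groups)))
  if (any(groups$n < 2)) stop("each group needs n >= 2", call. = FALSE)
  if (any(groups$sd <= 0)) stop("group sd must be positive", call. = FALSE)
  withr::with_seed(seed, {
    purrr::pmap_dfr(groups, function(group, mean, sd, n, ...) {
      x <- stats::rnorm(n, mean, sd)
      if (exact_moments) {
        x <- mean + sd * (x - base::mean(x)) / stats::sd(x)
      }
      tibble::tibble(
        sample_id = paste0(group, "_", seq_len(n)),
        group = group,
        value = x
      )
    })
  })
}
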