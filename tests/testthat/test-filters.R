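# build a bare variant tibble with given site-QC fields and calls
make_site <- function(n = 1, mq = 55, mq0 = 0, dp = 60, qual = 500, fs = 1,
                      csq = "nonsynonymous", af = NA_real_,
                      calls = NULL) {
  if (is.null(calls)) {
    calls <- tibble::tibble(sample_id = c("S1", "S2"), gt = c(1L, 0L),
                            depth = c(50L, 50L), alt_reads = c(25L, 0L),
                            carrier = c(TRUE, FALSE))
  }
  tibble::tibble(
    variant_id = paste0("v", seq_len(n)), chrom = "chr1",
    pos = seq_len(n), ref = "A", alt = "G", variant_type = "SNV",
    qual = qual, mq = mq, mq0 = mq0, dp = dp, fs = fs,
    gene = "G", region = "exonic", csq_class = csq, dbsnp = "rs1",
    af_1000g = af, calls = rep(list(calls), n)
  )
}

test_that("QC boundaries are inclusive on the passing side", {
  # exactly at every threshold: passes
  at <- make_site(mq = 30, mq0 = 4, dp = 5, qual = 50, fs = 10)
  expect_equal(nrow(qc_filter(at)), 1)
  # one unit over each boundary: fails with the first violated criterion
  cases <- list(
    list(args = list(mq = 29.9), reason = "low_mapping_quality"),
    list(args = list(mq0 = 5), reason = "excess_mq0_reads"),
    list(args = list(dp = 4), reason = "low_site_depth"),
    list(args = list(qual = 49.9), reason = "low_site_quality"),
    list(args = list(fs = 10.1), reason = "strand_bias")
  )
  for (case in cases) {
    v <- do.call(make_site, case$args)
    out <- qc_filter(v)
    expect_equal(nrow(out), 0)
    rep <- filter_reports(out)$qc
    expect_equal(unname(rep$reasons[case$reason]), 1L)
  }
  # multiple failures record the first criterion in documented order
  v <- make_site(mq = 10, qual = 10)
  rep <- filter_reports(qc_filter(v))$qc
  expect_equal(unname(rep$reasons["low_mapping_quality"]), 1L)
})

test_that("the literal MQ0 reading is available but off by default", {
  clean <- make_site(mq0 = 0)
  expect_equal(nrow(qc_filter(clean)), 1)
  expect_equal(nrow(qc_filter(clean, qc_thresholds(mq0_literal = TRUE))), 0)
})

test_that("missing QC fields reject by default and can pass through", {
  v <- make_site(mq = NA_real_)
  out <- qc_filter(v)
  expect_equal(nrow(out), 0)
  expect_equal(unname(filter_reports(out)$qc$reasons["missing_qc_field"]), 1L)
  expect_equal(nrow(qc_filter(v, missing = "pass")), 1)
})

test_that("QC survivors match brute-force re-checking on random fields", {
  withr::with_seed(31, {
    n <- 100
    v <- make_site(n)
    v$mq <- round(stats::runif(n, 20, 60), 1)
    v$mq0 <- sample(0:8, n, replace = TRUE)
    v$dp <- sample(0:80, n, replace = TRUE)
    v$qual <- round(stats::runif(n, 0, 800), 1)
    v$fs <- round(stats::runif(n, 0, 15), 1)
  })
  keep <- brute_qc_keep(v)
  out <- qc_filter(v)
  expect_identical(out$variant_id, v$variant_id[keep])
  expect_reports_conserve(filter_reports(out))
})

test_that("prevalence above 5% in any database rejects a variant", {
  common <- make_site(af = 0.06)
  out <- functional_filter(common)
  expect_equal(nrow(out), 0)
  expect_equal(unname(filter_reports(out)$functional$reasons["common_in_database"]),
               1L)
  # absent frequency is treated as zero
  rare <- make_site(af = NA_real_)
  expect_equal(nrow(functional_filter(rare)), 1)
  # boundary: exactly 5% passes ("> 5%" removes)
  expect_equal(nrow(functional_filter(make_site(af = 0.05))), 1)
})

test_that("functional filter checks consequence, carriers and support", {
  expect_equal(nrow(functional_filter(make_site(csq = "synonymous"))), 0)

  no_carrier <- make_site(calls = tibble::tibble(
    sample_id = c("S1", "S2"), gt = c(0L, 0L), depth = c(50L, 50L),
    alt_reads = c(0L, 0L), carrier = c(FALSE, FALSE)))
  out <- functional_filter(no_carrier)
  expect_equal(unname(filter_reports(out)$functional$reasons["no_carrier"]), 1L)

  shallow <- make_site(calls = tibble::tibble(
    sample_id = "S1", gt = 1L, depth = 4L, alt_reads = 2L, carrier = TRUE))
  expect_equal(nrow(functional_filter(shallow)), 0)

  low_vaf <- make_site(calls = tibble::tibble(
    sample_id = "S1", gt = 1L, depth = 70L, alt_reads = 10L, carrier = TRUE))
  expect_equal(nrow(functional_filter(low_vaf)), 0)

  good <- make_site(calls = tibble::tibble(
    sample_id = "S1", gt = 1L, depth = 70L, alt_reads = 35L, carrier = TRUE))
  expect_equal(nrow(functional_filter(good)), 1)
})

test_that("functional survivors match brute-force predicate evaluation", {
  withr::with_seed(73, {
    n <- 200
    v <- make_site(n)
    v$csq_class <- sample(c("synonymous", "nonsynonymous", "noncoding"),
                          n, replace = TRUE)
    v$af_1000g <- ifelse(stats::runif(n) < 0.3, NA_real_,
                         round(stats::runif(n, 0, 0.2), 4))
    v$calls <- purrr::map(seq_len(n), function(i) {
      gt <- sample(0:1, 3, replace = TRUE)
      depth <- sample(2:40, 3, replace = TRUE)
      tibble::tibble(
        sample_id = c("S1", "S2", "S3"), gt = as.integer(gt),
        depth = as.integer(depth),
        alt_reads = as.integer(round(depth * gt * stats::runif(3, 0.1, 0.6))),
        carrier = gt >= 1L)
    })
  })
  keep <- brute_functional_keep(v)
  out <- functional_filter(v)
  expect_identical(out$variant_id, v$variant_id[keep])
  expect_reports_conserve(filter_reports(out))
})

seg_fixture <- function(carriers, missing = character()) {
  ped <- read_ped(family_ped_lines())
  calls <- tibble::tibble(
    sample_id = ped$id,
    gt = ifelse(ped$id %in% carriers, 1L, 0L),
    depth = 60L, alt_reads = ifelse(ped$id %in% carriers, 30L, 0L),
    carrier = ped$id %in% carriers
  )
  calls$gt[calls$sample_id %in% missing] <- NA_integer_
  calls$carrier[calls$sample_id %in% missing] <- NA
  list(ped = ped, v = make_site(calls = calls))
}

affected_ids <- function() {
  ped <- read_ped(family_ped_lines())
  ped$id[ped$affected == "affected"]
}

test_that("segregation filter keeps full sharing and excludes marry-ins", {
  # carried by all 9 affected + obligate carrier A03, absent elsewhere
  fx <- seg_fixture(c(affected_ids(), "A03"))
  out <- segregation_filter(fx$v, fx$ped)
  expect_equal(nrow(out), 1)

  # one marry-in carrier: passes sharing, fails exclusion
  fx2 <- seg_fixture(c(affected_ids(), "A03", "A09"))
  out2 <- segregation_filter(fx2$v, fx2$ped)
  expect_equal(nrow(out2), 0)
  rep <- filter_reports(out2)$segregation
  expect_equal(rep$after_sharing, 1L)
  expect_equal(unname(rep$reasons["carried_by_marry_in"]), 1L)

  # missing an affected carrier: fails sharing
  fx3 <- seg_fixture(setdiff(c(affected_ids(), "A03"), "A21"))
  rep3 <- filter_reports(segregation_filter(fx3$v, fx3$ped))$segregation
  expect_equal(unname(rep3$reasons["not_shared_by_required"]), 1L)
})

test_that("missing genotypes fail sharing but never exclude", {
  # required sample uncalled: rejected by default, kept when compatible
  fx <- seg_fixture(c(affected_ids(), "A03"), missing = "A21")
  expect_equal(nrow(segregation_filter(fx$v, fx$ped)), 0)
  expect_equal(nrow(segregation_filter(fx$v, fx$ped,
                                       missing_as_compatible = TRUE)), 1)
  # marry-in uncalled: not treated as a carrier
  fx2 <- seg_fixture(c(affected_ids(), "A03"), missing = "A09")
  expect_equal(nrow(segregation_filter(fx2$v, fx2$ped)), 1)
})

test_that("filter stages are idempotent and per-record stages commute", {
  withr::with_seed(57, {
    n <- 80
    v <- make_site(n)
    v$mq <- round(stats::runif(n, 25, 60), 1)
    v$qual <- round(stats::runif(n, 20, 600), 1)
    v$csq_class <- sample(consequence_classes(), n, replace = TRUE)
    v$af_1000g <- round(stats::runif(n, 0, 0.1), 4)
  })
  once <- qc_filter(v)
  twice <- qc_filter(once)
  expect_identical(twice$variant_id, once$variant_id)

  ab <- functional_filter(qc_filter(v))
  ba <- qc_filter(functional_filter(v))
  expect_identical(ab$variant_id, ba$variant_id)

  f_once <- functional_filter(v)
  expect_identical(functional_filter(f_once)$variant_id, f_once$variant_id)
})

test_that("vacuous thresholds make every stage the identity", {
  withr::with_seed(58, {
    n <- 40
    v <- make_site(n)
    v$mq <- stats::runif(n, 0, 60)
    v$qual <- stats::runif(n, 0, 600)
    v$csq_class <- sample(consequence_classes(), n, replace = TRUE)
    v$af_1000g <- stats::runif(n)
  })
  qc_off <- qc_thresholds(min_mapping_quality = -Inf, max_mq0_reads = Inf,
                          min_site_depth = -Inf, min_qual = -Inf,
                          max_strand_bias_phred = Inf)
  expect_identical(qc_filter(v, qc_off)$variant_id, v$variant_id)

  fn_off <- functional_thresholds(max_db_frequency = Inf,
                                  min_carrier_depth = -Inf,
                                  min_alt_fraction = 0,
                                  drop_synonymous = FALSE)
  expect_identical(functional_filter(v, fn_off)$variant_id, v$variant_id)

  # segregation with no affected, no obligate carriers and no marry-ins
  # imposes no constraint
  lone <- read_ped(c("F A 0 0 1 1", "F B 0 0 2 1", "F C A B 1 1"))
  expect_identical(segregation_filter(v, lone)$variant_id, v$variant_id)
})

test_that("reports accumulate along a piped cascade and conserve counts", {
  sim <- simulate_pedigree_dataset(
    sim_spec(n_background_variants = 60, seed = 19,
             genotype_error = 0.01, missing_rate = 0.01))
  out <- sim$variants |>
    qc_filter() |>
    functional_filter() |>
    segregation_filter(sim$ped)
  reports <- filter_reports(out)
  expect_named(reports, c("qc", "functional", "segregation"))
  expect_reports_conserve(reports)
  expect_equal(reports$qc$input, nrow(sim$variants))
  expect_equal(reports$functional$input, reports$qc$output)
  expect_equal(reports$segregation$input, reports$functional$output)
  expect_equal(reports$segregation$output, nrow(out))
  # tidy/glance views agree with the report
  td <- tidy(reports$qc)
  expect_equal(sum(td$n), reports$qc$input)
  expect_equal(glance(reports$qc)$rejected,
               reports$qc$input - reports$qc$output)
})
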