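#' Pipeline configuration
#'
#' Bundles input paths and all stage parameters for [run_prioritize()].
#' Round-trips losslessly through YAML ([write_pipeline_config()],
#' [read_pipeline_config()]); unknown keys in a config file are rejected.
#'
#' @param vcf,ped Paths to the annotated VCF and PED inputs.
#' @param out_dir Optional output directory; when set, the ranked table,
#'   per-stage reports and a JSON run manifest are written there.
#' @param qc A [qc_thresholds()] object.
#' @param functional A [functional_thresholds()] object.
#' @param scoring A [scoring_config()] object.
#' @param obligate_carriers Explicit obligate-carrier ids to union with
#'   the inferred set.
#' @param missing_as_compatible Passed to [segregation_filter()].
#' @param verbose Log stage counts as messages?
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf = NULL, ped = NULL, out_dir = NULL,
                            qc = qc_thresholds(),
                            functional = functional_thresholds(),
                            scoring = scoring_config(),
                            obligate_carriers = character(),
                            missing_as_compatible = FALSE,
                            verbose = TRUE) {
  structure(
    list(vcf = vcf, ped = ped, out_dir = out_dir, qc = qc,
         functional = functional, scoring = scoring,
         obligate_carriers = obligate_carriers,
         missing_as_compatible = missing_as_compatible,
         verbose = verbose),
    class = "pipeline_config"
  )
}

config_builders <- function() {
  list(qc = qc_thresholds, functional = functional_thresholds,
       scoring = scoring_config)
}

#' Read a pipeline configuration from YAML
#'
#' @param file Path to a YAML file whose top-level keys are the arguments
#'   of [pipeline_config()]; the `qc`, `functional` and `scoring` sections
#'   take the arguments of their respective constructors. Unknown keys at
#'   any level are an error.
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(file) {
  raw <- yaml::read_yaml(file)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown config key: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  builders <- config_builders()
  for (section in names(builders)) {
    if (!is.null(raw[[section]])) {
      builder <- builders[[section]]
      bad <- setdiff(names(raw[[section]]), names(formals(builder)))
      if (length(bad) > 0L) {
        stop("unknown key in `", section, "`: ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      args <- raw[[section]]
      # named numeric sections come back from YAML as lists
      args <- purrr::map(args, function(v) {
        if (is.list(v)) unlist(v) else v
      })
      raw[[section]] <- do.call(builder, args)
    }
  }
  if (!is.null(raw$obligate_carriers)) {
    raw$obligate_carriers <- as.character(unlist(raw$obligate_carriers))
  }
  do.call(pipeline_config, raw)
}

#' Write a pipeline configuration to YAML
#'
#' @param config A `pipeline_config` object.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_pipeline_config <- function(config, file) {
  serial <- purrr::map(unclass(config), function(v) {
    if (inherits(v, c("qc_thresholds", "functional_thresholds",
                      "scoring_config"))) {
      purrr::map(unclass(v), function(x) {
        if (!is.null(names(x))) as.list(x) else x
      })
    } else {
      v
    }
  })
  serial <- purrr::compact(serial)
  yaml::write_yaml(serial, file)
  invisible(file)
}

#' Run the full variant prioritization pipeline
#'
#' Orchestrates the end-to-end analysis: read inputs, classify pedigree
#' roles, infer obligate carriers, apply the three filter stages (site
#' QC, functional/prevalence, segregation), score and rank the survivors.
#' Stage counts are logged in cascade order; outputs are deterministic
#' given inputs and configuration.
#'
#' @param config A [pipeline_config()]. `vcf` and `ped` may be omitted
#'   when `variants`/`ped` are passed directly.
#' @param variants Optional variant tibble (bypasses reading `config$vcf`).
#' @param ped Optional pedigree tibble (bypasses reading `config$ped`).
#' @return Object of class `pedscreen_result`: a list with `ranked` (the
#'   scored, ranked candidate tibble), `reports` (named list of
#'   `filter_report`s), `obligate_carriers`, and `config`. Has [tidy()],
#'   [glance()] and [ggplot2::autoplot()] methods.
#' @examples
#' sim <- simulate_pedigree_dataset(sim_spec(n_background_variants = 30,
#'                                           seed = 2))
#' res <- run_prioritize(pipeline_config(verbose = FALSE),
#'                       variants = sim$variants, ped = sim$ped)
#' glance(res)
#' @export
run_prioritize <- function(config = pipeline_config(), variants = NULL,
                           ped = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(ped)) {
    if (is.null(config$ped)) stop("no pedigree supplied", call. = FALSE)
    ped <- read_ped(config$ped)
  }
  ped <- classify_roles(ped)
  if (is.null(variants)) {
    if (is.null(config$vcf)) stop("no VCF supplied", call. = FALSE)
    variants <- read_vcf(config$vcf, ped = ped, on_missing_sample = "error")
  } else if (nrow(variants) > 0L) {
    vcf_samples <- variants$calls[[1]]$sample_id
    absent <- setdiff(ped$id, vcf_samples)
    if (length(absent) > 0L) {
      stop("pedigree samples missing from variant calls: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
  }
  oblig <- infer_obligate_carriers(ped, override = config$obligate_carriers)

  log_msg <- function(...) if (config$verbose) message(sprintf(...))
  log_msg("input: %d variants, %d pedigree members (%d affected, %d marry-ins, %d obligate carriers)",
          nrow(variants), nrow(ped), sum(ped$role == "affected"),
          sum(ped$role == "marry_in"), length(oblig))

  out <- qc_filter(variants, config$qc)
  log_msg("post-QC: %d variants", nrow(out))
  out <- functional_filter(out, config$functional)
  log_msg("post-functional: %d variants", nrow(out))
  out <- segregation_filter(out, ped, obligate_carriers = oblig,
                            missing_as_compatible =
                              config$missing_as_compatible)
  reports <- filter_reports(out)
  log_msg("shared by affected + obligate carriers: %d variants",
          reports$segregation$after_sharing)
  log_msg("after marry-in exclusion: %d candidate variants", nrow(out))

  ranked <- prioritize_variants(out, ped, config$scoring,
                                obligate_carriers = oblig)
  attr(ranked, "filter_reports") <- NULL
  result <- structure(
    list(ranked = ranked, reports = reports, obligate_carriers = oblig,
         ped = ped, config = config),
    class = "pedscreen_result"
  )
  if (!is.null(config$out_dir)) {
    write_result(result, config$out_dir)
  }
  result
}

write_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(
    dplyr::select(result$ranked, -"calls"),
    file.path(out_dir, "ranked_candidates.tsv"))
  readr::write_tsv(
    purrr::map_dfr(result$reports, tidy),
    file.path(out_dir, "filter_reports.tsv"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    manifest <- list(
      package = "pedscreen",
      version = as.character(utils::packageVersion("pedscreen")),
      inputs = list(vcf = result$config$vcf, ped = result$config$ped),
      obligate_carriers = result$obligate_carriers,
      stage_counts = purrr::map(result$reports,
                                ~ list(input = .x$input, output = .x$output))
    )
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(out_dir)
}

#' @export
print.pedscreen_result <- function(x, ...) {
  cat("<pedscreen_result>\n")
  for (r in x$reports) {
    cat(sprintf("  %-12s %6d -> %6d\n", r$stage, r$input, r$output))
  }
  cat(sprintf("  obligate carriers: %s\n",
              paste(x$obligate_carriers, collapse = ", ")))
  cat(sprintf("  %d ranked candidates; top: %s (overall %.3g)\n",
              nrow(x$ranked),
              if (nrow(x$ranked) > 0) x$ranked$variant_id[1] else "none",
              if (nrow(x$ranked) > 0) x$ranked$overall[1] else NA))
  invisible(x)
}

#' Tidy a prioritization result into the ranked candidate table
#' @param x A `pedscreen_result`.
#' @param ... Unused.
#' @method tidy pedscreen_result
#' @export
tidy.pedscreen_result <- function(x, ...) {
  dplyr::select(x$ranked, -"calls")
}

#' One row per filter stage of a prioritization run
#' @param x A `pedscreen_result`.
#' @param ... Unused.
#' @method glance pedscreen_result
#' @export
glance.pedscreen_result <- function(x, ...) {
  purrr::map_dfr(x$reports, glance)
}

#' Run an expression comparison analysis
#'
#' Accepts one of the three delimited layouts — raw values
#' (`sample_id`, `group`, `value`), group summaries (`group`, `mean`,
#' `sd`, `n`), or qPCR threshold cycles (`sample_id`, `condition`,
#' `ct_target`, `ct_reference`) — and produces the matching report: a
#' per-group normality check plus a t-test for each group pair (raw
#' mode), a t-test per pair (summary mode), or the comparative-Ct fold
#' change (ct mode).
#'
#' @param data Tibble or path to a TSV/CSV file in one of the layouts.
#' @param mode `"raw"`, `"summary"`, or `"ct"`; `"auto"` detects from the
#'   columns.
#' @param welch,paired Passed to the t-test (raw/summary modes).
#' @return A list of class `pedscreen_expression` with elements
#'   `normality` (tibble, raw mode only), `comparisons` (tibble of
#'   pairwise tests) or `fold_change` (ct mode), and `groups`.
#' @export
run_expression <- function(data, mode = c("auto", "raw", "summary", "ct"),
                           welch = FALSE, paired = FALSE) {
  mode <- match.arg(mode)
  if (is.character(data) && length(data) == 1L) {
    delim <- if (grepl("\\.csv$", data)) "," else "\t"
    data <- readr::read_delim(data, delim = delim, show_col_types = FALSE)
  }
  if (mode == "auto") {
    mode <- if (all(c("ct_target", "ct_reference") %in% names(data))) {
      "ct"
    } else if (all(c("mean", "sd", "n") %in% names(data))) {
      "summary"
    } else if (all(c("group", "value") %in% names(data))) {
      "raw"
    } else {
      stop("cannot detect table layout from columns: ",
           paste(names(data), collapse = ", "), call. = FALSE)
    }
  }
  out <- switch(
    mode,
    ct = list(fold_change = ddct_fold_change(data), groups = NULL),
    summary = {
      pairs <- group_pairs(data$group)
      comparisons <- purrr::map_dfr(pairs, function(p) {
        tidy(t_test_summary(data[match(p, data$group), ], welch = welch)) |>
          dplyr::mutate(group1 = p[1], group2 = p[2], .before = 1)
      })
      list(comparisons = comparisons, groups = data)
    },
    raw = {
      groups <- data |>
        dplyr::group_by(.data$group) |>
        dplyr::summarise(mean = mean(.data$value),
                         sd = stats::sd(.data$value),
                         n = dplyr::n(), .groups = "drop")
      normality <- data |>
        dplyr::group_by(.data$group) |>
        dplyr::group_modify(~ tidy(ks_normality(.x$value))) |>
        dplyr::ungroup()
      pairs <- group_pairs(unique(as.character(data$group)))
      comparisons <- purrr::map_dfr(pairs, function(p) {
        sub <- dplyr::filter(data, .data$group %in% p) |>
          dplyr::arrange(match(.data$group, p))
        tidy(t_test_raw(sub, welch = welch, paired = paired)) |>
          dplyr::mutate(group1 = p[1], group2 = p[2], .before = 1)
      })
      list(normality = normality, comparisons = comparisons,
           groups = groups)
    }
  )
  structure(c(out, list(mode = mode)), class = "pedscreen_expression")
}

group_pairs <- function(groups) {
  g <- unique(as.character(groups))
  if (length(g) < 2L) return(list())
  utils::combn(g, 2L, simplify = FALSE)
}

#' @export
print.pedscreen_expression <- function(x, ...) {
  cat(sprintf("<pedscreen_expression: %s mode>\n", x$mode))
  if (!is.null(x$groups)) {
    g <- x$groups
    for (i in seq_len(nrow(g))) {
      cat(sprintf("  %-12s %.4g +/- %.4g (n = %d)\n",
                  g$group[i], g$mean[i], g$sd[i], as.integer(g$n[i])))
    }
  }
  if (!is.null(x$comparisons)) {
    cmp <- x$comparisons
    for (i in seq_len(nrow(cmp))) {
      cat(sprintf("  %s vs %s: t = %.3f, df = %.4g, p = %.4g\n",
                  cmp$group1[i], cmp$group2[i], cmp$statistic[i],
                  cmp$parameter[i], cmp$p.value[i]))
    }
  }
  if (!is.null(x$fold_change)) {
    cat(sprintf("  ddCt = %.4g, fold change 2^-ddCt = %.4g\n",
                x$fold_change$delta_delta_ct, x$fold_change$fold_change))
  }
  invisible(x)
}
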