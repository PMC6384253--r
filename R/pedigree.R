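#' Read a PED-format pedigree
#'
#' Parses the standard 6-column whitespace-delimited PED layout
#' (family, individual, father, mother, sex, phenotype) into a tibble,
#' one row per individual. Missing parents are coded `"0"` in the file and
#' become `NA`. Sex codes 1/2/other map to `"male"`/`"female"`/`"unknown"`;
#' phenotype codes 2/1 map to `"affected"`/`"unaffected"`, and 0 or -9 to
#' `"unknown"`.
#'
#' The pedigree is validated on read: individual ids must be unique, every
#' referenced parent must be present in the same family, and the parentage
#' graph must be acyclic (no individual is its own ancestor).
#'
#' @param file Path to a PED file, or a character vector of PED lines.
#' @return A tibble with columns `family_id`, `id`, `father_id`, `mother_id`,
#'   `sex`, `affected`.
#' @examples
#' ped <- read_ped(c(
#'   "FAM1 P1 0 0 1 1",
#'   "FAM1 P2 0 0 2 1",
#'   "FAM1 P3 P1 P2 1 2"
#' ))
#' ped
#' @export
read_ped <- function(file) {
  lines <- if (length(file) == 1L && file.exists(file)) readLines(file) else file
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) stop("PED input contains no records", call. = FALSE)
  fields <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(fields) != 6L)
  if (length(bad) > 0L) {
    stop("PED line ", bad[1], " does not have 6 columns", call. = FALSE)
  }
  m <- do.call(rbind, fields)
  ped <- tibble::tibble(
    family_id = m[, 1],
    id        = m[, 2],
    father_id = dplyr::na_if(m[, 3], "0"),
    mother_id = dplyr::na_if(m[, 4], "0"),
    sex       = decode_sex(m[, 5]),
    affected  = decode_affection(m[, 6])
  )
  validate_ped(ped)
}

decode_sex <- function(x) {
  dplyr::case_match(x, "1" ~ "male", "2" ~ "female", .default = "unknown")
}

decode_affection <- function(x) {
  out <- dplyr::case_match(
    x,
    "2" ~ "affected",
    "1" ~ "unaffected",
    c("0", "-9") ~ "unknown"
  )
  if (anyNA(out)) {
    stop("unknown affection code: ", x[which(is.na(out))[1]], call. = FALSE)
  }
  out
}

#' Validate pedigree structure
#'
#' Checks id uniqueness, referential integrity of parent links, and
#' acyclicity of the parentage graph. Called by [read_ped()]; exported so
#' pedigrees built programmatically can be checked the same way.
#'
#' @param ped Pedigree tibble as returned by [read_ped()].
#' @return `ped`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_ped <- function(ped) {
  if (anyDuplicated(ped$id)) {
    stop("duplicate individual id: ",
         ped$id[duplicated(ped$id)][1], call. = FALSE)
  }
  parents <- c(ped$father_id, ped$mother_id)
  missing <- setdiff(stats::na.omit(parents), ped$id)
  if (length(missing) > 0L) {
    stop("parent id not present in pedigree: ", missing[1], call. = FALSE)
  }
  # acyclicity: follow each individual's ancestor closure
  up <- stats::setNames(
    purrr::map2(ped$father_id, ped$mother_id, ~ stats::na.omit(c(.x, .y))),
    ped$id
  )
  for (start in ped$id) {
    seen <- character()
    frontier <- up[[start]]
    while (length(frontier) > 0L) {
      if (start %in% frontier) {
        stop("pedigree contains a parentage cycle involving ", start,
             call. = FALSE)
      }
      seen <- union(seen, frontier)
      frontier <- setdiff(unique(unlist(up[frontier])), seen)
    }
  }
  invisible(ped)
}

is_founder <- function(ped) is.na(ped$father_id) & is.na(ped$mother_id)

# co-parent pairs: one row per (parent, co-parent) over all children
co_parent_pairs <- function(ped) {
  kids <- dplyr::filter(ped, !is.na(.data$father_id) | !is.na(.data$mother_id))
  dplyr::bind_rows(
    tibble::tibble(parent = kids$father_id, co_parent = kids$mother_id,
                   child = kids$id),
    tibble::tibble(parent = kids$mother_id, co_parent = kids$father_id,
                   child = kids$id)
  ) |>
    dplyr::filter(!is.na(.data$parent))
}

#' Classify pedigree members into segregation-analysis roles
#'
#' Adds a `role` column partitioning the pedigree into the sets the
#' segregation filter operates on:
#'
#' * `"marry_in"` — a founder (no parents in the pedigree) all of whose
#'   co-parents are themselves non-founders, i.e. an individual who joined
#'   the family by marriage. Members of a founding couple (founders whose
#'   co-parent is also a founder) are blood members, not marry-ins.
#' * `"affected"` / `"unaffected_blood"` — remaining members with known
#'   phenotype.
#' * `"unknown"` — members with unknown phenotype; these take part in no
#'   filter predicate.
#'
#' Marry-ins with an affected phenotype are kept in the affected set (the
#' within-family assumption concerns allele origin, not phenotype), so the
#' marry-in role is only assigned to unaffected or unknown-status founders.
#'
#' @param ped Pedigree tibble from [read_ped()].
#' @return `ped` with an additional character column `role`.
#' @examples
#' ped <- pedigree_template()
#' dplyr::count(classify_roles(ped), role)
#' @export
classify_roles <- function(ped) {
  validate_ped(ped)
  if (!any(is_founder(ped))) {
    stop("pedigree has no founders", call. = FALSE)
  }
  founder <- stats::setNames(is_founder(ped), ped$id)
  pairs <- co_parent_pairs(ped)
  marry_in <- purrr::map_lgl(ped$id, function(who) {
    if (!founder[[who]]) return(FALSE)
    cp <- pairs$co_parent[pairs$parent == who]
    cp <- unique(stats::na.omit(cp))
    length(cp) > 0L && all(!founder[cp])
  })
  role <- dplyr::case_when(
    ped$affected == "unknown"                     ~ "unknown",
    ped$affected == "affected"                    ~ "affected",
    marry_in                                      ~ "marry_in",
    TRUE                                          ~ "unaffected_blood"
  )
  dplyr::mutate(ped, role = role)
}

#' Infer obligate carriers under a dominant model
#'
#' Under a dominant model with incomplete penetrance, an unaffected
#' blood-line parent of an affected child must carry the causal allele
#' whenever the child's other parent is a marry-in: by the within-family
#' assumption the allele cannot have entered through the marry-in, so it
#' came through the blood parent, who is therefore a non-penetrant carrier.
#'
#' The rule is automatic but can be widened with an explicit override list
#' (e.g. when the analyst designates a carrier on external evidence); the
#' returned set is the union of the two.
#'
#' @param ped Pedigree tibble; roles are computed with [classify_roles()]
#'   if the `role` column is absent.
#' @param override Character vector of individual ids to force into the
#'   obligate-carrier set. Ids not present in the pedigree are an error;
#'   affected ids and marry-ins are rejected (an obligate carrier is by
#'   definition an unaffected blood member).
#' @return Character vector of obligate-carrier ids (possibly empty),
#'   sorted for determinism.
#' @examples
#' infer_obligate_carriers(pedigree_template())
#' @export
infer_obligate_carriers <- function(ped, override = character()) {
  if (!"role" %in% names(ped)) ped <- classify_roles(ped)
  role <- stats::setNames(ped$role, ped$id)
  bad <- setdiff(override, ped$id)
  if (length(bad) > 0L) {
    stop("override id not in pedigree: ", bad[1], call. = FALSE)
  }
  bad_role <- override[role[override] %in% c("affected", "marry_in")]
  if (length(bad_role) > 0L) {
    stop("obligate-carrier override must be an unaffected blood member: ",
         bad_role[1], call. = FALSE)
  }
  pairs <- co_parent_pairs(ped)
  affected <- ped$id[ped$role == "affected"]
  inferred <- pairs |>
    dplyr::filter(
      .data$child %in% affected,
      role[.data$parent] == "unaffected_blood",
      !is.na(.data$co_parent),
      role[.data$co_parent] == "marry_in"
    ) |>
    dplyr::pull("parent")
  sort(unique(c(inferred, override)))
}

#' Write a pedigree to PED format
#'
#' Inverse of [read_ped()] on the retained columns. Missing parents are
#' written as `"0"`; sex as 1/2/0 and affection as 2/1/0.
#'
#' @param ped Pedigree tibble.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_ped <- function(ped, file) {
  sex_code <- dplyr::case_match(ped$sex, "male" ~ "1", "female" ~ "2",
                                .default = "0")
  aff_code <- dplyr::case_match(ped$affected, "affected" ~ "2",
                                "unaffected" ~ "1", .default = "0")
  lines <- paste(ped$family_id, ped$id,
                 dplyr::coalesce(ped$father_id, "0"),
                 dplyr::coalesce(ped$mother_id, "0"),
                 sex_code, aff_code, sep = "\t")
  writeLines(lines, file)
  invisible(file)
}
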