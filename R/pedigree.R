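#' Read a 6-column PED pedigree file
#'
#' Parses the standard pre-makeped PED format: whitespace-delimited columns
#' family id, individual id, father id, mother id, sex (1 = male, 2 = female,
#' 0 = unknown) and phenotype (1 = unaffected, 2 = affected, 0 or -9 =
#' unknown). A parent id of `"0"` means the parent is absent (a member with
#' both parents absent is a founder).
#'
#' @param path Path to a PED file.
#' @return A `pedigree` tibble with columns `family_id`, `sample_id`,
#'   `father_id`, `mother_id` (`NA` for absent parents), `sex`
#'   (`"male"`/`"female"`/`"unknown"`) and `affection`
#'   (`"affected"`/`"unaffected"`/`"unknown"`).
#' @examples
#' ped <- read_ped(system.file("extdata", "family.ped", package = "pedseg"))
#' ped_partition(ped)
#' @export
read_ped <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) stop("PED file '", path, "' contains no records")
  fields <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(fields) < 6L)
  if (length(bad) > 0L) {
    stop("malformed PED line ", bad[1], ": expected >= 6 columns, got ",
         lengths(fields)[bad[1]])
  }
  mat <- do.call(rbind, lapply(fields, `[`, 1:6))
  ped <- tibble::tibble(
    family_id = mat[, 1],
    sample_id = mat[, 2],
    father_id = dplyr::na_if(mat[, 3], "0"),
    mother_id = dplyr::na_if(mat[, 4], "0"),
    sex = dplyr::case_match(mat[, 5], "1" ~ "male", "2" ~ "female",
                            .default = "unknown"),
    affection = dplyr::case_match(mat[, 6], "1" ~ "unaffected",
                                  "2" ~ "affected", .default = "unknown")
  )
  new_pedigree(ped)
}

#' Construct and validate a pedigree
#'
#' @param members A data frame with columns `family_id`, `sample_id`,
#'   `father_id`, `mother_id`, `sex`, `affection` (parent ids `NA` when
#'   absent).
#' @return The validated `pedigree` tibble.
#' @export
new_pedigree <- function(members) {
  ped <- tibble::as_tibble(members)
  req <- c("family_id", "sample_id", "father_id", "mother_id", "sex",
           "affection")
  missing_cols <- setdiff(req, names(ped))
  if (length(missing_cols) > 0L) {
    stop("pedigree is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  dup <- ped$sample_id[duplicated(ped$sample_id)]
  if (length(dup) > 0L) {
    stop("duplicate sample id(s) in pedigree: ", paste(unique(dup), collapse = ", "))
  }
  parents <- stats::na.omit(c(ped$father_id, ped$mother_id))
  dangling <- setdiff(parents, ped$sample_id)
  if (length(dangling) > 0L) {
    stop("parent id(s) not present in pedigree: ", paste(dangling, collapse = ", "))
  }
  assert_no_ancestry_cycle(ped)
  class(ped) <- c("pedigree", class(tibble::tibble()))
  ped
}

# Walk parent links from each member; revisiting the start means a cycle.
assert_no_ancestry_cycle <- function(ped) {
  parent_of <- stats::setNames(
    purrr::map2(ped$father_id, ped$mother_id, ~ stats::na.omit(c(.x, .y))),
    ped$sample_id
  )
  for (id in ped$sample_id) {
    frontier <- parent_of[[id]]
    seen <- character()
    while (length(frontier) > 0L) {
      if (id %in% frontier) stop("member '", id, "' is its own ancestor")
      seen <- union(seen, frontier)
      frontier <- setdiff(unique(unlist(parent_of[frontier])), seen)
    }
  }
  invisible(ped)
}

#' Write a pedigree back to PED format
#'
#' @param ped A `pedigree` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path) {
  sex_code <- dplyr::case_match(ped$sex, "male" ~ "1", "female" ~ "2",
                                .default = "0")
  aff_code <- dplyr::case_match(ped$affection, "unaffected" ~ "1",
                                "affected" ~ "2", .default = "0")
  lines <- paste(ped$family_id, ped$sample_id,
                 dplyr::coalesce(ped$father_id, "0"),
                 dplyr::coalesce(ped$mother_id, "0"),
                 sex_code, aff_code, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Partition a pedigree by affection status and generation
#'
#' Members with unknown affection are excluded from both phenotype sets but
#' remain family members. Children are members with both parents present in
#' the pedigree; parents are members named as father or mother by someone.
#'
#' @param ped A `pedigree` tibble.
#' @return A list with character vectors `affected`, `unaffected`, `children`
#'   and `parents`.
#' @export
ped_partition <- function(ped) {
  named_parents <- unique(stats::na.omit(c(ped$father_id, ped$mother_id)))
  list(
    affected = ped$sample_id[ped$affection == "affected"],
    unaffected = ped$sample_id[ped$affection == "unaffected"],
    children = ped$sample_id[!is.na(ped$father_id) & !is.na(ped$mother_id)],
    parents = ped$sample_id[ped$sample_id %in% named_parents]
  )
}

#' Assert that a pedigree is a single nuclear family
#'
#' Segregation and de novo stages are defined for one nuclear family: exactly
#' two founders (one mother, one father) and every other member naming both
#' as parents. Anything else (multi-generation pedigrees, half-siblings,
#' founder-only pedigrees for trio operations) is an unsupported structure.
#'
#' @param ped A `pedigree` tibble.
#' @param require_children Require at least one child (default `TRUE`).
#' @return A list with `mother`, `father` and `children` sample ids.
#' @export
nuclear_family <- function(ped, require_children = TRUE) {
  founders <- ped[is.na(ped$father_id) & is.na(ped$mother_id), ]
  non_founders <- ped[!(ped$sample_id %in% founders$sample_id), ]
  if (nrow(founders) != 2L) {
    stop("unsupported pedigree structure: expected exactly 2 founders, found ",
         nrow(founders))
  }
  mother <- founders$sample_id[founders$sex == "female"]
  father <- founders$sample_id[founders$sex == "male"]
  if (length(mother) != 1L || length(father) != 1L) {
    stop("unsupported pedigree structure: founders must be one female (mother) ",
         "and one male (father)")
  }
  ok <- non_founders$mother_id == mother & non_founders$father_id == father
  if (!all(ok)) {
    stop("unsupported pedigree structure: member(s) ",
         paste(non_founders$sample_id[!ok], collapse = ", "),
         " do not name the founder couple as parents (nuclear family required)")
  }
  if (require_children && nrow(non_founders) == 0L) {
    stop("unsupported pedigree structure: nuclear family has no children")
  }
  list(mother = mother, father = father, children = non_founders$sample_id)
}
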