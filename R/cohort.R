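#' Methylation cohort container
#'
#' Bundles per-sample metadata (chronological age in decimal years, sex,
#' cohort group and optional clinical subgroup) with a samples-by-CpGs matrix
#' of percent methylation (0--100, pyrosequencing scale). Missing methylation
#' values are stored as `NA`.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param age numeric chronological ages in decimal years, each in (0, 25).
#' @param sex character or factor with levels `"F"`/`"M"`.
#' @param group cohort label per sample (e.g. `"healthy"`, `"growth_disorder"`).
#' @param betas numeric matrix `[n_samples x n_cpgs]` of percent methylation;
#'   column names are CpG names (`"GENE_CpGk"` convention). `NA` allowed.
#' @param subgroup optional per-sample subgroup label (`NA` allowed).
#' @return An object of class `methylation_cohort`: a list with elements
#'   `sample_id`, `age`, `sex` (factor F/M), `group`, `subgroup` and `betas`.
#' @examples
#' b <- matrix(c(10, 50, 99.9), 3, 1, dimnames = list(NULL, "ELOVL2_CpG1"))
#' methylation_cohort(c("s1", "s2", "s3"), c(1.5, 9, 17.2),
#'                    c("F", "M", "F"), "healthy", b)
#' @export
methylation_cohort <- function(sample_id, age, sex, group, betas,
                               subgroup = NA_character_) {
  sample_id <- as.character(sample_id)
  n <- length(sample_id)
  if (anyDuplicated(sample_id))
    stop("duplicate sample_id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  age <- as.numeric(age)
  if (length(age) != n) stop("age length does not match sample_id")
  if (anyNA(age) || any(age <= 0 | age >= 25))
    stop("all ages must be finite, > 0 and < 25 years")
  sex <- as.character(sex)
  if (length(sex) == 1L) sex <- rep(sex, n)
  if (length(sex) != n) stop("sex length does not match sample_id")
  if (!all(sex %in% c("F", "M"))) stop("sex must be 'F' or 'M'")
  sex <- factor(sex, levels = c("F", "M"))
  group <- as.character(group)
  if (length(group) == 1L) group <- rep(group, n)
  if (length(group) != n) stop("group length does not match sample_id")
  subgroup <- as.character(subgroup)
  if (length(subgroup) == 1L) subgroup <- rep(subgroup, n)
  if (length(subgroup) != n) stop("subgroup length does not match sample_id")
  if (!is.matrix(betas)) betas <- as.matrix(betas)
  storage.mode(betas) <- "double"
  if (nrow(betas) != n) stop("betas row count does not match sample_id")
  if (is.null(colnames(betas)) && ncol(betas) > 0)
    stop("betas must have CpG column names")
  if (anyDuplicated(colnames(betas))) stop("duplicate CpG names in betas")
  bad <- which(!is.na(betas) & (betas < 0 | betas > 100), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("beta outside [0, 100] at sample '%s', CpG '%s' (value %g)",
                 sample_id[bad[1, 1]], colnames(betas)[bad[1, 2]],
                 betas[bad[1, 1], bad[1, 2]]))
  rownames(betas) <- sample_id
  structure(list(sample_id = sample_id, age = age, sex = sex, group = group,
                 subgroup = subgroup, betas = betas),
            class = "methylation_cohort")
}

#' @export
print.methylation_cohort <- function(x, ...) {
  cat(sprintf("methylation_cohort: %d samples x %d CpGs\n",
              length(x$sample_id), ncol(x$betas)))
  cat(sprintf("  ages %.2f-%.2f y; sex F/M = %d/%d\n",
              min(x$age), max(x$age), sum(x$sex == "F"), sum(x$sex == "M")))
  for (g in unique(x$group))
    cat(sprintf("  group '%s': n = %d\n", g, sum(x$group == g)))
  if (anyNA(x$betas))
    cat(sprintf("  missing betas: %d\n", sum(is.na(x$betas))))
  invisible(x)
}

#' @export
dim.methylation_cohort <- function(x) dim(x$betas)

#' CpG names of a cohort
#' @param cohort a [methylation_cohort()].
#' @return Character vector of CpG column names.
#' @export
cpg_names <- function(cohort) colnames(cohort$betas)

metadata_cols <- c("sample_id", "age_years", "sex", "group", "subgroup")

#' Read / write the cohort interchange table
#'
#' The interchange format is a UTF-8 CSV with `.` decimal separator and the
#' token `NA` for missing methylation values. Fixed metadata columns
#' `sample_id, age_years, sex, group, subgroup` come first; every remaining
#' column is a CpG. Numeric values are written with 4 decimals, so a
#' write/read round trip reproduces the cohort to that precision.
#'
#' @param path file path.
#' @param delimiter field separator (default `","`).
#' @param na_token token standing for a missing beta (default `"NA"`).
#' @return `read_cohort` returns a validated [methylation_cohort()];
#'   `write_cohort` returns `path` invisibly.
#' @export
read_cohort <- function(path, delimiter = ",", na_token = "NA") {
  if (!file.exists(path)) stop("no such file: ", path)
  hdr <- names(read.csv(path, sep = delimiter, nrows = 0,
                        check.names = FALSE))
  missing_md <- setdiff(metadata_cols, hdr)
  if (length(missing_md) > 0)
    stop("malformed header: missing metadata column(s) ",
         paste(missing_md, collapse = ", "))
  df <- read.csv(path, sep = delimiter, na.strings = na_token,
                 check.names = FALSE, stringsAsFactors = FALSE,
                 colClasses = c(sample_id = "character", sex = "character",
                                group = "character",
                                subgroup = "character"))
  cpgs <- setdiff(names(df), metadata_cols)
  betas <- as.matrix(df[, cpgs, drop = FALSE])
  storage.mode(betas) <- "double"
  colnames(betas) <- cpgs
  methylation_cohort(df$sample_id, df$age_years, df$sex, df$group, betas,
                     subgroup = df$subgroup)
}

#' @param cohort a [methylation_cohort()] to serialise.
#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path, delimiter = ",", na_token = "NA") {
  stopifnot(inherits(cohort, "methylation_cohort"))
  df <- data.frame(sample_id = cohort$sample_id,
                   age_years = sprintf("%.4f", cohort$age),
                   sex = as.character(cohort$sex),
                   group = cohort$group,
                   subgroup = cohort$subgroup,
                   check.names = FALSE, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(cohort$betas))) {
    v <- ifelse(is.na(cohort$betas[, j]), NA_character_,
                sprintf("%.4f", cohort$betas[, j]))
    df[[colnames(cohort$betas)[j]]] <- v
  }
  ok <- tryCatch({
    write.table(df, path, sep = delimiter, na = na_token, quote = FALSE,
                row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) stop("cannot write cohort table: ",
                              conditionMessage(e)))
  invisible(path)
}

#' Subset a cohort by sample index or group label
#'
#' Selection order is preserved; all container invariants are re-validated.
#'
#' @param cohort a [methylation_cohort()].
#' @param i integer or logical sample indices, or a single character group
#'   label (matched against `group`, then `subgroup`).
#' @return A [methylation_cohort()] with the selected samples and the same
#'   CpG columns.
#' @export
subset_cohort <- function(cohort, i) {
  stopifnot(inherits(cohort, "methylation_cohort"))
  if (is.character(i)) {
    stopifnot(length(i) == 1L)
    if (i %in% cohort$group) idx <- which(cohort$group == i)
    else if (i %in% cohort$subgroup) idx <- which(cohort$subgroup == i)
    else stop(sprintf("unknown group label '%s'; available: %s", i,
                      paste(unique(c(cohort$group,
                                     cohort$subgroup[!is.na(cohort$subgroup)])),
                            collapse = ", ")))
  } else if (is.logical(i)) {
    stopifnot(length(i) == length(cohort$sample_id))
    idx <- which(i)
  } else {
    idx <- as.integer(i)
    if (length(idx) > 0 &&
        (anyNA(idx) || any(idx < 1 | idx > length(cohort$sample_id))))
      stop("sample index out of range")
  }
  out <- list(sample_id = cohort$sample_id[idx],
              age = cohort$age[idx],
              sex = cohort$sex[idx],
              group = cohort$group[idx],
              subgroup = cohort$subgroup[idx],
              betas = cohort$betas[idx, , drop = FALSE])
  class(out) <- "methylation_cohort"
  out
}

#' Compare two cohorts field by field
#' @param a,b cohorts.
#' @param tol numeric tolerance on ages and betas.
#' @return `TRUE` if all fields agree within `tol`, else `FALSE`.
#' @export
cohorts_equal <- function(a, b, tol = 5e-5) {
  if (!identical(a$sample_id, b$sample_id)) return(FALSE)
  if (!identical(as.character(a$sex), as.character(b$sex))) return(FALSE)
  if (!identical(a$group, b$group)) return(FALSE)
  if (!identical(a$subgroup, b$subgroup)) return(FALSE)
  if (!identical(colnames(a$betas), colnames(b$betas))) return(FALSE)
  if (max(abs(a$age - b$age)) > tol) return(FALSE)
  na_a <- is.na(a$betas); na_b <- is.na(b$betas)
  if (!identical(na_a, na_b)) return(FALSE)
  if (any(!na_a) && max(abs(a$betas[!na_a] - b$betas[!na_b])) > tol)
    return(FALSE)
  TRUE
}
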