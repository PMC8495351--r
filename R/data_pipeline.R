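# Literature-database pipeline: canonical record schema, inclusion filters,
# development/evaluation split and descriptive summaries.

# Canonical CSV / data-frame schema for treatment-mean and per-cow records.
record_schema <- function() {
  c("study_id", "cow_id", "bw_kg", "my_kg_d", "fat_pct", "wol", "parity",
    "ndf_pct_dm", "cp_pct_dm", "adf_pct_dm", "starch_pct_dm", "fpdm_pct",
    "dmi_kg_d")
}

#' Read a record table from CSV
#'
#' Expects the canonical schema columns (`study_id`, `cow_id`, `bw_kg`,
#' `my_kg_d`, `fat_pct`, `wol`, `parity`, `ndf_pct_dm`, `cp_pct_dm`,
#' `adf_pct_dm`, `starch_pct_dm`, `fpdm_pct`, `dmi_kg_d`); extra columns
#' (e.g. `breed`, `month`) are carried through.
#'
#' @param path CSV file with a header row.
#' @param required columns that must be present.
#' @return data frame of records.
#' @export
read_records <- function(path, required = c("study_id", "bw_kg", "my_kg_d",
                                            "fat_pct", "dmi_kg_d")) {
  if (!file.exists(path)) stop_data(sprintf("input file not found: %s", path))
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(rec))
  if (length(missing_cols) > 0) {
    stop_schema(sprintf("input lacks required column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  }
  rec
}

#' Apply the literature-database inclusion filters
#'
#' Retains records satisfying, in order:
#' \describe{
#'   \item{i}{milk yield reported;}
#'   \item{ii}{breed is Holstein;}
#'   \item{iii}{DMI as a percentage of body weight >= 2\%;}
#'   \item{iv}{forage percentage of dietary DM in \[30, 100) — all-forage
#'     (100\%) diets are excluded along with low-forage ones;}
#'   \item{v}{dietary NDF >= 25\% of DM;}
#'   \item{vi}{week of lactation reported.}
#' }
#' Each rejected record is attributed to the first failing rule. Rows whose
#' DMI or body weight is missing or non-positive (so rule iii cannot be
#' evaluated) are rejected as `"parse"`; a missing value for the quantity a
#' rule tests (breed, FpDM, NDF) fails that rule. Filtering never errors and
#' is idempotent.
#'
#' @param records data frame in the canonical schema; an optional `breed`
#'   column defaults to `"Holstein"` when absent (treatment means already
#'   restricted to Holstein data).
#' @return list with `records` (retained rows) and `report` (a list with
#'   `n_input`, `n_retained` and per-rule `rejections`).
#' @export
apply_inclusion_filters <- function(records) {
  n <- nrow(records)
  rules <- c("parse", "i", "ii", "iii", "iv", "v", "vi")
  rejections <- stats::setNames(integer(length(rules)), rules)
  if (n == 0) {
    return(list(records = records,
                report = list(n_input = 0L, n_retained = 0L,
                              rejections = rejections)))
  }
  breed <- if ("breed" %in% names(records)) records$breed else
    rep("Holstein", n)
  dmi <- records$dmi_kg_d
  bw <- records$bw_kg
  fail <- rep(NA_character_, n)
  mark <- function(cond, rule) {
    hit <- is.na(fail) & cond
    fail[hit] <<- rule
  }
  mark(is.na(dmi) | is.na(bw) | !is.finite(dmi) | !is.finite(bw) |
         dmi <= 0 | bw <= 0, "parse")
  mark(is.na(records$my_kg_d), "i")
  mark(is.na(breed) | breed != "Holstein", "ii")
  mark(100 * dmi / bw < 2, "iii")
  mark(is.na(records$fpdm_pct) | records$fpdm_pct < 30 |
         records$fpdm_pct >= 100, "iv")
  mark(is.na(records$ndf_pct_dm) | records$ndf_pct_dm < 25, "v")
  mark(is.na(records$wol), "vi")
  tab <- table(factor(fail, levels = rules))
  rejections[] <- as.integer(tab)
  retained <- records[is.na(fail), , drop = FALSE]
  list(records = retained,
       report = list(n_input = n, n_retained = nrow(retained),
                     rejections = rejections))
}

#' Split records into development and evaluation sets by study size
#'
#' Studies contributing at least `min_obs_per_study` records go to the
#' development set; smaller studies go to the evaluation set. The split is a
#' partition: no study appears in both.
#'
#' @param records filtered records with a `study_id` column.
#' @param min_obs_per_study minimum study size for development (default 4).
#' @return list with `development` and `evaluation` data frames.
#' @export
split_dev_eval <- function(records, min_obs_per_study = 4) {
  if (!"study_id" %in% names(records) ||
      (nrow(records) > 0 && anyNA(records$study_id))) {
    stop_schema("records must carry a non-missing study_id")
  }
  if (nrow(records) == 0) {
    return(list(development = records, evaluation = records))
  }
  sizes <- table(records$study_id)
  dev_studies <- names(sizes)[sizes >= min_obs_per_study]
  in_dev <- records$study_id %in% dev_studies
  list(development = records[in_dev, , drop = FALSE],
       evaluation = records[!in_dev, , drop = FALSE])
}

#' Cap the number of observations retained per study
#'
#' Optionally mirrors a balanced design by keeping at most `cap` randomly
#' chosen records (without replacement, seeded) from each study.
#'
#' @param records data frame with `study_id`.
#' @param cap maximum records kept per study.
#' @param seed integer seed for the within-study sampling.
#' @return data frame with at most `cap` rows per study.
#' @export
cap_per_study <- function(records, cap = 4, seed = NULL) {
  if (!"study_id" %in% names(records)) stop_schema("records must carry study_id")
  if (!is.null(seed)) set.seed(seed)
  keep <- unlist(lapply(split(seq_len(nrow(records)), records$study_id),
                        function(idx) {
                          if (length(idx) <= cap) idx else sort(sample(idx, cap))
                        }), use.names = FALSE)
  records[sort(keep), , drop = FALSE]
}

#' Descriptive statistics per variable
#'
#' n, mean, sample SD, median, max and min over non-missing values for each
#' numeric variable, in the layout of a database descriptives table.
#'
#' @param records data frame.
#' @param vars variables to summarize; defaults to all numeric columns.
#' @return data frame with one row per variable.
#' @export
summarize_records <- function(records,
                              vars = names(records)[vapply(records, is.numeric,
                                                           logical(1))]) {
  vars <- setdiff(vars, grep("^\\.", vars, value = TRUE))
  rows <- lapply(vars, function(v) {
    x <- records[[v]]
    x <- x[!is.na(x)]
    if (length(x) == 0) {
      data.frame(variable = v, n = 0L, mean = NA_real_, sd = NA_real_,
                 median = NA_real_, max = NA_real_, min = NA_real_)
    } else {
      data.frame(variable = v, n = length(x), mean = mean(x),
                 sd = if (length(x) > 1) stats::sd(x) else 0,
                 median = stats::median(x), max = max(x), min = min(x))
    }
  })
  do.call(rbind, rows)
}
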