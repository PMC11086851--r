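PROMS_FEATURES <- c("vas", "odi", "tsk", "pcs", "pseq", "csq", "sbt")

#' Canonical patient-reported outcome measure names
#'
#' The seven PROM features in their fixed canonical order: VAS (pain
#' intensity, 0--100 mm), ODI (disability index, 0--100), TSK (Tampa Scale
#' of Kinesiophobia, 17--68), PCS (Pain Catastrophising Scale, 0--52), PSEQ
#' (Pain Self-Efficacy Questionnaire, 0--60), CSQ (Coping Strategies
#' Questionnaire total, 0--70) and SBT (STarT Back tool total, 0--9).
#' Feature-subset masks index into this order.
#'
#' @return Character vector of length 7.
#' @export
proms_feature_names <- function() PROMS_FEATURES

#' Validation schema for the PROMs table
#'
#' Closed allowed ranges per measure.  The CSQ total defaults to 0--70 (14
#' items scored 0--5); adjust `csq_max` if a different totalling convention
#' is used.
#'
#' @param csq_max Upper bound of the CSQ total (default 70).
#' @return Named list of `c(min, max)` ranges, one per PROM.
#' @export
proms_schema <- function(csq_max = 70) {
  list(vas = c(0, 100), odi = c(0, 100), tsk = c(17, 68), pcs = c(0, 52),
       pseq = c(0, 60), csq = c(0, csq_max), sbt = c(0, 9))
}

#' Validate a PROMs data frame
#'
#' Checks column presence, duplicate participant identifiers, missing
#' values, and that every score lies within its allowed range.  The SBT
#' risk band (low 0--3, medium 4--6, high 7--9 on the total score) is added
#' as a derived `sbt_risk` column.
#'
#' @param df Data frame with columns `participant_id` and the seven PROMs
#'   of [proms_feature_names()].
#' @param schema Allowed ranges, see [proms_schema()].
#' @return The validated data frame (invisibly augmented with `sbt_risk`).
#' @export
validate_proms <- function(df, schema = proms_schema()) {
  required <- c("participant_id", PROMS_FEATURES)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("PROMs table missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  dup <- df$participant_id[duplicated(df$participant_id)]
  if (length(dup)) {
    stop(sprintf("duplicate participant_id(s): %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  for (field in PROMS_FEATURES) {
    v <- df[[field]]
    if (!is.numeric(v)) {
      stop(sprintf("PROM '%s' must be numeric", field), call. = FALSE)
    }
    bad_na <- which(is.na(v))
    if (length(bad_na)) {
      stop(sprintf("participant %s: missing value for '%s' (no imputation is applied)",
                   df$participant_id[bad_na[1L]], field), call. = FALSE)
    }
    rng <- schema[[field]]
    bad <- which(v < rng[1] | v > rng[2])
    if (length(bad)) {
      stop(sprintf("participant %s: %s = %g outside allowed range [%g, %g]",
                   df$participant_id[bad[1L]], field, v[bad[1L]],
                   rng[1], rng[2]), call. = FALSE)
    }
  }
  df$sbt_risk <- cut(df$sbt, breaks = c(-0.5, 3.5, 6.5, 9.5),
                     labels = c("low", "medium", "high"))
  df
}

#' Load and validate a PROMs CSV
#'
#' Reads a CSV with one row per participant and columns `participant_id`,
#' `vas`, `odi`, `tsk`, `pcs`, `pseq`, `csq`, `sbt` (header required), and
#' validates it with [validate_proms()].
#'
#' @param path Path to the CSV file.
#' @param schema Allowed ranges, see [proms_schema()].
#' @return Validated data frame keyed by `participant_id`.
#' @export
load_proms <- function(path, schema = proms_schema()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- validate_proms(df, schema)
  message(sprintf("loaded %d PROMs record(s) from %s", nrow(df), path))
  df
}
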