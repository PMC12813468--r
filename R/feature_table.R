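# Canonical session-level feature table: one row per MRI session carrying the
# five scalar features (GM/WM/CSF volumes in ml, mean cortical thickness in
# mm, WMH volume in ml), TIV, months-from-baseline and the hierarchical
# "group.subject.scan" label.

#' Diagnostic group codes
#'
#' Integer codes for the five diagnostic strata used throughout the package:
#' AD = 0, CN = 1, MCI = 2, EMCI = 3, LMCI = 4.
#'
#' @format Named integer vector of length 5.
#' @export
GROUP_CODES <- c(AD = 0L, CN = 1L, MCI = 2L, EMCI = 3L, LMCI = 4L)

#' @rdname GROUP_CODES
#' @param code integer group code(s) in 0..4.
#' @return `group_name()` returns the group abbreviation(s) for `code`.
#' @export
group_name <- function(code) {
  code <- as.integer(code)
  if (any(is.na(code)) || any(code < 0L | code > 4L)) {
    stop("group code must be an integer in 0..4", call. = FALSE)
  }
  names(GROUP_CODES)[match(code, GROUP_CODES)]
}

# Columns every feature table must carry, in canonical order.
FEATURE_TABLE_COLUMNS <- c(
  "label", "group_code", "subject_num", "scan_num", "delta_t_months",
  "tiv_ml", "gm_ml", "wm_ml", "csf_ml", "ct_mm", "wmh_ml",
  "gm_pct", "wm_pct", "csf_pct", "wmh_pct"
)

# Volume features (ml) that get a %TIV companion column.
VOLUME_FEATURES <- c("gm", "wm", "csf", "wmh")

#' Express a volume as a percentage of total intracranial volume
#'
#' Head size varies substantially between people, so tissue volumes are
#' compared as fractions of total intracranial volume (TIV) rather than in
#' absolute millilitres.
#'
#' @param volume_ml volume in ml (vectorized, must be >= 0).
#' @param tiv_ml total intracranial volume in ml (> 0; recycled).
#' @return `100 * volume_ml / tiv_ml`.
#' @examples
#' pct_of_tiv(600, 1500)  # 40
#' @export
pct_of_tiv <- function(volume_ml, tiv_ml) {
  if (!is.numeric(volume_ml) || !is.numeric(tiv_ml)) {
    stop("volume_ml and tiv_ml must be numeric", call. = FALSE)
  }
  if (any(!is.finite(tiv_ml)) || any(tiv_ml <= 0)) {
    stop("tiv_ml must be finite and > 0", call. = FALSE)
  }
  100 * volume_ml / tiv_ml
}

#' Months-from-baseline for a subject's scan times
#'
#' The first scan of every subject defines that subject's baseline (0); each
#' later scan is expressed as months elapsed since it. Input times are sorted
#' before assignment, so acquisition order is recovered even from unsorted
#' records.
#'
#' @param months_absolute numeric vector of absolute scan times in months.
#' @return numeric vector of the same length, sorted ascending, first
#'   element 0.
#' @examples
#' assign_delta_t(c(12, 18, 30))  # 0 6 18
#' @export
assign_delta_t <- function(months_absolute) {
  if (length(months_absolute) < 1L) {
    stop("at least one session is required", call. = FALSE)
  }
  if (any(!is.finite(months_absolute))) {
    stop("scan times must be finite", call. = FALSE)
  }
  m <- sort(months_absolute)
  d <- m - m[1L]
  if (any(d < 0)) stop("negative scan interval", call. = FALSE)
  d
}

#' Hierarchical session labels
#'
#' Sessions are labelled `"group.subject.scan"`, e.g. `"0.1.1"` for the first
#' scan of the first AD subject. `parse_label()` inverts `make_label()`.
#'
#' @param group_code integer 0..4 (see [GROUP_CODES]).
#' @param subject_num 1-based subject index within the group.
#' @param scan_num 1-based scan index within the subject.
#' @return `make_label()`: character vector of labels. `parse_label()`: a
#'   data.frame with columns `group_code`, `subject_num`, `scan_num`.
#' @examples
#' make_label(0, 1, 1)     # "0.1.1"
#' parse_label("4.3.2")    # LMCI subject 3, scan 2
#' @export
make_label <- function(group_code, subject_num, scan_num) {
  g <- as.integer(group_code)
  s <- as.integer(subject_num)
  k <- as.integer(scan_num)
  if (any(is.na(g)) || any(g < 0L | g > 4L)) {
    stop("group_code must be in 0..4", call. = FALSE)
  }
  if (any(is.na(s)) || any(s < 1L) || any(is.na(k)) || any(k < 1L)) {
    stop("subject_num and scan_num must be integers >= 1", call. = FALSE)
  }
  paste(g, s, k, sep = ".")
}

#' @rdname make_label
#' @param label character vector of `"g.s.k"` labels.
#' @export
parse_label <- function(label) {
  parts <- strsplit(as.character(label), ".", fixed = TRUE)
  if (any(lengths(parts) != 3L)) {
    stop("malformed label; expected \"group.subject.scan\"", call. = FALSE)
  }
  m <- matrix(suppressWarnings(as.integer(unlist(parts))),
              ncol = 3L, byrow = TRUE)
  if (any(is.na(m))) stop("malformed label; non-integer field", call. = FALSE)
  out <- data.frame(group_code = m[, 1L], subject_num = m[, 2L],
                    scan_num = m[, 3L])
  if (any(out$group_code < 0L | out$group_code > 4L)) {
    stop("unknown group code in label", call. = FALSE)
  }
  if (any(out$subject_num < 1L) || any(out$scan_num < 1L)) {
    stop("subject and scan numbers must be >= 1", call. = FALSE)
  }
  out
}

#' Construct and validate a feature table
#'
#' Checks the full invariant set: required columns, label consistency, one
#' baseline (`scan_num == 1`, `delta_t_months == 0`) per subject, positive
#' TIV, non-negative volumes and delays, and agreement between stored %TIV
#' columns and the volume/TIV ratio.
#'
#' @param df data.frame with the columns listed in the package README
#'   (label, group_code, subject_num, scan_num, delta_t_months, tiv_ml,
#'   gm_ml, wm_ml, csf_ml, ct_mm, wmh_ml and the four *_pct columns).
#' @param pct_tol absolute tolerance for the stored-vs-recomputed %TIV check.
#' @return the validated data.frame with class `feature_table`.
#' @export
feature_table <- function(df, pct_tol = 1e-6) {
  if (!is.data.frame(df)) stop("df must be a data.frame", call. = FALSE)
  missing_cols <- setdiff(FEATURE_TABLE_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, union(FEATURE_TABLE_COLUMNS,
                   setdiff(names(df), FEATURE_TABLE_COLUMNS)), drop = FALSE]
  if (anyDuplicated(df$label)) stop("duplicate session label", call. = FALSE)
  lp <- parse_label(df$label)
  if (!all(lp$group_code == df$group_code &
           lp$subject_num == df$subject_num &
           lp$scan_num == df$scan_num)) {
    stop("label fields disagree with group/subject/scan columns",
         call. = FALSE)
  }
  if (any(df$delta_t_months < 0)) {
    stop("delta_t_months must be >= 0", call. = FALSE)
  }
  if (any(df$tiv_ml <= 0)) stop("tiv_ml must be > 0", call. = FALSE)
  if (any(df$ct_mm <= 0)) stop("ct_mm must be > 0", call. = FALSE)
  vols <- paste0(VOLUME_FEATURES, "_ml")
  if (any(as.matrix(df[vols]) < 0)) {
    stop("volumes must be >= 0", call. = FALSE)
  }
  subj <- paste(df$group_code, df$subject_num, sep = ".")
  base <- df$scan_num == 1L
  if (!all(tapply(base, subj, sum) == 1L)) {
    stop("each subject must have exactly one scan_num == 1 row",
         call. = FALSE)
  }
  if (any(df$delta_t_months[base] != 0)) {
    stop("baseline rows must have delta_t_months == 0", call. = FALSE)
  }
  if (any(df$delta_t_months[!base] <= 0)) {
    stop("follow-up rows must have delta_t_months > 0", call. = FALSE)
  }
  for (v in VOLUME_FEATURES) {
    expect <- pct_of_tiv(df[[paste0(v, "_ml")]], df$tiv_ml)
    if (any(abs(expect - df[[paste0(v, "_pct")]]) > pct_tol)) {
      stop(sprintf("%s_pct inconsistent with %s_ml / tiv_ml", v, v),
           call. = FALSE)
    }
  }
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Read / write a feature table CSV
#'
#' Plain comma-separated UTF-8 with a header row and `.` decimal separator.
#' Values are written with 17 significant digits so a write/read round trip
#' preserves doubles exactly; tables are validated on read.
#'
#' @param path file path.
#' @return `read_feature_table()` returns a validated [feature_table].
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(FEATURE_TABLE_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df$group_code <- as.integer(df$group_code)
  df$subject_num <- as.integer(df$subject_num)
  df$scan_num <- as.integer(df$scan_num)
  feature_table(df)
}

#' @rdname read_feature_table
#' @param table a [feature_table].
#' @export
write_feature_table <- function(table, path) {
  table <- feature_table(as.data.frame(table))
  out <- as.data.frame(table)
  num <- vapply(out, is.double, logical(1L))
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.feature_table <- function(x, ...) {
  subj <- unique(paste(x$group_code, x$subject_num, sep = "."))
  cat(sprintf("<feature_table> %d sessions, %d subjects, %d group(s)\n",
              nrow(x), length(subj), length(unique(x$group_code))))
  NextMethod()
}
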