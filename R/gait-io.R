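#' @useDynLib gaitqr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats mad median rnorm rlnorm predict
#' @importFrom utils read.csv write.csv head tail
NULL

#' Column order of a per-stride gait record
#'
#' The 13 timing features recorded for each gait cycle, in the column order
#' of the PhysioNet-style stride tables this package reads and writes:
#' elapsed time since the start of the walk, left/right stride intervals,
#' left/right swing intervals, swing as a percentage of the same-side
#' stride, left/right stance intervals and percentages, and the
#' double-support interval and its percentage (relative to the left
#' stride). All intervals are in seconds.
#'
#' @format Character vector of length 13.
#' @export
GAIT_COLUMNS <- c(
  "elapsed_time",
  "left_stride", "right_stride",
  "left_swing", "right_swing",
  "left_swing_pct", "right_swing_pct",
  "left_stance", "right_stance",
  "left_stance_pct", "right_stance_pct",
  "double_support", "double_support_pct"
)

#' Class labels recognised by the pipeline
#' @format Character vector: ALS, HD, PD, CONTROL.
#' @export
GAIT_CLASSES <- c("ALS", "HD", "PD", "CONTROL")

# filename prefix -> class, per the public gait database's naming scheme
.LABEL_PREFIXES <- c(als = "ALS", hunt = "HD", park = "PD", control = "CONTROL")

#' Construct a subject series
#'
#' Bundles a subject identifier, a disease label and an ordered data frame
#' of per-stride records (columns [GAIT_COLUMNS]) into a `subject_series`
#' object, validating the label, column layout and monotonicity of
#' `elapsed_time`.
#'
#' @param subject_id Character scalar.
#' @param label One of `GAIT_CLASSES`.
#' @param records Data frame with the 13 [GAIT_COLUMNS].
#' @param flags Optional logical vector marking records that failed a
#'   timing-consistency check (kept, not dropped).
#' @return A `subject_series` object.
#' @export
subject_series <- function(subject_id, label, records, flags = NULL) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  label <- match.arg(label, GAIT_CLASSES)
  records <- as.data.frame(records)
  if (!identical(names(records), GAIT_COLUMNS))
    stop("records must have exactly the 13 gait columns in order")
  if (nrow(records) == 0L)
    stop("empty series: subject '", subject_id, "' has no stride records")
  et <- records$elapsed_time
  if (nrow(records) > 1L && any(diff(et) <= 0))
    stop("elapsed_time must be strictly increasing for subject '", subject_id, "'")
  if (is.null(flags)) flags <- rep(FALSE, nrow(records))
  structure(
    list(subject_id = subject_id, label = label, records = records,
         flags = as.logical(flags)),
    class = "subject_series"
  )
}

#' @export
print.subject_series <- function(x, ...) {
  cat(sprintf("<subject_series> %s  label=%s  strides=%d  flagged=%d\n",
              x$subject_id, x$label, nrow(x$records), sum(x$flags)))
  invisible(x)
}

# Per-record timing consistency: swing + stance == stride per side, and each
# percentage column equals 100 * interval / same-side stride
# (double support relative to the left stride). Relative tolerance rtol.
check_stride_consistency <- function(records, rtol = 1e-2) {
  rel_ok <- function(a, b) {
    scale <- pmax(abs(a), abs(b), 1e-12)
    abs(a - b) / scale <= rtol
  }
  with(records,
    rel_ok(left_swing + left_stance, left_stride) &
    rel_ok(right_swing + right_stance, right_stride) &
    rel_ok(left_swing_pct, 100 * left_swing / left_stride) &
    rel_ok(right_swing_pct, 100 * right_swing / right_stride) &
    rel_ok(left_stance_pct, 100 * left_stance / left_stride) &
    rel_ok(right_stance_pct, 100 * right_stance / right_stride) &
    rel_ok(double_support_pct, 100 * double_support / left_stride)
  )
}

#' Read one subject's stride table
#'
#' Parses a whitespace/tab-delimited 13-column numeric stride table (the
#' dialect of the PhysioNet neurodegenerative gait database, one file per
#' subject) into a [subject_series()]. Rows whose swing/stance/percentage
#' fields are mutually inconsistent beyond a 1% relative tolerance are
#' flagged with a warning but kept; rows containing non-finite values are
#' rejected with a warning. A row that does not contain exactly 13 numeric
#' fields is an error.
#'
#' @param source Path to a file, or a connection.
#' @param label Class label; if `NULL`, inferred from the filename with
#'   [label_from_filename()].
#' @param subject_id Subject identifier; defaults to the file's basename
#'   without extension.
#' @param filter_outliers If `TRUE`, drop records whose left or right
#'   stride deviates more than 3 median absolute deviations from the
#'   subject's median stride (off by default: no cleaning is applied unless
#'   requested).
#' @return A `subject_series`.
#' @export
read_subject_file <- function(source, label = NULL, subject_id = NULL,
                              filter_outliers = FALSE) {
  if (is.character(source)) {
    if (is.null(subject_id))
      subject_id <- tools::file_path_sans_ext(basename(source))
    if (is.null(label))
      label <- label_from_filename(source)
    lines <- readLines(source, warn = FALSE)
  } else {
    lines <- readLines(source, warn = FALSE)
    if (is.null(subject_id)) subject_id <- "subject"
    if (is.null(label)) stop("label must be given when reading from a connection")
  }
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L)
    stop("empty series: no data rows in input for subject '", subject_id, "'")

  rows <- vector("list", length(nonblank))
  for (k in seq_along(nonblank)) {
    i <- nonblank[k]
    tokens <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    vals <- suppressWarnings(as.numeric(tokens))
    if (length(tokens) != 13L || anyNA(vals))
      stop(sprintf("parse error at line %d: expected 13 numeric fields, got %d%s",
                   i, length(tokens),
                   if (anyNA(vals)) " (non-numeric token present)" else ""))
    rows[[k]] <- vals
  }
  m <- do.call(rbind, rows)
  colnames(m) <- GAIT_COLUMNS
  records <- as.data.frame(m)

  finite <- apply(is.finite(m), 1L, all)
  if (!all(finite)) {
    warning(sprintf("subject '%s': rejected %d row(s) with non-finite values",
                    subject_id, sum(!finite)))
    records <- records[finite, , drop = FALSE]
  }
  if (nrow(records) == 0L)
    stop("empty series: all rows rejected for subject '", subject_id, "'")

  if (filter_outliers) {
    keep <- !stride_outliers(records)
    records <- records[keep, , drop = FALSE]
    if (nrow(records) == 0L)
      stop("empty series: outlier filter removed every record for subject '",
           subject_id, "'")
  }

  ok <- check_stride_consistency(records)
  if (any(!ok))
    warning(sprintf("subject '%s': %d record(s) fail timing-consistency checks (kept, flagged)",
                    subject_id, sum(!ok)))
  rownames(records) <- NULL
  subject_series(subject_id, label, records, flags = !ok)
}

# left/right stride > 3 MAD from the subject median (either side)
stride_outliers <- function(records, k = 3) {
  out_side <- function(x) {
    s <- mad(x)
    if (s == 0) return(rep(FALSE, length(x)))
    abs(x - median(x)) / s > k
  }
  out_side(records$left_stride) | out_side(records$right_stride)
}

#' Infer the class label from a gait file name
#'
#' The public gait database encodes the group in the filename prefix:
#' `als*` (amyotrophic lateral sclerosis), `hunt*` (Huntington's disease),
#' `park*` (Parkinson's disease), `control*` (healthy control). Matching is
#' case-insensitive on the basename.
#'
#' @param name File name or path.
#' @return One of `GAIT_CLASSES`.
#' @export
label_from_filename <- function(name) {
  base <- tolower(basename(name))
  for (p in names(.LABEL_PREFIXES))
    if (startsWith(base, p)) return(unname(.LABEL_PREFIXES[[p]]))
  stop("cannot infer class label from '", name,
       "': accepted filename prefixes are ",
       paste(names(.LABEL_PREFIXES), collapse = ", "))
}

#' Reduce a subject series to modeling feature vectors
#'
#' Drops the elapsed-time column (a clock, not a gait feature) and returns
#' one 12-value feature vector per stride record, preserving record order
#' and the original column order of the remaining fields.
#'
#' @param series A `subject_series`.
#' @return Data frame with one row per record: `subject_id`, `label`,
#'   `record_index`, then the 12 feature columns.
#' @export
to_feature_vectors <- function(series) {
  stopifnot(inherits(series, "subject_series"))
  feats <- series$records[, setdiff(GAIT_COLUMNS, "elapsed_time"), drop = FALSE]
  out <- cbind(
    data.frame(subject_id = series$subject_id,
               label = series$label,
               record_index = seq_len(nrow(feats)),
               stringsAsFactors = FALSE),
    feats
  )
  rownames(out) <- NULL
  out
}

#' Names of the 12 modeling features
#' @return Character vector (the gait columns minus `elapsed_time`).
#' @export
feature_names <- function() setdiff(GAIT_COLUMNS, "elapsed_time")

#' Read every subject file in a directory
#'
#' @param dir Directory containing `.ts` stride tables named with class
#'   prefixes.
#' @param filter_outliers Passed to [read_subject_file()].
#' @return List of `subject_series`.
#' @export
read_gait_dir <- function(dir, filter_outliers = FALSE) {
  files <- sort(list.files(dir, pattern = "\\.ts$", full.names = TRUE))
  if (length(files) == 0L) stop("no .ts subject files found in ", dir)
  lapply(files, read_subject_file, filter_outliers = filter_outliers)
}
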