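#' Define a synthetic gait class profile
#'
#' A class profile parameterises the stride-timing distribution used by the
#' synthetic generator: the mean stride interval, its coefficient of
#' variation (CV), the mean and spread of the swing fraction (swing time as
#' a fraction of the stride), and a left/right asymmetry offset. The
#' profile constants shipped by [default_profiles()] are synthetic
#' benchmark parameters chosen to separate the classes in the directions
#' reported for real cohorts (slower, more variable gait in disease); they
#' are not estimates of any real cohort.
#'
#' @param label One of `GAIT_CLASSES`.
#' @param mean_stride Mean stride interval, seconds (> 0).
#' @param stride_cv Coefficient of variation of the stride interval (>= 0).
#' @param swing_fraction_mean Mean swing fraction, in (0, 0.6).
#' @param swing_fraction_sd Standard deviation of the swing fraction.
#' @param lr_asymmetry Fractional left/right stride offset: the left mean
#'   is scaled by `1 + lr_asymmetry/2`, the right by `1 - lr_asymmetry/2`.
#' @return A `class_profile` object.
#' @export
class_profile <- function(label, mean_stride, stride_cv,
                          swing_fraction_mean, swing_fraction_sd = 0.01,
                          lr_asymmetry = 0) {
  label <- match.arg(label, GAIT_CLASSES)
  stopifnot(mean_stride > 0, stride_cv >= 0,
            swing_fraction_mean > 0, swing_fraction_mean < 0.6,
            swing_fraction_sd >= 0)
  structure(list(label = label, mean_stride = mean_stride,
                 stride_cv = stride_cv,
                 swing_fraction_mean = swing_fraction_mean,
                 swing_fraction_sd = swing_fraction_sd,
                 lr_asymmetry = lr_asymmetry),
            class = "class_profile")
}

#' Default synthetic profiles for the four classes
#'
#' Package defaults for the synthetic benchmark: controls walk with a
#' regular ~1.10 s stride (CV 2%); the Parkinson-like profile is slightly
#' faster with reduced swing and moderate variability; the Huntington-like
#' profile is the most variable (CV 9%); the ALS-like profile is markedly
#' slower (1.35 s). All constants are overridable.
#'
#' @return Named list of four `class_profile` objects (ALS, HD, PD,
#'   CONTROL).
#' @export
default_profiles <- function() {
  list(
    ALS     = class_profile("ALS",     1.35, 0.06, 0.40),
    HD      = class_profile("HD",      1.15, 0.09, 0.37),
    PD      = class_profile("PD",      1.05, 0.05, 0.33),
    CONTROL = class_profile("CONTROL", 1.10, 0.02, 0.38)
  )
}

#' Synthetic dataset configuration
#'
#' @param profiles Named list of `class_profile`s (default
#'   [default_profiles()]).
#' @param subjects_per_class Subjects generated per class (>= 1).
#' @param strides_per_subject Stride records per subject (>= 1).
#' @param seed Integer master seed; the full dataset is a deterministic
#'   function of the configuration.
#' @return A `synthetic_config` object.
#' @export
synthetic_config <- function(profiles = default_profiles(),
                             subjects_per_class = 10L,
                             strides_per_subject = 80L,
                             seed = 1L) {
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, inherits, logical(1), "class_profile")),
            subjects_per_class >= 1L, strides_per_subject >= 1L)
  structure(list(profiles = profiles,
                 subjects_per_class = as.integer(subjects_per_class),
                 strides_per_subject = as.integer(strides_per_subject),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# lognormal draw with arithmetic mean m and coefficient of variation cv
rlnorm_mean_cv <- function(n, m, cv) {
  if (cv == 0) return(rep(m, n))
  s2 <- log(1 + cv^2)
  rlnorm(n, meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

#' Generate one synthetic subject
#'
#' Stride intervals are drawn lognormally (positive by construction) with
#' the profile's mean and CV, per side; swing fractions are drawn normally
#' and clamped to (0.1, 0.6); stance is the stride minus the swing, so the
#' swing/stance/percentage identities hold exactly. The double-support
#' interval is the left stride minus both swing intervals, floored at
#' 0.01 s, and its percentage is relative to the left stride. Elapsed time
#' is the cumulative sum of left strides. An optional AR(1) coefficient
#' introduces temporal autocorrelation in the stride sequence (off by
#' default: records are treated as independent downstream).
#'
#' @param profile A `class_profile`.
#' @param n_strides Number of records (>= 1).
#' @param seed Integer seed; identical arguments give identical output.
#' @param subject_id Identifier (default derived from the label).
#' @param ar1 AR(1) coefficient in [0, 1) applied to the stride deviations.
#' @return A `subject_series`.
#' @export
generate_subject <- function(profile, n_strides, seed,
                             subject_id = NULL, ar1 = 0) {
  stopifnot(inherits(profile, "class_profile"))
  if (n_strides < 1L) stop("n_strides must be >= 1")
  if (is.null(subject_id))
    subject_id <- paste0(tolower(profile$label), "s", seed %% 1000L)

  withr::with_seed(as.integer(seed), {
    mL <- profile$mean_stride * (1 + profile$lr_asymmetry / 2)
    mR <- profile$mean_stride * (1 - profile$lr_asymmetry / 2)
    left  <- rlnorm_mean_cv(n_strides, mL, profile$stride_cv)
    right <- rlnorm_mean_cv(n_strides, mR, profile$stride_cv)
    if (ar1 > 0) {
      left  <- mL + as.numeric(stats::filter(left - mL, ar1, "recursive"))
      right <- mR + as.numeric(stats::filter(right - mR, ar1, "recursive"))
      left  <- pmax(left, 0.2 * mL)
      right <- pmax(right, 0.2 * mR)
    }
    fL <- pmin(pmax(rnorm(n_strides, profile$swing_fraction_mean,
                          profile$swing_fraction_sd), 0.1), 0.6)
    fR <- pmin(pmax(rnorm(n_strides, profile$swing_fraction_mean,
                          profile$swing_fraction_sd), 0.1), 0.6)
  })

  left_swing <- fL * left
  right_swing <- fR * right
  left_stance <- left - left_swing
  right_stance <- right - right_swing
  ds <- pmax(left - left_swing - right_swing, 0.01)

  records <- data.frame(
    elapsed_time = cumsum(left),
    left_stride = left, right_stride = right,
    left_swing = left_swing, right_swing = right_swing,
    left_swing_pct = 100 * left_swing / left,
    right_swing_pct = 100 * right_swing / right,
    left_stance = left_stance, right_stance = right_stance,
    left_stance_pct = 100 * left_stance / left,
    right_stance_pct = 100 * right_stance / right,
    double_support = ds,
    double_support_pct = 100 * ds / left
  )
  subject_series(subject_id, profile$label, records)
}

# deterministic per-subject seed derived from the master seed; < 2^31
derive_seed <- function(master, class_index, subject_index) {
  as.integer((as.numeric(master) * 7919 + class_index * 104729 +
                subject_index * 131) %% 2147483629)
}

#' Generate a labeled synthetic dataset
#'
#' @param config A [synthetic_config()].
#' @return List of `subject_series`, `subjects_per_class` per profile, with
#'   subject ids encoding class and index (e.g. `als03`).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  out <- list()
  prefix_of <- c(ALS = "als", HD = "hunt", PD = "park", CONTROL = "control")
  for (ci in seq_along(config$profiles)) {
    prof <- config$profiles[[ci]]
    for (si in seq_len(config$subjects_per_class)) {
      sid <- sprintf("%s%02d", prefix_of[[prof$label]], si)
      out[[length(out) + 1L]] <- generate_subject(
        prof, config$strides_per_subject,
        seed = derive_seed(config$seed, ci, si),
        subject_id = sid
      )
    }
  }
  out
}

#' Write a subject series in the stride-table dialect
#'
#' Emits one row per record, 13 tab-separated fields at 6-decimal fixed
#' precision — the same dialect [read_subject_file()] parses, so a
#' write/read round trip reproduces the values at the printed precision.
#'
#' @param series A `subject_series`.
#' @param sink File path or connection.
#' @export
write_subject_file <- function(series, sink) {
  stopifnot(inherits(series, "subject_series"))
  if (nrow(series$records) == 0L) stop("refusing to write an empty series")
  m <- as.matrix(series$records)
  lines <- apply(m, 1L, function(r) paste(sprintf("%.6f", r), collapse = "\t"))
  writeLines(lines, sink)
  invisible(NULL)
}

#' Materialise a synthetic dataset directory
#'
#' Writes one `.ts` file per generated subject plus a `manifest.csv`
#' (`subject_id,label,path`) into `dir`.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return The manifest data frame, invisibly.
#' @export
write_dataset <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  series <- generate_dataset(config)
  rows <- lapply(series, function(s) {
    path <- file.path(dir, paste0(s$subject_id, ".ts"))
    write_subject_file(s, path)
    data.frame(subject_id = s$subject_id, label = s$label, path = path,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
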