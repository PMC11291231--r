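## Trial CSV dialect: columns time_s, ankle_angle_deg, ankle_moment_Nm and
## optional knee_angle_deg.  Degrees and plantarflexion-positive moments in
## files; radians internally.

#' Read a trial CSV
#'
#' Reads the documented trial dialect (`time_s`, `ankle_angle_deg`,
#' `ankle_moment_Nm`, optional `knee_angle_deg`; angles in degrees,
#' dorsiflexion positive; moment in N·m, plantarflexion positive) and
#' validates it.  If a sidecar JSON written by [write_trial()] exists, event
#' times and metadata are restored from it.
#'
#' @param path CSV file path.
#' @param exercise Exercise label to attach when no sidecar is present.
#' @param dialect `"period"` for plain CSV, `"comma"` for semicolon-separated
#'   files with decimal commas.
#' @return A [ts_trial()].
#' @export
read_trial <- function(path, exercise = "heel_drop",
                       dialect = c("period", "comma")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("trial file not found: ", path)
  df <- if (dialect == "comma") utils::read.csv2(path) else utils::read.csv(path)
  need <- c("time_s", "ankle_angle_deg", "ankle_moment_Nm")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("trial file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  for (cn in intersect(c(need, "knee_angle_deg"), names(df))) {
    if (!is.numeric(df[[cn]]))
      stop("column ", cn, " is not numeric")
    bad <- which(!is.finite(df[[cn]]))
    if (length(bad))
      stop("column ", cn, " has non-finite value at row ", bad[1])
  }
  bad_t <- which(diff(df$time_s) <= 0)
  if (length(bad_t))
    stop("column time_s is not strictly increasing at row ", bad_t[1] + 1L)
  knee <- if ("knee_angle_deg" %in% names(df)) df$knee_angle_deg * pi / 180 else 0

  events <- NULL; meta <- list()
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  if (file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(sc$exercise)) exercise <- sc$exercise
    if (!is.null(sc$events)) events <- as.numeric(sc$events)
    if (!is.null(sc$meta)) meta <- sc$meta
  }
  ts_trial(df$time_s, df$ankle_angle_deg * pi / 180, df$ankle_moment_Nm,
           knee, exercise = exercise, events = events, meta = meta)
}

#' Write a trial CSV (plus sidecar JSON)
#'
#' Writes the trial dialect documented in [read_trial()] at full double
#' precision, plus a sidecar JSON (same basename, `.json`) carrying the
#' exercise label, event times and generator metadata.
#'
#' @param trial A [ts_trial()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "ts_trial"))
  fmt <- function(x) sprintf("%.17g", x)
  df <- data.frame(time_s = fmt(trial$time_s),
                   ankle_angle_deg = fmt(trial$theta_rad * 180 / pi),
                   ankle_moment_Nm = fmt(trial$moment_Nm),
                   knee_angle_deg = fmt(trial$knee_rad * 180 / pi))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(
    list(exercise = attr(trial, "exercise"),
         events = attr(trial, "events"),
         meta = attr(trial, "meta")),
    sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Deterministic configuration hash
#'
#' MD5 hash of a canonical YAML serialization of a configuration list, used
#' to stamp outputs for provenance.
#'
#' @param x A list (or any YAML-serializable object).
#' @return Character MD5 hash.
#' @export
config_hash <- function(x) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  sort_rec <- function(v) {
    if (is.list(v) && !is.null(names(v)) && length(v))
      lapply(v[order(names(v))], sort_rec)
    else v
  }
  yaml::write_yaml(sort_rec(x), tf)
  unname(tools::md5sum(tf))
}

#' Write the sharing and difference tables
#'
#' Writes a [grid_run()] result as CSV tables (contributions and
#' percentage-point differences, rounded to 2 decimals as reported) and a
#' JSON summary with the maximal twist- and compliance-induced changes,
#' stamped with the seed and configuration hash.
#'
#' @param table A `sharing_table`.
#' @param dir Output directory (created if needed).
#' @return Invisible character vector of the files written.
#' @export
write_sharing_table <- function(table, dir) {
  stopifnot(inherits(table, "sharing_table"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  round2 <- function(df) {
    for (cn in c("SOL", "GM", "GL")) df[[cn]] <- round(df[[cn]], 2)
    df
  }
  f1 <- file.path(dir, "sharing.csv")
  f2 <- file.path(dir, "differences.csv")
  f3 <- file.path(dir, "summary.json")
  utils::write.csv(round2(table$sharing), f1, row.names = FALSE)
  utils::write.csv(round2(table$diffs), f2, row.names = FALSE)
  jsonlite::write_json(
    list(max_abs_change_twist_pp = table$stats$max_abs_change_twist,
         max_abs_change_compliance_pp = table$stats$max_abs_change_compliance,
         generic_k = table$generic_k, seed = table$seed,
         config_hash = config_hash(list(seed = table$seed,
                                        table = table$sharing))),
    f3, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(f1, f2, f3))
}
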