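#' Construct a dynamic perfusion study
#'
#' A dynamic study bundles the frame schedule with the frame-averaged
#' time-activity curves (TACs) of the left-ventricular blood pool, the 17
#' myocardial segments, and optionally an extracardiac (hepatic/intestinal)
#' region, for one acquisition condition (rest or stress).
#'
#' @param condition `"rest"` or `"stress"`.
#' @param schedule Frame-schedule tibble (see [frame_schedule()]).
#' @param tacs Tibble with one row per frame and numeric columns `blood`,
#'   `seg01`..`seg17`, and optionally `extracardiac`. Activity is in
#'   arbitrary concentration units; both kinetic models only use blood /
#'   myocardium ratios, so no absolute calibration is assumed.
#' @param patient_id Optional label.
#' @param truth Optional tibble of per-segment ground-truth kinetics
#'   (`segment`, `mbf`, `k1`, `k2`, `f_v`, `scar`) carried by synthetic data.
#' @param blood_fine Optional tibble (`time_s`, `value`) with the
#'   finely sampled blood input curve from which a synthetic study was
#'   generated; used by the compartment fit when available.
#' @param extracardiac_fine Optional tibble (`time_s`, `value`) with the fine
#'   extracardiac curve.
#' @return An object of class `dynamic_study`.
#' @export
dynamic_study <- function(condition, schedule, tacs, patient_id = NULL,
                          truth = NULL, blood_fine = NULL,
                          extracardiac_fine = NULL) {
  condition <- match.arg(condition, c("rest", "stress"))
  validate_schedule(schedule)
  seg_cols <- sprintf("seg%02d", 1:17)
  need <- c("blood", seg_cols)
  missing_cols <- setdiff(need, names(tacs))
  if (length(missing_cols) > 0)
    abort_input("`tacs` is missing column(s): %s", paste(missing_cols, collapse = ", "))
  if (nrow(tacs) != nrow(schedule))
    abort_input("`tacs` has %d rows but the schedule has %d frames",
                nrow(tacs), nrow(schedule))
  keep <- intersect(c("blood", seg_cols, "extracardiac"), names(tacs))
  tacs <- tibble::as_tibble(tacs)[keep]
  for (cl in keep) {
    v <- tacs[[cl]]
    if (!is.numeric(v) || any(!is.finite(v)))
      abort_input("TAC column `%s` must be finite numeric", cl)
  }
  structure(
    list(condition = condition, schedule = schedule, tacs = tacs,
         patient_id = patient_id, truth = truth, blood_fine = blood_fine,
         extracardiac_fine = extracardiac_fine),
    class = "dynamic_study")
}

#' @export
print.dynamic_study <- function(x, ...) {
  cat(sprintf("<dynamic_study> %s%s: %d frames over %g s, %d regions%s\n",
              x$condition,
              if (!is.null(x$patient_id)) paste0(" [", x$patient_id, "]") else "",
              nrow(x$schedule), max(x$schedule$t_end_s), ncol(x$tacs),
              if (!is.null(x$truth)) ", with ground truth" else ""))
  invisible(x)
}

#' Pair a rest and a stress study of one patient
#'
#' @param rest,stress `dynamic_study` objects with matching schedules.
#' @param patient_id Label for the pair.
#' @return An object of class `study_pair`.
#' @export
study_pair <- function(rest, stress, patient_id = rest$patient_id %||% "patient") {
  stopifnot(inherits(rest, "dynamic_study"), inherits(stress, "dynamic_study"))
  if (rest$condition != "rest" || stress$condition != "stress")
    abort_input("`rest` and `stress` must have matching condition tags")
  if (!isTRUE(all.equal(rest$schedule, stress$schedule)))
    abort_input("rest and stress schedules must be identical")
  structure(list(rest = rest, stress = stress, patient_id = patient_id),
            class = "study_pair")
}

#' @export
print.study_pair <- function(x, ...) {
  cat(sprintf("<study_pair> %s: rest + stress, %d frames\n",
              x$patient_id, nrow(x$rest$schedule)))
  invisible(x)
}

#' Long (tidy) view of a study's time-activity curves
#'
#' @param study A `dynamic_study`.
#' @return Tibble with columns `frame`, `t_mid_s`, `duration_s`, `region`,
#'   `value`.
#' @export
tac_long <- function(study) {
  stopifnot(inherits(study, "dynamic_study"))
  dplyr::bind_cols(study$schedule[c("frame", "t_mid_s", "duration_s")], study$tacs) |>
    tidyr::pivot_longer(-c("frame", "t_mid_s", "duration_s"),
                        names_to = "region", values_to = "value")
}

#' Write a dynamic study to CSV
#'
#' The dialect is fixed (decimal point, comma separator, UTF-8): `#`-prefixed
#' metadata lines (`condition`, `patient_id`), then a header
#' `frame,t_start_s,duration_s,blood,seg01,...,seg17[,extracardiac]` and one
#' row per frame in time order. Values are written with 12 significant
#' digits so a write/read round trip is exact to well below 1e-9.
#'
#' @param study A `dynamic_study`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tac_csv <- function(study, path) {
  stopifnot(inherits(study, "dynamic_study"))
  df <- dplyr::bind_cols(study$schedule[c("frame", "t_start_s", "duration_s")],
                         study$tacs)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# condition: %s", study$condition), con)
  if (!is.null(study$patient_id))
    writeLines(sprintf("# patient_id: %s", study$patient_id), con)
  writeLines(paste(names(df), collapse = ","), con)
  num <- vapply(df, function(col) formatC(col, digits = 12, format = "g"),
                character(nrow(df)))
  writeLines(apply(num, 1, paste, collapse = ","), con)
  invisible(path)
}

#' Read a dynamic study from CSV
#'
#' Inverse of [write_tac_csv()]. The frame schedule is reconstructed from the
#' `t_start_s`/`duration_s` columns; if `schedule` is supplied the file must
#' match it frame for frame.
#'
#' @param path CSV file written in the [write_tac_csv()] dialect.
#' @param schedule Optional frame schedule to check the file against.
#' @return A `dynamic_study`.
#' @export
read_tac_csv <- function(path, schedule = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (m in meta_lines) {
    kv <- regmatches(m, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", m))[[1]]
    if (length(kv) == 3) meta[[kv[2]]] <- trimws(kv[3])
  }
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = body, stringsAsFactors = FALSE)
  for (cl in setdiff(names(df), "frame")) {
    if (!is.numeric(df[[cl]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cl]]))))[1]
      abort_input("non-numeric value in column `%s`, data row %d", cl,
                  if (is.na(bad)) 1L else bad)
    }
  }
  if (!"blood" %in% names(df))
    abort_input("CSV is missing the required `blood` column")
  need <- c("frame", "t_start_s", "duration_s")
  if (!all(need %in% names(df)))
    abort_input("CSV is missing schedule column(s): %s",
                paste(setdiff(need, names(df)), collapse = ", "))
  sched <- frame_schedule(df$duration_s, t0_s = df$t_start_s[1])
  if (max(abs(sched$t_start_s - df$t_start_s)) > 1e-6)
    abort_input("t_start_s column is not contiguous with duration_s")
  if (!is.null(schedule)) {
    validate_schedule(schedule)
    if (nrow(schedule) != nrow(df))
      abort_input("CSV has %d frames but the schedule expects %d",
                  nrow(df), nrow(schedule))
    if (max(abs(schedule$t_start_s - df$t_start_s)) > 1e-6 ||
        max(abs(schedule$duration_s - df$duration_s)) > 1e-6)
      abort_input("CSV frame timing does not match the supplied schedule")
  }
  cond <- meta[["condition"]] %||% "rest"
  dynamic_study(cond, sched, df[setdiff(names(df), need)],
                patient_id = meta[["patient_id"]])
}
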