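# Tabular serialization of patient records.
#
# CSV dialect: one row per patient. Flat columns `patient_id, rf, acpa, esr,
# crp, ana, mmp3, wbc, gender, skin_abnormality, body_temperature,
# trunk_pain, onset_days, patient_vas, doctor_vas, label`, plus 150 joint
# columns `J_{side}_{site}_{a|b|c|d|e}` (e.g. `J_right_MCP2_d`). Flags are
# 0/1; gender is male/female; label is RA/nonRA or empty. UTF-8, header
# required, column order-independent on read. The JSON mirror nests the
# joint findings under a `joints` object keyed by side then site.

record_csv_columns <- function() {
  scalar <- c("patient_id", "rf", "acpa", "esr", "crp", "ana", "mmp3", "wbc",
              "gender", "skin_abnormality", "body_temperature", "trunk_pain",
              "onset_days", "patient_vas", "doctor_vas", "label")
  jcols <- as.vector(t(outer(tda_joint_keys(), names(tda_channels()),
                             paste, sep = "_")))
  c(scalar, paste0("J_", jcols))
}

record_to_row <- function(record) {
  row <- list(patient_id = record$patient_id,
              rf = record$rf, acpa = record$acpa, esr = record$esr,
              crp = record$crp, ana = record$ana, mmp3 = record$mmp3,
              wbc = record$wbc, gender = record$gender,
              skin_abnormality = as.integer(record$skin_abnormality),
              body_temperature = record$body_temperature,
              trunk_pain = as.integer(record$trunk_pain),
              onset_days = record$onset_days,
              patient_vas = record$patient_vas,
              doctor_vas = record$doctor_vas,
              label = if (is.na(record$label)) "" else record$label)
  ch <- tda_channels()
  for (k in tda_joint_keys()) {
    j <- record$joints[[k]]
    for (letter in names(ch)) {
      val <- j[[ch[[letter]]]]
      if (is.logical(val)) val <- as.integer(val)
      row[[paste("J", k, letter, sep = "_")]] <- val
    }
  }
  row
}

row_to_record <- function(row) {
  ch <- tda_channels()
  joints <- list()
  for (k in tda_joint_keys()) {
    joints[[k]] <- joint_finding(
      symptom = row[[paste0("J_", k, "_a")]] != 0,
      tenderness = row[[paste0("J_", k, "_b")]] != 0,
      swelling = row[[paste0("J_", k, "_c")]] != 0,
      gs_score = row[[paste0("J_", k, "_d")]],
      pd_score = row[[paste0("J_", k, "_e")]])
  }
  lab <- row[["label"]]
  if (is.null(lab) || is.na(lab) || !nzchar(lab)) lab <- NA_character_
  patient_record(patient_id = row[["patient_id"]], label = lab,
                 gender = row[["gender"]],
                 body_temperature = row[["body_temperature"]],
                 onset_days = row[["onset_days"]],
                 trunk_pain = row[["trunk_pain"]] != 0,
                 skin_abnormality = row[["skin_abnormality"]] != 0,
                 patient_vas = row[["patient_vas"]],
                 doctor_vas = row[["doctor_vas"]],
                 rf = row[["rf"]], acpa = row[["acpa"]], esr = row[["esr"]],
                 crp = row[["crp"]], ana = row[["ana"]], mmp3 = row[["mmp3"]],
                 wbc = row[["wbc"]], joints = joints)
}

record_to_json_obj <- function(record) {
  obj <- record[setdiff(names(record), "joints")]
  obj$label <- if (is.na(record$label)) NULL else record$label
  joints <- list()
  for (side in tda_sides()) {
    joints[[side]] <- list()
    for (site in tda_sites()) {
      j <- record$joints[[paste(side, site, sep = "_")]]
      joints[[side]][[site]] <- list(a = j$symptom, b = j$tenderness,
                                     c = j$swelling, d = j$gs_score,
                                     e = j$pd_score)
    }
  }
  obj$joints <- joints
  obj
}

json_obj_to_record <- function(obj) {
  joints <- list()
  for (side in tda_sides()) {
    for (site in tda_sites()) {
      j <- obj$joints[[side]][[site]]
      if (is.null(j)) next
      joints[[paste(side, site, sep = "_")]] <-
        joint_finding(j$a, j$b, j$c, j$d, j$e)
    }
  }
  patient_record(patient_id = obj$patient_id,
                 label = if (is.null(obj$label)) NA_character_ else obj$label,
                 gender = obj$gender,
                 body_temperature = obj$body_temperature,
                 onset_days = obj$onset_days, trunk_pain = obj$trunk_pain,
                 skin_abnormality = obj$skin_abnormality,
                 patient_vas = obj$patient_vas, doctor_vas = obj$doctor_vas,
                 rf = obj$rf, acpa = obj$acpa, esr = obj$esr, crp = obj$crp,
                 ana = obj$ana, mmp3 = obj$mmp3, wbc = obj$wbc,
                 joints = joints)
}

#' Read patient records from a CSV or JSON file
#'
#' Reads the flat CSV dialect (columns `patient_id`, the 15 scalar clinical
#' fields, `label`, and `J_{side}_{site}_{a-e}` joint columns, any order) or
#' its JSON mirror (an array of objects with a nested `joints` object).
#' Every returned record passes [validate_record()]; rows that do not are
#' dropped with a warning naming the row and the first violation.
#'
#' @param path file to read.
#' @param format `"csv"`, `"json"`, or `"auto"` (by file extension).
#' @param allow_missing passed to [validate_record()].
#' @return List of [patient_record()] objects.
#' @export
read_records <- function(path, format = c("auto", "csv", "json"),
                         allow_missing = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "csv"
  }
  if (!file.exists(path)) stop("cannot read records: no such file: ", path)
  if (format == "json") {
    objs <- jsonlite::read_json(path, simplifyVector = FALSE)
    recs <- lapply(objs, json_obj_to_record)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(patient_id = "character"),
                          check.names = FALSE)
    unknown <- setdiff(names(df), record_csv_columns())
    if (length(unknown) > 0) {
      stop("unknown column(s) in ", path, ": ",
           paste(unknown, collapse = ", "))
    }
    missing_cols <- setdiff(record_csv_columns(), names(df))
    if (length(missing_cols) > 0) {
      stop("missing column(s) in ", path, ": ",
           paste(missing_cols, collapse = ", "))
    }
    recs <- lapply(seq_len(nrow(df)), function(i) row_to_record(df[i, ]))
  }
  keep <- vapply(recs, function(r) {
    v <- validate_record(r, allow_missing = allow_missing)
    if (length(v) > 0) {
      warning(sprintf("dropping record '%s': %s", r$patient_id, v[1]),
              call. = FALSE)
      FALSE
    } else TRUE
  }, logical(1))
  recs[keep]
}

#' Write patient records to a CSV or JSON file
#'
#' The inverse of [read_records()]: deterministic column order, so a
#' write-read-write cycle is byte-identical.
#'
#' @param records list of [patient_record()] objects.
#' @param path destination file.
#' @param format `"csv"`, `"json"`, or `"auto"` (by file extension).
#' @return Invisibly, the number of records written.
#' @export
write_records <- function(records, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "csv"
  }
  if (format == "json") {
    objs <- lapply(records, record_to_json_obj)
    jsonlite::write_json(objs, path, auto_unbox = TRUE, digits = NA,
                         pretty = FALSE)
  } else {
    cols <- record_csv_columns()
    if (length(records) == 0) {
      df <- as.data.frame(stats::setNames(rep(list(character(0)),
                                              length(cols)), cols))
    } else {
      rows <- lapply(records, function(r) {
        as.data.frame(record_to_row(r), check.names = FALSE)
      })
      df <- do.call(rbind, rows)[, cols]
    }
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(length(records))
}
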