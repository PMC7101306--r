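#' Joint sites encoded on each hand
#'
#' The 15 finger and wrist joint sites recorded per side: the wrist, the five
#' metacarpophalangeal joints (MCP1-5), the 2nd-5th proximal interphalangeal
#' joints (PIP2-5), the thumb interphalangeal joint (IP) and the 2nd-5th
#' distal interphalangeal joints (DIP2-5). The thumb has MCP1 and IP only
#' (no PIP1/DIP1).
#'
#' @return Character vector of the 15 site names, in canonical order.
#' @export
tda_sites <- function() {
  c("wrist", paste0("MCP", 1:5), paste0("PIP", 2:5), "IP", paste0("DIP", 2:5))
}

#' @rdname tda_sites
#' @return `tda_sides()`: the two sides, `"left"` and `"right"`.
#' @export
tda_sides <- function() c("left", "right")

#' @rdname tda_sites
#' @return `tda_joint_keys()`: the 30 canonical `side_site` joint keys.
#' @export
tda_joint_keys <- function() {
  as.vector(t(outer(tda_sides(), tda_sites(), paste, sep = "_")))
}

# channel letters used in the cruciform block and their record field names
tda_channels <- function() {
  c(a = "symptom", b = "tenderness", c = "swelling",
    d = "gs_score", e = "pd_score")
}

# the 14 clinical square fields, in the order of the numbered squares 1-14
tda_clinical_fields <- function() {
  c("rf", "acpa", "esr", "onset_days", "crp", "ana", "mmp3", "wbc",
    "gender", "skin_abnormality", "body_temperature", "trunk_pain",
    "patient_vas", "doctor_vas")
}

#' One joint's findings (the five cruciform channels)
#'
#' @param symptom logical; patient-reported pain/stiffness at the joint
#'   (channel a).
#' @param tenderness logical; tenderness on examination (channel b).
#' @param swelling logical; swelling on examination (channel c).
#' @param gs_score integer 0-3; OMERACT grayscale ultrasound synovitis score
#'   (channel d).
#' @param pd_score integer 0-3; OMERACT power Doppler score (channel e).
#' @return A list of class `tda_joint`.
#' @export
joint_finding <- function(symptom = FALSE, tenderness = FALSE,
                          swelling = FALSE, gs_score = 0L, pd_score = 0L) {
  structure(list(symptom = isTRUE(as.logical(symptom)),
                 tenderness = isTRUE(as.logical(tenderness)),
                 swelling = isTRUE(as.logical(swelling)),
                 gs_score = as.integer(gs_score),
                 pd_score = as.integer(pd_score)),
            class = "tda_joint")
}

#' A patient's full clinical record
#'
#' Bundles the demographics, seven laboratory values, symptom/examination
#' flags, the two 0-100 visual analog scale (VAS) scores and the 30 joint
#' findings (15 sites x 2 sides) that the image encoder consumes, plus an
#' optional RA/nonRA diagnosis label.
#'
#' @param patient_id opaque identifier (coerced to character).
#' @param label `"RA"`, `"nonRA"`, or `NA` for unlabelled records.
#' @param gender `"male"` or `"female"`.
#' @param body_temperature degrees Celsius.
#' @param onset_days days from symptom onset to the visit (nonnegative).
#' @param trunk_pain,skin_abnormality logical flags.
#' @param patient_vas,doctor_vas VAS scores in \[0, 100\].
#' @param rf rheumatoid factor, IU/mL.
#' @param acpa anti-citrullinated protein/peptide antibody, U/mL.
#' @param esr erythrocyte sedimentation rate, mm/hour.
#' @param crp C-reactive protein, mg/dL.
#' @param ana anti-nuclear antibody reciprocal titre (0, 40, 80, 160, ...).
#' @param mmp3 matrix metalloproteinase-3, ng/mL.
#' @param wbc white blood cell count, cells/uL.
#' @param joints named list of [joint_finding()] objects keyed `side_site`
#'   (e.g. `"right_MCP2"`); missing entries are filled with all-negative
#'   findings.
#' @return A list of class `tda_patient`.
#' @seealso [validate_record()], [render_tda()]
#' @export
patient_record <- function(patient_id, label = NA_character_,
                           gender = "female", body_temperature = 36.5,
                           onset_days = 30, trunk_pain = FALSE,
                           skin_abnormality = FALSE, patient_vas = 0,
                           doctor_vas = 0, rf = 0, acpa = 0, esr = 5,
                           crp = 0.02, ana = 0, mmp3 = 30, wbc = 6000,
                           joints = list()) {
  keys <- tda_joint_keys()
  full <- stats::setNames(vector("list", length(keys)), keys)
  for (k in keys) {
    full[[k]] <- if (k %in% names(joints)) joints[[k]] else joint_finding()
  }
  extra <- setdiff(names(joints), keys)
  if (length(extra) > 0) {
    stop("unknown joint key(s): ", paste(extra, collapse = ", "))
  }
  structure(list(patient_id = as.character(patient_id),
                 label = as.character(label),
                 gender = as.character(gender),
                 body_temperature = as.numeric(body_temperature),
                 onset_days = as.numeric(onset_days),
                 trunk_pain = as.logical(trunk_pain),
                 skin_abnormality = as.logical(skin_abnormality),
                 patient_vas = as.numeric(patient_vas),
                 doctor_vas = as.numeric(doctor_vas),
                 rf = as.numeric(rf), acpa = as.numeric(acpa),
                 esr = as.numeric(esr), crp = as.numeric(crp),
                 ana = as.numeric(ana), mmp3 = as.numeric(mmp3),
                 wbc = as.numeric(wbc), joints = full),
            class = "tda_patient")
}

#' @export
print.tda_patient <- function(x, ...) {
  lab <- if (is.na(x$label)) "unlabelled" else x$label
  inv <- sum(vapply(x$joints, function(j) {
    j$symptom || j$tenderness || j$swelling || j$gs_score > 0 || j$pd_score > 0
  }, logical(1)))
  cat(sprintf("<tda_patient %s> %s, %s; %d/30 joints with findings\n",
              x$patient_id, lab, x$gender, inv))
  invisible(x)
}

#' Validate a patient record against the schema invariants
#'
#' Checks every type invariant: gender and label domains, nonnegative
#' laboratory values, VAS scores within \[0, 100\], ultrasound scores in
#' 0-3, and the presence of exactly the 30 canonical joint entries.
#' Validation reports; it never raises on a structurally complete input.
#'
#' @param record a [patient_record()].
#' @param allow_missing if `TRUE`, `NA` field values are tolerated (they are
#'   rendered with the "missing" palette colour downstream); by default a
#'   missing value is a violation.
#' @return Character vector of violation descriptions; empty when the record
#'   satisfies every invariant.
#' @export
validate_record <- function(record, allow_missing = FALSE) {
  v <- character(0)
  bad <- function(msg) v <<- c(v, msg)
  num_ok <- function(x) length(x) == 1 && is.numeric(x) &&
    (!is.na(x) || allow_missing)

  if (!inherits(record, "tda_patient")) {
    return("not a tda_patient record")
  }
  if (!is.na(record$label) && !record$label %in% c("RA", "nonRA")) {
    bad(sprintf("label: '%s' is not RA/nonRA/NA", record$label))
  }
  if (is.na(record$gender) || !record$gender %in% c("male", "female")) {
    bad("gender: must be 'male' or 'female'")
  }
  for (f in c("rf", "acpa", "esr", "crp", "ana", "mmp3", "wbc",
              "onset_days")) {
    x <- record[[f]]
    if (!num_ok(x)) bad(sprintf("%s: missing or non-numeric", f))
    else if (!is.na(x) && x < 0) bad(sprintf("%s: negative value %g", f, x))
  }
  if (!num_ok(record$body_temperature)) {
    bad("body_temperature: missing or non-numeric")
  }
  for (f in c("patient_vas", "doctor_vas")) {
    x <- record[[f]]
    if (!num_ok(x)) bad(sprintf("%s: missing or non-numeric", f))
    else if (!is.na(x) && (x < 0 || x > 100)) {
      bad(sprintf("%s: %g outside [0, 100]", f, x))
    }
  }
  for (f in c("trunk_pain", "skin_abnormality")) {
    x <- record[[f]]
    if (length(x) != 1 || !is.logical(x) || (is.na(x) && !allow_missing)) {
      bad(sprintf("%s: must be a single logical", f))
    }
  }
  keys <- tda_joint_keys()
  miss <- setdiff(keys, names(record$joints))
  for (k in miss) bad(sprintf("missing joint: %s", k))
  extra <- setdiff(names(record$joints), keys)
  for (k in extra) bad(sprintf("unknown joint: %s", k))
  for (k in intersect(keys, names(record$joints))) {
    j <- record$joints[[k]]
    for (ch in c("symptom", "tenderness", "swelling")) {
      x <- j[[ch]]
      if (length(x) != 1 || !is.logical(x) || (is.na(x) && !allow_missing)) {
        bad(sprintf("joint %s %s: must be a single logical", k, ch))
      }
    }
    for (ch in c("gs_score", "pd_score")) {
      x <- j[[ch]]
      if (length(x) != 1 || (is.na(x) && !allow_missing)) {
        bad(sprintf("joint %s %s: missing", k, ch))
      } else if (!is.na(x) && !x %in% 0:3) {
        bad(sprintf("joint %s %s: %s not in 0-3", k, ch, format(x)))
      }
    }
  }
  v
}
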