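# Semi-quantitative colouring rules.
#
# Each clinical field and cruciform channel maps to an ordered colour
# category. Numeric rules are bands over the value axis; the convention
# throughout is that a value equal to a cutoff takes the severer colour
# (v >= cutoff), except where a rule is printed with an open boundary
# (MMP-3: yellow up to 120 inclusive, red above). Severity is ordered
# green < yellow < orange < red; orange is reachable only from the two
# ultrasound score channels.

#' Colour category severity order
#'
#' @return Character vector `green, yellow, orange, red` in increasing
#'   severity.
#' @export
tda_categories <- function() c("green", "yellow", "orange", "red")

category_severity <- function(cat) {
  match(cat, tda_categories())
}

interval_rule <- function(breaks, categories, left_open = FALSE) {
  stopifnot(length(categories) == length(breaks) + 1)
  list(type = "interval", breaks = breaks, categories = categories,
       left_open = left_open)
}

categorical_rule <- function(map) {
  list(type = "categorical", map = map)
}

#' Default discretization rule set
#'
#' The shipped rules reproduce the published cutoffs verbatim: RF
#' green < 15, 15-30 yellow, >= 30 red; ACPA green < 4.5, >= 4.5 red; ESR
#' green < 10, 10-20 yellow, >= 20 red; symptom onset yellow < 42 days,
#' >= 42 red; CRP yellow < 0.3, >= 0.3 red; ANA titre 0 green, 40/80
#' yellow, >= 160 red; MMP-3 yellow <= 120, > 120 red; WBC green < 4000,
#' 4000-8000 yellow, >= 8000 red; male yellow / female red; skin
#' abnormality and trunk pain negative green / positive yellow; body
#' temperature green < 37.5, 37.5-38 yellow, >= 38 red; both VAS green
#' < 10, 10-50 yellow, >= 50 red. Cruciform channels: symptom, tenderness
#' and swelling negative green / positive red; ultrasound grayscale and
#' power Doppler scores 0 green, 1 yellow, 2 orange, 3 red.
#'
#' ANA titres other than the printed anchors interpolate: green below 40,
#' yellow in \[40, 160), red at or above 160.
#'
#' @return A named list of per-field rules with class `tda_rules` and a
#'   `version` attribute.
#' @seealso [discretize_field()], [read_rules()]
#' @export
default_rules <- function() {
  flag_red <- categorical_rule(c(negative = "green", positive = "red"))
  flag_yellow <- categorical_rule(c(negative = "green", positive = "yellow"))
  gyr <- function(b1, b2) interval_rule(c(b1, b2),
                                        c("green", "yellow", "red"))
  rules <- list(
    rf = gyr(15, 30),
    acpa = interval_rule(4.5, c("green", "red")),
    esr = gyr(10, 20),
    onset_days = interval_rule(42, c("yellow", "red")),
    crp = interval_rule(0.3, c("yellow", "red")),
    ana = gyr(40, 160),
    mmp3 = interval_rule(120, c("yellow", "red"), left_open = TRUE),
    wbc = gyr(4000, 8000),
    gender = categorical_rule(c(male = "yellow", female = "red")),
    skin_abnormality = flag_yellow,
    body_temperature = gyr(37.5, 38),
    trunk_pain = flag_yellow,
    patient_vas = gyr(10, 50),
    doctor_vas = gyr(10, 50),
    symptom = flag_red,
    tenderness = flag_red,
    swelling = flag_red,
    gs_score = categorical_rule(c(`0` = "green", `1` = "yellow",
                                  `2` = "orange", `3` = "red")),
    pd_score = categorical_rule(c(`0` = "green", `1` = "yellow",
                                  `2` = "orange", `3` = "red"))
  )
  structure(rules, class = "tda_rules", version = "table2-default-1")
}

# map a layout block field id (e.g. "J_left_wrist_d" or "crp") to the rule
# name that discretizes it
rule_name_for_field <- function(field) {
  if (startsWith(field, "J_")) {
    letter <- sub(".*_", "", field)
    ch <- tda_channels()
    if (!letter %in% names(ch)) stop("unknown joint channel: ", field)
    unname(ch[letter])
  } else {
    field
  }
}

#' Discretize one field value to its colour category
#'
#' Applies the rule for `field` to `value`. Numeric bands use
#' v >= cutoff takes-the-severer-colour semantics (MMP-3's open boundary
#' excepted); flags map negative/positive; gender maps male/female;
#' ultrasound scores map 0-3 directly.
#'
#' @param field a clinical field name (e.g. `"rf"`), a cruciform channel
#'   name (`"symptom"`, ..., `"pd_score"`), or a layout block id
#'   (`"J_left_wrist_d"`).
#' @param value the raw value; `NA` returns `"missing"`.
#' @param rules a rule set from [default_rules()] or [read_rules()].
#' @return A single category string.
#' @export
discretize_field <- function(field, value, rules = default_rules()) {
  rname <- rule_name_for_field(field)
  rule <- rules[[rname]]
  if (is.null(rule)) stop("unknown field: ", field)
  if (length(value) != 1) stop(field, ": value must be length 1")
  if (is.na(value)) return("missing")
  if (rule$type == "interval") {
    if (!is.numeric(value)) stop(field, ": expected a numeric value")
    idx <- findInterval(value, rule$breaks, left.open = rule$left_open) + 1
    return(rule$categories[idx])
  }
  key <- if (is.logical(value) || (is.numeric(value) &&
                                   all(names(rule$map) %in%
                                       c("negative", "positive")))) {
    if (as.logical(value)) "positive" else "negative"
  } else {
    as.character(value)
  }
  out <- rule$map[key]
  if (is.na(out)) {
    stop(sprintf("%s: value '%s' outside rule domain", field, format(value)))
  }
  unname(out)
}

#' Discretize every encoded field of a record
#'
#' @param record a validated [patient_record()].
#' @param rules a rule set.
#' @return Named character vector of categories over all 164 block fields:
#'   the 14 clinical squares plus 5 channels for each of the 30 joints
#'   (names `J_{side}_{site}_{a-e}`).
#' @export
discretize_record <- function(record, rules = default_rules()) {
  out <- character(0)
  for (f in tda_clinical_fields()) {
    out[f] <- discretize_field(f, record[[f]], rules)
  }
  ch <- tda_channels()
  for (k in tda_joint_keys()) {
    j <- record$joints[[k]]
    for (letter in names(ch)) {
      out[paste("J", k, letter, sep = "_")] <-
        discretize_field(ch[[letter]], j[[ch[[letter]]]], rules)
    }
  }
  out
}

#' Read or write a rule set as a versioned YAML file
#'
#' @param path YAML file.
#' @return `read_rules()`: a `tda_rules` object; `write_rules()`: the path,
#'   invisibly.
#' @export
read_rules <- function(path) {
  y <- yaml::read_yaml(path)
  rules <- lapply(y$rules, function(r) {
    if (r$type == "interval") {
      interval_rule(as.numeric(r$breaks), as.character(r$categories),
                    isTRUE(r$left_open))
    } else {
      categorical_rule(unlist(r$map))
    }
  })
  structure(rules, class = "tda_rules",
            version = as.character(y$version))
}

#' @rdname read_rules
#' @param rules a `tda_rules` object.
#' @export
write_rules <- function(rules, path) {
  y <- list(version = attr(rules, "version"),
            rules = lapply(unclass(rules), function(r) {
              if (r$type == "interval") {
                list(type = "interval", breaks = r$breaks,
                     categories = r$categories, left_open = r$left_open)
              } else {
                list(type = "categorical", map = as.list(r$map))
              }
            }))
  yaml::write_yaml(y, path)
  invisible(path)
}
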