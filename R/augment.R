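# Diagnosis-preserving data augmentation.
#
# The original study expanded each RA record 1->6 and each nonRA record
# 1->5 by manual, rheumatologist-made modifications that "could not affect
# the original diagnosis". Those edits are unknowable, so this module
# substitutes an explicit stochastic proxy with a hard guard: every
# continuous field is jittered, but a clone may change the colour category
# of at most `max_changed` fields, each by at most `max_drift` levels of
# that field's own ordered category scale, and the categories of protected
# fields (default: ACPA and RF, the diagnosis-critical serology) never
# change. The patient's identity fields (id, label, gender) are never
# touched. "Does not affect the diagnosis" is thus operationalized as a
# category-drift bound, not a clinical re-adjudication.

#' Augmentation policy
#'
#' @param multiplier_ra,multiplier_nonra how many records each original
#'   yields, the original included (published expansion: 6 and 5).
#' @param jitter relative jitter scale for continuous laboratory fields
#'   (log-normal multiplicative noise with this standard deviation).
#' @param vas_sd additive jitter (VAS points) for the two VAS scores.
#' @param temp_sd additive jitter (degrees C) for body temperature.
#' @param flag_flip_prob probability of flipping each non-protected
#'   clinical flag.
#' @param joint_toggle_prob per-joint probability of modifying one channel
#'   (toggle a flag or move an ultrasound score by one).
#' @param max_drift maximum category drift per field, in levels of the
#'   field's own ordered category list.
#' @param max_changed maximum number of fields allowed to change category
#'   in one clone.
#' @param protected fields whose category may never change.
#' @return A list of class `tda_policy`.
#' @export
augmentation_policy <- function(multiplier_ra = 6, multiplier_nonra = 5,
                                jitter = 0.1, vas_sd = 4, temp_sd = 0.1,
                                flag_flip_prob = 0.05,
                                joint_toggle_prob = 0.05,
                                max_drift = 1, max_changed = 4,
                                protected = c("acpa", "rf")) {
  stopifnot(multiplier_ra >= 1, multiplier_nonra >= 1, max_drift >= 0,
            max_changed >= 0, jitter >= 0)
  structure(list(multiplier_ra = multiplier_ra,
                 multiplier_nonra = multiplier_nonra, jitter = jitter,
                 vas_sd = vas_sd, temp_sd = temp_sd,
                 flag_flip_prob = flag_flip_prob,
                 joint_toggle_prob = joint_toggle_prob,
                 max_drift = max_drift, max_changed = max_changed,
                 protected = protected),
            class = "tda_policy")
}

#' The identity augmentation policy
#'
#' Zero jitter, zero drift: clones are category-identical to the original.
#' @return A `tda_policy`.
#' @export
identity_policy <- function() {
  augmentation_policy(jitter = 0, vas_sd = 0, temp_sd = 0,
                      flag_flip_prob = 0, joint_toggle_prob = 0,
                      max_drift = 0, max_changed = 0)
}

# category position within a field's own rule ordering (for drift)
category_level <- function(field, cat, rules) {
  rule <- rules[[rule_name_for_field(field)]]
  cats <- if (rule$type == "interval") rule$categories
          else unique(unname(rule$map))
  match(cat, cats)
}

#' Perturb one record under a policy
#'
#' Proposes jittered/toggled values field by field, then enforces the
#' policy: protected fields and fields whose category would drift more
#' than allowed revert to their original value, and if more than
#' `max_changed` fields still changed category, randomly chosen excess
#' fields revert too. The result always passes [validate_record()] with the
#' original label. Uses the current RNG state; seed upstream.
#'
#' @param record a validated, labelled [patient_record()].
#' @param policy a [augmentation_policy()].
#' @param rules discretization rules used for the category guard.
#' @return A perturbed copy of `record`.
#' @export
perturb_record <- function(record, policy = augmentation_policy(),
                           rules = default_rules()) {
  orig_cats <- discretize_record(record, rules)
  out <- record

  mult_jitter <- function(v) {
    if (policy$jitter <= 0) v else v * exp(stats::rnorm(1, 0, policy$jitter))
  }
  for (f in c("rf", "acpa", "esr", "crp", "mmp3", "wbc", "onset_days")) {
    out[[f]] <- mult_jitter(out[[f]])
  }
  if (policy$jitter > 0) {
    out$wbc <- round(out$wbc)
    out$onset_days <- round(out$onset_days)
  }
  if (policy$temp_sd > 0) {
    out$body_temperature <-
      round(out$body_temperature + stats::rnorm(1, 0, policy$temp_sd), 1)
  }
  if (policy$vas_sd > 0) {
    for (f in c("patient_vas", "doctor_vas")) {
      out[[f]] <- min(max(round(out[[f]] + stats::rnorm(1, 0, policy$vas_sd)),
                          0), 100)
    }
  }
  if (policy$flag_flip_prob > 0) {
    for (f in c("skin_abnormality", "trunk_pain")) {
      if (stats::runif(1) < policy$flag_flip_prob) out[[f]] <- !out[[f]]
    }
    # ANA moves one titre step
    if (stats::runif(1) < policy$flag_flip_prob) {
      out$ana <- if (out$ana == 0) 40
                 else if (stats::runif(1) < 0.5) out$ana * 2
                 else if (out$ana == 40) 0 else out$ana / 2
    }
  }
  if (policy$joint_toggle_prob > 0) {
    for (k in tda_joint_keys()) {
      if (stats::runif(1) >= policy$joint_toggle_prob) next
      j <- out$joints[[k]]
      ch <- sample(c("symptom", "tenderness", "swelling", "gs_score",
                     "pd_score"), 1)
      if (ch %in% c("gs_score", "pd_score")) {
        step <- if (j[[ch]] == 0) 1L else if (j[[ch]] == 3) -1L
                else sample(c(-1L, 1L), 1)
        j[[ch]] <- j[[ch]] + step
      } else {
        j[[ch]] <- !j[[ch]]
      }
      out$joints[[k]] <- j
    }
  }

  # guard: revert protected / over-drifted fields, then cap the count
  new_cats <- discretize_record(out, rules)
  changed <- names(orig_cats)[new_cats != orig_cats]
  revert_field <- function(f) {
    if (startsWith(f, "J_")) {
      key <- sub("^J_", "", sub("_[a-e]$", "", f))
      ch <- tda_channels()[[sub(".*_", "", f)]]
      out$joints[[key]][[ch]] <<- record$joints[[key]][[ch]]
    } else {
      out[[f]] <<- record[[f]]
    }
  }
  for (f in changed) {
    protected <- rule_name_for_field(f) %in% policy$protected ||
      f %in% policy$protected
    drift <- abs(category_level(f, new_cats[[f]], rules) -
                 category_level(f, orig_cats[[f]], rules))
    if (protected || drift > policy$max_drift) revert_field(f)
  }
  new_cats <- discretize_record(out, rules)
  changed <- names(orig_cats)[new_cats != orig_cats]
  if (length(changed) > policy$max_changed) {
    keep <- sample(changed, policy$max_changed)
    for (f in setdiff(changed, keep)) revert_field(f)
  }
  out
}

#' Expand a labelled dataset by diagnosis-preserving clones
#'
#' Each RA original yields `multiplier_ra` records (itself plus clones) and
#' each nonRA original `multiplier_nonra`, reproducing the published 1->6 /
#' 1->5 expansion: 42 RA + 157 nonRA originals become 252 + 785 = 1037.
#' Originals are always retained, first in each group; output order is
#' deterministic given the seed.
#'
#' @param records list of validated, labelled records.
#' @param policy a [augmentation_policy()].
#' @param seed integer seed for the perturbations.
#' @param rules discretization rules for the category guard.
#' @return List of records (originals plus clones); clone ids get an
#'   `_augN` suffix.
#' @export
expand_dataset <- function(records, policy = augmentation_policy(),
                           seed = 1, rules = default_rules()) {
  labels <- vapply(records, function(r) r$label, character(1))
  if (anyNA(labels)) {
    stop("all records must be labelled before augmentation")
  }
  with_seed(seed, {
    out <- list()
    for (r in records) {
      mult <- if (r$label == "RA") policy$multiplier_ra
              else policy$multiplier_nonra
      out[[length(out) + 1L]] <- r
      for (i in seq_len(mult - 1)) {
        clone <- perturb_record(r, policy, rules)
        clone$patient_id <- paste0(r$patient_id, "_aug", i)
        out[[length(out) + 1L]] <- clone
      }
    }
    out
  })
}
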