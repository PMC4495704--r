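#' Published derivation-cohort screening counts
#'
#' Per-procedure admission-day utilisation counts in the derivation cohort of
#' the original severity-index study, split by in-hospital outcome
#' (244,416 surviving and 25,638 deceased admissions).  These are the 38
#' procedures whose overall prevalence reached 1 percent, as reported in the
#' study's screening table; they are bundled so that the screening stage can
#' be exercised against the published numbers without access to the source
#' (non-deposited) claims database.
#'
#' @return A data frame with columns `procedure`, `surviving_n` and
#'   `deceased_n`, carrying attributes `n_surviving` (244416) and
#'   `n_deceased` (25638) giving the outcome-group denominators.
#' @seealso [screen_counts()], [published_coefficients()]
#' @export
published_screen_counts <- function() {
  x <- data.frame(
    procedure = c(
      "blood_chemistry_tests", "hematology_tests",
      "plasma_protein_immunology_tests", "radiography", "electrocardiogram",
      "peripheral_iv_infusion", "coagulation_tests", "computed_tomography",
      "infectious_disease_immunology_tests", "hepatitis_virus_tests",
      "heart_rate_respiration_monitoring", "pulse_oximetry",
      "oxygen_administration", "urine_tests_general", "endocrinology_tests",
      "bacterial_culture", "urine_microscopy", "immunohematology_tests",
      "bacterial_microscopy", "urinary_catheter_insertion",
      "ultrasound_imaging", "magnetic_resonance_imaging",
      "acid_fast_bacilli_culture", "bacterial_drug_susceptibility_tests",
      "sputum_suction", "catecholamines_or_vasopressin",
      "red_blood_cell_transfusion", "nucleic_acid_amplification_tests",
      "tumor_markers", "invasive_arterial_pressure", "autoantibody_tests",
      "urine_chemistry_tests", "gastric_drainage_tube_insertion",
      "central_venous_catheter_insertion", "intratracheal_intubation",
      "stool_tests", "central_venous_infusion",
      "temporary_urinary_catheterization"),
    surviving_n = c(
      213046L, 210402L, 198064L, 190981L, 169490L, 159043L, 145418L, 123559L,
      123481L, 96552L, 91457L, 85254L, 74526L, 78225L, 69282L, 61069L, 52891L,
      53197L, 49180L, 43933L, 46118L, 45489L, 20879L, 17667L, 13061L, 12371L,
      12268L, 9102L, 8018L, 5649L, 5740L, 5130L, 3993L, 2997L, 2252L, 3377L,
      2467L, 2465L),
    deceased_n = c(
      22949L, 22704L, 21896L, 20922L, 17869L, 18581L, 15937L, 15938L, 12622L,
      9681L, 12770L, 13128L, 13961L, 9046L, 8222L, 8852L, 6211L, 5486L, 7127L,
      9534L, 4830L, 2615L, 2727L, 3267L, 5680L, 3143L, 1324L, 1178L, 667L,
      1130L, 488L, 654L, 1559L, 1346L, 1963L, 311L, 1163L, 352L),
    stringsAsFactors = FALSE)
  attr(x, "n_surviving") <- 244416L
  attr(x, "n_deceased") <- 25638L
  x
}

#' Published multivariable model coefficients and procedure points
#'
#' Transcription of the published derivation-cohort logistic regression:
#' log-odds coefficients for the admission-precipitating diagnosis, sex, age
#' band and Charlson comorbidity index (CCI) category, and for the 22
#' candidate procedure variables, together with the integer points assigned
#' to the 19 procedures whose coefficients reached P < 0.05.  Reported
#' P values of "<0.001" are stored as 0.0005.
#'
#' The published points were anchored to a reference coefficient of 0.091
#' (half the CCI = 2 coefficient of 0.182, because CCI = 1 was not
#' significantly associated with death).  Note one internal inconsistency of
#' the published table: the temporary-urinary-catheterization row prints a
#' coefficient of -0.18 but a point of -1, whereas -0.18/0.091 rounds to -2
#' (the urinalyses row, with the same printed coefficient, is assigned -2).
#' The printed coefficients are rounded too coarsely to reproduce every point
#' deterministically, so the bundled points are transcribed, not recomputed.
#'
#' @return A data frame with columns `term` (coefficient label), `type`
#'   (`"diagnosis"`, `"sex"`, `"age"`, `"cci"` or `"procedure"`), `beta`,
#'   `p`, and `points` (integer, `NA` for non-procedure terms and for
#'   non-significant procedures).
#' @seealso [published_index()]
#' @export
published_coefficients <- function() {
  data.frame(
    term = c(
      "congestive_heart_failure", "acute_cerebrovascular_disease",
      "gastrointestinal_hemorrhage", "pneumonia", "septicemia",
      "sex_female",
      "age_60_69", "age_70_79", "age_80_89", "age_90_plus",
      "cci_1", "cci_2", "cci_3_plus",
      "invasive_arterial_pressure", "blood_tests_excl_coagulation",
      "radiography", "urinalyses_excl_chemistry",
      "temporary_urinary_catheterization", "endocrinology_tests",
      "bacterial_microscopy_or_culture", "acid_fast_bacilli_culture",
      "coagulation_tests", "nucleic_acid_amplification_tests",
      "bacterial_drug_susceptibility_tests", "urine_chemistry_tests",
      "heart_rate_respiration_monitoring", "peripheral_iv_infusion",
      "computed_tomography", "pulse_oximetry",
      "gastric_drainage_tube_insertion", "urinary_catheter_insertion",
      "central_venous_catheter_insertion", "catecholamines_or_vasopressin",
      "sputum_suction", "intratracheal_intubation"),
    type = c(rep("diagnosis", 5L), "sex", rep("age", 4L), rep("cci", 3L),
             rep("procedure", 22L)),
    beta = c(
      -0.10, -0.11, -0.51, 0.04, 0.73,
      -0.12,
      0.35, 0.68, 1.14, 1.60,
      0.03, 0.182, 0.72,
      -0.30, -0.26, -0.20, -0.18, -0.18, -0.06, -0.05, -0.04, -0.03, 0.01,
      0.06, 0.10, 0.18, 0.18, 0.25, 0.29, 0.32, 0.47, 0.49, 0.70, 1.11, 2.05),
    p = c(
      0.012, 0.010, 5e-04, 0.405, 5e-04,
      5e-04,
      5e-04, 5e-04, 5e-04, 5e-04,
      0.233, 5e-04, 5e-04,
      5e-04, 5e-04, 5e-04, 5e-04, 0.004, 5e-04, 0.019, 0.206, 0.117, 0.842,
      0.022, 0.041, 5e-04, 5e-04, 5e-04, 5e-04, 5e-04, 5e-04, 5e-04, 5e-04,
      5e-04, 5e-04),
    points = c(
      rep(NA_integer_, 13L),
      -3L, -3L, -2L, -2L, -1L, -1L, -1L, NA_integer_, NA_integer_,
      NA_integer_, 1L, 1L, 2L, 2L, 3L, 3L, 4L, 5L, 5L, 8L, 12L, 23L),
    stringsAsFactors = FALSE)
}

#' The published 19-procedure severity-index point table
#'
#' Integer points for the 19 admission-day procedures of the published
#' severity index, from -3 (invasive arterial pressure measurement; blood
#' tests excluding coagulation) to 23 (intratracheal intubation), with the
#' published reference coefficient of 0.091.  The resulting index has a
#' possible range of -13 to 69.
#'
#' @return A [point_table] object.
#' @examples
#' pt <- published_index()
#' pt["sputum_suction"]
#' index_range(pt)
#' @export
published_index <- function() {
  pub <- published_coefficients()
  pub <- pub[pub$type == "procedure" & !is.na(pub$points), , drop = FALSE]
  point_table(stats::setNames(pub$points, pub$term),
              reference_coefficient = 0.091,
              note = "transcribed published point table")
}
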