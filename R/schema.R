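#' Modeling feature schema
#'
#' The fixed 27-feature schema used throughout the package: 25 state features
#' (block index, vital signs, laboratory tests, blood gas values and
#' demographics), one continuous action precursor (fluid balance, derived from
#' per-block input/output volumes) and one terminal outcome. For each measured
#' feature the schema records its group, the per-record missingness rate used
#' by the synthetic generator, the affine severity loading (intercept `mu`,
#' `slope` per unit latent severity, residual `sd`) and the physiologic range
#' the generator clips to.
#'
#' @return A data.frame with one row per measured record feature (columns
#'   `feature`, `group`, `missing_rate`, `mu`, `slope`, `sd`, `lo`, `hi`).
#'   The state vector additionally contains the derived `bloc` index, making
#'   25 state dimensions in total (see [state_features()]).
#' @export
feature_schema <- function() {
  s <- function(feature, group, miss, mu, slope, sd, lo, hi) {
    data.frame(feature = feature, group = group, missing_rate = miss,
               mu = mu, slope = slope, sd = sd, lo = lo, hi = hi,
               stringsAsFactors = FALSE)
  }
  rbind(
    s("mean_bp",          "vital", 0.033,  88,  -8,    6,    30, 160),
    s("sys_bp",           "vital", 0.034,  131, -10,   8,    50, 250),
    s("dia_bp",           "vital", 0.034,  67,  -6,    5,    30, 150),
    s("temperature",      "vital", 0.004,  37,   0.3,  0.3,  34, 42),
    s("resp_rate",        "vital", 0.0002, 18,   2.5,  2,    6,  60),
    s("o2_concentration", "vital", 0.204,  31,   5,    4,    21, 100),
    s("perfusion_index",  "vital", 0.004,  1.6, -0.4,  0.4,  0.1, 20),
    s("cvp",              "vital", 0.250,  8,    1.2,  1.5,  1,  25),
    s("spo2",             "vital", 0.001,  98.3, -1,   0.8,  70, 100),
    s("heart_rate",       "vital", 0.0002, 93,   8,    7,    30, 180),
    s("wbc",              "lab",   0.581,  12,   3,    3,    0.5, 50),
    s("neutrophil_pct",   "lab",   0.583,  86,   3,    4,    20, 99),
    s("hemoglobin",       "lab",   0.581,  96,  -5,    8,    40, 180),
    s("platelets",        "lab",   0.581,  145, -30,   40,   5,  600),
    s("creatinine",       "lab",   0.675,  90,   40,   30,   20, 800),
    s("bilirubin",        "lab",   0.725,  20,   10,   8,    2,  300),
    s("po2",              "gas",   0.074,  93,  -5,    10,   40, 300),
    s("pco2",             "gas",   0.074,  39,   1,    3,    15, 90),
    s("base_excess",      "gas",   0.096,  3,   -1.5,  1.5, -25, 25),
    s("ph",               "gas",   0.074,  7.45, -0.03, 0.02, 6.8, 7.7),
    s("lactate",          "gas",   0.074,  1.5,  0.8,  0.5,  0.2, 25),
    s("gender",           "demo",  0,      NA,   NA,   NA,   0,  1),
    s("age",              "demo",  0,      NA,   NA,   NA,   18, 95),
    s("weight",           "demo",  0,      NA,   NA,   NA,   35, 150)
  )
}

#' Names of the 25 state features
#'
#' The measured features of [feature_schema()] plus the derived block index
#' `bloc`, in the fixed column order used by every state matrix in the
#' package.
#'
#' @return Character vector of length 25.
#' @export
state_features <- function() {
  c("bloc", feature_schema()$feature)
}

#' Names of the laboratory features (forward-fill imputation group)
#'
#' Laboratory tests are drawn sparsely (every few blocks) and are imputed by
#' within-patient forward fill; all other features use KNN imputation.
#'
#' @return Character vector.
#' @export
lab_features <- function() {
  sch <- feature_schema()
  sch$feature[sch$group == "lab"]
}

# Features allowed in a raw records table.
record_features <- function() {
  c(feature_schema()$feature, "fluid_input", "fluid_output")
}

# Outlier-handling rule table. Each rule either excludes the offending record
# or clamps its value; predicates may depend on whether the patient died
# (the zero-vitals rules only fire for patients who survived).
outlier_rule_list <- function() {
  excl <- function(id, feature, test) {
    list(id = id, feature = feature, type = "exclude", test = test)
  }
  clamp <- function(id, feature, test, value) {
    list(id = id, feature = feature, type = "clamp", test = test, value = value)
  }
  zero_not_dead <- function(v, dead) !is.na(v) & v == 0 & !dead
  below0 <- function(v, dead) !is.na(v) & v < 0
  list(
    excl("mean_bp_negative",        "mean_bp", below0),
    excl("mean_bp_zero_not_dead",   "mean_bp", zero_not_dead),
    excl("sys_bp_negative",         "sys_bp",  below0),
    excl("sys_bp_zero_not_dead",    "sys_bp",  zero_not_dead),
    excl("dia_bp_negative",         "dia_bp",  below0),
    excl("dia_bp_zero_not_dead",    "dia_bp",  zero_not_dead),
    excl("resp_rate_high",          "resp_rate", function(v, dead) !is.na(v) & v > 100),
    excl("resp_rate_zero_not_dead", "resp_rate", zero_not_dead),
    clamp("o2_concentration_low_clamp", "o2_concentration",
          function(v, dead) !is.na(v) & v < 21, 21),
    excl("o2_concentration_high",   "o2_concentration", function(v, dead) !is.na(v) & v > 100),
    excl("perfusion_index_high",    "perfusion_index", function(v, dead) !is.na(v) & v > 50),
    excl("cvp_nonpositive",         "cvp", function(v, dead) !is.na(v) & v <= 0),
    excl("spo2_range",              "spo2", function(v, dead) !is.na(v) & (v == 0 | v > 100)),
    excl("heart_rate_zero_not_dead", "heart_rate", zero_not_dead),
    excl("neutrophil_pct_zero",     "neutrophil_pct", function(v, dead) !is.na(v) & v == 0),
    excl("ph_lower",                "ph", function(v, dead) !is.na(v) & v < 6.7),
    excl("lactate_high",            "lactate", function(v, dead) !is.na(v) & v > 30),
    excl("fluid_input_range",       "fluid_input",
         function(v, dead) is.na(v) | v < 0 | v > 5000),
    excl("fluid_output_range",      "fluid_output",
         function(v, dead) is.na(v) | v < 0 | v > 5000)
  )
}

# Out-of-range values the generator can inject to exercise each rule.
outlier_injection_values <- function() {
  list(
    mean_bp = c(-5, 0), sys_bp = c(-10, 0), dia_bp = c(-5, 0),
    resp_rate = c(150, 0), o2_concentration = c(12, 110),
    perfusion_index = 80, cvp = c(0, -2), spo2 = c(0, 104),
    heart_rate = 0, neutrophil_pct = 0, ph = 6.5, lactate = 35,
    fluid_input = 6500, fluid_output = 6500
  )
}
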