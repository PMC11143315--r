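#' Built-in cohort schemas
#'
#' A schema declares, for one tabular cohort layout, the ordered feature
#' columns, which of them are categorical, the label column, and the columns
#' that are mandatory (a row missing a mandatory value is dropped during
#' cleaning rather than imputed).
#'
#' Two schemas ship with the package:
#' \describe{
#'   \item{\code{"kaggle16"}}{16 admission features (demographics, vitals,
#'     biochemistry) with categorical residence type and smoking status, and a
#'     4-level triage label. Gender is mandatory.}
#'   \item{\code{"mimic14"}}{14 emergency-department triage features (vital
#'     signs, pain score, demographics, transport/disposition and medication
#'     text fields) with a 4-level acuity label (1 = most severe).}
#' }
#'
#' @param schema_id one of \code{"kaggle16"}, \code{"mimic14"}.
#' @return a list with elements \code{schema_id}, \code{feature_names},
#'   \code{categorical} (character vector of categorical feature columns),
#'   \code{label_column}, \code{mandatory} (character vector) and
#'   \code{levels} (named list of declared category levels).
#' @export
#' @examples
#' s <- get_schema("kaggle16")
#' length(s$feature_names)  # 16
get_schema <- function(schema_id) {
  switch(schema_id,
    kaggle16 = list(
      schema_id = "kaggle16",
      feature_names = c(
        "age", "gender", "chest_pain_type", "blood_pressure", "cholesterol",
        "max_heart_rate", "exercise_angina", "plasma_glucose",
        "skin_thickness", "insulin", "bmi", "diabetes_pedigree",
        "hypertension", "heart_disease", "residence_type", "smoking_status"
      ),
      categorical = c("residence_type", "smoking_status"),
      label_column = "triage",
      mandatory = "gender",
      levels = list(
        residence_type = c("Rural", "Urban"),
        smoking_status = c("Unknown", "never smoked",
                           "previously smoked", "smoke"),
        triage = c("Green", "Orange", "Red", "Yellow")
      )
    ),
    mimic14 = list(
      schema_id = "mimic14",
      feature_names = c(
        "temperature", "heartrate", "resprate", "o2sat", "sbp", "dbp",
        "pain", "gender", "race", "arrival_transport", "disposition",
        "name", "etcdescription", "times_minutes"
      ),
      categorical = c("gender", "race", "arrival_transport", "disposition",
                      "name", "etcdescription"),
      label_column = "acuity",
      mandatory = "gender",
      levels = list(
        gender = c("F", "M"),
        race = c("ASIAN", "BLACK", "HISPANIC", "OTHER", "WHITE"),
        arrival_transport = c("AMBULANCE", "HELICOPTER", "OTHER", "WALK IN"),
        disposition = c("ADMITTED", "ELOPED", "HOME", "TRANSFER"),
        name = c("acetaminophen", "aspirin", "ibuprofen", "morphine",
                 "ondansetron"),
        etcdescription = c("analgesic", "antiemetic", "antiplatelet",
                           "nsaid", "opioid"),
        acuity = c("1", "2", "3", "4")
      )
    ),
    stop2("unknown schema_id: ", schema_id)
  )
}

#' Read a schema declaration from a YAML or JSON file
#'
#' The file must declare \code{feature_names}, \code{label_column} and may
#' declare \code{categorical}, \code{mandatory} and \code{levels}.
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return a schema list as returned by [get_schema()], with
#'   \code{schema_id = "custom"} unless the file states otherwise.
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) stop2("schema file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$feature_names) || is.null(raw$label_column)) {
    stop2("schema file must declare feature_names and label_column")
  }
  list(
    schema_id = raw$schema_id %||% "custom",
    feature_names = as.character(raw$feature_names),
    categorical = as.character(raw$categorical %||% character()),
    label_column = as.character(raw$label_column),
    mandatory = as.character(raw$mandatory %||% character()),
    levels = raw$levels %||% list()
  )
}

# Schema for an arbitrary table: every column numeric unless declared.
custom_schema <- function(feature_names, label_column = NULL,
                          categorical = character(),
                          mandatory = character(), levels = list()) {
  list(schema_id = "custom", feature_names = feature_names,
       categorical = categorical, label_column = label_column,
       mandatory = mandatory, levels = levels)
}
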