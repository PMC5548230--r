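#' @keywords internal
"_PACKAGE"

## Systemic-score item names (the 20-point checklist of the revised Ghent
## nosology).  Stored in the cohort as logical columns prefixed "sys_".
SYS_ITEMS <- c(
  "pectus_carinatum",
  "pectus_excavatum_or_chest_asymmetry",
  "reduced_us_ls_and_increased_armspan_no_scoliosis",
  "characteristic_face",
  "wrist_sign",
  "thumb_sign",
  "scoliosis_or_kyphosis",
  "reduced_elbow_extension",
  "pes_planus",
  "hindfoot_deformity",
  "protrusio_acetabulae",
  "myopia_gt3_diopters",
  "mitral_valve_prolapse",
  "spontaneous_pneumothorax",
  "striae_atrophicae",
  "dural_ectasia"
)

## Skeletal subset used by the Kid-SMS "3 skeletal features" rule: counted as
## distinct present items, not Ghent points.
SKELETAL_ITEMS <- SYS_ITEMS[1:11]

SEX_LEVELS <- c("female", "male", "unknown")
FBN1_LEVELS <- c("positive", "negative", "not_tested")
VISIT_LEVELS <- c("baseline", "follow_up")

#' Cohort column schema
#'
#' The fixed column schema for patient-visit cohorts.  One column per field,
#' snake_case names, no fuzzy header matching.  Units are fixed: diameters in
#' mm, body-surface area in m\eqn{^2}, ages in years.  Booleans are
#' serialized as `"true"`/`"false"`/`""` where the empty string means
#' *absent* (not assessed) -- absent is never silently treated as `false`.
#'
#' @return A data.frame with columns `name`, `type`
#'   (`"character"`/`"numeric"`/`"logical"`/`"enum"`), and `required`
#'   (whether a value must be present in every row).
#' @export
cohort_columns <- function() {
  base <- data.frame(
    name = c("patient_id", "visit", "age_years", "sex",
             "bsa_m2", "sv_diameter_mm", "sv_dilated", "aortic_dissection",
             "pa_diameter_mm", "pa_dilated",
             "ectopia_lentis", "mitral_valve_prolapse",
             "tricuspid_valve_prolapse", "family_history_mfs", "fbn1_status"),
    type = c("character", "enum", "numeric", "enum",
             "numeric", "numeric", "logical", "logical",
             "numeric", "logical",
             "logical", "logical", "logical", "logical", "enum"),
    required = c(TRUE, TRUE, TRUE, TRUE,
                 FALSE, FALSE, FALSE, FALSE,
                 FALSE, FALSE,
                 FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  sys <- data.frame(
    name = paste0("sys_", SYS_ITEMS),
    type = "logical",
    required = FALSE,
    stringsAsFactors = FALSE
  )
  rbind(base, sys)
}

enum_levels <- function(column) {
  switch(column,
    sex = SEX_LEVELS,
    fbn1_status = FBN1_LEVELS,
    visit = VISIT_LEVELS,
    stop("no enum levels for column '", column, "'")
  )
}

#' Construct the full systemic-item vector
#'
#' The standard constructor requires every one of the 16 checklist items to
#' be stated explicitly; [systemic_items_none()] is the explicit
#' "assume all absent manifestations are negative" constructor.
#'
#' @param ... Named logical values, one per item in `SYS_ITEMS` order or by
#'   name; all 16 must be supplied.
#' @return Named logical vector of length 16.
#' @export
systemic_items <- function(...) {
  vals <- list(...)
  if (length(vals) != length(SYS_ITEMS) || is.null(names(vals)) ||
      !setequal(names(vals), SYS_ITEMS)) {
    missing <- setdiff(SYS_ITEMS, names(vals))
    stop("systemic_items() requires all 16 items stated; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- vapply(vals[SYS_ITEMS], function(v) as.logical(v)[1], logical(1))
  names(out) <- SYS_ITEMS
  out
}

#' @rdname systemic_items
#' @export
systemic_items_none <- function() {
  stats::setNames(rep(FALSE, length(SYS_ITEMS)), SYS_ITEMS)
}

#' Construct a single patient-visit record
#'
#' Returns a one-row cohort data.frame.  Optional clinical fields left as
#' `NA` are *absent*: operations that depend on them fail loudly rather than
#' defaulting to negative.
#'
#' @param patient_id Opaque string identifier.
#' @param age_years Non-negative age in years.
#' @param sex `"female"`, `"male"` or `"unknown"`.
#' @param visit `"baseline"` or `"follow_up"`.
#' @param bsa_m2,sv_diameter_mm,pa_diameter_mm Optional positive reals
#'   (m\eqn{^2} / mm).
#' @param sv_dilated,pa_dilated Optional direct dilatation flags; when
#'   present they override any nomogram.
#' @param aortic_dissection,ectopia_lentis,mitral_valve_prolapse,tricuspid_valve_prolapse,family_history_mfs
#'   Logical clinical features (`NA` = not assessed).
#' @param fbn1_status `"positive"`, `"negative"` or `"not_tested"`.
#' @param systemic Named logical vector from [systemic_items()] /
#'   [systemic_items_none()], or `NA` to leave all items unstated.
#' @return One-row cohort data.frame.
#' @export
phenotype_record <- function(patient_id, age_years, sex = "unknown",
                             visit = "baseline",
                             bsa_m2 = NA_real_, sv_diameter_mm = NA_real_,
                             sv_dilated = NA, aortic_dissection = FALSE,
                             pa_diameter_mm = NA_real_, pa_dilated = NA,
                             ectopia_lentis = NA, mitral_valve_prolapse = NA,
                             tricuspid_valve_prolapse = NA,
                             family_history_mfs = NA,
                             fbn1_status = "not_tested",
                             systemic = systemic_items_none()) {
  if (length(systemic) == 1 && is.na(systemic[1])) {
    systemic <- stats::setNames(rep(NA, length(SYS_ITEMS)), SYS_ITEMS)
  }
  stopifnot(setequal(names(systemic), SYS_ITEMS))
  rec <- data.frame(
    patient_id = as.character(patient_id),
    visit = as.character(visit),
    age_years = as.numeric(age_years),
    sex = as.character(sex),
    bsa_m2 = as.numeric(bsa_m2),
    sv_diameter_mm = as.numeric(sv_diameter_mm),
    sv_dilated = as.logical(sv_dilated),
    aortic_dissection = as.logical(aortic_dissection),
    pa_diameter_mm = as.numeric(pa_diameter_mm),
    pa_dilated = as.logical(pa_dilated),
    ectopia_lentis = as.logical(ectopia_lentis),
    mitral_valve_prolapse = as.logical(mitral_valve_prolapse),
    tricuspid_valve_prolapse = as.logical(tricuspid_valve_prolapse),
    family_history_mfs = as.logical(family_history_mfs),
    fbn1_status = as.character(fbn1_status),
    stringsAsFactors = FALSE
  )
  for (it in SYS_ITEMS) rec[[paste0("sys_", it)]] <- as.logical(systemic[[it]])
  as_cohort(rec)
}

#' Validate a cohort data.frame
#'
#' Checks the column schema, types, enum values and value invariants
#' (non-negative ages, strictly positive diameters and BSA where present).
#'
#' @param x A data.frame.
#' @param allow_extra Character vector of extra column names tolerated
#'   (and preserved) beyond the fixed schema.
#' @return `x`, validated, with columns ordered schema-first.
#' @export
as_cohort <- function(x, allow_extra = character()) {
  stopifnot(is.data.frame(x))
  schema <- cohort_columns()
  missing <- setdiff(schema$name, names(x))
  if (length(missing) > 0) {
    stop("cohort is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(x), c(schema$name, allow_extra))
  if (length(unknown) > 0) {
    stop("unknown cohort column(s): ", paste(unknown, collapse = ", "),
         "; pass allow_extra= to accept them", call. = FALSE)
  }
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    col <- x[[nm]]
    x[[nm]] <- switch(schema$type[i],
      character = as.character(col),
      numeric = as.numeric(col),
      logical = as.logical(col),
      enum = {
        col <- as.character(col)
        bad <- !is.na(col) & !(col %in% enum_levels(nm))
        if (any(bad)) {
          stop("invalid value(s) in column '", nm, "': ",
               paste(unique(col[bad]), collapse = ", "),
               " (allowed: ", paste(enum_levels(nm), collapse = ", "), ")",
               call. = FALSE)
        }
        col
      })
  }
  req <- schema$name[schema$required]
  for (nm in req) {
    if (anyNA(x[[nm]])) {
      stop("column '", nm, "' is mandatory but has missing values (rows ",
           paste(which(is.na(x[[nm]])), collapse = ", "), ")", call. = FALSE)
    }
  }
  if (any(x$age_years < 0, na.rm = TRUE)) {
    stop("age_years must be non-negative", call. = FALSE)
  }
  for (nm in c("bsa_m2", "sv_diameter_mm", "pa_diameter_mm")) {
    if (any(x[[nm]] <= 0, na.rm = TRUE)) {
      stop("column '", nm, "' must be strictly positive when present",
           call. = FALSE)
    }
  }
  x[, c(schema$name, intersect(allow_extra, names(x))), drop = FALSE]
}

parse_cell <- function(value, type, column, row) {
  if (type != "character" && !nzchar(value)) {
    return(switch(type, numeric = NA_real_, logical = NA, enum = NA_character_))
  }
  switch(type,
    character = value,
    numeric = {
      out <- suppressWarnings(as.numeric(value))
      if (is.na(out)) {
        stop("row ", row, ": cannot parse '", value,
             "' in column '", column, "' as a number", call. = FALSE)
      }
      out
    },
    logical = {
      if (!value %in% c("true", "false")) {
        stop("row ", row, ": cannot parse '", value, "' in column '", column,
             "' as a boolean (use \"true\"/\"false\"/\"\")", call. = FALSE)
      }
      value == "true"
    },
    enum = value
  )
}

#' Read a cohort from CSV
#'
#' RFC-4180-style CSV with a mandatory header row.  Header names must match
#' [cohort_columns()] exactly; unknown columns are rejected unless listed in
#' `allow_extra`.  Empty cells in optional fields are preserved as *absent*
#' (`NA`), never coerced to `false`/zero.
#'
#' @param path Path to a CSV file.
#' @param allow_extra Extra column names to accept; they are read as-is
#'   (logical if every non-empty cell is `"true"`/`"false"`).
#' @return A validated cohort data.frame, one row per record.
#' @export
read_cohort <- function(path, allow_extra = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         stringsAsFactors = FALSE)
  schema <- cohort_columns()
  missing <- setdiff(schema$name, names(raw))
  if (length(missing) > 0) {
    stop("schema error: missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(raw), c(schema$name, allow_extra))
  if (length(unknown) > 0) {
    stop("schema error: unknown column(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) stop("cohort file has no data rows: ", path,
                           call. = FALSE)
  out <- raw
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    type <- schema$type[i]
    out[[nm]] <- vapply(seq_len(nrow(raw)), function(r) {
      parse_cell(raw[[nm]][r], if (type == "enum") "enum" else type, nm, r)
    }, switch(type, character = , enum = character(1),
              numeric = numeric(1), logical = logical(1)))
  }
  for (nm in intersect(allow_extra, names(raw))) {
    vals <- raw[[nm]]
    if (all(vals %in% c("true", "false", ""))) {
      out[[nm]] <- ifelse(vals == "", NA, vals == "true")
    }
  }
  as_cohort(out, allow_extra = allow_extra)
}

format_cell <- function(value, type) {
  if (is.na(value)) return("")
  switch(type,
    character = , enum = as.character(value),
    numeric = format(value, digits = 15, scientific = FALSE, trim = TRUE),
    logical = if (value) "true" else "false"
  )
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x))` reproduces `x`
#' field-for-field, including absent (`NA`) optional fields, which are
#' written as empty cells.
#'
#' @param cohort A validated cohort data.frame (non-empty).
#' @param path Output path.
#' @param allow_extra Extra columns to validate and serialize alongside the
#'   schema (logical extras use the `"true"`/`"false"`/`""` convention).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, allow_extra = character()) {
  cohort <- as_cohort(cohort, allow_extra = allow_extra)
  if (nrow(cohort) == 0) stop("refusing to write an empty cohort",
                              call. = FALSE)
  schema <- cohort_columns()
  out <- cohort
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    out[[nm]] <- vapply(cohort[[nm]], format_cell, character(1),
                        type = schema$type[i])
  }
  for (nm in intersect(allow_extra, names(cohort))) {
    if (is.logical(cohort[[nm]])) {
      out[[nm]] <- vapply(cohort[[nm]], format_cell, character(1),
                          type = "logical")
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

## Extract the 16 systemic-item columns of a cohort as a plain logical
## data.frame named by item (prefix stripped).  Errors if any item is
## unstated (NA) -- absent manifestations make the score uncomputable.
sys_matrix <- function(cohort, context = "systemic score") {
  cols <- paste0("sys_", SYS_ITEMS)
  m <- cohort[, cols, drop = FALSE]
  names(m) <- SYS_ITEMS
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1, any))
    stop(context, " is not computable: systemic items not stated for row(s) ",
         paste(bad, collapse = ", "),
         " (absent is not treated as negative)", call. = FALSE)
  }
  m
}
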