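# Per-examination organ/effective dose tables for the six MIRD phantom age
# categories, and age interpolation of dose vectors.

#' Organ sites tracked by the dose tables and risk models
#'
#' The fixed list of organ dose rows carried by every dose vector, in
#' table order.  `"other_solid"` aggregates solid organs not listed
#' individually; effective dose and (for CT) total-body dose are carried
#' separately.
#'
#' @return Character vector of the twelve organ identifiers.
#' @export
#' @examples
#' organ_sites()
organ_sites <- function() {
  c("bone_marrow", "stomach", "colon", "liver", "lung", "breast",
    "prostate", "uterus", "ovary", "bladder", "other_solid", "thyroid")
}

#' @rdname organ_sites
#' @export
exam_types <- function() c("WB_CT", "NECK_CHEST_CT", "PET")

#' @rdname organ_sites
#' @export
phantom_ages <- function() c("0", "1", "5", "10", "15", "adult")

# rows every (exam, age) cell must provide; total_body additionally for CT
.dose_rows <- function() c("effective_dose", organ_sites())

#' Load a per-examination organ dose table
#'
#' Reads the organ/effective dose table giving, for each examination type
#' (whole-body CT, neck--chest CT, 18F-FDG PET) and each of six phantom age
#' categories (newborn, 1, 5, 10, 15 years, adult), the organ doses,
#' effective dose and (CT only) total-body dose in mSv.  With no argument
#' the bundled table is used; a user file must be a CSV with columns
#' `exam_type`, `phantom_age`, `organ`, `dose_mSv`.
#'
#' @param source Path to a CSV file, or `NULL` for the bundled table.
#' @return A data frame of class `"organ_dose_table"` with columns
#'   `exam_type`, `phantom_age`, `organ`, `dose_mSv`.
#' @export
#' @examples
#' doses <- load_dose_table()
#' subset(doses, exam_type == "WB_CT" & phantom_age == "adult" &
#'               organ == "effective_dose")
load_dose_table <- function(source = NULL) {
  if (is.null(source)) {
    source <- system.file("extdata", "organ_doses_mird_ct_pet.csv",
                          package = "lymphorad", mustWork = TRUE)
  }
  if (!file.exists(source)) stop("dose table file not found: ", source)
  tab <- utils::read.csv(source, stringsAsFactors = FALSE)
  need <- c("exam_type", "phantom_age", "organ", "dose_mSv")
  if (!all(need %in% names(tab))) {
    stop("dose table must have columns ", paste(need, collapse = ", "),
         "; missing: ", paste(setdiff(need, names(tab)), collapse = ", "))
  }
  tab$phantom_age <- as.character(tab$phantom_age)
  validate_dose_table(tab)
  class(tab) <- c("organ_dose_table", "data.frame")
  tab
}

validate_dose_table <- function(tab) {
  bad <- !tab$exam_type %in% exam_types()
  if (any(bad)) stop("unknown exam_type: ", paste(unique(tab$exam_type[bad]), collapse = ", "))
  bad <- !tab$phantom_age %in% phantom_ages()
  if (any(bad)) stop("unknown phantom_age: ", paste(unique(tab$phantom_age[bad]), collapse = ", "))
  if (any(!is.finite(tab$dose_mSv))) {
    i <- which(!is.finite(tab$dose_mSv))[1]
    stop("non-finite dose at exam_type=", tab$exam_type[i],
         ", phantom_age=", tab$phantom_age[i], ", organ=", tab$organ[i])
  }
  if (any(tab$dose_mSv < 0)) {
    i <- which(tab$dose_mSv < 0)[1]
    stop("negative dose at exam_type=", tab$exam_type[i],
         ", phantom_age=", tab$phantom_age[i], ", organ=", tab$organ[i])
  }
  for (ex in exam_types()) {
    rows <- .dose_rows()
    if (ex != "PET") rows <- c("total_body", rows)
    for (ag in phantom_ages()) {
      have <- tab$organ[tab$exam_type == ex & tab$phantom_age == ag]
      miss <- setdiff(rows, have)
      if (length(miss)) {
        stop("dose table incomplete: exam_type=", ex, ", phantom_age=", ag,
             " is missing row(s): ", paste(miss, collapse = ", "))
      }
      if (anyDuplicated(have)) {
        stop("duplicated organ rows for exam_type=", ex, ", phantom_age=", ag)
      }
    }
  }
  invisible(tab)
}

# numeric anchor ages for interpolation; "adult" sits at adult_anchor_age
.anchor_ages <- function(adult_anchor_age) c(0, 1, 5, 10, 15, adult_anchor_age)

#' Age-interpolated dose vector for one examination
#'
#' Returns the organ, effective and (CT) total-body doses for an
#' examination performed at an arbitrary patient age.  Doses are taken
#' exactly from the table at the six anchor ages and linearly interpolated
#' component-wise in between.  The adult column is anchored at
#' `adult_anchor_age` (default 18 years, the upper bound of the paediatric
#' protocols); at or beyond that age the adult doses apply unchanged.
#'
#' @param table An `organ_dose_table` from [load_dose_table()].
#' @param exam One of `"WB_CT"`, `"NECK_CHEST_CT"`, `"PET"`.
#' @param age_years Patient age in years (non-negative scalar).
#' @param adult_anchor_age Age (years) at which the adult dose column
#'   applies; linear interpolation is used between 15 years and this age.
#' @return Named numeric vector over `effective_dose`, the twelve organ
#'   sites, and `total_body` (`NA` for PET, which tabulates no total-body
#'   dose), in mSv.
#' @export
#' @examples
#' tab <- load_dose_table()
#' interpolate_doses(tab, "WB_CT", 3)[["effective_dose"]]  # midway 1 y and 5 y
interpolate_doses <- function(table, exam, age_years, adult_anchor_age = 18) {
  stopifnot(inherits(table, "organ_dose_table"))
  exam <- match.arg(exam, exam_types())
  if (!is.numeric(age_years) || length(age_years) != 1L || is.na(age_years) ||
      age_years < 0) {
    stop("age_years must be a single non-negative number")
  }
  if (adult_anchor_age <= 15) stop("adult_anchor_age must exceed 15 years")
  rows <- .dose_rows()
  if (exam != "PET") rows <- c(rows, "total_body")
  x <- .anchor_ages(adult_anchor_age)
  a <- min(age_years, adult_anchor_age)
  sub <- table[table$exam_type == exam, ]
  out <- vapply(rows, function(org) {
    y <- vapply(phantom_ages(), function(ag) {
      sub$dose_mSv[sub$phantom_age == ag & sub$organ == org]
    }, numeric(1))
    stats::approx(x, y, xout = a, rule = 2)$y
  }, numeric(1))
  if (exam == "PET") out <- c(out, total_body = NA_real_)
  out
}

#' Administered 18F-FDG activity per phantom age category
#'
#' The fixed administered activities assumed for PET, corresponding to
#' 3 MBq of 18F-FDG per kg body weight at each phantom category's
#' reference weight.
#'
#' @param age_category One of `"0"` (accepts `"newborn"`), `"1"`, `"5"`,
#'   `"10"`, `"15"`, `"adult"`.
#' @return Administered activity in MBq.
#' @export
#' @examples
#' pet_administered_activity("adult")
pet_administered_activity <- function(age_category) {
  age_category <- as.character(age_category)
  if (identical(age_category, "newborn")) age_category <- "0"
  act <- c("0" = 10, "1" = 30, "5" = 60, "10" = 100, "15" = 170, "adult" = 220)
  if (!age_category %in% names(act)) {
    stop("unknown phantom age category: ", age_category,
         " (expected one of ", paste(names(act), collapse = ", "), ")")
  }
  unname(act[age_category])
}
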