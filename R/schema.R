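# Cohort data model: the 18 transplant parameters and the 3-class outcome.

OUTCOME_LEVELS <- c("alive", "dead", "alive_lt24")

#' Default allo-HSCT cohort schema
#'
#' Returns the schema of the 18 pre- and post-transplant parameters used for
#' survival-status classification, with the categorical groupings and the
#' continuous ranges of the source cohort's descriptive statistics.
#' Categorical features carry consecutive integer codes starting at 1
#' (engraftment, chronic GvHD and secondary malignancy use the conventional
#' yes = 1 / no = 0 coding); continuous features carry their clinical units
#' and admissible range.
#'
#' @return An object of class `derga_schema`: a list with `features` (ordered
#'   list of 18 feature definitions, each with `name`, `kind`, and either
#'   `levels` or `units`/`range`) and `outcome_levels`
#'   (`c("alive", "dead", "alive_lt24")`).
#' @examples
#' sch <- hsct_schema()
#' length(sch$features)         # 18
#' schema_feature_names(sch)
#' @export
hsct_schema <- function() {
  cat_f <- function(name, levels) {
    list(name = name, kind = "categorical", levels = levels)
  }
  num_f <- function(name, units, range) {
    stopifnot(range[1] < range[2])
    list(name = name, kind = "continuous", units = units, range = range)
  }
  features <- list(
    cat_f("gender", c(male = 1, female = 2)),
    num_f("age", "years", c(18, 88)),
    cat_f("disease", c(lymphoid = 1, myeloid = 2, other = 3)),
    cat_f("disease_phase", c(chemosensitive = 1, chemoresistant = 2)),
    cat_f("donor_type", c(sibling = 1, unrelated = 2, haploidentical = 3)),
    cat_f("hla_group", c(full_match = 1, mismatch = 2)),
    cat_f("graft_source", c(peripheral = 1, bone_marrow = 2, other = 3)),
    cat_f("conditioning", c(myeloablative = 1, reduced = 2)),
    num_f("plt_day2", "10^9/L", c(3, 922.2)),
    num_f("ldh_day2", "mg/dL", c(14, 4326)),
    num_f("crea_day2", "mg/dL", c(0.6, 5.3)),
    num_f("cd34", "10^6/kg", c(1.23, 19.8)),
    cat_f("neut_engraft", c(no = 0, yes = 1)),
    cat_f("plt_engraft", c(no = 0, yes = 1)),
    cat_f("dri", c(low = 1, intermediate = 2, high = 3)),
    cat_f("agvhd", c(grade0_or_I = 1, other = 2)),
    cat_f("cgvhd", c(no = 0, yes = 1)),
    cat_f("sec_malig", c(no = 0, yes = 1))
  )
  names(features) <- vapply(features, `[[`, "", "name")
  structure(list(features = features, outcome_levels = OUTCOME_LEVELS),
            class = "derga_schema")
}

#' @export
print.derga_schema <- function(x, ...) {
  cat("Cohort schema:", length(x$features), "features,",
      length(x$outcome_levels), "outcome classes\n")
  for (f in x$features) {
    if (f$kind == "categorical") {
      cat(sprintf("  %-14s categorical {%s}\n", f$name,
                  paste(sprintf("%s=%d", names(f$levels), f$levels),
                        collapse = ", ")))
    } else {
      cat(sprintf("  %-14s continuous  [%g, %g] %s\n", f$name,
                  f$range[1], f$range[2], f$units))
    }
  }
  cat("  outcome:", paste(x$outcome_levels, collapse = " / "), "\n")
  invisible(x)
}

#' Feature names of a schema
#'
#' @param schema A `derga_schema`.
#' @return Character vector of feature names in schema order.
#' @export
schema_feature_names <- function(schema = hsct_schema()) {
  unname(vapply(schema$features, `[[`, "", "name"))
}

#' Mapping from report abbreviations to schema features
#'
#' The accuracy-matrix reports abbreviate the 18 parameters (Age, aGVHD,
#' CD34, cGVHD, CR, Crea, DF, DRI, DT, GS, HLA, LDH, NEUT, PLAT, PLT, sMAL,
#' Gender, Disease).  This returns the abbreviation -> feature-name map.
#'
#' @return Named character vector of length 18.
#' @export
parameter_abbreviations <- function() {
  c(Gender = "gender", Age = "age", Disease = "disease",
    DF = "disease_phase", DT = "donor_type", HLA = "hla_group",
    GS = "graft_source", CR = "conditioning", PLT = "plt_day2",
    LDH = "ldh_day2", Crea = "crea_day2", CD34 = "cd34",
    NEUT = "neut_engraft", PLAT = "plt_engraft", DRI = "dri",
    aGVHD = "agvhd", cGVHD = "cgvhd", sMAL = "sec_malig")
}

#' Export a schema as JSON
#'
#' Machine-readable description of the feature definitions, for validation
#' tooling and documentation.
#'
#' @param schema A `derga_schema`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when written to `path`).
#' @export
schema_to_json <- function(schema = hsct_schema(), path = NULL) {
  obj <- list(
    features = lapply(unname(schema$features), function(f) {
      if (f$kind == "categorical") {
        list(name = f$name, kind = f$kind, levels = as.list(f$levels))
      } else {
        list(name = f$name, kind = f$kind, units = f$units,
             range = f$range)
      }
    }),
    outcome_levels = schema$outcome_levels
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(as.character(json))
}

# --- cohort table ----------------------------------------------------------

#' Construct and validate a cohort table
#'
#' Validates a data frame of patient records against a schema and stamps it
#' as a cohort table.  Every row must supply a value for each of the 18
#' features (categorical values in the coded level set, continuous values
#' within the admissible range) plus an outcome label; rows with missing
#' values are rejected.
#'
#' @param df Data frame with one column per schema feature plus `outcome`.
#' @param schema A `derga_schema`.
#' @param provenance Free-text provenance tag (e.g. `"synthetic seed=7"` or
#'   a source path).
#' @return A `cohort` object (a data frame with `schema` and `provenance`
#'   attributes); `outcome` is a factor with levels alive/dead/alive_lt24.
#' @export
as_cohort <- function(df, schema = hsct_schema(), provenance = "unspecified") {
  stopifnot(is.data.frame(df))
  names(df) <- normalise_header(names(df))
  fn <- schema_feature_names(schema)
  missing_cols <- setdiff(c(fn, "outcome"), names(df))
  if (length(missing_cols) > 0) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[, c(fn, "outcome"), drop = FALSE]
  if (nrow(df) < 1) stop("cohort has no records")

  out <- normalise_outcome(df$outcome, schema$outcome_levels)
  bad <- which(is.na(out))
  if (length(bad) > 0) {
    stop("invalid outcome label at row(s): ", paste(utils::head(bad, 5),
                                                    collapse = ", "))
  }
  df$outcome <- out

  for (f in schema$features) {
    v <- df[[f$name]]
    if (anyNA(v)) {
      stop("missing values in '", f$name, "' at row(s): ",
           paste(utils::head(which(is.na(v)), 5), collapse = ", "))
    }
    if (!is.numeric(v)) {
      v <- suppressWarnings(as.numeric(v))
      if (anyNA(v)) {
        stop("non-numeric values in '", f$name, "' at row(s): ",
             paste(utils::head(which(is.na(v)), 5), collapse = ", "))
      }
    }
    v <- as.double(v)
    df[[f$name]] <- v
    if (f$kind == "categorical") {
      bad <- which(!(v %in% unname(f$levels)))
    } else {
      bad <- which(v < f$range[1] | v > f$range[2])
    }
    if (length(bad) > 0) {
      stop("value out of ", if (f$kind == "categorical") "level set" else
           "range", " for '", f$name, "' at row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  rownames(df) <- NULL
  structure(df, schema = schema, provenance = provenance,
            class = c("cohort", "data.frame"))
}

#' @export
print.cohort <- function(x, ...) {
  cat("Cohort table:", nrow(x), "records x", ncol(x) - 1,
      "features (provenance:", attr(x, "provenance"), ")\n")
  cat("outcome:",
      paste(sprintf("%s=%d", levels(x$outcome), as.vector(table(x$outcome))),
            collapse = ", "), "\n")
  invisible(x)
}

normalise_header <- function(x) {
  tolower(gsub("[[:space:]]+", "", x))
}

# Accepts the canonical labels plus common long-form synonyms,
# case-insensitively; returns a factor on the canonical levels with NA for
# anything unrecognised.
normalise_outcome <- function(x, levels = OUTCOME_LEVELS) {
  key <- tolower(gsub("[^a-z0-9]+", "", tolower(as.character(x))))
  syn <- c(alive = "alive", dead = "dead", alivelt24 = "alive_lt24",
           alivebutfollowuplessthan24months = "alive_lt24",
           alivefollowuplessthan24months = "alive_lt24",
           alivebutfollowuplt24months = "alive_lt24")
  factor(unname(syn[key]), levels = levels)
}

#' Read a cohort table from CSV or XLSX
#'
#' Reads a patient-level cohort file (one header row naming the 18 schema
#' features plus an `outcome` column, in any column order; header matching is
#' case-insensitive after whitespace removal) and validates it against the
#' schema.  Long-form outcome labels ("Alive", "Dead", "Alive but follow-up
#' less than 24 months") are accepted.  XLSX files are read from their first
#' worksheet and require the `readxl` package.
#'
#' @param path Path to a `.csv` or `.xlsx` file.
#' @param schema A `derga_schema`.
#' @return A validated `cohort` object.
#' @export
read_cohort <- function(path, schema = hsct_schema()) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading XLSX requires the 'readxl' package")
    }
    df <- as.data.frame(readxl::read_excel(path, sheet = 1))
  } else {
    df <- utils::read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  }
  if (nrow(df) == 0) stop("cohort file is empty: ", path)
  as_cohort(df, schema, provenance = paste0("file:", path))
}

#' Write a cohort table to CSV
#'
#' Writes a cohort as RFC 4180 CSV ("." decimal, up to 15 significant
#' digits) such that `read_cohort()` reproduces the records exactly.
#'
#' @param table A `cohort` object.
#' @param path Output path.
#' @export
write_cohort <- function(table, path) {
  stopifnot(inherits(table, "cohort"))
  df <- as.data.frame(table)
  df$outcome <- as.character(df$outcome)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Encode a cohort as a numeric feature matrix
#'
#' Projects a cohort onto a feature pattern: categorical features pass
#' through as their integer codes, continuous features unscaled (the tree
#' learners are scale-invariant), columns in schema order restricted to the
#' pattern.  Outcome labels map alive -> 0, dead -> 1, alive_lt24 -> 2.
#'
#' @param table A `cohort` object.
#' @param pattern Character vector of feature names (default: all 18).
#' @return List with `x` (numeric matrix), `y` (outcome factor), `labels`
#'   (integer codes 0/1/2) and `feature_names`.
#' @export
encode_cohort <- function(table, pattern = NULL) {
  stopifnot(inherits(table, "cohort"))
  schema <- attr(table, "schema")
  fn <- schema_feature_names(schema)
  if (is.null(pattern)) pattern <- fn
  pattern <- as.character(pattern)
  if (length(pattern) == 0) stop("pattern must be non-empty")
  unknown <- setdiff(pattern, fn)
  if (length(unknown) > 0) {
    stop("pattern names not in schema: ", paste(unknown, collapse = ", "))
  }
  cols <- fn[fn %in% pattern]  # canonical schema order
  x <- as.matrix(as.data.frame(table)[, cols, drop = FALSE])
  storage.mode(x) <- "double"
  dimnames(x) <- list(NULL, cols)
  y <- table$outcome
  list(x = x, y = y, labels = as.integer(y) - 1L, feature_names = cols)
}
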