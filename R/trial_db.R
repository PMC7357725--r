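#' Schema of the trial-observation table
#'
#' One row per treatment-control pair from an on-farm maize fertilizer
#' trial. Canonical units: yields in kg/ha, N rate in kg N/ha, total C and
#' N in g/kg, extractable P in mg/kg (Olsen scale), exchangeable cations in
#' cmol/kg, texture fractions in percent, rainfall in mm per growing
#' season, altitude in m.
#'
#' @return A data frame with columns `column`, `type` (`"character"` or
#'   `"numeric"` or `"integer"` or `"logical"`), `required` and `unit`,
#'   one row per schema column.
#' @export
trial_schema <- function() {
  rbind(
    data.frame(column = c("study_id", "site_id", "region", "soil_order",
                          "texture_class", "aez", "nutrient_type", "manager"),
               type = "character",
               required = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
               unit = ""),
    data.frame(column = c("yield_t_mean", "yield_c_mean", "yield_t_sd",
                          "yield_c_sd", "yield_t_se", "yield_c_se",
                          "yield_t_cv", "yield_c_cv"),
               type = "numeric",
               required = c(TRUE, TRUE, rep(FALSE, 6)),
               unit = c(rep("kg/ha", 6), "%", "%")),
    data.frame(column = c("n_t", "n_c"), type = "integer", required = TRUE,
               unit = "count"),
    data.frame(column = "n_rate", type = "numeric", required = TRUE,
               unit = "kg N/ha"),
    data.frame(column = c("soil_ph", "total_c", "total_n", "p_olsen",
                          "p_bray1", "p_bray2", "exch_k", "exch_ca",
                          "exch_mg", "clay", "sand", "silt", "rainfall",
                          "altitude"),
               type = "numeric", required = FALSE,
               unit = c("", "g/kg", "g/kg", "mg/kg", "mg/kg", "mg/kg",
                        "cmol/kg", "cmol/kg", "cmol/kg", "%", "%", "%",
                        "mm", "m")),
    data.frame(column = c("sd_imputed_flag", "p_olsen_converted"),
               type = "logical", required = FALSE, unit = "")
  )
}

.schema_cols <- function() trial_schema()$column

.regions <- c("kenya", "ssa_other")
.nutrient_types <- c("N_only", "NPK")
.managers <- c("farmer", "researcher")

#' Validate trial observations against the schema invariants
#'
#' Checks positivity of yield means, non-negativity of dispersions and the
#' N rate, replicate counts of at least one, texture fractions in
#' \[0, 100\] summing (when complete) to 95-105, valid factor levels, and
#' that at most one extractable-P method carries a measured value.
#'
#' @param db Data frame in the [trial_schema()] layout.
#' @return A data frame of violations with columns `row`, `column`,
#'   `message` (zero rows when the table is valid).
#' @export
validate_trials <- function(db) {
  sch <- trial_schema()
  for (i in which(!sch$column %in% names(db)))
    db[[sch$column[i]]] <- switch(sch$type[i], character = NA_character_,
                                  numeric = NA_real_, integer = NA_integer_,
                                  logical = NA)
  bad <- list()
  note <- function(rows, column, message) {
    if (length(rows))
      bad[[length(bad) + 1L]] <<- data.frame(row = rows, column = column,
                                             message = message)
  }
  pos <- function(col) {
    v <- db[[col]]
    note(which(!is.na(v) & v <= 0), col, "must be > 0")
  }
  nonneg <- function(col) {
    v <- db[[col]]
    note(which(!is.na(v) & v < 0), col, "must be >= 0")
  }
  pos("yield_t_mean"); pos("yield_c_mean")
  for (col in c("yield_t_sd", "yield_c_sd", "yield_t_se", "yield_c_se",
                "yield_t_cv", "yield_c_cv", "n_rate",
                "p_olsen", "p_bray1", "p_bray2"))
    nonneg(col)
  for (col in c("n_t", "n_c"))
    note(which(!is.na(db[[col]]) & db[[col]] < 1), col, "must be >= 1")
  for (col in c("clay", "sand", "silt")) {
    v <- db[[col]]
    note(which(!is.na(v) & (v < 0 | v > 100)), col, "must be in [0, 100]")
  }
  tex <- db$clay + db$sand + db$silt
  note(which(!is.na(tex) & (tex < 95 | tex > 105)), "clay+sand+silt",
       "texture fractions must sum to 95-105")
  lev <- function(col, levels) {
    v <- db[[col]]
    note(which(!is.na(v) & !(v %in% levels)), col,
         paste("must be one of:", paste(levels, collapse = ", ")))
  }
  lev("region", .regions)
  lev("nutrient_type", .nutrient_types)
  lev("manager", .managers)
  # measured-P exclusivity: a converted p_olsen does not count as measured
  measured_olsen <- !is.na(db$p_olsen) &
    !(if (!is.null(db$p_olsen_converted)) db$p_olsen_converted %in% TRUE
      else FALSE)
  n_p <- measured_olsen + (!is.na(db$p_bray1)) + (!is.na(db$p_bray2))
  note(which(n_p > 1), "p_olsen/p_bray1/p_bray2",
       "at most one extractable-P method may carry a measured value")
  if (length(bad)) do.call(rbind, bad)
  else data.frame(row = integer(), column = character(), message = character())
}

.coerce_schema <- function(db) {
  sch <- trial_schema()
  for (i in seq_len(nrow(sch))) {
    col <- sch$column[i]
    if (is.null(db[[col]])) {
      db[[col]] <- switch(sch$type[i], character = NA_character_,
                          numeric = NA_real_, integer = NA_integer_,
                          logical = NA)
      next
    }
    v <- db[[col]]
    if (is.character(v)) v[!is.na(v) & v == ""] <- NA
    db[[col]] <- switch(sch$type[i],
      character = as.character(v),
      numeric = {
        w <- suppressWarnings(as.numeric(v))
        if (any(is.na(w) & !is.na(v) & trimws(as.character(v)) != ""))
          stop("non-numeric value in numeric column '", col, "'")
        w
      },
      integer = {
        w <- suppressWarnings(as.integer(as.numeric(v)))
        if (any(is.na(w) & !is.na(v) & trimws(as.character(v)) != ""))
          stop("non-numeric value in integer column '", col, "'")
        w
      },
      logical = as.logical(v))
  }
  db[, sch$column]
}

#' Read a trial-observation table from CSV
#'
#' CSV dialect is fixed: UTF-8, comma separator, `.` decimal, empty string
#' for missing. Header names are matched case-insensitively against the
#' schema. Rows violating the schema invariants are reported, not dropped.
#'
#' @param path Path to a CSV file.
#' @param check If `TRUE` (default) stop when invariant violations are
#'   found; the error carries the per-row report.
#' @return A data frame in the schema layout, with attribute
#'   `"violations"` holding the validation report.
#' @export
read_trials <- function(path, check = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  db <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE,
                        fileEncoding = "UTF-8")
  names(db) <- tolower(names(db))
  sch <- trial_schema()
  mandatory <- sch$column[sch$required]
  missing_cols <- setdiff(mandatory, names(db))
  if (length(missing_cols))
    stop("mandatory column(s) missing: ", paste(missing_cols, collapse = ", "))
  db <- .coerce_schema(db)
  viol <- validate_trials(db)
  if (check && nrow(viol) > 0)
    stop("invalid trial records:\n",
         paste(sprintf("  row %d, %s: %s", viol$row, viol$column,
                       viol$message), collapse = "\n"))
  attr(db, "violations") <- viol
  db
}

#' Write a trial-observation table to CSV
#'
#' @param db Data frame in the schema layout.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(db, path) {
  utils::write.csv(db[, intersect(.schema_cols(), names(db))], path,
                   row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Convert a Bray extractable-P value to the Olsen scale
#'
#' Uses the published conversion factors P-Olsen = 0.44 P-Bray1 and
#' P-Olsen = 0.79 P-Bray2.
#'
#' @param value Extractable P, mg/kg (non-negative).
#' @param method `"bray1"` or `"bray2"`.
#' @return P on the Olsen scale, mg/kg.
#' @export
#' @examples
#' convert_p(10, "bray1")  # 4.4
#' convert_p(10, "bray2")  # 7.9
convert_p <- function(value, method = c("bray1", "bray2")) {
  method <- match.arg(method)
  if (any(value < 0, na.rm = TRUE)) stop("extractable P must be >= 0")
  value * switch(method, bray1 = 0.44, bray2 = 0.79)
}

#' Default unit-conversion rules
#'
#' Declarative multiplicative rules mapping common source units to the
#' canonical schema units. Each rule names the columns it covers and the
#' factor applied.
#'
#' @return A list of rules, each `list(columns, from, factor)`.
#' @export
default_unit_map <- function() {
  list(
    list(columns = c("yield_t_mean", "yield_c_mean", "yield_t_sd",
                     "yield_c_sd", "yield_t_se", "yield_c_se"),
         from = "t/ha", factor = 1000),
    list(columns = c("total_c", "total_n"), from = "%", factor = 10),
    list(columns = c("exch_k", "exch_ca", "exch_mg"),
         from = "mmol/kg", factor = 0.1)
  )
}

#' Harmonize a trial database into canonical units and a single P scale
#'
#' Applies declarative unit rules for any columns declared in non-canonical
#' source units, fills `p_olsen` from a Bray measurement through the fixed
#' conversion factors (with a provenance flag), and optionally relabels
#' `soil_order` through a user-supplied mapping table. A measured `p_olsen`
#' always wins over a converted one; if both a measured Olsen and a Bray
#' value are present (which the source data should not contain) the
#' measured value is kept with a warning. Idempotent.
#'
#' @param db Trial table in the schema layout.
#' @param unit_map List of rules as in [default_unit_map()].
#' @param source_units Named character vector declaring, per column, the
#'   unit the input is in; columns not named are assumed canonical.
#' @param soil_order_map Optional named character vector relabeling
#'   `soil_order` values (`old = "new"`).
#' @return The harmonized table; converted P values carry
#'   `p_olsen_converted = TRUE`.
#' @export
harmonize <- function(db, unit_map = default_unit_map(),
                      source_units = NULL, soil_order_map = NULL) {
  if (length(source_units)) {
    for (col in names(source_units)) {
      unit <- source_units[[col]]
      hit <- Filter(function(r) unit == r$from && col %in% r$columns, unit_map)
      if (!length(hit))
        stop("no unit rule for column '", col, "' in unit '", unit, "'")
      db[[col]] <- db[[col]] * hit[[1]]$factor
    }
  }
  for (col in c("p_olsen", "p_bray1", "p_bray2"))
    if (is.null(db[[col]])) db[[col]] <- NA_real_
  if (is.null(db$p_olsen_converted)) db$p_olsen_converted <- NA
  conv <- db$p_olsen_converted %in% TRUE
  measured <- !is.na(db$p_olsen) & !conv
  both <- measured & (!is.na(db$p_bray1) | !is.na(db$p_bray2))
  if (any(both))
    warning(sum(both), " record(s) have both a measured p_olsen and a ",
            "Bray value; keeping the measured p_olsen")
  fill1 <- is.na(db$p_olsen) & !is.na(db$p_bray1)
  db$p_olsen[fill1] <- convert_p(db$p_bray1[fill1], "bray1")
  db$p_olsen_converted[fill1] <- TRUE
  fill2 <- is.na(db$p_olsen) & !is.na(db$p_bray2)
  db$p_olsen[fill2] <- convert_p(db$p_bray2[fill2], "bray2")
  db$p_olsen_converted[fill2] <- TRUE
  db$p_olsen_converted[is.na(db$p_olsen_converted) & !is.na(db$p_olsen)] <- FALSE
  if (length(soil_order_map)) {
    hit <- db$soil_order %in% names(soil_order_map)
    db$soil_order[hit] <- unname(soil_order_map[db$soil_order[hit]])
  }
  db
}
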