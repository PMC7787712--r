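#' Default column mapping for field observation CSVs
#'
#' Maps the canonical record fields to the column names expected in an input
#' CSV. Override entries to ingest files with different headers.
#'
#' @return Named character vector: canonical field -> CSV column name.
#' @export
default_schema <- function() {
  c(
    crab_id = "crab_id",
    date = "date",
    site = "site",
    sex = "sex",
    carapace_width_mm = "carapace_width_mm",
    body_temp_c = "body_temp_c",
    surface_temp_c = "surface_temp_c",
    burrow_temp_c = "burrow_temp_c",
    month = "month"
  )
}

#' Month levels used throughout the package
#' @keywords internal
month_levels <- function() c("March", "May", "August", "October")

#' Size-class labels
#' @keywords internal
size_class_levels <- function() {
  c("small_female", "large_female", "small_male", "large_male", "out_of_range")
}

normalize_month <- function(x) {
  x <- trimws(as.character(x))
  # "September" is accepted as an alias for the October collection dates
  x[tolower(x) == "september"] <- "October"
  x <- tolower(x)
  paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))
}

normalize_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("f", "female")] <- "female"
  out[x %in% c("m", "male")] <- "male"
  out
}

#' Read per-crab field observations from a CSV file
#'
#' Reads a flat table of field measurements (one crab per row: sex, carapace
#' width, body temperature Tb, surface temperature S, burrow reference
#' temperature B, month, site), validates each row, and returns the accepted
#' records alongside a reason-coded validation report. Rows are never silently
#' dropped: every input row is either accepted (possibly with a flag, e.g. a
#' missing burrow reading) or rejected with a reason.
#'
#' @param path Path to a CSV file.
#' @param schema Named character vector mapping canonical field names to the
#'   file's column names; see [default_schema()].
#' @param plausibility_window Length-2 numeric, the inclusive window (degrees C)
#'   outside which a temperature is considered implausible. Default 0-60.
#' @return An object of class `record_set`: a list with elements
#'   `records` (data.frame of accepted records, one row per crab, with a
#'   `size_class` column), `validation` (data.frame with columns `row`,
#'   `crab_id`, `code`, `detail`, `disposition`), and `counts`
#'   (accepted / flagged / rejected / total).
#' @export
read_records <- function(path, schema = default_schema(),
                         plausibility_window = c(0, 60)) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", "", "NaN"))
  required <- c("sex", "carapace_width_mm", "body_temp_c", "surface_temp_c",
                "month")
  for (f in required) {
    col <- schema[[f]]
    if (is.null(col) || !col %in% names(raw)) {
      stop("required column missing from input: '", col %||% f,
           "' (field ", f, ")")
    }
  }
  validate_records(remap_columns(raw, schema),
                   plausibility_window = plausibility_window)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

remap_columns <- function(df, schema) {
  out <- data.frame(row.names = seq_len(nrow(df)))
  for (f in names(default_schema())) {
    col <- schema[[f]]
    if (!is.null(col) && col %in% names(df)) {
      out[[f]] <- df[[col]]
    } else {
      out[[f]] <- NA
    }
  }
  out
}

#' Validate a data.frame of observation records
#'
#' Applies the same row-level checks as [read_records()] to an in-memory
#' table (canonical column names). Temperatures outside the plausibility
#' window, non-positive carapace widths, unparseable numbers, unknown sex or
#' month reject the row; a missing burrow temperature only flags it (the
#' record still enters analyses that do not need B).
#'
#' @param df data.frame with canonical columns (see [default_schema()]).
#' @param plausibility_window Inclusive temperature window in degrees C.
#' @return A `record_set`; see [read_records()].
#' @export
validate_records <- function(df, plausibility_window = c(0, 60)) {
  stopifnot(length(plausibility_window) == 2,
            plausibility_window[1] < plausibility_window[2])
  n <- nrow(df)
  reports <- list()
  add_report <- function(row, id, code, detail, disposition) {
    reports[[length(reports) + 1L]] <<- data.frame(
      row = row, crab_id = as.character(id %||% NA), code = code,
      detail = detail, disposition = disposition, stringsAsFactors = FALSE)
  }

  num <- function(x) suppressWarnings(as.numeric(x))
  sex <- normalize_sex(df$sex)
  month <- normalize_month(df$month)
  cw <- num(df$carapace_width_mm)
  tb <- num(df$body_temp_c)
  s <- num(df$surface_temp_c)
  b <- num(df$burrow_temp_c)

  in_window <- function(x) {
    !is.na(x) & x >= plausibility_window[1] & x <= plausibility_window[2]
  }

  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    id <- df$crab_id[i]
    reject <- function(code, detail) {
      add_report(i, id, code, detail, "rejected")
      keep[i] <<- FALSE
    }
    if (is.na(sex[i])) reject("unknown_sex", paste0("sex = '", df$sex[i], "'"))
    if (!month[i] %in% month_levels()) {
      reject("unknown_month", paste0("month = '", df$month[i], "'"))
    }
    if (is.na(cw[i]) || cw[i] <= 0) {
      reject("bad_carapace_width",
             paste0("carapace_width_mm = '", df$carapace_width_mm[i], "'"))
    }
    for (fld in c("body_temp_c", "surface_temp_c")) {
      v <- if (fld == "body_temp_c") tb[i] else s[i]
      rawv <- df[[fld]][i]
      if (is.na(v) && !is.na(rawv)) {
        reject("unparseable_number", paste0(fld, " = '", rawv, "'"))
      } else if (is.na(v)) {
        reject("missing_field", fld)
      } else if (!in_window(v)) {
        reject("temperature_outside_plausibility_window",
               paste0(fld, " = ", v))
      }
    }
    if (keep[i]) {
      if (is.na(b[i])) {
        if (!is.na(df$burrow_temp_c[i])) {
          reject("unparseable_number",
                 paste0("burrow_temp_c = '", df$burrow_temp_c[i], "'"))
        } else {
          add_report(i, id, "no_burrow_reading",
                     "record excluded from thermoregulation-axes analyses",
                     "flagged")
        }
      } else if (!in_window(b[i])) {
        reject("temperature_outside_plausibility_window",
               paste0("burrow_temp_c = ", b[i]))
      }
    }
  }

  records <- data.frame(
    crab_id = as.character(df$crab_id),
    date = as.character(df$date),
    site = as.character(df$site),
    sex = sex,
    carapace_width_mm = cw,
    body_temp_c = tb,
    surface_temp_c = s,
    burrow_temp_c = b,
    month = month,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  if (nrow(records)) {
    records$size_class <- assign_size_class(records$sex,
                                            records$carapace_width_mm)
  } else {
    records$size_class <- character(0)
  }
  rownames(records) <- NULL

  validation <- if (length(reports)) {
    do.call(rbind, reports)
  } else {
    data.frame(row = integer(0), crab_id = character(0), code = character(0),
               detail = character(0), disposition = character(0),
               stringsAsFactors = FALSE)
  }
  flagged_rows <- unique(validation$row[validation$disposition == "flagged"])
  rejected_rows <- unique(validation$row[validation$disposition == "rejected"])
  flagged_rows <- setdiff(flagged_rows, rejected_rows)

  structure(
    list(records = records, validation = validation,
         counts = c(total = n, accepted = sum(keep),
                    flagged = length(flagged_rows),
                    rejected = length(rejected_rows))),
    class = "record_set"
  )
}

#' @export
print.record_set <- function(x, ...) {
  cat("Field observation record set\n")
  cat(sprintf("  %d rows read: %d accepted (%d flagged), %d rejected\n",
              x$counts["total"], x$counts["accepted"], x$counts["flagged"],
              x$counts["rejected"]))
  if (nrow(x$records)) {
    tab <- table(x$records$size_class)
    cat("  size classes:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    cat(sprintf("  burrow temperature present for %d of %d records\n",
                sum(!is.na(x$records$burrow_temp_c)), nrow(x$records)))
  }
  invisible(x)
}

#' Assign sex-by-size classes from carapace width
#'
#' Classes follow the field convention of splitting each sex at the midpoint
#' of the collected size range: small females 9-12.9 mm CW, large females
#' 13-17 mm, small males 10-14.9 mm, large males 15-20 mm. Interval endpoints
#' are closed. Widths strictly inside the 0.1 mm gap between the printed
#' endpoints (e.g. 12.95 mm, unreachable with a 0.1 mm caliper) are assigned
#' to the lower class. Widths outside a sex's full range map to
#' `out_of_range`.
#'
#' @param sex Character vector, "female" or "male" (vectorized, recycled
#'   against `carapace_width_mm`).
#' @param carapace_width_mm Positive numeric vector of carapace widths (mm).
#' @return Character vector of class labels; see [size_class_levels()].
#' @export
assign_size_class <- function(sex, carapace_width_mm) {
  n <- max(length(sex), length(carapace_width_mm))
  sex <- rep_len(normalize_sex(sex), n)
  cw <- rep_len(as.numeric(carapace_width_mm), n)
  if (any(is.na(cw)) || any(cw <= 0)) {
    stop("carapace_width_mm must be positive")
  }
  out <- rep("out_of_range", n)
  f <- !is.na(sex) & sex == "female"
  m <- !is.na(sex) & sex == "male"
  # gap widths (12.9, 13) and (14.9, 15) fall to the lower class
  out[f & cw >= 9 & cw < 13] <- "small_female"
  out[f & cw >= 13 & cw <= 17] <- "large_female"
  out[m & cw >= 10 & cw < 15] <- "small_male"
  out[m & cw >= 15 & cw <= 20] <- "large_male"
  out
}

#' Derive thermoregulation-axes coordinates
#'
#' Computes, per record, the cooling capacity of the burrow x = B - S and the
#' thermoregulation capacity of the crab y = Tb - S. Negative x means the
#' burrow is cooler than the surface; negative y means the crab is cooler
#' than the surface.
#'
#' @param records data.frame with columns `body_temp_c`, `surface_temp_c`,
#'   `burrow_temp_c` (a `record_set$records`, typically).
#' @param require_burrow If TRUE (default) records with a missing burrow
#'   temperature raise an error; set to FALSE to receive NA coordinates for
#'   those rows instead.
#' @return data.frame with columns `cooling_capacity_c` and
#'   `thermoreg_capacity_c`, plus all input columns.
#' @export
compute_axes <- function(records, require_burrow = TRUE) {
  stopifnot(all(c("body_temp_c", "surface_temp_c", "burrow_temp_c") %in%
                  names(records)))
  missing_b <- is.na(records$burrow_temp_c)
  if (require_burrow && any(missing_b)) {
    stop(sum(missing_b), " record(s) lack a burrow temperature and cannot ",
         "enter the thermoregulation-axes analysis; drop them or call with ",
         "require_burrow = FALSE")
  }
  records$cooling_capacity_c <- records$burrow_temp_c - records$surface_temp_c
  records$thermoreg_capacity_c <- records$body_temp_c - records$surface_temp_c
  records
}

#' Write observation records to CSV
#'
#' Temperatures are written at 0.1 degree precision and carapace widths at
#' 0.1 mm, matching the field instruments, so a written file re-reads
#' bit-identically at that declared precision.
#'
#' @param records data.frame of records (canonical columns).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  out <- records[, intersect(names(default_schema()), names(records)),
                 drop = FALSE]
  for (col in c("carapace_width_mm", "body_temp_c", "surface_temp_c",
                "burrow_temp_c")) {
    if (col %in% names(out)) {
      v <- round(as.numeric(out[[col]]), 1)
      out[[col]] <- ifelse(is.na(v), "", sprintf("%.1f", v))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
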