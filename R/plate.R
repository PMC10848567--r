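## 96-well harvesting-array data model: well addresses, sample IDs,
## specimen records and plate-level metadata I/O.

PLATE_ROWS <- LETTERS[1:8]
PLATE_COLS <- 1:12

#' Linnaean ranks tracked for each specimen
#'
#' Seven ranks, coarse to fine. Finer ranks (subgenus, subspecies) are out
#' of scope.
#' @export
TAXONOMY_RANKS <- c("phylum", "class", "order", "family", "subfamily",
                    "genus", "species")

#' Well addresses of a 96-well array
#'
#' @param row letter A..H (or a vector thereof).
#' @param column integer 1..12.
#' @return a `well_address` data frame with columns `row` and `column`,
#'   one row per address.
#' @examples
#' well_address("A", 1)
#' @export
well_address <- function(row, column) {
  row <- toupper(as.character(row))
  column <- as.integer(column)
  n <- max(length(row), length(column))
  row <- rep_len(row, n)
  column <- rep_len(column, n)
  bad <- !(row %in% PLATE_ROWS) | is.na(column) |
    column < 1L | column > 12L
  if (any(bad)) {
    stop("invalid well address: ",
         paste0(row[bad], column[bad], collapse = ", "))
  }
  structure(data.frame(row = row, column = column,
                       stringsAsFactors = FALSE),
            class = c("well_address", "data.frame"))
}

#' All 96 wells in row-major order (A01, A02, ..., H12)
#'
#' @return a `well_address` data frame of all 96 addresses.
#' @export
all_wells <- function() {
  well_address(rep(PLATE_ROWS, each = 12), rep(PLATE_COLS, times = 8))
}

#' Format a well as its zero-padded label ("A01")
#'
#' @param well a `well_address`.
#' @return character vector of labels.
#' @export
well_label <- function(well) {
  sprintf("%s%02d", well$row, well$column)
}

#' Parse well labels ("A01") back to addresses
#'
#' @param x character vector of labels.
#' @return a `well_address`.
#' @export
parse_well <- function(x) {
  ok <- grepl("^[A-H](0[1-9]|1[0-2])$", x)
  if (!all(ok)) stop("invalid well label: ", paste(x[!ok], collapse = ", "))
  well_address(substr(x, 1, 1), as.integer(substr(x, 2, 3)))
}

## Row-major index 1..96 of a well (A01 = 1, H12 = 96).
well_index <- function(well) {
  (match(well$row, PLATE_ROWS) - 1L) * 12L + well$column
}

#' Build a canonical sample identifier
#'
#' Sample IDs tie a specimen to its plate and square: plate code plus the
#' zero-padded well label, e.g. `"CCDB-31120-A01"`. The codec is a
#' bijection over valid plate codes and the 96 wells:
#' `parse_sample_id(format_sample_id(p, w))` recovers `p` and `w`.
#'
#' @param plate_code plate identifier of the form `"CCDB-"` + digits.
#' @param well a `well_address` (recycled against `plate_code`).
#' @return character vector of sample IDs.
#' @examples
#' format_sample_id("CCDB-31120", well_address("A", 1))
#' @export
format_sample_id <- function(plate_code, well) {
  if (!all(grepl("^CCDB-[0-9]+$", plate_code))) {
    stop("malformed plate code (expected \"CCDB-\" + digits): ",
         paste(plate_code[!grepl("^CCDB-[0-9]+$", plate_code)],
               collapse = ", "))
  }
  paste0(plate_code, "-", well_label(well))
}

#' Parse a sample identifier
#'
#' @param x character vector of sample IDs.
#' @return data frame with columns `plate_code`, `row`, `column`.
#' @export
parse_sample_id <- function(x) {
  ok <- grepl("^CCDB-[0-9]+-[A-H](0[1-9]|1[0-2])$", x)
  if (!all(ok)) stop("malformed sample ID: ", paste(x[!ok], collapse = ", "))
  label <- sub("^.*-", "", x)
  data.frame(plate_code = sub("-[A-H][0-9]{2}$", "", x),
             row = substr(label, 1, 1),
             column = as.integer(substr(label, 2, 3)),
             stringsAsFactors = FALSE)
}

#' Specimen records
#'
#' One row per specimen: sample ID, optional catalogue number, the seven
#' Linnaean ranks, collection year and country, and a semicolon-separated
#' set of QC flag labels. A named rank implies all coarser ranks are also
#' named (hierarchy check).
#'
#' @param sample_id canonical sample IDs.
#' @param catalogue_number museum catalogue numbers ("" if unknown).
#' @param taxonomy data frame with the columns in [TAXONOMY_RANKS]
#'   (missing columns are filled with "").
#' @param collection_year integer year, `NA` if unknown.
#' @param country country of collection.
#' @param flags character vector of flag sets (";"-separated labels).
#' @return a `specimen_record` data frame.
#' @export
specimen_record <- function(sample_id, catalogue_number = "",
                            taxonomy = NULL, collection_year = NA_integer_,
                            country = "", flags = "") {
  n <- length(sample_id)
  parse_sample_id(sample_id)  # validates
  tax <- matrix("", nrow = n, ncol = length(TAXONOMY_RANKS),
                dimnames = list(NULL, TAXONOMY_RANKS))
  if (!is.null(taxonomy)) {
    for (r in intersect(names(taxonomy), TAXONOMY_RANKS)) {
      tax[, r] <- ifelse(is.na(taxonomy[[r]]), "", as.character(taxonomy[[r]]))
    }
  }
  check_taxonomy_hierarchy(as.data.frame(tax, stringsAsFactors = FALSE))
  year <- suppressWarnings(as.integer(collection_year))
  df <- data.frame(sample_id = sample_id,
                   catalogue_number = rep_len(as.character(catalogue_number), n),
                   tax,
                   collection_year = rep_len(year, n),
                   country = rep_len(as.character(country), n),
                   flags = rep_len(as.character(flags), n),
                   stringsAsFactors = FALSE)
  structure(df, class = c("specimen_record", "data.frame"))
}

## The mandatory-rank hierarchy ignores subfamily, which is legitimately
## absent for many genera.
check_taxonomy_hierarchy <- function(tax) {
  strict <- setdiff(TAXONOMY_RANKS, "subfamily")
  for (i in seq_len(nrow(tax))) {
    named <- nzchar(unlist(tax[i, strict]))
    deepest <- if (any(named)) max(which(named)) else 0L
    if (deepest > 0L && !all(named[seq_len(deepest)])) {
      stop("taxonomy ranks are not hierarchical in row ", i,
           " (a named rank requires all coarser ranks named)")
    }
  }
  invisible(TRUE)
}

#' A 96-well harvesting plate
#'
#' Holds up to 95 specimen records plus one reserved negative-control
#' well (H12 by default: the array is filled row-major, making the 96th
#' square H12; the control square is configurable because the physical
#' layout is a lab choice).
#'
#' @param plate_code plate identifier (`"CCDB-"` + digits).
#' @param specimens a `specimen_record` data frame whose sample IDs all
#'   belong to this plate; may be empty.
#' @param control_well a single `well_address` (default H12).
#' @return a `plate_array` object.
#' @export
plate_array <- function(plate_code, specimens = specimen_record(character(0)),
                        control_well = well_address("H", 12)) {
  stopifnot(length(plate_code) == 1)
  format_sample_id(plate_code, well_address("A", 1))  # validates code
  if (nrow(control_well) != 1) stop("exactly one control well required")
  if (nrow(specimens) > 0) {
    parsed <- parse_sample_id(specimens$sample_id)
    if (any(parsed$plate_code != plate_code)) {
      stop("specimen sample IDs do not match plate code ", plate_code)
    }
    if (anyDuplicated(specimens$sample_id)) {
      stop("duplicate sample IDs: ",
           paste(unique(specimens$sample_id[duplicated(specimens$sample_id)]),
                 collapse = ", "))
    }
    ctrl_id <- format_sample_id(plate_code, control_well)
    if (ctrl_id %in% specimens$sample_id) {
      stop("cannot place a specimen in the control well ",
           well_label(control_well))
    }
  }
  if (nrow(specimens) > 95) stop("plate capacity is 95 specimen wells")
  structure(list(plate_code = plate_code,
                 specimens = specimens,
                 control_well = control_well),
            class = "plate_array")
}

#' @export
print.plate_array <- function(x, ...) {
  cat(sprintf("<plate_array> %s: %d specimen(s), control well %s\n",
              x$plate_code, nrow(x$specimens), well_label(x$control_well)))
  invisible(x)
}

#' Number of specimens on a plate
#' @param x a `plate_array`.
#' @return integer count.
#' @export
n_specimens <- function(x) nrow(x$specimens)

PLATE_TSV_COLUMNS <- c("sample_id", "catalogue_number", TAXONOMY_RANKS,
                       "collection_year", "country", "flags")

#' Read plate metadata from a TSV file
#'
#' Expects a UTF-8, tab-delimited file with a header containing at least
#' `sample_id`; taxonomy rank, `collection_year`, `country`,
#' `catalogue_number` and `flags` columns are optional. A row whose
#' well equals the control well marker (or `control_well`) is treated as
#' the reserved negative-control square, not a specimen.
#'
#' @param path TSV file path.
#' @param plate_code plate code; inferred from the sample IDs if `NULL`
#'   (the file must then contain exactly one plate).
#' @param control_well the reserved control square (default H12).
#' @return a `plate_array`.
#' @export
read_plate_metadata <- function(path, plate_code = NULL,
                                control_well = well_address("H", 12)) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character", check.names = FALSE)
  if (!"sample_id" %in% names(df)) stop("missing sample_id column in ", path)
  if (nrow(df) == 0) {
    if (is.null(plate_code)) {
      stop("cannot infer plate code from an empty table; pass plate_code")
    }
    return(plate_array(plate_code, control_well = control_well))
  }
  parsed <- parse_sample_id(df$sample_id)
  if (is.null(plate_code)) {
    plate_code <- unique(parsed$plate_code)
    if (length(plate_code) != 1) {
      stop("file contains multiple plates; pass plate_code explicitly")
    }
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample IDs in ", path, ": ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  keep <- parsed$plate_code == plate_code
  df <- df[keep, , drop = FALSE]
  parsed <- parsed[keep, , drop = FALSE]
  is_ctrl <- parsed$row == control_well$row[1] &
    parsed$column == control_well$column[1]
  df <- df[!is_ctrl, , drop = FALSE]
  year <- if ("collection_year" %in% names(df)) df$collection_year else NA
  rec <- specimen_record(
    sample_id = df$sample_id,
    catalogue_number = if ("catalogue_number" %in% names(df))
      df$catalogue_number else "",
    taxonomy = df[, intersect(names(df), TAXONOMY_RANKS), drop = FALSE],
    collection_year = ifelse(year == "" | is.na(year), NA, year),
    country = if ("country" %in% names(df)) df$country else "",
    flags = if ("flags" %in% names(df)) df$flags else ""
  )
  plate_array(plate_code, rec, control_well = control_well)
}

#' Write a submission table for one or more plates
#'
#' One row per specimen, stable column order
#' (`sample_id`, `catalogue_number`, the seven taxonomy ranks,
#' `collection_year`, `country`, `flags`), tab-delimited with a header.
#' [read_plate_metadata()] inverts it plate by plate, and writing the
#' result again is byte-identical.
#'
#' @param plates a `plate_array` or list of them.
#' @param path output file path.
#' @return (invisibly) the table written.
#' @export
write_submission_table <- function(plates, path) {
  if (inherits(plates, "plate_array")) plates <- list(plates)
  rows <- lapply(plates, function(p) as.data.frame(p$specimens))
  df <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(specimen_record(character(0)))
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample IDs across plates")
  }
  df <- df[, PLATE_TSV_COLUMNS, drop = FALSE]
  df$collection_year <- ifelse(is.na(df$collection_year), "",
                               as.character(df$collection_year))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(df)
}

#' Specimen age at time of analysis
#'
#' @param records a `specimen_record`.
#' @param analysis_year calendar year of the analysis (the study that
#'   motivates the defaults processed its specimens in 2017).
#' @return integer ages in years (`NA` where the collection year is
#'   unknown).
#' @export
specimen_age <- function(records, analysis_year = 2017) {
  if (any(!is.na(records$collection_year) &
          records$collection_year > analysis_year)) {
    stop("collection_year later than analysis_year")
  }
  analysis_year - records$collection_year
}
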