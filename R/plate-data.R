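# Plate layout, kinetic-data I/O, and the packaged day-7 endpoint table.

# md5 of the packaged endpoint-table transcription; load_table1() refuses to
# return a silently corrupted fixture.
.TABLE1_MD5 <- "b2cbda2005dbd454835492524eb2c93e"

.WELLS_96 <- paste0(rep(LETTERS[1:8], each = 12L), rep(1:12, times = 8L))

#' The 96-well FF plate layout
#'
#' Returns the well-to-substrate map of the Biolog FF filamentous-fungus
#' plate: 95 unique carbon sources plus one water (negative-control) well.
#' Wells are assigned `A1` through `H12` in the order of the packaged
#' endpoint table, with the water control last (`H12`). The physical
#' well order of the commercial plate is not encoded anywhere in the
#' analyses (only substrate identity enters any computation), so this
#' ordering is a documented convention, not a claim about plate geometry.
#'
#' @return A `plate_layout` data frame with columns `well`, `substrate`,
#'   `class` (substrate class heading, e.g. `"monosaccharides"`), and
#'   `is_control`.
#' @examples
#' layout <- ff_plate_layout()
#' nrow(layout)           # 96
#' sum(layout$is_control) # 1 (water)
#' @export
ff_plate_layout <- function() {
  tab <- load_table1()
  layout <- data.frame(
    well = .WELLS_96,
    substrate = tab$substrate,
    class = tab$class,
    is_control = tab$substrate == "water",
    stringsAsFactors = FALSE
  )
  class(layout) <- c("plate_layout", "data.frame")
  validate_plate_layout(layout)
}

validate_plate_layout <- function(layout) {
  stopifnot(is.data.frame(layout))
  need <- c("well", "substrate", "class", "is_control")
  if (!all(need %in% names(layout))) {
    stop("plate layout must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(layout) != 96L) stop("plate layout must have exactly 96 wells")
  if (anyDuplicated(layout$well)) stop("duplicated well ids in layout")
  if (sum(layout$is_control) != 1L) {
    stop("plate layout must have exactly one control (water) well")
  }
  subs <- layout$substrate[!layout$is_control]
  if (length(unique(subs)) != 95L) {
    stop("plate layout must carry 95 unique non-control substrate names")
  }
  invisible(layout)
}

parse_p_adj <- function(x) {
  x <- trimws(x)
  out <- rep(NA_real_, length(x))
  keep <- !is.na(x) & x != "NA" & x != ""
  val <- sub("^<", "", x[keep])
  out[keep] <- as.numeric(val)
  if (anyNA(out[keep])) stop("unparseable adjusted p-value entries")
  out
}

read_summary_rows <- function(path) {
  tab <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                    check.names = FALSE, fileEncoding = "UTF-8",
                    na.strings = NULL, stringsAsFactors = FALSE)
  need <- c("substrate", "class", "mean_plus", "sd_plus", "mean_minus",
            "sd_minus", "t", "df", "p_adj", "outcome")
  if (!all(need %in% names(tab))) {
    stop("summary table must have columns ", paste(need, collapse = ", "))
  }
  num <- function(col) suppressWarnings(as.numeric(ifelse(tab[[col]] == "NA",
                                                          NA, tab[[col]])))
  out <- data.frame(
    substrate = tab$substrate,
    class = tab$class,
    mean_plus = num("mean_plus"),
    sd_plus = num("sd_plus"),
    mean_minus = num("mean_minus"),
    sd_minus = num("sd_minus"),
    t = num("t"),
    df = num("df"),
    p_adj = parse_p_adj(tab$p_adj),
    p_adj_printed = tab$p_adj,
    outcome = as.integer(ifelse(tab$outcome == "NA", NA, tab$outcome)),
    is_control = tab$substrate == "water",
    stringsAsFactors = FALSE
  )
  bad <- which(!is.na(out$sd_plus) & out$sd_plus < 0 |
                 !is.na(out$sd_minus) & out$sd_minus < 0)
  if (length(bad)) stop("negative SD in summary rows: ", bad[1])
  class(out) <- c("substrate_summary", "data.frame")
  out
}

#' Load the packaged day-7 endpoint comparison table
#'
#' Reads the transcription of the published day-7 A750 endpoint comparison
#' between the EHB+ and EHB- strains shipped with the package: one row per
#' well (95 substrates plus the water control) with per-strain endpoint mean
#' and SD, Welch t and degrees of freedom, the Benjamini-Hochberg adjusted
#' p-value as printed (upper bounds such as `<0.00001` are kept verbatim in
#' `p_adj_printed` and parsed to their numeric bound in `p_adj`; printed
#' `NA` for untested, negligible-growth rows stays absent), and the printed
#' outcome code. Values are stored at printed precision (two decimals); no
#' extra digits are invented.
#'
#' @param check_integrity verify the fixture checksum before parsing
#'   (default `TRUE`); a mismatch is an error.
#' @return A `substrate_summary` data frame with 96 rows.
#' @examples
#' tab <- load_table1()
#' tab[tab$substrate == "α-D-glucose", c("mean_plus", "t", "outcome")]
#' @export
load_table1 <- function(check_integrity = TRUE) {
  path <- system.file("extdata", "table1_ff_a750_day7.tsv",
                      package = "pmcompare", mustWork = TRUE)
  if (isTRUE(check_integrity)) {
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, .TABLE1_MD5)) {
      stop("packaged endpoint table failed its checksum (", md5,
           "); the fixture appears corrupted")
    }
  }
  out <- read_summary_rows(path)
  if (nrow(out) != 96L) stop("packaged endpoint table must have 96 rows")
  out
}

#' Write / re-read substrate summary tables
#'
#' `write_summary_tsv()` writes a collection of per-substrate summary rows
#' as a UTF-8 TSV in the endpoint-table column order (substrate, class,
#' per-strain mean/SD, Welch t and df, adjusted p, outcome). Absent adjusted
#' p-values are rendered as `NA`; rows loaded from the packaged table keep
#' their printed form (e.g. `<0.00001`). `read_summary_tsv()` is the
#' inverse; writing then re-reading is the identity on values.
#'
#' @param rows a `substrate_summary` data frame (non-empty).
#' @param path file path.
#' @return `write_summary_tsv()` returns `path` invisibly;
#'   `read_summary_tsv()` returns a `substrate_summary` data frame.
#' @export
write_summary_tsv <- function(rows, path) {
  if (!is.data.frame(rows) || nrow(rows) == 0L) {
    stop("`rows` must be a non-empty collection of substrate summaries")
  }
  p_col <- if ("p_adj_printed" %in% names(rows)) {
    rows$p_adj_printed
  } else {
    ifelse(is.na(rows$p_adj), "NA", vapply(rows$p_adj, format_number, ""))
  }
  fmt <- function(x) ifelse(is.na(x), "NA", vapply(x, format_number, ""))
  out <- data.frame(
    substrate = rows$substrate,
    class = rows$class,
    mean_plus = fmt(rows$mean_plus),
    sd_plus = fmt(rows$sd_plus),
    mean_minus = fmt(rows$mean_minus),
    sd_minus = fmt(rows$sd_minus),
    t = fmt(rows$t),
    df = fmt(rows$df),
    p_adj = p_col,
    outcome = ifelse(is.na(rows$outcome), "NA", as.character(rows$outcome)),
    stringsAsFactors = FALSE,
    check.names = FALSE
  )
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary_tsv
#' @export
read_summary_tsv <- function(path) {
  read_summary_rows(path)
}

# Decimal representation that round-trips exactly: as.character() where it
# preserves the double, full 17 significant digits otherwise.
format_number <- function(x) {
  s <- as.character(x)
  bad <- is.finite(x) & suppressWarnings(as.numeric(s)) != x
  s[bad] <- sprintf("%.17g", x[bad])
  s
}

#' Assemble and validate a kinetic phenotype-microarray dataset
#'
#' A kinetic dataset holds absorbance readings indexed by strain, replicate
#' plate, well, wavelength (490 or 750 nm) and time (days). Construction
#' validates completeness: every combination of strain, replicate, well,
#' wavelength and time-grid point must be present exactly once, and all
#' absorbance values must be finite. Raw values above 3.0 (beyond the
#' measurable-growth ceiling) are legal but counted in the `n_above_upper`
#' attribute.
#'
#' @param readings data frame with columns `strain`, `replicate`, `well`,
#'   `wavelength`, `time_d`, `absorbance`.
#' @param layout optional [ff_plate_layout()]-style layout; wells are
#'   validated against it and the dataset must cover every layout well.
#' @param time_grid time grid in days; defaults to the sorted unique times
#'   present.
#' @return A `kinetic_dataset` object (list with elements `readings`,
#'   `time_grid`, `strains`, `replicates`, `wells`, `n_rep`).
#' @export
kinetic_dataset <- function(readings, layout = NULL, time_grid = NULL) {
  need <- c("strain", "replicate", "well", "wavelength", "time_d", "absorbance")
  if (!is.data.frame(readings) || !all(need %in% names(readings))) {
    stop("`readings` must be a data frame with columns ",
         paste(need, collapse = ", "))
  }
  readings <- readings[need]
  readings$strain <- as.character(readings$strain)
  readings$well <- as.character(readings$well)
  readings$replicate <- as.integer(readings$replicate)
  readings$wavelength <- as.numeric(readings$wavelength)
  readings$time_d <- as.numeric(readings$time_d)
  readings$absorbance <- as.numeric(readings$absorbance)

  if (!all(is.finite(readings$absorbance))) {
    stop("non-finite absorbance values at rows ",
         paste(utils::head(which(!is.finite(readings$absorbance)), 5L),
               collapse = ", "))
  }
  if (!all(readings$wavelength %in% c(490, 750))) {
    stop("wavelength must be 490 or 750 nm")
  }

  wells <- if (!is.null(layout)) {
    validate_plate_layout(layout)
    unknown <- setdiff(unique(readings$well), layout$well)
    if (length(unknown)) {
      stop("unknown well id(s) not in layout: ",
           paste(utils::head(unknown, 5L), collapse = ", "))
    }
    layout$well
  } else {
    sort(unique(readings$well))
  }
  if (is.null(time_grid)) time_grid <- sort(unique(readings$time_d))
  strains <- unique(readings$strain)
  replicates <- sort(unique(readings$replicate))

  key <- function(s, r, w, l, t) paste(s, r, w, l, format(t), sep = "\r")
  present <- key(readings$strain, readings$replicate, readings$well,
                 readings$wavelength, readings$time_d)
  if (anyDuplicated(present)) {
    stop("duplicated readings for ",
         gsub("\r", "/", present[anyDuplicated(present)]))
  }
  grid <- expand.grid(strain = strains, replicate = replicates, well = wells,
                      wavelength = c(490, 750), time_d = time_grid,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  expected <- key(grid$strain, grid$replicate, grid$well, grid$wavelength,
                  grid$time_d)
  gaps <- setdiff(expected, present)
  if (length(gaps)) {
    miss <- grid[match(utils::head(gaps, 5L), expected), , drop = FALSE]
    stop("incomplete kinetic dataset; missing ", length(gaps),
         " cell(s), e.g. ",
         paste(sprintf("%s rep %d well %s %g nm day %g", miss$strain,
                       miss$replicate, miss$well, miss$wavelength,
                       miss$time_d),
               collapse = "; "))
  }
  extra <- setdiff(present, expected)
  if (length(extra)) {
    stop("readings outside the declared grid, e.g. ",
         gsub("\r", "/", extra[1]))
  }

  o <- order(readings$strain != strains[1], readings$strain,
             readings$replicate, readings$well, readings$wavelength,
             readings$time_d)
  readings <- readings[o, , drop = FALSE]
  rownames(readings) <- NULL
  structure(
    list(readings = readings, time_grid = time_grid, strains = strains,
         replicates = replicates, wells = wells,
         n_rep = length(replicates)),
    n_above_upper = sum(readings$absorbance > 3.0),
    class = "kinetic_dataset"
  )
}

#' @export
print.kinetic_dataset <- function(x, ...) {
  cat("Kinetic phenotype-microarray dataset\n")
  cat("  strains:   ", paste(x$strains, collapse = ", "), "\n")
  cat("  replicates:", x$n_rep, "per strain\n")
  cat("  wells:     ", length(x$wells), "\n")
  cat("  time grid: ", length(x$time_grid), "points, day",
      min(x$time_grid), "to", max(x$time_grid), "\n")
  cat("  readings:  ", nrow(x$readings), "\n")
  flagged <- attr(x, "n_above_upper")
  if (flagged > 0) cat("  flagged:   ", flagged, "readings above 3.0\n")
  invisible(x)
}

#' Read and write kinetic plate reads as long-format CSV
#'
#' The interchange format is a UTF-8 CSV with mandatory header
#' `strain,replicate,well,wavelength,time_d,absorbance`, one row per
#' reading. `read_kinetic_csv()` validates the rows against a plate layout
#' and returns a complete [kinetic_dataset()]; missing cells, unknown well
#' ids and non-numeric absorbance values (reported with their line number)
#' are errors.
#'
#' @param path CSV file path.
#' @param layout a [ff_plate_layout()]-style layout.
#' @param dataset a `kinetic_dataset`.
#' @return `read_kinetic_csv()` returns a `kinetic_dataset`;
#'   `write_kinetic_csv()` returns `path` invisibly.
#' @export
read_kinetic_csv <- function(path, layout = ff_plate_layout()) {
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  need <- c("strain", "replicate", "well", "wavelength", "time_d", "absorbance")
  if (!identical(names(raw), need)) {
    stop("kinetic CSV must have header ", paste(need, collapse = ","))
  }
  ab <- suppressWarnings(as.numeric(raw$absorbance))
  if (anyNA(ab)) {
    lines <- which(is.na(ab)) + 1L  # +1 for the header line
    stop("non-numeric absorbance at line(s) ",
         paste(utils::head(lines, 5L), collapse = ", "))
  }
  raw$absorbance <- ab
  kinetic_dataset(raw, layout = layout)
}

#' @rdname read_kinetic_csv
#' @export
write_kinetic_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "kinetic_dataset"))
  r <- dataset$readings
  out <- data.frame(
    strain = r$strain,
    replicate = r$replicate,
    well = r$well,
    wavelength = format_number(r$wavelength),
    time_d = vapply(r$time_d, format_number, ""),
    absorbance = vapply(r$absorbance, format_number, ""),
    stringsAsFactors = FALSE
  )
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  write.table(out, con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
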