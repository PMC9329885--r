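# Readers/writers for measurement tables and study configuration, unit
# conversion, and the concentration-ratio report.

.measurement_cols <- c("experiment", "replicate", "treatment", "alive",
                       "hatched", "BL_mm", "SBA_mm2", "YSA_mm2")

#' Write a measurement table as CSV
#'
#' Columns: `experiment, replicate, treatment, alive, hatched, BL_mm,
#' SBA_mm2, YSA_mm2`; missing morphometrics (dead fish) are written as empty
#' fields. The output is re-readable by [read_measurements()].
#'
#' @param table A measurement table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(table, path) {
  stopifnot(is.data.frame(table))
  missing_cols <- setdiff(.measurement_cols, names(table))
  if (length(missing_cols) > 0) {
    stop("table is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- table[.measurement_cols]
  out$alive <- as.integer(out$alive)
  out$hatched <- as.integer(out$hatched)
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read and validate a per-fish measurement table
#'
#' Reads the CSV layout written by [write_measurements()], validates it, and
#' logs the row and per-group counts. Validation failures name the offending
#' row.
#'
#' @param path CSV file path.
#' @param design Optional [study_design()]; when given, treatment labels are
#'   validated against it.
#' @param quiet Suppress the count message (default `FALSE`).
#' @return A tibble with logical `alive`/`hatched` and numeric endpoints.
#' @export
read_measurements <- function(path, design = NULL, quiet = FALSE) {
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing_hdr <- setdiff(.measurement_cols, hdr)
  if (length(missing_hdr) > 0) {
    stop("missing column(s): ", paste(missing_hdr, collapse = ", "),
         call. = FALSE)
  }
  tab <- readr::read_csv(path, show_col_types = FALSE, na = c("", "NA"),
                         col_types = readr::cols(
                           experiment = readr::col_character(),
                           replicate = readr::col_integer(),
                           treatment = readr::col_character(),
                           alive = readr::col_integer(),
                           hatched = readr::col_integer(),
                           BL_mm = readr::col_double(),
                           SBA_mm2 = readr::col_double(),
                           YSA_mm2 = readr::col_double()
                         ))
  missing_cols <- setdiff(.measurement_cols, names(tab))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (ep in c("BL_mm", "SBA_mm2", "YSA_mm2")) {
    bad <- which(!is.na(tab[[ep]]) & tab[[ep]] < 0)
    if (length(bad) > 0) {
      stop("negative ", ep, " value at row ", bad[1], call. = FALSE)
    }
  }
  if (!is.null(design)) {
    stopifnot(inherits(design, "study_design"))
    bad_trt <- which(!tab$treatment %in% design$groups$label)
    if (length(bad_trt) > 0) {
      stop("unknown treatment label '", tab$treatment[bad_trt[1]],
           "' at row ", bad_trt[1], call. = FALSE)
    }
  }
  bad_alive <- which(!tab$alive %in% c(0L, 1L))
  if (length(bad_alive) > 0) {
    stop("alive flag not 0/1 at row ", bad_alive[1], call. = FALSE)
  }
  tab$alive <- tab$alive == 1L
  tab$hatched <- tab$hatched == 1L
  if (!quiet) {
    counts <- table(tab$treatment)
    message(sprintf("read %d records over %d groups (%s)",
                    nrow(tab), length(counts),
                    paste(sprintf("%s: %d", names(counts), counts),
                          collapse = ", ")))
  }
  tab
}

#' Convert a mass concentration to a molar concentration
#'
#' @param conc Concentration in ug/L.
#' @param molecular_weight Molecular weight in ug/uM (e.g. 500.13 for PFOS,
#'   428.17 for 6:2 FTS).
#' @return Concentration in uM.
#' @examples
#' convert_units(2066, 500.13)  # ~4.13 uM
#' @export
convert_units <- function(conc, molecular_weight) {
  stopifnot(is.numeric(conc), is.numeric(molecular_weight),
            all(molecular_weight > 0))
  conc / molecular_weight
}

#' Per-group co/index concentration ratios of a mixture regimen
#'
#' Reports the measured co-chemical to index-chemical concentration ratio in
#' each treatment group of a two-analyte regimen, rounded to integers as
#' conventionally quoted (e.g. "1:10 to 1:33"), plus the range.
#'
#' @param regimen Data frame with columns `treatment`, `conc_index`,
#'   `conc_co` (control rows with a zero index concentration are skipped).
#' @return A list with `ratios` (tibble: `treatment`, `ratio`) and
#'   `range = c(min, max)`.
#' @export
concentration_ratio_report <- function(regimen) {
  stopifnot(is.data.frame(regimen),
            all(c("treatment", "conc_index", "conc_co") %in% names(regimen)))
  keep <- regimen$conc_index > 0
  if (!any(keep)) stop("no group with a nonzero index concentration", call. = FALSE)
  ratios <- tibble::tibble(
    treatment = regimen$treatment[keep],
    ratio = round(regimen$conc_co[keep] / regimen$conc_index[keep])
  )
  list(ratios = ratios, range = range(ratios$ratio))
}

#' Write a study design and truth model to a YAML configuration
#'
#' @param design A [study_design()].
#' @param truth A [truth_model()], or `NULL` to omit.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_study_config <- function(design, truth, path) {
  stopifnot(inherits(design, "study_design"))
  cfg <- list(design = list(
    analytes = as.list(design$analytes),
    groups = lapply(seq_len(nrow(design$groups)), function(i) {
      row <- as.list(design$groups[i, ])
      row[c("label", design$analytes)]
    }),
    n_replicates = design$n_replicates,
    n_embryos_per_replicate = design$n_embryos_per_replicate,
    endpoints = as.list(design$endpoints)
  ))
  if (!is.null(truth)) {
    stopifnot(inherits(truth, "truth_model"))
    cfg$truth <- list(
      endpoints = truth$endpoints,
      weights = as.list(truth$weights),
      mortality = as.list(truth$mortality),
      hatch = as.list(truth$hatch)
    )
  }
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Read a study design (and optional truth model) from YAML
#'
#' @param path Path to a file written by [write_study_config()].
#' @return A list with elements `design` ([study_design()]) and `truth`
#'   ([truth_model()] or `NULL`).
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$design)) stop("config has no `design` section", call. = FALSE)
  d <- cfg$design
  groups <- dplyr::bind_rows(lapply(d$groups, tibble::as_tibble))
  design <- study_design(
    analytes = unlist(d$analytes),
    groups = groups,
    n_replicates = d$n_replicates,
    n_embryos_per_replicate = d$n_embryos_per_replicate,
    endpoints = unlist(d$endpoints)
  )
  truth <- NULL
  if (!is.null(cfg$truth)) {
    truth <- truth_model(
      endpoints = cfg$truth$endpoints,
      weights = unlist(cfg$truth$weights),
      mortality = unlist(cfg$truth$mortality),
      hatch = unlist(cfg$truth$hatch)
    )
  }
  list(design = design, truth = truth)
}

# read (a, b, R0) fit triples from a config section
.fits_from_config <- function(cfg) {
  lapply(cfg, function(f) linear_dr_fit(a = f$a, b = f$b, R0 = f$R0))
}
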