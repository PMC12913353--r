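#' @name dataset-io
#' @title Trial-level dataset schema and I/O
#'
#' @description
#' Observer datasets are flat delimited text with header columns
#' `observer_id`, `trial_index`, `n_flashes`, `n_beeps`, `soa_ms`, `lead`,
#' `resp_flashes`, `resp_beeps`. Counts and responses are integers in 0..2;
#' a count of 0 means the modality was absent on that trial, and the
#' corresponding response must then be `NA`. SOAs must come from the design's
#' set (0, 150, 300, 500 ms) with unisensory trials at 0. Validation reports
#' the offending row numbers.
NULL

DATASET_COLUMNS <- c("observer_id", "trial_index", "n_flashes", "n_beeps",
                     "soa_ms", "lead", "resp_flashes", "resp_beeps")

#' Validate a trial-level dataset
#'
#' Checks the standard schema (see [dataset-io]) and returns the data with
#' class `"bci_data"`. Malformed rows are rejected with row-numbered
#' diagnostics.
#'
#' @param data A data frame.
#' @return The validated dataset (class `"bci_data"`).
#' @export
validate_bci_data <- function(data) {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(DATASET_COLUMNS, names(data))
  if (length(missing_cols))
    stop("dataset is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  bad_rows <- function(cond, what) {
    rows <- which(cond)
    if (length(rows))
      stop(sprintf("%s (row%s %s)", what, if (length(rows) > 1) "s" else "",
                   paste(utils::head(rows, 10), collapse = ", ")),
           call. = FALSE)
  }
  nf <- data$n_flashes; nb <- data$n_beeps
  bad_rows(!(nf %in% 0:2), "n_flashes must be an integer in 0..2")
  bad_rows(!(nb %in% 0:2), "n_beeps must be an integer in 0..2")
  bad_rows(nf + nb < 1, "at least one modality must be present")
  bad_rows(!(data$soa_ms %in% c(0L, 150L, 300L, 500L)),
           "soa_ms must be one of 0, 150, 300, 500")
  bad_rows((nf == 0 | nb == 0) & data$soa_ms != 0,
           "unisensory trials must have soa_ms = 0")
  bad_rows(!(data$lead %in% c("visual_first", "auditory_first")),
           "lead must be 'visual_first' or 'auditory_first'")
  rf <- data$resp_flashes; rb <- data$resp_beeps
  bad_rows(nf >= 1 & (is.na(rf) | !(rf %in% 0:2)),
           "resp_flashes must be in 0..2 when flashes are present")
  bad_rows(nb >= 1 & (is.na(rb) | !(rb %in% 0:2)),
           "resp_beeps must be in 0..2 when beeps are present")
  bad_rows(nf == 0 & !is.na(rf), "resp_flashes must be NA when flashes are absent")
  bad_rows(nb == 0 & !is.na(rb), "resp_beeps must be NA when beeps are absent")
  data$n_flashes <- as.integer(nf); data$n_beeps <- as.integer(nb)
  data$soa_ms <- as.integer(data$soa_ms)
  data$resp_flashes <- as.integer(rf); data$resp_beeps <- as.integer(rb)
  if (!inherits(data, "bci_data")) class(data) <- c("bci_data", "data.frame")
  data
}

#' Read / write trial-level datasets
#'
#' `write_bci_data()` writes a dataset as CSV in the standard schema (absent
#' responses encoded as `NA`); `read_bci_data()` reads and validates one.
#' A write-then-read round trip reproduces the dataset exactly.
#'
#' @param data A `"bci_data"` dataset.
#' @param path File path.
#' @return `read_bci_data()` returns a validated `"bci_data"` data frame;
#'   `write_bci_data()` returns `path` invisibly.
#' @examples
#' d <- simulate_observer(build_design(reps = 1), seed = 1)
#' f <- tempfile(fileext = ".csv")
#' write_bci_data(d, f)
#' identical(as.data.frame(read_bci_data(f)), as.data.frame(d))
#' @export
read_bci_data <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  validate_bci_data(raw)
}

#' @rdname read_bci_data
#' @export
write_bci_data <- function(data, path) {
  data <- validate_bci_data(data)
  write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE,
            na = "NA")
  invisible(path)
}

#' Per-condition response accuracy
#'
#' Accuracy is the proportion of trials whose report equals the true count,
#' computed per condition and modality. Bimodal conditions contribute a flash
#' and a beep accuracy; unisensory conditions only the present modality's.
#'
#' @param data A `"bci_data"` dataset or a `"bci_cohort"` list of datasets
#'   (cohorts are pooled over observers).
#' @return A data frame with columns `condition`, `n_flashes`, `n_beeps`,
#'   `soa_ms`, `modality`, `n_trials`, `accuracy`.
#' @examples
#' d <- simulate_observer(build_design(reps = 2), seed = 1)
#' head(accuracy_summary(d))
#' @export
accuracy_summary <- function(data) {
  if (inherits(data, "bci_cohort") || (is.list(data) && !is.data.frame(data)))
    data <- do.call(rbind, lapply(data, as.data.frame))
  data <- validate_bci_data(as.data.frame(data))
  if (nrow(data) == 0L) stop("empty dataset", call. = FALSE)
  ct <- condition_table(data)
  key <- condition_id(data$n_flashes, data$n_beeps, data$soa_ms)
  rows <- list()
  for (i in seq_len(nrow(ct))) {
    sel <- key == ct$condition[i]
    if (ct$n_flashes[i] >= 1) {
      rows[[length(rows) + 1L]] <- data.frame(
        condition = ct$condition[i], n_flashes = ct$n_flashes[i],
        n_beeps = ct$n_beeps[i], soa_ms = ct$soa_ms[i], modality = "flash",
        n_trials = sum(sel),
        accuracy = mean(data$resp_flashes[sel] == ct$n_flashes[i]),
        stringsAsFactors = FALSE)
    }
    if (ct$n_beeps[i] >= 1) {
      rows[[length(rows) + 1L]] <- data.frame(
        condition = ct$condition[i], n_flashes = ct$n_flashes[i],
        n_beeps = ct$n_beeps[i], soa_ms = ct$soa_ms[i], modality = "beep",
        n_trials = sum(sel),
        accuracy = mean(data$resp_beeps[sel] == ct$n_beeps[i]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
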