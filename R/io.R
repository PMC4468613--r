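#' Read a wide multichannel series from CSV/TSV
#'
#' Expects a header row of channel names (or `<channel>_<wavelength>` names
#' for optical-density input) and one numeric column per channel; an optional
#' `time` column is kept. Comment lines starting with `#` are skipped. Any
#' missing or non-numeric cell fails with a message naming the row and
#' column.
#'
#' @param path File path; a `.tsv` extension switches to tab separation.
#'
#' @return Tibble of numeric columns.
#' @export
read_channel_series <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  reader <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  x <- reader(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  for (nm in names(x)) {
    col <- x[[nm]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(col)))))[1]
      abort(paste0("non-numeric cell at row ", bad %||% 1, ", column ", nm))
    }
    if (anyNA(col) || any(is.nan(col))) {
      abort(paste0("missing/NaN value at row ", which(!is.finite(col))[1],
                   ", column ", nm))
    }
  }
  x
}

#' Write a wide multichannel series to CSV with provenance comments
#'
#' @param data Data frame to write.
#' @param path Output path.
#' @param comments Character vector written as leading `# ` comment lines.
#' @return `path`, invisibly.
#' @export
write_channel_series <- function(data, path, comments = character()) {
  header <- c(
    paste0("# written by nirsfit ",
           as.character(utils::packageVersion("nirsfit"))),
    if (length(comments)) paste0("# ", comments)
  )
  writeLines(header, path)
  readr::write_csv(data, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a channel layout file
#'
#' @param path CSV with columns `channel`, `grid_row`, `grid_col`.
#' @return Layout tibble as used by [activation_map()].
#' @export
read_layout <- function(path) {
  x <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  need <- c("channel", "grid_row", "grid_col")
  if (!all(need %in% names(x))) {
    abort("layout file needs columns channel, grid_row, grid_col")
  }
  x[need]
}

#' Write the fifteen-dataset validation suite to disk
#'
#' One `dataset_<id>.csv` (time, y) plus one `dataset_<id>.json` manifest
#' (truth, seed, noise_sd, paradigm) per dataset.
#'
#' @param suite A [simulate_reference_suite()] suite.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_suite <- function(suite, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pdg <- attr(suite, "paradigm")
  for (i in seq_len(nrow(suite))) {
    id <- suite$dataset[i]
    write_channel_series(
      suite$data[[i]],
      file.path(dir, sprintf("dataset_%02d.csv", id)),
      comments = sprintf("simulated dataset %d (synthetic ground truth)", id)
    )
    manifest <- list(
      dataset = id,
      truth = as.list(suite$truth[[i]]),
      seed = suite$seed[i],
      noise_sd = suite$noise_sd[i],
      paradigm = list(
        fs = pdg$fs, rest_pre = pdg$rest_pre, task = pdg$task,
        rest_post = pdg$rest_post, n_trials = pdg$n_trials
      )
    )
    jsonlite::write_json(manifest,
                         file.path(dir, sprintf("dataset_%02d.json", id)),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
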