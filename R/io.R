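#' Write a step recording to columnar TSV
#'
#' Columns `time_ms`, `voltage_mV`, `current_pA`, `sweep_id`; protocol
#' metadata is stored in `#`-prefixed header lines so the recording can be
#' round-tripped with [read_traces_tsv()].
#'
#' @param recording a step recording tibble with a `protocol` attribute.
#' @param path output path.
#' @export
write_traces_tsv <- function(recording, path) {
  p <- recording_protocol(recording)
  hdr <- c(
    sprintf("# duration_ms: %g", p$duration_ms),
    sprintf("# onset_ms: %g", p$onset_ms),
    sprintf("# post_ms: %g", p$post_ms),
    sprintf("# sampling_khz: %g", p$sampling_khz),
    sprintf("# step_pa: %s", paste(p$step_pa, collapse = ","))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(
    data.frame(time_ms = recording$time_ms,
               voltage_mV = recording$voltage_mv,
               current_pA = recording$current_pa,
               sweep_id = recording$sweep_id),
    con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a step recording from columnar TSV
#'
#' @param path file written by [write_traces_tsv()].
#' @return A recording tibble with its `protocol` attribute restored.
#' @export
read_traces_tsv <- function(path) {
  lines <- readLines(path, n = 20)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(sprintf("^# %s: ", key), "",
                           grep(sprintf("^# %s:", key), hdr, value = TRUE))
  tbl <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#")
  out <- tibble::tibble(sweep_id = tbl$sweep_id, time_ms = tbl$time_ms,
                        voltage_mv = tbl$voltage_mV,
                        current_pa = tbl$current_pA)
  attr(out, "protocol") <- step_protocol(
    step_pa = as.numeric(strsplit(get("step_pa"), ",")[[1]]),
    duration_ms = as.numeric(get("duration_ms")),
    onset_ms = as.numeric(get("onset_ms")),
    post_ms = as.numeric(get("post_ms")),
    sampling_khz = as.numeric(get("sampling_khz"))
  )
  out
}

#' Serialize a recording cohort to JSON
#'
#' Neurons (positions in um, type labels), tested pairs, and ground-truth
#' edges, one object per recording set.
#'
#' @param cohort a `recording_cohort`.
#' @param path output path.
#' @export
write_recording_sets_json <- function(cohort, path) {
  sets <- purrr::map(split(cohort$cells, cohort$cells$set_id), function(cl) {
    s <- cl$set_id[1]
    pr <- cohort$pairs[cohort$pairs$set_id == s, ]
    list(
      set_id = s,
      neurons = cl[, c("cell_id", "cell_type", "x_um", "y_um")],
      pairs = pr[, c("cell_i", "cell_j", "distance_um", "tested",
                     "connected", "cc_true")]
    )
  })
  jsonlite::write_json(unname(sets), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Read a recording cohort from JSON
#'
#' @param path file written by [write_recording_sets_json()].
#' @return A `recording_cohort` list with `cells` and `pairs` tibbles.
#' @export
read_recording_sets_json <- function(path) {
  sets <- jsonlite::read_json(path, simplifyVector = TRUE)
  cells <- purrr::map_dfr(seq_len(nrow(sets)), function(k) {
    dplyr::mutate(tibble::as_tibble(sets$neurons[[k]]),
                  set_id = sets$set_id[k], .before = 1)
  })
  pairs <- purrr::map_dfr(seq_len(nrow(sets)), function(k) {
    pr <- tibble::as_tibble(sets$pairs[[k]])
    cl <- sets$neurons[[k]]
    pr$type_i <- cl$cell_type[match(pr$cell_i, cl$cell_id)]
    pr$type_j <- cl$cell_type[match(pr$cell_j, cl$cell_id)]
    dplyr::mutate(pr, set_id = sets$set_id[k], .before = 1)
  })
  structure(list(cells = cells, pairs = pairs), class = "recording_cohort")
}
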