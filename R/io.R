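# Plain tabular artifact I/O shared by every stage: delimited spike-event
# tables, receptive-field layout tables, and layout provenance.

#' Write / read a spike-event table
#'
#' Tab-delimited with columns `neuron_id`, `direction_deg`, `trial`,
#' `time_s`.
#'
#' @param trains a `spike_trains` data.frame.
#' @param path file path.
#' @return `read_spike_table` returns a `spike_trains` data.frame.
#' @export
write_spike_table <- function(trains, path) {
  write.table(trains[, c("neuron_id", "direction_deg", "trial", "time_s")],
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spike_table
#' @export
read_spike_table <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t")
  class(d) <- c("spike_trains", "data.frame")
  d
}

#' Write / read a receptive-field layout table
#'
#' Tab-delimited with columns `neuron_id`, `center_az`, `center_el`,
#' `diameter`, `polarity` (plus any member columns present).
#'
#' @param rfs a `receptive_fields` data.frame.
#' @param path file path.
#' @return `read_rf_table` returns a `receptive_fields` data.frame.
#' @export
write_rf_table <- function(rfs, path) {
  write.table(as.data.frame(rfs), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_rf_table
#' @export
read_rf_table <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  class(d) <- c("receptive_fields", "data.frame")
  d
}

#' Write layout provenance (template, shift, assigned trial, latency)
#'
#' @param layout a [fill_population()] result.
#' @param assigned optional `assigned_trial` attribute from
#'   [assemble_population_spikes()].
#' @param path file path.
#' @export
write_layout_provenance <- function(layout, path, assigned = NULL) {
  prov <- layout$members[, c("member_id", "template_id", "shift_az",
                             "shift_el", "anchored_sep")]
  if (!is.null(assigned))
    prov <- merge(prov, assigned[, c("member_id", "trial", "latency_s")],
                  by = "member_id")
  write.table(prov, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
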