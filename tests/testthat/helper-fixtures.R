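# Small constructors shared across test files.

make_event <- function(id, year = NA, seq_idx = NA_integer_, kind = NULL,
                       trigger = "married", flagged = FALSE,
                       confidence = 1) {
  ts <- if (is.na(year)) event_timestamp() else {
    event_timestamp(if (is.null(kind)) "absolute" else kind,
                    as.integer(year), confidence = confidence,
                    flagged_for_review = flagged)
  }
  structured_event(event_id = id, event_type = "test", trigger = trigger,
                   time = ts, source_sequence_index = seq_idx)
}

tmp_path <- function(ext = "") {
  tempfile("eventline-test-", fileext = ext)
}
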