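# small builders shared across test files

tiny_schedule <- function(per_phase = 60, block_dur = 5) {
  make_phase_schedule(per_phase, per_phase, per_phase, block_dur)
}

blocks_from_values <- function(values, schedule,
                               observed = rep(TRUE, length(values))) {
  stopifnot(length(values) == schedule$n_blocks)
  values[!observed] <- NA_real_
  structure(data.frame(block = seq_len(schedule$n_blocks),
                       phase = schedule$phase,
                       value = values, observed = observed),
            class = c("cee_blocks", "data.frame"), schedule = schedule)
}
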