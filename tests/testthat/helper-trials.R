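# Build a small trial table by hand for classification tests. `rows` is a
# list of lists with task, the four features, correct and rt; block/trial
# indices are filled in sequentially within one block unless given.
make_trials <- function(rows, participant = "p1", group = "pro",
                        mapping = 1, block = 1) {
  n <- length(rows)
  df <- do.call(rbind, lapply(seq_len(n), function(i) {
    r <- rows[[i]]
    data.frame(
      participant = participant, group = group, mapping = mapping,
      block = if (is.null(r$block)) block else r$block,
      trial = if (is.null(r$trial)) i else r$trial,
      task = r$task,
      colour = r$colour, shape = r$shape,
      vertical = r$vertical, horizontal = r$horizontal,
      correct = if (is.null(r$correct)) TRUE else r$correct,
      rt_ms = if (is.null(r$rt)) 800 else r$rt,
      stringsAsFactors = FALSE)
  }))
  df
}

# One quick error-free simulated session, reused across tests.
sim_clean_session <- function(seed = 1, id = "p1", mapping = 1) {
  simulate_participant(id, "pro", mapping = mapping,
                       params = gen_params(base_error_rate = 0,
                                           error_slope = 0),
                       seed = seed)
}
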