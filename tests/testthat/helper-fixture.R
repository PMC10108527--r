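# Shared synthetic pipeline fixture: two tagged animals, ~1.5 days of
# detections plus a tide record, written as interchange CSVs.

make_fixture <- function(dir, n_intervals = 150, seed = 141) {
  set.seed(seed)
  tide <- simulate_tide(n_intervals * 900 * 1.1, amplitude = 1,
                        datum_offset = 1)
  write_tide(tide, file.path(dir, "tide.csv"))
  beta <- trmat_to_beta(default_transition_matrix())
  dets <- lapply(c("7789", "7793"), function(tag) {
    s <- simulate_state_sequence(matrix(1, n_intervals, 1), beta, 2)
    path <- simulate_observations(s, default_emission_pars(),
                                  start_position = runif(2, -50, 50))
    simulate_detections(path, p_detect = 0.9, tag_id = tag)
  })
  write_detections(do.call(rbind, dets), file.path(dir, "detections.csv"),
                   params = list(seed = seed))
  list(detections = file.path(dir, "detections.csv"),
       tide = file.path(dir, "tide.csv"))
}

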