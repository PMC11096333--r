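# Shared fixtures: everything is generated in code at test time.

# small two-condition design: one melody per condition, {E:2, F:2, A:2, C:2}
tiny_specs <- function() {
  counts <- c(E = 2, F = 2, A = 2, C = 2)
  list(melody_spec("m1", "familiar", counts),
       melody_spec("m1s", "unfamiliar", counts))
}

tiny_schedule <- function(presentations = 6, seed = 11)
  build_schedule(tiny_specs(), presentations_per_melody = presentations,
                 omission_rate = 0.5, seed = seed)

# simulation config with tame sizes for unit tests
tiny_sim_config <- function(...) {
  args <- list(...)
  if (is.null(args$n_participants)) args$n_participants <- 2
  do.call(simulation_config, args)
}

roi_series_of <- function(time, value)
  structure(list(time = time, value = value), class = "roi_series")

# hand-built epoch set: values supplied per epoch as n_samples x n_channels
manual_epoch_set <- function(epoch_list, time = seq(-200, 300), fs = 1000,
                             channels = frontocentral_roi(),
                             labels = NULL) {
  n_ep <- length(epoch_list)
  if (is.null(labels)) labels <- rep_len(c("E", "F", "A", "C"), n_ep)
  arr <- array(0, dim = c(length(time), length(channels), n_ep))
  for (i in seq_len(n_ep)) arr[, , i] <- epoch_list[[i]]
  epoch_set(arr, time, channels, labels, fs, condition = "familiar",
            participant_id = "T01")
}

jaccard_ms <- function(a_lo, a_hi, b_lo, b_hi, grid) {
  a <- grid[grid >= a_lo & grid <= a_hi]
  b <- grid[grid >= b_lo & grid <= b_hi]
  length(intersect(a, b)) / length(union(a, b))
}
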