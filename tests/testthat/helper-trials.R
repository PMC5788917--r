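# Minimal trial tables built in code for unit tests.

toy_trials <- function(initial, social, final, condition = "face",
                       pid = "P1", gid = "G1", rule = "all") {
  n <- length(initial)
  data.frame(participant_id = rep_len(pid, n),
             group_id = rep_len(gid, n),
             block_index = 1L,
             condition = rep_len(condition, n),
             image_id = sprintf("img%02d", seq_len(n)),
             social_rule = rep_len(rule, n),
             initial_raw = initial, social_raw = social, final_raw = final,
             stringsAsFactors = FALSE)
}

toy_dataset <- function(scores = c(A = 0, B = 1, C = 3, D = 6)) {
  participants <- data.frame(participant_id = names(scores),
                             group_id = "G1",
                             orientation_score = as.integer(unname(scores)),
                             stringsAsFactors = FALSE)
  trials <- do.call(rbind, lapply(names(scores), function(p) {
    toy_trials(c(30, 60), c(50, 40), c(35, 55), pid = p)
  }))
  social_dataset(trials, participants)
}

# trials in which the social rating equals the initial rating, so the
# influence parameter is unidentified and its posterior equals its prior
uninformative_trials <- function(n_participants = 5, n_trials = 8,
                                 seed = 404) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_participants), function(p) {
    x <- round(runif(n_trials, 10, 90), 2)
    y <- round(pmin(pmax(x + rnorm(n_trials, 0, 5), 0), 100), 2)
    toy_trials(x, x, y, pid = sprintf("P%02d", p))
  }))
}
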