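# shared fixtures: toy sequence sets, random states, and brute-force
# oracles used by the sampler and acceptance tests

toy_set <- function(strings, ids = sprintf("s%d", seq_along(strings))) {
  sequence_set(unname(Map(function(x, id) {
    chars <- strsplit(x, "")[[1]]
    code <- encode_bases(chars)
    motifmix:::new_encoded_sequence(id, code,
                                    chars != toupper(chars) | code == 5L)
  }, strings, ids)))
}

random_toy <- function(n = 6, L = 20, seed = 1) {
  set.seed(seed)
  toy_set(vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1)))
}

# random valid model state over a toy set
random_state <- function(set, bg, m = 2, widths = NULL, seed = 1,
                         w_ref = 6L) {
  set.seed(seed)
  if (is.null(widths)) widths <- sample(4:8, m, replace = TRUE)
  lens <- vapply(set$sequences, function(s) s$length, integer(1))
  mode <- sample.int(m, set$n, replace = TRUE)
  pos <- vapply(seq_len(set$n), function(i)
    sample.int(lens[i] - widths[mode[i]] + 1L, 1L) - 1L, integer(1))
  rev <- sample(0:1, set$n, replace = TRUE)
  new_model_state(set, bg, m, mode, pos, rev, widths)
}

# brute-force conditional over all (mode, position, strand) candidates:
# re-insert sequence i at each candidate and softmax the from-scratch
# log posterior. Candidate order matches conditional_distribution.
brute_conditional <- function(state, i, both_strands = TRUE) {
  s <- state$set$sequences[[i]]
  rows <- list()
  for (k in seq_len(state$m)) {
    w <- state$widths[k]
    if (w > s$length) next
    for (p in 0:(s$length - w))
      for (r in if (both_strands) c(0L, 1L) else 0L)
        rows[[length(rows) + 1L]] <- c(k, p, r)
  }
  lp <- vapply(rows, function(cand) {
    st <- state
    st$mode[i] <- cand[1L]; st$pos[i] <- cand[2L]; st$rev[i] <- cand[3L]
    st <- update_counts(st, i, "add")
    model_log_posterior(st, check = TRUE)
  }, numeric(1))
  e <- exp(lp - max(lp))
  data.frame(mode = vapply(rows, `[`, numeric(1), 1L),
             pos = vapply(rows, `[`, numeric(1), 2L),
             rev = vapply(rows, `[`, numeric(1), 3L),
             prob = e / sum(e))
}

# planted 3-mode spec used by the recovery tests; sharply informative
# columns (about 1.5 bits each), uniform mode proportions, widths 8/10/12
planted3_spec <- function(seed, n = 300, L = 100) {
  plant_spec(n, L, rep(1/3, 3),
             list(consensus_pwm("TGACGTCA"),
                  consensus_pwm("GGGATTACAG"),
                  consensus_pwm("AACCGGTTAACC")),
             seed = seed)
}
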