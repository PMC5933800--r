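test_that("site_bases slices and reverse-complements", {
  s <- encode_bases("ACGTT")
  expect_equal(decode_bases(site_bases(s, 1, 3, "+")), "CGT")
  expect_equal(decode_bases(site_bases(s, 1, 3, "-")), "ACG")
  expect_equal(decode_bases(site_bases(s, 0, 5, "+")), "ACGTT")
  expect_equal(decode_bases(site_bases(encode_bases("ANG"), 0, 3, "-")), "CNT")
  expect_error(site_bases(s, 3, 3, "+"), "out of range")
})

test_that("update_counts add/remove are exact inverses and flag errors", {
  set <- random_toy(6, 15, seed = 2)
  bg <- fit_background(set, 2)
  st <- random_state(set, bg, m = 2, seed = 5)
  before <- list(st$counts, st$members)
  st2 <- update_counts(st, 3, "remove")
  st3 <- update_counts(st2, 3, "add")
  expect_identical(list(st3$counts, st3$members), before)
  expect_error(update_counts(st, 3, "add"), "already included")
  expect_error(update_counts(st2, 3, "remove"), "already excluded")
})

test_that("cached counts equal a from-scratch rebuild after many random moves", {
  set <- random_toy(8, 18, seed = 9)
  bg <- fit_background(set, 2)
  st <- random_state(set, bg, m = 3, widths = c(5L, 6L, 7L), seed = 1)
  lens <- vapply(set$sequences, `[[`, integer(1), "length")
  set.seed(33)
  for (rep in 1:300) {
    i <- sample.int(set$n, 1)
    st <- update_counts(st, i, "remove")
    k <- sample.int(3, 1)
    st$mode[i] <- k
    st$pos[i] <- sample.int(lens[i] - st$widths[k] + 1L, 1L) - 1L
    st$rev[i] <- sample(0:1, 1)
    st <- update_counts(st, i, "add")
  }
  rb <- rebuild_counts(st)
  expect_identical(rb$counts, st$counts)
  expect_identical(rb$members, st$members)
})

test_that("collapsed_site_score matches the Dirichlet-multinomial predictive", {
  hyper <- list(beta = rep(0.25, 4), alpha_gamma = 1)
  # empty mode, uniform prior mean = uniform background: score 0 when the
  # mode-choice factor is also 1 (single sequence, single mode)
  cm <- matrix(0L, 3, 4)
  site <- encode_bases("ACG")
  bgw <- 3 * log(0.25)
  expect_equal(collapsed_site_score(cm, 0L, site, hyper, bgw, 1, 1), 0)

  # one column with counts A:2 -> predictive (2 + 0.25)/(2 + 1) = 0.75
  # mode factor (2+1)/(3-1+1) = 1 cancels; predictive (2+0.25)/(2+1) = 0.75
  cm1 <- matrix(c(2L, 0L, 0L, 0L), 1, 4)
  sc <- collapsed_site_score(cm1, 2L, encode_bases("A"), hyper, 0, 3, 1)
  expect_equal(sc, log(0.75))
})

test_that("score differences equal full-posterior differences", {
  set <- random_toy(6, 16, seed = 12)
  bg <- fit_background(set, 2)
  st <- random_state(set, bg, m = 2, widths = c(5L, 6L), seed = 3)
  i <- 4L
  st <- update_counts(st, i, "remove")
  cond <- conditional_distribution(st, i)
  lp <- vapply(seq_len(nrow(cond)), function(j) {
    s2 <- st
    s2$mode[i] <- cond$mode[j]; s2$pos[i] <- cond$pos[j]; s2$rev[i] <- cond$rev[j]
    model_log_posterior(update_counts(s2, i, "add"))
  }, numeric(1))
  d_score <- cond$score - cond$score[1]
  d_post <- lp - lp[1]
  expect_equal(d_score, d_post, tolerance = 1e-9)
})

test_that("model_log_posterior has a closed form for identical sites, m = 1", {
  # every site is AAAA: each motif column has counts (n,0,0,0); the
  # Dirichlet-multinomial marginal is a product of rising factorials
  set <- toy_set(rep("AAAA", 5))
  bg0 <- fit_background(toy_set("ACGT"), order = 0, pseudocount = 0)
  hyper <- list(beta = rep(0.25, 4), alpha_gamma = 1)
  st <- new_model_state(set, bg0, 1, rep(1L, 5), rep(0L, 5), rep(0L, 5), 4L,
                        hyper)
  n <- 5; w <- 4
  col_marginal <- lgamma(1) - lgamma(n + 1) + lgamma(n + 0.25) - lgamma(0.25)
  members_marginal <- lgamma(1) - lgamma(n + 1) + lgamma(n + 1) - lgamma(1)
  expect_equal(model_log_posterior(st), w * col_marginal + members_marginal)
})

test_that("log posterior is invariant to relabeling and strand flips", {
  set <- random_toy(7, 14, seed = 21)
  bg <- fit_background(set, 2)
  st <- random_state(set, bg, m = 3, widths = c(5L, 5L, 6L), seed = 8)
  lp <- model_log_posterior(st, check = TRUE)

  perm <- c(3L, 1L, 2L)
  st2 <- new_model_state(set, bg, 3, perm[st$mode], st$pos, st$rev,
                         st$widths[order(perm)], st$hyper)
  expect_equal(model_log_posterior(st2, check = TRUE), lp)

  # flipping the recorded strand of every member of a mode replaces its
  # count matrix by the reverse complement; with symmetric column priors
  # the Dirichlet-multinomial marginal (and so the posterior) is unchanged
  st_sym <- random_state(set, bg, m = 3, widths = c(5L, 5L, 6L), seed = 8)
  st_sym$hyper$beta <- rep(0.25, 4)
  lp_sym <- model_log_posterior(st_sym, check = TRUE)
  st3 <- new_model_state(set, bg, 3, st_sym$mode, st_sym$pos,
                         ifelse(st_sym$mode == 2L, 1L - st_sym$rev, st_sym$rev),
                         st_sym$widths, st_sym$hyper)
  expect_equal(model_log_posterior(st3, check = TRUE), lp_sym)
})

test_that("sequence_log_likelihood reduces to known products", {
  bg0 <- fit_background(toy_set("ACGT"), order = 0, pseudocount = 0)
  set <- toy_set("ACGT")
  hyper <- list(beta = rep(0.25, 4), alpha_gamma = 1)

  # width-2 PWM at Z = 1: bg * pwm * pwm * bg
  st <- new_model_state(set, bg0, 1, 1L, 1L, 0L, 2L, hyper)
  pwm <- matrix(0.25, 2, 4); pwm[1, 2] <- 0.5; pwm[1, -2] <- 1/6
  pwm[2, 3] <- 0.5; pwm[2, -3] <- 1/6
  params <- list(list(pwm = pwm))
  expect_equal(sequence_log_likelihood(st, bg0, 1, params),
               log(0.25 * 0.5 * 0.5 * 0.25))

  # w = L: pure PWM term
  st2 <- new_model_state(set, bg0, 1, 1L, 0L, 0L, 4L, hyper)
  pwm4 <- matrix(0.25, 4, 4)
  expect_equal(sequence_log_likelihood(st2, bg0, 1, list(list(pwm = pwm4))),
               4 * log(0.25))

  # PWM rows equal to background composition: background-only probability
  expect_equal(sequence_log_likelihood(st, bg0, 1,
                                       list(list(pwm = matrix(0.25, 2, 4)))),
               segment_log_prob(bg0, set$sequences[[1]], 0, 4))
})

test_that("mode_models normalizes PWMs and proportions", {
  set <- random_toy(9, 15, seed = 14)
  bg <- fit_background(set, 2)
  st <- random_state(set, bg, m = 3, widths = c(4L, 5L, 6L), seed = 2)
  mm <- mode_models(st)
  for (e in mm)
    expect_equal(rowSums(e$pwm), rep(1, nrow(e$pwm)), tolerance = 1e-12,
                 ignore_attr = TRUE)
  expect_equal(sum(vapply(mm, `[[`, numeric(1), "gamma_hat")), 1,
               tolerance = 1e-12)
})
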