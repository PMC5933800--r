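# Mixture-of-PWMs model state and collapsed (Dirichlet-multinomial)
# likelihood arithmetic. Each sequence carries exactly one site of its
# assigned mode (one occurrence per sequence); PWM columns and mode
# proportions are integrated out under Dirichlet priors, so the state is
# just the discrete assignments plus cached aligned base-count matrices.
#
# Internal coordinates are 0-based, half-open; strands are stored as
# rev = 0 ('+') or 1 ('-').

strand_to_rev <- function(strand) {
  if (is.numeric(strand)) return(as.integer(strand))
  ifelse(strand %in% c("-", "-1"), 1L, 0L)
}

#' Extract the oriented bases of a candidate site
#'
#' @param seq encoded sequence or integer base codes.
#' @param position 0-based start of the site.
#' @param width site width in bases.
#' @param strand `"+"` or `"-"` (or 0/1); on `"-"` the reverse complement
#'   of the window is returned. N passes through unchanged.
#' @return integer vector of `width` base codes, motif-strand oriented.
#' @export
site_bases <- function(seq, position, width, strand = "+") {
  b <- if (inherits(seq, "encoded_sequence")) seq$bases else as.integer(seq)
  if (position < 0 || position + width > length(b) || width < 1)
    stop("site [", position, ",", position + width, ") out of range")
  win <- b[(position + 1L):(position + width)]
  if (strand_to_rev(strand) == 1L) rev(BASE_COMP[win]) else win
}

#' Reverse-complement a vector of base codes
#' @param code integer base codes (1..5).
#' @return integer base codes of the reverse complement.
#' @export
revcomp_bases <- function(code) rev(BASE_COMP[code])

#' Default Dirichlet hyperparameters
#'
#' PWM column pseudocounts are the background mononucleotide frequencies
#' (total weight 1), a composition-weighted smoothing standard in Gibbs
#' motif samplers; the mode-proportion pseudocount is 1.
#'
#' @param bg a `background_model`.
#' @return list with `beta` (length-4 numeric) and `alpha_gamma`.
#' @export
default_hyper <- function(bg) {
  list(beta = as.numeric(background_frequencies(bg)), alpha_gamma = 1)
}

#' Construct a model state
#'
#' Bundles the per-sequence (mode, position, strand) assignments, the
#' per-mode widths, and the cached aligned base-count matrices the
#' collapsed sampler mutates. Background per-position log-probabilities
#' of every sequence are precomputed as prefix sums.
#'
#' @param set a [sequence_set()].
#' @param bg a `background_model`.
#' @param m number of modes.
#' @param mode,pos,rev integer vectors of length `n`: mode index (1..m),
#'   0-based site start, and strand flag (0 = `+`, 1 = `-`).
#' @param widths integer vector of `m` motif widths.
#' @param hyper Dirichlet hyperparameters; default [default_hyper()].
#' @return object of class `model_state`.
#' @export
new_model_state <- function(set, bg, m, mode, pos, rev, widths, hyper = NULL) {
  n <- set$n
  stopifnot(length(mode) == n, length(pos) == n, length(rev) == n,
            length(widths) == m, all(mode >= 1L), all(mode <= m))
  lens <- seq_lengths(set)
  if (any(bad <- pos < 0L | pos + widths[mode] > lens))
    stop("site does not fit in sequence(s): ",
         paste(seq_ids(set)[bad], collapse = ", "))
  if (is.null(hyper)) hyper <- default_hyper(bg)
  bgpref <- lapply(set$sequences, function(s) bg_prefix(bg, s))
  state <- structure(
    list(m = as.integer(m), n = n,
         mode = as.integer(mode), pos = as.integer(pos), rev = as.integer(rev),
         widths = as.integer(widths),
         counts = lapply(widths, function(w)
           matrix(0L, w, 4L, dimnames = list(NULL, BASE_LETTERS[1:4]))),
         members = integer(m),
         included = rep(FALSE, n),
         hyper = hyper, set = set, bgpref = bgpref,
         bgtotal = vapply(bgpref, function(p) p[length(p)], numeric(1))),
    class = "model_state")
  for (i in seq_len(n)) state <- update_counts(state, i, "add")
  state
}

#' Add or remove one sequence's site from the cached counts
#'
#' The member count and aligned count matrix of sequence `i`'s mode are
#' incremented/decremented by its oriented site bases. N bases at a site
#' contribute to no base cell.
#'
#' @param state a `model_state`.
#' @param i sequence index.
#' @param direction `"add"` or `"remove"`.
#' @return the updated `model_state`.
#' @export
update_counts <- function(state, i, direction = c("add", "remove")) {
  direction <- match.arg(direction)
  if (direction == "add" && state$included[i])
    stop("sequence ", i, " already included")
  if (direction == "remove" && !state$included[i])
    stop("sequence ", i, " already excluded")
  k <- state$mode[i]
  w <- state$widths[k]
  site <- site_bases(state$set$sequences[[i]], state$pos[i], w, state$rev[i])
  d <- if (direction == "add") 1L else -1L
  cm <- state$counts[[k]]
  at <- which(site != 5L)
  idx <- cbind(at, site[at])
  cm[idx] <- cm[idx] + d
  if (any(cm < 0L)) stop("internal consistency error: negative count in mode ", k)
  state$counts[[k]] <- cm
  state$members[k] <- state$members[k] + d
  if (state$members[k] < 0L) stop("internal consistency error: negative members")
  state$included[i] <- direction == "add"
  state
}

#' Rebuild count matrices from scratch from the assignments
#' @param state a `model_state` (with all sequences included).
#' @return list with `counts` (list of matrices) and `members`.
#' @export
rebuild_counts <- function(state) {
  counts <- lapply(state$widths, function(w)
    matrix(0L, w, 4L, dimnames = list(NULL, BASE_LETTERS[1:4])))
  members <- integer(state$m)
  for (i in seq_len(state$n)) {
    if (!state$included[i]) next
    k <- state$mode[i]
    site <- site_bases(state$set$sequences[[i]], state$pos[i],
                       state$widths[k], state$rev[i])
    at <- which(site != 5L)
    counts[[k]][cbind(at, site[at])] <- counts[[k]][cbind(at, site[at])] + 1L
    members[k] <- members[k] + 1L
  }
  list(counts = counts, members = members)
}

#' Collapsed predictive score of a site under one mode
#'
#' Log of the Dirichlet-multinomial predictive probability of the site's
#' oriented bases given the mode's current count matrix (which must
#' exclude the sequence being scored), times the collapsed mode-choice
#' factor `(members + alpha_gamma) / (n_total - 1 + m * alpha_gamma)`,
#' minus the background log-probability of the same window. N positions
#' contribute a factor 1 to both the motif and the background term.
#'
#' @param counts `width x 4` count matrix of the mode (excluding the
#'   scored sequence).
#' @param members number of member sequences in those counts.
#' @param site integer base codes of the oriented candidate site.
#' @param hyper list with `beta` (length 4) and `alpha_gamma`.
#' @param bg_log_prob background log-probability of the window (with
#'   true flanking context).
#' @param n_total total number of sequences in the model.
#' @param m number of modes.
#' @return scalar log score.
#' @export
collapsed_site_score <- function(counts, members, site, hyper, bg_log_prob,
                                 n_total, m) {
  if (length(site) != nrow(counts)) stop("site length != mode width")
  beta <- hyper$beta
  beta0 <- sum(beta)
  s <- log(members + hyper$alpha_gamma) -
    log(n_total - 1 + m * hyper$alpha_gamma)
  for (a in seq_along(site)) {
    b <- site[a]
    if (b == 5L) next
    tot <- sum(counts[a, ])
    s <- s + log((counts[a, b] + beta[b]) / (tot + beta0))
  }
  s - bg_log_prob
}

# log Dirichlet-multinomial marginal of a w x 4 count matrix under
# column prior beta
log_dirmult_matrix <- function(counts, beta) {
  if (nrow(counts) == 0L) return(0)
  beta0 <- sum(beta)
  rs <- rowSums(counts)
  sum(lgamma(beta0) - lgamma(rs + beta0)) +
    sum(lgamma(sweep(counts, 2L, beta, "+")) ) - nrow(counts) * sum(lgamma(beta))
}

# background log-prob of the site window of sequence i (prefix sums)
window_bg <- function(state, i, pos = state$pos[i],
                      w = state$widths[state$mode[i]]) {
  p <- state$bgpref[[i]]
  p[pos + w + 1L] - p[pos + 1L]
}

#' Collapsed log posterior of a model state
#'
#' Up to an additive constant: the sum over modes of the log
#' Dirichlet-multinomial marginal of the aligned count matrix, plus the
#' Dirichlet-multinomial marginal of the mode membership counts, plus
#' the background log-probability of every sequence outside its site.
#' This is the quantity traced for convergence and maximised.
#'
#' @param state a `model_state` (all sequences included).
#' @param check if `TRUE`, verify cached counts against a rebuild first.
#' @return scalar log posterior (unnormalised).
#' @export
model_log_posterior <- function(state, check = FALSE) {
  if (!all(state$included)) stop("all sequences must be included")
  if (check) {
    rb <- rebuild_counts(state)
    if (!identical(rb$counts, state$counts) ||
        !identical(rb$members, state$members))
      stop("inconsistent cached counts")
  }
  ag <- state$hyper$alpha_gamma
  lp <- sum(vapply(seq_len(state$m), function(k)
    log_dirmult_matrix(state$counts[[k]], state$hyper$beta), numeric(1)))
  lp <- lp + lgamma(state$m * ag) - lgamma(state$n + state$m * ag) +
    sum(lgamma(state$members + ag)) - state$m * lgamma(ag)
  for (i in seq_len(state$n))
    lp <- lp + state$bgtotal[i] - window_bg(state, i)
  lp
}

#' Posterior-mean mode models (PWMs and proportions)
#'
#' @param state a `model_state`.
#' @return list of `m` mode models, each with `pwm` (`width x 4` rows
#'   summing to 1), `members`, and `gamma_hat` (posterior-mean mode
#'   proportion; the `gamma_hat` values sum to 1 across modes).
#' @export
mode_models <- function(state) {
  ag <- state$hyper$alpha_gamma
  lapply(seq_len(state$m), function(k) {
    cm <- state$counts[[k]]
    num <- sweep(cm, 2L, state$hyper$beta, "+")
    pwm <- num / rowSums(num)
    dimnames(pwm) <- list(NULL, BASE_LETTERS[1:4])
    list(pwm = pwm, members = state$members[k],
         gamma_hat = (state$members[k] + ag) / (state$n + state$m * ag),
         width = state$widths[k])
  })
}

#' Point-estimate log-likelihood of one sequence
#'
#' Background prefix + PWM window (oriented by strand) + background
#' suffix, using the supplied point-estimate PWMs. N bases contribute a
#' factor 1 throughout.
#'
#' @param state a `model_state` (for the assignment of sequence `i`).
#' @param bg a `background_model`.
#' @param i sequence index.
#' @param params list of mode models as from [mode_models()].
#' @return scalar log-likelihood.
#' @export
sequence_log_likelihood <- function(state, bg, i, params) {
  k <- state$mode[i]
  w <- state$widths[k]
  z <- state$pos[i]
  s <- state$set$sequences[[i]]
  site <- site_bases(s, z, w, state$rev[i])
  pwm <- params[[k]]$pwm
  lp <- segment_log_prob(bg, s, 0L, z) +
    segment_log_prob(bg, s, z + w, s$length)
  for (a in seq_len(w)) if (site[a] != 5L) lp <- lp + log(pwm[a, site[a]])
  lp
}
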