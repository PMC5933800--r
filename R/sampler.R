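# Collapsed Gibbs sampling of (mode, position, strand) assignments and
# motif widths; convergence by the slope of the recent log-posterior
# trace; an update cap of 2*n^2 assignment draws; terminal hill
# climbing from the best sample. One chain per (m, seed).
#
# The R engine here is the readable reference; run_chain() dispatches to
# a C++ engine with an identical draw-for-draw RNG discipline, so both
# engines produce the same chain from the same seed.

#' Configuration of one sampling chain
#'
#' @param m number of binding modes.
#' @param seed integer RNG seed; the chain is a pure function of
#'   (data, config), so a fixed seed reproduces it exactly.
#' @param w_init initial motif width for every mode (bases).
#' @param w_min,w_max bounds on sampled widths (bases).
#' @param slope_tol convergence threshold: absolute OLS slope of the
#'   recent log-posterior trace, in log-posterior units per sweep.
#' @param trace_window number of recent sweeps the slope is fitted to;
#'   default `min(n, 50)` at run time.
#' @param max_updates cap on (position, mode) sampling events; default
#'   `2 * n^2` at run time, i.e. `2n` sweeps.
#' @param hill_climb_max_rounds cap on terminal hill-climbing rounds.
#' @param both_strands search both strands (default) or `+` only.
#' @param log_every progress interval in sweeps (sweep number, log
#'   posterior, widths); 0 disables logging.
#' @return a `chain_config` list.
#' @export
chain_config <- function(m, seed = 0L, w_init = 12L, w_min = 6L, w_max = 40L,
                         slope_tol = 1e-3, trace_window = NULL,
                         max_updates = NULL, hill_climb_max_rounds = 50L,
                         both_strands = TRUE, log_every = 0L) {
  stopifnot(m >= 1L, w_min >= 1L, w_min <= w_init, w_init <= w_max)
  structure(list(m = as.integer(m), seed = as.integer(seed),
                 w_init = as.integer(w_init), w_min = as.integer(w_min),
                 w_max = as.integer(w_max), slope_tol = slope_tol,
                 trace_window = trace_window, max_updates = max_updates,
                 hill_climb_max_rounds = as.integer(hill_climb_max_rounds),
                 both_strands = isTRUE(both_strands),
                 log_every = as.integer(log_every)),
            class = "chain_config")
}

resolve_config <- function(config, n) {
  if (is.null(config$trace_window)) config$trace_window <- min(n, 50L)
  if (is.null(config$max_updates)) config$max_updates <- 2 * n^2
  if (is.null(config$log_every)) config$log_every <- 0L
  stopifnot(config$trace_window >= 2L)
  config
}

#' Random initial state of a chain
#'
#' Positions uniform over valid starts, modes uniform over `1..m`,
#' strands uniform (when both strands are searched); all widths start at
#' `w_init`. The RNG is seeded from `config$seed` only.
#'
#' @param set a [sequence_set()].
#' @param bg a `background_model`.
#' @param config a [chain_config()].
#' @param reseed set the RNG seed from the config (default); `FALSE`
#'   continues the current RNG stream.
#' @return a `model_state`.
#' @export
init_state <- function(set, bg, config, reseed = TRUE) {
  if (reseed) set.seed(config$seed)
  n <- set$n
  lens <- seq_lengths(set)
  if (any(short <- lens < config$w_init))
    stop("sequence(s) shorter than initial width ", config$w_init, ": ",
         paste(seq_ids(set)[short], collapse = ", "))
  pos <- integer(n); mode <- integer(n); rev <- integer(n)
  for (i in seq_len(n)) {
    pos[i] <- floor(runif(1) * (lens[i] - config$w_init + 1L))
    mode[i] <- floor(runif(1) * config$m) + 1L
    rev[i] <- if (config$both_strands) as.integer(runif(1) >= 0.5) else 0L
  }
  new_model_state(set, bg, config$m, mode, pos, rev,
                  rep(config$w_init, config$m), default_hyper(bg))
}

#' Full conditional over (mode, position, strand) for one sequence
#'
#' Requires sequence `i`'s counts to be removed from the state. One
#' entry per mode (skipping modes wider than the sequence), valid
#' position, and strand, in the fixed candidate order mode-major, then
#' position, then `+` before `-`; probabilities proportional to
#' `exp(collapsed_site_score)`, normalised to sum 1.
#'
#' @param state a `model_state` with sequence `i` excluded.
#' @param i sequence index.
#' @param both_strands include `-` strand candidates.
#' @return data frame with columns `mode`, `pos` (0-based), `rev`,
#'   `score` (log), `prob`.
#' @export
conditional_distribution <- function(state, i, both_strands = TRUE) {
  if (state$included[i]) stop("sequence ", i, " must be removed first")
  s <- state$set$sequences[[i]]
  L <- s$length
  pref <- state$bgpref[[i]]
  cand_mode <- integer(0); cand_pos <- integer(0); cand_rev <- integer(0)
  score <- numeric(0)
  for (k in seq_len(state$m)) {
    w <- state$widths[k]
    if (w > L) next
    for (p in 0:(L - w)) {
      bgw <- pref[p + w + 1L] - pref[p + 1L]
      for (r in if (both_strands) c(0L, 1L) else 0L) {
        site <- site_bases(s, p, w, r)
        sc <- collapsed_site_score(state$counts[[k]], state$members[k], site,
                                   state$hyper, bgw, state$n, state$m)
        cand_mode <- c(cand_mode, k); cand_pos <- c(cand_pos, p)
        cand_rev <- c(cand_rev, r); score <- c(score, sc)
      }
    }
  }
  if (length(score) == 0L)
    stop("no valid candidate for sequence ", s$id,
         " (all mode widths exceed its length)")
  e <- exp(score - max(score))
  data.frame(mode = cand_mode, pos = cand_pos, rev = cand_rev,
             score = score, prob = e / sum(e))
}

# inverse-CDF draw over unnormalised weights e, single uniform u
draw_candidate <- function(e, u) {
  target <- u * sum(e)
  cs <- cumsum(e)
  idx <- which(cs >= target)
  if (length(idx) == 0L) length(e) else idx[1L]
}

#' Gibbs update of one sequence's assignment
#'
#' Removes sequence `i`, draws one (mode, position, strand) candidate
#' from the full conditional via a single uniform variate
#' (inverse CDF over the fixed candidate ordering), and re-adds the
#' sequence with the drawn assignment.
#'
#' @inheritParams conditional_distribution
#' @return the updated `model_state`.
#' @export
sample_assignment <- function(state, i, both_strands = TRUE) {
  u <- runif(1)
  state <- update_counts(state, i, "remove")
  cond <- conditional_distribution(state, i, both_strands)
  e <- exp(cond$score - max(cond$score))
  j <- draw_candidate(e, u)
  state$mode[i] <- cond$mode[j]
  state$pos[i] <- cond$pos[j]
  state$rev[i] <- cond$rev[j]
  update_counts(state, i, "add")
}

# width move candidates, in the fixed order used for sampling and
# hill climbing. Start/end deltas are given per strand: a motif-left
# move touches the 5' end of the motif, which is the window start for
# '+' members and the window end for '-' members.
WIDTH_MOVES <- data.frame(
  move = c("none", "grow_left", "shrink_left", "grow_right", "shrink_right"),
  dw   = c(0L, 1L, -1L, 1L, -1L),
  ds_f = c(0L, -1L, 1L, 0L, 0L),  de_f = c(0L, 0L, 0L, 1L, -1L),
  ds_r = c(0L, 0L, 0L, -1L, 1L),  de_r = c(0L, 1L, -1L, 0L, 0L),
  stringsAsFactors = FALSE)

# score and feasibility of all width moves for mode k; returns a data
# frame of feasible candidates with new starts per member attached
width_candidates <- function(state, k) {
  idx <- which(state$mode == k & state$included)
  w <- state$widths[k]
  lens <- seq_lengths(state$set)
  out <- list()
  for (j in seq_len(nrow(WIDTH_MOVES))) {
    mv <- WIDTH_MOVES[j, ]
    nw <- w + mv$dw
    if (nw < 1L || (mv$dw != 0L && (nw < state$w_min_eff || nw > state$w_max_eff)))
      next
    ds <- ifelse(state$rev[idx] == 1L, mv$ds_r, mv$ds_f)
    de <- ifelse(state$rev[idx] == 1L, mv$de_r, mv$de_f)
    ns <- state$pos[idx] + ds
    ne <- state$pos[idx] + w + de
    if (any(ns < 0L) || any(ne > lens[idx])) next
    cm <- matrix(0L, nw, 4L)
    bgsum <- 0
    for (t in seq_along(idx)) {
      i <- idx[t]
      site <- site_bases(state$set$sequences[[i]], ns[t], nw, state$rev[i])
      at <- which(site != 5L)
      cm[cbind(at, site[at])] <- cm[cbind(at, site[at])] + 1L
      pref <- state$bgpref[[i]]
      bgsum <- bgsum + pref[ne[t] + 1L] - pref[ns[t] + 1L]
    }
    out[[length(out) + 1L]] <-
      list(move = mv$move, width = nw, new_start = ns,
           counts = cm, score = log_dirmult_matrix(cm, state$hyper$beta) - bgsum)
  }
  out
}

#' Gibbs update of all mode widths
#'
#' For each mode in turn, each width is allowed to stay, or to grow or
#' shrink by one position at the motif's left or right end. A candidate
#' is feasible iff the new width lies in `[w_min, w_max]` and every
#' member sequence can host the shifted window. Candidates are scored
#' by the collapsed Dirichlet-multinomial marginal of the realigned
#' count matrix minus the background log-probability of the member bases
#' the new window covers, and one is drawn proportional to
#' `exp(score)`. A mode with no members keeps its width.
#'
#' @param state a `model_state` (all sequences included).
#' @param w_min,w_max width bounds (bases).
#' @return the updated `model_state`.
#' @export
sample_widths <- function(state, w_min = 6L, w_max = 40L) {
  state$w_min_eff <- w_min; state$w_max_eff <- w_max
  for (k in seq_len(state$m)) {
    if (state$members[k] == 0L) next
    cands <- width_candidates(state, k)
    u <- runif(1)
    sc <- vapply(cands, `[[`, numeric(1), "score")
    e <- exp(sc - max(sc))
    j <- draw_candidate(e, u)
    state <- apply_width_move(state, k, cands[[j]])
  }
  state$w_min_eff <- NULL; state$w_max_eff <- NULL
  state
}

apply_width_move <- function(state, k, cand) {
  if (cand$move == "none") return(state)
  idx <- which(state$mode == k & state$included)
  state$pos[idx] <- cand$new_start
  state$widths[k] <- cand$width
  cm <- cand$counts
  dimnames(cm) <- list(NULL, BASE_LETTERS[1:4])
  state$counts[[k]] <- cm
  state
}

#' One full Gibbs sweep
#'
#' Assignment updates for every sequence in fixed index order, then a
#' width update per mode; appends the log posterior to the state trace.
#'
#' @param state a `model_state`.
#' @param config a resolved [chain_config()].
#' @return the updated `model_state` (with `$trace` grown by one).
#' @export
gibbs_sweep <- function(state, config) {
  for (i in seq_len(state$n))
    state <- sample_assignment(state, i, config$both_strands)
  state <- sample_widths(state, config$w_min, config$w_max)
  state$trace <- c(state$trace, model_log_posterior(state))
  state
}

#' Slope-based convergence check
#'
#' Fits an ordinary-least-squares line through the last `window` trace
#' entries and declares convergence when the absolute slope falls below
#' `slope_tol` (log-posterior units per sweep). Fewer than `window`
#' entries: not converged.
#'
#' @param trace numeric vector of per-sweep log posteriors.
#' @param window number of recent sweeps to fit.
#' @param slope_tol slope threshold.
#' @return logical flag.
#' @export
check_convergence <- function(trace, window, slope_tol) {
  stopifnot(window >= 2L)
  if (length(trace) < window) return(FALSE)
  y <- trace[(length(trace) - window + 1L):length(trace)]
  x <- seq_along(y)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  abs(slope) < slope_tol
}

#' Deterministic hill climbing to a local posterior maximum
#'
#' Repeats rounds of: set every sequence's (mode, position, strand) to
#' the argmax of its full conditional (first candidate on ties), then
#' set every mode's width to the argmax width candidate (no-change
#' first on ties); stops when a full round changes nothing or
#' `max_rounds` is reached. Uses no RNG; the log posterior is
#' non-decreasing at every single move.
#'
#' @param state a `model_state`.
#' @param config a resolved [chain_config()].
#' @param max_rounds round cap.
#' @return the climbed `model_state`.
#' @export
hill_climb <- function(state, config, max_rounds = config$hill_climb_max_rounds) {
  for (round in seq_len(max_rounds)) {
    changed <- FALSE
    for (i in seq_len(state$n)) {
      state <- update_counts(state, i, "remove")
      cond <- conditional_distribution(state, i, config$both_strands)
      j <- which.max(cond$score)
      if (cond$mode[j] != state$mode[i] || cond$pos[j] != state$pos[i] ||
          cond$rev[j] != state$rev[i]) changed <- TRUE
      state$mode[i] <- cond$mode[j]; state$pos[i] <- cond$pos[j]
      state$rev[i] <- cond$rev[j]
      state <- update_counts(state, i, "add")
    }
    state$w_min_eff <- config$w_min; state$w_max_eff <- config$w_max
    for (k in seq_len(state$m)) {
      if (state$members[k] == 0L) next
      cands <- width_candidates(state, k)
      sc <- vapply(cands, `[[`, numeric(1), "score")
      j <- which.max(sc)
      if (cands[[j]]$move != "none") changed <- TRUE
      state <- apply_width_move(state, k, cands[[j]])
    }
    state$w_min_eff <- NULL; state$w_max_eff <- NULL
    if (!changed) break
  }
  state
}

#' Run one sampling chain
#'
#' Initialises from `config$seed`, sweeps until the convergence check
#' fires or the assignment-update cap (`2 n^2` by default) is reached,
#' tracks the sampled state with the highest log posterior, and hill
#' climbs from it.
#'
#' @param set a [sequence_set()].
#' @param bg a `background_model`.
#' @param config a [chain_config()].
#' @param engine `"cpp"` (default, fast) or `"r"` (reference); both
#'   follow the same draw-for-draw RNG discipline.
#' @return a `chain_result` with `best_state`, `map_log_post`, `trace`,
#'   `sweeps_run`, `converged`, `updates`.
#' @export
run_chain <- function(set, bg, config, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  config <- resolve_config(config, set$n)
  if (engine == "cpp") return(run_chain_cpp(set, bg, config))
  state <- init_state(set, bg, config)
  state$trace <- numeric(0)
  updates <- 0
  best <- NULL; best_lp <- -Inf
  converged <- FALSE
  repeat {
    state <- gibbs_sweep(state, config)
    updates <- updates + state$n
    lp <- state$trace[length(state$trace)]
    if (config$log_every > 0L && length(state$trace) %% config$log_every == 0L)
      message(sprintf("sweep %d: log posterior %.3f, widths %s",
                      length(state$trace), lp,
                      paste(state$widths, collapse = ",")))
    if (lp > best_lp) { best_lp <- lp; best <- state }
    if (check_convergence(state$trace, config$trace_window, config$slope_tol)) {
      converged <- TRUE; break
    }
    if (updates >= config$max_updates) break
  }
  trace <- state$trace
  best$trace <- NULL
  best <- hill_climb(best, config)
  structure(list(best_state = best,
                 map_log_post = model_log_posterior(best),
                 trace = trace, sweeps_run = length(trace),
                 converged = converged, updates = updates,
                 config = config),
            class = "chain_result")
}

run_chain_cpp <- function(set, bg, config) {
  set.seed(config$seed)
  lens <- seq_lengths(set)
  if (any(short <- lens < config$w_init))
    stop("sequence(s) shorter than initial width ", config$w_init, ": ",
         paste(seq_ids(set)[short], collapse = ", "))
  hyper <- default_hyper(bg)
  seqs <- lapply(set$sequences, function(s) s$bases - 1L)  # 0..3, 4=N
  pref <- lapply(set$sequences, function(s) bg_prefix(bg, s))
  res <- cpp_run_chain(seqs, pref, hyper$beta, hyper$alpha_gamma,
                       config$m, config$w_init, config$w_min, config$w_max,
                       config$slope_tol, config$trace_window,
                       config$max_updates, config$hill_climb_max_rounds,
                       config$both_strands, config$log_every)
  best <- new_model_state(set, bg, config$m, res$mode, res$pos, res$rev,
                          res$widths, hyper)
  structure(list(best_state = best,
                 map_log_post = model_log_posterior(best),
                 trace = res$trace, sweeps_run = length(res$trace),
                 converged = res$converged, updates = res$updates,
                 config = config),
            class = "chain_result")
}

#' @export
print.chain_result <- function(x, ...) {
  cat(sprintf(
    "chain_result: m=%d, MAP log posterior %.3f, %d sweeps (%s), widths %s\n",
    x$best_state$m, x$map_log_post, x$sweeps_run,
    if (x$converged) "converged" else "update cap",
    paste(x$best_state$widths, collapse = ",")))
  invisible(x)
}
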