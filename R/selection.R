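# Bayesian selection of the number of modes: chains across an m range,
# MAP plug-in for the model evidence, and a prior exponential in the
# number of free parameters.

#' Number of free parameters of a model state
#'
#' Three free entries per PWM column plus `m - 1` free mode
#' proportions: `sum_k 3 * w_k + (m - 1)`, with the fitted widths of the
#' state.
#'
#' @param state a `model_state`.
#' @return integer parameter count.
#' @export
count_free_parameters <- function(state) {
  as.integer(3L * sum(state$widths) + (state$m - 1L))
}

#' Selection score of a fitted chain
#'
#' MAP log posterior minus `lambda` times the free-parameter count,
#' implementing a model prior exponential in the parameter count. The
#' score is comparable across values of m: the proportionality
#' constants dropped from the posterior are identical across models.
#'
#' @param result a `chain_result`.
#' @param lambda penalty per free parameter (default 5).
#' @return scalar selection score.
#' @export
selection_score <- function(result, lambda = 5) {
  result$map_log_post - lambda * count_free_parameters(result$best_state)
}

#' Deterministic per-chain seed from (base seed, m, start)
#'
#' Stable integer mixing, below 2^31, so adding starts or m values never
#' perturbs existing chains.
#'
#' @param base_seed integer base seed.
#' @param m mode count of the chain.
#' @param s start index of the chain.
#' @return integer seed.
#' @export
mix_seed <- function(base_seed, m, s) {
  p <- 2147483629
  h <- (as.numeric(base_seed) %% p)
  h <- (h * 1000003 + m * 7919) %% p
  h <- (h * 1000003 + s * 104729) %% p
  as.integer(h)
}

#' Configuration of a model search
#'
#' @param m_min,m_max range of mode counts searched (default 1..20).
#' @param n_starts random initialisations per m (default 5).
#' @param lambda free-parameter penalty of the selection score.
#' @param base_seed integer seed from which all chain seeds derive.
#' @param workers number of parallel worker processes.
#' @param ... further arguments passed to [chain_config()] (widths,
#'   convergence, strand handling, update cap).
#' @return a `search_config` list.
#' @export
search_config <- function(m_min = 1L, m_max = 20L, n_starts = 5L, lambda = 5,
                          base_seed = 0L, workers = 1L, ...) {
  stopifnot(m_min >= 1L, m_min <= m_max, n_starts >= 1L, lambda >= 0)
  structure(list(m_min = as.integer(m_min), m_max = as.integer(m_max),
                 n_starts = as.integer(n_starts), lambda = lambda,
                 base_seed = as.integer(base_seed),
                 workers = as.integer(workers), chain_args = list(...)),
            class = "search_config")
}

#' Search over the number of modes
#'
#' Runs `n_starts` chains for every m in `[m_min, m_max]`, each with a
#' seed derived deterministically from `(base_seed, m, start)`; keeps
#' the chain with the highest MAP log posterior per m and selects the m
#' maximising the selection score (ties broken toward smaller m). The
#' result is independent of the worker count and scheduling.
#'
#' @param set a [sequence_set()].
#' @param bg a `background_model`.
#' @param config a [search_config()].
#' @param engine passed to [run_chain()].
#' @return a `motif_search` with `per_m` (one entry per m: best chain,
#'   MAP, parameter count, selection score), `best_m`, and `best_model`
#'   (posterior-mean mode models plus per-sequence assignments).
#' @export
search_models <- function(set, bg, config, engine = "cpp") {
  grid <- expand.grid(s = seq_len(config$n_starts),
                      m = config$m_min:config$m_max)
  run_one <- function(g) {
    m <- grid$m[g]; s <- grid$s[g]
    cc <- do.call(chain_config,
                  c(list(m = m, seed = mix_seed(config$base_seed, m, s)),
                    config$chain_args))
    res <- tryCatch(run_chain(set, bg, cc, engine = engine),
                    error = function(e)
                      stop("chain (m=", m, ", start=", s, ") failed: ",
                           conditionMessage(e), call. = FALSE))
    res
  }
  nw <- max(1L, config$workers)
  chains <- if (nw > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(nrow(grid)), run_one, mc.cores = nw,
                       mc.preschedule = TRUE)
  } else {
    lapply(seq_len(nrow(grid)), run_one)
  }
  for (ch in chains) if (inherits(ch, "try-error")) stop(ch)
  ms <- config$m_min:config$m_max
  per_m <- lapply(ms, function(m) {
    rows <- which(grid$m == m)
    maps <- vapply(chains[rows], function(r) r$map_log_post, numeric(1))
    best <- chains[[rows[which.max(maps)]]]
    list(m = m, result = best, map_log_post = best$map_log_post,
         n_params = count_free_parameters(best$best_state),
         selection_score = selection_score(best, config$lambda),
         converged = best$converged, sweeps = best$sweeps_run)
  })
  scores <- vapply(per_m, `[[`, numeric(1), "selection_score")
  best_i <- which.max(scores)   # first max: ties go to smaller m
  best_state <- per_m[[best_i]]$result$best_state
  assignments <- data.frame(
    id = seq_ids(set), mode = best_state$mode, pos = best_state$pos,
    rev = best_state$rev, stringsAsFactors = FALSE)
  structure(list(per_m = per_m, best_m = ms[best_i],
                 best_model = list(modes = mode_models(best_state),
                                   assignments = assignments),
                 config = config),
            class = "motif_search")
}

#' @export
print.motif_search <- function(x, ...) {
  cat("motif_search over m =", x$config$m_min, "..", x$config$m_max,
      "; best m =", x$best_m, "\n")
  tab <- summary_table(x)
  print(tab, row.names = FALSE)
  invisible(x)
}

summary_table <- function(search) {
  do.call(rbind, lapply(search$per_m, function(e)
    data.frame(m = e$m, map_log_post = e$map_log_post,
               n_params = e$n_params, selection_score = e$selection_score,
               converged = e$converged, sweeps = e$sweeps)))
}
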