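#' Fit a mixture-of-motifs model to ChIP-bound sequences
#'
#' Partitions the input sequences into binding modes, learning one de
#' novo PWM (with its own width) per mode by collapsed Gibbs sampling,
#' and selects the number of modes by Bayesian model selection with a
#' prior exponential in the number of free parameters.
#'
#' @param x path to a FASTA file, or a [sequence_set()].
#' @param modes integer vector (a range) of mode counts to consider.
#' @param n_starts random initialisations per mode count.
#' @param lambda penalty per free parameter in the selection score.
#' @param w_init,w_min,w_max initial and bounding motif widths (bases).
#' @param bg_order order of the Markov background model.
#' @param max_masked repeat filter: drop sequences with more masked
#'   bases than this (bp); `NULL` disables filtering.
#' @param min_length drop sequences shorter than this; defaults to
#'   `w_max` so every sequence admits a site of every mode.
#' @param both_strands search both strands (default).
#' @param seed base seed; the whole fit is deterministic given it.
#' @param workers parallel worker processes for the chain grid.
#' @param sweep_factor update cap = `sweep_factor * n^2` assignment draws.
#' @param slope_tol,trace_window convergence rule: stop when the OLS
#'   slope of the last `trace_window` per-sweep log posteriors is below
#'   `slope_tol` (window defaults to `min(n, 50)`).
#' @param hill_climb_max_rounds cap on terminal hill-climbing rounds.
#' @param engine `"cpp"` (default) or `"r"` reference sampler.
#' @return an object of class `motif_mix` with components `search` (the
#'   full per-m results), `set`, `bg`, `config`, `call`. Methods:
#'   `print`, `summary`, `coef` (PWMs of the best model), `logLik`,
#'   `predict`, `plot`, `simulate`.
#' @examples
#' pwm <- consensus_pwm("TATAAT")
#' dat <- generate_dataset(plant_spec(40, 60, 1, list(pwm), seed = 7))
#' fit <- motif_mix(dat$set, modes = 1, n_starts = 2, w_init = 6,
#'                  w_min = 4, w_max = 10)
#' fit
#' @export
motif_mix <- function(x, modes = 1:20, n_starts = 5L, lambda = 5,
                      w_init = 12L, w_min = 6L, w_max = 40L, bg_order = 2L,
                      max_masked = 150L, min_length = NULL,
                      both_strands = TRUE, seed = 0L, workers = 1L,
                      sweep_factor = 2, slope_tol = 1e-3,
                      trace_window = NULL, hill_climb_max_rounds = 50L,
                      engine = "cpp") {
  cl <- match.call()
  set <- if (is.character(x)) read_fasta(x) else x
  if (!inherits(set, "sequence_set")) stop("x must be a FASTA path or sequence_set")
  if (!is.null(max_masked)) {
    if (is.null(min_length)) min_length <- w_max
    set <- filter_repeats(set, max_masked, min_length)
  }
  n <- set$n
  bg <- fit_background(set, order = bg_order)
  sc <- search_config(m_min = min(modes), m_max = max(modes),
                      n_starts = n_starts, lambda = lambda,
                      base_seed = seed, workers = workers,
                      w_init = w_init, w_min = w_min, w_max = w_max,
                      slope_tol = slope_tol, trace_window = trace_window,
                      max_updates = sweep_factor * n^2,
                      hill_climb_max_rounds = hill_climb_max_rounds,
                      both_strands = both_strands)
  search <- search_models(set, bg, sc, engine = engine)
  structure(list(search = search, set = set, bg = bg, config = sc,
                 call = cl),
            class = "motif_mix")
}

best_entry <- function(object) {
  ms <- vapply(object$search$per_m, `[[`, integer(1), "m")
  object$search$per_m[[which(ms == object$search$best_m)]]
}

consensus_of <- function(pwm) {
  paste(BASE_LETTERS[apply(pwm, 1L, which.max)], collapse = "")
}

#' @export
print.motif_mix <- function(x, ...) {
  e <- best_entry(x)
  cat(sprintf("motif_mix fit: %d sequences, m searched %d..%d\n",
              x$set$n, x$search$config$m_min, x$search$config$m_max))
  cat(sprintf("best model: %d mode(s), selection score %.2f (lambda = %g)\n",
              x$search$best_m, e$selection_score, x$search$config$lambda))
  mm <- x$search$best_model$modes
  for (k in seq_along(mm))
    cat(sprintf("  mode %d: width %2d, %4d sequences (gamma_hat %.3f), consensus %s\n",
                k, mm[[k]]$width, mm[[k]]$members, mm[[k]]$gamma_hat,
                consensus_of(mm[[k]]$pwm)))
  invisible(x)
}

#' @export
summary.motif_mix <- function(object, ...) {
  out <- list(table = summary_table(object$search),
              best_m = object$search$best_m,
              modes = object$search$best_model$modes, n = object$set$n)
  class(out) <- "summary.motif_mix"
  out
}

#' @export
print.summary.motif_mix <- function(x, ...) {
  cat("model selection over m (selection score = MAP log posterior - lambda * |M|):\n")
  print(x$table, row.names = FALSE)
  cat("\nbest m =", x$best_m, "\n")
  invisible(x)
}

#' @export
coef.motif_mix <- function(object, ...) {
  lapply(object$search$best_model$modes, `[[`, "pwm")
}

#' @export
logLik.motif_mix <- function(object, ...) {
  e <- best_entry(object)
  structure(e$map_log_post, df = e$n_params, class = "logLik")
}

#' Assign sequences to the fitted modes
#'
#' Scores every (mode, position, strand) candidate of each sequence
#' under the point-estimate PWMs, mode proportions and the fitted
#' background, and reports the argmax assignment.
#'
#' @param object a `motif_mix` fit.
#' @param newdata a [sequence_set()] or FASTA path; default: training set.
#' @param ... unused.
#' @return data frame with id, mode, 1-based start/end, strand, site
#'   sequence, and the log-odds score of the chosen site versus
#'   background.
#' @export
predict.motif_mix <- function(object, newdata = NULL, ...) {
  set <- if (is.null(newdata)) object$set
         else if (is.character(newdata)) read_fasta(newdata) else newdata
  mm <- object$search$best_model$modes
  logpwm <- lapply(mm, function(e) log(e$pwm))
  loggamma <- log(vapply(mm, `[[`, numeric(1), "gamma_hat"))
  widths <- vapply(mm, `[[`, integer(1), "width")
  both <- !identical(object$search$config$chain_args$both_strands, FALSE)
  out <- vector("list", set$n)
  for (i in seq_len(set$n)) {
    s <- set$sequences[[i]]
    pref <- bg_prefix(object$bg, s)
    best <- NULL; best_sc <- -Inf
    for (k in seq_along(mm)) {
      w <- widths[k]
      if (w > s$length) next
      for (p in 0:(s$length - w)) {
        bgw <- pref[p + w + 1L] - pref[p + 1L]
        for (r in if (both) c(0L, 1L) else 0L) {
          site <- site_bases(s, p, w, r)
          sc <- loggamma[k] - bgw
          for (a in seq_len(w))
            if (site[a] != 5L) sc <- sc + logpwm[[k]][a, site[a]]
          if (sc > best_sc) { best_sc <- sc; best <- c(k, p, r) }
        }
      }
    }
    if (is.null(best)) stop("sequence ", s$id, " shorter than every motif")
    out[[i]] <- data.frame(
      id = s$id, mode = best[1L], start_1based = best[2L] + 1L,
      end_1based = best[2L] + widths[best[1L]],
      strand = ifelse(best[3L] == 1L, "-", "+"),
      site_sequence = decode_bases(site_bases(s, best[2L], widths[best[1L]],
                                              best[3L])),
      score = best_sc, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Plot the model-selection curve
#'
#' Selection score (and MAP log posterior) against the number of modes;
#' the selected m is marked.
#'
#' @param x a `motif_mix` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.motif_mix <- function(x, ...) {
  tab <- summary_table(x$search)
  graphics::plot(tab$m, tab$selection_score, type = "b", pch = 19,
                 xlab = "number of modes m", ylab = "selection score", ...)
  graphics::abline(v = x$search$best_m, lty = 2, col = "grey40")
  graphics::mtext(sprintf("best m = %d", x$search$best_m), side = 3, line = 0.2)
  invisible(x)
}

#' Simulate sequence sets from the fitted model
#'
#' Draws datasets from the fitted best model read generatively: modes
#' from the posterior-mean proportions, sites from the posterior-mean
#' PWMs, background bases from the mononucleotide composition of the
#' fitted background.
#'
#' @param object a `motif_mix` fit.
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param n,length sequences per dataset and their length; default the
#'   fitted data's size and median length.
#' @param ... unused.
#' @return list of `nsim` lists, each with `set` and `truth` as from
#'   [generate_dataset()].
#' @export
simulate.motif_mix <- function(object, nsim = 1, seed = 0L, n = NULL,
                               length = NULL, ...) {
  mm <- object$search$best_model$modes
  if (is.null(n)) n <- object$set$n
  if (is.null(length))
    length <- as.integer(stats::median(seq_lengths(object$set)))
  gamma <- vapply(mm, `[[`, numeric(1), "gamma_hat")
  lapply(seq_len(nsim), function(j)
    generate_dataset(plant_spec(
      n = n, length = length, gamma = gamma / sum(gamma),
      pwms = lapply(mm, `[[`, "pwm"),
      background = as.numeric(background_frequencies(object$bg)),
      double_strand = !identical(object$search$config$chain_args$both_strands,
                                 FALSE),
      seed = as.integer(seed) + j - 1L)))
}
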