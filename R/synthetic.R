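# Synthetic sequence sets with known planted mode structure, and
# scoring of recovery against the planted truth. The generator is the
# model read generatively: mode ~ gamma, start uniform over valid
# positions, strand uniform, background bases from a Markov model, and
# site bases column-wise from the mode's PWM (reverse-complemented into
# place on the minus strand). Planting replaces background bases, so
# sequence lengths stay fixed.

#' Specification of a planted synthetic dataset
#'
#' @param n number of sequences.
#' @param length sequence length L (bases).
#' @param gamma probability vector over the K planted modes (sums to 1).
#' @param pwms list of K PWMs (`width x 4` row-stochastic matrices;
#'   widths may differ).
#' @param background a `background_model`, or a length-4 vector of
#'   mononucleotide frequencies (default uniform).
#' @param double_strand plant on both strands (default) or `+` only.
#' @param seed integer seed; generation is deterministic per seed.
#' @return a `plant_spec` list.
#' @export
plant_spec <- function(n, length, gamma, pwms, background = NULL,
                       double_strand = TRUE, seed = 0L) {
  stopifnot(abs(sum(gamma) - 1) < 1e-9, length(gamma) == length(pwms))
  for (p in pwms) {
    stopifnot(is.matrix(p), ncol(p) == 4L,
              max(abs(rowSums(p) - 1)) < 1e-9)
    if (nrow(p) > length) stop("sequence length smaller than a PWM width")
  }
  if (is.null(background)) background <- rep(0.25, 4)
  structure(list(n = as.integer(n), length = as.integer(length),
                 gamma = gamma, pwms = pwms, background = background,
                 double_strand = isTRUE(double_strand),
                 seed = as.integer(seed)),
            class = "plant_spec")
}

sample_background_bases <- function(background, L) {
  if (is.numeric(background) && !inherits(background, "background_model"))
    return(sample.int(4L, L, replace = TRUE, prob = background))
  bg <- background
  b <- integer(L)
  for (j in seq_len(L)) {
    c <- min(bg$order, j - 1L)
    idx <- if (c == 0L) 1L else context_index(b[(j - c):(j - 1L)])
    b[j] <- sample.int(4L, 1L, prob = bg$cond_prob[[c + 1L]][idx, ])
  }
  b
}

#' Generate a planted dataset with its truth table
#'
#' @param spec a [plant_spec()].
#' @return list with `set` (a [sequence_set()]) and `truth` (data frame
#'   with per-sequence `id`, true `mode`, 0-based `pos`, and `rev`
#'   strand flag).
#' @export
generate_dataset <- function(spec) {
  set.seed(spec$seed)
  K <- length(spec$pwms)
  widths <- vapply(spec$pwms, nrow, integer(1))
  sequences <- vector("list", spec$n)
  mode <- integer(spec$n); pos <- integer(spec$n); rev <- integer(spec$n)
  for (i in seq_len(spec$n)) {
    k <- sample.int(K, 1L, prob = spec$gamma)
    w <- widths[k]
    p <- sample.int(spec$length - w + 1L, 1L) - 1L
    r <- if (spec$double_strand) sample.int(2L, 1L) - 1L else 0L
    b <- sample_background_bases(spec$background, spec$length)
    site <- vapply(seq_len(w), function(a)
      sample.int(4L, 1L, prob = spec$pwms[[k]][a, ]), integer(1))
    placed <- if (r == 1L) revcomp_bases(site) else site
    b[(p + 1L):(p + w)] <- placed
    id <- sprintf("seq_%04d", i)
    sequences[[i]] <- new_encoded_sequence(id, b, rep(FALSE, spec$length))
    mode[i] <- k; pos[i] <- p; rev[i] <- r
  }
  set <- sequence_set(sequences)
  truth <- data.frame(id = seq_ids(set), mode = mode, pos = pos, rev = rev,
                      stringsAsFactors = FALSE)
  list(set = set, truth = truth)
}

#' A sharply peaked PWM from a consensus string
#'
#' Each column puts probability `dominant` on the consensus base and
#' spreads the rest evenly; `dominant = 0.94` gives about 1.5 bits of
#' information per column.
#'
#' @param consensus string over A/C/G/T.
#' @param dominant probability of the consensus base per column.
#' @return a `width x 4` PWM.
#' @export
consensus_pwm <- function(consensus, dominant = 0.94) {
  code <- encode_bases(consensus)
  stopifnot(all(code <= 4L))
  w <- length(code)
  pwm <- matrix((1 - dominant) / 3, w, 4L,
                dimnames = list(NULL, BASE_LETTERS[1:4]))
  pwm[cbind(seq_len(w), code)] <- dominant
  pwm
}

# all injective label assignments of inferred labels (1..m) to true
# labels (1..K), maximising agreement of the confusion matrix
best_label_matching <- function(conf) {
  K <- nrow(conf); m <- ncol(conf)
  small <- min(K, m)
  best <- NULL; best_agree <- -1
  recurse <- function(chosen, used, agree) {
    d <- length(chosen)
    if (d == small) {
      if (agree > best_agree) { best_agree <<- agree; best <<- chosen }
      return()
    }
    # assign inferred label d+1 (if m <= K) or true label d+1 (if K < m)
    for (cand in seq_len(max(K, m))) {
      if (used[cand]) next
      a <- if (m <= K) conf[cand, d + 1L] else conf[d + 1L, cand]
      used[cand] <- TRUE
      recurse(c(chosen, cand), used, agree + a)
      used[cand] <- FALSE
    }
  }
  recurse(integer(0), rep(FALSE, max(K, m)), 0)
  list(agree = best_agree, match = best)
}

# minimum mean absolute difference between two PWMs over all offsets
# where the shorter matrix fully overlaps the longer, both orientations
pwm_mad <- function(p1, p2) {
  rc <- function(p) p[rev(seq_len(nrow(p))), c(4L, 3L, 2L, 1L), drop = FALSE]
  one <- function(a, b) {
    if (nrow(a) > nrow(b)) { tmp <- a; a <- b; b <- tmp }
    wa <- nrow(a); wb <- nrow(b)
    min(vapply(0:(wb - wa), function(off)
      mean(abs(a - b[(off + 1L):(off + wa), , drop = FALSE])), numeric(1)))
  }
  min(one(p1, p2), one(p1, rc(p2)))
}

#' Score recovery of planted structure
#'
#' Reports (a) mode-label accuracy after optimal one-to-one matching of
#' true and inferred labels, (b) site accuracy: the fraction of
#' sequences whose inferred start is within `slack` of the true start
#' (strand-aware: when inferred and true strands disagree, the motif
#' 3' ends are compared instead of the 5' starts), and (c) per matched
#' mode, the minimum mean absolute difference between inferred
#' posterior-mean PWM and true PWM over overlapping columns, across
#' offsets and orientations.
#'
#' @param truth truth data frame from [generate_dataset()].
#' @param result a `motif_search` (its best model is scored), or a list
#'   with elements `assignments` (data frame `mode`, `pos`, `rev`),
#'   `widths`, and `pwms`.
#' @param slack positional tolerance in bases (default 1).
#' @param true_pwms list of planted PWMs (for the PWM error; optional).
#' @return list with `label_accuracy`, `site_accuracy`, `matching`,
#'   `pwm_mad` (per matched mode) and `mean_pwm_mad`.
#' @export
score_recovery <- function(truth, result, slack = 1L, true_pwms = NULL) {
  if (inherits(result, "motif_search")) {
    asn <- result$best_model$assignments
    modes <- result$best_model$modes
    widths <- vapply(modes, `[[`, integer(1), "width")
    pwms <- lapply(modes, `[[`, "pwm")
  } else {
    asn <- result$assignments; widths <- result$widths; pwms <- result$pwms
  }
  stopifnot(nrow(asn) == nrow(truth))
  K <- max(truth$mode); m <- length(widths)
  conf <- table(factor(truth$mode, levels = seq_len(K)),
                factor(asn$mode, levels = seq_len(m)))
  mb <- best_label_matching(unclass(conf))
  label_accuracy <- mb$agree / nrow(truth)
  # matched pairs (true, inferred)
  pairs <- if (m <= K) cbind(true = mb$match, inf = seq_len(m))
           else cbind(true = seq_len(K), inf = mb$match)
  tw <- if (!is.null(true_pwms)) vapply(true_pwms, nrow, integer(1)) else NULL
  d <- ifelse(asn$rev == truth$rev,
              abs(asn$pos - truth$pos),
              abs((asn$pos + widths[asn$mode]) -
                  (truth$pos + (if (is.null(tw)) widths[asn$mode] else tw[truth$mode]))))
  site_accuracy <- mean(d <= slack)
  mads <- NULL
  if (!is.null(true_pwms)) {
    mads <- apply(pairs, 1L, function(pr)
      pwm_mad(true_pwms[[pr["true"]]], pwms[[pr["inf"]]]))
    names(mads) <- paste0("true", pairs[, "true"], "_inf", pairs[, "inf"])
  }
  list(label_accuracy = label_accuracy, site_accuracy = site_accuracy,
       matching = pairs, pwm_mad = mads,
       mean_pwm_mad = if (is.null(mads)) NA_real_ else mean(mads))
}

#' Write a truth table as TSV (1-based coordinates)
#' @param truth truth data frame from [generate_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  out <- data.frame(id = truth$id, mode = truth$mode,
                    start_1based = truth$pos + 1L,
                    strand = ifelse(truth$rev == 1L, "-", "+"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
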