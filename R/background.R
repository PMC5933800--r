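# Order-k Markov background model of the whole dataset, with lower-order
# tables for sequence starts. Fitted once from the input and frozen.

context_index <- function(bases) {
  # bases: integer codes 1..4, most recent last -> 1-based row index in 4^c table
  c <- length(bases)
  if (c == 0L) return(1L)
  idx <- 0L
  for (b in bases) idx <- idx * 4L + (b - 1L)
  idx + 1L
}

context_label <- function(row, c) {
  if (c == 0L) return(".")
  idx <- row - 1L
  out <- integer(c)
  for (j in c:1) { out[j] <- idx %% 4L; idx <- idx %/% 4L }
  paste(BASE_LETTERS[out + 1L], collapse = "")
}

#' Fit the Markov background model
#'
#' Fits an order-`order` Markov chain over A/C/G/T from all sequences of
#' the set (given strands only; no reverse-complement pooling). For each
#' context length `c` in `0..order`, counts of each base following each
#' c-mer are accumulated over all windows of the data; windows containing
#' an N are skipped. Conditional probabilities are
#' `(count + pseudocount) / (context_total + 4 * pseudocount)`.
#' The lower-order tables serve sequence starts, where fewer than
#' `order` preceding bases exist.
#'
#' @param set a [sequence_set()].
#' @param order Markov order (non-negative integer; default 2).
#' @param pseudocount added to every (context, base) count cell; must be
#'   positive for strictly positive probabilities (default 1).
#' @return object of class `background_model` with per-context-length
#'   count and conditional-probability tables.
#' @export
fit_background <- function(set, order = 2L, pseudocount = 1) {
  stopifnot(order >= 0L, pseudocount >= 0)
  if (!inherits(set, "sequence_set") || set$n == 0L)
    stop("empty sequence set")
  counts <- lapply(0:order, function(c) matrix(0, nrow = 4L^c, ncol = 4L,
                                               dimnames = list(NULL, BASE_LETTERS[1:4])))
  for (s in set$sequences) {
    b <- s$bases
    L <- s$length
    ok <- b != 5L
    for (c in 0:order) {
      if (L < c + 1L) next
      pos <- seq_len(L - c)                 # window start
      valid <- rep(TRUE, length(pos))
      for (j in 0:c) valid <- valid & ok[pos + j]
      if (!any(valid)) next
      pos <- pos[valid]
      idx <- rep(1L, length(pos))
      if (c > 0L) {
        idx <- integer(length(pos))
        for (j in 1:c) idx <- idx * 4L + (b[pos + j - 1L] - 1L)
        idx <- idx + 1L
      }
      tgt <- b[pos + c]
      tab <- counts[[c + 1L]]
      inc <- table(factor(idx, levels = seq_len(nrow(tab))),
                   factor(tgt, levels = 1:4))
      counts[[c + 1L]] <- tab + unclass(inc)
    }
  }
  cond <- lapply(counts, function(tab) {
    num <- tab + pseudocount
    num / rowSums(num)
  })
  structure(list(order = as.integer(order), pseudocount = pseudocount,
                 counts = counts, cond_prob = cond,
                 log_prob = lapply(cond, log)),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("background_model: order %d, pseudocount %g\n", x$order, x$pseudocount))
  cat("mononucleotide probabilities:",
      paste(sprintf("%s=%.3f", BASE_LETTERS[1:4], x$cond_prob[[1L]][1L, ]),
            collapse = " "), "\n")
  invisible(x)
}

#' Background mononucleotide frequencies (used as PWM pseudocounts)
#' @param bg a `background_model`.
#' @return numeric vector of 4 probabilities (A, C, G, T).
#' @export
background_frequencies <- function(bg) {
  p <- bg$cond_prob[[1L]][1L, ]
  names(p) <- BASE_LETTERS[1:4]
  p
}

#' Per-position background log-probabilities of a sequence
#'
#' Position `j` is conditioned on the `min(order, available)` actual
#' bases preceding it in the full sequence. An N base contributes 0 to
#' the log-probability, and an N inside a context truncates the context
#' to the bases after the N.
#'
#' @param bg a `background_model`.
#' @param seq an encoded sequence, or an integer vector of base codes.
#' @return numeric vector of length `L`.
#' @export
position_log_probs <- function(bg, seq) {
  b <- if (inherits(seq, "encoded_sequence")) seq$bases else as.integer(seq)
  L <- length(b)
  out <- numeric(L)
  run <- 0L   # consecutive non-N bases ending just before j
  for (j in seq_len(L)) {
    if (b[j] == 5L) {
      out[j] <- 0
    } else {
      c <- min(bg$order, run)
      idx <- if (c == 0L) 1L else context_index(b[(j - c):(j - 1L)])
      out[j] <- bg$log_prob[[c + 1L]][idx, b[j]]
    }
    run <- if (b[j] == 5L) 0L else run + 1L
  }
  out
}

bg_prefix <- function(bg, seq) c(0, cumsum(position_log_probs(bg, seq)))

#' Background log-probability of a sequence segment
#'
#' Log-probability of the bases in the 0-based, half-open window
#' `[start, end)`, each conditioned on the actual preceding bases of the
#' full sequence (the context may extend left of `start`).
#'
#' @param bg a `background_model`.
#' @param seq encoded sequence or integer base codes.
#' @param start,end 0-based half-open bounds, `0 <= start <= end <= L`.
#' @return scalar log-probability (0 for an empty segment).
#' @export
segment_log_prob <- function(bg, seq, start, end) {
  b <- if (inherits(seq, "encoded_sequence")) seq$bases else as.integer(seq)
  L <- length(b)
  if (start < 0 || end < start || end > L)
    stop("segment [", start, ",", end, ") out of range for length ", L)
  if (start == end) return(0)
  plp <- position_log_probs(bg, b)
  sum(plp[(start + 1L):end])
}

#' Write a background model as a plain-text table
#'
#' One line per context (`.` for the empty context) with the four
#' conditional probabilities, full precision; header comments record the
#' order and fitting pseudocount.
#'
#' @param bg a `background_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_background <- function(bg, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# background_model order=%d pseudocount=%.17g",
                       bg$order, bg$pseudocount),
               "# context P(A) P(C) P(G) P(T)"), con)
  for (c in 0:bg$order) {
    tab <- bg$cond_prob[[c + 1L]]
    for (r in seq_len(nrow(tab))) {
      writeLines(paste(context_label(r, c),
                       paste(sprintf("%.17g", tab[r, ]), collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read a background model written by [write_background()]
#' @param path file path.
#' @return a `background_model` (probability tables only; counts absent).
#' @export
read_background <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1L]
  ord <- as.integer(sub(".*order=(\\d+).*", "\\1", hdr))
  pc <- as.numeric(sub(".*pseudocount=([0-9eE.+-]+).*", "\\1", hdr))
  body <- lines[!startsWith(lines, "#")]
  parts <- strsplit(trimws(body), "\\s+")
  ctx <- vapply(parts, `[`, character(1), 1L)
  probs <- t(vapply(parts, function(p) as.numeric(p[2:5]), numeric(4)))
  cond <- vector("list", ord + 1L)
  clen <- ifelse(ctx == ".", 0L, nchar(ctx))
  for (c in 0:ord) {
    rows <- which(clen == c)
    tab <- matrix(NA_real_, 4L^c, 4L, dimnames = list(NULL, BASE_LETTERS[1:4]))
    for (r in rows) {
      idx <- if (c == 0L) 1L else context_index(encode_bases(ctx[r]))
      tab[idx, ] <- probs[r, ]
    }
    cond[[c + 1L]] <- tab
  }
  structure(list(order = ord, pseudocount = pc, counts = NULL,
                 cond_prob = cond, log_prob = lapply(cond, log)),
            class = "background_model")
}
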