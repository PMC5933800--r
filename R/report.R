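# Result writers: per-model assignment tables, PWM probability and
# count matrices, per-mode summaries, a cross-model score table, and a
# static HTML index. All written coordinates are 1-based inclusive;
# internal coordinates are 0-based half-open.

write_pwm_file <- function(mat, path, digits = 6) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# pos A C G T", con)
  fmt <- if (is.double(mat)) paste0("%.", digits, "f") else "%d"
  for (a in seq_len(nrow(mat)))
    writeLines(paste(a, paste(sprintf(fmt, mat[a, ]), collapse = " ")), con)
  invisible(path)
}

#' Read a PWM (or count) matrix written by the result writers
#' @param path file path.
#' @return numeric `width x 4` matrix with columns A, C, G, T.
#' @export
read_pwm_file <- function(path) {
  tab <- utils::read.table(path, comment.char = "#")
  mat <- as.matrix(tab[, 2:5])
  dimnames(mat) <- list(NULL, BASE_LETTERS[1:4])
  mat
}

assignments_table <- function(state, set) {
  w <- state$widths[state$mode]
  site <- vapply(seq_len(state$n), function(i)
    decode_bases(site_bases(set$sequences[[i]], state$pos[i],
                            w[i], state$rev[i])),
    character(1))
  data.frame(id = seq_ids(set), mode = state$mode,
             start_1based = state$pos + 1L,
             end_1based = state$pos + w,
             strand = ifelse(state$rev == 1L, "-", "+"),
             site_sequence = site, stringsAsFactors = FALSE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Write the full result tree of a model search
#'
#' For every m searched: an assignment table (`assignments_<m>.tsv`
#' with id, mode, 1-based start/end, strand, and the motif-strand
#' oriented site sequence), one PWM probability file and one count file
#' per mode, and a per-mode member/proportion summary. At the top
#' level: `models.tsv` with per-m scores, `best_model.txt` naming the
#' selected m, and a static `index.html` linking everything.
#'
#' @param result a `motif_search`.
#' @param set the [sequence_set()] that was fitted.
#' @param outdir output directory (created if missing).
#' @return a run manifest: list of all written paths plus `best_m`,
#'   invisibly.
#' @export
write_results <- function(result, set, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  manifest <- list(outdir = outdir, best_m = result$best_m, files = character(0))
  add <- function(p) manifest$files <<- c(manifest$files, p)
  for (e in result$per_m) {
    st <- e$result$best_state
    add(write_tsv(assignments_table(st, set),
                  file.path(outdir, sprintf("assignments_%d.tsv", e$m))))
    mm <- mode_models(st)
    for (k in seq_along(mm)) {
      pp <- file.path(outdir, sprintf("pwm_m%d_mode%d.txt", e$m, k))
      write_pwm_file(mm[[k]]$pwm, pp); add(pp)
      cp <- file.path(outdir, sprintf("counts_m%d_mode%d.txt", e$m, k))
      write_pwm_file(st$counts[[k]], cp); add(cp)
    }
    summ <- data.frame(mode = seq_along(mm),
                       width = vapply(mm, `[[`, integer(1), "width"),
                       members = vapply(mm, `[[`, integer(1), "members"),
                       gamma_hat = sprintf("%.6f", vapply(mm, `[[`, numeric(1),
                                                          "gamma_hat")))
    add(write_tsv(summ, file.path(outdir, sprintf("summary_%d.tsv", e$m))))
  }
  tab <- summary_table(result)
  add(write_tsv(tab, file.path(outdir, "models.tsv")))
  bm <- file.path(outdir, "best_model.txt")
  writeLines(sprintf("best_m\t%d", result$best_m), bm); add(bm)
  idx <- file.path(outdir, "index.html")
  rel <- basename(manifest$files)
  html <- c("<!DOCTYPE html><html><head><title>motifmix results</title></head><body>",
            sprintf("<h1>motifmix: best model has %d mode(s)</h1>", result$best_m),
            "<ul>",
            sprintf("<li><a href='%s'>%s</a></li>", rel, rel),
            "</ul></body></html>")
  writeLines(html, idx); add(idx)
  stopifnot(all(file.exists(manifest$files)))
  invisible(manifest)
}
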