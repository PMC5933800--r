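fit_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dat <- generate_dataset(plant_spec(30, 40, c(0.5, 0.5),
                                         list(consensus_pwm("TGACGTCA"),
                                              consensus_pwm("GGGGTTTT")),
                                         seed = 55))
      cache <<- list(
        dat = dat,
        fit = motif_mix(dat$set, modes = 1:2, n_starts = 2, lambda = 5,
                        w_init = 8, w_min = 6, w_max = 10, max_masked = NULL,
                        seed = 4))
    }
    cache
  }
})

test_that("write_results emits a complete, self-consistent result tree", {
  fs <- fit_small()
  outdir <- withr::local_tempdir()
  manifest <- write_results(fs$fit$search, fs$fit$set, outdir)
  expect_true(all(file.exists(manifest$files)))
  expect_true(file.exists(file.path(outdir, "index.html")))

  for (m in 1:2) {
    asn <- read.delim(file.path(outdir, sprintf("assignments_%d.tsv", m)))
    # every input id appears exactly once
    ids <- vapply(fs$fit$set$sequences, `[[`, character(1), "id")
    expect_setequal(asn$id, ids)
    expect_false(anyDuplicated(asn$id) > 0)
    # coordinate arithmetic: end - start + 1 == width == nchar(site)
    st <- fs$fit$search$per_m[[m]]$result$best_state
    w <- st$widths[asn$mode]
    expect_equal(asn$end_1based - asn$start_1based + 1L, w)
    expect_equal(nchar(asn$site_sequence), w)
  }

  models <- read.delim(file.path(outdir, "models.tsv"))
  best <- read.delim(file.path(outdir, "best_model.txt"), header = FALSE)
  expect_equal(best$V2, models$m[which.max(models$selection_score)])
})

test_that("written count matrices match a rebuild from the assignment table", {
  fs <- fit_small()
  outdir <- withr::local_tempdir()
  write_results(fs$fit$search, fs$fit$set, outdir)
  for (m in 1:2) {
    asn <- read.delim(file.path(outdir, sprintf("assignments_%d.tsv", m)))
    st <- fs$fit$search$per_m[[m]]$result$best_state
    for (k in seq_len(m)) {
      rows <- asn[asn$mode == k, ]
      w <- st$widths[k]
      rebuilt <- matrix(0L, w, 4)
      for (j in seq_len(nrow(rows))) {
        site <- encode_bases(rows$site_sequence[j])
        ok <- site != 5L
        rebuilt[cbind(which(ok), site[ok])] <-
          rebuilt[cbind(which(ok), site[ok])] + 1L
      }
      written <- read_pwm_file(file.path(outdir,
                                         sprintf("counts_m%d_mode%d.txt", m, k)))
      expect_equal(unname(written), rebuilt + 0)
    }
  }
})

test_that("cli_main validates arguments and runs end to end", {
  expect_equal(suppressMessages(cli_main(c("-f"))), 1L)      # missing value
  expect_equal(suppressMessages(cli_main(character(0))), 1L) # missing -f
  expect_equal(suppressMessages(
    cli_main(c("-f", "x.fa", "-minMode", "3", "-maxMode", "2"))), 1L)
  expect_equal(suppressMessages(cli_main(c("-bogus", "1"))), 1L)

  fa <- withr::local_tempfile(fileext = ".fa")
  dat <- generate_dataset(plant_spec(20, 40, 1, list(consensus_pwm("TGACGTCA")),
                                     seed = 31))
  write_fasta(dat$set, fa)
  out1 <- withr::local_tempdir()
  code <- suppressMessages(cli_main(c(
    "-f", fa, "-minMode", "1", "-maxMode", "1", "-r", "2", "-wInit", "8",
    "-wMin", "6", "-wMax", "10", "-seed", "3", "-workers", "1", "-o", out1)))
  expect_identical(code, 0L)
  expect_true(file.exists(file.path(out1, "best_model.txt")))

  # fixed seed: identical tables across runs
  out2 <- withr::local_tempdir()
  code2 <- suppressMessages(cli_main(c(
    "-f", fa, "-minMode", "1", "-maxMode", "1", "-r", "2", "-wInit", "8",
    "-wMin", "6", "-wMax", "10", "-seed", "3", "-workers", "1", "-o", out2)))
  expect_identical(code2, 0L)
  for (f in c("assignments_1.tsv", "models.tsv", "pwm_m1_mode1.txt"))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
})
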