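truth_fixture <- function(n = 3) {
  data.frame(chr1 = paste0("chr", seq_len(n)), bkpt1 = 1e6 * seq_len(n),
             strand1 = "+", chr2 = paste0("chr", seq_len(n) + 10),
             bkpt2 = 2e6 * seq_len(n), strand2 = "+", type = "U",
             stringsAsFactors = FALSE)
}

calls_from_truth <- function(truth, jitter1 = 0, jitter2 = 0) {
  calls <- data.frame(chrom_i = truth$chr1, bkpt_i = truth$bkpt1 + jitter1,
                      strand_i = "+", chrom_j = truth$chr2,
                      bkpt_j = truth$bkpt2 + jitter2, strand_j = "-",
                      stringsAsFactors = FALSE)
  calls$call_id <- seq_len(nrow(calls))
  calls
}

test_that("perfect calls score n/n with zero error; offsets average per breakpoint", {
  tr <- truth_fixture(3)
  ev <- evaluate_calls(calls_from_truth(tr), tr, match_tol = 500)
  expect_equal(c(ev$se_num, ev$se_den, ev$sp_num, ev$sp_den), c(3, 3, 3, 3))
  expect_equal(ev$abe, 0)
  # +3 bp on one side of every event: per-event errors |3| and |0|, ABE 1.5
  ev2 <- evaluate_calls(calls_from_truth(tr, jitter1 = 3), tr, match_tol = 500)
  expect_equal(ev2$abe, 1.5)
  # an extra unmatched call costs specificity, not sensitivity
  extra <- rbind(calls_from_truth(tr),
                 data.frame(chrom_i = "chr9", bkpt_i = 5e6, strand_i = "+",
                            chrom_j = "chr20", bkpt_j = 6e6, strand_j = "-",
                            call_id = 99))
  ev3 <- evaluate_calls(extra, tr, match_tol = 500)
  expect_equal(c(ev3$se_num, ev3$sp_num, ev3$sp_den), c(3, 3, 4))
  # a missed truth event costs sensitivity
  ev4 <- evaluate_calls(calls_from_truth(tr)[1:2, ], tr, match_tol = 500)
  expect_equal(c(ev4$se_num, ev4$se_den, ev4$sp_num, ev4$sp_den), c(2, 3, 2, 2))
})

test_that("matching works across swapped chromosome order and respects the tolerance", {
  tr <- truth_fixture(1)
  swapped <- data.frame(chrom_i = tr$chr2, bkpt_i = tr$bkpt2, strand_i = "-",
                        chrom_j = tr$chr1, bkpt_j = tr$bkpt1 + 2,
                        strand_j = "+", call_id = 1L)
  ev <- evaluate_calls(swapped, tr, match_tol = 10)
  expect_equal(ev$se_num, 1)
  expect_equal(ev$abe, 1)
  beyond <- swapped; beyond$bkpt_j <- tr$bkpt1 + 11
  ev2 <- evaluate_calls(beyond, tr, match_tol = 10)
  expect_equal(ev2$se_num, 0)
  expect_true(is.na(ev2$abe))
})

test_that("scores are invariant to call and truth order", {
  tr <- truth_fixture(5)
  calls <- calls_from_truth(tr, jitter1 = c(0, 1, -2, 0, 3))
  base <- evaluate_calls(calls, tr, match_tol = 100)
  for (seed in 1:4) {
    set.seed(seed)
    perm <- evaluate_calls(calls[sample(5), ], tr[sample(5), ],
                           match_tol = 100)
    expect_equal(perm$se_num, base$se_num)
    expect_equal(perm$sp_num, base$sp_num)
    expect_equal(perm$abe, base$abe)
  }
})

test_that("greedy matching agrees with the exhaustive oracle on small cases", {
  for (seed in 1:12) {
    set.seed(seed)
    n <- sample(2:5, 1)
    tr <- truth_fixture(n)
    # jittered detections for a random subset, plus 0-2 noise calls
    keep <- sort(sample(n, sample(seq_len(n), 1)))
    calls <- calls_from_truth(tr[keep, , drop = FALSE],
                              jitter1 = round(rnorm(length(keep), 0, 5)),
                              jitter2 = round(rnorm(length(keep), 0, 5)))
    n_noise <- sample(0:2, 1)
    if (n_noise) {
      calls <- rbind(calls, data.frame(
        chrom_i = paste0("chrN", seq_len(n_noise)), bkpt_i = 1e6,
        strand_i = "+", chrom_j = "chrZ", bkpt_j = 1e6, strand_j = "-",
        call_id = 100 + seq_len(n_noise)))
    }
    calls$call_id <- seq_len(nrow(calls))
    got <- evaluate_calls(calls, tr, match_tol = 50)
    want <- match_oracle(calls, tr, tol = 50)
    expect_equal(got$se_num, want$se_num, info = paste("seed", seed))
    expect_equal(got$abe, want$abe, tolerance = 1e-9,
                 info = paste("seed", seed))
  }
})

test_that("the config-driven pipeline runs end-to-end, deterministically", {
  out1 <- tempfile("run1_"); out2 <- tempfile("run2_")
  truth_path <- tempfile(fileext = ".tsv")
  d <- tiny_design()
  write_truth(d$truth, truth_path)
  cfg <- list(simulate = list(truth = truth_path,
                              chrom_lengths = as.list(d$chrom_lengths),
                              coverage = 10),
              seed = 5, out_dir = out1)
  res1 <- run_pipeline(cfg)
  cfg$out_dir <- out2
  res2 <- run_pipeline(cfg)
  expect_identical(readLines(file.path(out1, "calls.tsv")),
                   readLines(file.path(out2, "calls.tsv")))
  expect_true(file.exists(file.path(out1, "events.tsv")))
  expect_true(file.exists(file.path(out1, "run_log.txt")))
  expect_equal(res1$evaluation$se_num, 1)
  expect_equal(res1$events$label, "UNBALANCED")
})

test_that("an input with no chimeric pairs yields zero calls, not an error", {
  ref <- random_reference(c(chrA = 50000), seed = 41)
  # concordant-only alignment table
  pos <- seq(1000, 40000, by = 250)
  seq100 <- strrep("ACGTATTGCA", 10)
  raw <- rbind(
    data.frame(qname = sprintf("q%03d", seq_along(pos)), flag = 99,
               chrom = "chrA", pos = pos, strand = "+", mapq = 60,
               cigar = "100M", mchrom = "chrA", mpos = pos + 300,
               seq = seq100),
    data.frame(qname = sprintf("q%03d", seq_along(pos)), flag = 147,
               chrom = "chrA", pos = pos + 300, strand = "-", mapq = 60,
               cigar = "100M", mchrom = "chrA", mpos = pos, seq = seq100))
  aln <- interloc:::.finish_alignments(raw[order(raw$pos), ])
  attr(aln, "ref_lengths") <- c(chrA = 50000)
  fit <- interloc(aln, ref)
  expect_equal(nrow(fit$calls), 0L)
  expect_equal(fit$n_chimeric_pairs, 0L)
  expect_output(print(fit), "no candidates")
})
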