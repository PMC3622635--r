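test_that("unbalanced splice arithmetic matches direct string construction", {
  lens <- c(chrA = 10000, chrB = 10000)
  ref <- random_reference(lens, seed = 2)
  truth <- data.frame(chr1 = "chrA", bkpt1 = 1000, strand1 = "+",
                      chr2 = "chrB", bkpt2 = 2000, strand2 = "+",
                      type = "U", stringsAsFactors = FALSE)
  fg <- forge_genome(ref, truth)
  der <- assemble_genome(fg)
  # fused derivative: chrA[1..1000] + chrB[2000..10000] (junction-adjacent
  # retained bases are the truth coordinates on both sides)
  sa <- as.character(ref[["chrA"]]); sb <- as.character(ref[["chrB"]])
  want <- paste0(substr(sa, 1, 1000), substr(sb, 2000, 10000))
  expect_equal(as.character(der[["der_chrA_chrB"]]), want)
  expect_equal(nchar(want), 9001)
  # remainders conserve total content for U events
  expect_equal(sum(Biostrings::width(der)), sum(lens))
  # junction map reproduces the truth row
  j <- fg$junctions[fg$junctions$chimeric, ]
  expect_equal(j$bkpt1, 1000); expect_equal(j$bkpt2, 2000)
  # truth round-trips through TSV and exports as 0-based BEDPE
  tsv <- tempfile(fileext = ".tsv")
  write_truth(truth, tsv)
  expect_equal(read_truth(tsv), truth)
  bedpe <- tempfile(fileext = ".bedpe")
  write_truth_bedpe(truth, bedpe)
  fields <- strsplit(readLines(bedpe), "\t")[[1]]
  expect_equal(fields[1:6], c("chrA", "999", "1000", "chrB", "1999", "2000"))
  # empty truth table: derived genome identical to the input
  fg0 <- forge_genome(ref, truth[0, ])
  expect_equal(as.character(assemble_genome(fg0)), as.character(ref))
})

test_that("insertion and balanced splices conserve sequence content", {
  lens <- c(chrR = 30000, chrD = 30000)
  ref <- random_reference(lens, seed = 4)
  ins <- data.frame(chr1 = c("chrR", "chrD"), bkpt1 = c(10000, 22000),
                    strand1 = "+", chr2 = c("chrD", "chrR"),
                    bkpt2 = c(20000, 10001), strand2 = "+",
                    type = "II", stringsAsFactors = FALSE)
  fg <- forge_genome(ref, ins)
  der <- assemble_genome(fg)
  expect_equal(sum(Biostrings::width(der)), sum(lens))  # excision = insertion
  # recipient gains exactly the donor segment, which equals the excised string
  donor_seg <- substr(as.character(ref[["chrD"]]), 20000, 22000)
  expect_equal(length(der[["der_chrR_chrD"]]), 30000 + 2001)
  expect_equal(as.character(Biostrings::subseq(der[["der_chrR_chrD"]],
                                               10001, 12001)), donor_seg)
  # inverted insertion: the planted segment is the reverse complement
  inv <- ins; inv$strand1[2] <- "-"; inv$strand2[1] <- "-"
  # rows for an inverted donor carry the donor end first
  inv$bkpt1[2] <- 20000; inv$bkpt2[1] <- 22000
  fgi <- forge_genome(ref, inv)
  deri <- assemble_genome(fgi)
  expect_equal(sum(Biostrings::width(deri)), sum(lens))
  got <- as.character(Biostrings::subseq(deri[["der_chrR_chrD"]], 10001, 12001))
  expect_equal(got, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(donor_seg))))
  # balanced exchange with a 1 kb duplication gains exactly the duplication
  bal <- data.frame(chr1 = c("chrR", "chrD"), bkpt1 = c(10000, 21000),
                    strand1 = "+", chr2 = c("chrD", "chrR"),
                    bkpt2 = c(20000, 10001), strand2 = "+",
                    type = "B", stringsAsFactors = FALSE)
  fgb <- forge_genome(ref, bal)
  expect_equal(sum(Biostrings::width(assemble_genome(fgb))),
               sum(lens) + 1001)
  # a chromosome may participate in only one event
  two <- data.frame(chr1 = c("chrR", "chrR"), bkpt1 = c(5000, 15000),
                    strand1 = "+", chr2 = c("chrD", "chrD"),
                    bkpt2 = c(5000, 15000), strand2 = "+", type = "U",
                    stringsAsFactors = FALSE)
  expect_error(forge_genome(ref, two), "more than one event")
})

test_that("zero-error reads are exact reference substrings; junction reads clip at the truth boundary", {
  tw <- tiny_sim(seed = 23, coverage = 25)
  aln <- tw$sim$alignments
  ref <- tw$ref
  # exhaustive fidelity for plain alignments
  for (ch in c("chrA", "chrB")) {
    full <- aln[aln$cigar == "100M" & aln$chrom == ch, ]
    want <- as.character(Biostrings::extractAt(
      ref[[ch]], IRanges::IRanges(full$pos, full$pos + 99)))
    expect_identical(full$seq, want)
  }
  # soft-clipped junction reads: every junction-facing boundary sits exactly
  # on the planted junction, and the clipped bases continue on the partner
  clips <- extract_softclips(aln, min_clip = 1)
  atA <- clips[clips$chrom == "chrA" & clips$side == "right", ]
  atB <- clips[clips$chrom == "chrB" & clips$side == "left", ]
  expect_gt(nrow(atA), 0)
  expect_gt(nrow(atB), 0)
  expect_true(all(atA$boundary == 60000))
  expect_true(all(atB$boundary == 40000))
  # a read split 60/40 carries CIGAR 60M40S on the anchored side
  w <- atA[atA$clip_len == 40, ]
  if (nrow(w)) {
    rec <- aln[aln$qname == w$qname[1] & aln$chrom == "chrA", ]
    expect_true(any(grepl("^60M40S$", rec$cigar)))
  }
  # clip sequences equal the partner chromosome's junction flank
  for (r in seq_len(min(5, nrow(atA)))) {
    want <- as.character(Biostrings::subseq(ref[["chrB"]], 40000,
                                            40000 + atA$clip_len[r] - 1))
    expect_equal(atA$clip_seq[r], want)
  }
})

test_that("pair count follows the coverage identity and fragments are logged", {
  tw <- tiny_sim(seed = 27, coverage = 10)
  expect_equal(tw$sim$log$n_pairs, ceiling(10 * 200000 / (2 * 100)))
  expect_equal(tw$sim$log$n_snv, 0L)
  aln <- tw$sim$alignments
  expect_equal(nrow(aln), 2L * (tw$sim$log$n_pairs - tw$sim$log$n_dropped_pairs))
})

test_that("the haplotype mutation layer plants SNVs and indels", {
  tw <- tiny_sim(seed = 29, coverage = 6, mut_rate = 0.01, base_error = 0)
  lg <- tw$sim$log
  # counts near binomial expectation: 0.01 * 200 kb = 2000, 15% indels
  expect_gt(lg$n_snv, 1400); expect_lt(lg$n_snv, 2100)
  expect_gt(lg$n_indel, 180); expect_lt(lg$n_indel, 430)
  aln <- tw$sim$alignments
  # indel-crossing reads are rendered with I/D CIGARs
  expect_gt(sum(grepl("[ID]", aln$cigar)), 0)
  # reads still map: a sampling of plain reads differs from the reference
  # only at SNV sites (no coordinate shift)
  full <- aln[aln$cigar == "100M" & aln$chrom == "chrA", ][1:200, ]
  want <- as.character(Biostrings::extractAt(
    tw$ref[["chrA"]], IRanges::IRanges(full$pos, full$pos + 99)))
  mism <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
                 full$seq, want)
  expect_lt(mean(mism), 3)               # sparse substitutions only
})

test_that("the same seed reproduces byte-identical output", {
  d <- tiny_design()
  run <- function() {
    tw <- tiny_sim(seed = 31, coverage = 4, mut_rate = 0.001,
                   base_error = 0.02, design = d)
    f <- tempfile(fileext = ".sam")
    write_sim_sam(tw$sim, f)
    tools::md5sum(f)[[1]]
  }
  expect_identical(run(), run())
})

test_that("down-sampling keeps pairs atomically, scales linearly and nests", {
  qn <- sprintf("q%05d", 1:10000)
  aln <- data.frame(qname = rep(qn, each = 2),
                    flag = rep(c(99, 147), 10000), chrom = "chr1",
                    pos = seq_len(20000), stringsAsFactors = FALSE)
  expect_identical(downsample_pairs(aln, 1, seed = 3)$qname, aln$qname)
  half <- downsample_pairs(aln, 0.5, seed = 3)
  n_half <- length(unique(half$qname))
  expect_lt(abs(n_half - 5000), 3 * sqrt(10000 * 0.25))   # binomial bound
  expect_true(all(table(half$qname) == 2))                # no orphans
  rates <- c(0.75, 0.5, 0.25, 0.10)
  kept <- lapply(rates, function(r) unique(downsample_pairs(aln, r, seed = 3)$qname))
  for (i in 2:4) expect_true(all(kept[[i]] %in% kept[[i - 1]]))  # nesting
  ns <- lengths(kept)
  expect_true(all(abs(ns - 10000 * rates) < 3 * sqrt(10000 * rates * (1 - rates))))
  expect_error(downsample_pairs(aln, 0), "rate")
  expect_error(downsample_pairs(aln, 1.2), "rate")
})
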