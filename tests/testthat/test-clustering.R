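test_that("chimeric pairs are collected, joined by qname and canonicalised", {
  seq50 <- strrep("GATCA", 10)
  rec <- function(q, chrom, pos, mchrom, mpos, flag = 97)
    data.frame(qname = q, flag = flag, chrom = chrom, pos = pos,
               strand = if (bitwAnd(flag, 16L) > 0) "-" else "+", mapq = 60,
               cigar = "50M", mchrom = mchrom, mpos = mpos, seq = seq50,
               stringsAsFactors = FALSE)
  raw <- rbind(
    # entered with chr2 side first to exercise canonicalisation
    rec("c1", "chr2", 5000, "chr1", 900, flag = 97 + 16),
    rec("c1", "chr1", 900, "chr2", 5000),
    rec("c2", "chr1", 950, "chr2", 5050), rec("c2", "chr2", 5050, "chr1", 950, flag = 113),
    rec("c3", "chr1", 980, "chr2", 5100), rec("c3", "chr2", 5100, "chr1", 980, flag = 113),
    rec("n1", "chr1", 100, "chr1", 400), rec("n1", "chr1", 400, "chr1", 100, flag = 145),
    rec("n2", "chr1", 200, "chr1", 500), rec("n2", "chr1", 500, "chr1", 200, flag = 145),
    rec("orphan", "chr1", 999, "chr2", 7000))
  aln <- interloc:::.finish_alignments(raw)
  expect_message(
    pairs <- collect_chimeric_pairs(aln, chrom_order = c("chr1", "chr2")),
    "without a usable mate")
  expect_equal(nrow(pairs), 3L)
  expect_true(all(pairs$chrom_i == "chr1" & pairs$chrom_j == "chr2"))
  expect_setequal(pairs$qname, c("c1", "c2", "c3"))
  expect_equal(attr(pairs, "n_orphans"), 1L)
  # all-concordant input yields an empty pair set
  conc <- interloc:::.finish_alignments(raw[7:10, ])
  expect_equal(nrow(collect_chimeric_pairs(conc, c("chr1", "chr2"))), 0L)
})

test_that("collected pairs on a planted junction flank it consistently", {
  tw <- tiny_sim(seed = 13, coverage = 15)
  aln <- tw$sim$alignments
  pairs <- collect_chimeric_pairs(aln)
  # independent count of qnames whose mates sit on different chromosomes
  two_chrom <- tapply(aln$chrom, aln$qname, function(x) length(unique(x)) == 2)
  expect_equal(nrow(pairs), sum(two_chrom))
  expect_gt(nrow(pairs), 10)
  # geometry: chrA reads end at/before the junction, chrB reads start at/after
  expect_true(all(pairs$chrom_i == "chrA" & pairs$chrom_j == "chrB"))
  expect_true(all(pairs$end_i <= 60000))
  expect_true(all(pairs$pos_j >= 40000))
  expect_true(all(pairs$strand_i == "+" & pairs$strand_j == "-"))
})

test_that("clusters split on distance and never merge across strands", {
  st <- insert_stats(400, 80, 3)   # L = 640
  p <- make_pairs(c(100, 150, 9000, 9050), c(5000, 5040, 7000, 7030))
  cl <- cluster_pairs(p, st, min_pairs = 2)
  expect_length(cl, 2L)            # 9000 - 150 >> L
  expect_setequal(vapply(cl, `[[`, integer(1), "n_pairs"), c(2L, 2L))
  # identical coordinates, differing i-side strand: never merged
  p2 <- rbind(make_pairs(c(100, 150), c(5000, 5040), strand_i = "+"),
              make_pairs(c(100, 150), c(5000, 5040), strand_i = "-",
                         qname = c("q1", "q2")))
  cl2 <- cluster_pairs(p2, st, min_pairs = 2)
  expect_length(cl2, 2L)
  expect_setequal(vapply(cl2, `[[`, character(1), "strand_i"), c("+", "-"))
  # groups below min_pairs are discarded, and only those
  p3 <- rbind(make_pairs(c(100, 150, 200), c(5000, 5040, 5100)),
              make_pairs(9000, 12000, qname = "lone"))
  cl3 <- cluster_pairs(p3, st, min_pairs = 2)
  expect_length(cl3, 1L)
  expect_equal(cl3[[1]]$n_pairs, 3L)
})

test_that("two planted fusions on one chromosome pair resolve to two clusters", {
  # same chromosome pair, 100 kb apart (>> L): simulate both junctions by
  # composing two far-apart clouds of pairs
  st <- insert_stats(400, 80, 3)
  set.seed(42)
  p <- rbind(
    make_pairs(100000 + sort(round(runif(20, 0, 500))),
               200000 + sort(round(runif(20, 0, 500))),
               qname = sprintf("a%02d", 1:20)),
    make_pairs(100000 + 100000 + sort(round(runif(15, 0, 500))),
               200000 + 100000 + sort(round(runif(15, 0, 500))),
               qname = sprintf("b%02d", 1:15)))
  cl <- cluster_pairs(p, st, min_pairs = 2)
  expect_length(cl, 2L)
  expect_setequal(vapply(cl, `[[`, integer(1), "n_pairs"), c(20L, 15L))
})

test_that("cluster partition matches the brute-force closure oracle", {
  st <- insert_stats(350, 50, 3)   # L = 500
  for (seed in 1:8) {
    set.seed(seed)
    n_centres <- sample(2:5, 1)
    rows <- lapply(seq_len(n_centres), function(g) {
      ci <- sample(c("chrA", "chrC"), 1)
      si <- sample(c("+", "-"), 1); sj <- sample(c("+", "-"), 1)
      centre_i <- runif(1, 2000, 5e5); centre_j <- runif(1, 2000, 5e5)
      n <- sample(1:8, 1)
      make_pairs(round(centre_i + runif(n, 0, st$L / 3)),
                 round(centre_j + runif(n, 0, st$L / 3)),
                 strand_i = si, strand_j = sj, chrom_i = ci,
                 qname = sprintf("s%d_g%d_%02d", seed, g, seq_len(n)))
    })
    p <- do.call(rbind, rows)
    p <- p[sample(nrow(p)), ]      # shuffle input order
    got <- cluster_groups(cluster_pairs(p, st, min_pairs = 2))
    want <- cluster_oracle(p, st$L, min_pairs = 2)
    expect_equal(got, want, info = paste("seed", seed))
    # partition property: every pair in at most one cluster
    all_q <- unlist(got)
    expect_false(anyDuplicated(all_q) > 0)
  }
})

test_that("clustering output is invariant under input permutation", {
  st <- insert_stats(400, 80, 3)
  set.seed(7)
  p <- rbind(make_pairs(round(runif(10, 1000, 1400)),
                        round(runif(10, 8000, 8400))),
             make_pairs(round(runif(6, 50000, 50200)),
                        round(runif(6, 9000, 9100)),
                        qname = sprintf("z%02d", 1:6)))
  base <- cluster_table(cluster_pairs(p, st))
  for (i in 1:5) {
    perm <- cluster_table(cluster_pairs(p[sample(nrow(p)), ], st))
    expect_equal(perm, base)
  }
})

test_that("fusion typing: breakpoint side follows cluster strand; arms optional", {
  st <- insert_stats(400, 80, 3)
  p <- make_pairs(c(30000, 30100), c(70000, 70050),
                  strand_i = "+", strand_j = "-")
  cl <- cluster_pairs(p, st)[[1]]
  sig <- type_fusion(cl)
  expect_equal(sig$side_i, "right")   # + reads face the junction rightward
  expect_equal(sig$side_j, "left")
  expect_true(is.na(sig$arm_fusion))
  # centromeres: chrA breakpoint side right of a span at 30 kb, centromere
  # at 50-51 kb -> p arm; chrB span at 70 kb, centromere 20-21 kb -> q arm
  cen <- data.frame(chrom = c("chrA", "chrB"), start = c(50000, 20000),
                    end = c(51000, 21000), stringsAsFactors = FALSE)
  sig2 <- type_fusion(cl, centromeres = cen)
  expect_equal(sig2$arm_fusion, "p-q")
  expect_equal(sig2[c("strand_i", "strand_j", "side_i", "side_j")],
               sig[c("strand_i", "strand_j", "side_i", "side_j")])
  # span overlapping the centromere: arm unset with a warning
  cen_bad <- data.frame(chrom = "chrA", start = 30050, end = 30060)
  expect_warning(sig3 <- type_fusion(cl, centromeres = cen_bad),
                 "centromere")
  expect_true(is.na(sig3$arm_fusion))
})
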