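# wgsim-style paired-end read simulation over a forged genome, with truth
# alignments emitted in ORIGINAL reference coordinates.
#
# Two mutation layers, as in wgsim: haplotype variants (SNVs and small
# indels at mut_rate, indel_frac of them indels) are planted on the derived
# genome before fragments are drawn; per-base sequencing errors are applied
# to the reads afterwards. Haplotype indels are planted on the segment
# structure itself, so read-to-reference mapping stays exact: a read
# crossing a small same-chromosome gap gets an I/D CIGAR, a read crossing a
# chimeric junction aligns its longer side and is soft-clipped, exactly as
# a short-read aligner renders these cases.

#' Simulation configuration
#'
#' @param coverage Haploid fold coverage of the derived genome.
#' @param read_len Read length (bp).
#' @param insert_mean,insert_stdev Fragment (outer) size distribution, bp.
#' @param mut_rate Per-base haplotype mutation probability.
#' @param indel_frac Fraction of mutations that are indels (rest are SNVs).
#' @param base_error Per-base sequencing error probability.
#' @param seed RNG seed; the whole simulation is a deterministic function
#'   of it.
#' @param min_anchor Minimum aligned bases for a junction read's anchor;
#'   junction reads whose longer side is shorter align entirely to the
#'   other side (default 20).
#' @param max_del_gap Largest same-chromosome reference gap rendered as a
#'   CIGAR deletion; larger gaps split the alignment (default 50).
#' @return A `sim_config` list.
#' @export
sim_config <- function(coverage = 40, read_len = 100, insert_mean = 400,
                       insert_stdev = 80, mut_rate = 0.001, indel_frac = 0.15,
                       base_error = 0.02, seed = 1, min_anchor = 20,
                       max_del_gap = 50) {
  stopifnot(coverage > 0, insert_mean > 2 * read_len,
            mut_rate >= 0, mut_rate <= 1, indel_frac >= 0, indel_frac <= 1,
            base_error >= 0, base_error <= 1)
  structure(list(coverage = coverage, read_len = read_len,
                 insert_mean = insert_mean, insert_stdev = insert_stdev,
                 mut_rate = mut_rate, indel_frac = indel_frac,
                 base_error = base_error, seed = seed,
                 min_anchor = min_anchor, max_del_gap = max_del_gap),
            class = "sim_config")
}

# Plant haplotype mutations on one derived chromosome's segments.
# Returns list(segments, snv_pos, snv_ref_width_changed)
.plant_mutations <- function(segs, mut_rate, indel_frac) {
  W <- seg_total(segs)
  n_mut <- stats::rbinom(1, W, mut_rate)
  if (n_mut == 0) return(list(segments = segs, n_snv = 0L, n_indel = 0L))
  is_indel <- stats::runif(n_mut) < indel_frac
  n_indel <- sum(is_indel)
  if (n_indel) {
    pos <- sort(sample.int(W, n_indel), decreasing = TRUE)
    for (p in pos) {
      len <- 1 + stats::rgeom(1, 0.7)
      if (stats::runif(1) < 0.5) {
        len <- min(len, seg_total(segs) - p + 1)
        segs <- seg_delete(segs, p, len)
      } else {
        ins <- paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
        segs <- seg_insert(segs, p, ins)
      }
    }
  }
  list(segments = segs, n_snv = n_mut - n_indel, n_indel = n_indel)
}

# Apply n SNVs at random positions of a DNAString (base changed to one of
# the other three). Returns the modified DNAString.
.apply_snvs <- function(dna, n_snv) {
  if (n_snv == 0) return(dna)
  pos <- sample.int(length(dna), min(n_snv, length(dna)))
  old <- as.character(Biostrings::extractAt(
    dna, IRanges::IRanges(pos, pos)))
  bases <- c("A", "C", "G", "T")
  new <- vapply(old, function(b) {
    alt <- setdiff(bases, b)
    if (length(alt) < 4) sample(alt, 1) else sample(bases, 1)
  }, character(1), USE.NAMES = FALSE)
  Biostrings::replaceLetterAt(dna, pos, paste(new, collapse = ""))
}

# Render one multi-segment read as an alignment: anchor the longest real
# block, soft-clip the rest. pieces from seg_extract(); derived order.
.render_split_read <- function(pieces, max_del_gap) {
  blocks <- list()
  cur <- NULL
  pend_novel <- 0
  push <- function(b) blocks[[length(blocks) + 1L]] <<- b
  for (r in seq_len(nrow(pieces))) {
    p <- pieces[r, ]
    w <- p$q2 - p$q1 + 1
    if (!is.na(p$seq)) {
      if (is.null(cur)) push(list(novel = TRUE, qlen = w))
      else pend_novel <- pend_novel + w
      next
    }
    if (!is.null(cur) && cur$src == p$src && cur$orient == p$orient) {
      g <- if (p$orient == "+") p$start - cur$ref_end - 1 else
        cur$ref_start - p$end - 1
      if (g >= 0 && g <= max_del_gap) {
        if (pend_novel > 0) {
          cur$ops <- c(cur$ops, paste0(pend_novel, "I"))
          cur$qlen <- cur$qlen + pend_novel
          pend_novel <- 0
        }
        if (g > 0) cur$ops <- c(cur$ops, paste0(g, "D"))
        cur$ops <- c(cur$ops, paste0(w, "M"))
        cur$qlen <- cur$qlen + w
        if (p$orient == "+") cur$ref_end <- p$end else cur$ref_start <- p$start
        next
      }
    }
    if (!is.null(cur)) push(cur)
    if (pend_novel > 0) { push(list(novel = TRUE, qlen = pend_novel)); pend_novel <- 0 }
    cur <- list(novel = FALSE, src = p$src, orient = p$orient,
                ref_start = p$start, ref_end = p$end,
                ops = paste0(w, "M"), qlen = w)
  }
  if (!is.null(cur)) push(cur)
  if (pend_novel > 0) push(list(novel = TRUE, qlen = pend_novel))
  real <- which(!vapply(blocks, `[[`, logical(1), "novel"))
  if (!length(real)) return(NULL)
  qlens <- vapply(blocks, `[[`, numeric(1), "qlen")
  anchor <- real[which.max(qlens[real])]
  b <- blocks[[anchor]]
  leftS <- sum(qlens[seq_len(anchor - 1)])
  rightS <- sum(qlens[-seq_len(anchor)])
  ops <- b$ops
  if (b$orient == "-") { ops <- rev(ops); tmp <- leftS; leftS <- rightS; rightS <- tmp }
  cigar <- paste0(if (leftS > 0) paste0(leftS, "S") else "",
                  paste(ops, collapse = ""),
                  if (rightS > 0) paste0(rightS, "S") else "")
  list(chrom = b$src, pos = b$ref_start, orient = b$orient, cigar = cigar)
}

#' Simulate paired-end reads from a forged genome
#'
#' Draws fragments uniformly (fragment length normal, rejected and redrawn
#' when not longer than the read length), plants haplotype mutations first
#' and sequencing errors last, and renders every read's true alignment in
#' original reference coordinates via the derived genome's segment map.
#' Reads whose two mates fall on opposite sides of a chimeric junction
#' become chimeric pairs; reads crossing a junction are soft-clipped on
#' their shorter side.
#'
#' @param fg A `forged_genome` from [forge_genome()].
#' @param config A [sim_config()].
#' @return A `sim_reads` object: list with `alignments` (coordinate-sorted
#'   alignment table, `ref_lengths` attribute set to the ORIGINAL
#'   reference), `truth` (the forge's truth table), `config`, and `log`
#'   (fragment/mutation bookkeeping).
#' @export
simulate_reads <- function(fg, config = sim_config()) {
  stopifnot(inherits(fg, "forged_genome"))
  set.seed(config$seed)
  rl <- config$read_len
  segs <- fg$segments
  n_snv <- integer(length(segs)); names(n_snv) <- names(segs)
  n_indel <- 0L
  for (nm in names(segs)) {
    m <- .plant_mutations(segs[[nm]], config$mut_rate, config$indel_frac)
    segs[[nm]] <- m$segments
    n_snv[nm] <- m$n_snv
    n_indel <- n_indel + m$n_indel
  }
  widths <- vapply(segs, seg_total, numeric(1))
  seqs <- lapply(names(segs), function(nm) {
    .apply_snvs(seg_assemble(segs[[nm]], fg$ref), n_snv[nm])
  })
  names(seqs) <- names(segs)

  total <- sum(widths)
  n_pairs <- ceiling(config$coverage * total / (2 * rl))
  chrom_idx <- sample.int(length(widths), n_pairs, replace = TRUE,
                          prob = widths / total)
  frag <- round(stats::rnorm(n_pairs, config$insert_mean, config$insert_stdev))
  n_redraw <- 0L
  bad <- which(frag <= rl | frag > widths[chrom_idx])
  while (length(bad)) {
    n_redraw <- n_redraw + length(bad)
    frag[bad] <- round(stats::rnorm(length(bad), config$insert_mean,
                                    config$insert_stdev))
    bad <- bad[frag[bad] <= rl | frag[bad] > widths[chrom_idx[bad]]]
  }
  start <- floor(stats::runif(n_pairs) * (widths[chrom_idx] - frag + 1)) + 1

  # flatten to reads: r1 = derived-forward at fragment start, r2 =
  # reverse-complemented tail
  a <- c(start, start + frag - rl)
  b <- a + rl - 1
  pair_id <- rep(seq_len(n_pairs), 2)
  is_r1 <- rep(c(TRUE, FALSE), each = n_pairs)
  rchrom <- rep(chrom_idx, 2)

  chrom <- character(length(a)); pos <- numeric(length(a))
  orient <- character(length(a)); cigar <- character(length(a))
  keep <- rep(TRUE, length(a))
  for (ci in unique(rchrom)) {
    nm <- names(segs)[ci]
    sg <- segs[[nm]]
    cum <- seg_cum(sg)
    ds <- c(1, head(cum, -1) + 1)
    ii <- which(rchrom == ci)
    k1 <- findInterval(a[ii] - 1, cum) + 1
    k2 <- findInterval(b[ii] - 1, cum) + 1
    fast <- k1 == k2 & is.na(sg$seq[k1])
    fi <- ii[fast]
    if (length(fi)) {
      kk <- k1[fast]
      o1 <- a[fi] - ds[kk] + 1
      o2 <- b[fi] - ds[kk] + 1
      plus <- sg$orient[kk] == "+"
      chrom[fi] <- sg$src[kk]
      pos[fi] <- ifelse(plus, sg$start[kk] + o1 - 1, sg$end[kk] - o2 + 1)
      orient[fi] <- sg$orient[kk]
      cigar[fi] <- paste0(rl, "M")
    }
    for (s in ii[!fast]) {
      pieces <- seg_extract(sg, a[s], b[s])
      r <- .render_split_read(pieces, config$max_del_gap)
      if (is.null(r)) { keep[s] <- FALSE; next }
      chrom[s] <- r$chrom; pos[s] <- r$pos; orient[s] <- r$orient
      cigar[s] <- r$cigar
    }
  }
  # drop pairs with an unmappable read (entirely inside a novel insertion)
  bad_pairs <- unique(pair_id[!keep])
  if (length(bad_pairs)) keep <- !(pair_id %in% bad_pairs)

  # stored sequence: derived-forward slice, reverse-complemented when the
  # anchor segment is inverted (SAM stores reference-forward bases)
  seq_out <- character(length(a))
  for (ci in unique(rchrom)) {
    ii <- which(rchrom == ci & keep)
    if (!length(ii)) next
    ss <- Biostrings::extractAt(seqs[[names(segs)[ci]]],
                                IRanges::IRanges(a[ii], b[ii]))
    rc <- orient[ii] == "-"
    if (any(rc)) ss[rc] <- Biostrings::reverseComplement(ss[rc])
    seq_out[ii] <- as.character(ss)
  }

  strand <- ifelse(is_r1, orient, ifelse(orient == "+", "-", "+"))
  idx <- which(keep)
  reads <- data.frame(
    qname = sprintf("frag%08d", pair_id[idx]),
    pair_id = pair_id[idx], is_r1 = is_r1[idx],
    chrom = chrom[idx], pos = pos[idx], strand = strand[idx],
    mapq = 60L, cigar = cigar[idx], seq = seq_out[idx],
    stringsAsFactors = FALSE)
  reads$seq <- .apply_seq_errors(reads$seq, rl, config$base_error)

  # mate fields
  o <- order(reads$pair_id, !reads$is_r1)
  reads <- reads[o, , drop = FALSE]
  m1 <- seq(1, nrow(reads), by = 2); m2 <- m1 + 1
  reads$mchrom <- NA_character_; reads$mpos <- NA_real_
  reads$mchrom[m1] <- reads$chrom[m2]; reads$mchrom[m2] <- reads$chrom[m1]
  reads$mpos[m1] <- reads$pos[m2]; reads$mpos[m2] <- reads$pos[m1]
  mstrand <- character(nrow(reads))
  mstrand[m1] <- reads$strand[m2]; mstrand[m2] <- reads$strand[m1]
  reads$flag <- .FLAG_PAIRED +
    ifelse(reads$is_r1, .FLAG_READ1, .FLAG_READ2) +
    ifelse(reads$strand == "-", .FLAG_REVERSE, 0L) +
    ifelse(mstrand == "-", .FLAG_MREVERSE, 0L)

  ref_lengths <- stats::setNames(Biostrings::width(fg$ref), names(fg$ref))
  ord <- order(match(reads$chrom, names(ref_lengths)), reads$pos,
               reads$qname, reads$is_r1)
  reads <- reads[ord, , drop = FALSE]
  aln <- .finish_alignments(reads[, c("qname", "flag", "chrom", "pos",
                                      "strand", "mapq", "cigar", "mchrom",
                                      "mpos", "seq")])
  attr(aln, "ref_lengths") <- ref_lengths
  structure(list(
    alignments = aln, truth = fg$truth, config = config,
    log = list(n_pairs = n_pairs, n_dropped_pairs = length(bad_pairs),
               n_redraw = n_redraw, n_snv = sum(n_snv), n_indel = n_indel,
               derived_total = total)),
    class = "sim_reads")
}

# Per-base sequencing errors on equal-width reads; vectorised in passes over
# the k-th error of each read.
.apply_seq_errors <- function(reads, rl, base_error) {
  if (base_error <= 0 || !length(reads)) return(reads)
  n <- length(reads)
  k <- stats::rbinom(n, rl, base_error)
  tot <- sum(k)
  if (!tot) return(reads)
  idx <- rep.int(seq_len(n), k)
  pos <- sample.int(rl, tot, replace = TRUE)
  dd <- !duplicated(paste0(idx, "_", pos))
  idx <- idx[dd]; pos <- pos[dd]
  o <- order(idx)
  rank <- integer(length(idx))
  rank[o] <- sequence(rle(idx[o])$lengths)
  bases <- c("A", "C", "G", "T")
  alt <- rbind(c("C", "G", "T"), c("A", "G", "T"),
               c("A", "C", "T"), c("A", "C", "G"))
  for (p in seq_len(max(rank))) {
    sel <- rank == p
    i <- idx[sel]; j <- pos[sel]
    cur <- substr(reads[i], j, j)
    bi <- match(cur, bases)
    bi[is.na(bi)] <- sample.int(4, sum(is.na(bi)), replace = TRUE)
    newb <- alt[cbind(bi, sample.int(3, length(bi), replace = TRUE))]
    substr(reads[i], j, j) <- newb
  }
  reads
}

#' @export
print.sim_reads <- function(x, ...) {
  cat(sprintf(
    "simulated reads: %d pairs (%dX over %s bp derived genome), %d bp reads\n",
    x$log$n_pairs, x$config$coverage,
    format(x$log$derived_total, big.mark = ","), x$config$read_len))
  cat(sprintf("  haplotype variants: %d SNVs, %d indels; %d chimeric truth junction(s)\n",
              x$log$n_snv, x$log$n_indel, nrow(x$truth)))
  invisible(x)
}

#' Write simulated reads as SAM / FASTQ
#'
#' `write_sim_sam()` writes the coordinate-sorted truth SAM (header from the
#' original reference). `write_sim_fastq()` writes the read pair as two
#' FASTQ files (`<prefix>_1.fq`, `<prefix>_2.fq`), sequences in sequencing
#' orientation (stored reverse-strand records are reverse-complemented
#' back).
#'
#' @param sim A `sim_reads` object.
#' @param path,prefix Output SAM path / FASTQ path prefix.
#' @return The written path(s), invisibly.
#' @export
write_sim_sam <- function(sim, path) {
  write_alignments(sim$alignments, path)
}

#' @rdname write_sim_sam
#' @export
write_sim_fastq <- function(sim, prefix) {
  aln <- sim$alignments
  for (mate in 1:2) {
    bit <- if (mate == 1) .FLAG_READ1 else .FLAG_READ2
    rec <- aln[.has_flag(aln$flag, bit), , drop = FALSE]
    rec <- rec[order(rec$qname), , drop = FALSE]
    sq <- Biostrings::DNAStringSet(rec$seq)
    rev <- .has_flag(rec$flag, .FLAG_REVERSE)
    if (any(rev)) sq[rev] <- Biostrings::reverseComplement(sq[rev])
    qual <- strrep("I", nchar(rec$seq))
    out <- paste0("@", rec$qname, "/", mate, "\n", as.character(sq),
                  "\n+\n", qual)
    writeLines(out, paste0(prefix, "_", mate, ".fq"))
  }
  invisible(paste0(prefix, "_", 1:2, ".fq"))
}

#' Down-sample an alignment table by read pair
#'
#' Each pair (query name) is kept independently with probability `rate`,
#' both mates together, deterministically under `seed`. With a shared seed
#' the kept sets are nested across rates (the 10% sample is a subset of the
#' 25% sample), which gives clean coverage trends.
#'
#' @param aln Alignment table.
#' @param rate Keep probability in (0, 1].
#' @param seed RNG seed.
#' @return Subset alignment table (attributes preserved).
#' @export
downsample_pairs <- function(aln, rate, seed = 1) {
  if (!(rate > 0 && rate <= 1)) stop("rate must be in (0, 1]")
  qn <- sort(unique(aln$qname))
  set.seed(seed)
  u <- stats::runif(length(qn))
  keep <- qn[u <= rate]
  out <- aln[aln$qname %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "ref_lengths") <- attr(aln, "ref_lengths")
  out
}
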