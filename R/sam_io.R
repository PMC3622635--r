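# Alignment input/output and library statistics.

# SAM flag bits used throughout.
.FLAG_PAIRED <- 1L; .FLAG_UNMAPPED <- 4L; .FLAG_MUNMAPPED <- 8L
.FLAG_REVERSE <- 16L; .FLAG_MREVERSE <- 32L; .FLAG_READ1 <- 64L
.FLAG_READ2 <- 128L; .FLAG_SECONDARY <- 256L; .FLAG_DUP <- 1024L
.FLAG_SUPPLEMENTARY <- 2048L

.has_flag <- function(flag, bit) bitwAnd(flag, bit) != 0L

# Split CIGAR strings into parallel op/length lists (vectorised).
.cigar_ops <- function(cigar) {
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)
  regmatches(cigar, m)
}

# Reference-consuming width of each CIGAR (M/D/N/=/X).
cigar_ref_width <- function(cigar) {
  vapply(.cigar_ops(cigar), function(ops) {
    op <- substring(ops, nchar(ops), nchar(ops))
    len <- as.integer(substring(ops, 1, nchar(ops) - 1))
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, numeric(1))
}

# Query-consuming width (M/I/S/=/X); must equal nchar(seq) for a valid record.
cigar_query_width <- function(cigar) {
  vapply(.cigar_ops(cigar), function(ops) {
    op <- substring(ops, nchar(ops), nchar(ops))
    len <- as.integer(substring(ops, 1, nchar(ops) - 1))
    sum(len[op %in% c("M", "I", "S", "=", "X")])
  }, numeric(1))
}

# Terminal soft-clip lengths, vectorised: list(left=, right=).
.cigar_clips <- function(cigar) {
  left <- integer(length(cigar))
  lm <- grepl("^[0-9]+S", cigar)
  left[lm] <- as.integer(sub("^([0-9]+)S.*$", "\\1", cigar[lm]))
  right <- integer(length(cigar))
  rm_ <- grepl("[MIDNP=XH][0-9]+S$", cigar)
  right[rm_] <- as.integer(sub("^.*[MIDNP=XH]([0-9]+)S$", "\\1", cigar[rm_]))
  list(left = left, right = right)
}

#' Read a coordinate-sorted SAM or BAM file into an alignment table
#'
#' Loads primary alignment records, parses CIGAR-derived quantities, and
#' applies the standard record filters: unmapped, secondary, supplementary and
#' duplicate-flagged records are skipped, as are records below `min_mapq`.
#' SAM input is converted through [Rsamtools::asBam()]; BAM is read directly.
#'
#' The file must be coordinate-sorted (positions non-decreasing within each
#' reference, references in contiguous blocks); a detectably unsorted file is
#' a hard error naming the first offending record.
#'
#' @param path Path to a SAM (`.sam`) or BAM file with a header.
#' @param min_mapq Minimum mapping quality to retain a record. The default of
#'   20 suppresses chimeric artifacts from ambiguously mapped reads.
#' @return A `data.frame` with one row per retained record: `qname`, `flag`,
#'   `chrom`, `pos`, `strand`, `mapq`, `cigar`, `mchrom`, `mpos`, `seq`,
#'   `ref_end` (last aligned reference base), `clip_left`, `clip_right`
#'   (terminal soft-clip lengths). Reference names and lengths are attached
#'   as the `ref_lengths` attribute (named numeric vector, header order).
#' @export
read_alignments <- function(path, min_mapq = 20) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  is_sam <- grepl("\\.sam$", path, ignore.case = TRUE)
  bam <- if (is_sam) {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  } else path
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  what <- c("qname", "flag", "rname", "pos", "strand", "mapq", "cigar",
            "mrnm", "mpos", "seq")
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(what = what))[[1]]
  aln <- data.frame(qname = res$qname, flag = res$flag,
                    chrom = as.character(res$rname), pos = res$pos,
                    strand = as.character(res$strand), mapq = res$mapq,
                    cigar = res$cigar, mchrom = as.character(res$mrnm),
                    mpos = res$mpos, seq = as.character(res$seq),
                    stringsAsFactors = FALSE)
  drop <- .has_flag(aln$flag, .FLAG_UNMAPPED) |
    .has_flag(aln$flag, .FLAG_SECONDARY) |
    .has_flag(aln$flag, .FLAG_SUPPLEMENTARY) |
    .has_flag(aln$flag, .FLAG_DUP) |
    (!is.na(aln$mapq) & aln$mapq < min_mapq)
  aln <- aln[!drop, , drop = FALSE]
  .check_sorted(aln)
  qw <- cigar_query_width(aln$cigar)
  bad <- which(qw != nchar(aln$seq))
  if (length(bad)) {
    stop("malformed CIGAR (query width != sequence length) for record ",
         aln$qname[bad[1]], " at ", aln$chrom[bad[1]], ":", aln$pos[bad[1]])
  }
  aln <- .finish_alignments(aln)
  attr(aln, "ref_lengths") <- hdr
  aln
}

.finish_alignments <- function(aln) {
  aln$ref_end <- aln$pos + cigar_ref_width(aln$cigar) - 1
  cl <- .cigar_clips(aln$cigar)
  aln$clip_left <- cl$left
  aln$clip_right <- cl$right
  rownames(aln) <- NULL
  aln
}

.check_sorted <- function(aln) {
  if (nrow(aln) < 2) return(invisible(TRUE))
  r <- rle(aln$chrom)
  if (anyDuplicated(r$values)) {
    stop("input is not coordinate-sorted: reference ",
         r$values[anyDuplicated(r$values)], " occurs in disjoint blocks")
  }
  blocks <- rep(seq_along(r$lengths), r$lengths)
  bad <- which(diff(aln$pos) < 0 & diff(blocks) == 0)
  if (length(bad)) {
    i <- bad[1] + 1
    stop("input is not coordinate-sorted: record ", aln$qname[i], " at ",
         aln$chrom[i], ":", aln$pos[i], " follows position ", aln$pos[i - 1])
  }
  invisible(TRUE)
}

#' Write an alignment table as a SAM file
#'
#' Emits a coordinate-sorted SAM file (with `@HD`/`@SQ` header lines) from an
#' alignment table of the shape produced by [read_alignments()] or
#' [simulate_reads()]. Round-trips losslessly through [read_alignments()].
#'
#' @param aln Alignment `data.frame` (needs `qname`, `flag`, `chrom`, `pos`,
#'   `mapq`, `cigar`, `mchrom`, `mpos`, `seq`).
#' @param path Output path (`.sam`).
#' @param ref_lengths Named vector of reference lengths; defaults to the
#'   table's `ref_lengths` attribute.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(aln, path, ref_lengths = attr(aln, "ref_lengths")) {
  if (is.null(ref_lengths)) stop("ref_lengths required to write a SAM header")
  ord <- order(match(aln$chrom, names(ref_lengths)), aln$pos)
  aln <- aln[ord, , drop = FALSE]
  rnext <- ifelse(is.na(aln$mchrom), "*",
                  ifelse(aln$mchrom == aln$chrom, "=", aln$mchrom))
  tlen <- if (!is.null(aln$tlen)) aln$tlen else 0L
  qual <- if (!is.null(aln$qual)) aln$qual else
    vapply(nchar(aln$seq), function(n) strrep("I", n), character(1))
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                   as.integer(ref_lengths)))
  rec <- paste(aln$qname, aln$flag, aln$chrom,
               format(aln$pos, scientific = FALSE, trim = TRUE), aln$mapq,
               aln$cigar, rnext,
               format(ifelse(is.na(aln$mpos), 0, aln$mpos),
                      scientific = FALSE, trim = TRUE),
               format(tlen, scientific = FALSE, trim = TRUE),
               aln$seq, qual, sep = "\t")
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Estimate insert-size statistics and the proximity length L
#'
#' Computes the mean and standard deviation of the outer distance (leftmost to
#' rightmost aligned base of a pair) over concordant read pairs -- both mates
#' on the same reference, in convergent (+/-) orientation -- and derives the
#' proximity length `L = mean + k * stdev` that bounds both cluster cohesion
#' and the breakpoint search windows. Chimeric pairs carry no mapped distance
#' and contribute nothing.
#'
#' @param aln Alignment table from [read_alignments()].
#' @param k Multiplier on the standard deviation (user constant; default 3
#'   covers ~99.7% of a Gaussian insert distribution).
#' @param max_pairs Use at most this many concordant pairs (first in
#'   coordinate order).
#' @return An object of class `insert_stats`: list with `mean`, `stdev`, `k`,
#'   `L`, `n_pairs`.
#' @export
estimate_insert_stats <- function(aln, k = 3, max_pairs = 10000) {
  same <- !is.na(aln$mchrom) & aln$mchrom == aln$chrom &
    .has_flag(aln$flag, .FLAG_PAIRED)
  a <- aln[same, c("qname", "pos", "ref_end", "strand")]
  first <- a[!duplicated(a$qname), ]
  second <- a[duplicated(a$qname), ]
  second <- second[!duplicated(second$qname), ]
  m <- match(first$qname, second$qname)
  ok <- !is.na(m)
  f <- first[ok, ]; s <- second[m[ok], ]
  lo_pos <- pmin(f$pos, s$pos)
  hi_end <- pmax(f$ref_end, s$ref_end)
  lo_strand <- ifelse(f$pos <= s$pos, f$strand, s$strand)
  hi_strand <- ifelse(f$pos <= s$pos, s$strand, f$strand)
  conc <- lo_strand == "+" & hi_strand == "-"
  outer <- (hi_end - lo_pos + 1)[conc]
  if (length(outer) < 100) {
    stop("only ", length(outer), " concordant pairs found (>= 100 needed); ",
         "supply mean/stdev explicitly via insert_stats()")
  }
  outer <- outer[seq_len(min(length(outer), max_pairs))]
  insert_stats(mean(outer), stats::sd(outer), k, length(outer))
}

#' Construct insert-size statistics from known values
#'
#' @param mean,stdev Mean and standard deviation of the outer distance (bp).
#' @param k Multiplier defining `L = mean + k * stdev`.
#' @param n_pairs Number of pairs the estimate is based on (informational).
#' @return An `insert_stats` object.
#' @export
insert_stats <- function(mean, stdev, k = 3, n_pairs = NA_integer_) {
  stopifnot(stdev >= 0, k > 0)
  structure(list(mean = mean, stdev = stdev, k = k,
                 L = mean + k * stdev, n_pairs = n_pairs),
            class = "insert_stats")
}

#' @export
print.insert_stats <- function(x, ...) {
  cat(sprintf("Insert size: mean %.1f bp, sd %.1f bp (n=%s); L = mean + %g*sd = %.0f bp\n",
              x$mean, x$stdev, format(x$n_pairs), x$k, x$L))
  invisible(x)
}

#' Extract qualifying terminal soft clips from an alignment table
#'
#' One row per terminal soft-clip (`S`) operation of length at least
#' `min_clip`. The clip boundary is the aligned base adjacent to the clip:
#' the last aligned reference base for a right clip, the first for a left
#' clip. Hard clips are ignored (their bases are absent from the record).
#'
#' @param aln Alignment table.
#' @param min_clip Minimum clip length (default 20 bp, the realignment
#'   minimum for short subsequences).
#' @return `data.frame` with `qname`, `chrom`, `side` ("left"/"right"),
#'   `boundary`, `clip_len`, `clip_seq`, `strand`.
#' @export
extract_softclips <- function(aln, min_clip = 20) {
  out <- list()
  li <- which(aln$clip_left >= min_clip)
  if (length(li)) {
    out$left <- data.frame(
      qname = aln$qname[li], chrom = aln$chrom[li], side = "left",
      boundary = aln$pos[li], clip_len = aln$clip_left[li],
      clip_seq = substr(aln$seq[li], 1, aln$clip_left[li]),
      strand = aln$strand[li], stringsAsFactors = FALSE)
  }
  ri <- which(aln$clip_right >= min_clip)
  if (length(ri)) {
    n <- nchar(aln$seq[ri])
    out$right <- data.frame(
      qname = aln$qname[ri], chrom = aln$chrom[ri], side = "right",
      boundary = aln$ref_end[ri], clip_len = aln$clip_right[ri],
      clip_seq = substr(aln$seq[ri], n - aln$clip_right[ri] + 1, n),
      strand = aln$strand[ri], stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(qname = character(), chrom = character(),
                      side = character(), boundary = numeric(),
                      clip_len = integer(), clip_seq = character(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
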