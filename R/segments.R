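# Segment model for derived (rearranged) chromosomes.
#
# A derived chromosome is an ordered run of segments, each either a slice of a
# reference chromosome taken forward ('+') or reverse-complemented ('-'), or a
# run of novel bases (haplotype insertions planted by the mutation layer).
# Every coordinate transformation in the simulator -- splicing variants,
# planting indels, mapping simulated reads back to reference space -- is
# expressed on this structure, so derived->reference bookkeeping stays exact.
#
# Columns: src (reference name, NA for novel), start, end (1-based inclusive
# reference interval; for novel segments 1..nchar(seq)), orient ('+'/'-'),
# seq (novel bases, NA otherwise).

seg_new <- function(src, start, end, orient = "+", seq = NA_character_) {
  data.frame(src = src, start = as.numeric(start), end = as.numeric(end),
             orient = orient, seq = seq, stringsAsFactors = FALSE)
}

seg_novel <- function(seq) {
  seg_new(NA_character_, 1, nchar(seq), "+", seq)
}

seg_widths <- function(segs) segs$end - segs$start + 1

seg_total <- function(segs) sum(seg_widths(segs))

# Derived coordinate of the last base of each segment.
seg_cum <- function(segs) cumsum(seg_widths(segs))

# Reference coordinate of derived offset `o` (1-based within the segment).
.seg_ref_at <- function(seg, o) {
  if (seg$orient == "+") seg$start + o - 1 else seg$end - o + 1
}

# Sub-slice of one segment keeping derived offsets [o1, o2].
.seg_slice <- function(seg, o1, o2) {
  if (!is.na(seg$seq)) {
    s <- substr(seg$seq, o1, o2)
    return(seg_novel(s))
  }
  if (seg$orient == "+") {
    seg_new(seg$src, seg$start + o1 - 1, seg$start + o2 - 1, "+")
  } else {
    seg_new(seg$src, seg$end - o2 + 1, seg$end - o1 + 1, "-")
  }
}

# Decompose a derived interval [a, b] into per-segment pieces.  Returns a data
# frame with one row per piece: src, start, end, orient, seq, q1, q2 (derived
# offsets within [a, b], i.e. query coordinates along the interval).
seg_extract <- function(segs, a, b) {
  cum <- seg_cum(segs)
  ds <- c(1, head(cum, -1) + 1)           # derived start of each segment
  i1 <- findInterval(a - 1, cum) + 1
  i2 <- findInterval(b - 1, cum) + 1
  out <- vector("list", i2 - i1 + 1)
  for (k in i1:i2) {
    o1 <- max(a, ds[k]) - ds[k] + 1
    o2 <- min(b, cum[k]) - ds[k] + 1
    piece <- .seg_slice(segs[k, , drop = FALSE], o1, o2)
    piece$q1 <- (ds[k] + o1 - 1) - a + 1
    piece$q2 <- (ds[k] + o2 - 1) - a + 1
    out[[k - i1 + 1]] <- piece
  }
  do.call(rbind, out)
}

# Delete derived interval [pos, pos + len - 1].
seg_delete <- function(segs, pos, len) {
  stopifnot(pos >= 1, pos + len - 1 <= seg_total(segs))
  a <- pos; b <- pos + len - 1
  cum <- seg_cum(segs)
  ds <- c(1, head(cum, -1) + 1)
  keep <- list()
  for (k in seq_len(nrow(segs))) {
    sa <- ds[k]; sb <- cum[k]
    if (sb < a || sa > b) {               # untouched
      keep[[length(keep) + 1]] <- segs[k, , drop = FALSE]
      next
    }
    if (sa < a)                            # left remnant
      keep[[length(keep) + 1]] <- .seg_slice(segs[k, , drop = FALSE], 1, a - sa)
    if (sb > b)                            # right remnant
      keep[[length(keep) + 1]] <- .seg_slice(segs[k, , drop = FALSE],
                                             b - sa + 2, sb - sa + 1)
  }
  do.call(rbind, keep)
}

# Insert novel bases immediately after derived position `pos` (0 = prepend).
seg_insert <- function(segs, pos, seq) {
  stopifnot(pos >= 0, pos <= seg_total(segs))
  ins <- seg_novel(seq)
  if (pos == 0) return(rbind(ins, segs))
  cum <- seg_cum(segs)
  ds <- c(1, head(cum, -1) + 1)
  k <- findInterval(pos - 1, cum) + 1
  left <- if (k > 1) segs[seq_len(k - 1), , drop = FALSE] else NULL
  right <- if (k < nrow(segs)) segs[(k + 1):nrow(segs), , drop = FALSE] else NULL
  o <- pos - ds[k] + 1
  w <- cum[k] - ds[k] + 1
  mid1 <- .seg_slice(segs[k, , drop = FALSE], 1, o)
  mid2 <- if (o < w) .seg_slice(segs[k, , drop = FALSE], o + 1, w) else NULL
  do.call(rbind, Filter(Negate(is.null), list(left, mid1, ins, mid2, right)))
}

# Assemble the derived sequence of one segment run against a reference
# DNAStringSet.  Returns a DNAString.
seg_assemble <- function(segs, ref) {
  pieces <- vector("list", nrow(segs))
  for (k in seq_len(nrow(segs))) {
    if (!is.na(segs$seq[k])) {
      pieces[[k]] <- Biostrings::DNAString(segs$seq[k])
    } else {
      s <- Biostrings::subseq(ref[[segs$src[k]]], segs$start[k], segs$end[k])
      if (segs$orient[k] == "-") s <- Biostrings::reverseComplement(s)
      pieces[[k]] <- s
    }
  }
  unlist(Biostrings::DNAStringSet(pieces))
}
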