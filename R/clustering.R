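# Discordant-pair clustering and fusion typing.

#' Collect chimeric read pairs from an alignment table
#'
#' A chimeric pair is a read pair whose mates align to different references,
#' implying the sequenced fragment spans a fusion junction. Mates are joined
#' by query name and the chromosome pair is canonicalised to header order
#' (side `i` precedes side `j`). Records whose mate never appears in the
#' table are counted and dropped, not fatal.
#'
#' @param aln Alignment table from [read_alignments()].
#' @param chrom_order Reference-name order used for canonicalisation;
#'   defaults to the order of the `ref_lengths` attribute.
#' @return `data.frame` with one row per pair: `qname`, then `chrom`, `pos`,
#'   `end`, `strand` for sides `i` and `j` (suffixes `_i`, `_j`), plus `c_i`,
#'   `c_j`: the junction-facing aligned coordinate of each read (its 3' end
#'   for a `+` alignment, 5' start for `-`). The number of dropped orphan
#'   records is attached as attribute `n_orphans`.
#' @export
collect_chimeric_pairs <- function(aln, chrom_order = names(attr(aln, "ref_lengths"))) {
  chim <- aln[!is.na(aln$mchrom) & aln$mchrom != aln$chrom, , drop = FALSE]
  empty <- data.frame(qname = character(), chrom_i = character(),
                      pos_i = numeric(), end_i = numeric(), strand_i = character(),
                      chrom_j = character(), pos_j = numeric(), end_j = numeric(),
                      strand_j = character(), c_i = numeric(), c_j = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(chim)) { attr(empty, "n_orphans") <- 0L; return(empty) }
  tab <- table(chim$qname)
  paired <- names(tab)[tab == 2L]
  n_orphans <- sum(tab != 2L)
  if (n_orphans) {
    message(n_orphans, " chimeric record(s) without a usable mate dropped")
  }
  chim <- chim[chim$qname %in% paired, , drop = FALSE]
  if (!nrow(chim)) { attr(empty, "n_orphans") <- n_orphans; return(empty) }
  if (is.null(chrom_order)) chrom_order <- sort(unique(chim$chrom))
  chim <- chim[order(chim$qname, match(chim$chrom, chrom_order)), , drop = FALSE]
  a <- chim[seq(1, nrow(chim), by = 2), ]
  b <- chim[seq(2, nrow(chim), by = 2), ]
  stopifnot(all(a$qname == b$qname))
  pairs <- data.frame(
    qname = a$qname,
    chrom_i = a$chrom, pos_i = a$pos, end_i = a$ref_end, strand_i = a$strand,
    chrom_j = b$chrom, pos_j = b$pos, end_j = b$ref_end, strand_j = b$strand,
    stringsAsFactors = FALSE)
  pairs$c_i <- ifelse(pairs$strand_i == "+", pairs$end_i, pairs$pos_i)
  pairs$c_j <- ifelse(pairs$strand_j == "+", pairs$end_j, pairs$pos_j)
  rownames(pairs) <- NULL
  attr(pairs, "n_orphans") <- n_orphans
  pairs
}

# Split a sorted coordinate vector into 1D single-linkage components
# (consecutive gap > L starts a new component), then enforce a hard span
# bound by cutting at the largest internal gap until every component spans
# <= L. Returns component ids aligned to the *sorted* order.
.linkage_1d <- function(x_sorted, L) {
  n <- length(x_sorted)
  if (n == 1) return(1L)
  comp <- cumsum(c(1L, as.integer(diff(x_sorted) > L)))
  repeat {
    spans <- tapply(x_sorted, comp, function(v) max(v) - min(v))
    wide <- names(spans)[spans > L]
    if (!length(wide)) break
    for (w in wide) {
      idx <- which(comp == as.integer(w))
      gaps <- diff(x_sorted[idx])
      cut <- which.max(gaps)
      comp[idx[(cut + 1):length(idx)]] <- max(comp) + 1L
    }
  }
  comp
}

#' Cluster chimeric pairs into candidate rearrangement loci
#'
#' Pairs are stratified by (canonical chromosome pair, strand pair); within a
#' stratum, pairs whose junction-facing coordinates co-locate within the
#' proximity length `L` on *both* sides form a cluster. Grouping is
#' single-linkage on the `i`-side coordinate with link distance `L`, then
#' verified and split on the `j` side by the same rule; a component whose
#' span still exceeds `L` on either side is cut at its largest internal gap.
#' Groups smaller than `min_pairs` are discarded.
#'
#' @param pairs Chimeric pair table from [collect_chimeric_pairs()].
#' @param stats [insert_stats()] object providing `L`.
#' @param min_pairs Minimum supporting pairs per cluster (default 2; a single
#'   stray chimeric fragment never nominates a locus).
#' @return List of `chimeric_cluster` objects: each a list with `chrom_i`,
#'   `chrom_j`, `strand_i`, `strand_j`, `n_pairs`, per-side read coordinates
#'   (`pos_i`, `end_i`, `pos_j`, `end_j`, `c_i`, `c_j`), `span_i`, `span_j`
#'   and supporting `qnames`. Output order is deterministic (by chromosome
#'   pair, strands, then leftmost coordinate) and invariant to input order.
#' @export
cluster_pairs <- function(pairs, stats, min_pairs = 2) {
  if (!nrow(pairs)) return(list())
  L <- stats$L
  key <- paste(pairs$chrom_i, pairs$chrom_j, pairs$strand_i, pairs$strand_j,
               sep = "\r")
  clusters <- list()
  for (k in sort(unique(key))) {
    p <- pairs[key == k, , drop = FALSE]
    p <- p[order(p$c_i, p$c_j, p$qname), , drop = FALSE]
    comp_i <- .linkage_1d(p$c_i, L)
    for (ci in unique(comp_i)) {
      q <- p[comp_i == ci, , drop = FALSE]
      q <- q[order(q$c_j, q$c_i, q$qname), , drop = FALSE]
      comp_j <- .linkage_1d(q$c_j, L)
      for (cj in unique(comp_j)) {
        g <- q[comp_j == cj, , drop = FALSE]
        # re-verify the i side after the j-side split
        g <- g[order(g$c_i, g$c_j, g$qname), , drop = FALSE]
        comp_i2 <- .linkage_1d(g$c_i, L)
        for (ci2 in unique(comp_i2)) {
          h <- g[comp_i2 == ci2, , drop = FALSE]
          if (nrow(h) < min_pairs) next
          clusters[[length(clusters) + 1]] <- structure(list(
            chrom_i = h$chrom_i[1], chrom_j = h$chrom_j[1],
            strand_i = h$strand_i[1], strand_j = h$strand_j[1],
            n_pairs = nrow(h),
            pos_i = h$pos_i, end_i = h$end_i, c_i = h$c_i,
            pos_j = h$pos_j, end_j = h$end_j, c_j = h$c_j,
            span_i = range(h$c_i), span_j = range(h$c_j),
            qnames = h$qname), class = "chimeric_cluster")
        }
      }
    }
  }
  ord <- order(vapply(clusters, function(cl) cl$chrom_i, character(1)),
               vapply(clusters, function(cl) cl$chrom_j, character(1)),
               vapply(clusters, function(cl) cl$strand_i, character(1)),
               vapply(clusters, function(cl) cl$strand_j, character(1)),
               vapply(clusters, function(cl) cl$span_i[1], numeric(1)))
  clusters[ord]
}

#' @export
print.chimeric_cluster <- function(x, ...) {
  cat(sprintf("chimeric cluster: %s:%.0f-%.0f (%s) <-> %s:%.0f-%.0f (%s), %d pairs\n",
              x$chrom_i, x$span_i[1], x$span_i[2], x$strand_i,
              x$chrom_j, x$span_j[1], x$span_j[2], x$strand_j, x$n_pairs))
  invisible(x)
}

#' Derive the fusion-orientation signature of a cluster
#'
#' Reads point into the junction, so the breakpoint lies to the right of a
#' `+` read set and to the left of a `-` read set; the strand pair therefore
#' fixes on which side of each cluster span the fusion lies. When a
#' centromere annotation is supplied the implied arm-to-arm fusion
#' (`p-p`, `p-q`, `q-p`, `q-q`) is reported as well; the strand/side
#' signature is identical with or without it.
#'
#' @param cluster A `chimeric_cluster`.
#' @param centromeres Optional centromere table from [read_centromeres()]
#'   (columns `chrom`, `start`, `end`, 1-based).
#' @return An `orientation_signature`: list with `strand_i`, `strand_j`,
#'   `side_i`, `side_j` ("left"/"right") and `arm_fusion` (`NA` without
#'   annotation, or when a cluster span overlaps its centromere, with a
#'   warning).
#' @export
type_fusion <- function(cluster, centromeres = NULL) {
  side <- function(strand) if (strand == "+") "right" else "left"
  sig <- list(strand_i = cluster$strand_i, strand_j = cluster$strand_j,
              side_i = side(cluster$strand_i), side_j = side(cluster$strand_j),
              arm_fusion = NA_character_)
  if (!is.null(centromeres)) {
    arm <- function(chrom, span, side) {
      cen <- centromeres[centromeres$chrom == chrom, , drop = FALSE]
      if (!nrow(cen)) return(NA_character_)
      if (span[2] >= cen$start[1] && span[1] <= cen$end[1]) {
        warning("cluster span on ", chrom, " overlaps the centromere; ",
                "arm fusion left unset")
        return(NA_character_)
      }
      # the junction-side end of the span decides the arm
      at <- if (side == "right") span[2] else span[1]
      if (at < cen$start[1]) "p" else "q"
    }
    ai <- arm(cluster$chrom_i, cluster$span_i, sig$side_i)
    aj <- arm(cluster$chrom_j, cluster$span_j, sig$side_j)
    if (!is.na(ai) && !is.na(aj)) sig$arm_fusion <- paste(ai, aj, sep = "-")
  }
  structure(sig, class = "orientation_signature")
}

#' Read a centromere annotation from a BED file
#'
#' BED intervals (0-based half-open) are converted to 1-based inclusive
#' coordinates. One interval per chromosome is expected; extras are ignored
#' with a warning.
#'
#' @param path BED file with at least chrom/start/end columns.
#' @return `data.frame` with `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_centromeres <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = BiocGenerics::start(gr),
                   end = BiocGenerics::end(gr), stringsAsFactors = FALSE)
  if (anyDuplicated(df$chrom)) {
    warning("multiple centromere intervals for one chromosome; using the first")
    df <- df[!duplicated(df$chrom), , drop = FALSE]
  }
  df
}

#' Summarise clusters as a table (debug dump)
#'
#' @param clusters List from [cluster_pairs()].
#' @return `data.frame` with one row per cluster.
#' @export
cluster_table <- function(clusters) {
  do.call(rbind, lapply(clusters, function(cl) {
    data.frame(chrom_i = cl$chrom_i, start_i = cl$span_i[1],
               end_i = cl$span_i[2], strand_i = cl$strand_i,
               chrom_j = cl$chrom_j, start_j = cl$span_j[1],
               end_j = cl$span_j[2], strand_j = cl$strand_j,
               n_pairs = cl$n_pairs, stringsAsFactors = FALSE)
  }))
}
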