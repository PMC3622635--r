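# Independent brute-force oracles and small fixture builders used across the
# test files. The oracles share no code with the implementation paths they
# check.

# Transitive-closure clustering oracle: pairs belong together iff they share
# (chromosome pair, strand pair) and their junction-facing coordinates are
# within L on both sides, closed transitively; groups below min_pairs are
# dropped. Returns a canonical set representation (sorted list of sorted
# qname vectors).
cluster_oracle <- function(pairs, L, min_pairs = 2) {
  n <- nrow(pairs)
  if (!n) return(list())
  adj <- matrix(FALSE, n, n)
  for (u in seq_len(n)) {
    for (v in seq_len(n)) {
      adj[u, v] <- pairs$chrom_i[u] == pairs$chrom_i[v] &&
        pairs$chrom_j[u] == pairs$chrom_j[v] &&
        pairs$strand_i[u] == pairs$strand_i[v] &&
        pairs$strand_j[u] == pairs$strand_j[v] &&
        abs(pairs$c_i[u] - pairs$c_i[v]) <= L &&
        abs(pairs$c_j[u] - pairs$c_j[v]) <= L
    }
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (u in seq_len(n)) for (v in seq_len(n)) {
      if (adj[u, v] && comp[v] != comp[u]) {
        comp[comp == comp[v]] <- comp[u]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  groups <- split(pairs$qname, comp)
  groups <- Filter(function(g) length(g) >= min_pairs, groups)
  canonical_groups(groups)
}

canonical_groups <- function(groups) {
  groups <- unname(lapply(groups, function(g) sort(unname(g))))
  groups[order(vapply(groups, `[`, character(1), 1))]
}

cluster_groups <- function(clusters) {
  canonical_groups(lapply(clusters, `[[`, "qnames"))
}

# Exhaustive truth/call matching oracle: maximise the number of matched
# truth junctions, then minimise total breakpoint error. Small n only.
match_oracle <- function(calls, truth, tol) {
  n_t <- nrow(truth)
  errs <- function(t, cc) {
    same <- calls$chrom_i[cc] == truth$chr1[t] & calls$chrom_j[cc] == truth$chr2[t]
    cross <- calls$chrom_i[cc] == truth$chr2[t] & calls$chrom_j[cc] == truth$chr1[t]
    if (same) c(abs(calls$bkpt_i[cc] - truth$bkpt1[t]),
                abs(calls$bkpt_j[cc] - truth$bkpt2[t]))
    else if (cross) c(abs(calls$bkpt_j[cc] - truth$bkpt1[t]),
                      abs(calls$bkpt_i[cc] - truth$bkpt2[t]))
    else c(Inf, Inf)
  }
  best <- list(n = -1, err = Inf)
  recurse <- function(t, used, n_matched, tot_err, errv) {
    if (t > n_t) {
      if (n_matched > best$n ||
          (n_matched == best$n && tot_err < best$err)) {
        best <<- list(n = n_matched, err = tot_err, errv = errv)
      }
      return(invisible())
    }
    recurse(t + 1, used, n_matched, tot_err, errv)  # truth t unmatched
    for (cc in seq_len(nrow(calls))) {
      if (used[cc]) next
      e <- errs(t, cc)
      if (all(e <= tol)) {
        used[cc] <- TRUE
        recurse(t + 1, used, n_matched + 1, tot_err + sum(e), c(errv, e))
        used[cc] <- FALSE
      }
    }
  }
  recurse(1, logical(nrow(calls)), 0, 0, numeric(0))
  list(se_num = best$n,
       abe = if (best$n > 0) best$err / (2 * best$n) else NA_real_)
}

# Synthetic chimeric-pair table builder (for clustering tests).
make_pairs <- function(c_i, c_j, strand_i = "+", strand_j = "-",
                       chrom_i = "chrA", chrom_j = "chrB",
                       qname = sprintf("p%03d", seq_along(c_i))) {
  data.frame(qname = qname,
             chrom_i = chrom_i, pos_i = c_i - 99, end_i = c_i,
             strand_i = strand_i,
             chrom_j = chrom_j, pos_j = c_j, end_j = c_j + 99,
             strand_j = strand_j,
             c_i = c_i, c_j = c_j, stringsAsFactors = FALSE)
}

# Synthetic breakpoint-call row (cluster-strand signature convention).
make_call <- function(ci, bi, si, cj, bj, sj, id = 1L) {
  data.frame(chrom_i = ci, bkpt_i = bi, strand_i = si,
             chrom_j = cj, bkpt_j = bj, strand_j = sj,
             n_pairs = 10L, n_clips_i = 3L, n_clips_j = 3L, n_realign = 2L,
             mode_support_i = 3L, mode_support_j = 3L, call_id = id,
             stringsAsFactors = FALSE)
}

# One-junction toy study: unbalanced chrA->chrB fusion.
tiny_design <- function(bkpt1 = 60000, bkpt2 = 40000,
                        len = c(chrA = 100000, chrB = 100000)) {
  list(truth = data.frame(chr1 = "chrA", bkpt1 = bkpt1, strand1 = "+",
                          chr2 = "chrB", bkpt2 = bkpt2, strand2 = "+",
                          type = "U", stringsAsFactors = FALSE),
       chrom_lengths = len)
}

tiny_sim <- function(seed = 7, coverage = 15, mut_rate = 0, base_error = 0,
                     design = tiny_design(), ...) {
  ref <- random_reference(design$chrom_lengths, seed = seed)
  fg <- forge_genome(ref, design$truth)
  sim <- simulate_reads(fg, sim_config(coverage = coverage, seed = seed,
                                       mut_rate = mut_rate,
                                       base_error = base_error, ...))
  list(ref = ref, fg = fg, sim = sim)
}

# Minimal inline SAM text fixture.
sam_fixture <- function(records, lengths = c(chr1 = 10000, chr2 = 10000)) {
  path <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(lengths), lengths))
  writeLines(c(hdr, records), path)
  path
}

sam_record <- function(qname, flag, chrom, pos, mapq, cigar, seq,
                       mchrom = "=", mpos = pos) {
  paste(qname, flag, chrom, pos, mapq, cigar, mchrom, mpos, 0, seq,
        strrep("I", nchar(seq)), sep = "\t")
}
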