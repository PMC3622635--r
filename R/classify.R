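# Chimeric breakpoint classification: balanced / unbalanced translocation,
# direct / inverted interchromosomal insertion.
#
# The classification rules are reconstructed from the structure of the truth
# encoding and the default reciprocal tolerance; see the methods vignette for
# the derivation and its limits. In brief, for two calls on one chromosome
# pair with opposite strand signatures on both chromosomes:
#   * one chromosome's breakpoints co-locating (recipient) while the other's
#     bracket a sizeable segment (donor)  -> interchromosomal insertion,
#     inverted when each call's two strands are equal (an inversion across
#     the junction flips one side's read orientation);
#   * both separations small (within recip_tol) -> balanced translocation,
#     the separation being a duplication/deletion at the exchange point.
# A breakpoint-adjacent duplication at a reciprocal exchange is structurally
# identical, in reference coordinates, to a direct insertion of the
# duplicated segment; `min_donor_span` draws the scale line between the two.

#' Classify breakpoint calls into rearrangement events
#'
#' Calls are grouped by unordered chromosome pair and partnered greedily
#' (closest pair of calls first, by summed per-chromosome separation, with a
#' deterministic tie order), each call joining at most one event. A partnered
#' pair is an insertion or balanced translocation per the rules above; every
#' unpartnered call is an unbalanced translocation.
#'
#' @param calls Breakpoint-call table from [resolve_breakpoints()].
#' @param recip_tol Maximum overlap or separation (bp) of reciprocal
#'   breakpoints on each chromosome for a balanced translocation
#'   (default 1e6).
#' @param insertion_site_tol Maximum separation (bp) of the two recipient
#'   breakpoints of an insertion; they arise from one physical site, so the
#'   default is the paired-end uncertainty `L` when `stats` is supplied,
#'   else 1000.
#' @param min_donor_span Minimum donor-side separation (bp) for an insertion
#'   (default 1e4); smaller bracketed segments are read as breakpoint
#'   duplications of a balanced exchange.
#' @param stats Optional [insert_stats()]; sets `insertion_site_tol = L`.
#' @param centromeres Optional centromere table ([read_centromeres()]);
#'   events with any breakpoint inside a centromere are flagged
#'   low-confidence rather than dropped.
#' @return `data.frame` of events: `event_id`, `label` (`UNBALANCED`,
#'   `BALANCED`, `INSERTION_DIRECT`, `INSERTION_INVERTED`), `call_ids`
#'   (comma-separated), call coordinates, `donor_chrom`, `donor_start`,
#'   `donor_end`, `recipient_chrom`, `recipient_pos` (insertions only),
#'   `low_confidence`.
#' @export
classify_events <- function(calls, recip_tol = 1e6, insertion_site_tol = NULL,
                            min_donor_span = 1e4, stats = NULL,
                            centromeres = NULL) {
  if (is.null(insertion_site_tol)) {
    insertion_site_tol <- if (!is.null(stats)) stats$L else 1000
  }
  n <- nrow(calls)
  if (!n) return(.empty_events())
  if (is.null(calls$call_id)) calls$call_id <- seq_len(n)
  # canonical unordered chromosome pair key
  key <- ifelse(calls$chrom_i <= calls$chrom_j,
                paste(calls$chrom_i, calls$chrom_j, sep = "\r"),
                paste(calls$chrom_j, calls$chrom_i, sep = "\r"))
  # per-call coordinates keyed by canonical side A (= lexicographically or
  # header-order first chromosome of the pair): within one group all calls
  # share the same canonical pair, so A/B are comparable across calls.
  swap <- calls$chrom_i > calls$chrom_j
  A_chrom <- ifelse(swap, calls$chrom_j, calls$chrom_i)
  B_chrom <- ifelse(swap, calls$chrom_i, calls$chrom_j)
  A_bkpt <- ifelse(swap, calls$bkpt_j, calls$bkpt_i)
  B_bkpt <- ifelse(swap, calls$bkpt_i, calls$bkpt_j)
  A_strand <- ifelse(swap, calls$strand_j, calls$strand_i)
  B_strand <- ifelse(swap, calls$strand_i, calls$strand_j)

  assigned <- rep(FALSE, n)
  events <- list()
  add_event <- function(label, ids, donor = rep(NA, 3), recip = rep(NA, 2)) {
    events[[length(events) + 1]] <<- data.frame(
      label = label, call_ids = paste(calls$call_id[ids], collapse = ","),
      chrom_1 = calls$chrom_i[ids[1]], bkpt_1 = calls$bkpt_i[ids[1]],
      chrom_2 = calls$chrom_j[ids[1]], bkpt_2 = calls$bkpt_j[ids[1]],
      donor_chrom = as.character(donor[1]), donor_start = as.numeric(donor[2]),
      donor_end = as.numeric(donor[3]), recipient_chrom = as.character(recip[1]),
      recipient_pos = as.numeric(recip[2]), low_confidence = FALSE,
      stringsAsFactors = FALSE)
  }

  for (g in sort(unique(key))) {
    idx <- which(key == g)
    if (length(idx) >= 2) {
      cand <- .partner_candidates(idx, calls$call_id, A_bkpt, B_bkpt,
                                  A_strand, B_strand, recip_tol,
                                  insertion_site_tol, min_donor_span)
      for (r in seq_len(nrow(cand))) {
        a <- cand$a[r]; b <- cand$b[r]
        if (assigned[a] || assigned[b]) next
        assigned[c(a, b)] <- TRUE
        # deterministic representative: smaller call id first
        if (calls$call_id[b] < calls$call_id[a]) { tmp <- a; a <- b; b <- tmp }
        if (cand$type[r] == "INSERTION") {
          donor_is_A <- cand$donor_is_A[r]
          d_bk <- sort(c(if (donor_is_A) A_bkpt[a] else B_bkpt[a],
                         if (donor_is_A) A_bkpt[b] else B_bkpt[b]))
          d_chrom <- if (donor_is_A) A_chrom[a] else B_chrom[a]
          r_chrom <- if (donor_is_A) B_chrom[a] else A_chrom[a]
          r_pos <- min(if (donor_is_A) B_bkpt[c(a, b)] else A_bkpt[c(a, b)])
          inverted <- calls$strand_i[a] == calls$strand_j[a]
          add_event(if (inverted) "INSERTION_INVERTED" else "INSERTION_DIRECT",
                    c(a, b), donor = c(d_chrom, d_bk), recip = c(r_chrom, r_pos))
        } else {
          add_event("BALANCED", c(a, b))
        }
      }
    }
    for (i in idx[!assigned[idx]]) {
      assigned[i] <- TRUE
      add_event("UNBALANCED", i)
    }
  }
  ev <- do.call(rbind, events)
  ev <- ev[order(ev$chrom_1, ev$bkpt_1, ev$chrom_2, ev$bkpt_2), , drop = FALSE]
  ev <- cbind(event_id = seq_len(nrow(ev)), ev)
  rownames(ev) <- NULL
  if (!is.null(centromeres)) {
    in_cen <- function(chrom, pos) {
      m <- match(chrom, centromeres$chrom)
      !is.na(m) & pos >= centromeres$start[m] & pos <= centromeres$end[m]
    }
    ev$low_confidence <- in_cen(ev$chrom_1, ev$bkpt_1) |
      in_cen(ev$chrom_2, ev$bkpt_2)
  }
  ev
}

# Enumerate partnerable call pairs within one chromosome-pair group, ordered
# by summed breakpoint separation (then call order) for greedy matching.
.partner_candidates <- function(idx, call_ids, A_bkpt, B_bkpt, A_strand,
                                B_strand, recip_tol, site_tol,
                                min_donor_span) {
  out <- data.frame(a = integer(), b = integer(), dist = numeric(),
                    type = character(), donor_is_A = logical(),
                    stringsAsFactors = FALSE)
  for (u in seq_along(idx)) {
    for (v in seq_len(u - 1L)) {
      a <- idx[v]; b <- idx[u]
      if (A_strand[a] == A_strand[b] || B_strand[a] == B_strand[b]) next
      sepA <- abs(A_bkpt[a] - A_bkpt[b])
      sepB <- abs(B_bkpt[a] - B_bkpt[b])
      type <- NA_character_; donor_is_A <- NA
      if (min(sepA, sepB) <= site_tol && max(sepA, sepB) >= min_donor_span) {
        type <- "INSERTION"
        donor_is_A <- sepA >= sepB
      } else if (sepA <= recip_tol && sepB <= recip_tol) {
        type <- "BALANCED"
      }
      if (!is.na(type)) {
        out <- rbind(out, data.frame(a = a, b = b, dist = sepA + sepB,
                                     type = type, donor_is_A = donor_is_A,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  # content-based tie order so greedy matching ignores input row order
  out[order(out$dist, pmin(call_ids[out$a], call_ids[out$b]),
            pmax(call_ids[out$a], call_ids[out$b])), , drop = FALSE]
}

.empty_events <- function() {
  data.frame(event_id = integer(), label = character(), call_ids = character(),
             chrom_1 = character(), bkpt_1 = numeric(), chrom_2 = character(),
             bkpt_2 = numeric(), donor_chrom = character(),
             donor_start = numeric(), donor_end = numeric(),
             recipient_chrom = character(), recipient_pos = numeric(),
             low_confidence = logical(), stringsAsFactors = FALSE)
}
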