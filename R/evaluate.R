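# Scoring predicted breakpoints against a truth table.

#' Evaluate breakpoint calls against a variant truth table
#'
#' A call matches a truth junction when the unordered chromosome pair agrees
#' and both breakpoints lie within `match_tol` of the truth coordinates.
#' Candidate matches are ranked by total breakpoint distance and accepted
#' greedily, so each truth junction is matched by at most one call (the
#' nearest) and each call matches at most one junction. Reported metrics
#' follow the conventional table layout:
#' sensitivity SE = matched junctions / all junctions;
#' SP = matched calls / all calls (a precision-style quantity: the
#' denominator is the call count, not a true-negative count); average
#' breakpoint error ABE = mean absolute difference over both breakpoints of
#' every matched junction, in bp.
#'
#' @param calls Breakpoint-call table ([resolve_breakpoints()]).
#' @param truth Truth table ([read_truth()] / the simulator's `truth`).
#' @param match_tol Matching tolerance (bp); use the proximity length `L`
#'   unless there is a reason not to.
#' @return An `eval_result`: list with `se_num`, `se_den`, `sp_num`,
#'   `sp_den`, `abe` (`NA` when nothing matched), and `per_event` (one row
#'   per truth junction with the matched call and per-side errors).
#' @export
evaluate_calls <- function(calls, truth, match_tol) {
  stopifnot(nrow(truth) > 0, match_tol > 0)
  n_truth <- nrow(truth)
  n_calls <- nrow(calls)
  per <- data.frame(truth_row = seq_len(n_truth),
                    chr1 = truth$chr1, bkpt1 = truth$bkpt1,
                    chr2 = truth$chr2, bkpt2 = truth$bkpt2,
                    call_id = NA_integer_, err1 = NA_real_, err2 = NA_real_,
                    stringsAsFactors = FALSE)
  if (n_calls) {
    cand <- list()
    for (t in seq_len(n_truth)) {
      same <- calls$chrom_i == truth$chr1[t] & calls$chrom_j == truth$chr2[t]
      cross <- calls$chrom_i == truth$chr2[t] & calls$chrom_j == truth$chr1[t]
      e1 <- ifelse(same, abs(calls$bkpt_i - truth$bkpt1[t]),
                   abs(calls$bkpt_j - truth$bkpt1[t]))
      e2 <- ifelse(same, abs(calls$bkpt_j - truth$bkpt2[t]),
                   abs(calls$bkpt_i - truth$bkpt2[t]))
      ok <- (same | cross) & e1 <= match_tol & e2 <= match_tol
      if (any(ok)) {
        cand[[length(cand) + 1]] <- data.frame(
          truth_row = t, call = which(ok), err1 = e1[ok], err2 = e2[ok])
      }
    }
    if (length(cand)) {
      cand <- do.call(rbind, cand)
      cand <- cand[order(cand$err1 + cand$err2, cand$truth_row, cand$call), ]
      used_t <- logical(n_truth); used_c <- logical(n_calls)
      for (r in seq_len(nrow(cand))) {
        t <- cand$truth_row[r]; cc <- cand$call[r]
        if (used_t[t] || used_c[cc]) next
        used_t[t] <- TRUE; used_c[cc] <- TRUE
        per$call_id[t] <- if (!is.null(calls$call_id)) calls$call_id[cc] else cc
        per$err1[t] <- cand$err1[r]; per$err2[t] <- cand$err2[r]
      }
    }
  }
  matched <- !is.na(per$call_id)
  errs <- c(per$err1[matched], per$err2[matched])
  structure(list(se_num = sum(matched), se_den = n_truth,
                 sp_num = sum(matched), sp_den = n_calls,
                 abe = if (length(errs)) mean(errs) else NA_real_,
                 per_event = per),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("SE %d/%d  SP %d/%d  ABE %s\n", x$se_num, x$se_den,
              x$sp_num, x$sp_den,
              if (is.na(x$abe)) "NA" else sprintf("%.2f bp", x$abe)))
  invisible(x)
}
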