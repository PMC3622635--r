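# Top-level caller: estimate -> cluster -> resolve, plus output writers and
# the config-driven end-to-end runner.

#' Call interchromosomal rearrangements from paired-end alignments
#'
#' The full hybrid pipeline: estimates insert-size statistics (unless
#' supplied), collects chimeric read pairs, clusters them under the
#' proximity length `L`, types each cluster's fusion orientation, and
#' resolves base-pair breakpoints by soft-clip harvest and windowed
#' realignment. Classification of the resulting calls into events is a
#' separate step ([classify_events()], or `summary()` on the returned
#' object).
#'
#' @param alignments Path to a coordinate-sorted SAM/BAM file, an alignment
#'   table from [read_alignments()], or a `sim_reads` object.
#' @param reference Reference sequences ([Biostrings::DNAStringSet] or
#'   FASTA path); must be the reference the reads were aligned to.
#' @param stats Optional [insert_stats()]; estimated from the data when
#'   `NULL`.
#' @param k Stdev multiplier for `L` when estimating stats.
#' @param min_mapq Mapping-quality filter applied when `alignments` is a
#'   file path.
#' @param min_pairs Minimum chimeric pairs per cluster.
#' @param min_clip Minimum soft-clip length considered for realignment
#'   (20 bp default; shorter clips realign unreliably).
#' @param max_clips Per-window soft-clip cap (efficiency).
#' @param max_mismatch_frac Realignment edit-distance budget.
#' @param centromeres Optional centromere table ([read_centromeres()]) for
#'   arm nomenclature and low-confidence flags.
#' @return An object of class `interloc`: list with `calls` (breakpoint
#'   call table), `clusters` (cluster summary table), `unresolved`,
#'   `stats`, `orientations` (per-call arm/side signatures), and the
#'   parameters used.
#' @examples
#' design <- list(truth = data.frame(
#'   chr1 = "chrA", bkpt1 = 60000, strand1 = "+",
#'   chr2 = "chrB", bkpt2 = 40000, strand2 = "+", type = "U"),
#'   chrom_lengths = c(chrA = 100000, chrB = 100000))
#' ref <- random_reference(design$chrom_lengths, seed = 7)
#' fg <- forge_genome(ref, design$truth)
#' sim <- simulate_reads(fg, sim_config(coverage = 12, seed = 7))
#' fit <- interloc(sim, ref)
#' fit
#' @export
interloc <- function(alignments, reference, stats = NULL, k = 3,
                     min_mapq = 20, min_pairs = 2, min_clip = 20,
                     max_clips = 5, max_mismatch_frac = 0.1,
                     centromeres = NULL) {
  if (inherits(alignments, "sim_reads")) alignments <- alignments$alignments
  aln <- if (is.character(alignments)) {
    read_alignments(alignments, min_mapq = min_mapq)
  } else alignments
  ref <- load_reference(reference)
  ref_lengths <- attr(aln, "ref_lengths")
  if (is.null(ref_lengths)) {
    ref_lengths <- stats::setNames(Biostrings::width(ref), names(ref))
  }
  if (is.null(stats)) stats <- estimate_insert_stats(aln, k = k)
  pairs <- collect_chimeric_pairs(aln, chrom_order = names(ref_lengths))
  clusters <- cluster_pairs(pairs, stats, min_pairs = min_pairs)
  clips <- extract_softclips(aln, min_clip = min_clip)
  calls <- resolve_breakpoints(clusters, clips, stats, ref, ref_lengths,
                               min_clip = min_clip, max_clips = max_clips,
                               max_mismatch_frac = max_mismatch_frac)
  orientations <- lapply(clusters, type_fusion, centromeres = centromeres)
  structure(list(
    calls = calls,
    clusters = cluster_table(clusters),
    unresolved = attr(calls, "unresolved"),
    orientations = orientations,
    stats = stats,
    n_chimeric_pairs = nrow(pairs),
    params = list(k = k, min_mapq = min_mapq, min_pairs = min_pairs,
                  min_clip = min_clip, max_clips = max_clips,
                  max_mismatch_frac = max_mismatch_frac),
    centromeres = centromeres,
    ref_lengths = ref_lengths), class = "interloc")
}

#' @export
print.interloc <- function(x, ...) {
  cat("interloc: interchromosomal rearrangement calls\n")
  print(x$stats)
  cat(sprintf("%d chimeric pair(s), %d cluster(s), %d breakpoint call(s)",
              x$n_chimeric_pairs,
              if (is.null(x$clusters)) 0L else nrow(x$clusters),
              nrow(x$calls)))
  nu <- if (is.null(x$unresolved)) 0L else nrow(x$unresolved)
  cat(sprintf(", %d unresolved candidate(s)\n", nu))
  if (nrow(x$calls)) {
    print(utils::head(x$calls[, c("chrom_i", "bkpt_i", "strand_i", "chrom_j",
                                  "bkpt_j", "strand_j", "n_pairs",
                                  "n_clips_i", "n_clips_j")], 10))
    if (nrow(x$calls) > 10) cat("... (", nrow(x$calls), "calls )\n")
  } else if (x$n_chimeric_pairs == 0) {
    cat("no candidates: no chimeric read pairs in input\n")
  }
  invisible(x)
}

#' @export
summary.interloc <- function(object, recip_tol = 1e6,
                             insertion_site_tol = NULL,
                             min_donor_span = 1e4, ...) {
  events <- classify_events(object$calls, recip_tol = recip_tol,
                            insertion_site_tol = insertion_site_tol,
                            min_donor_span = min_donor_span,
                            stats = object$stats,
                            centromeres = object$centromeres)
  out <- list(object = object, events = events)
  class(out) <- "summary.interloc"
  out
}

#' @export
print.summary.interloc <- function(x, ...) {
  print(x$object)
  cat("\nevent classification:\n")
  if (nrow(x$events)) {
    print(table(x$events$label))
    ins <- x$events[grepl("^INSERTION", x$events$label), , drop = FALSE]
    for (r in seq_len(nrow(ins))) {
      cat(sprintf("  %s: donor %s:%.0f-%.0f -> recipient %s:%.0f\n",
                  ins$label[r], ins$donor_chrom[r], ins$donor_start[r],
                  ins$donor_end[r], ins$recipient_chrom[r],
                  ins$recipient_pos[r]))
    }
  } else cat("  (no events)\n")
  invisible(x)
}

#' @export
as.data.frame.interloc <- function(x, ...) x$calls

#' Write breakpoint calls as TSV / BEDPE / VCF
#'
#' `write_calls()` mirrors the truth-table columns
#' (`Chr1/Bkpt1/Strand1/Chr2/Bkpt2/Strand2`, strand here being the cluster
#' strand signature) plus support columns. `write_calls_bedpe()` writes
#' 0-based half-open BEDPE. `write_calls_vcf()` writes paired VCF 4.2
#' breakend (BND) records cross-referenced by MATEID, the bracket notation
#' encoding the orientation signature.
#'
#' @param fit An `interloc` object (or a bare call table for `write_calls`).
#' @param path Output path.
#' @param reference Reference sequences (VCF only; REF base lookup).
#' @return `path`, invisibly.
#' @export
write_calls <- function(fit, path) {
  calls <- if (inherits(fit, "interloc")) fit$calls else fit
  out <- data.frame(Chr1 = calls$chrom_i, Bkpt1 = calls$bkpt_i,
                    Strand1 = calls$strand_i, Chr2 = calls$chrom_j,
                    Bkpt2 = calls$bkpt_j, Strand2 = calls$strand_j,
                    NPairs = calls$n_pairs, NClips1 = calls$n_clips_i,
                    NClips2 = calls$n_clips_j, NRealign = calls$n_realign,
                    ModeSupport1 = calls$mode_support_i,
                    ModeSupport2 = calls$mode_support_j,
                    CallId = calls$call_id, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls
#' @export
write_calls_bedpe <- function(fit, path) {
  calls <- if (inherits(fit, "interloc")) fit$calls else fit
  out <- data.frame(calls$chrom_i, calls$bkpt_i - 1, calls$bkpt_i,
                    calls$chrom_j, calls$bkpt_j - 1, calls$bkpt_j,
                    paste0("call", calls$call_id), calls$n_pairs,
                    calls$strand_i, calls$strand_j)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_calls
#' @export
write_calls_vcf <- function(fit, path, reference) {
  calls <- if (inherits(fit, "interloc")) fit$calls else fit
  ref <- load_reference(reference)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=interloc",
           sprintf("##contig=<ID=%s,length=%d>", names(ref),
                   Biostrings::width(ref)),
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Partner breakend\">",
           "##INFO=<ID=PAIRS,Number=1,Type=Integer,Description=\"Supporting chimeric pairs\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  recs <- character(0)
  for (r in seq_len(nrow(calls))) {
    # bracket notation: a '+' cluster strand joins sequence extending left
    # of (and including) the breakpoint; '-' joins rightward.
    bnd <- function(chrom, pos, strand, mchrom, mpos, mstrand, id, mid) {
      base <- as.character(Biostrings::subseq(ref[[chrom]], pos, pos))
      mate <- sprintf("%s:%d", mchrom, mpos)
      alt <- if (strand == "+" && mstrand == "-") paste0(base, "[", mate, "[")
      else if (strand == "+" && mstrand == "+") paste0(base, "]", mate, "]")
      else if (strand == "-" && mstrand == "+") paste0("]", mate, "]", base)
      else paste0("[", mate, "[", base)
      sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\tSVTYPE=BND;MATEID=%s;PAIRS=%d",
              chrom, pos, id, base, alt, mid, calls$n_pairs[r])
    }
    ida <- sprintf("bnd_%d_a", calls$call_id[r])
    idb <- sprintf("bnd_%d_b", calls$call_id[r])
    recs <- c(recs,
              bnd(calls$chrom_i[r], calls$bkpt_i[r], calls$strand_i[r],
                  calls$chrom_j[r], calls$bkpt_j[r], calls$strand_j[r],
                  ida, idb),
              bnd(calls$chrom_j[r], calls$bkpt_j[r], calls$strand_j[r],
                  calls$chrom_i[r], calls$bkpt_i[r], calls$strand_i[r],
                  idb, ida))
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Write classified events as TSV
#'
#' @param events Event table from [classify_events()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline from a configuration
#'
#' Config-driven end-to-end execution: either `simulate` a design (design
#' name or truth-table path plus simulation settings) or `call` on an
#' existing SAM/BAM + FASTA, then resolve, classify, optionally evaluate,
#' and write the outputs (calls TSV, events TSV, optional BEDPE/VCF, and a
#' run log capturing every parameter and seed).
#'
#' @param config A YAML file path or an equivalent named list. Recognised
#'   top-level keys: `alignments`, `reference`, `centromeres`, `truth`,
#'   `simulate` (logical or list of [sim_config()] overrides plus `design`
#'   = "design1"/"design2"), `out_dir`, `seed`, caller parameters
#'   (`k`, `min_mapq`, `min_pairs`, `min_clip`, `max_clips`,
#'   `max_mismatch_frac`, `recip_tol`, `insertion_site_tol`,
#'   `min_donor_span`, `match_tol`).
#' @return List with `fit` (`interloc` object), `events`, and (when truth
#'   is available) `evaluation`, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  get <- function(key, default) if (!is.null(cfg[[key]])) cfg[[key]] else default
  out_dir <- get("out_dir", ".")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- get("seed", 1)
  logf <- file.path(out_dir, "run_log.txt")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                               append = TRUE)
  cat("", file = logf)
  logline("interloc run: %s", format(Sys.time()))
  logline("seed: %d", as.integer(seed))

  truth <- NULL
  if (!is.null(cfg$simulate) && !identical(cfg$simulate, FALSE)) {
    sc <- if (is.list(cfg$simulate)) cfg$simulate else list()
    design_name <- if (!is.null(sc$design)) sc$design else "design1"
    design <- if (!is.null(sc$truth)) {
      list(truth = read_truth(sc$truth), chrom_lengths = unlist(sc$chrom_lengths))
    } else if (design_name == "design2") sim_design_2() else sim_design_1()
    sc$design <- NULL; sc$truth <- NULL; sc$chrom_lengths <- NULL
    sc$seed <- seed
    conf <- do.call(sim_config, sc)
    ref <- random_reference(design$chrom_lengths, seed = seed)
    fg <- forge_genome(ref, design$truth)
    sim <- simulate_reads(fg, conf)
    truth <- sim$truth
    aln <- sim$alignments
    logline("simulated: %d pairs, coverage %gX, read length %d",
            sim$log$n_pairs, conf$coverage, conf$read_len)
  } else {
    if (is.null(cfg$alignments) || is.null(cfg$reference)) {
      stop("config needs 'alignments' and 'reference' (or 'simulate')")
    }
    ref <- load_reference(cfg$reference)
    aln <- cfg$alignments
    if (!is.null(cfg$truth)) truth <- read_truth(cfg$truth)
  }
  centro <- if (!is.null(cfg$centromeres)) read_centromeres(cfg$centromeres)
  fit <- interloc(aln, ref,
                  k = get("k", 3), min_mapq = get("min_mapq", 20),
                  min_pairs = get("min_pairs", 2),
                  min_clip = get("min_clip", 20),
                  max_clips = get("max_clips", 5),
                  max_mismatch_frac = get("max_mismatch_frac", 0.1),
                  centromeres = centro)
  for (p in names(fit$params)) logline("%s: %s", p, format(fit$params[[p]]))
  logline("L: %.1f", fit$stats$L)
  if (!nrow(fit$calls) && fit$n_chimeric_pairs == 0) {
    logline("no candidates: no chimeric read pairs in input")
    message("no candidates: no chimeric read pairs in input")
  }
  events <- classify_events(fit$calls, recip_tol = get("recip_tol", 1e6),
                            insertion_site_tol = cfg$insertion_site_tol,
                            min_donor_span = get("min_donor_span", 1e4),
                            stats = fit$stats, centromeres = centro)
  write_calls(fit, file.path(out_dir, "calls.tsv"))
  write_events(events, file.path(out_dir, "events.tsv"))
  if (isTRUE(cfg$bedpe)) write_calls_bedpe(fit, file.path(out_dir, "calls.bedpe"))
  if (isTRUE(cfg$vcf)) write_calls_vcf(fit, file.path(out_dir, "calls.vcf"), ref)
  res <- list(fit = fit, events = events)
  if (!is.null(truth)) {
    ev <- evaluate_calls(fit$calls, truth,
                         match_tol = get("match_tol", fit$stats$L))
    logline("evaluation: SE %d/%d SP %d/%d ABE %s", ev$se_num, ev$se_den,
            ev$sp_num, ev$sp_den, format(ev$abe))
    res$evaluation <- ev
  }
  invisible(res)
}
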