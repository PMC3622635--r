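# Forging rearranged genomes from a variant truth table.
#
# Truth-table convention: one row per chimeric junction, columns
# chr1/bkpt1/strand1/chr2/bkpt2/strand2/type. The (chr1, bkpt1) side
# immediately precedes the junction in the derived chromosome and
# (chr2, bkpt2) immediately follows it; each bkpt is the reference
# coordinate of the junction-adjacent *retained* base, and each strand is
# the orientation of that side's segment in the derived genome ('-' =
# reverse-complemented). Types: U (one-way fusion, one row), B (reciprocal
# exchange, two partnered rows, optionally with a breakpoint duplication),
# II (interchromosomal insertion, two partnered rows; '-' donor strands
# mark an inverted insertion). Partnered B/II rows must be adjacent in the
# table.

#' Read / write a variant truth table
#'
#' Tab-separated, columns `chr1, bkpt1, strand1, chr2, bkpt2, strand2, type`.
#'
#' @param path File path.
#' @return `data.frame` truth table.
#' @export
read_truth <- function(path) {
  tr <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "numeric", "character",
                                         "character", "numeric", "character",
                                         "character"))
  .validate_truth(tr)
  tr
}

#' @rdname read_truth
#' @param truth Truth table to write.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a truth table as BEDPE
#'
#' One line per junction, both breakpoints as single-base intervals
#' (0-based half-open per the BED convention), name = row type + index,
#' strands from the truth columns.
#'
#' @param truth Truth table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_bedpe <- function(truth, path) {
  .validate_truth(truth)
  out <- data.frame(truth$chr1, truth$bkpt1 - 1, truth$bkpt1,
                    truth$chr2, truth$bkpt2 - 1, truth$bkpt2,
                    paste0(truth$type, seq_len(nrow(truth))), 0,
                    truth$strand1, truth$strand2)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.validate_truth <- function(truth) {
  need <- c("chr1", "bkpt1", "strand1", "chr2", "bkpt2", "strand2", "type")
  if (!all(need %in% names(truth))) {
    stop("truth table must have columns ", paste(need, collapse = ", "))
  }
  if (!all(truth$type %in% c("U", "B", "II"))) {
    stop("truth types must be U, B or II")
  }
  if (any(truth$chr1 == truth$chr2)) {
    stop("truth rows must be interchromosomal (chr1 != chr2)")
  }
  invisible(truth)
}

# Group truth rows into events: U rows stand alone; B and II rows pair with
# the next row of the same type.
.truth_events <- function(truth) {
  events <- list()
  i <- 1
  while (i <= nrow(truth)) {
    ty <- truth$type[i]
    if (ty == "U") {
      events[[length(events) + 1]] <- list(type = "U", rows = truth[i, , drop = FALSE])
      i <- i + 1
    } else {
      if (i == nrow(truth) || truth$type[i + 1] != ty) {
        stop(ty, " rows must come in adjacent partnered pairs (row ", i, ")")
      }
      events[[length(events) + 1]] <- list(type = ty,
                                           rows = truth[i:(i + 1), , drop = FALSE])
      i <- i + 2
    }
  }
  events
}

#' Forge a derived genome carrying the variants of a truth table
#'
#' Builds derived chromosomes by splicing reference slices according to each
#' event: an unbalanced translocation joins two chromosome parts one-way
#' (the unused parts are kept as remainder chromosomes, so sequence content
#' is conserved); a balanced pair performs the reciprocal exchange
#' (duplications at the exchange point fall out of the row coordinates); an
#' insertion excises the donor segment and splices it, reverse-complemented
#' for an inverted insertion, into the recipient site. Each reference
#' chromosome may participate in at most one event.
#'
#' @param ref Reference sequences ([Biostrings::DNAStringSet] or FASTA path).
#' @param truth Truth table (see [read_truth()]).
#' @return A `forged_genome`: list with `segments` (named list of
#'   segment runs, one per derived chromosome), `ref`, `truth` (input rows),
#'   and `junctions` (all inter-segment junctions regenerated from the
#'   derived structure; interchromosomal ones reproduce the truth rows).
#' @export
forge_genome <- function(ref, truth) {
  ref <- load_reference(ref)
  .validate_truth(truth)
  lens <- stats::setNames(Biostrings::width(ref), names(ref))
  bad1 <- truth$bkpt1 < 1 | truth$bkpt1 > lens[truth$chr1]
  bad2 <- truth$bkpt2 < 1 | truth$bkpt2 > lens[truth$chr2]
  if (any(bad1 | bad2, na.rm = TRUE) || anyNA(lens[truth$chr1]) ||
      anyNA(lens[truth$chr2])) {
    stop("truth coordinates outside their chromosomes (or unknown chromosome)")
  }
  events <- .truth_events(truth)
  used <- unlist(lapply(events, function(e) unique(c(e$rows$chr1, e$rows$chr2))))
  if (anyDuplicated(used)) {
    stop("overlapping variants: chromosome ", used[duplicated(used)][1],
         " participates in more than one event (unsupported)")
  }
  segs <- list()
  add <- function(name, s) { if (!is.null(s) && nrow(s)) segs[[name]] <<- s }
  nonempty <- function(s) if (s$end >= s$start) s else NULL
  for (e in events) {
    r <- e$rows
    if (e$type == "U") {
      c1 <- r$chr1; b1 <- r$bkpt1; s1 <- r$strand1
      c2 <- r$chr2; b2 <- r$bkpt2; s2 <- r$strand2
      p1 <- if (s1 == "+") seg_new(c1, 1, b1) else seg_new(c1, b1, lens[[c1]], "-")
      p2 <- if (s2 == "+") seg_new(c2, b2, lens[[c2]]) else seg_new(c2, 1, b2, "-")
      add(paste0("der_", c1, "_", c2), rbind(p1, p2))
      rem1 <- if (s1 == "+") seg_new(c1, b1 + 1, lens[[c1]]) else seg_new(c1, 1, b1 - 1)
      rem2 <- if (s2 == "+") seg_new(c2, 1, b2 - 1) else seg_new(c2, b2 + 1, lens[[c2]])
      add(paste0("rem_", c1), nonempty(rem1))
      add(paste0("rem_", c2), nonempty(rem2))
    } else if (e$type == "B") {
      if (any(r$strand1 != "+") || any(r$strand2 != "+")) {
        stop("balanced rows with inverted segments are not supported")
      }
      cA <- r$chr1[1]; a1 <- r$bkpt1[1]; cB <- r$chr2[1]; b1 <- r$bkpt2[1]
      if (r$chr1[2] != cB || r$chr2[2] != cA) {
        stop("balanced pair rows do not mirror each other")
      }
      b2 <- r$bkpt1[2]; a2 <- r$bkpt2[2]
      add(paste0("der_", cA, "_", cB),
          rbind(seg_new(cA, 1, a1), seg_new(cB, b1, lens[[cB]])))
      add(paste0("der_", cB, "_", cA),
          rbind(seg_new(cB, 1, b2), seg_new(cA, a2, lens[[cA]])))
    } else { # II
      chroms <- c(r$chr1, r$chr2)
      coords <- c(r$bkpt1, r$bkpt2)
      strands <- c(r$strand1, r$strand2)
      by_chrom <- split(seq_along(chroms), chroms)
      if (length(by_chrom) != 2 || any(lengths(by_chrom) != 2)) {
        stop("insertion pair rows must involve the same two chromosomes twice")
      }
      spread <- vapply(by_chrom, function(ii) diff(range(coords[ii])), numeric(1))
      recip <- names(by_chrom)[which.min(spread)]
      donor <- setdiff(names(by_chrom), recip)
      rc <- sort(coords[by_chrom[[recip]]])
      dc <- sort(coords[by_chrom[[donor]]])
      ds <- unique(strands[by_chrom[[donor]]])
      if (length(ds) != 1) stop("inconsistent donor strands in insertion pair")
      if (any(strands[by_chrom[[recip]]] != "+")) {
        stop("recipient strands of an insertion must be '+'")
      }
      add(paste0("der_", recip, "_", donor),
          rbind(seg_new(recip, 1, rc[1]),
                seg_new(donor, dc[1], dc[2], ds),
                seg_new(recip, rc[2], lens[[recip]])))
      rem <- Filter(Negate(is.null),
                    list(nonempty(seg_new(donor, 1, dc[1] - 1)),
                         nonempty(seg_new(donor, dc[2] + 1, lens[[donor]]))))
      add(paste0("rem_", donor), do.call(rbind, rem))
    }
  }
  untouched <- setdiff(names(ref), used)
  for (ch in untouched) segs[[ch]] <- seg_new(ch, 1, lens[[ch]])
  fg <- structure(list(segments = segs, ref = ref, truth = truth),
                  class = "forged_genome")
  fg$junctions <- genome_junctions(fg)
  fg
}

#' Enumerate the junctions of a forged (or mutated) genome
#'
#' Walks every derived chromosome's segment run and reports each adjacency
#' between two real reference slices: the junction-adjacent retained base
#' and segment orientation on both sides, the derived coordinate of the
#' junction, and whether it is interchromosomal (`chimeric = TRUE`; the
#' rows with `chimeric` reproduce the forge's truth table).
#'
#' @param fg A `forged_genome`.
#' @return `data.frame` with `der_chrom`, `der_pos` (derived coordinate of
#'   the last base before the junction), `chr1`, `bkpt1`, `strand1`, `chr2`,
#'   `bkpt2`, `strand2`, `chimeric`.
#' @export
genome_junctions <- function(fg) {
  out <- list()
  for (nm in names(fg$segments)) {
    s <- fg$segments[[nm]]
    real <- which(is.na(s$seq))
    if (length(real) < 2) next
    cum <- seg_cum(s)
    for (t in seq_len(length(real) - 1)) {
      k <- real[t]; k2 <- real[t + 1]
      if (k2 != k + 1) next  # separated by a novel (inserted) segment
      left <- s[k, ]; right <- s[k2, ]
      out[[length(out) + 1]] <- data.frame(
        der_chrom = nm, der_pos = cum[k],
        chr1 = left$src,
        bkpt1 = if (left$orient == "+") left$end else left$start,
        strand1 = left$orient,
        chr2 = right$src,
        bkpt2 = if (right$orient == "+") right$start else right$end,
        strand2 = right$orient,
        chimeric = left$src != right$src,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(der_chrom = character(), der_pos = numeric(),
                      chr1 = character(), bkpt1 = numeric(),
                      strand1 = character(), chr2 = character(),
                      bkpt2 = numeric(), strand2 = character(),
                      chimeric = logical(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Assemble the derived sequences of a forged genome
#'
#' @param fg A `forged_genome`.
#' @return [Biostrings::DNAStringSet] of derived chromosomes.
#' @export
assemble_genome <- function(fg) {
  out <- Biostrings::DNAStringSet(lapply(fg$segments, seg_assemble, ref = fg$ref))
  names(out) <- names(fg$segments)
  out
}

#' @export
print.forged_genome <- function(x, ...) {
  w <- vapply(x$segments, seg_total, numeric(1))
  cat("forged genome:", length(w), "derived chromosomes,",
      format(sum(w), big.mark = ","), "bp total;",
      sum(x$junctions$chimeric), "chimeric junction(s)\n")
  invisible(x)
}

#' Generate a random reference genome
#'
#' Independent uniform A/C/G/T sequence (GC fraction `gc`). Random toy
#' references carry no repeats or homology, so chimeric clusters can only
#' arise from planted junctions.
#'
#' @param lengths Named vector of chromosome lengths (bp).
#' @param seed RNG seed.
#' @param gc GC fraction (default 0.41, human-like).
#' @return [Biostrings::DNAStringSet].
#' @export
random_reference <- function(lengths, seed = 1, gc = 0.41) {
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- lapply(lengths, function(n) {
    paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
  })
  out <- Biostrings::DNAStringSet(unlist(seqs))
  names(out) <- names(lengths)
  out
}

#' Bundled desk-scale rearrangement study designs
#'
#' Two toy multi-chromosome designs mirroring the published simulated
#' datasets at reduced scale: breakpoint coordinates scaled 1/200 (design 1)
#' or 1/400 (design 2) with 50 kb of sequence beyond each chromosome's
#' outermost breakpoint; insertion donor segments scaled 1/10 (20 kb and
#' 60 kb) so they remain far above both the proximity length and the
#' balanced-duplication scale; the balanced exchange of design 1 keeps its
#' absolute ~1 kb breakpoint duplication. Design 1: 12 junction rows
#' (6 U, 1 balanced pair with duplication, 2 insertion pairs, one
#' inverted), 18 chromosomes, ~4.4 Mb. Design 2: 9 rows (7 U, 1 balanced
#' pair, exactly reciprocal), 16 chromosomes, ~2.6 Mb.
#'
#' @return List with `truth` (truth table) and `chrom_lengths` (named
#'   vector).
#' @export
sim_design_1 <- function() {
  truth <- data.frame(
    chr1 = c("chr9", "chr5", "chr7", "chr10", "chr16", "chr4",
             "chr3", "chr6", "chr13", "chr14", "chr22", "chr1"),
    bkpt1 = c(365000, 200000, 55000, 25000, 30000, 45000,
              175000, 71000, 225000, 170000, 125000, 525000),
    strand1 = c("+", "+", "+", "-", "-", "+", "+", "+", "+", "+", "+", "-"),
    chr2 = c("chr11", "chr2", "chr12", "chr20", "chr18", "chr17",
             "chr6", "chr3", "chr14", "chr13", "chr1", "chr22"),
    bkpt2 = c(315000, 700000, 225000, 75000, 60000, 85000,
              70000, 175001, 150000, 225001, 585000, 125001),
    strand2 = c("+", "+", "-", "+", "+", "+", "+", "+", "+", "+", "-", "+"),
    type = c(rep("U", 6), "B", "B", "II", "II", "II", "II"),
    stringsAsFactors = FALSE)
  lengths <- c(chr9 = 415000, chr11 = 365000, chr5 = 250000, chr2 = 750000,
               chr7 = 105000, chr12 = 275000, chr10 = 75000, chr20 = 125000,
               chr16 = 80000, chr18 = 110000, chr4 = 95000, chr17 = 135000,
               chr3 = 225000, chr6 = 121000, chr13 = 275000, chr14 = 220000,
               chr22 = 175000, chr1 = 635000)
  list(truth = truth, chrom_lengths = lengths)
}

#' @rdname sim_design_1
#' @export
sim_design_2 <- function() {
  truth <- data.frame(
    chr1 = c("chr15", "chr13", "chr9", "chr21", "chr11",
             "chr16", "chr7", "chr6", "chr19"),
    bkpt1 = c(102500, 77500, 52500, 75000, 27500,
              57500, 110000, 230000, 87500),
    strand1 = c("+", "+", "-", "+", "+", "+", "+", "-", "+"),
    chr2 = c("chr18", "chr20", "chr17", "chr2", "chr12",
             "chr7", "chr16", "chr10", "chr14"),
    bkpt2 = c(125000, 107500, 150000, 87500, 167500,
              110001, 57501, 162500, 137500),
    strand2 = c("+", "+", "+", "-", "+", "+", "+", "+", "-"),
    type = c("U", "U", "U", "U", "U", "B", "B", "U", "U"),
    stringsAsFactors = FALSE)
  lengths <- c(chr15 = 152500, chr18 = 175000, chr13 = 127500, chr20 = 157500,
               chr9 = 102500, chr17 = 200000, chr21 = 125000, chr2 = 137500,
               chr11 = 77500, chr12 = 217500, chr16 = 107500, chr7 = 160000,
               chr6 = 280000, chr10 = 212500, chr19 = 137500, chr14 = 187500)
  list(truth = truth, chrom_lengths = lengths)
}
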