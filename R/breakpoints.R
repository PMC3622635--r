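# Base-pair breakpoint resolution: search windows, soft-clip harvest,
# windowed realignment across the fusion, and the coordinate-mode call.

#' Build the breakpoint search windows W and X for a cluster
#'
#' Each window extends from the cluster-side read that lies farthest from the
#' presumed junction toward the junction, for the proximity length `L`, so it
#' covers the read set's own span up to and including the junction (every
#' cluster read starts within `L` of the breakpoint). For a `+` side the
#' window runs rightward from the leftmost aligned base; for a `-` side,
#' leftward from the rightmost aligned base. Windows are truncated at the
#' chromosome ends.
#'
#' @param cluster A `chimeric_cluster`.
#' @param stats [insert_stats()] object providing `L`.
#' @param ref_lengths Named vector of reference lengths.
#' @return List with `W` and `X`, each a `break_window`: list with `chrom`,
#'   `start`, `end` (1-based inclusive), `side` ("i"/"j"), `facing`
#'   ("left"/"right": which read end faces the junction), `strand`.
#' @export
build_windows <- function(cluster, stats, ref_lengths) {
  L <- ceiling(stats$L)   # integer window length
  mk <- function(chrom, pos, end, strand, side) {
    if (strand == "+") {
      a <- min(pos); w <- c(a, a + L - 1)
    } else {
      b <- max(end); w <- c(b - L + 1, b)
    }
    w[1] <- max(1, w[1])
    w[2] <- min(ref_lengths[[chrom]], w[2])
    structure(list(chrom = chrom, start = w[1], end = w[2], side = side,
                   facing = if (strand == "+") "right" else "left",
                   strand = strand),
              class = "break_window")
  }
  list(W = mk(cluster$chrom_i, cluster$pos_i, cluster$end_i,
              cluster$strand_i, "i"),
       X = mk(cluster$chrom_j, cluster$pos_j, cluster$end_j,
              cluster$strand_j, "j"))
}

#' Harvest junction-facing soft clips inside a search window
#'
#' Keeps soft clips whose boundary lies inside the window and whose clipped
#' end faces the junction (a right clip for a right-facing window, a left
#' clip otherwise), with clip length at least `min_clip`. At most `max_clips`
#' clips are returned per window, first-encountered in coordinate order (an
#' efficiency cap: a single spanning read already resolves the boundary).
#'
#' @param clips Soft-clip table from [extract_softclips()].
#' @param window A `break_window` from [build_windows()].
#' @param min_clip Minimum clip length (default 20 bp).
#' @param max_clips Per-window cap (default 5).
#' @return Subset of `clips`, ordered by boundary.
#' @export
harvest_clips <- function(clips, window, min_clip = 20, max_clips = 5) {
  sel <- clips$chrom == window$chrom &
    clips$boundary >= window$start & clips$boundary <= window$end &
    clips$side == window$facing & clips$clip_len >= min_clip
  out <- clips[sel, , drop = FALSE]
  out <- out[order(out$boundary, out$qname), , drop = FALSE]
  if (nrow(out) > max_clips) out <- out[seq_len(max_clips), , drop = FALSE]
  out
}

#' Realign one clipped subsequence into the partner window
#'
#' End-free (fit) alignment of the whole clip against the partner window's
#' reference sequence under unit edit costs, in place of a genome-wide BLAT
#' search: the call criterion only asks whether the clip remaps into W or X.
#' The clip is reverse-complemented first when the cluster's orientation
#' signature implies an inverted fusion (equal cluster strands). A placement
#' is accepted when its edit distance is at most
#' `ceiling(max_mismatch_frac * clip_len)`.
#'
#' @param clip_seq Clipped bases (character, as stored in the SAM record).
#' @param target A `break_window` naming the partner chromosome and interval.
#' @param ref Reference sequences ([Biostrings::DNAStringSet] or FASTA path).
#' @param revcomp Reverse-complement the clip before aligning (inverted
#'   fusion)?
#' @param max_mismatch_frac Edit-distance budget as a fraction of clip
#'   length (default 0.1).
#' @return `NULL` when rejected, else list with `target_chrom`, `target_start`,
#'   `target_end` (reference coordinates of the placement), `target_pos`
#'   (junction-adjacent terminus: the placement end for a right-facing...
#'   see Details), `edit_distance`.
#' @details The junction-adjacent terminus is the placement end closest to
#'   the fusion: the rightmost base when the target window belongs to a `+`
#'   cluster side (junction to its right), the leftmost base for a `-` side.
#' @export
realign_clip <- function(clip_seq, target, ref, revcomp = FALSE,
                         max_mismatch_frac = 0.1) {
  ref <- load_reference(ref)
  if (!target$chrom %in% names(ref)) {
    stop("window sequence unavailable: reference ", target$chrom,
         " not found in FASTA")
  }
  win_seq <- Biostrings::subseq(ref[[target$chrom]], target$start, target$end)
  pat <- Biostrings::DNAString(clip_seq)
  if (revcomp) pat <- Biostrings::reverseComplement(pat)
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(match = 0, mismatch = -1)
  aln <- Biostrings::pairwiseAlignment(pat, win_seq, type = "global-local",
                                       substitutionMatrix = sub_mat,
                                       gapOpening = 0, gapExtension = 1)
  edit <- -Biostrings::score(aln)
  if (edit > ceiling(max_mismatch_frac * nchar(clip_seq))) return(NULL)
  s <- target$start + BiocGenerics::start(Biostrings::subject(aln)) - 1
  e <- target$start + BiocGenerics::end(Biostrings::subject(aln)) - 1
  list(target_chrom = target$chrom, target_start = s, target_end = e,
       target_pos = if (target$strand == "+") e else s,
       edit_distance = edit)
}

# Smallest modal value of an integer-valued vector (deterministic tie-break).
.coord_mode <- function(x) {
  tab <- table(x)
  best <- names(tab)[tab == max(tab)]
  list(value = min(as.numeric(best)), support = max(tab))
}

#' Call a base-pair breakpoint for one cluster
#'
#' Collects, for each side, the junction-adjacent coordinates of (a) the
#' aligned portions of clips harvested on that side (their clip boundaries)
#' and (b) successful realignments of the partner side's clips landing in
#' this side's window. The breakpoint is the modal coordinate (ties break to
#' the smallest). A call is emitted only if at least one clip realigned into
#' W or X; otherwise the cluster remains an unresolved candidate.
#'
#' @param cluster A `chimeric_cluster`.
#' @param windows List with `W`, `X` from [build_windows()].
#' @param clips_W,clips_X Harvested clips for each window
#'   ([harvest_clips()]).
#' @param ref Reference sequences.
#' @param max_mismatch_frac Realignment edit budget (see [realign_clip()]).
#' @return A `breakpoint_call` (one-row `data.frame` with `chrom_i`,
#'   `bkpt_i`, `strand_i`, `chrom_j`, `bkpt_j`, `strand_j`, `n_pairs`,
#'   `n_clips_i`, `n_clips_j`, `n_realign`, `mode_support_i`,
#'   `mode_support_j`), or `NULL` when the realignment criterion fails.
#' @export
call_breakpoints <- function(cluster, windows, clips_W, clips_X, ref,
                             max_mismatch_frac = 0.1) {
  inverted <- cluster$strand_i == cluster$strand_j
  realign_into <- function(clips, target) {
    if (!nrow(clips)) return(numeric(0))
    hits <- lapply(clips$clip_seq, realign_clip, target = target, ref = ref,
                   revcomp = inverted, max_mismatch_frac = max_mismatch_frac)
    vapply(Filter(Negate(is.null), hits), `[[`, numeric(1), "target_pos")
  }
  into_X <- realign_into(clips_W, windows$X)   # Clipped(j): clips of side-i reads
  into_W <- realign_into(clips_X, windows$W)   # Clipped(i)
  n_realign <- length(into_X) + length(into_W)
  if (n_realign < 1) return(NULL)
  S <- c(clips_W$boundary, into_W)             # Align(i) + Clipped(i)
  T <- c(clips_X$boundary, into_X)             # Align(j) + Clipped(j)
  if (!length(S) || !length(T)) return(NULL)   # unreachable given n_realign >= 1
  mi <- .coord_mode(S)
  mj <- .coord_mode(T)
  structure(data.frame(
    chrom_i = cluster$chrom_i, bkpt_i = mi$value, strand_i = cluster$strand_i,
    chrom_j = cluster$chrom_j, bkpt_j = mj$value, strand_j = cluster$strand_j,
    n_pairs = cluster$n_pairs,
    n_clips_i = nrow(clips_W), n_clips_j = nrow(clips_X),
    n_realign = n_realign,
    mode_support_i = as.integer(mi$support),
    mode_support_j = as.integer(mj$support),
    stringsAsFactors = FALSE), class = c("breakpoint_call", "data.frame"))
}

#' Resolve breakpoints for a list of clusters
#'
#' Convenience driver: builds windows, harvests clips and calls breakpoints
#' for every cluster; clusters failing the realignment criterion are
#' reported in the `unresolved` attribute.
#'
#' @param clusters List from [cluster_pairs()].
#' @param clips Soft-clip table ([extract_softclips()]).
#' @param stats [insert_stats()] object.
#' @param ref Reference sequences.
#' @param ref_lengths Named reference lengths.
#' @param min_clip,max_clips,max_mismatch_frac Stage parameters.
#' @return `data.frame` of breakpoint calls (possibly 0 rows) with a
#'   `call_id` column; unresolved cluster summaries in attribute
#'   `unresolved`.
#' @export
resolve_breakpoints <- function(clusters, clips, stats, ref, ref_lengths,
                                min_clip = 20, max_clips = 5,
                                max_mismatch_frac = 0.1) {
  ref <- load_reference(ref)
  calls <- list(); unresolved <- list()
  for (cl in clusters) {
    w <- build_windows(cl, stats, ref_lengths)
    cw <- harvest_clips(clips, w$W, min_clip = min_clip, max_clips = max_clips)
    cx <- harvest_clips(clips, w$X, min_clip = min_clip, max_clips = max_clips)
    call <- call_breakpoints(cl, w, cw, cx, ref,
                             max_mismatch_frac = max_mismatch_frac)
    if (is.null(call)) {
      unresolved[[length(unresolved) + 1]] <- cluster_table(list(cl))
    } else {
      calls[[length(calls) + 1]] <- call
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(chrom_i = character(), bkpt_i = numeric(), strand_i = character(),
               chrom_j = character(), bkpt_j = numeric(), strand_j = character(),
               n_pairs = integer(), n_clips_i = integer(), n_clips_j = integer(),
               n_realign = integer(), mode_support_i = integer(),
               mode_support_j = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out$call_id <- seq_len(nrow(out))
  attr(out, "unresolved") <- if (length(unresolved))
    do.call(rbind, unresolved) else NULL
  out
}

#' Load reference sequences
#'
#' @param ref A [Biostrings::DNAStringSet] (returned unchanged) or a FASTA
#'   path.
#' @return A `DNAStringSet`.
#' @export
load_reference <- function(ref) {
  if (methods::is(ref, "DNAStringSet")) return(ref)
  if (is.character(ref) && length(ref) == 1 && file.exists(ref)) {
    return(Biostrings::readDNAStringSet(ref))
  }
  stop("reference must be a DNAStringSet or a FASTA file path")
}
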