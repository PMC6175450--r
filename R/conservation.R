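# Pairwise global alignment, sliding-window percent identity and
# conserved-region calling for cis-regulatory comparison.

check_nucleotides <- function(seq, what) {
  chars <- strsplit(toupper(seq), "")[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T", "N"))
  if (length(bad) > 0) {
    stop(sprintf("%s contains non-ACGTN characters at position(s): %s",
                 what, paste(head(bad, 10L), collapse = ", ")))
  }
  paste(chars, collapse = "")
}

#' Global pairwise alignment of two nucleotide sequences
#'
#' Needleman-Wunsch global alignment with affine gaps via
#' \code{Biostrings::pairwiseAlignment}. Default scoring: match +1,
#' mismatch -1, and a gap of length L costs gap_open + L * gap_extend
#' (so 5 + L by default). N scores as a mismatch against everything,
#' including N.
#'
#' @param seq_a,seq_b nucleotide sequences (ACGTN).
#' @param match,mismatch substitution scores.
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @return object of class \code{pairwise_alignment} with the two aligned
#'   strings (gap character "-"), the \code{score} and the scoring
#'   parameters.
#' @export
global_align <- function(seq_a, seq_b, match = 1, mismatch = -1,
                         gap_open = 5, gap_extend = 1) {
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0) {
    stop("sequences must be non-empty")
  }
  seq_a <- check_nucleotides(seq_a, "seq_a")
  seq_b <- check_nucleotides(seq_b, "seq_b")
  letters5 <- c("A", "C", "G", "T", "N")
  mat <- matrix(mismatch, 5, 5, dimnames = list(letters5, letters5))
  diag(mat) <- match
  mat["N", "N"] <- mismatch
  aln <- Biostrings::pairwiseAlignment(
    seq_a, seq_b, type = "global", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  structure(list(aligned_a = as.character(Biostrings::alignedPattern(aln)),
                 aligned_b = as.character(Biostrings::alignedSubject(aln)),
                 score = Biostrings::score(aln),
                 params = list(match = match, mismatch = mismatch,
                               gap_open = gap_open,
                               gap_extend = gap_extend)),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("Global alignment: %d columns, score %.1f\n",
              nchar(x$aligned_a), x$score))
  invisible(x)
}

# Per-column match indicator; gap columns count as mismatch.
alignment_matches <- function(alignment) {
  a <- strsplit(alignment$aligned_a, "")[[1]]
  b <- strsplit(alignment$aligned_b, "")[[1]]
  (a == b) & a != "-" & b != "-"
}

#' Sliding-window percent identity along an alignment
#'
#' Identity per window of alignment columns: 100 * matches / window,
#' with gap columns counting as mismatch. Alignments shorter than the
#' window yield a single truncated window with a warning.
#'
#' @param alignment a \code{\link{global_align}} result.
#' @param window window size in alignment columns (default 100).
#' @param step step between window starts (default 1).
#' @return data frame of class \code{conservation_profile} with 0-based
#'   \code{start}, \code{centre}, \code{end} (half-open) and
#'   \code{identity} (percent); window size kept as attribute.
#' @export
sliding_identity <- function(alignment, window = 100L, step = 1L) {
  m <- alignment_matches(alignment)
  L <- length(m)
  if (L < window) {
    warning(sprintf(
      "alignment (%d columns) shorter than the window (%d): truncated",
      L, window))
    window <- L
  }
  starts <- seq.int(0L, L - window, by = step)
  cs <- c(0L, cumsum(m))
  ident <- 100 * (cs[starts + window + 1L] - cs[starts + 1L]) / window
  out <- data.frame(start = starts, centre = starts + window / 2,
                    end = starts + window, identity = ident)
  attr(out, "window") <- window
  attr(out, "alignment_length") <- L
  class(out) <- c("conservation_profile", "data.frame")
  out
}

#' Call conserved regions from a conservation profile
#'
#' Maximal runs of consecutive windows at or above the identity
#' threshold; runs shorter than \code{min_run} windows are dropped and
#' overlapping window spans are merged. Regions are reported in 0-based
#' half-open alignment coordinates from the first window start to the
#' last window end, with the mean and maximum identity of the
#' contributing windows.
#'
#' @param profile a \code{\link{sliding_identity}} result.
#' @param threshold percent identity threshold (default 70).
#' @param min_run minimum run length in windows (default 1).
#' @return data frame (start, end, mean_identity, max_identity), sorted
#'   and non-overlapping; empty when nothing passes.
#' @export
call_regions <- function(profile, threshold = 70, min_run = 1L) {
  hot <- profile$identity >= threshold
  empty <- data.frame(start = integer(), end = integer(),
                      mean_identity = numeric(), max_identity = numeric())
  if (!any(hot)) return(empty)
  r <- rle(hot)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  runs <- which(r$values & r$lengths >= min_run)
  if (length(runs) == 0L) return(empty)
  spans <- data.frame(start = profile$start[idx_start[runs]],
                      end = profile$end[idx_end[runs]],
                      i0 = idx_start[runs], i1 = idx_end[runs])
  spans <- spans[order(spans$start), , drop = FALSE]
  merged <- list()
  cur <- spans[1L, ]
  for (i in seq_len(nrow(spans))[-1L]) {
    if (spans$start[i] <= cur$end) {
      cur$end <- max(cur$end, spans$end[i])
      cur$i1 <- max(cur$i1, spans$i1[i])
    } else {
      merged[[length(merged) + 1L]] <- cur
      cur <- spans[i, ]
    }
  }
  merged[[length(merged) + 1L]] <- cur
  out <- do.call(rbind, lapply(merged, function(sp) {
    ids <- profile$identity[sp$i0:sp$i1]
    ids <- ids[ids >= threshold]
    data.frame(start = sp$start, end = sp$end,
               mean_identity = mean(ids), max_identity = max(ids))
  }))
  rownames(out) <- NULL
  out
}

#' Project alignment coordinates onto each input sequence
#'
#' @param alignment a \code{\link{global_align}} result.
#' @param pos 0-based alignment column positions.
#' @return data frame with \code{pos_a} and \code{pos_b}: the 0-based
#'   position in each ungapped sequence of the last non-gap character at
#'   or before each alignment column.
#' @export
project_coordinates <- function(alignment, pos) {
  a <- strsplit(alignment$aligned_a, "")[[1]] != "-"
  b <- strsplit(alignment$aligned_b, "")[[1]] != "-"
  data.frame(pos = pos,
             pos_a = pmax(cumsum(a)[pos + 1L] - 1L, 0L),
             pos_b = pmax(cumsum(b)[pos + 1L] - 1L, 0L))
}

#' Conservation summary per annotated feature
#'
#' For each feature interval (BED-style, 0-based half-open, in alignment
#' coordinates): the fraction of its span covered by called regions and
#' the mean window identity of profile windows centred inside it.
#' Features outside the alignment span get coverage 0 and are flagged.
#'
#' @param regions a \code{\link{call_regions}} result.
#' @param features data frame with columns start, end, name.
#' @param profile the \code{\link{sliding_identity}} profile.
#' @return data frame (name, start, end, covered_fraction,
#'   mean_identity, outside_alignment).
#' @export
annotate_overlap <- function(regions, features, profile) {
  assert_cols(features, c("start", "end", "name"))
  L <- attr(profile, "alignment_length")
  res <- lapply(seq_len(nrow(features)), function(i) {
    fs <- features$start[i]
    fe <- features$end[i]
    outside <- fe <= 0 || fs >= L
    cov <- 0
    if (!outside && nrow(regions) > 0) {
      inter <- pmin(fe, regions$end) - pmax(fs, regions$start)
      cov <- sum(pmax(inter, 0)) / (fe - fs)
    }
    inwin <- profile$centre >= fs & profile$centre < fe
    data.frame(name = features$name[i], start = fs, end = fe,
               covered_fraction = cov,
               mean_identity = if (any(inwin))
                 mean(profile$identity[inwin]) else NA_real_,
               outside_alignment = outside, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
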