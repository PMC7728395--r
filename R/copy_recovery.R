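# Reconstruction of full-length TE copies from fragmented homology hits:
# bit-score filtering, proximity merging, and sequence extraction.

#' Filter homology hits by bit score
#'
#' Keeps hits whose bit score is strictly greater than the threshold
#' (a score exactly at the threshold is discarded); input order preserved.
#'
#' @param hsps normalized hit table from [read_blast_tab()].
#' @param min_bit_score threshold (default 200).
#' @return filtered hit table.
#' @export
filter_hsps <- function(hsps, min_bit_score = 200) {
  hsps[hsps$bit_score > min_bit_score, , drop = FALSE]
}

#' Merge nearby hits of the same family into TE copy intervals
#'
#' Hits are grouped by (family, contig, strand); within a group, hits whose
#' genomic gap is at most `max_gap` nucleotides are merged transitively into
#' a single copy interval spanning the union.  Output intervals within a
#' group are pairwise disjoint with gaps greater than `max_gap`, and the
#' result does not depend on input order.
#'
#' @param hsps normalized hit table (0-based half-open subject coordinates).
#' @param max_gap maximum allowed gap between merged hits (default 1000).
#' @return `data.frame` of copy intervals with columns `family_label`,
#'   `contig`, `strand`, `start`, `end`, `source_hsp_count`, plus a
#'   list-column `hsp_rows` giving the rows of `hsps` behind each copy.
#' @export
merge_hsps <- function(hsps, max_gap = 1000) {
  if (nrow(hsps) == 0) {
    return(data.frame(
      family_label = character(0), contig = character(0),
      strand = character(0), start = numeric(0), end = numeric(0),
      source_hsp_count = integer(0), stringsAsFactors = FALSE
    ))
  }
  key <- paste(hsps$query_id, hsps$subject_id, hsps$strand, sep = "\r")
  groups <- split(seq_len(nrow(hsps)), key)
  groups <- groups[order(names(groups))]        # deterministic output order
  pieces <- lapply(groups, function(rows) {
    # IRanges is 1-based closed: shift starts by +1.  reduce() merges ranges
    # whose gap is < min.gapwidth, so min.gapwidth = max_gap + 1 merges
    # gaps <= max_gap exactly.
    ir <- IRanges::IRanges(start = hsps$s_start[rows] + 1,
                           end = hsps$s_end[rows])
    red <- IRanges::reduce(ir, min.gapwidth = max_gap + 1, with.revmap = TRUE)
    revmap <- S4Vectors::mcols(red)$revmap
    data.frame(
      family_label = hsps$query_id[rows[1]],
      contig = hsps$subject_id[rows[1]],
      strand = hsps$strand[rows[1]],
      start = IRanges::start(red) - 1,
      end = IRanges::end(red),
      source_hsp_count = lengths(revmap),
      hsp_rows = I(lapply(revmap, function(v) rows[v])),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Extract TE copy sequences from genome contigs
#'
#' Minus-strand copies are reverse-complemented into family orientation;
#' the returned sequence length always equals the interval length.
#'
#' @param intervals copy intervals from [merge_hsps()] (or any table with
#'   `contig`, `start`, `end`, `strand` and optionally `family_label`,
#'   `source_hsp_count`).
#' @param genome named character vector of contig sequences, or the path to
#'   a genome FASTA file.
#' @param species optional species label recorded on every copy.
#' @return `data.frame` of TE copies with the interval columns plus
#'   `species` and `sequence`.
#' @export
extract_copy_sequences <- function(intervals, genome, species = NA_character_) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- read_fasta(genome)
  }
  n <- nrow(intervals)
  seqs <- character(n)
  for (i in seq_len(n)) {
    ctg <- intervals$contig[i]
    if (!ctg %in% names(genome)) stop("missing contig: ", ctg)
    clen <- nchar(genome[[ctg]])
    if (intervals$end[i] > clen || intervals$start[i] < 0) {
      stop("interval [", intervals$start[i], ",", intervals$end[i],
           ") exceeds contig ", ctg, " of length ", clen)
    }
    s <- substring(genome[[ctg]], intervals$start[i] + 1, intervals$end[i])
    if (identical(intervals$strand[i], "-")) s <- revcomp(s)
    seqs[i] <- s
  }
  out <- intervals
  out$species <- species
  out$sequence <- seqs
  out
}
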