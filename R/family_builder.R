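# Cross-species TE family construction: greedy identity/coverage clustering,
# star-alignment consensus building, ORF discovery, the HTT candidate
# filters, and reference-based codon-alignment trimming.

#' Pairwise global alignment with identity and coverage
#'
#' Needleman-Wunsch alignment with fixed default scoring (match +1,
#' mismatch -1, gap open 2, gap extend 1).  Identity is matches over
#' alignment columns excluding terminal gaps; coverage is the number of
#' columns where both sequences have a base, relative to the shorter
#' sequence.
#'
#' @param a,b nucleotide sequences (character scalars).
#' @param type alignment type passed to the aligner (`"global"` or
#'   `"local"`).
#' @param match,mismatch,gap_open,gap_extend scoring parameters.
#' @return list with `aligned_a`, `aligned_b`, `identity`, `coverage`,
#'   `score`.
#' @export
align_global <- function(a, b, type = "global", match = 1, mismatch = -1,
                         gap_open = 2, gap_extend = 1) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = FALSE)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(normalize_alphabet(a)),
    Biostrings::DNAString(normalize_alphabet(b)),
    substitutionMatrix = sm, gapOpening = gap_open,
    gapExtension = gap_extend, type = type
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  both <- pa != "-" & sa != "-"
  inner <- if (any(both)) seq(min(which(both)), max(which(both))) else integer(0)
  matches <- sum(pa[inner] == sa[inner] & both[inner])
  identity <- if (length(inner)) matches / length(inner) else 0
  coverage <- sum(both) / min(nchar(a), nchar(b))
  list(aligned_a = paste(pa, collapse = ""),
       aligned_b = paste(sa, collapse = ""),
       identity = identity, coverage = coverage,
       score = Biostrings::score(al))
}

#' Greedy incremental clustering of sequences
#'
#' Records are processed in length-descending order (ties broken by id);
#' each record joins the best existing cluster whose representative it
#' matches at `min_identity` global identity with coverage of the shorter
#' sequence at least `min_coverage`, otherwise it founds a new cluster.
#' Deterministic for any input permutation.
#'
#' @param records named character vector of sequences.
#' @param min_identity global identity threshold (default 0.80).
#' @param min_coverage coverage-of-shorter threshold (default 0.80).
#' @return list of clusters, each a list with `representative` (id) and
#'   `members` (character vector of ids, representative first).
#' @export
cluster_sequences <- function(records, min_identity = 0.80,
                              min_coverage = 0.80) {
  if (length(records) == 0) stop("need at least one record")
  ids <- names(records)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("records must have unique names")
  }
  ord <- order(-nchar(records), ids, method = "radix")
  reps <- character(0)
  members <- list()
  for (i in ord) {
    best <- 0L
    best_id <- -Inf
    for (ci in seq_along(reps)) {
      al <- align_global(records[[reps[ci]]], records[[ids[i]]])
      if (al$identity >= min_identity && al$coverage >= min_coverage &&
          al$identity > best_id) {
        best <- ci
        best_id <- al$identity
      }
    }
    if (best == 0L) {
      reps <- c(reps, ids[i])
      members[[length(members) + 1]] <- ids[i]
    } else {
      members[[best]] <- c(members[[best]], ids[i])
    }
  }
  mapply(function(r, m) list(representative = r, members = m),
         reps, members, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Majority-rule consensus of a cluster via star alignment
#'
#' Members are globally aligned pairwise against the longest member and
#' projected onto its coordinates (insertions relative to the reference are
#' dropped).  Per column the plurality base wins, ties broken in fixed
#' A < C < G < T order; columns where gaps are in the strict majority are
#' dropped.
#'
#' @param cluster_seqs named character vector of member sequences.
#' @return consensus nucleotide string.
#' @export
build_consensus <- function(cluster_seqs) {
  if (length(cluster_seqs) == 0) stop("empty cluster")
  if (length(cluster_seqs) == 1) return(unname(cluster_seqs[[1]]))
  ids <- names(cluster_seqs)
  ord <- order(-nchar(cluster_seqs), ids, method = "radix")
  ref_id <- ids[ord[1]]
  ref <- toupper(cluster_seqs[[ref_id]])
  ref_len <- nchar(ref)
  n <- length(cluster_seqs)
  mat <- matrix("-", nrow = n, ncol = ref_len)
  mat[1, ] <- strsplit(ref, "")[[1]]
  others <- ids[ord[-1]]
  for (k in seq_along(others)) {
    al <- align_global(ref, cluster_seqs[[others[k]]])
    pa <- strsplit(al$aligned_a, "")[[1]]
    sa <- strsplit(toupper(al$aligned_b), "")[[1]]
    ref_pos <- cumsum(pa != "-")
    keep <- pa != "-"
    mat[k + 1, ref_pos[keep]] <- sa[keep]
  }
  bases <- c("A", "C", "G", "T")
  out <- character(ref_len)
  keep_col <- logical(ref_len)
  for (j in seq_len(ref_len)) {
    col <- mat[, j]
    n_gap <- sum(col == "-")
    if (n_gap > n / 2) next
    cnt <- vapply(bases, function(b) sum(col == b), integer(1))
    if (all(cnt == 0)) { out[j] <- "N"; keep_col[j] <- TRUE; next }
    out[j] <- bases[which.max(cnt)]   # which.max: first max => A<C<G<T ties
    keep_col[j] <- TRUE
  }
  paste(out[keep_col], collapse = "")
}

#' Find the longest open reading frame across six frames
#'
#' An ORF is a maximal stop-to-stop (or sequence-edge-bounded) run of sense
#' codons under the standard genetic code; no start codon is required, a
#' convention suited to start-degraded TE coding regions.  Ties are broken
#' in favour of the plus strand, then lower frame, then leftmost position.
#'
#' @param sequence nucleotide string.
#' @return list with `start`, `end` (0-based half-open on the oriented
#'   sequence), `frame` (0/1/2), `strand`, `aa_length` and the ORF
#'   `sequence` itself.  Sequences shorter than one codon give an ORF of
#'   length 0.
#' @export
find_longest_orf <- function(sequence) {
  best <- list(start = 0L, end = 0L, frame = 0L, strand = "+",
               aa_length = 0L, sequence = "")
  if (is.na(sequence) || nchar(sequence) < 3) return(best)
  tab <- codon_tables()
  for (strand in c("+", "-")) {
    s <- toupper(if (strand == "+") sequence else revcomp(sequence))
    n <- nchar(s)
    for (frame in 0:2) {
      n_cod <- (n - frame) %/% 3
      if (n_cod == 0) next
      starts <- seq.int(frame + 1, by = 3, length.out = n_cod)
      cods <- substring(s, starts, starts + 2)
      ci <- unname(tab$idx[cods])
      # runs of sense codons delimited by stop codons or invalid codons
      is_break <- is.na(ci) | tab$is_stop[ifelse(is.na(ci), 1L, ci)]
      r <- rle(!is_break)
      pos <- cumsum(c(1, r$lengths))
      for (k in seq_along(r$lengths)) {
        if (!r$values[k]) next
        len <- r$lengths[k]
        if (len > best$aa_length) {
          first <- pos[k]
          st <- frame + (first - 1L) * 3L
          best <- list(start = st, end = st + 3L * len, frame = frame,
                       strand = strand, aa_length = len,
                       sequence = substring(s, st + 1, st + 3 * len))
        }
      }
    }
  }
  best
}

#' Apply the three HTT candidate filters to TE families
#'
#' A family is kept iff (i) it has members from at least two species,
#' (ii) every member sequence is at least `min_len` nucleotides, and
#' (iii) at least one member carries an ORF strictly longer than the
#' class-specific amino-acid threshold (Class I 300 aa, Class II 200 aa by
#' default).  Rejections name the first failed rule.
#'
#' @param families list of families; each family is a list with
#'   `family_id`, `te_class` (`"ClassI"` or `"ClassII"`), and `members`, a
#'   `data.frame` with columns `species` and `sequence`.
#' @param min_len minimum member length in nucleotides (default 600).
#' @param orf_min_aa named vector of strict ORF thresholds per class.
#' @param min_species minimum number of species (default 2).
#' @return list with `kept` (families) and `rejected`
#'   (`data.frame` of `family_id`, `reason`).
#' @export
filter_htt_candidates <- function(families, min_len = 600,
                                  orf_min_aa = c(ClassI = 300, ClassII = 200),
                                  min_species = 2) {
  kept <- list()
  rej <- list()
  for (fam in families) {
    cls <- fam$te_class
    if (is.null(cls) || !cls %in% names(orf_min_aa)) {
      stop("family ", fam$family_id, " has unknown TE class '", cls,
           "'; supply an orf_min_aa threshold for it")
    }
    reason <- NA_character_
    if (length(unique(fam$members$species)) < min_species) {
      reason <- sprintf("fewer than %d species", min_species)
    } else if (any(nchar(fam$members$sequence) < min_len)) {
      reason <- sprintf("member shorter than %d nt", min_len)
    } else {
      longest <- max(vapply(fam$members$sequence,
                            function(s) find_longest_orf(s)$aa_length,
                            integer(1)))
      if (!(longest > orf_min_aa[[cls]])) {
        reason <- sprintf("no ORF longer than %d aa", orf_min_aa[[cls]])
      }
    }
    if (is.na(reason)) {
      kept[[length(kept) + 1]] <- fam
    } else {
      rej[[length(rej) + 1]] <- data.frame(family_id = fam$family_id,
                                           reason = reason,
                                           stringsAsFactors = FALSE)
    }
  }
  rejected <- if (length(rej)) do.call(rbind, rej) else
    data.frame(family_id = character(0), reason = character(0))
  list(kept = kept, rejected = rejected)
}

#' Trim a codon alignment to its reference coding region
#'
#' Removes all alignment columns before the reference's first non-gap
#' character and after its last, then drops trailing columns so the width
#' is a multiple of three (reference reading frame).
#'
#' @param alignment named character vector of equal-length aligned
#'   sequences including the reference.
#' @param reference_id name of the reference record (largest-ORF sequence).
#' @return trimmed alignment (named character vector).
#' @export
trim_to_reference <- function(alignment, reference_id) {
  if (!reference_id %in% names(alignment)) {
    stop("reference '", reference_id, "' absent from alignment")
  }
  widths <- nchar(alignment)
  if (length(unique(widths)) != 1) stop("alignment rows differ in width")
  ref <- strsplit(alignment[[reference_id]], "")[[1]]
  non_gap <- which(ref != "-")
  if (length(non_gap) == 0) stop("reference is all gaps")
  from <- min(non_gap)
  to <- max(non_gap)
  w <- to - from + 1
  to <- from + 3 * (w %/% 3) - 1
  if (to < from) stop("trimmed reference region shorter than one codon")
  vapply(alignment, function(s) substring(s, from, to), character(1))
}

#' Pick the family member most similar to the consensus
#'
#' Used to select one representative copy per species before the pairwise
#' dS-CUB test.  Similarity is global alignment identity to the consensus
#' (direct per-site identity when lengths already match); ties go to the
#' lexicographically first id.
#'
#' @param copies named character vector of member sequences.
#' @param consensus consensus nucleotide string.
#' @return the id of the most consensus-like member.
#' @export
pick_representative <- function(copies, consensus) {
  if (length(copies) == 0) stop("no copies")
  ids <- sort(names(copies))
  sim <- vapply(ids, function(id) {
    s <- copies[[id]]
    if (nchar(s) == nchar(consensus)) {
      a <- strsplit(toupper(s), "")[[1]]
      b <- strsplit(toupper(consensus), "")[[1]]
      mean(a == b)
    } else {
      align_global(consensus, s)$identity
    }
  }, numeric(1))
  ids[which.max(sim)]
}
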