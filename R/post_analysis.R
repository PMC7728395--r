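# Downstream accounting once HTT calls exist: introgression discrimination
# from flanking sequence, genome fraction covered by HTT families,
# correlation of that coverage with genome size, geography, and the
# long-range cross-taxon screen.

#' Extract the flanking sequences of a genomic interval
#'
#' @param genome named character vector of contigs (or a FASTA path).
#' @param contig,start,end interval (0-based half-open).
#' @param flank requested flank length in nucleotides (default 4000, the
#'   midpoint of the 3-5 kb window used for introgression checks).
#' @param min_flank flanks truncated below this by a contig edge come back
#'   `NA` (default 3000).
#' @return list with `upstream` and `downstream` sequences (or `NA`).
#' @export
extract_flanks <- function(genome, contig, start, end, flank = 4000,
                           min_flank = 3000) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- read_fasta(genome)
  }
  if (!contig %in% names(genome)) stop("missing contig: ", contig)
  clen <- nchar(genome[[contig]])
  up_start <- max(0, start - flank)
  up <- if (start - up_start >= min_flank) {
    substring(genome[[contig]], up_start + 1, start)
  } else NA_character_
  down_end <- min(clen, end + flank)
  down <- if (down_end - end >= min_flank) {
    substring(genome[[contig]], end + 1, down_end)
  } else NA_character_
  list(upstream = up, downstream = down)
}

#' Discriminate horizontal transfer from introgression via flanks
#'
#' A horizontally transferred TE lands in unrelated genomic context, so the
#' flanking regions of the copies in the two species should be different;
#' introgression moves the TE together with its chromosomal neighbourhood,
#' so the flanks are shared.  Each side (upstream, downstream) is aligned
#' between the two species; a side is "shared" when the aligned identity
#' reaches `shared_identity` over at least `shared_coverage` of the
#' shorter flank.  Any shared side yields `putative_introgression`, no
#' shared side with at least one comparable side yields `HTT`, and missing
#' flanks yield `indeterminate`.
#'
#' @param flanks_a,flanks_b lists with `upstream`/`downstream` sequences
#'   (as from [extract_flanks()]); `NA` marks a missing flank.
#' @param shared_identity identity threshold (default 0.70).
#' @param shared_coverage coverage-of-shorter threshold (default 0.50).
#' @param family_id,species_a,species_b labels carried through.
#' @return list of class `flank_comparison` with per-side identities and
#'   coverages, and `verdict` in
#'   `{"HTT", "putative_introgression", "indeterminate"}`.
#' @export
classify_introgression <- function(flanks_a, flanks_b,
                                   shared_identity = 0.70,
                                   shared_coverage = 0.50,
                                   family_id = NA_character_,
                                   species_a = NA_character_,
                                   species_b = NA_character_) {
  side <- function(a, b) {
    if (is.na(a) || is.na(b) || nchar(a) == 0 || nchar(b) == 0) {
      return(list(identity = NA_real_, coverage = NA_real_, shared = NA))
    }
    al <- align_global(a, b, type = "local")
    cov <- al$coverage
    list(identity = al$identity, coverage = cov,
         shared = al$identity >= shared_identity && cov >= shared_coverage)
  }
  up <- side(flanks_a$upstream, flanks_b$upstream)
  down <- side(flanks_a$downstream, flanks_b$downstream)
  shared_flags <- c(up$shared, down$shared)
  verdict <- if (isTRUE(any(shared_flags, na.rm = TRUE))) {
    "putative_introgression"
  } else if (all(is.na(shared_flags))) {
    "indeterminate"
  } else {
    "HTT"
  }
  structure(list(
    family_id = family_id, species_a = species_a, species_b = species_b,
    upstream = up, downstream = down, verdict = verdict
  ), class = "flank_comparison")
}

#' Genome fraction covered by HTT-family copies
#'
#' Per species, all intervals are merged into a union (overlaps and
#' duplicates counted once) and the covered base count is divided by the
#' genome size.
#'
#' @param intervals `data.frame` with columns `species`, `contig`,
#'   `start`, `end` (0-based half-open).
#' @param genome_sizes named numeric vector of genome sizes in bp.
#' @param contig_sizes optional named vector of contig lengths; when
#'   supplied, intervals beyond a contig end are an error.
#' @return `data.frame` with columns `species`, `htt_bp`, `genome_size`,
#'   `fraction`.
#' @export
genome_htt_fraction <- function(intervals, genome_sizes,
                                contig_sizes = NULL) {
  species <- names(genome_sizes)
  if (nrow(intervals)) {
    if (any(intervals$start < 0 | intervals$start >= intervals$end)) {
      stop("intervals must satisfy 0 <= start < end")
    }
    if (!is.null(contig_sizes)) {
      lim <- contig_sizes[intervals$contig]
      bad <- which(is.na(lim) | intervals$end > lim)
      if (length(bad)) {
        stop("interval out of contig bounds: ", intervals$contig[bad[1]],
             ":", intervals$start[bad[1]], "-", intervals$end[bad[1]])
      }
    }
  }
  htt_bp <- vapply(species, function(sp) {
    sub <- intervals[intervals$species == sp, , drop = FALSE]
    if (nrow(sub) == 0) return(0)
    per_contig <- split(seq_len(nrow(sub)), sub$contig)
    sum(vapply(per_contig, function(rows) {
      ir <- IRanges::IRanges(start = sub$start[rows] + 1,
                             end = sub$end[rows])
      sum(IRanges::width(IRanges::reduce(ir)))
    }, numeric(1)))
  }, numeric(1))
  frac <- htt_bp / genome_sizes
  if (any(frac > 1)) {
    stop("covered bases exceed genome size for ",
         species[which(frac > 1)[1]])
  }
  data.frame(species = species, htt_bp = unname(htt_bp),
             genome_size = unname(genome_sizes), fraction = unname(frac),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Spearman correlation between coverage and genome size
#'
#' Rank correlation with average ranks for ties; the p-value uses the
#' t approximation on the rank correlation.
#'
#' @param x,y paired numeric vectors, `n >= 4`.
#' @param method only `"spearman"` is supported (kept for interface
#'   symmetry with `stats::cor`).
#' @return list with `rho` and `p`.
#' @export
correlate_fraction_size <- function(x, y, method = "spearman") {
  stopifnot(identical(method, "spearman"))
  if (length(x) != length(y) || length(x) < 4) {
    stop("need at least 4 paired observations")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("constant vector: rank correlation undefined")
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  n <- length(x)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p)
}

#' Point-biserial correlation between range overlap and HTT counts
#'
#' r_pb = (M1 - M0)/s_n * sqrt(n1 n0 / n^2) with s_n the population
#' standard deviation of the counts; algebraically identical to the
#' Pearson correlation with the binary variable coded 0/1.  The two-sided
#' p-value uses the t transform with n - 2 degrees of freedom.
#'
#' @param overlap binary vector (1 = ranges overlap) per species pair.
#' @param counts number of transfers per species pair.
#' @return list with `r_pb`, `t`, `df`, `p`.
#' @export
geo_correlation <- function(overlap, counts) {
  if (length(overlap) != length(counts)) stop("length mismatch")
  if (!all(overlap %in% c(0, 1))) stop("overlap must be binary 0/1")
  n1 <- sum(overlap == 1)
  n0 <- sum(overlap == 0)
  if (n1 == 0 || n0 == 0) stop("both overlap groups must be represented")
  if (stats::var(counts) == 0) stop("counts are constant")
  n <- length(counts)
  s_n <- sqrt(sum((counts - mean(counts))^2) / n)
  r <- (mean(counts[overlap == 1]) - mean(counts[overlap == 0])) / s_n *
    sqrt(n1 * n0 / n^2)
  if (abs(r) >= 1) {
    tstat <- sign(r) * Inf
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r_pb = r, t = tstat, df = n - 2, p = p)
}

#' Long-range (cross-taxon) HTT candidate screen
#'
#' Scans homology hits of mosquito TE family consensuses against external
#' genomes.  Per family and external assembly, hits are merged into copies
#' (same proximity rule as copy recovery); a copy "qualifies" when its
#' merged query coverage exceeds `min_coverage` and its length-weighted
#' identity reaches `identity_min`.  A (family, species) pair is a
#' candidate when some assembly has a qualifying copy and strictly more
#' than `min_copies` copies, or - for species with several assemblies -
#' when qualifying matches are present in a strict majority of the
#' assemblies.
#'
#' @param hsps normalized hit table with an extra `assembly` column
#'   naming the external assembly of each hit.
#' @param assembly_map `data.frame` with columns `assembly`, `species`.
#' @param family_lengths named numeric vector: consensus length per
#'   family (query) id.
#' @param min_coverage strict query-coverage threshold (default 0.80).
#' @param identity_min identity threshold (default 0.80).
#' @param min_copies strict copy-number threshold (default 5).
#' @param max_gap merge gap passed to [merge_hsps()] (default 1000).
#' @return `data.frame` per (family, species) with `n_assemblies`,
#'   `n_assemblies_qualifying`, `max_copies`, `max_coverage`,
#'   `max_identity`, `candidate`, `basis`.
#' @export
long_range_screen <- function(hsps, assembly_map, family_lengths,
                              min_coverage = 0.80, identity_min = 0.80,
                              min_copies = 5, max_gap = 1000) {
  stopifnot("assembly" %in% names(hsps))
  if (nrow(hsps) == 0) {
    return(data.frame(family = character(0), species = character(0),
                      candidate = logical(0)))
  }
  hsps$species <- assembly_map$species[match(hsps$assembly,
                                             assembly_map$assembly)]
  if (anyNA(hsps$species)) stop("hit with unmapped assembly")
  out <- list()
  for (fam in sort(unique(hsps$query_id))) {
    if (!fam %in% names(family_lengths)) {
      stop("no consensus length for family ", fam)
    }
    flen <- family_lengths[[fam]]
    fh <- hsps[hsps$query_id == fam, , drop = FALSE]
    for (sp in sort(unique(fh$species))) {
      asms <- sort(unique(assembly_map$assembly[assembly_map$species == sp]))
      n_asm <- length(asms)
      per_asm <- lapply(asms, function(asm) {
        ah <- fh[fh$assembly == asm, , drop = FALSE]
        if (nrow(ah) == 0) {
          return(list(n_copies = 0L, qualifying = 0L, max_cov = 0,
                      max_id = 0))
        }
        copies <- merge_hsps(ah, max_gap = max_gap)
        stats_per_copy <- lapply(copies$hsp_rows, function(rows) {
          qir <- IRanges::IRanges(start = ah$q_start[rows] + 1,
                                  end = ah$q_end[rows])
          cov <- sum(IRanges::width(IRanges::reduce(qir))) / flen
          w <- ah$aln_length[rows]
          list(cov = cov,
               id = sum(ah$percent_identity[rows] * w) / sum(w))
        })
        covs <- vapply(stats_per_copy, `[[`, numeric(1), "cov")
        idents <- vapply(stats_per_copy, `[[`, numeric(1), "id")
        list(n_copies = nrow(copies),
             qualifying = sum(covs > min_coverage & idents >= identity_min),
             max_cov = max(covs), max_id = max(idents))
      })
      n_copies <- vapply(per_asm, `[[`, integer(1), "n_copies")
      qual <- vapply(per_asm, `[[`, integer(1), "qualifying")
      single_rule <- any(qual > 0 & n_copies > min_copies)
      majority_rule <- n_asm > 1 && sum(qual > 0) > n_asm / 2
      out[[length(out) + 1]] <- data.frame(
        family = fam, species = sp, n_assemblies = n_asm,
        n_assemblies_qualifying = sum(qual > 0),
        max_copies = max(n_copies),
        max_coverage = max(vapply(per_asm, `[[`, numeric(1), "max_cov")),
        max_identity = max(vapply(per_asm, `[[`, numeric(1), "max_id")),
        candidate = single_rule || majority_rule,
        basis = if (single_rule) "copy_number" else if (majority_rule) {
          "assembly_majority"
        } else NA_character_,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
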