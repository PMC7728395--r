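# Core molecular-evolution statistics: Nei-Gojobori (1986) synonymous
# divergence with Jukes-Cantor correction, Wright's effective number of
# codons (ENC), and the Kimura two-parameter distance.

#' Nei-Gojobori synonymous and nonsynonymous divergence
#'
#' Fractional synonymous site counts are averaged over the two sequences;
#' differences at multiply-substituted codons are averaged over all
#' shortest mutational pathways (pathways through stop codons excluded).
#' Rates are Jukes-Cantor corrected: dS = -3/4 log(1 - 4/3 pS).  Codon
#' pairs containing a gap, an N, or a stop codon are skipped pairwise.
#'
#' @param seq_a,seq_b equal-length in-frame nucleotide sequences.
#' @return object of class `pairwise_divergence`: list with `S`, `N`
#'   (site counts), `Sd`, `Nd` (difference counts), `pS`, `pN`
#'   (proportions), `dS`, `dN` (corrected rates, `NA` when saturated),
#'   `n_codons` (comparable codons) and `saturated` (logical, pS >= 3/4).
#' @export
ds_ng86 <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("sequences must have equal length")
  }
  tab <- codon_tables()
  ia <- codon_indices(seq_a, tab)
  ib <- codon_indices(seq_b, tab)
  keep <- !is.na(ia) & !is.na(ib)
  keep[keep] <- !tab$is_stop[ia[keep]] & !tab$is_stop[ib[keep]]
  ia <- ia[keep]; ib <- ib[keep]
  L <- length(ia)
  if (L == 0) stop("no comparable codons")
  S <- (sum(tab$syn_sites[ia]) + sum(tab$syn_sites[ib])) / 2
  N <- 3 * L - S
  Sd <- sum(tab$sd_mat[cbind(ia, ib)])
  Nd <- sum(tab$nd_mat[cbind(ia, ib)])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  jc <- function(p) {
    if (is.na(p) || p >= 3 / 4) return(NA_real_)
    -3 / 4 * log(1 - 4 / 3 * p)
  }
  structure(list(
    S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
    dS = jc(pS), dN = jc(pN), n_codons = L,
    saturated = !is.na(pS) && pS >= 3 / 4
  ), class = "pairwise_divergence")
}

#' @export
print.pairwise_divergence <- function(x, ...) {
  cat(sprintf(
    "NG86 divergence over %d codons: S=%.2f N=%.2f Sd=%.2f Nd=%.2f\n",
    x$n_codons, x$S, x$N, x$Sd, x$Nd))
  cat(sprintf("  pS=%.4f pN=%.4f dS=%s dN=%s%s\n", x$pS, x$pN,
              format(x$dS, digits = 5), format(x$dN, digits = 5),
              if (x$saturated) "  [saturated]" else ""))
  invisible(x)
}

#' Wright's effective number of codons (ENC)
#'
#' Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6 where Fk is the mean codon
#' homozygosity of amino acids with k synonymous codons,
#' F = (n * sum(p^2) - 1) / (n - 1).  Amino acids observed fewer than
#' twice, and non-positive homozygosities, are excluded from the class
#' mean; a missing 3-fold class is imputed as the mean of the 2- and
#' 4-fold classes, any other missing class as the mean of the represented
#' ones.  The result is clipped to \[20, 61\] (one codon per amino acid to
#' uniform usage).
#'
#' @param sequence in-frame coding sequence (codons with gaps or N and
#'   stop codons are ignored).
#' @return object of class `codon_usage`: list with `Nc`, per-class mean
#'   homozygosity `F_class`, and the `codon_counts` table.
#' @export
enc <- function(sequence) {
  tab <- codon_tables()
  ci <- codon_indices(sequence, tab)
  ci <- ci[!is.na(ci)]
  ci <- ci[!tab$is_stop[ci]]
  if (length(ci) < 1) stop("fewer than 1 usable codon")
  counts <- tabulate(ci, nbins = 64)
  F_aa <- numeric(0)
  k_aa <- integer(0)
  for (a in tab$aas) {
    k <- tab$degeneracy[[a]]
    if (k == 1) next                       # Met, Trp carry no bias signal
    members <- which(tab$aa == a & !tab$is_stop)
    n <- sum(counts[members])
    if (n < 2) next
    p <- counts[members] / n
    f <- (n * sum(p^2) - 1) / (n - 1)
    if (f <= 0) next
    F_aa <- c(F_aa, f)
    k_aa <- c(k_aa, k)
  }
  class_sizes <- c(`2` = 9, `3` = 1, `4` = 5, `6` = 3)
  F_class <- vapply(names(class_sizes), function(k) {
    v <- F_aa[k_aa == as.integer(k)]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  if (is.na(F_class[["3"]]) && !is.na(F_class[["2"]]) &&
      !is.na(F_class[["4"]])) {
    F_class[["3"]] <- (F_class[["2"]] + F_class[["4"]]) / 2
  }
  if (anyNA(F_class)) {
    if (all(is.na(F_class))) stop("no degeneracy class represented")
    F_class[is.na(F_class)] <- mean(F_class, na.rm = TRUE)
  }
  nc <- 2 + sum(class_sizes / F_class)
  nc <- min(max(nc, 20), 61)
  structure(list(Nc = nc, F_class = F_class,
                 codon_counts = stats::setNames(counts, tab$codons)),
            class = "codon_usage")
}

#' @export
print.codon_usage <- function(x, ...) {
  cat(sprintf("ENC: Nc = %.3f over %d codons\n", x$Nc, sum(x$codon_counts)))
  invisible(x)
}

#' Kimura two-parameter distance
#'
#' K = -1/2 log((1 - 2p - q) sqrt(1 - 2q)) with p the transition and q the
#' transversion proportion.  Columns containing a gap or anything other
#' than A/C/G/T are excluded; a non-positive logarithm argument flags
#' saturation (K = `NA`).
#'
#' @param seq_a,seq_b equal-length aligned nucleotide sequences.
#' @return object of class `k2p_result`: list with `p`, `q`, `K`,
#'   `n_sites`, `saturated`.
#' @export
k2p <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) stop("sequences must have equal length")
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  ok <- a %in% BASES & b %in% BASES
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n == 0) stop("no comparable sites")
  diff <- a != b
  purine <- c("A", "G")
  transition <- diff & ((a %in% purine) == (b %in% purine))
  p <- sum(transition) / n
  q <- sum(diff & !transition) / n
  w1 <- 1 - 2 * p - q
  w2 <- 1 - 2 * q
  saturated <- w1 <= 0 || w2 <= 0
  K <- if (saturated) NA_real_ else -0.5 * log(w1 * sqrt(w2))
  structure(list(p = p, q = q, K = K, n_sites = n, saturated = saturated),
            class = "k2p_result")
}

#' @export
print.k2p_result <- function(x, ...) {
  cat(sprintf("K2P over %d sites: p=%.4f q=%.4f K=%s%s\n", x$n_sites, x$p,
              x$q, format(x$K, digits = 5),
              if (x$saturated) " [saturated]" else ""))
  invisible(x)
}

#' Copy-to-consensus K2P profile of a TE family
#'
#' The distribution of copy-to-consensus K2P distances proxies the
#' intragenomic age of a family: a recently active family has copies close
#' to the consensus, an old burst sits at higher divergence.  Copies whose
#' length differs from the consensus are globally aligned to it first.
#'
#' @param copies named character vector of copy sequences.
#' @param consensus family consensus string.
#' @return list with `per_copy` (named K2P distances, `NA` when
#'   saturated), `mean`, `median` (over unsaturated copies), and
#'   `n_saturated`.
#' @export
family_k2p_profile <- function(copies, consensus) {
  if (length(copies) == 0) stop("no copies to profile")
  ks <- vapply(names(copies), function(id) {
    s <- copies[[id]]
    if (nchar(s) != nchar(consensus)) {
      al <- align_global(consensus, s)
      k2p(al$aligned_a, al$aligned_b)$K
    } else {
      k2p(consensus, s)$K
    }
  }, numeric(1))
  usable <- ks[!is.na(ks)]
  if (length(usable) == 0) stop("no alignable (unsaturated) copies")
  list(per_copy = ks, mean = mean(usable), median = stats::median(usable),
       n_saturated = sum(is.na(ks)))
}
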