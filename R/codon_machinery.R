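# Genetic-code lookup tables shared by the divergence statistics and the
# forward simulator.  Built once per session and cached; everything indexes
# codons 1..64 in a fixed A<C<G<T nested order so that results are
# reproducible independently of locale or package load order.

.httscan_cache <- new.env(parent = emptyenv())

BASES <- c("A", "C", "G", "T")

#' @keywords internal
codon_tables <- function() {
  if (!is.null(.httscan_cache$tab)) return(.httscan_cache$tab)

  codons <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
  codons <- sort(codons)                      # A<C<G<T, positions 1..3
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  is_stop <- aa == "*"
  idx <- stats::setNames(seq_along(codons), codons)

  codon_mat <- do.call(rbind, strsplit(codons, ""))

  # one-step mutational neighbourhood: for codon i, position p, base b
  mutate1 <- function(i, p, b) {
    cd <- codon_mat[i, ]
    cd[p] <- b
    idx[[paste0(cd[1], cd[2], cd[3])]]
  }

  # fractional synonymous site counts (NG86): per position, the fraction of
  # the three alternative bases that preserve the amino acid.  Changes to a
  # stop codon count as nonsynonymous so that S + N == 3 * codons.
  syn_sites <- numeric(64)
  syn_neighbors <- vector("list", 64)
  for (i in seq_len(64)) {
    if (is_stop[i]) {
      syn_sites[i] <- NA_real_
      next
    }
    nb <- integer(0)
    s <- 0
    for (p in 1:3) {
      for (b in setdiff(BASES, codon_mat[i, p])) {
        j <- mutate1(i, p, b)
        if (!is_stop[j] && aa[j] == aa[i]) {
          s <- s + 1
          nb <- c(nb, j)
        }
      }
    }
    syn_sites[i] <- s / 3
    syn_neighbors[[i]] <- nb
  }

  # NG86 pathway-averaged synonymous / nonsynonymous difference counts for
  # every codon pair.  All shortest mutational pathways are enumerated;
  # pathways passing through a stop codon are discarded (all-blocked pairs
  # fall back to averaging over every pathway).
  perms <- list(
    `1` = list(1L),
    `2` = list(c(1L, 2L), c(2L, 1L)),
    `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
               c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  )
  sd_mat <- matrix(0, 64, 64, dimnames = list(codons, codons))
  nd_mat <- matrix(0, 64, 64, dimnames = list(codons, codons))
  path_counts <- function(i, j, order_pos) {
    cur <- codon_mat[i, ]
    tgt <- codon_mat[j, ]
    sdd <- 0; ndd <- 0; blocked <- FALSE
    for (p in order_pos) {
      nxt <- cur
      nxt[p] <- tgt[p]
      a1 <- gc[[paste0(cur[1], cur[2], cur[3])]]
      a2 <- gc[[paste0(nxt[1], nxt[2], nxt[3])]]
      if (a2 == "*" && !identical(nxt, tgt)) blocked <- TRUE
      if (a1 == a2 && a1 != "*") sdd <- sdd + 1 else ndd <- ndd + 1
      cur <- nxt
    }
    c(sd = sdd, nd = ndd, blocked = as.numeric(blocked))
  }
  for (i in seq_len(64)) {
    if (is_stop[i]) { sd_mat[i, ] <- NA; nd_mat[i, ] <- NA; next }
    for (j in seq_len(64)) {
      if (is_stop[j]) { sd_mat[i, j] <- NA; nd_mat[i, j] <- NA; next }
      dpos <- which(codon_mat[i, ] != codon_mat[j, ])
      d <- length(dpos)
      if (d == 0) next
      res <- t(vapply(perms[[as.character(d)]],
                      function(ord) path_counts(i, j, dpos[ord]),
                      numeric(3)))
      ok <- res[, "blocked"] == 0
      if (!any(ok)) ok <- rep(TRUE, nrow(res))
      sd_mat[i, j] <- mean(res[ok, "sd"])
      nd_mat[i, j] <- mean(res[ok, "nd"])
    }
  }

  # fixed preferred codon per amino acid (first in A<C<G<T order); the
  # simulator's codon-bias parameter beta concentrates usage on these.
  aas <- sort(unique(aa[!is_stop]))
  preferred <- vapply(aas, function(a) min(which(aa == a & !is_stop)),
                      integer(1))
  degeneracy <- stats::setNames(
    vapply(aas, function(a) sum(aa == a & !is_stop), integer(1)), aas)

  tab <- list(
    codons = codons, idx = idx, aa = aa, is_stop = is_stop,
    codon_mat = codon_mat, syn_sites = syn_sites,
    syn_neighbors = syn_neighbors, sd_mat = sd_mat, nd_mat = nd_mat,
    aas = aas, preferred = preferred, degeneracy = degeneracy
  )
  .httscan_cache$tab <- tab
  tab
}

# codon preference vector over the 64 codons for bias strength beta in [0,1]:
# within each amino acid the preferred codon has probability 1/k + beta(1-1/k),
# the others share (1-beta)/k each.  beta = 0 is uniform usage (Nc -> 61),
# beta = 1 collapses to one codon per amino acid (Nc -> 20).
#' @keywords internal
codon_preference <- function(beta, tab = codon_tables()) {
  stopifnot(beta >= 0, beta <= 1)
  p <- numeric(64)
  for (a in tab$aas) {
    k <- tab$degeneracy[[a]]
    members <- which(tab$aa == a & !tab$is_stop)
    p[members] <- (1 - beta) / k
    p[tab$preferred[[a]]] <- 1 / k + beta * (1 - 1 / k)
  }
  p
}

# split a sequence into codon indices; codons containing anything outside
# A/C/G/T (gaps, N, ambiguity codes) come back NA
#' @keywords internal
codon_indices <- function(sequence, tab = codon_tables()) {
  sequence <- toupper(sequence)
  n <- nchar(sequence) %/% 3
  if (n == 0) return(integer(0))
  starts <- seq.int(1, by = 3, length.out = n)
  unname(tab$idx[substring(sequence, starts, starts + 2)])
}

#' Reverse-complement a nucleotide sequence
#'
#' Case is preserved; IUPAC ambiguity codes are complemented where defined
#' and any other character is left untouched.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of reverse-complemented sequences.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTUMRWSYKVHDBNacgtumrwsykvhdbn",
                 "TGCAAKYWSRMBDHVNtgcaakywsrmbdhvn", x)
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""),
         character(1))
}
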