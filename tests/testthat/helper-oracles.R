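# Independent brute-force oracles.  Everything here is written against the
# definitions directly (recursive enumeration, boolean arrays, closed
# forms) and shares no code with the package internals it checks.

ORACLE_BASES <- c("A", "C", "G", "T")
ORACLE_GC <- as.list(Biostrings::GENETIC_CODE)

oracle_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in oracle_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# NG86 synonymous site count of one codon (stop mutations = nonsynonymous)
oracle_syn_sites <- function(cod) {
  s <- 0
  for (p in 1:3) {
    for (b in setdiff(ORACLE_BASES, substr(cod, p, p))) {
      alt <- cod
      substr(alt, p, p) <- b
      if (ORACLE_GC[[alt]] != "*" && ORACLE_GC[[alt]] == ORACLE_GC[[cod]]) {
        s <- s + 1
      }
    }
  }
  s / 3
}

# NG86 pathway-averaged (syn, nonsyn) differences for one codon pair,
# enumerating substitution orderings; stop-crossing paths dropped unless
# all paths cross a stop
oracle_pair_diffs <- function(c1, c2) {
  a1 <- strsplit(c1, "")[[1]]
  a2 <- strsplit(c2, "")[[1]]
  dpos <- which(a1 != a2)
  if (length(dpos) == 0) return(c(sd = 0, nd = 0))
  paths <- list()
  for (ord in oracle_perms(dpos)) {
    cur <- a1
    sdd <- 0; ndd <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- cur
      nxt[p] <- a2[p]
      aa_from <- ORACLE_GC[[paste(cur, collapse = "")]]
      aa_to <- ORACLE_GC[[paste(nxt, collapse = "")]]
      if (aa_to == "*" && !all(nxt == a2)) blocked <- TRUE
      if (aa_from == aa_to && aa_from != "*") sdd <- sdd + 1 else {
        ndd <- ndd + 1
      }
      cur <- nxt
    }
    paths[[length(paths) + 1]] <- c(sdd, ndd, blocked)
  }
  m <- do.call(rbind, paths)
  ok <- m[, 3] == 0
  if (!any(ok)) ok <- rep(TRUE, nrow(m))
  c(sd = mean(m[ok, 1]), nd = mean(m[ok, 2]))
}

# full NG86 dS over two codon strings
oracle_ng86 <- function(seq_a, seq_b) {
  n <- nchar(seq_a) %/% 3
  S <- 0; Sd <- 0; L <- 0
  for (i in seq_len(n)) {
    c1 <- toupper(substr(seq_a, 3 * i - 2, 3 * i))
    c2 <- toupper(substr(seq_b, 3 * i - 2, 3 * i))
    if (grepl("[^ACGT]", c1) || grepl("[^ACGT]", c2)) next
    if (ORACLE_GC[[c1]] == "*" || ORACLE_GC[[c2]] == "*") next
    L <- L + 1
    S <- S + (oracle_syn_sites(c1) + oracle_syn_sites(c2)) / 2
    Sd <- Sd + oracle_pair_diffs(c1, c2)[["sd"]]
  }
  pS <- Sd / S
  list(S = S, Sd = Sd, pS = pS, n_codons = L,
       dS = if (pS < 0.75) -3 / 4 * log(1 - 4 / 3 * pS) else NA_real_)
}

# direct per-amino-acid homozygosity recomputation of Wright's Nc
oracle_enc <- function(sequence) {
  n <- nchar(sequence) %/% 3
  cods <- toupper(substring(sequence, 3 * (1:n) - 2, 3 * (1:n)))
  cods <- cods[!grepl("[^ACGT]", cods)]
  cods <- cods[vapply(cods, function(cd) ORACLE_GC[[cd]] != "*", logical(1))]
  aa_of <- vapply(cods, function(cd) ORACLE_GC[[cd]], character(1))
  all_aa <- unique(unlist(ORACLE_GC))
  all_aa <- setdiff(all_aa, "*")
  deg <- vapply(all_aa, function(a) sum(unlist(ORACLE_GC) == a), numeric(1))
  names(deg) <- all_aa
  F_list <- list()
  for (a in all_aa) {
    if (deg[[a]] == 1) next
    obs <- cods[aa_of == a]
    n_a <- length(obs)
    if (n_a < 2) next
    p <- table(obs) / n_a
    f <- (n_a * sum(p^2) - 1) / (n_a - 1)
    if (f <= 0) next
    F_list[[a]] <- c(f = f, k = deg[[a]])
  }
  m <- do.call(rbind, F_list)
  Fbar <- function(k) {
    v <- m[m[, "k"] == k, "f"]
    if (length(v)) mean(v) else NA_real_
  }
  F2 <- Fbar(2); F3 <- Fbar(3); F4 <- Fbar(4); F6 <- Fbar(6)
  if (is.na(F3) && !is.na(F2) && !is.na(F4)) F3 <- (F2 + F4) / 2
  fs <- c(F2, F3, F4, F6)
  if (any(is.na(fs))) fs[is.na(fs)] <- mean(fs, na.rm = TRUE)
  nc <- 2 + 9 / fs[1] + 1 / fs[2] + 5 / fs[3] + 3 / fs[4]
  min(max(nc, 20), 61)
}

# boolean-array union of 0-based half-open intervals
oracle_union_bp <- function(starts, ends, max_pos) {
  covered <- logical(max_pos)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) covered[(starts[i] + 1):ends[i]] <- TRUE
  }
  sum(covered)
}

# transitive closure of the "gap <= max_gap" relation over intervals
oracle_merge <- function(starts, ends, max_gap) {
  n <- length(starts)
  group <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        gap <- max(starts[i], starts[j]) - min(ends[i], ends[j])
        if (gap <= max_gap && group[i] != group[j]) {
          g <- min(group[i], group[j])
          group[group == group[i] | group == group[j]] <- g
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  out <- lapply(unique(group), function(g) {
    c(start = min(starts[group == g]), end = max(ends[group == g]))
  })
  m <- do.call(rbind, out)
  m[order(m[, "start"]), , drop = FALSE]
}

# exhaustive six-frame ORF scan (longest stop-to-stop / edge run)
oracle_longest_orf_aa <- function(sequence) {
  rc <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", toupper(s)), "")[[1]]),
          collapse = "")
  }
  best <- 0
  for (s in c(toupper(sequence), rc(sequence))) {
    for (f in 0:2) {
      n_cod <- (nchar(s) - f) %/% 3
      if (n_cod < 1) next
      run <- 0
      for (i in seq_len(n_cod)) {
        cod <- substr(s, f + 3 * i - 2, f + 3 * i)
        if (grepl("[^ACGT]", cod) || ORACLE_GC[[cod]] == "*") {
          best <- max(best, run)
          run <- 0
        } else {
          run <- run + 1
        }
      }
      best <- max(best, run)
    }
  }
  best
}

random_codon <- function(n = 1) {
  sense <- names(ORACLE_GC)[unlist(ORACLE_GC) != "*"]
  sample(sense, n, replace = TRUE)
}

random_dna <- function(n) {
  paste(sample(ORACLE_BASES, n, replace = TRUE), collapse = "")
}

# deterministic point mutations (A<->C, G<->T style: first other base)
mutate_at <- function(seq, pos) {
  ch <- strsplit(seq, "")[[1]]
  for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  paste(ch, collapse = "")
}

# stop-bounded cassette whose longest six-frame ORF is exactly n_aa: the
# repeat unit TATCTAATTAAC is sense in frame 0 but every other frame
# (including the reverse strand) hits a stop within each period
orf_cassette <- function(n_aa) {
  unit <- "TATCTAATTAAC"
  paste0("TAA", strrep(unit, n_aa %/% 4), substr(unit, 1, 3 * (n_aa %% 4)),
         "TAA")
}
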