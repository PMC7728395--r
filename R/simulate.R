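# Forward codon-sequence simulator.  Proteins are held fixed and only
# synonymous substitutions accumulate, so every emitted "alignment" is
# trivially column-correct and dS is the only divergence statistic with
# signal - exactly the quantity the detection test consumes.  The codon
# usage bias parameter beta couples to the synonymous rate through
# r_s = r_max * (1 - lambda * beta), generating the dS-CUB relation the
# vertical-expectation regression assumes.

#' Simulation configuration
#'
#' @param species_tree Newick string, file path, or `ape::phylo` object;
#'   branch lengths in million years.
#' @param n_genes number of orthologous genes (default 50).
#' @param codons_per_gene gene length in codons (default 500).
#' @param codons_per_te TE length in codons (default 600).
#' @param r_max maximal synonymous rate, substitutions per synonymous site
#'   per million years (default 0.02).
#' @param lambda_cub strength of the CUB-rate coupling in \[0, 1)
#'   (default 0.5): a fully biased gene evolves at
#'   `r_max * (1 - lambda_cub)`.
#' @param te_specs list of TE specifications; each a list with `mode`
#'   (`"vertical"` or `"horizontal"`), `beta`, and for horizontal mode
#'   `donor`, `recipient`, `t_ht` (My before present); optional `te_class`
#'   and `te_group` labels.
#' @param seed root seed; per-unit child seeds are derived by stable
#'   hashing of unit ids so adding units does not perturb existing ones.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(species_tree = "(A:10,B:10);", n_genes = 50,
                       codons_per_gene = 500, codons_per_te = 600,
                       r_max = 0.02, lambda_cub = 0.5, te_specs = list(),
                       seed = 1) {
  tree <- if (inherits(species_tree, "phylo")) {
    species_tree
  } else if (file.exists(species_tree)) {
    ape::read.tree(species_tree)
  } else {
    ape::read.tree(text = species_tree)
  }
  if (is.null(tree) || is.null(tree$edge.length)) {
    stop("invalid species tree: need branch lengths")
  }
  stopifnot(lambda_cub >= 0, lambda_cub < 1, r_max > 0,
            n_genes >= 1, codons_per_gene >= 1, codons_per_te >= 1)
  for (spec in te_specs) {
    if (!spec$mode %in% c("vertical", "horizontal")) {
      stop("TE mode must be 'vertical' or 'horizontal'")
    }
    if (spec$mode == "horizontal") {
      if (!all(c(spec$donor, spec$recipient) %in% tree$tip.label)) {
        stop("donor/recipient must be tips of the species tree")
      }
      div <- tip_pair_divergence(tree, spec$donor, spec$recipient)
      if (spec$t_ht >= div) {
        stop("t_ht must predate the donor/recipient divergence (",
             div, " My)")
      }
    }
  }
  structure(list(tree = tree, n_genes = n_genes,
                 codons_per_gene = codons_per_gene,
                 codons_per_te = codons_per_te, r_max = r_max,
                 lambda_cub = lambda_cub, te_specs = te_specs,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# time (My) since the two tips last shared an ancestor, measured along the
# path to tip a (equals the b-side for ultrametric trees)
#' @keywords internal
tip_pair_divergence <- function(tree, a, b) {
  ia <- match(a, tree$tip.label)
  ib <- match(b, tree$tip.label)
  if (is.na(ia) || is.na(ib)) stop("tip not in tree")
  mrca <- ape::getMRCA(tree, c(ia, ib))
  depths <- ape::node.depth.edgelength(tree)
  depths[ia] - depths[mrca]
}

# deterministic 31-bit string hash for per-unit child seeds
#' @keywords internal
stable_hash <- function(s) {
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}

#' @keywords internal
child_seed <- function(root_seed, unit_id) {
  as.integer((as.numeric(root_seed) + stable_hash(unit_id)) %% 2147483647)
}

# One branch of synonymous evolution.  Each codon accrues
# Poisson(r_s * t * s_c) substitution events, s_c its fractional
# synonymous site count; each event moves to a single-nucleotide synonymous
# neighbour drawn by the codon preference (uniform fallback when all
# neighbour weights vanish).  Codons with no synonymous neighbour (ATG,
# TGG) never change.
#' @keywords internal
evolve_codons <- function(cod, t_my, r_s, pref64, tab = codon_tables()) {
  lam <- r_s * t_my * tab$syn_sites[cod]
  k <- stats::rpois(length(cod), lam)
  draw_neighbor <- function(cv, n_draw) {
    nb <- tab$syn_neighbors[[cv]]
    if (length(nb) == 1L) return(rep(nb, n_draw))
    w <- pref64[nb]
    if (sum(w) <= 0) w <- rep(1, length(nb))
    nb[sample.int(length(nb), n_draw, replace = TRUE, prob = w)]
  }
  idx1 <- which(k == 1L)
  if (length(idx1)) {
    vals <- cod[idx1]                 # snapshot: one event per codon exactly
    for (cv in unique(vals)) {
      sel <- idx1[vals == cv]
      cod[sel] <- draw_neighbor(cv, length(sel))
    }
  }
  for (i in which(k >= 2L)) {
    cv <- cod[i]
    for (step in seq_len(k[i])) cv <- draw_neighbor(cv, 1L)
    cod[i] <- cv
  }
  attr(cod, "n_events") <- sum(k)
  cod
}

# root codon sequence: amino acids uniform over the 20, codons by the
# beta-weighted preference
#' @keywords internal
sample_root_codons <- function(n_codons, beta, tab = codon_tables()) {
  pref <- codon_preference(beta, tab)
  aa_draw <- sample(tab$aas, n_codons, replace = TRUE)
  cod <- integer(n_codons)
  for (a in unique(aa_draw)) {
    members <- which(tab$aa == a & !tab$is_stop)
    sel <- which(aa_draw == a)
    if (length(members) == 1L) {
      cod[sel] <- members
    } else {
      w <- pref[members]
      cod[sel] <- members[sample.int(length(members), length(sel),
                                     replace = TRUE, prob = w)]
    }
  }
  cod
}

#' @keywords internal
sim_along_tree <- function(tree, root_cod, r_s, pref64,
                           tab = codon_tables()) {
  tree <- stats::reorder(tree, "cladewise")   # parents before children
  n_tip <- length(tree$tip.label)
  seqs <- vector("list", n_tip + tree$Nnode)
  seqs[[n_tip + 1L]] <- root_cod
  edge_events <- numeric(nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    res <- evolve_codons(seqs[[tree$edge[e, 1]]], tree$edge.length[e],
                         r_s, pref64, tab)
    edge_events[e] <- attr(res, "n_events")
    seqs[[tree$edge[e, 2]]] <- res
  }
  tips <- stats::setNames(seqs[seq_len(n_tip)], tree$tip.label)
  list(tips = tips, edge_events = edge_events)
}

codons_to_string <- function(cod, tab = codon_tables()) {
  paste(tab$codons[cod], collapse = "")
}

#' Simulate one orthologous gene along the species tree
#'
#' @param beta codon-bias strength in \[0, 1\].
#' @param config a [sim_config()] object (its tree, gene length, `r_max`
#'   and `lambda_cub` are used).
#' @return named character vector of tip coding sequences (equal length,
#'   already "aligned" since the protein is invariant), with attributes
#'   `beta`, `r_s` and `n_events` (total realized substitutions).
#' @export
simulate_gene <- function(beta, config) {
  tab <- codon_tables()
  r_s <- config$r_max * (1 - config$lambda_cub * beta)
  pref <- codon_preference(beta, tab)
  root <- sample_root_codons(config$codons_per_gene, beta, tab)
  sim <- sim_along_tree(config$tree, root, r_s, pref, tab)
  out <- vapply(sim$tips, codons_to_string, character(1), tab = tab)
  attr(out, "beta") <- beta
  attr(out, "r_s") <- r_s
  attr(out, "n_events") <- sum(sim$edge_events)
  out
}

#' Simulate a TE family with a vertical or horizontal history
#'
#' Vertical mode evolves the element like a gene along the whole tree.
#' Horizontal mode evolves it along the donor lineage only; at `t_ht`
#' million years before the present the donor-lineage sequence is copied
#' into the recipient lineage and both evolve independently afterwards, so
#' the donor-recipient divergence reflects `t_ht`, not the species split.
#'
#' @param spec list with `mode` (`"vertical"`/`"horizontal"`), `beta`, and
#'   for horizontal mode `donor`, `recipient`, `t_ht`.
#' @param config a [sim_config()] object.
#' @return list with `sequences` (named character vector; all tips for
#'   vertical mode, donor and recipient only for horizontal mode) and
#'   `truth` (one-row `data.frame`: mode, beta, donor, recipient, t_ht,
#'   n_events).
#' @export
simulate_te <- function(spec, config) {
  tab <- codon_tables()
  beta <- spec$beta
  r_s <- config$r_max * (1 - config$lambda_cub * beta)
  pref <- codon_preference(beta, tab)
  root <- sample_root_codons(config$codons_per_te, beta, tab)
  if (spec$mode == "vertical") {
    sim <- sim_along_tree(config$tree, root, r_s, pref, tab)
    seqs <- vapply(sim$tips, codons_to_string, character(1), tab = tab)
    truth <- data.frame(mode = "vertical", beta = beta,
                        donor = NA_character_, recipient = NA_character_,
                        t_ht = NA_real_, n_events = sum(sim$edge_events),
                        stringsAsFactors = FALSE)
    return(list(sequences = seqs, truth = truth))
  }
  if (!spec$recipient %in% config$tree$tip.label) {
    stop("recipient not in tree: ", spec$recipient)
  }
  # donor lineage: root -> donor tip, with a snapshot t_ht before present
  tree <- config$tree
  donor_tip <- match(spec$donor, tree$tip.label)
  path_edges <- integer(0)
  node <- donor_tip
  root_node <- length(tree$tip.label) + 1L
  while (node != root_node) {
    e <- which(tree$edge[, 2] == node)
    path_edges <- c(e, path_edges)
    node <- tree$edge[e, 1]
  }
  lens <- tree$edge.length[path_edges]
  total <- sum(lens)
  snap_depth <- total - spec$t_ht          # distance from root to snapshot
  cur <- root
  acc <- 0
  snapshot <- NULL
  n_events <- 0
  for (i in seq_along(path_edges)) {
    len <- lens[i]
    if (is.null(snapshot) && acc + len >= snap_depth) {
      first <- snap_depth - acc
      cur <- evolve_codons(cur, first, r_s, pref, tab)
      n_events <- n_events + attr(cur, "n_events")
      snapshot <- cur
      cur <- evolve_codons(cur, len - first, r_s, pref, tab)
    } else {
      cur <- evolve_codons(cur, len, r_s, pref, tab)
    }
    n_events <- n_events + attr(cur, "n_events")
    acc <- acc + len
  }
  if (is.null(snapshot)) snapshot <- cur     # t_ht == 0
  recip <- evolve_codons(snapshot, spec$t_ht, r_s, pref, tab)
  n_events <- n_events + attr(recip, "n_events")
  seqs <- stats::setNames(
    c(codons_to_string(cur, tab), codons_to_string(recip, tab)),
    c(spec$donor, spec$recipient))
  truth <- data.frame(mode = "horizontal", beta = beta,
                      donor = spec$donor, recipient = spec$recipient,
                      t_ht = spec$t_ht, n_events = n_events,
                      stringsAsFactors = FALSE)
  list(sequences = seqs, truth = truth)
}

#' Simulate an intragenomic copy burst of known age
#'
#' Each copy is the consensus with `Poisson(rate * age * length)`
#' substitutions placed uniformly along the sequence; substitutions are
#' transitions with probability kappa/(kappa + 2) (default kappa = 2) and
#' otherwise a uniform transversion.  The expected copy-to-consensus K2P
#' distance is approximately `rate * age`.
#'
#' @param consensus nucleotide string.
#' @param age_my burst age in million years.
#' @param per_site_rate substitutions per site per million years.
#' @param n_copies number of copies to emit.
#' @param kappa transition:transversion event ratio parameter (default 2).
#' @return list with `copies` (named character vector) and `truth`
#'   (`data.frame` with per-copy realized substitution and transition
#'   counts).
#' @export
simulate_copy_burst <- function(consensus, age_my, per_site_rate, n_copies,
                                kappa = 2) {
  stopifnot(age_my >= 0, per_site_rate >= 0, n_copies >= 1)
  transit <- c(A = "G", G = "A", C = "T", T = "C")
  L <- nchar(consensus)
  base <- strsplit(toupper(consensus), "")[[1]]
  copies <- character(n_copies)
  n_sub <- integer(n_copies)
  n_ti <- integer(n_copies)
  for (i in seq_len(n_copies)) {
    s <- base
    n <- stats::rpois(1, per_site_rate * age_my * L)
    if (n > 0) {
      pos <- sample.int(L, n, replace = TRUE)
      is_ti <- stats::runif(n) < kappa / (kappa + 2)
      for (j in seq_len(n)) {
        b <- s[pos[j]]
        if (!b %in% BASES) next
        s[pos[j]] <- if (is_ti[j]) {
          transit[[b]]
        } else {
          sample(setdiff(BASES, c(b, transit[[b]])), 1)
        }
      }
      n_ti[i] <- sum(is_ti)
    }
    n_sub[i] <- n
    copies[i] <- paste(s, collapse = "")
  }
  names(copies) <- sprintf("copy_%03d", seq_len(n_copies))
  list(copies = copies,
       truth = data.frame(copy = names(copies), n_substitutions = n_sub,
                          n_transition_events = n_ti,
                          stringsAsFactors = FALSE))
}

#' Generate a complete synthetic study bundle
#'
#' Writes, under `out_dir`: per-gene and per-TE codon alignments (FASTA),
#' ground-truth TSVs (gene betas; TE mode/donor/recipient/transfer time),
#' the species tree (Newick), a rate table, tip-pair divergence times, a
#' random symmetric range-overlap matrix, a TE class table, and a toy
#' genome + homology-hit fixture (copies of the first TE implanted in a
#' random contig, with split HSP rows exercising the merge rule).
#' Deterministic for a fixed seed: per-unit seeds are derived by stable
#' hashing of unit ids.
#'
#' @param config a [sim_config()] object.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory `genes`, `tes`, `truth`
#'   tables and the paths written.
#' @export
generate_study <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "genes"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "tes"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)

  ape::write.tree(config$tree, file.path(out_dir, "tree.nwk"))

  tsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  # genes: betas drawn under a dedicated child seed, then one unit each
  set.seed(child_seed(config$seed, "gene_betas"))
  gene_betas <- stats::runif(config$n_genes)
  genes <- list()
  for (g in seq_len(config$n_genes)) {
    id <- sprintf("gene_%03d", g)
    set.seed(child_seed(config$seed, id))
    genes[[id]] <- simulate_gene(gene_betas[g], config)
    write_fasta(genes[[id]], file.path(out_dir, "genes",
                                       paste0(id, ".fa")))
  }
  tsv(data.frame(unit_id = names(genes), kind = "gene", beta = gene_betas),
      file.path(out_dir, "truth", "genes.tsv"))

  # TEs
  tes <- list()
  te_truth <- list()
  te_classes <- list()
  for (t in seq_along(config$te_specs)) {
    spec <- config$te_specs[[t]]
    id <- sprintf("te_%03d", t)
    set.seed(child_seed(config$seed, id))
    sim <- simulate_te(spec, config)
    tes[[id]] <- sim$sequences
    write_fasta(sim$sequences, file.path(out_dir, "tes",
                                         paste0(id, ".fa")))
    tr <- cbind(data.frame(unit_id = id, kind = "te",
                           stringsAsFactors = FALSE), sim$truth)
    te_truth[[t]] <- tr
    te_classes[[t]] <- data.frame(
      family_id = id,
      te_class = if (is.null(spec$te_class)) "ClassI" else spec$te_class,
      te_group = if (is.null(spec$te_group)) "LTR" else spec$te_group,
      stringsAsFactors = FALSE
    )
  }
  if (length(te_truth)) {
    tsv(do.call(rbind, te_truth), file.path(out_dir, "truth", "tes.tsv"))
    tsv(do.call(rbind, te_classes), file.path(out_dir, "te_classes.tsv"))
  }

  tsv(default_rate_table(), file.path(out_dir, "rates.tsv"))

  tips <- config$tree$tip.label
  pairs <- utils::combn(sort(tips), 2)
  tsv(data.frame(
    species_a = pairs[1, ], species_b = pairs[2, ],
    divergence_my = apply(pairs, 2, function(p) {
      tip_pair_divergence(config$tree, p[1], p[2])
    })
  ), file.path(out_dir, "divergence.tsv"))

  set.seed(child_seed(config$seed, "overlap_matrix"))
  n_sp <- length(tips)
  m <- matrix(0L, n_sp, n_sp, dimnames = list(sort(tips), sort(tips)))
  draws <- stats::rbinom(ncol(pairs), 1, 0.5)
  for (p in seq_len(ncol(pairs))) {
    m[pairs[1, p], pairs[2, p]] <- m[pairs[2, p], pairs[1, p]] <- draws[p]
  }
  diag(m) <- 1L
  utils::write.table(m, file.path(out_dir, "overlap.tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)

  # toy genome + HSP fixture: implant copies of the first TE into a random
  # contig per species, and emit 1-based hit rows (each copy split in two
  # HSPs with a small gap so the merge rule has work to do)
  if (length(tes)) {
    first <- tes[[1]]
    set.seed(child_seed(config$seed, "toy_genome"))
    hsp_lines <- character(0)
    genome <- character(0)
    truth_iv <- list()
    for (sp in names(first)) {
      te_seq <- first[[sp]]
      te_len <- nchar(te_seq)
      pad <- paste(sample(BASES, 2000, replace = TRUE), collapse = "")
      pad2 <- paste(sample(BASES, 2000, replace = TRUE), collapse = "")
      contig <- paste0(pad, te_seq, pad2, revcomp(te_seq))
      ctg_id <- paste0(sp, "_ctg1")
      genome[[ctg_id]] <- contig
      starts0 <- c(2000, 2000 + te_len + 2000)      # 0-based copy starts
      strands <- c("+", "-")
      for (ci in seq_along(starts0)) {
        s0 <- starts0[ci]
        half <- te_len %/% 2
        # two HSPs covering the copy with a 200-nt gap between them
        seg <- rbind(c(s0, s0 + half - 100), c(s0 + half + 100, s0 + te_len))
        for (r in seq_len(nrow(seg))) {
          ss <- seg[r, 1] + 1                       # to 1-based inclusive
          se <- seg[r, 2]
          if (strands[ci] == "-") { tmp <- ss; ss <- se; se <- tmp }
          hsp_lines <- c(hsp_lines, sprintf(
            "%s\t%s\t%.2f\t%d\t0\t0\t%d\t%d\t%d\t%d\t0.0\t%d",
            names(tes)[1], ctg_id, 98.5, abs(se - ss) + 1,
            1, abs(se - ss) + 1, ss, se, 500))
        }
        truth_iv[[length(truth_iv) + 1]] <- data.frame(
          contig = ctg_id, start = s0, end = s0 + te_len,
          name = names(tes)[1], strand = strands[ci],
          stringsAsFactors = FALSE)
      }
    }
    write_fasta(genome, file.path(out_dir, "toy_genome.fa"))
    con <- file(file.path(out_dir, "toy_hits.tsv"), open = "wb")
    writeLines(hsp_lines, con)
    close(con)
    write_bed(do.call(rbind, truth_iv),
              file.path(out_dir, "truth", "toy_copies.bed"))
  }

  invisible(list(genes = genes, tes = tes, gene_betas = gene_betas,
                 te_truth = if (length(te_truth)) do.call(rbind, te_truth)
                            else NULL,
                 out_dir = out_dir))
}
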