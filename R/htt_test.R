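# The core horizontal-transfer inference.  Per species pair, the vertical
# expectation is an OLS regression of gene dS on gene codon usage bias
# (ENC); a TE family is called horizontally transferred when its dS falls
# significantly below the prediction at its own CUB, judged by a
# studentized prediction residual against a t distribution (one-tailed,
# alpha = 0.01 by default).

pair_key <- function(a, b) {
  paste(sort(c(a, b)), collapse = "|")
}

# in-frame codons with all-ACGT bases, as a plain sequence (drops alignment
# gap codons so that ENC sees only usable codons)
coding_codons <- function(seq) {
  tab <- codon_tables()
  ci <- codon_indices(seq, tab)
  ci <- ci[!is.na(ci)]
  paste(tab$codons[ci], collapse = "")
}

#' Build (CUB, dS) observation points from codon alignments
#'
#' For every unit (gene or TE family) and every unordered species pair in
#' its alignment, computes the NG86 dS between the two sequences and the
#' mean ENC of the pair.
#'
#' @param alignments named list of codon alignments; each alignment is a
#'   named character vector with one sequence per species.
#' @param kind `"gene"` or `"te"`, recorded per point.
#' @return `data.frame` with columns `unit_id`, `species_a`, `species_b`
#'   (sorted within pair), `ds`, `cub`, `saturated`, `kind`.
#' @export
build_pair_points <- function(alignments, kind = c("gene", "te")) {
  kind <- match.arg(kind)
  rows <- list()
  for (unit in names(alignments)) {
    aln <- alignments[[unit]]
    species <- sort(names(aln))
    nc <- vapply(species, function(sp) enc(coding_codons(aln[[sp]]))$Nc,
                 numeric(1))
    if (length(species) < 2) next
    for (i in seq_len(length(species) - 1)) {
      for (j in seq(i + 1, length(species))) {
        d <- ds_ng86(aln[[species[i]]], aln[[species[j]]])
        rows[[length(rows) + 1]] <- data.frame(
          unit_id = unit, species_a = species[i], species_b = species[j],
          ds = d$dS, cub = mean(c(nc[i], nc[j])),
          saturated = d$saturated, kind = kind, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(unit_id = character(0), species_a = character(0),
                      species_b = character(0), ds = numeric(0),
                      cub = numeric(0), saturated = logical(0),
                      kind = character(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit the vertical-expectation gene regression for one species pair
#'
#' Ordinary least squares of gene dS on gene CUB.  Saturated dS values are
#' excluded before fitting; residuals are retained for the diagnostic
#' checks.
#'
#' @param points `data.frame` with columns `ds` and `cub` (one row per
#'   gene), e.g. a per-pair subset of [build_pair_points()] output.
#' @param min_genes minimum number of usable gene points (default 10).
#' @param species_a,species_b optional labels stored on the model.
#' @return object of class `htt_model`: list with `slope`, `intercept`,
#'   `residual_sd`, `df` (n - 2), `n`, `x_mean`, `sxx`, `residuals`,
#'   `points` and the species labels.
#' @export
fit_gene_regression <- function(points, min_genes = 10,
                                species_a = NA_character_,
                                species_b = NA_character_) {
  pts <- points[!is.na(points$ds), , drop = FALSE]
  n <- nrow(pts)
  if (n < max(min_genes, 3)) {
    stop("need at least ", max(min_genes, 3),
         " unsaturated gene points, got ", n)
  }
  if (stats::var(pts$cub) == 0) {
    stop("zero CUB variance: regression slope undefined")
  }
  fit <- stats::lm(ds ~ cub, data = pts)
  res <- stats::residuals(fit)
  structure(list(
    species_a = species_a, species_b = species_b,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    residual_sd = sqrt(sum(res^2) / (n - 2)),
    df = n - 2, n = n,
    x_mean = mean(pts$cub),
    sxx = sum((pts$cub - mean(pts$cub))^2),
    residuals = unname(res),
    points = pts
  ), class = "htt_model")
}

#' @export
print.htt_model <- function(x, ...) {
  cat(sprintf(
    "dS ~ CUB gene regression (%s vs %s): n=%d slope=%.5g intercept=%.5g sigma=%.5g\n",
    x$species_a, x$species_b, x$n, x$slope, x$intercept, x$residual_sd))
  invisible(x)
}

#' Test a TE observation against the vertical expectation
#'
#' Computes the studentized prediction residual
#' t = (te_dS - expected) / (sigma * sqrt(1 + 1/n + leverage)) and the
#' one-tailed p-value P(T_df <= t): small p means the TE diverged far less
#' than vertically inherited genes with the same codon usage bias, the
#' horizontal-transfer signature.
#'
#' @param model fitted `htt_model` for the species pair.
#' @param te_ds TE synonymous divergence (NA if saturated).
#' @param te_cub TE codon usage bias (mean ENC of the pair).
#' @param family_id label recorded on the call.
#' @param alpha significance level (default 0.01).
#' @return one-row `data.frame` of class `htt_call` columns: `family_id`,
#'   `species_a`, `species_b`, `te_ds`, `te_cub`, `expected_ds`,
#'   `t_statistic`, `p_value`, `significant`, `reason` (non-NA when the
#'   call is suppressed, e.g. for saturated dS).
#' @export
te_ht_pvalue <- function(model, te_ds, te_cub, family_id = "TE",
                         alpha = 0.01) {
  stopifnot(inherits(model, "htt_model"))
  expected <- model$intercept + model$slope * te_cub
  if (is.na(te_ds)) {
    return(data.frame(
      family_id = family_id, species_a = model$species_a,
      species_b = model$species_b, te_ds = NA_real_, te_cub = te_cub,
      expected_ds = expected, t_statistic = NA_real_, p_value = NA_real_,
      significant = NA, reason = "saturated dS", stringsAsFactors = FALSE
    ))
  }
  se <- model$residual_sd *
    sqrt(1 + 1 / model$n + (te_cub - model$x_mean)^2 / model$sxx)
  if (se <= 1e-10) {
    # degenerate exact-fit model: direction decides the tail outright
    p <- if (te_ds < expected) 0 else if (te_ds > expected) 1 else 0.5
    tstat <- if (te_ds == expected) 0 else sign(te_ds - expected) * Inf
  } else {
    tstat <- (te_ds - expected) / se
    p <- stats::pt(tstat, df = model$df)
  }
  data.frame(
    family_id = family_id, species_a = model$species_a,
    species_b = model$species_b, te_ds = te_ds, te_cub = te_cub,
    expected_ds = expected, t_statistic = tstat, p_value = p,
    significant = p < alpha, reason = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Pairwise HTT significance matrix for one TE family
#'
#' Runs the dS-CUB test for every unordered pair of species carrying the
#' family, against that pair's gene regression.  Pairs without a fitted
#' model or without alignable sequence get `NA` cells.
#'
#' @param te_aln named character vector: the family's trimmed codon
#'   alignment, one sequence per species (names are species labels).
#' @param gene_models named list of `htt_model` objects keyed by
#'   `"A|B"` with the species pair sorted (see [fit_pair_models()]).
#' @param family_id family label.
#' @param alpha significance level (default 0.01).
#' @return list with `p` (symmetric p-value matrix, species x species),
#'   `significant` (logical mask), and `calls` (data.frame of the
#'   underlying calls).
#' @export
htt_matrix <- function(te_aln, gene_models, family_id = "TE", alpha = 0.01) {
  species <- sort(names(te_aln))
  if (length(species) < 2) stop("family must span at least two species")
  pm <- matrix(NA_real_, length(species), length(species),
               dimnames = list(species, species))
  calls <- list()
  nc <- vapply(species, function(sp) enc(coding_codons(te_aln[[sp]]))$Nc,
               numeric(1))
  for (i in seq_len(length(species) - 1)) {
    for (j in seq(i + 1, length(species))) {
      key <- pair_key(species[i], species[j])
      model <- gene_models[[key]]
      if (is.null(model)) next
      d <- tryCatch(ds_ng86(te_aln[[species[i]]], te_aln[[species[j]]]),
                    error = function(e) NULL)
      if (is.null(d)) next
      call <- te_ht_pvalue(model, d$dS, mean(c(nc[i], nc[j])),
                           family_id = family_id, alpha = alpha)
      pm[i, j] <- pm[j, i] <- call$p_value
      calls[[length(calls) + 1]] <- call
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else NULL
  list(p = pm, significant = !is.na(pm) & pm < alpha, calls = calls)
}

#' Fit gene regressions for every species pair
#'
#' @param gene_points output of [build_pair_points()] on gene alignments.
#' @param min_genes minimum usable genes per pair (default 10).
#' @return named list of `htt_model` objects keyed by `"A|B"`.
#' @export
fit_pair_models <- function(gene_points, min_genes = 10) {
  keys <- unique(pair_key2(gene_points$species_a, gene_points$species_b))
  models <- list()
  for (k in keys) {
    sel <- pair_key2(gene_points$species_a, gene_points$species_b) == k
    sp <- strsplit(k, "|", fixed = TRUE)[[1]]
    models[[k]] <- fit_gene_regression(gene_points[sel, , drop = FALSE],
                                       min_genes = min_genes,
                                       species_a = sp[1], species_b = sp[2])
  }
  models
}

pair_key2 <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Aggregate pairwise HTT signals into family-level events
#'
#' A family is an HTT family iff at least one species pair is significant;
#' each such family contributes one event (the minimal-event reading of a
#' significance network).  Per-species counts tally, for each species and
#' TE group, the HTT families in which the species appears in at least one
#' significant pair; the edge list counts significant families per species
#' pair.
#'
#' @param matrices named list of [htt_matrix()] results (names are family
#'   ids).
#' @param family_groups named character vector mapping family id to a TE
#'   group label (e.g. `"ClassII"`, `"nonLTR"`, `"LTR"`).
#' @return list with `events` (`data.frame`: family, group, number of
#'   significant pairs, species involved), `species_counts` (species x
#'   group count matrix plus totals), and `edges` (`data.frame`:
#'   species_a, species_b, n_families).
#' @export
call_family_events <- function(matrices, family_groups = NULL) {
  events <- list()
  species_hits <- list()   # per family: species involved in signif pairs
  edge_count <- new.env(parent = emptyenv())
  for (fam in names(matrices)) {
    m <- matrices[[fam]]$significant
    sig_pairs <- which(m & upper.tri(m), arr.ind = TRUE)
    if (nrow(sig_pairs) == 0) next
    sps <- sort(unique(c(rownames(m)[sig_pairs[, 1]],
                         colnames(m)[sig_pairs[, 2]])))
    grp <- if (!is.null(family_groups) && fam %in% names(family_groups)) {
      family_groups[[fam]]
    } else {
      "unclassified"
    }
    events[[length(events) + 1]] <- data.frame(
      family_id = fam, group = grp, n_significant_pairs = nrow(sig_pairs),
      species = paste(sps, collapse = ","), stringsAsFactors = FALSE
    )
    species_hits[[fam]] <- list(species = sps, group = grp)
    for (r in seq_len(nrow(sig_pairs))) {
      k <- pair_key(rownames(m)[sig_pairs[r, 1]],
                    colnames(m)[sig_pairs[r, 2]])
      edge_count[[k]] <- (if (is.null(edge_count[[k]])) 0L
                          else edge_count[[k]]) + 1L
    }
  }
  if (length(events) == 0) {
    return(list(
      events = data.frame(family_id = character(0), group = character(0),
                          n_significant_pairs = integer(0),
                          species = character(0)),
      species_counts = matrix(integer(0), 0, 0),
      edges = data.frame(species_a = character(0), species_b = character(0),
                         n_families = integer(0))
    ))
  }
  events <- do.call(rbind, events)
  all_species <- sort(unique(unlist(lapply(species_hits,
                                           function(h) h$species))))
  groups <- sort(unique(events$group))
  counts <- matrix(0L, length(all_species), length(groups),
                   dimnames = list(all_species, groups))
  for (h in species_hits) {
    counts[h$species, h$group] <- counts[h$species, h$group] + 1L
  }
  counts <- cbind(counts, Total = rowSums(counts))
  ekeys <- sort(ls(edge_count))
  edges <- data.frame(
    species_a = vapply(strsplit(ekeys, "|", fixed = TRUE), `[[`, "", 1),
    species_b = vapply(strsplit(ekeys, "|", fixed = TRUE), `[[`, "", 2),
    n_families = vapply(ekeys, function(k) edge_count[[k]], integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(edges) <- NULL
  list(events = events, species_counts = counts, edges = edges)
}

#' Diagnostics for a fitted gene regression
#'
#' Checks the assumptions behind the prediction-residual test: a
#' Kolmogorov-Smirnov test of the standardized residuals against the
#' standard normal, and a Pearson correlation between dS and CUB as a
#' linearity check.  A pair is flagged when residual normality is rejected
#' or no linear dS-CUB relation is detectable at `alpha_diag`.
#'
#' @param model fitted `htt_model`.
#' @param alpha_diag diagnostic significance level (default 0.05).
#' @return list with `ks_p`, `normal_ok`, `pearson_r`, `pearson_p`,
#'   `linear_ok`, `degenerate` (TRUE for an exact fit) and `flagged`.
#' @export
check_assumptions <- function(model, alpha_diag = 0.05) {
  stopifnot(inherits(model, "htt_model"))
  if (model$residual_sd <= 1e-10) {
    return(list(ks_p = NA_real_, normal_ok = NA, pearson_r = NA_real_,
                pearson_p = NA_real_, linear_ok = NA, degenerate = TRUE,
                flagged = FALSE))
  }
  std_res <- model$residuals / model$residual_sd
  ks <- suppressWarnings(stats::ks.test(std_res, "pnorm"))
  ct <- stats::cor.test(model$points$ds, model$points$cub,
                        method = "pearson")
  normal_ok <- ks$p.value >= alpha_diag
  linear_ok <- ct$p.value < alpha_diag
  list(ks_p = ks$p.value, normal_ok = normal_ok,
       pearson_r = unname(ct$estimate), pearson_p = ct$p.value,
       linear_ok = linear_ok, degenerate = FALSE,
       flagged = !(normal_ok && linear_ok))
}
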