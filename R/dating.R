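# Molecular-clock dating of horizontal transfers: per-taxon synonymous
# rates estimated from orthologous genes, T = k/2r for each event, and
# binned age profiles.

#' Default taxon-pair synonymous rate table
#'
#' Rates in substitutions per synonymous site per million years for
#' transfers within the Anophelinae subfamily (17.567e-3), within the
#' Culicinae subfamily (9.205e-3) and between the two subfamilies
#' (10.006e-3).
#'
#' @return `data.frame` with columns `taxon_pair_class`, `r`.
#' @export
default_rate_table <- function() {
  data.frame(
    taxon_pair_class = c("within_anophelinae", "within_culicinae",
                         "between_subfamilies"),
    r = c(17.567e-3, 9.205e-3, 10.006e-3),
    stringsAsFactors = FALSE
  )
}

#' Estimate a synonymous rate from orthologous gene divergences
#'
#' r = mean(gene dS) / (2 * divergence time); saturated (NA) gene values
#' are dropped.  The factor two reflects the two independent lineages
#' accumulating substitutions since the split.
#'
#' @param gene_ds numeric vector of per-gene dS values for one species
#'   pair (NA = saturated).
#' @param divergence_my divergence time of the pair in million years.
#' @param aggregate `"mean"` (default) or `"median"`.
#' @return list with `r` (substitutions per synonymous site per My),
#'   `n_genes` used, and `degenerate` (TRUE when r == 0).
#' @export
estimate_rate <- function(gene_ds, divergence_my, aggregate = c("mean",
                                                                "median")) {
  aggregate <- match.arg(aggregate)
  stopifnot(divergence_my > 0)
  usable <- gene_ds[!is.na(gene_ds)]
  if (length(usable) == 0) stop("all gene dS values saturated")
  k <- if (aggregate == "mean") mean(usable) else stats::median(usable)
  r <- k / (2 * divergence_my)
  list(r = r, n_genes = length(usable), degenerate = r == 0)
}

#' Date horizontal transfer events with T = k/2r
#'
#' @param k numeric vector of TE synonymous divergences between the
#'   species pairs (dS of the two representative copies).
#' @param taxon_pair_class character vector of rate-table classes, one per
#'   event (recycled if scalar).
#' @param rate_table table with columns `taxon_pair_class` and `r`
#'   (default [default_rate_table()]).
#' @param family_id,species_a,species_b optional labels carried through.
#' @return `data.frame` with columns `family_id`, `species_a`,
#'   `species_b`, `k`, `taxon_pair_class`, `r`, `T_my`.
#' @export
date_htt <- function(k, taxon_pair_class, rate_table = default_rate_table(),
                     family_id = NA_character_, species_a = NA_character_,
                     species_b = NA_character_) {
  n <- length(k)
  taxon_pair_class <- rep_len(taxon_pair_class, n)
  missing <- setdiff(unique(taxon_pair_class), rate_table$taxon_pair_class)
  if (length(missing)) {
    stop("no rate for taxon pair class: ", paste(missing, collapse = ", "))
  }
  if (any(!is.na(k) & k < 0)) stop("k must be non-negative")
  r <- rate_table$r[match(taxon_pair_class, rate_table$taxon_pair_class)]
  data.frame(
    family_id = rep_len(family_id, n), species_a = rep_len(species_a, n),
    species_b = rep_len(species_b, n), k = k,
    taxon_pair_class = taxon_pair_class, r = r, T_my = k / (2 * r),
    stringsAsFactors = FALSE
  )
}

#' Binned age profiles of dated transfer events
#'
#' Histograms of event ages by TE group and by host taxon class; total
#' counts are conserved across both tables.
#'
#' @param dating `data.frame` with at least `T_my` plus `te_group` and/or
#'   `taxon_class` columns (e.g. [date_htt()] output with annotation).
#' @param bin_width bin width in million years (default 5).
#' @return list with `by_te_group` and `by_taxon` count matrices
#'   (bins x categories) and the `breaks` used.
#' @export
age_profiles <- function(dating, bin_width = 5) {
  if (nrow(dating) == 0) stop("no dated events")
  t_max <- max(dating$T_my)
  breaks <- seq(0, bin_width * max(1, ceiling(t_max / bin_width)),
                by = bin_width)
  bins <- cut(dating$T_my, breaks = breaks, include.lowest = TRUE,
              right = FALSE)
  # events exactly at the upper edge belong to the last bin
  bins[dating$T_my == max(breaks)] <- levels(bins)[length(levels(bins))]
  tab_for <- function(col) {
    if (!col %in% names(dating)) return(NULL)
    as.matrix(table(bins, dating[[col]]))
  }
  list(by_te_group = tab_for("te_group"), by_taxon = tab_for("taxon_class"),
       breaks = breaks, n_events = nrow(dating))
}
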