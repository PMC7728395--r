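# End-to-end pipeline: wires gene and TE codon alignments through the
# dS-CUB test, event aggregation, dating and diagnostics, writing TSV
# results plus a manifest that records every threshold, input checksum and
# the package version.  All analysis stages are deterministic, so a rerun
# on the same inputs is byte-identical.

#' Default pipeline configuration
#'
#' All thresholds of the pipeline with their standard defaults: bit-score
#' > 200 to keep a hit, merge gap <= 1000 nt, 80/80 identity/coverage
#' clustering, members >= 600 nt, ORF > 300 aa (Class I) or > 200 aa
#' (Class II), test level alpha = 0.01, flanks of 4000 nt (3000 minimum)
#' for the introgression check, and at least 10 usable genes per pair.
#'
#' @param ... named overrides of any default.
#' @return named list of thresholds.
#' @export
pipeline_config <- function(...) {
  config <- list(
    min_bit_score = 200, max_gap = 1000,
    cluster_identity = 0.80, cluster_coverage = 0.80,
    min_len = 600, orf_min_aa_class1 = 300, orf_min_aa_class2 = 200,
    alpha = 0.01, flank = 4000, min_flank = 3000,
    shared_identity = 0.70, shared_coverage = 0.50,
    min_genes = 10, seed = 1
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(config))
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  utils::modifyList(config, overrides)
}

read_alignment_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.fa(sta)?$",
                           full.names = TRUE))
  alns <- lapply(files, read_fasta)
  names(alns) <- sub("\\.fa(sta)?$", "", basename(files))
  alns
}

#' Run the HTT detection pipeline on a study bundle
#'
#' Expects the directory layout written by [generate_study()]: `genes/`
#' and `tes/` with one codon-alignment FASTA per unit, `te_classes.tsv`
#' (family_id, te_class, te_group) and `rates.tsv`.  Stages: candidate
#' filters on TE families, per-pair gene regressions, the pairwise dS-CUB
#' test for every family, family-level event aggregation, molecular-clock
#' dating of significant pairs, and regression diagnostics.  A stage
#' failure aborts with the stage name.
#'
#' @param input_dir study bundle directory.
#' @param out_dir results directory (created if needed).
#' @param config configuration from [pipeline_config()].
#' @param taxon_pair_class rate-table class used to date events (default:
#'   first class in the bundle's rate table).
#' @return invisibly, a list with `calls`, `events`, `species_counts`,
#'   `edges`, `dating`, `diagnostics`, `rejected_families` and `manifest`.
#' @export
run_pipeline <- function(input_dir, out_dir, config = pipeline_config(),
                         taxon_pair_class = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  inputs <- character(0)
  track <- function(path) {
    inputs <<- c(inputs, path)
    path
  }

  rates_path <- file.path(input_dir, "rates.tsv")
  if (!file.exists(rates_path)) {
    stop("pipeline stage 'inputs' failed: missing rate table ", rates_path,
         call. = FALSE)
  }
  rates <- stage("inputs", read_rate_table(track(rates_path)))
  if (is.null(taxon_pair_class)) {
    taxon_pair_class <- rates$taxon_pair_class[1]
  }
  genes_dir <- file.path(input_dir, "genes")
  tes_dir <- file.path(input_dir, "tes")
  genes <- stage("inputs", read_alignment_dir(genes_dir))
  tes <- stage("inputs", read_alignment_dir(tes_dir))
  for (d in c(genes_dir, tes_dir)) {
    for (f in list.files(d, full.names = TRUE)) track(f)
  }
  if (length(genes) == 0) {
    stop("pipeline stage 'inputs' failed: no gene alignments",
         call. = FALSE)
  }
  classes_path <- file.path(input_dir, "te_classes.tsv")
  te_meta <- if (file.exists(classes_path)) {
    stage("inputs", utils::read.delim(track(classes_path),
                                      stringsAsFactors = FALSE))
  } else {
    data.frame(family_id = names(tes), te_class = "ClassI",
               te_group = "LTR", stringsAsFactors = FALSE)
  }

  # candidate filters
  fams <- lapply(names(tes), function(id) {
    cls <- te_meta$te_class[match(id, te_meta$family_id)]
    list(family_id = id,
         te_class = if (is.na(cls)) "ClassI" else cls,
         members = data.frame(species = names(tes[[id]]),
                              sequence = unname(tes[[id]]),
                              stringsAsFactors = FALSE))
  })
  filt <- stage("candidate_filters", filter_htt_candidates(
    fams, min_len = config$min_len,
    orf_min_aa = c(ClassI = config$orf_min_aa_class1,
                   ClassII = config$orf_min_aa_class2)))
  kept_ids <- vapply(filt$kept, `[[`, "", "family_id")

  gene_points <- stage("gene_regressions",
                       build_pair_points(genes, kind = "gene"))
  models <- stage("gene_regressions",
                  fit_pair_models(gene_points,
                                  min_genes = config$min_genes))

  matrices <- stage("htt_test", {
    out <- list()
    for (id in kept_ids) {
      out[[id]] <- htt_matrix(tes[[id]], models, family_id = id,
                              alpha = config$alpha)
    }
    out
  })
  calls <- do.call(rbind, c(lapply(matrices, `[[`, "calls"),
                            make.row.names = FALSE))
  if (is.null(calls)) {
    calls <- data.frame(family_id = character(0), species_a = character(0),
                        species_b = character(0), te_ds = numeric(0),
                        te_cub = numeric(0), expected_ds = numeric(0),
                        t_statistic = numeric(0), p_value = numeric(0),
                        significant = logical(0), reason = character(0))
  }

  groups <- stats::setNames(te_meta$te_group, te_meta$family_id)
  agg <- stage("event_calling", call_family_events(matrices, groups))

  sig <- calls[!is.na(calls$significant) & calls$significant, ,
               drop = FALSE]
  dating <- stage("dating", if (nrow(sig)) {
    d <- date_htt(sig$te_ds, taxon_pair_class, rates,
                  family_id = sig$family_id, species_a = sig$species_a,
                  species_b = sig$species_b)
    d$te_group <- unname(groups[d$family_id])
    d
  } else {
    data.frame(family_id = character(0), species_a = character(0),
               species_b = character(0), k = numeric(0),
               taxon_pair_class = character(0), r = numeric(0),
               T_my = numeric(0), te_group = character(0))
  })

  diagnostics <- stage("diagnostics", do.call(rbind, lapply(
    names(models), function(k) {
      d <- check_assumptions(models[[k]])
      data.frame(pair = k, n_genes = models[[k]]$n, ks_p = d$ks_p,
                 pearson_r = d$pearson_r, pearson_p = d$pearson_p,
                 flagged = d$flagged, stringsAsFactors = FALSE)
    })))

  tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    con <- file(path, open = "wb")
    on.exit(close(con))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
    path
  }
  tsv(calls, "htt_calls.tsv")
  tsv(agg$events, "htt_events.tsv")
  tsv(as.data.frame(agg$species_counts), "species_counts.tsv")
  tsv(agg$edges, "htt_edges.tsv")
  tsv(dating, "dating.tsv")
  tsv(diagnostics, "diagnostics.tsv")
  tsv(filt$rejected, "rejected_families.tsv")

  manifest <- list(
    package = "httscan",
    version = as.character(utils::packageVersion("httscan")),
    config = config,
    taxon_pair_class = taxon_pair_class,
    input_dir = normalizePath(input_dir),
    input_checksums = as.list(tools::md5sum(sort(unique(inputs)))),
    n_gene_alignments = length(genes),
    n_te_families = length(tes),
    n_families_kept = length(kept_ids)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(calls = calls, events = agg$events,
                 species_counts = agg$species_counts, edges = agg$edges,
                 dating = dating, diagnostics = diagnostics,
                 rejected_families = filt$rejected, manifest = manifest))
}
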