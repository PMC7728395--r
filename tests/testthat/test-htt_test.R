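# The dS-CUB regression test: fitting, the prediction-residual p-value,
# matrices, event aggregation, diagnostics.

gauss_points <- function(n = 50, slope = 0.002, intercept = -0.02,
                         sd = 0.01) {
  cub <- runif(n, 25, 60)
  data.frame(unit_id = paste0("g", seq_len(n)),
             ds = intercept + slope * cub + rnorm(n, 0, sd), cub = cub)
}

test_that("an exact linear relation is recovered with zero residual sd", {
  pts <- data.frame(ds = 0.002 * c(30, 40, 50, 55, 60, 35, 45, 52, 38,
                                   58) - 0.02,
                    cub = c(30, 40, 50, 55, 60, 35, 45, 52, 38, 58))
  m <- fit_gene_regression(pts, min_genes = 10)
  expect_equal(m$slope, 0.002, tolerance = 1e-12)
  expect_equal(m$intercept, -0.02, tolerance = 1e-12)
  expect_equal(m$residual_sd, 0, tolerance = 1e-10)
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_gene_regression(data.frame(ds = c(1, 2),
                                              cub = c(30, 40)),
                                   min_genes = 2), "at least")
  same_x <- data.frame(ds = rnorm(12), cub = rep(40, 12))
  expect_error(fit_gene_regression(same_x), "zero CUB variance")
})

test_that("OLS estimates match the closed-form normal equations", {
  set.seed(12)
  for (i in 1:8) {
    pts <- gauss_points()
    m <- fit_gene_regression(pts)
    X <- cbind(1, pts$cub)
    beta <- solve(t(X) %*% X, t(X) %*% pts$ds)
    expect_equal(m$intercept, beta[1], tolerance = 1e-10)
    expect_equal(m$slope, beta[2], tolerance = 1e-10)
    res <- pts$ds - X %*% beta
    expect_equal(m$residual_sd, sqrt(sum(res^2) / (nrow(pts) - 2)),
                 tolerance = 1e-10)
  }
})

test_that("the one-tailed p-value behaves as a lower-tail test", {
  set.seed(13)
  pts <- gauss_points()
  m <- fit_gene_regression(pts, species_a = "A", species_b = "B")
  # a TE exactly on the line sits at the median
  on_line <- m$intercept + m$slope * 45
  expect_equal(te_ht_pvalue(m, on_line, 45)$p_value, 0.5)
  # large negative deviations approach the normal lower tail
  pts_big <- gauss_points(n = 2000)
  mb <- fit_gene_regression(pts_big)
  se <- mb$residual_sd
  p3 <- te_ht_pvalue(mb, mb$intercept + mb$slope * 45 - 3 * se, 45)$p_value
  expect_equal(p3, pnorm(-3), tolerance = 0.002)
  p2 <- te_ht_pvalue(mb, mb$intercept + mb$slope * 45 + 2 * se, 45)$p_value
  expect_equal(p2, pnorm(2), tolerance = 0.002)
  expect_false(te_ht_pvalue(mb, mb$intercept + mb$slope * 45 + 2 * se,
                            45)$significant)
  # saturated dS suppresses the call
  sup <- te_ht_pvalue(m, NA_real_, 45)
  expect_true(is.na(sup$p_value))
  expect_equal(sup$reason, "saturated dS")
})

test_that("lowering the TE dS never increases the p-value", {
  set.seed(14)
  m <- fit_gene_regression(gauss_points(), species_a = "A",
                           species_b = "B")
  ds_grid <- seq(0.1, 0, length.out = 30)
  p <- vapply(ds_grid, function(d) te_ht_pvalue(m, d, 45)$p_value,
              numeric(1))
  expect_true(all(diff(p) <= 1e-14))
})

test_that("p-values are exactly uniform under a Gaussian-residual null", {
  # model-level null: the new observation is drawn from the same Gaussian
  # regression process as the reference genes, so the studentized
  # prediction residual is exactly t-distributed
  set.seed(15)
  pvals <- replicate(1500, {
    pts <- gauss_points(n = 30, sd = 0.02)
    m <- fit_gene_regression(pts)
    x0 <- runif(1, 25, 60)
    y0 <- -0.02 + 0.002 * x0 + rnorm(1, 0, 0.02)
    te_ht_pvalue(m, y0, x0)$p_value
  })
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.015)
})

test_that("htt_matrix fills one symmetric cell per species pair", {
  set.seed(16)
  species <- c("A", "B", "C")
  models <- list()
  for (i in 1:2) for (j in (i + 1):3) {
    pts <- gauss_points()
    models[[paste(species[i], species[j], sep = "|")]] <-
      fit_gene_regression(pts, species_a = species[i],
                          species_b = species[j])
  }
  # related sequences (a few synonymous-ish mutations) so dS is defined
  base <- paste(random_codon(200), collapse = "")
  aln <- stats::setNames(
    c(base, mutate_at(base, c(33, 90, 150)),
      mutate_at(base, c(60, 210, 399))), species)
  res <- htt_matrix(aln, models, family_id = "fam")
  expect_true(isSymmetric(res$p))
  expect_equal(sum(!is.na(res$p[upper.tri(res$p)])), 3)
  expect_equal(nrow(res$calls), 3)
  # a pair without a model stays NA
  res2 <- htt_matrix(aln, models[1], family_id = "fam")
  expect_equal(sum(is.na(res2$p[upper.tri(res2$p)])), 2)
})

test_that("family events aggregate to one event per family", {
  mk <- function(species, sig_pairs) {
    p <- matrix(0.5, length(species), length(species),
                dimnames = list(species, species))
    for (pr in sig_pairs) p[pr[1], pr[2]] <- p[pr[2], pr[1]] <- 0.001
    list(p = p, significant = !is.na(p) & p < 0.01, calls = NULL)
  }
  res <- call_family_events(
    list(f1 = mk(c("A", "B"), list(c("A", "B"))),
         f2 = mk(c("A", "B", "C"), list(c("A", "B"), c("A", "C"))),
         f3 = mk(c("A", "B"), list())),
    family_groups = c(f1 = "LTR", f2 = "ClassII", f3 = "LTR"))
  expect_equal(nrow(res$events), 2)            # f3 has no significant pair
  expect_equal(res$events$n_significant_pairs[res$events$family_id == "f2"],
               2L)                             # still a single family event
  expect_equal(unname(res$species_counts["A", "Total"]), 2L)
  expect_equal(unname(res$species_counts["C", "ClassII"]), 1L)
  expect_equal(res$edges$n_families[res$edges$species_a == "A" &
                                    res$edges$species_b == "B"], 2L)
  empty <- call_family_events(list(f3 = mk(c("A", "B"), list())))
  expect_equal(nrow(empty$events), 0)
  expect_equal(nrow(empty$edges), 0)
})

test_that("assumption diagnostics flag what they should", {
  set.seed(17)
  good <- fit_gene_regression(gauss_points(n = 60))
  dg <- check_assumptions(good)
  expect_gt(dg$ks_p, 0.01)
  expect_true(dg$linear_ok)

  # heavy-tailed residuals get flagged more often than Gaussian ones
  flags <- function(rgen, reps = 60) {
    mean(replicate(reps, {
      cub <- runif(40, 25, 60)
      pts <- data.frame(ds = 0.002 * cub + rgen(40) * 0.01, cub = cub)
      isTRUE(!check_assumptions(fit_gene_regression(pts))$normal_ok)
    }))
  }
  f_gauss <- flags(rnorm)
  f_heavy <- flags(function(n) rt(n, df = 1))
  expect_gt(f_heavy, f_gauss)

  # exact fit reports degeneracy instead of a test
  cub <- seq(25, 60, length.out = 20)
  exact <- fit_gene_regression(data.frame(ds = 0.002 * cub, cub = cub))
  expect_true(check_assumptions(exact)$degenerate)
})
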