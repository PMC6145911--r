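# one plate of NT + library wells with chosen alp values
stats_wells <- function(alp, cells = rep(4000, length(alp)),
                        roles = c(rep("non_targeting", 2),
                                  rep("library", length(alp) - 2))) {
  genes <- ifelse(roles == "library",
                  sprintf("g%02d", seq_along(alp)), "")
  well_row("p1", format_well(1, seq_along(alp)), roles, genes, cells, alp)
}

test_that("percent-of-control normalization hits the published boundaries", {
  w <- stats_wells(alp = c(2.0, 2.0, 3.2, 0.8, 2.0))
  norm <- normalize_to_nt(w)
  expect_equal(norm$pct_alp[norm$gene_symbol == "g03"], 160)  # suppressor bound
  expect_equal(norm$pct_alp[norm$gene_symbol == "g04"], 40)   # activator bound
  expect_equal(norm$pct_alp[norm$gene_symbol == "g05"], 100)
  # NT wells average to exactly 100 on every plate
  expect_equal(mean(norm$pct_alp[norm$role == "non_targeting"]), 100)
  expect_equal(mean(norm$pct_cell_number[norm$role == "non_targeting"]), 100)
})

test_that("normalization fails without usable Non-Targeting wells", {
  w <- stats_wells(alp = c(1, 2, 3))
  w$role <- c("library", "library", "library")
  w$gene_symbol <- c("a", "b", "c")
  expect_error(suppressWarnings(normalize_to_nt(w)), "no non_targeting")
  w0 <- stats_wells(alp = c(0, 0, 3))
  expect_error(normalize_to_nt(w0), "zero or undefined")
})

test_that("zero ALP wells get a flagged pseudocount before the log", {
  w <- stats_wells(alp = c(2, 2, 0, 1))
  norm <- normalize_to_nt(w)
  zero_row <- norm[norm$gene_symbol == "g03", ]
  expect_true(zero_row$log2_pseudocount)
  expect_equal(zero_row$log2_alp, log2(0.5))  # half the smallest positive (1)
})

test_that("z-scores standardize log2 ALP within the plate", {
  # log2 values {0, 1, 2}: z must be {-1, 0, 1} with sample sd
  w <- stats_wells(alp = c(1, 2, 4), roles = c("non_targeting", "library",
                                               "library"))
  z <- zscore_log2(normalize_to_nt(w))
  expect_equal(z$z_alp, c(-1, 0, 1))
  expect_equal(z$z_nt, rep(-1, 3))

  # mean 0, sd 1 within 1e-9
  w2 <- stats_wells(alp = c(2, 2.3, 3.2, 0.8, 1.7, 4.1))
  z2 <- zscore_log2(normalize_to_nt(w2))
  expect_lt(abs(mean(z2$z_alp)), 1e-9)
  expect_lt(abs(stats::sd(z2$z_alp) - 1), 1e-9)

  # location invariance: scaling ALP by a constant shifts log2, not z
  w3 <- w2
  w3$alp_per_cell <- w3$alp_per_cell * 8
  z3 <- zscore_log2(normalize_to_nt(w3))
  expect_equal(z3$z_alp, z2$z_alp)

  # all equal: zero variance is an error naming the plate
  w4 <- stats_wells(alp = rep(2, 4))
  expect_error(zscore_log2(normalize_to_nt(w4)), "p1")
})

test_that("the replicate t-test matches the textbook pooled formula", {
  g <- c(0.9, 1.0, 1.1)
  nt <- c(-0.1, 0.0, 0.1)
  # closed-form pooled-variance two-tailed t-test
  sp2 <- (2 * stats::var(g) + 2 * stats::var(nt)) / 4
  tstat <- (mean(g) - mean(nt)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_expected <- 2 * stats::pt(-abs(tstat), df = 4)
  expect_equal(test_vs_nt(g, nt), p_expected, tolerance = 1e-12)
  # symmetry and the identical-group case
  expect_equal(test_vs_nt(nt, g), test_vs_nt(g, nt))
  expect_equal(test_vs_nt(c(1, 1), c(1, 1)), 1)
  expect_warning(p0 <- test_vs_nt(c(1, 1), c(2, 2)), "limit 0")
  expect_equal(p0, 0)
})

test_that("hit calling reproduces the published archetypes", {
  results <- tibble::tibble(
    gene_symbol = c("H2-Ob", "Hgfac", "Kif11like", "Null"),
    mean_pct_cell_number = c(95, 90, 25, 100),
    mean_pct_alp = c(231.79, 12.52, 300, 100),
    mean_z_alp = c(2.5, -2.5, 3, 0),
    p_value = c(0.01, 1e-4, 1e-4, 0.9),
    n_replicates = 3L,
    z_nt = 0
  )
  hits <- call_hits(results)
  expect_equal(hits$category,
               c("suppressor", "activator", "excluded_viability", "not_hit"))
  # flags are consistent with the categories
  expect_true(all(hits$passed_viability[hits$category == "suppressor"]))
  expect_false(hits$passed_viability[3])
})

test_that("hit categories are exclusive, exhaustive and monotone in ALP", {
  set.seed(8)
  results <- tibble::tibble(
    gene_symbol = sprintf("g%03d", 1:200),
    mean_pct_cell_number = stats::runif(200, 10, 150),
    mean_pct_alp = stats::runif(200, 5, 300),
    mean_z_alp = stats::rnorm(200, 0, 2),
    p_value = stats::runif(200),
    n_replicates = 3L,
    z_nt = 0.3
  )
  hits <- call_hits(results)
  expect_true(all(hits$category %in% c("suppressor", "activator",
                                       "excluded_viability", "not_hit")))
  expect_equal(nrow(hits), 200)
  # raising pct_alp (all else fixed) never turns a suppressor into an activator
  bumped <- call_hits(dplyr::mutate(results, mean_pct_alp = mean_pct_alp + 50))
  expect_false(any(hits$category == "suppressor" &
                     bumped$category == "activator"))
  # the z criterion is centred on the Non-Targeting mean z
  strong <- results[1, ]
  strong$mean_pct_alp <- 200; strong$p_value <- 0.001
  strong$mean_pct_cell_number <- 100
  strong$mean_z_alp <- 1.1  # above 0 + 1 but below z_nt + 1 = 1.3
  expect_equal(call_hits(strong)$category, "not_hit")
  strong$mean_z_alp <- 1.4
  expect_equal(call_hits(strong)$category, "suppressor")
})

test_that("classify_table applies the ALP and p criteria to printed rows", {
  empty <- tibble::tibble(gene_symbol = character(0), pct_alp = numeric(0),
                          p_bound = numeric(0))
  expect_true(all(classify_table(empty)$counts$n == 0))

  rows <- tibble::tibble(
    gene_symbol = c("up", "down", "mid", "weak_p"),
    pct_alp = c(160, 40, 100, 200),
    p_bound = c(0.05, 0.001, 0.001, 0.2)
  )
  ct <- classify_table(rows)
  expect_equal(ct$rows$category, c("suppressor", "activator",
                                   "not_hit", "not_hit"))
})

test_that("a simulated 320-gene triplicate screen recovers planted hits", {
  genes <- sprintf("g%03d", 1:320)
  lay <- default_screen_layout(genes)
  set.seed(99)
  supp <- sample(genes, 5)
  act <- sample(setdiff(genes, supp), 60)
  eff <- dplyr::bind_rows(
    gene_effects(genes, alp_fold = ifelse(genes %in% supp, 2.0,
                                          ifelse(genes %in% act, 0.3, 1.0))),
    gene_effects(c("Alpl", "Il11", "Sp7", "Runx2"), alp_fold = 0.3)
  )
  scr <- simulate_and_analyze(lay, eff,
                              simulation_config(noise_cv = 0.10, seed = 7))
  h <- dplyr::filter(tidy(scr), role == "library")
  planted <- h$gene_symbol %in% c(supp, act)
  called <- h$category %in% c("suppressor", "activator")
  expect_gte(mean(called[planted]), 0.90)
  expect_lte(mean(called[!planted]), 0.05)
  # direction is recovered too
  expect_true(all(h$category[h$gene_symbol %in% supp] != "activator"))
  expect_true(all(h$category[h$gene_symbol %in% act] != "suppressor"))
})
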