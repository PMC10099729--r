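test_that("gene model simulation is deterministic and round-trips", {
  cfg <- sim_config(n_genes = 20L)
  m1 <- simulate_gene_models(cfg, 3L)
  m2 <- simulate_gene_models(cfg, 3L)
  expect_identical(m1$transcripts, m2$transcripts)
  expect_identical(m1$truth, m2$truth)
  expect_true(all(m1$truth$type_realized))

  gtf <- tempfile(fileext = ".gtf")
  gtf2 <- tempfile(fileext = ".gtf")
  write_gtf(m1$transcripts, gtf)
  write_gtf(simulate_gene_models(cfg, 3L)$transcripts, gtf2)
  expect_identical(readLines(gtf), readLines(gtf2))
  unlink(c(gtf, gtf2))
})

test_that("a cassette-only config produces skip/include transcript pairs", {
  cfg <- sim_config(n_genes = 3L, event_mix = c(CE = 1), ce_with_aa = 0)
  m <- simulate_gene_models(cfg, 11L)
  for (gid in names(m$graphs)) {
    p <- m$graphs[[gid]]$transcript_paths
    expect_equal(length(p), 2L)
    # the two isoforms differ by exactly one internal node
    expect_equal(length(setdiff(p[[1L]], p[[2L]])), 1L)
  }
})

test_that("infeasible mixes are rejected", {
  expect_error(sim_config(transcripts_per_gene = c(1L, 1L)),
               "at least 2 transcripts")
  expect_error(sim_config(event_mix = c(CE = -1)), "non-negative")
})

test_that("Dirichlet concentration controls entropy as designed", {
  # near-zero concentration: one-hot abundances, entropy near 0
  low <- simulate_path_abundances(4L, 0.001, seed = 2L, n = 200L)
  expect_lt(mean(apply(low, 1L, splicentropy::splicing_entropy)), 0.05)
  # symmetric Dirichlet(10) on 4 paths: mean entropy close to 2 bits
  high <- simulate_path_abundances(4L, 10, seed = 3L, n = 2000L)
  ents <- apply(high, 1L, splicentropy::splicing_entropy)
  expect_gt(mean(ents), 1.85)
  expect_lt(mean(ents), 2.0)
})

test_that("the two-regime schedule yields a bimodal entropy profile", {
  cfg <- sim_config()
  set.seed(10)
  regime <- runif(3000) < cfg$high_frac
  ab <- rbind(
    simulate_path_abundances(4L, cfg$conc_low, seed = 4L,
                             n = sum(!regime)),
    simulate_path_abundances(4L, cfg$conc_high, seed = 5L, n = sum(regime)))
  ents <- apply(ab, 1L, splicing_entropy)
  # mass at both ends, sparse in the middle trough
  expect_gt(mean(ents < 0.5), 0.2)
  expect_gt(mean(ents > 1.5), 0.2)
  expect_lt(mean(ents >= 0.9 & ents <= 1.1), 0.15)
})

test_that("edge-count simulation conserves depth and seeds", {
  g <- cassette_graph()
  ev <- enumerate_event_paths(g, 2L)
  ab <- c(0.6, 0.4)
  cnt <- simulate_edge_counts(ev, ab, 1000L, seed = 6L)
  expect_equal(sum(cnt), 1000)
  expect_identical(cnt, simulate_edge_counts(ev, ab, 1000L, seed = 6L))
  expect_true(all(simulate_edge_counts(ev, ab, 0L, seed = 6L) == 0))
})

test_that("evolutionary histories respect flip probabilities", {
  tr <- species_tree7()
  frozen <- simulate_evolutionary_history(tr, gain_prob = 0, loss_prob = 0,
                                          root_state = "C", seed = 1L)
  expect_true(all(frozen$states == "C"))
  expect_equal(frozen$n_flips, 0L)

  # constrained histories have at most one flip, and the recorded flip
  # reproduces the leaf pattern
  for (i in 1:30) {
    h <- simulate_evolutionary_history(tr, gain_prob = 0.2, loss_prob = 0.1,
                                       constrain_single_change = TRUE,
                                       seed = i)
    expect_lte(h$n_flips, 1L)
    if (h$n_flips == 1L) {
      f <- h$flips[[1L]]
      expected <- setNames(ifelse(tr$tip.label %in% f$clade, "A", "C"),
                           tr$tip.label)
      expect_identical(h$states, expected)
    }
  }
})

test_that("unconstrained histories label complex iff no clade pattern", {
  tr <- species_tree7()
  n_complex_label <- 0L
  n_complex_oracle <- 0L
  for (i in 1:200) {
    h <- simulate_evolutionary_history(tr, gain_prob = 0.25, loss_prob = 0.2,
                                       seed = 5000L + i)
    lab <- assign_splicing_age(h$states, tr)$label
    oracle <- oracle_single_change(h$states, tr)
    is_complex <- !oracle$uniform && length(oracle$scenarios) == 0L
    n_complex_label <- n_complex_label + (lab == "complex")
    n_complex_oracle <- n_complex_oracle + is_complex
    expect_equal(lab == "complex", is_complex, info = i)
  }
  expect_equal(n_complex_label, n_complex_oracle)
  expect_gt(n_complex_oracle, 0L)
})

test_that("stage-series truths are self-consistent", {
  s <- simulate_stage_series("e", "dev_dynamic", seed = 9L)
  # entropy recomputable from stored true abundances
  expect_equal(s$series$entropy,
               apply(s$truth$abundances, 1L, splicing_entropy))
  # PSI equals the node-containing half of the abundance mass
  expect_equal(s$series$psi, rowSums(s$truth$abundances[, 1:2]))
  expect_true(s$truth$true_dev)
  expect_true(s$truth$true_dynamic)

  s0 <- simulate_stage_series("e", "null", amplitude = 0, seed = 9L)
  expect_false(s0$truth$true_dev)
  expect_equal(diff(range(s0$series$psi)), 0)
  expect_error(simulate_stage_series("e", "null", n_stages = 4L), "6 stages")
})
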