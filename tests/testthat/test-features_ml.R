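# toy locus with a hand-checkable genome: one gene, three exons
toy_feature_gene <- function(strand = "+") {
  cfg <- sim_config(n_genes = 1L, event_mix = c(CE = 1), ce_with_aa = 0)
  m <- simulate_gene_models(cfg, 77L)
  m
}

test_that("PWM scoring matches direct per-position summation", {
  pwm <- matrix(c(0.7, 0.1, 0.1, 0.1,
                  0.1, 0.7, 0.1, 0.1,
                  0.25, 0.25, 0.25, 0.25), nrow = 4L,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  pwms <- list(donor = pwm, acceptor = pwm)
  # direct summation oracle
  expect_equal(splice_site_strength("ACA", "donor", pwms),
               log2(0.7 / 0.25) + log2(0.7 / 0.25) + log2(0.25 / 0.25))
  # consensus achieves the maximal score
  cons <- paste(rownames(pwm)[apply(pwm, 2L, which.max)], collapse = "")
  scores <- vapply(c("AAA", "CCC", "GGG", "TTT", cons), splice_site_strength,
                   numeric(1L), kind = "donor", pwms = pwms)
  expect_equal(names(which.max(scores)), cons)
  # all-N window scores zero
  expect_equal(splice_site_strength("NNN", "donor", pwms), 0)
  expect_true(is.na(splice_site_strength("AC", "donor", pwms)))
})

test_that("trained PWMs recognise the planted splice motifs", {
  cfg <- sim_config(n_genes = 8L)
  m <- simulate_gene_models(cfg, 5L)
  genome <- simulate_genome(m$transcripts, 6L)
  pwms <- train_splice_pwm(m$transcripts, genome)
  expect_equal(dim(pwms$donor), c(4L, 9L))
  expect_equal(dim(pwms$acceptor), c(4L, 23L))
  # planted GT at intron positions 4-5 of the donor window
  expect_gt(pwms$donor["G", 4L], 0.8)
  expect_gt(pwms$donor["T", 5L], 0.8)
  # planted AG at acceptor window positions 19-20
  expect_gt(pwms$acceptor["A", 19L], 0.8)
  expect_gt(pwms$acceptor["G", 20L], 0.8)
})

test_that("exon features are deterministic and hand-checkable", {
  m <- toy_feature_gene()
  g <- m$graphs[[1L]]
  genome <- simulate_genome(m$transcripts, 3L)
  pwms <- train_splice_pwm(m$transcripts, genome)
  node <- m$truth$event_node[1L]
  fv <- extract_exon_features(g, genome, node, pwms)
  # lengths agree with the node table
  expect_equal(unname(fv["target_len"]),
               g$nodes$end[node] - g$nodes$start[node])
  expect_true(all(fv[c("upstream_intron_len", "downstream_intron_len")] > 0))
  expect_true(all(fv[grep("_gc$", names(fv))] >= 0 &
                    fv[grep("_gc$", names(fv))] <= 1))
  # GC of the target exon recomputed by hand from the genome string
  chrom <- g$chrom
  s <- substr(as.character(genome[[chrom]]), g$nodes$start[node] + 1L,
              g$nodes$end[node])
  gc <- mean(strsplit(s, "")[[1L]] %in% c("G", "C"))
  expect_equal(unname(fv["target_gc"]), gc)
  expect_identical(fv, extract_exon_features(g, genome, node, pwms))
})

test_that("feature extraction is strand symmetric", {
  cfg <- sim_config(n_genes = 1L, event_mix = c(CE = 1), ce_with_aa = 0)
  m <- simulate_gene_models(cfg, 77L)
  tx <- m$transcripts
  g <- m$graphs[[1L]]
  genome <- simulate_genome(tx, 3L)
  node <- m$truth$event_node[1L]

  # mirrored locus: reverse-complement the chromosome and flip coordinates
  chrom <- tx$chrom[1L]
  L <- Biostrings::width(genome[chrom])
  rc <- Biostrings::reverseComplement(genome[[chrom]])
  genome_rc <- Biostrings::DNAStringSet(setNames(as.character(rc), chrom))
  tx_rc <- tx
  tx_rc$start <- L - tx$end
  tx_rc$end <- L - tx$start
  tx_rc$strand <- if (tx$strand[1L] == "+") "-" else "+"
  tx_rc <- transcript_models(tx_rc)
  g_rc <- build_splice_graph(tx_rc)
  expect_equal(g$nodes$node_type, g_rc$nodes$node_type)

  pwms <- train_splice_pwm(tx, genome)
  pwms_rc <- train_splice_pwm(tx_rc, genome_rc)
  expect_equal(pwms$donor, pwms_rc$donor, tolerance = 1e-12)

  fv <- extract_exon_features(g, genome, node, pwms)
  fv_rc <- extract_exon_features(g_rc, genome_rc, node, pwms_rc)
  expect_equal(fv, fv_rc, tolerance = 1e-12)
})

test_that("terminal exons are rejected for feature extraction", {
  m <- toy_feature_gene()
  g <- m$graphs[[1L]]
  genome <- simulate_genome(m$transcripts, 3L)
  pwms <- train_splice_pwm(m$transcripts, genome)
  expect_error(extract_exon_features(g, genome, 1L, pwms), "terminal")
})

test_that("a noiseless linear signal is recovered almost perfectly", {
  set.seed(4)
  x <- matrix(rnorm(300 * 4L), ncol = 4L,
              dimnames = list(NULL, paste0("f", 1:4)))
  y <- 2 * x[, 2L] + 1
  rep <- train_entropy_regressor(x, y, "linear", seed = 1L)
  expect_gte(rep$pcc, 0.999)
  expect_gte(rep$r2, 0.99)
  expect_equal(names(rep$importance)[1L], "f2")
})

test_that("permuted targets give near-zero held-out correlation", {
  set.seed(8)
  x <- matrix(rnorm(1000 * 5L), ncol = 5L,
              dimnames = list(NULL, paste0("f", 1:5)))
  y <- x %*% runif(5L) + rnorm(1000, 0, 0.1)
  pccs <- vapply(1:10, function(k) {
    train_entropy_regressor(x, sample(y), "linear", seed = k)$pcc
  }, numeric(1L))
  # the null distribution is centred on zero: its mean magnitude stays
  # below 0.1 and no single permutation strays far
  expect_lt(mean(abs(pccs)), 0.1)
  expect_lt(max(abs(pccs)), 0.2)
})

test_that("generative features rank at the top of importance", {
  cfg <- sim_config(n_genes = 80L, event_mix = c(CE = 1), ce_with_aa = 0)
  m <- simulate_gene_models(cfg, 19L)
  genome <- simulate_genome(m$transcripts, 20L)
  pwms <- train_splice_pwm(m$transcripts, genome)
  feats <- list()
  for (r in seq_len(nrow(m$truth))) {
    fv <- tryCatch(extract_exon_features(m$graphs[[m$truth$gene_id[r]]],
                                         genome, m$truth$event_node[r], pwms),
                   error = function(e) NULL)
    if (!is.null(fv)) feats[[m$truth$gene_id[r]]] <- fv
  }
  x <- do.call(rbind, feats)
  set.seed(30)
  y <- 0.4 * scale(x[, "upstream_exon_len"])[, 1L] +
    0.4 * scale(x[, "donor_strength"])[, 1L] + rnorm(nrow(x), 0, 0.15) + 1
  rep <- train_entropy_regressor(x, y, "linear", seed = 2L)
  top3 <- names(rep$importance)[1:3]
  expect_true(all(c("upstream_exon_len", "donor_strength") %in% top3))
  # a feature unrelated to the target never outranks the generative ones
  expect_lt(rep$importance[["exon_rank"]],
            min(rep$importance[c("upstream_exon_len", "donor_strength")]))
})

test_that("constant targets yield a flagged undefined report", {
  x <- matrix(rnorm(200), ncol = 2L, dimnames = list(NULL, c("a", "b")))
  rep <- train_entropy_regressor(x, rep(1, 100L), "linear")
  expect_true(rep$undefined)
  expect_true(is.na(rep$pcc))
})

test_that("gbt family runs and reports plausible metrics", {
  set.seed(14)
  x <- matrix(rnorm(400 * 3L), ncol = 3L,
              dimnames = list(NULL, c("a", "b", "c")))
  y <- sin(x[, 1L]) + 0.5 * x[, 2L]^2 + rnorm(400, 0, 0.1)
  rep <- train_entropy_regressor(x, y, "gbt", seed = 3L)
  expect_gt(rep$pcc, 0.8)
  rep2 <- train_entropy_regressor(x, y, "gbt", seed = 3L)
  expect_equal(rep$pcc, rep2$pcc)
})
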