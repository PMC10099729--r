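test_that("cassette exon collapses to three nodes with a skip path", {
  g <- cassette_graph()
  expect_equal(nrow(g$nodes), 3L)
  expect_equal(g$nodes$start, c(0, 200, 400))
  expect_equal(g$transcript_paths$T1, c(1L, 2L, 3L))
  expect_equal(g$transcript_paths$T2, c(1L, 3L))
  # node 2 is only on T1's path
  expect_true(2L %in% g$transcript_paths$T1)
  expect_false(2L %in% g$transcript_paths$T2)
})

test_that("overlapping exon boundaries force a node split joined by adjacency", {
  tx <- transcript_models(data.frame(
    gene_id = "g", transcript_id = c("T1", "T2", "T2"), chrom = "c",
    strand = "+", start = c(0, 0, 300), end = c(100, 150, 400)))
  g <- build_splice_graph(tx)
  expect_equal(g$nodes$start[1:2], c(0, 100))
  expect_equal(g$nodes$end[1:2], c(100, 150))
  expect_equal(g$transcript_paths$T2[1:2], c(1L, 2L))
  expect_true(any(g$edges$from == 1L & g$edges$to == 2L &
                    g$edges$kind == "adjacency"))
})

test_that("node set equals the brute-force boundary partition", {
  for (seed in 1:10) {
    tx <- random_transcript_set(seed)
    g <- build_splice_graph(tx)
    oracle <- oracle_partition(tx)
    got <- g$nodes[order(g$nodes$start), c("start", "end")]
    expect_equal(unname(as.matrix(got)), unname(as.matrix(oracle)),
                 info = paste("seed", seed))
    # partition property: union of nodes equals union of exons, no overlap
    expect_true(all(got$start[-1L] >= got$end[-nrow(got)]))
    expect_equal(sum(got$end - got$start),
                 sum(oracle$end - oracle$start))
  }
})

test_that("each transcript exon is an exact concatenation of nodes", {
  for (seed in 11:15) {
    tx <- random_transcript_set(seed)
    g <- build_splice_graph(tx)
    for (tid in unique(tx$transcript_id)) {
      ex <- tx[tx$transcript_id == tid, ]
      covered <- sum(g$nodes$end[g$transcript_paths[[tid]]] -
                       g$nodes$start[g$transcript_paths[[tid]]])
      expect_equal(covered, sum(ex$end - ex$start))
    }
  }
})

test_that("graphs are invariant to transcript input order", {
  tx <- cassette_aa_transcripts()
  g1 <- build_splice_graph(tx)
  g2 <- build_splice_graph(tx[rev(seq_len(nrow(tx))), ])
  expect_equal(g1$nodes, g2$nodes)
  expect_equal(g1$edges, g2$edges)
  expect_equal(g1$transcript_paths[sort(names(g1$transcript_paths))],
               g2$transcript_paths[sort(names(g2$transcript_paths))])
})

test_that("mixed strands and zero-length exons are rejected", {
  bad <- data.frame(gene_id = "g", transcript_id = c("a", "b"), chrom = "c",
                    strand = c("+", "-"), start = c(0, 0), end = c(10, 10))
  expect_error(build_splice_graph(bad), "strand")
  expect_error(transcript_models(
    data.frame(gene_id = "g", transcript_id = "a", chrom = "c", strand = "+",
               start = 5, end = 5)), "length")
})

test_that("node typing covers the event templates", {
  g <- cassette_graph()
  expect_equal(classify_node_type(g, 2L), "CE")

  # retained intron: T1 splices the intron out, T2 keeps it
  ri <- build_splice_graph(transcript_models(data.frame(
    gene_id = "g", transcript_id = rep(c("T1", "T2"), c(2L, 1L)),
    chrom = "c", strand = "+", start = c(0, 200, 0), end = c(100, 300, 300))))
  expect_equal(ri$nodes$node_type[2L], "RI")

  # alternative first exon: distinct first nodes joined by junctions
  af <- build_splice_graph(transcript_models(data.frame(
    gene_id = "g", transcript_id = rep(c("T1", "T2"), each = 2L),
    chrom = "c", strand = "+",
    start = c(0, 400, 200, 400), end = c(100, 500, 300, 500))))
  expect_setequal(af$nodes$node_type[1:2], c("AF", "AF"))

  # simulator round trip realises every requested type
  cfg <- sim_config(n_genes = 60L)
  m <- simulate_gene_models(cfg, 42L)
  expect_true(all(m$truth$type_realized))
  expect_setequal(unique(m$truth$type_requested),
                  names(cfg$event_mix))
})

test_that("minus-strand graphs mirror plus-strand structure", {
  gp <- cassette_graph("+")
  gm <- cassette_graph("-")
  expect_equal(nrow(gm$nodes), 3L)
  # transcription order reverses genomic order
  expect_equal(gm$nodes$start, c(400, 200, 0))
  expect_equal(gm$transcript_paths$T1, c(1L, 2L, 3L))
  expect_equal(gm$transcript_paths$T2, c(1L, 3L))
  expect_equal(gp$nodes$node_type, gm$nodes$node_type)
})

test_that("event enumeration matches the subset-enumeration oracle", {
  g <- cassette_graph()
  ev <- enumerate_event_paths(g, 2L)
  expect_equal(length(ev$paths), 2L)
  expect_equal(sum(ev$contains_node), 1L)
  expect_equal(ev$paths, oracle_paths(g, 1L, 3L))

  g3 <- build_splice_graph(cassette_aa_transcripts())
  node <- which(g3$nodes$node_type == "CE" & g3$nodes$start == 200)
  ev3 <- enumerate_event_paths(g3, node)
  expect_equal(ev3$paths, oracle_paths(g3, ev3$anchors[1L], ev3$anchors[2L]))
  expect_equal(length(ev3$paths), 3L)

  # path closure: each transcript's local restriction is an enumerated path
  for (p in g3$transcript_paths) {
    local <- p[p >= ev3$anchors[1L] & p <= ev3$anchors[2L]]
    expect_true(any(vapply(ev3$paths, identical, logical(1L), local)))
  }
})

test_that("single-transcript and single-node genes yield one-path events", {
  tx <- transcript_models(data.frame(
    gene_id = "g", transcript_id = "T1", chrom = "c", strand = "+",
    start = c(0, 200), end = c(100, 300)))
  g <- build_splice_graph(tx)
  ev <- enumerate_event_paths(g, 1L)
  expect_equal(length(ev$paths), 1L)
  expect_true(ev$contains_node[1L])

  mono <- build_splice_graph(transcript_models(data.frame(
    gene_id = "g", transcript_id = "T1", chrom = "c", strand = "+",
    start = 0, end = 100)))
  ev1 <- enumerate_event_paths(mono, 1L)
  expect_equal(ev1$paths, list(1L))
})

test_that("path truncation flags combinatorial events", {
  # two linked cassettes between one anchor pair -> 4 local combinations
  ex <- data.frame(start = seq(0, 600, by = 200),
                   end = seq(0, 600, by = 200) + 100)
  mk <- function(tid, drop) data.frame(gene_id = "g", transcript_id = tid,
                                       chrom = "c", strand = "+",
                                       start = ex$start[setdiff(1:4, drop)],
                                       end = ex$end[setdiff(1:4, drop)])
  g <- build_splice_graph(transcript_models(rbind(
    mk("T0", NULL), mk("TA", 2L), mk("TB", 3L), mk("TC", c(2L, 3L)))))
  ev <- enumerate_event_paths(g, 2L, max_paths = 3L)
  expect_true(ev$truncated)
  expect_error(estimate_path_abundances(ev, c("1-2" = 5)), "truncated")
})

test_that("GTF round trip preserves transcript models", {
  tx <- cassette_aa_transcripts()
  gtf <- tempfile(fileext = ".gtf")
  write_gtf(tx, gtf)
  back <- read_gtf_transcripts(gtf)
  expect_equal(back$start, tx$start)
  expect_equal(back$end, tx$end)
  expect_equal(back$transcript_id, tx$transcript_id)
  unlink(gtf)
})
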