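# stage orchestration: file-based pipeline with manifests

#' Pipeline run configuration
#'
#' Collects paths, thresholds and the seed driving a pipeline run. All
#' threshold defaults are the canonical analysis values: constitutive PSI
#' 0.97, expressed-gene TPM 1, 10 supporting reads, high-complexity entropy
#' 1.0, delta-PSI 0.1 with posterior 0.85 over at least 5 stages, and
#' developmental entropy change 0.5.
#'
#' @param out_dir output directory (created if absent).
#' @param seed run seed.
#' @param sim a [sim_config()] for the simulate-based stages.
#' @param psi_const,min_tpm,min_reads,entropy_high,delta_psi,posterior,
#'   entropy_change,dev_min_stages thresholds.
#' @param tissues tissue labels.
#' @param reference_stage reference stage index for development calls.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, sim = sim_config(n_genes = 50L),
                       psi_const = 0.97, min_tpm = 1.0, min_reads = 10,
                       entropy_high = 1.0, delta_psi = 0.1, posterior = 0.85,
                       entropy_change = 0.5, dev_min_stages = 5L,
                       tissues = c("brain", "cerebellum"),
                       reference_stage = 1L) {
  stopifnot(psi_const > 0, psi_const <= 1, posterior >= 0, posterior <= 1)
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 psi_const = psi_const, min_tpm = min_tpm,
                 min_reads = min_reads, entropy_high = entropy_high,
                 delta_psi = delta_psi, posterior = posterior,
                 entropy_change = entropy_change,
                 dev_min_stages = dev_min_stages, tissues = tissues,
                 reference_stage = reference_stage),
            class = "run_config")
}

#' Write transcript models as GTF
#'
#' Converts the internal 0-based half-open exons back to 1-based inclusive
#' GTF records (via rtracklayer).
#'
#' @param transcripts `transcript_models`.
#' @param path output GTF.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(transcripts, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = transcripts$chrom,
    ranges = IRanges::IRanges(start = transcripts$start + 1L,
                              end = transcripts$end),
    strand = transcripts$strand)
  gr$type <- "exon"
  gr$gene_id <- transcripts$gene_id
  gr$transcript_id <- transcripts$transcript_id
  gr$source <- "splicentropy"
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read/write long-format edge-count tables
#'
#' Columns: `sample_id, gene_id, from, to, count`.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_counts_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "gene_id", "from", "to", "count")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L)
    stop("malformed counts file ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  tab
}

#' @rdname read_counts_tsv
#' @param counts long-format counts data.frame.
#' @export
write_counts_tsv <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# counts vector ("from-to" keys) for one gene+sample from the long table
counts_vector <- function(counts, gene, sample) {
  sub <- counts[counts$gene_id == gene & counts$sample_id == sample, ,
                drop = FALSE]
  stats::setNames(sub$count, edge_key(sub$from, sub$to))
}

manifest_path <- function(config, stage) {
  file.path(config$out_dir, paste0("manifest_", stage, ".json"))
}

write_manifest <- function(config, stage, inputs, outputs) {
  m <- list(stage = stage,
            package_version = as.character(utils::packageVersion("splicentropy")),
            seed = config$seed,
            thresholds = config[c("psi_const", "min_tpm", "min_reads",
                                  "entropy_high", "delta_psi", "posterior",
                                  "entropy_change", "dev_min_stages")],
            inputs = lapply(inputs, function(p)
              list(path = p, md5 = unname(tools::md5sum(p)))),
            outputs = lapply(outputs, function(p)
              list(path = p, md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(m, manifest_path(config, stage), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(m)
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (gene models, GTF, per-tissue edge counts with
#' two-regime abundances, gene annotation, tree, truth), `graph` (node
#' table from the GTF), `quantify` (per-sample event tables), `classify`
#' (tissue-pair classes and the transition table), `evolve` (synthetic
#' cross-species ages and age summaries), `develop` (stage-series calls and
#' crosstab), `context` (tau groups and entropy comparisons), `mlbench`
#' (feature extraction and regressor benchmark). Each stage writes its
#' outputs plus a JSON manifest (input/output md5 hashes, thresholds,
#' package version) into `config$out_dir`; missing or malformed inputs stop
#' with a diagnostic naming the file.
#'
#' @param stage stage name.
#' @param config a [run_config()].
#' @return named list of output paths, invisibly.
#' @export
run_stage <- function(stage = c("simulate", "graph", "quantify", "classify",
                                "evolve", "develop", "context", "mlbench"),
                      config) {
  stage <- match.arg(stage)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- switch(stage,
                simulate = stage_simulate(config),
                graph = stage_graph(config),
                quantify = stage_quantify(config),
                classify = stage_classify(config),
                evolve = stage_evolve(config),
                develop = stage_develop(config),
                context = stage_context(config),
                mlbench = stage_mlbench(config))
  invisible(out)
}

#' Run a chain of pipeline stages in order
#'
#' @param stages character vector of stage names.
#' @param config a [run_config()].
#' @return named list of per-stage output paths, invisibly.
#' @export
run_pipeline <- function(stages = c("simulate", "graph", "quantify",
                                    "classify"),
                         config) {
  res <- lapply(stages, run_stage, config = config)
  names(res) <- stages
  invisible(res)
}

need_input <- function(path, stage) {
  if (!file.exists(path))
    stop("stage '", stage, "': missing input ", path,
         " (run the producing stage first)")
  path
}

stage_simulate <- function(config) {
  sim <- config$sim
  models <- simulate_gene_models(sim, config$seed)
  gtf <- file.path(config$out_dir, "annotation.gtf")
  write_gtf(models$transcripts, gtf)

  # per-tissue edge counts from the two-regime concentration schedule
  rows <- list()
  tpm <- list()
  for (r in seq_len(nrow(models$truth))) {
    gid <- models$truth$gene_id[r]
    g <- models$graphs[[gid]]
    node <- models$truth$event_node[r]
    if (is.na(node)) next
    ev <- enumerate_event_paths(g, node)
    m <- length(ev$paths)
    for (tt in seq_along(config$tissues)) {
      sub_seed <- (config$seed + 131L * r + tt) %% 2000000000L
      conc <- with_seed(sub_seed, {
        if (stats::runif(1) < sim$high_frac) sim$conc_high else sim$conc_low
      })
      ab <- simulate_path_abundances(m, conc, sub_seed + 1L)[1L, ]
      cnt <- simulate_edge_counts(ev, ab, sim$depth, sub_seed + 2L)
      if (length(cnt) == 0L) next
      ft <- do.call(rbind, strsplit(names(cnt), "-", fixed = TRUE))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = config$tissues[tt], gene_id = gid,
        from = as.integer(ft[, 1L]), to = as.integer(ft[, 2L]),
        count = as.integer(cnt), stringsAsFactors = FALSE)
      tpm[[length(tpm) + 1L]] <- data.frame(
        sample_id = config$tissues[tt], gene_id = gid,
        tpm = round(with_seed(sub_seed + 3L, stats::rlnorm(1, log(30), 0.5)),
                    3L), stringsAsFactors = FALSE)
    }
  }
  counts_path <- file.path(config$out_dir, "edge_counts.tsv")
  write_counts_tsv(do.call(rbind, rows), counts_path)
  tpm_path <- file.path(config$out_dir, "gene_tpm.tsv")
  utils::write.table(do.call(rbind, tpm), tpm_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tree_path <- file.path(config$out_dir, "species_tree.nwk")
  ape::write.tree(sim$tree, tree_path)
  truth_path <- file.path(config$out_dir, "simulation_truth.tsv")
  utils::write.table(models$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  outs <- list(gtf = gtf, counts = counts_path, tpm = tpm_path,
               tree = tree_path, truth = truth_path)
  write_manifest(config, "simulate", list(), outs)
  outs
}

stage_graph <- function(config) {
  gtf <- need_input(file.path(config$out_dir, "annotation.gtf"), "graph")
  tx <- read_gtf_transcripts(gtf)
  graphs <- lapply(split(seq_len(nrow(tx)), tx$gene_id), function(idx)
    build_splice_graph(tx[idx, , drop = FALSE]))
  nodes_path <- file.path(config$out_dir, "nodes.tsv")
  write_node_table(graphs, nodes_path)
  outs <- list(nodes = nodes_path)
  write_manifest(config, "graph", list(gtf = gtf), outs)
  outs
}

stage_quantify <- function(config) {
  gtf <- need_input(file.path(config$out_dir, "annotation.gtf"), "quantify")
  counts_path <- need_input(file.path(config$out_dir, "edge_counts.tsv"),
                            "quantify")
  tpm_path <- need_input(file.path(config$out_dir, "gene_tpm.tsv"), "quantify")
  tx <- read_gtf_transcripts(gtf)
  counts <- read_counts_tsv(counts_path)
  tpm <- utils::read.delim(tpm_path, stringsAsFactors = FALSE)
  graphs <- lapply(split(seq_len(nrow(tx)), tx$gene_id), function(idx)
    build_splice_graph(tx[idx, , drop = FALSE]))
  outs <- list()
  for (sample in unique(counts$sample_id)) {
    quant <- do.call(rbind, lapply(names(graphs), function(gid) {
      tv <- tpm$tpm[tpm$gene_id == gid & tpm$sample_id == sample]
      quantify_gene(graphs[[gid]], counts_vector(counts, gid, sample),
                    gene_tpm = if (length(tv) == 1L) tv else 0,
                    sample_id = sample, min_tpm = config$min_tpm,
                    min_reads = config$min_reads)
    }))
    p <- file.path(config$out_dir, paste0("events_", sample, ".tsv"))
    utils::write.table(quant, p, sep = "\t", quote = FALSE, row.names = FALSE)
    outs[[sample]] <- p
  }
  write_manifest(config, "quantify",
                 list(gtf = gtf, counts = counts_path, tpm = tpm_path), outs)
  outs
}

stage_classify <- function(config) {
  t1 <- config$tissues[1L]
  t2 <- config$tissues[2L]
  p1 <- need_input(file.path(config$out_dir, paste0("events_", t1, ".tsv")),
                   "classify")
  p2 <- need_input(file.path(config$out_dir, paste0("events_", t2, ".tsv")),
                   "classify")
  a <- utils::read.delim(p1, stringsAsFactors = FALSE)
  b <- utils::read.delim(p2, stringsAsFactors = FALSE)
  pairs <- classify_tissue_pair(a, b)
  pairs_path <- file.path(config$out_dir,
                          paste0("classes_", t1, "_", t2, ".tsv"))
  utils::write.table(pairs, pairs_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tab <- tissue_transition_table(pairs)
  tab_path <- file.path(config$out_dir,
                        paste0("transitions_", t1, "_", t2, ".tsv"))
  utils::write.table(as.data.frame(tab), tab_path, sep = "\t", quote = FALSE,
                     row.names = TRUE)
  outs <- list(classes = pairs_path, transitions = tab_path)
  write_manifest(config, "classify", list(a = p1, b = p2), outs)
  outs
}

stage_evolve <- function(config) {
  study <- simulate_study(config$sim, seed = config$seed, n_dev = 0L)
  ages_path <- file.path(config$out_dir, "splicing_ages.tsv")
  utils::write.table(study$events, ages_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summary_path <- file.path(config$out_dir, "age_summary.tsv")
  utils::write.table(study$age_summary, summary_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  outs <- list(ages = ages_path, summary = summary_path)
  write_manifest(config, "evolve", list(), outs)
  outs
}

stage_develop <- function(config) {
  study_dev <- with_seed(config$seed, {
    kinds <- sample(c(rep("dev", 40L), rep("dynamic", 7L), rep("null", 53L)))
    rows <- lapply(seq_along(kinds), function(j) {
      sim <- simulate_stage_series(paste0("dev", j), kind = kinds[j],
                                   n_stages = config$sim$n_stages,
                                   seed = (config$seed + 11L * j) %%
                                     2000000000L)
      cl <- call_dev_events(sim$series,
                            min_significant_stages = config$dev_min_stages,
                            delta = config$delta_psi,
                            posterior_cut = config$posterior,
                            seed = (config$seed + 13L * j) %% 2000000000L)
      data.frame(event_id = sim$series$event_id, kind = kinds[j],
                 call = cl$call, n_significant = cl$n_significant,
                 dynamic_flag = entropy_dynamic_flag(
                   sim$series, min_change = config$entropy_change),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  calls_path <- file.path(config$out_dir, "dev_calls.tsv")
  utils::write.table(study_dev, calls_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ct <- dev_entropy_crosstab(study_dev$call, study_dev$dynamic_flag)
  ct_path <- file.path(config$out_dir, "dev_crosstab.tsv")
  utils::write.table(as.data.frame(ct$table), ct_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  outs <- list(calls = calls_path, crosstab = ct_path)
  write_manifest(config, "develop", list(), outs)
  outs
}

stage_context <- function(config) {
  n_genes <- config$sim$n_genes
  ann <- with_seed(config$seed + 7L, {
    # heterogeneous tissue spread so both tau groups are populated
    sdg <- stats::runif(n_genes, 0.05, 1.5)
    tpm <- t(vapply(sdg, function(s) stats::rlnorm(6L, log(20), s),
                    numeric(6L)))
    data.frame(gene_id = sprintf("gene%03d", seq_len(n_genes)),
               housekeeping = stats::runif(n_genes) < 0.2,
               age_class = sample(c("young", "old"), n_genes, replace = TRUE,
                                  prob = c(0.1, 0.9)),
               dnds = stats::rlnorm(n_genes, log(0.1), 1),
               ppi_degree = stats::rpois(n_genes, 30),
               tau = apply(tpm, 1L, tau), stringsAsFactors = FALSE)
  })
  ann_path <- file.path(config$out_dir, "gene_annotation.tsv")
  utils::write.table(ann, ann_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  # entropy draws per gene group: high-specificity genes lean high-entropy
  ent <- with_seed(config$seed + 8L, {
    grp <- group_genes(ann$tau, "tau")
    e <- stats::rbeta(n_genes, 2, 4) * 2
    e[grp == "High"] <- e[grp == "High"] + 0.3
    list(grp = grp, e = e)
  })
  hi <- ent$e[!is.na(ent$grp) & ent$grp == "High"]
  lo <- ent$e[!is.na(ent$grp) & ent$grp == "Low"]
  report <- if (length(hi) > 0L && length(lo) > 0L) {
    cmp <- compare_entropy_groups(hi, lo)
    data.frame(feature = "tau", group_a = "High", group_b = "Low",
               n_a = cmp$n_a, n_b = cmp$n_b, median_a = cmp$median_a,
               median_b = cmp$median_b, statistic = cmp$statistic,
               p_value = cmp$p_value)
  } else {
    data.frame(feature = "tau", group_a = "High", group_b = "Low",
               n_a = length(hi), n_b = length(lo), median_a = NA_real_,
               median_b = NA_real_, statistic = NA_real_, p_value = NA_real_)
  }
  report_path <- file.path(config$out_dir, "context_report.tsv")
  utils::write.table(report, report_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  outs <- list(annotation = ann_path, report = report_path)
  write_manifest(config, "context", list(), outs)
  outs
}

stage_mlbench <- function(config) {
  models <- simulate_gene_models(config$sim, config$seed)
  genome <- simulate_genome(models$transcripts, config$seed + 1L)
  pwms <- train_splice_pwm(models$transcripts, genome)
  feats <- list()
  for (r in seq_len(nrow(models$truth))) {
    node <- models$truth$event_node[r]
    gid <- models$truth$gene_id[r]
    if (is.na(node) || models$truth$type_requested[r] != "CE") next
    fv <- tryCatch(extract_exon_features(models$graphs[[gid]], genome, node,
                                         pwms), error = function(e) NULL)
    if (!is.null(fv))
      feats[[paste0(gid, ".n", node)]] <- fv
  }
  if (length(feats) < 50L)
    stop("stage 'mlbench': too few cassette events with flanking exons (",
         length(feats), "); increase sim n_genes or the CE share")
  x <- do.call(rbind, feats)
  y <- with_seed(config$seed + 2L, {
    0.5 + 0.3 * scale(x[, "upstream_exon_len"])[, 1L] +
      0.3 * scale(x[, "donor_strength"])[, 1L] +
      stats::rnorm(nrow(x), 0, 0.2)
  })
  rep_lin <- train_entropy_regressor(x, y, "linear", seed = config$seed)
  rep_gbt <- train_entropy_regressor(x, y, "gbt", seed = config$seed)
  report <- data.frame(model = c("linear", "gbt"),
                       pcc = c(rep_lin$pcc, rep_gbt$pcc),
                       scc = c(rep_lin$scc, rep_gbt$scc),
                       r2 = c(rep_lin$r2, rep_gbt$r2))
  report_path <- file.path(config$out_dir, "mlbench_report.tsv")
  utils::write.table(report, report_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  feats_path <- file.path(config$out_dir, "exon_features.tsv")
  ft <- data.frame(event_id = rownames(x), x, stringsAsFactors = FALSE)
  utils::write.table(ft, feats_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  outs <- list(report = report_path, features = feats_path)
  write_manifest(config, "mlbench", list(), outs)
  outs
}
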