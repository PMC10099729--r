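# synthetic-data generators with recorded ground truth

#' Simulation configuration
#'
#' Defaults define the emulated study: 200 genes, six tissues, the
#' seven-species tree with chicken outgroup, ten developmental stages, and a
#' two-regime Dirichlet concentration schedule producing the bimodal
#' splicing-entropy landscape (a low-concentration regime near one-hot path
#' usage and a symmetric high-concentration regime near uniform usage).
#'
#' @param n_genes number of genes.
#' @param exons_per_gene integer range `c(min, max)`.
#' @param transcripts_per_gene integer range; alternative event templates
#'   need at least 2.
#' @param event_mix named proportions over
#'   `CE, AA, AD, RI, AF, AL, TS, TE`.
#' @param ce_with_aa fraction of CE genes additionally given an
#'   acceptor-extended inclusion isoform (three local paths, complexity K2).
#' @param tissues tissue labels.
#' @param n_stages developmental stages for the stage-series subset.
#' @param tree rooted species tree ([species_tree7()] by default).
#' @param gain_prob,loss_prob per-branch state-flip probabilities for
#'   unconstrained evolutionary histories.
#' @param conc_low,conc_high,high_frac Dirichlet concentration schedule:
#'   abundances draw from `Dirichlet(conc_low)` with probability
#'   `1 - high_frac`, else `Dirichlet(conc_high)`.
#' @param depth reads per event per sample.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200L, exons_per_gene = c(4L, 8L),
                       transcripts_per_gene = c(2L, 3L),
                       event_mix = c(CE = 0.40, AA = 0.12, AD = 0.12,
                                     RI = 0.12, AF = 0.06, AL = 0.06,
                                     TS = 0.06, TE = 0.06),
                       ce_with_aa = 0.5,
                       tissues = c("brain", "cerebellum", "heart", "liver",
                                   "kidney", "testis"),
                       n_stages = 10L, tree = species_tree7(),
                       gain_prob = 0.1, loss_prob = 0.05,
                       conc_low = 0.15, conc_high = 10, high_frac = 0.35,
                       depth = 120L) {
  if (any(event_mix < 0) || sum(event_mix) <= 0)
    stop("event_mix must be non-negative with positive sum")
  if (transcripts_per_gene[2L] < 2L &&
      any(event_mix[c("CE", "AA", "AD", "RI", "AF", "AL", "TS", "TE")] > 0))
    stop("alternative event templates need at least 2 transcripts per gene")
  structure(list(n_genes = n_genes, exons_per_gene = exons_per_gene,
                 transcripts_per_gene = transcripts_per_gene,
                 event_mix = event_mix / sum(event_mix),
                 ce_with_aa = ce_with_aa, tissues = tissues,
                 n_stages = n_stages, tree = tree, gain_prob = gain_prob,
                 loss_prob = loss_prob, conc_low = conc_low,
                 conc_high = conc_high, high_frac = high_frac, depth = depth),
            class = "sim_config")
}

# local->genomic interval conversion for one gene
local_to_genomic <- function(ex_local, g0, L, strand) {
  if (strand == "+")
    data.frame(start = g0 + ex_local$start, end = g0 + ex_local$end)
  else
    data.frame(start = g0 + L - ex_local$end, end = g0 + L - ex_local$start)
}

#' Simulate multi-isoform gene models instantiating an event-type mix
#'
#' Each gene gets a backbone transcript plus one alternative transcript
#' realising a drawn event template (cassette exon, alternative
#' acceptor/donor, retained intron, alternative first/last exon, tandem
#' start/polyadenylation site); CE genes optionally carry a third,
#' acceptor-extended inclusion isoform. Every gene is placed on its own
#' synthetic chromosome and a random strand. Each intended event is verified
#' to appear in the built splice graph (round-trip check).
#'
#' @param config a [sim_config()].
#' @param seed RNG seed; output is a pure function of `(config, seed)`.
#' @return list: `transcripts` (`transcript_models` over all genes),
#'   `graphs` (named list of `splice_graph`s), `truth` (data.frame:
#'   `gene_id, chrom, strand, type_requested, type_realized, event_node,
#'   n_event_paths`).
#' @export
simulate_gene_models <- function(config, seed) {
  with_seed(seed, {
    all_exons <- list()
    truth <- list()
    for (g in seq_len(config$n_genes)) {
      gid <- sprintf("gene%03d", g)
      chrom <- paste0("chr", g)
      strand <- sample(c("+", "-"), 1L)
      type <- sample(names(config$event_mix), 1L, prob = config$event_mix)
      n_min <- max(config$exons_per_gene[1L], 3L)
      n_ex <- sample(n_min:max(config$exons_per_gene[2L], n_min), 1L)
      el <- sample(80:250, n_ex, replace = TRUE)
      il <- sample(200:800, n_ex - 1L, replace = TRUE)
      starts <- cumsum(c(0L, el[-n_ex] + il))
      ex <- data.frame(start = starts, end = starts + el)
      L <- ex$end[n_ex]
      g0 <- 100L
      k <- sample(2:(n_ex - 1L), 1L)   # internal exon for CE/AA/AD/RI
      d <- sample(30:80, 1L)

      t2 <- switch(type,
        CE = ex[-k, ],
        AA = { v <- ex; v$start[k] <- v$start[k] - d; v },
        AD = { v <- ex; v$end[k] <- v$end[k] + min(d, il[k] - 40L); v },
        RI = { v <- ex[-(k + 1L), ]
               v$end[v$start == ex$start[k]] <- ex$end[k + 1L]; v },
        AF = rbind(data.frame(start = ex$end[1L] + 40L,
                              end = ex$end[1L] + 40L + sample(80:150, 1L)),
                   ex[-1L, ]),
        AL = rbind(ex[-n_ex, ],
                   data.frame(start = ex$start[n_ex] - 40L -
                                sample(80:150, 1L) - 1L,
                              end = ex$start[n_ex] - 40L)),
        TS = { v <- ex; v$start[1L] <- v$start[1L] + min(d, el[1L] - 40L); v },
        TE = { v <- ex; v$end[n_ex] <- v$end[n_ex] - min(d, el[n_ex] - 40L); v })
      tset <- list(T1 = ex, T2 = t2)
      if (type == "CE" && stats::runif(1) < config$ce_with_aa) {
        v <- ex
        v$start[k] <- v$start[k] - d
        tset$T3 <- v
      }
      for (tn in names(tset)) {
        gi <- local_to_genomic(tset[[tn]], g0, L, strand)
        all_exons[[length(all_exons) + 1L]] <- data.frame(
          gene_id = gid, transcript_id = paste0(gid, ".", tn), chrom = chrom,
          strand = strand, start = gi$start, end = gi$end,
          stringsAsFactors = FALSE)
      }
      truth[[g]] <- data.frame(gene_id = gid, chrom = chrom, strand = strand,
                               type_requested = type, stringsAsFactors = FALSE)
    }
    tx <- transcript_models(do.call(rbind, all_exons))
    graphs <- lapply(split(seq_len(nrow(tx)), tx$gene_id), function(idx) {
      build_splice_graph(tx[idx, , drop = FALSE])
    })
    truth <- do.call(rbind, truth)
    truth$type_realized <- FALSE
    truth$event_node <- NA_integer_
    truth$n_event_paths <- NA_integer_
    for (r in seq_len(nrow(truth))) {
      g <- graphs[[truth$gene_id[r]]]
      hit <- which(g$nodes$node_type == truth$type_requested[r])
      if (length(hit) > 0L) {
        # prefer a node whose local event is informative: several paths and
        # node inclusion differing between them (constitutive flanking nodes
        # can share the CE fallback type but sit on every local path)
        evs <- lapply(hit, function(i) enumerate_event_paths(g, i))
        np <- vapply(evs, function(e) length(e$paths), integer(1L))
        informative <- vapply(evs, function(e)
          length(e$paths) >= 2L && any(e$contains_node) &&
            any(!e$contains_node), logical(1L))
        best <- if (any(informative)) which(informative)[1L]
                else if (any(np >= 2L)) which(np >= 2L)[1L] else 1L
        truth$type_realized[r] <- TRUE
        truth$event_node[r] <- hit[best]
        truth$n_event_paths[r] <- np[best]
      }
    }
    list(transcripts = tx, graphs = graphs, truth = truth)
  })
}

#' Simulate a genome matching an annotation
#'
#' Random sequence per chromosome with canonical splice motifs planted at
#' every annotated junction (GT..AG intron boundaries preceded by a
#' polypyrimidine tract), so that PWM splice-site training has signal.
#'
#' @param transcripts `transcript_models`.
#' @param seed RNG seed.
#' @param flank extra sequence beyond the outermost exon.
#' @return named [Biostrings::DNAStringSet].
#' @export
simulate_genome <- function(transcripts, seed, flank = 100L) {
  with_seed(seed, {
    out <- list()
    for (chrom in unique(transcripts$chrom)) {
      tx <- transcripts[transcripts$chrom == chrom, , drop = FALSE]
      len <- max(tx$end) + flank
      s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      for (tid in unique(tx$transcript_id)) {
        ex <- tx[tx$transcript_id == tid, , drop = FALSE]
        ex <- ex[order(ex$start), ]
        strand <- ex$strand[1L]
        if (nrow(ex) < 2L) next
        for (j in seq_len(nrow(ex) - 1L)) {
          left <- ex$end[j]          # 0-based: intron = [left, right)
          right <- ex$start[j + 1L]
          if (strand == "+") {
            s[(left + 1L):(left + 2L)] <- c("G", "T")
            tract <- pmax(right - 20L, left) : (right - 2L)
            s[tract + 1L] <- sample(c("C", "T"), length(tract), replace = TRUE)
            s[(right - 1L):right] <- c("A", "G")
          } else {
            # transcribed donor at genomic right end, acceptor at left
            s[(right - 1L):right] <- c("A", "C")  # revcomp of GT
            tract <- (left + 2L) : pmin(left + 20L, right)
            s[tract] <- sample(c("A", "G"), length(tract), replace = TRUE)
            s[(left + 1L):(left + 2L)] <- c("C", "T")  # revcomp of AG
          }
        }
      }
      out[[chrom]] <- paste(s, collapse = "")
    }
    Biostrings::DNAStringSet(unlist(out))
  })
}

#' Draw true path abundances from the concentration schedule
#'
#' Symmetric Dirichlet draws: concentration near zero gives near-one-hot
#' abundances (low entropy); large symmetric concentration gives
#' near-uniform abundances (entropy near `log2(n_paths)`); the two-regime
#' mixture of [sim_config()] produces a bimodal entropy distribution.
#'
#' @param n_paths paths of the event.
#' @param concentration scalar symmetric Dirichlet concentration, or vector
#'   of per-path concentrations.
#' @param seed RNG seed.
#' @param n number of draws.
#' @return `n x n_paths` matrix of abundances (rows sum to 1).
#' @export
simulate_path_abundances <- function(n_paths, concentration, seed, n = 1L) {
  alpha <- if (length(concentration) == 1L) rep(concentration, n_paths)
           else concentration
  stopifnot(length(alpha) == n_paths)
  with_seed(seed, rdirichlet(n, alpha))
}

#' Simulate edge read counts for one event
#'
#' Expected intensity of an edge is the summed abundance of the paths
#' containing it; counts are one multinomial draw of `depth` reads over the
#' event's edges.
#'
#' @param event `event_paths`.
#' @param abundances normalized path-abundance vector.
#' @param depth total reads.
#' @param seed RNG seed.
#' @return named count vector over the event's edges (`"from-to"` keys).
#' @export
simulate_edge_counts <- function(event, abundances, depth, seed) {
  stopifnot(length(abundances) == length(event$paths))
  keys <- lapply(event$path_edges, function(e) edge_key(e$from, e$to))
  all_keys <- unique(unlist(keys))
  if (length(all_keys) == 0L)
    return(stats::setNames(numeric(0), character(0)))
  intensity <- stats::setNames(rep(0, length(all_keys)), all_keys)
  for (p in seq_along(keys))
    intensity[keys[[p]]] <- intensity[keys[[p]]] + abundances[p]
  if (depth == 0L || sum(intensity) == 0)
    return(stats::setNames(rep(0L, length(all_keys)), all_keys))
  with_seed(seed, {
    cnt <- as.integer(stats::rmultinom(1L, depth, intensity / sum(intensity)))
    stats::setNames(cnt, all_keys)
  })
}

#' Simulate a gain/loss history of splicing states on a rooted tree
#'
#' The root receives `root_state`; each branch flips the state with the
#' direction-appropriate probability (`gain_prob` C to A, `loss_prob` A to
#' C). With `constrain_single_change`, histories are rejection-sampled until
#' at most one flip occurred, and the flipped branch (as its leaf set) and
#' direction are recorded.
#'
#' @param tree rooted `phylo`.
#' @param gain_prob,loss_prob flip probabilities per branch.
#' @param root_state `"C"` or `"A"`.
#' @param constrain_single_change logical.
#' @param seed RNG seed.
#' @return list: `states` (named leaf vector), `n_flips`, `flips` (list of
#'   `list(clade, direction)`).
#' @export
simulate_evolutionary_history <- function(tree, gain_prob = 0.1,
                                          loss_prob = 0.05,
                                          root_state = "C",
                                          constrain_single_change = FALSE,
                                          seed = 1L) {
  tips <- tree$tip.label
  n_tip <- length(tips)
  root <- n_tip + 1L
  draw <- function() {
    node_state <- stats::setNames(rep(NA_character_,
                                      max(tree$edge)), NULL)
    node_state[root] <- root_state
    flips <- list()
    # preorder: ape edge matrix of read.tree is already parent-before-child
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1L]
      child <- tree$edge[e, 2L]
      st <- node_state[par]
      p_flip <- if (st == "C") gain_prob else loss_prob
      if (stats::runif(1) < p_flip) {
        st <- if (st == "C") "A" else "C"
        clade <- if (child <= n_tip) tips[child]
                 else tips[phangorn_descendants(tree, child)]
        flips[[length(flips) + 1L]] <-
          list(clade = sort(clade),
               direction = if (st == "A") "gain" else "loss")
      }
      node_state[child] <- st
    }
    list(states = stats::setNames(node_state[seq_len(n_tip)], tips),
         n_flips = length(flips), flips = flips)
  }
  with_seed(seed, {
    h <- draw()
    if (constrain_single_change) {
      tries <- 1L
      while (h$n_flips > 1L && tries < 10000L) {
        h <- draw()
        tries <- tries + 1L
      }
      if (h$n_flips > 1L) stop("could not sample a single-change history")
    }
    h
  })
}

#' Simulate a developmental stage series with known truth
#'
#' The event has four local paths factorised as (node in / node out) x
#' (within-route split): PSI follows a logistic sweep of the configured
#' amplitude for Dev-true events and stays flat otherwise;
#' entropy-dynamic-true events sweep the within-route split from
#' near-one-hot to even, which changes entropy by about `entropy_span` bits
#' while leaving PSI untouched. Inclusion/exclusion reads are binomial at
#' `depth` per stage.
#'
#' @param event_id label.
#' @param kind `"null"`, `"dev"`, `"dynamic"` or `"dev_dynamic"`.
#' @param n_stages ordered stages (>= 6).
#' @param amplitude PSI sweep amplitude for Dev-true events.
#' @param entropy_span approximate entropy change for dynamic-true events
#'   (bits; realised span is `H2(0.5) - H2(w0)` based).
#' @param depth reads per stage.
#' @param tpm constant host-gene TPM.
#' @param psi0 baseline PSI.
#' @param seed RNG seed.
#' @return list: `series` (a [stage_series()]), `truth` (list with
#'   `true_dev`, `true_dynamic`, `psi`, `abundances`).
#' @export
simulate_stage_series <- function(event_id, kind = c("null", "dev", "dynamic",
                                                     "dev_dynamic"),
                                  n_stages = 10L, amplitude = 0.3,
                                  entropy_span = 0.8, depth = 200L, tpm = 50,
                                  psi0 = 0.45, seed = 1L) {
  kind <- match.arg(kind)
  if (n_stages < 6L) stop("need at least 6 stages")
  t <- seq_len(n_stages)
  dev <- kind %in% c("dev", "dev_dynamic")
  dyn <- kind %in% c("dynamic", "dev_dynamic")
  psi <- if (dev) {
    # early-development logistic switch (midpoint at ~1/3 of the series):
    # most of the sweep is completed by mid-series, as developmental
    # splicing programs typically are
    mid <- max(2L, ceiling(n_stages * 0.3))
    lg <- stats::plogis(1.5 * (seq_len(n_stages) - mid))
    psi0 + amplitude * (lg - lg[1L]) / (lg[n_stages] - lg[1L])
  } else rep(psi0, n_stages)
  # within-route split w controls entropy independently of PSI
  w0 <- 0.97
  w1 <- if (dyn) seq(w0, 0.5, length.out = n_stages) else rep(w0, n_stages)
  abund <- t(vapply(t, function(i) {
    c(psi[i] * w1[i], psi[i] * (1 - w1[i]),
      (1 - psi[i]) * w1[i], (1 - psi[i]) * (1 - w1[i]))
  }, numeric(4L)))
  entropy <- apply(abund, 1L, shannon_bits)
  with_seed(seed, {
    incl <- stats::rbinom(n_stages, depth, psi)
    excl <- depth - incl
    series <- stage_series(event_id, stages = paste0("stage", t), psi = psi,
                           entropy = entropy, reads = rep(depth, n_stages),
                           tpm = rep(tpm, n_stages), incl = incl, excl = excl,
                           reference_stage = 1L)
    list(series = series,
         truth = list(true_dev = dev, true_dynamic = dyn, psi = psi,
                      abundances = abund))
  })
}
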