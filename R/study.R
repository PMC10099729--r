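# end-to-end synthetic study: gene models -> cross-species quantification ->
# parsimony ages -> development calls, with recorded truth

# age rank of a simulated scenario: 1 species-specific change, 2 multi-species
# clade change, 3 mammal-conserved (MCA/MCC), 4 vertebrate-conserved (VCA)
scenario_rank <- function(category, clade_size = NA_integer_) {
  switch(category,
         VCA = 4L, MCA = 3L, MCC = 3L,
         gain = if (clade_size >= 2L) 2L else 1L,
         loss = if (clade_size >= 2L) 2L else 1L,
         VCC = NA_integer_, complex = NA_integer_,
         NA_integer_)
}

# non-root, non-trivial branches of a rooted tree (clades that are proper
# subsets of the ingroup)
candidate_branches <- function(tree, outgroup) {
  ingroup <- setdiff(tree$tip.label, outgroup)
  cl <- tree_clades(tree)
  cl[vapply(cl, function(x) all(x %in% ingroup) && length(x) < length(ingroup),
            logical(1L))]
}

# a leaf subset that no single-change scenario explains
draw_complex_pattern <- function(tree) {
  tips <- tree$tip.label
  cl <- tree_clades(tree)
  is_clade <- function(s) any(vapply(cl, function(x) setequal(x, s),
                                     logical(1L)))
  repeat {
    k <- sample(2:(length(tips) - 2L), 1L)
    a <- sort(sample(tips, k))
    if (!is_clade(a) && !is_clade(setdiff(tips, a))) return(a)
  }
}

#' Run the full synthetic study
#'
#' Simulates gene models, plants an evolutionary scenario per cassette-exon
#' event (conserved classes, single-branch gains/losses and multi-change
#' "complex" patterns), couples the Dirichlet concentration of true path
#' abundances to the event's splicing age (older groups draw higher-entropy
#' abundances), samples edge reads per species and tissue, quantifies every
#' event by EM, calls per-species states and parsimony ages, and summarises
#' high-complexity ratios per true age rank. A developmental subset of stage
#' series with planted Dev and entropy-dynamic truth is generated and called
#' alongside.
#'
#' @param config [sim_config()]; for the age analysis a CE-rich mix is the
#'   natural choice.
#' @param seed study seed.
#' @param n_dev events in the developmental subset.
#' @param dev_frac fraction of dev-subset events with a true PSI sweep.
#' @param dynamic_frac planted entropy-dynamic fraction among non-Dev truth.
#' @param scenario_probs named probabilities over
#'   `VCC, VCA, MCA, MCC, gain, loss, complex`.
#' @param alpha_by_rank Dirichlet concentrations for age ranks 1..4.
#' @param gene_tpm host-gene TPM recorded for every sample.
#' @return list with `events` (per-event truth + recovered labels),
#'   `age_summary` (per-rank ratios over observed human entropies),
#'   `states_true`, `states_obs`, `human_entropy` (events x tissues),
#'   `dev` (per-event truth and calls plus `crosstab`), `models`.
#' @export
simulate_study <- function(config = sim_config(event_mix = c(CE = 1),
                                               ce_with_aa = 1),
                           seed = 1L, n_dev = 200L, dev_frac = 0.4,
                           dynamic_frac = 0.12,
                           scenario_probs = c(VCC = 0.26, VCA = 0.12,
                                              MCA = 0.06, MCC = 0.04,
                                              gain = 0.30, loss = 0.08,
                                              complex = 0.14),
                           alpha_by_rank = c(0.25, 0.5, 0.9, 1.8),
                           gene_tpm = 30) {
  tree <- config$tree
  tips <- tree$tip.label
  tissues <- config$tissues
  models <- simulate_gene_models(config, seed)
  ce <- models$truth[models$truth$type_realized &
                       models$truth$type_requested == "CE", , drop = FALSE]
  if (nrow(ce) == 0L) stop("no realized cassette exons in the simulation")

  root_kids <- tree$edge[tree$edge[, 1L] == length(tips) + 1L, 2L]
  sets <- lapply(root_kids, function(k) {
    if (k <= length(tips)) tips[k] else tips[phangorn_descendants(tree, k)]
  })
  outgroup <- sets[[which.min(lengths(sets))]]
  ingroup <- setdiff(tips, outgroup)
  branches <- candidate_branches(tree, outgroup)

  events <- data.frame(event_id = paste0(ce$gene_id, ".n", ce$event_node),
                       gene_id = ce$gene_id, node_index = ce$event_node,
                       stringsAsFactors = FALSE)
  n_ev <- nrow(events)

  plan <- with_seed(seed + 101L, {
    category <- sample(names(scenario_probs), n_ev, replace = TRUE,
                       prob = scenario_probs)
    lapply(seq_len(n_ev), function(i) {
      cat_i <- category[i]
      if (cat_i == "VCC") list(category = cat_i, a_set = character(0))
      else if (cat_i == "VCA") list(category = cat_i, a_set = tips)
      else if (cat_i == "MCA") list(category = cat_i, a_set = ingroup)
      else if (cat_i == "MCC") list(category = cat_i, a_set = outgroup)
      else if (cat_i == "complex")
        list(category = cat_i, a_set = draw_complex_pattern(tree))
      else {
        cl <- branches[[sample(length(branches), 1L)]]
        a_set <- if (cat_i == "gain") cl else setdiff(tips, cl)
        list(category = cat_i, a_set = sort(a_set), clade = sort(cl))
      }
    })
  })

  states_true <- matrix(NA_character_, n_ev, length(tips),
                        dimnames = list(events$event_id, tips))
  ranks <- integer(n_ev)
  for (i in seq_len(n_ev)) {
    states_true[i, ] <- ifelse(tips %in% plan[[i]]$a_set, "A", "C")
    ranks[i] <- scenario_rank(plan[[i]]$category,
                              length(plan[[i]]$clade))
  }
  events$true_group <- vapply(plan, `[[`, character(1L), "category")
  events$true_rank <- ranks

  # per species x tissue quantification of each event
  states_obs <- matrix(NA_character_, n_ev, length(tips),
                       dimnames = list(events$event_id, tips))
  human_entropy <- matrix(NA_real_, n_ev, length(tissues),
                          dimnames = list(events$event_id, tissues))
  ev_paths <- lapply(seq_len(n_ev), function(i) {
    enumerate_event_paths(models$graphs[[events$gene_id[i]]],
                          events$node_index[i])
  })
  kappa <- 40   # per-tissue precision around the event's base abundances
  for (i in seq_len(n_ev)) {
    ev <- ev_paths[[i]]
    m <- length(ev$paths)
    incl_first <- which(ev$contains_node)[1L]
    alpha <- alpha_by_rank[max(ranks[i], 1L)]
    if (is.na(ranks[i])) alpha <- 1
    # each event has an intrinsic splicing character: one base abundance
    # vector per event (entropy coupled to age), tissues jitter around it
    base <- with_seed((seed + 811L * i) %% 2000000000L, {
      tries <- 0L
      repeat {
        x <- rdirichlet(1L, rep(alpha, m))[1L, ]
        psi <- sum(x[ev$contains_node])
        if ((psi > 0.01 && psi < 0.96) || tries > 50L) break
        tries <- tries + 1L
      }
      x
    })
    for (s in seq_along(tips)) {
      st <- states_true[i, s]
      statuses <- character(length(tissues))
      for (tt in seq_along(tissues)) {
        sub_seed <- (seed + 193L * i + 17L * s + tt) %% 2000000000L
        ab <- if (st == "C") {
          v <- rep(0.003 / max(m - 1L, 1L), m)
          v[incl_first] <- 1 - sum(v[-incl_first])
          v
        } else {
          with_seed(sub_seed, rdirichlet(1L, base * kappa + 0.02)[1L, ])
        }
        cnt <- simulate_edge_counts(ev, ab, config$depth, sub_seed + 1L)
        pa <- estimate_path_abundances(ev, cnt)
        psi <- node_psi(pa, ev)
        keep <- event_filter(list(gene_tpm = gene_tpm,
                                  total_event_reads = pa$total_event_reads))
        statuses[tt] <- splicing_status(psi, keep)
        if (tips[s] == "human")
          human_entropy[i, tt] <- splicing_entropy(pa)
      }
      states_obs[i, s] <- species_splicing_state(statuses)
    }
  }

  assignments <- lapply(seq_len(n_ev), function(i)
    assign_splicing_age(states_obs[i, ], tree))
  events$label_obs <- vapply(assignments, `[[`, character(1L), "label")
  events$recovered <- vapply(seq_len(n_ev), function(i) {
    p <- plan[[i]]
    a <- assignments[[i]]
    switch(p$category,
      VCC = a$label == "VCC", VCA = a$label == "VCA",
      MCA = a$label == "MCA", MCC = a$label == "MCC",
      complex = a$label == "complex",
      any(vapply(a$scenarios, function(sc)
        setequal(sc$clade, p$clade) && sc$direction == p$category,
        logical(1L))))
  }, logical(1L))

  # Fig-5D-style summary: observed human entropies of alternative events,
  # grouped by the simulated age rank
  alt_human <- states_obs[, "human"] == "A" & !is.na(events$true_rank)
  alt_human[is.na(alt_human)] <- FALSE
  age_summary <- if (any(alt_human))
    age_group_summaries(as.character(events$true_rank[alt_human]),
                        human_entropy[alt_human, , drop = FALSE])
  else NULL

  # developmental subset
  dev <- if (n_dev == 0L) NULL else with_seed(seed + 202L, {
    n_devev <- round(n_dev * dev_frac)
    n_null <- n_dev - n_devev
    n_dyn <- round(n_null * dynamic_frac)
    kinds <- c(rep("dev", n_devev), rep("dynamic", n_dyn),
               rep("null", n_null - n_dyn))
    kinds <- sample(kinds)
    rows <- lapply(seq_len(n_dev), function(j) {
      sim <- simulate_stage_series(paste0("dev", j), kind = kinds[j],
                                   n_stages = config$n_stages,
                                   seed = (seed + 11L * j) %% 2000000000L)
      cl <- call_dev_events(sim$series, seed = (seed + 13L * j) %% 2000000000L)
      data.frame(event_id = sim$series$event_id, kind = kinds[j],
                 true_dev = sim$truth$true_dev,
                 true_dynamic = sim$truth$true_dynamic,
                 call = cl$call, n_significant = cl$n_significant,
                 dynamic_flag = entropy_dynamic_flag(sim$series),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  dev_tab <- if (is.null(dev)) NULL
             else dev_entropy_crosstab(dev$call, dev$dynamic_flag)

  list(events = events, age_summary = age_summary,
       states_true = states_true, states_obs = states_obs,
       human_entropy = human_entropy,
       dev = if (is.null(dev)) NULL
             else list(events = dev, crosstab = dev_tab,
                       planted_dynamic_frac = dynamic_frac),
       models = models)
}
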