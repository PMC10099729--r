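#' Posterior delta-PSI call between a stage and the reference stage
#'
#' PSI in each condition is modelled as Beta(incl + 0.5, excl + 0.5)
#' (Jeffreys prior on the inclusion/exclusion read split); the posterior
#' probability of a splicing change is the fraction of paired posterior draws
#' with `|Psi_a - Psi_b| >= delta`. An event is significant when the point
#' estimate satisfies `|dPsi| >= 0.1` and the posterior reaches 0.85.
#'
#' @param ref_counts,stage_counts length-2 numeric vectors
#'   `c(inclusion, exclusion)` read counts.
#' @param delta effect-size threshold on `|dPsi|` inside the posterior.
#' @param n_draws Monte-Carlo draws.
#' @param seed RNG seed (calls are reproducible for a fixed seed).
#' @param posterior_cut,point_cut significance thresholds (0.85 / 0.1).
#' @return object of class `delta_psi_call`: list with `delta_psi` (point
#'   estimate, stage minus reference), `posterior`, `significant`; all `NA`
#'   when either condition has zero total reads.
#' @export
delta_psi_posterior <- function(ref_counts, stage_counts, delta = 0.1,
                                n_draws = 2000L, seed = 1L,
                                posterior_cut = 0.85, point_cut = 0.1) {
  if (any(c(ref_counts, stage_counts) < 0)) stop("negative read counts")
  if (sum(ref_counts) == 0 || sum(stage_counts) == 0) {
    return(structure(list(delta_psi = NA_real_, posterior = NA_real_,
                          significant = NA), class = "delta_psi_call"))
  }
  psi_ref <- ref_counts[1L] / sum(ref_counts)
  psi_stage <- stage_counts[1L] / sum(stage_counts)
  post <- with_seed(seed, {
    a <- stats::rbeta(n_draws, ref_counts[1L] + 0.5, ref_counts[2L] + 0.5)
    b <- stats::rbeta(n_draws, stage_counts[1L] + 0.5, stage_counts[2L] + 0.5)
    mean(abs(a - b) >= delta)
  })
  dpsi <- psi_stage - psi_ref
  structure(list(delta_psi = dpsi, posterior = post,
                 significant = abs(dpsi) >= point_cut && post >= posterior_cut),
            class = "delta_psi_call")
}

#' Assemble a developmental stage series for one event
#'
#' @param event_id event identifier.
#' @param stages ordered stage labels.
#' @param psi,entropy,reads,tpm,incl,excl per-stage vectors (same length as
#'   `stages`); `incl`/`excl` are the binary inclusion/exclusion read counts
#'   feeding the posterior calls.
#' @param reference_stage index of the reference (earliest) stage.
#' @return object of class `stage_series`.
#' @export
stage_series <- function(event_id, stages, psi, entropy, reads, tpm,
                         incl, excl, reference_stage = 1L) {
  n <- length(stages)
  stopifnot(length(psi) == n, length(entropy) == n, length(reads) == n,
            length(tpm) == n, length(incl) == n, length(excl) == n,
            reference_stage >= 1L, reference_stage <= n)
  structure(list(event_id = event_id, stages = stages, psi = psi,
                 entropy = entropy, reads = reads, tpm = tpm,
                 incl = incl, excl = excl,
                 reference_stage = as.integer(reference_stage)),
            class = "stage_series")
}

#' Call a developmentally regulated (Dev) event from a stage series
#'
#' Every non-reference stage is compared with the reference stage by
#' [delta_psi_posterior()]; the event is `"Dev"` when significant in at least
#' `min_significant_stages` stages, `"non-Dev"` otherwise, and
#' `"unclassified"` when fewer than `min_significant_stages` non-reference
#' stages could be compared.
#'
#' @param series a `stage_series`.
#' @param min_significant_stages stage threshold (5).
#' @param delta,n_draws,seed,posterior_cut,point_cut forwarded to
#'   [delta_psi_posterior()] (per-stage seeds are derived from `seed`).
#' @return list: `call` (`"Dev"`/`"non-Dev"`/`"unclassified"`),
#'   `n_significant`, `n_tested`, `calls` (per-stage `delta_psi_call`s).
#' @export
call_dev_events <- function(series, min_significant_stages = 5L, delta = 0.1,
                            n_draws = 2000L, seed = 1L, posterior_cut = 0.85,
                            point_cut = 0.1) {
  ref <- series$reference_stage
  idx <- setdiff(seq_along(series$stages), ref)
  calls <- vector("list", length(idx))
  names(calls) <- series$stages[idx]
  for (k in seq_along(idx)) {
    i <- idx[k]
    calls[[k]] <- delta_psi_posterior(
      c(series$incl[ref], series$excl[ref]),
      c(series$incl[i], series$excl[i]),
      delta = delta, n_draws = n_draws, seed = seed + 7L * i,
      posterior_cut = posterior_cut, point_cut = point_cut)
  }
  sig <- vapply(calls, function(x) isTRUE(x$significant), logical(1L))
  tested <- vapply(calls, function(x) !is.na(x$posterior), logical(1L))
  call <- if (sum(tested) < min_significant_stages) "unclassified"
          else if (sum(sig) >= min_significant_stages) "Dev" else "non-Dev"
  list(call = call, n_significant = sum(sig), n_tested = sum(tested),
       calls = calls)
}

#' Entropy-dynamic flag for a stage series
#'
#' `TRUE` when the splicing-entropy range (max minus min) over eligible
#' stages reaches `min_change`, where a stage is eligible when its event has
#' more than `min_reads` supporting reads and its host gene more than
#' `min_tpm` TPM, and at least `min_stages` stages are eligible.
#'
#' @param series a `stage_series`.
#' @param min_change entropy range threshold in bits (0.5).
#' @param min_reads,min_tpm eligibility thresholds (strict `>`; 20 reads,
#'   10 TPM).
#' @param min_stages minimum eligible stages (5).
#' @return logical.
#' @export
entropy_dynamic_flag <- function(series, min_change = 0.5, min_reads = 20,
                                 min_tpm = 10, min_stages = 5L) {
  ok <- !is.na(series$entropy) & series$reads > min_reads &
    series$tpm > min_tpm
  if (sum(ok) < min_stages) return(FALSE)
  e <- series$entropy[ok]
  (max(e) - min(e)) >= min_change
}

#' Cross-tabulate Dev status against entropy dynamics
#'
#' @param dev_call per-event `"Dev"`/`"non-Dev"` labels.
#' @param dynamic per-event logical entropy-dynamic flags.
#' @return list: `table` (2 x 2 counts, Dev status x dynamic status),
#'   `nondev_dynamic_ratio` (fraction of dynamic events among non-Dev;
#'   `NA` when there are no non-Dev events), `dev_dynamic_ratio`.
#' @export
dev_entropy_crosstab <- function(dev_call, dynamic) {
  stopifnot(length(dev_call) == length(dynamic))
  keep <- dev_call %in% c("Dev", "non-Dev") & !is.na(dynamic)
  dev_call <- dev_call[keep]
  dynamic <- dynamic[keep]
  tab <- table(factor(dev_call, levels = c("Dev", "non-Dev")),
               factor(ifelse(dynamic, "dynamic", "static"),
                      levels = c("dynamic", "static")))
  nd <- dev_call == "non-Dev"
  dv <- dev_call == "Dev"
  list(table = tab,
       nondev_dynamic_ratio = if (any(nd)) mean(dynamic[nd]) else NA_real_,
       dev_dynamic_ratio = if (any(dv)) mean(dynamic[dv]) else NA_real_)
}
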