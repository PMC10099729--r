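test_that("species state summarises per-tissue statuses", {
  expect_equal(species_splicing_state(
    c("alternative", "constitutive", "constitutive", NA, NA, NA)), "A")
  expect_equal(species_splicing_state(c("constitutive", "constitutive")), "C")
  expect_true(is.na(species_splicing_state(c(NA, NA))))
  expect_true(is.na(species_splicing_state(
    c("excluded", "excluded"))))
})

test_that("parsimony labels the canonical patterns", {
  tr <- species_tree7()
  all_a <- setNames(rep("A", 7L), tr$tip.label)
  expect_equal(assign_splicing_age(all_a, tr)$label, "VCA")
  all_c <- setNames(rep("C", 7L), tr$tip.label)
  expect_equal(assign_splicing_age(all_c, tr)$label, "VCC")

  mca <- all_c
  mca[setdiff(tr$tip.label, "chicken")] <- "A"
  a_mca <- assign_splicing_age(mca, tr)
  expect_equal(a_mca$label, "MCA")
  expect_equal(length(a_mca$scenarios), 2L)  # ingroup gain or outgroup loss

  hg <- all_c
  hg["human"] <- "A"
  expect_equal(assign_splicing_age(hg, tr)$label, "human_gain")

  cx <- all_c
  cx[c("human", "mouse")] <- "A"
  expect_equal(assign_splicing_age(cx, tr)$label, "complex")

  na_case <- all_c
  na_case["mouse"] <- NA
  expect_equal(assign_splicing_age(na_case, tr)$label, "unassignable")
  expect_equal(assign_splicing_age(na_case, tr, require_complete = FALSE)$label,
               "VCC")
})

test_that("parsimony agrees with the brute-force oracle on all 128 patterns", {
  tr <- species_tree7()
  tips <- tr$tip.label
  for (code in 0:127) {
    states <- setNames(ifelse(bitwAnd(code, 2^(0:6)) > 0, "A", "C"), tips)
    got <- assign_splicing_age(states, tr)
    oracle <- oracle_single_change(states, tr)
    if (oracle$uniform) {
      expect_true(got$label %in% c("VCA", "VCC"), info = code)
    } else if (length(oracle$scenarios) == 0L) {
      expect_equal(got$label, "complex", info = code)
    } else {
      expect_false(got$label %in% c("complex", "VCA", "VCC", "unassignable"),
                   info = code)
      # the scenario sets must match exactly
      key <- function(s) paste(s$direction, paste(s$clade, collapse = ","))
      expect_setequal(vapply(got$scenarios, key, character(1L)),
                      vapply(oracle$scenarios, key, character(1L)))
    }
  }
})

test_that("A/C relabelling swaps gains and losses symmetrically", {
  tr <- species_tree7()
  tips <- tr$tip.label
  swap <- c(A = "C", C = "A")
  set.seed(31)
  for (i in 1:40) {
    states <- setNames(sample(c("A", "C"), 7L, replace = TRUE), tips)
    a1 <- assign_splicing_age(states, tr)
    a2 <- assign_splicing_age(setNames(swap[states], tips), tr)
    map <- c(VCA = "VCC", VCC = "VCA", MCA = "MCC", MCC = "MCA",
             complex = "complex")
    if (a1$label %in% names(map)) {
      expect_equal(a2$label, unname(map[a1$label]))
    } else {
      expect_equal(sub("_gain$", "", sub("_loss$", "", a2$label)),
                   sub("_gain$", "", sub("_loss$", "", a1$label)))
      expect_false(endsWith(a1$label, sub("^.*_", "_", a2$label)))
    }
  }
})

test_that("simulated single-change histories are recovered", {
  tr <- species_tree7()
  for (i in 1:60) {
    h <- simulate_evolutionary_history(tr, gain_prob = 0.15, loss_prob = 0.1,
                                       constrain_single_change = TRUE,
                                       seed = i)
    got <- assign_splicing_age(h$states, tr)
    if (h$n_flips == 0L) {
      expect_equal(got$label, "VCC", info = i)
    } else {
      f <- h$flips[[1L]]
      key <- paste(f$direction, paste(sort(f$clade), collapse = ","))
      keys <- vapply(got$scenarios, function(s)
        paste(s$direction, paste(s$clade, collapse = ",")), character(1L))
      expect_true(key %in% keys, info = i)
    }
  }
})

test_that("entropy correlation, arg-max species and trends behave", {
  expect_equal(pairwise_entropy_correlation(1:10, 1:10)$rho, 1)
  expect_equal(pairwise_entropy_correlation(1:10, 10:1)$rho, -1)
  expect_false(pairwise_entropy_correlation(c(1, 2), c(2, 1))$defined)

  e <- c(human = 2.2, mouse = 1.0, chicken = 0.8)
  expect_equal(max_entropy_species(e), "human")
  expect_true(is.na(max_entropy_species(c(human = 2.2, mouse = 1.5))))
  expect_true(is.na(max_entropy_species(c(a = 2, b = 2, c = 0.5))))

  expect_equal(monotonic_entropy_trend(c(0.2, 0.5, 0.9, 1.4)), "increase")
  expect_equal(monotonic_entropy_trend(rep(1, 4L)), "none")
  expect_equal(monotonic_entropy_trend(c(1.4, 0.9, 1.0, 0.2)), "none")
  expect_equal(monotonic_entropy_trend(c(1.4, 0.9, 0.2)), "decrease")
})

test_that("entropy similarity decays with simulated divergence", {
  # divergence-scaled noise: farther species get noisier entropies
  set.seed(11)
  base <- runif(300, 0, 2)
  noise <- c(0.1, 0.5, 1.5)
  rhos <- vapply(noise, function(s)
    pairwise_entropy_correlation(base, base + rnorm(300, 0, s))$rho,
    numeric(1L))
  expect_true(all(diff(rhos) < 0))
})

test_that("age-group summaries compute per-group ratios", {
  labels <- c("old", "old", "young", "young", "empty")
  m <- rbind(c(2.0, 1.5, NA), c(1.2, 0.5, 0.1), c(0.2, 0.3, 0.4),
             c(0.9, NA, NA), c(NA, NA, NA))
  s <- age_group_summaries(labels, m)
  old <- s[s$group == "old", ]
  expect_equal(old$high_ratio, 1.0)       # both maxima >= 1
  expect_equal(old$range_ratio, 0.5)      # only the second spans >= 1
  young <- s[s$group == "young", ]
  expect_equal(young$high_ratio, 0.0)
  expect_equal(young$range_ratio, 0.0)    # single-tissue event contributes 0
  expect_true(is.na(s[s$group == "empty", "high_ratio"]))
})
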