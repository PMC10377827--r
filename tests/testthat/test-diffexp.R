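mk_profile <- function(dct, id = "p", method = "global_mean") {
  structure(list(id = id, method = method, reference_value = 25,
                 dct = dct, n_detected = length(dct)),
            class = "normalized_profile")
}

test_that("delta-delta-Ct subtracts reference delta-Ct and flags missing assays", {
  t <- mk_profile(c(A = 3, B = 1), "t2d")
  r <- mk_profile(c(A = 5, C = 2), "ctrl")
  dd <- delta_delta_ct(t, r)
  expect_equal(dd$ddct[dd$mirna == "A"], -2)
  expect_false(dd$evaluable[dd$mirna == "B"])   # undetected in reference
  expect_false(dd$evaluable[dd$mirna == "C"])

  expect_error(delta_delta_ct(t, mk_profile(c(A = 5), method = "spike_in")),
               "different methods")
})

test_that("delta-delta-Ct is additive across the three contrasts of a cohort", {
  eff <- balanced_effects()
  sim <- simulate_cohort(recovery_sim_config(effects = eff), seed = 13)
  profs <- normalize_matrix(pool_cohort(sim$ct, sim$panel), sim$panel)
  tg <- sim$panel$targets
  d_ifg  <- delta_delta_ct(profs$IFG, profs$control, tg)$ddct
  d_t2d  <- delta_delta_ct(profs$T2D, profs$control, tg)$ddct
  d_prog <- delta_delta_ct(profs$T2D, profs$IFG, tg)$ddct
  expect_equal(d_prog, d_t2d - d_ifg, tolerance = 1e-9)
})

test_that("fold regulation follows the signed convention", {
  fr <- fold_regulation(c(-1, 1, 0))
  expect_equal(fr$fold_change, c(2, 0.5, 1))
  expect_equal(fr$fold_regulation, c(2, -2, 1))

  # inversion of the convention at a published magnitude
  expect_equal(fold_regulation(-log2(124.8))$fold_regulation, 124.8)

  set.seed(20)
  dd <- runif(200, -9, 9)
  f <- fold_regulation(dd)
  expect_true(all(f$fold_change > 0))
  expect_true(all(abs(f$fold_regulation) >= 1))
  expect_equal(f$fold_change * 2^dd, rep(1, 200), tolerance = 1e-12)
  # antisymmetry over reversed contrasts
  g <- fold_regulation(-dd)
  flip <- f$fold_change != 1
  expect_equal(g$fold_regulation[flip], -f$fold_regulation[flip])
  expect_equal(g$fold_regulation[!flip], f$fold_regulation[!flip])
})

test_that("classification applies inclusive thresholds at printed precision", {
  rec <- classify_contrast(rec_df(letters[1:5], c(1.99, 2, -2, -1.99, NA)))
  expect_equal(as.character(rec$label),
               c("unchanged", "up", "down", "unchanged", "not_evaluable"))

  # monotone: raising the threshold never adds up/down members
  fr <- c(seq(-30, 30, by = 0.7), 2, -2, 10)
  recs <- rec_df(paste0("m", seq_along(fr)), fr)
  up2 <- recs$mirna[classify_contrast(recs, 2)$label == "up"]
  up5 <- recs$mirna[classify_contrast(recs, 5)$label == "up"]
  dn2 <- recs$mirna[classify_contrast(recs, 2)$label == "down"]
  dn5 <- recs$mirna[classify_contrast(recs, 5)$label == "down"]
  expect_true(all(up5 %in% up2))
  expect_true(all(dn5 %in% dn2))
})

test_that("high-stringency rule selects |FR| at or above the cut-off in any contrast", {
  a <- rec_df(c("x", "y"), c(12, 9.9))
  s <- high_stringency_set(list(a = a), threshold = 10)
  expect_identical(s$members, "x")

  s1 <- high_stringency_set(list(a = a), threshold = 1)
  expect_setequal(s1$members, c("x", "y"))

  b <- rec_df(c("x", "y"), c(1.2, -15))
  s2 <- high_stringency_set(list(a = a, b = b), threshold = 10)
  expect_setequal(s2$members, c("x", "y"))

  expect_error(high_stringency_set(list()), "at least one")
})

test_that("18 over-expressed miRNAs reach fold regulation 10 in the IFG table", {
  fx <- packaged_fixtures()$ifg_vs_control
  over <- fx[fx$fold_regulation > 0, ]
  s <- high_stringency_set(list(ifg = over), threshold = 10)
  expect_length(s$members, 18)
})

test_that("progression rule demands a strict increase with a floor", {
  ifg <- rec_df(c("a", "b", "c"), c(5, 5, 7.85))
  t2d <- rec_df(c("a", "b", "c"), c(9, 5, 14.9))
  s <- progression_signature(ifg, t2d)
  expect_setequal(s$members, c("a", "c"))    # b fails strict inequality

  # floor on the overt-condition fold regulation
  s2 <- progression_signature(rec_df("d", 1.1), rec_df("d", 1.5))
  expect_length(s2$members, 0)

  expect_error(progression_signature(ifg, t2d[0, ]), NA)  # empty is legal
})

test_that("noiseless simulation recovers the planted progression set exactly", {
  eff <- balanced_effects()
  sim <- simulate_cohort(recovery_sim_config(effects = eff, noise_sd = 0,
                                             offset_sd = 0.3), seed = 21)
  fit <- mirct_fit(sim$ct, sim$panel, reference = "control")
  expect_setequal(fit$signatures$progression$members,
                  eff$mirna[eff$T2D > 0])
})

test_that("condition-specific rule selects regulation unique to the focal group", {
  focal <- rec_df(c("hsa-miR-1225-3p", "hsa-miR-146a-5p", "z"),
                  c(3.62, -2.64, 2.5))
  other <- rec_df(c("hsa-miR-1225-3p", "hsa-miR-146a-5p", "z"),
                  c(1.9, -1.3, 2.5))
  s <- condition_specific_set(focal, other)
  expect_setequal(s$members, c("hsa-miR-1225-3p", "hsa-miR-146a-5p"))
  ev <- s$evidence[match(s$members, s$evidence$mirna), ]
  expect_identical(ev$direction, c("up", "down"))

  # absent in the other contrast counts as unchanged
  s2 <- condition_specific_set(rec_df("w", 4), rec_df("v", 3))
  expect_identical(s2$members, "w")
})

test_that("normalization concordance measures label and sign agreement", {
  a <- classify_contrast(rec_df(paste0("m", 1:10), c(3, 4, -3, 2.5, 1.2, -5, 6, -2.2, 1.5, 12)))
  r <- normalization_concordance(list(global_mean = a, reference_genes = a))
  expect_equal(r$label_agreement, 1)
  expect_equal(r$sign_agreement, 1)

  b <- a
  b$fold_regulation[1] <- -3; b <- classify_contrast(b)
  r2 <- normalization_concordance(list(global_mean = a, reference_genes = b))
  expect_equal(r2$sign_agreement, 0.9)

  # oracle comparison on random labellings
  set.seed(31)
  fr1 <- runif(40, 1, 20) * sample(c(-1, 1), 40, TRUE)
  fr2 <- fr1 * exp(rnorm(40, 0, 0.3)) * sample(c(-1, 1), 40, TRUE, c(0.1, 0.9))
  c1 <- classify_contrast(rec_df(paste0("m", 1:40), fr1))
  c2 <- classify_contrast(rec_df(paste0("m", 1:40), fr2))
  r3 <- normalization_concordance(list(global_mean = c1, spike_in = c2))
  expect_equal(r3$sign_agreement, mean(sign(fr1) == sign(fr2)))
  expect_equal(r3$label_agreement,
               mean(as.character(c1$label) == as.character(c2$label)))
  expect_equal(r3$n_baseline_not_larger, sum(abs(fr1) <= abs(fr2)))
})
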