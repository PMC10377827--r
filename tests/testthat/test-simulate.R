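test_that("null model yields identical samples and unit fold regulation", {
  cfg <- sim_config(noise_sd = 0, offset_sd = 0)
  sim <- simulate_cohort(cfg, seed = 1)
  m <- unclass(sim$ct)
  expect_true(all(apply(m, 1, function(r) length(unique(r[!is.na(r)])) <= 1)))

  fit <- mirct_fit(sim$ct, sim$panel, reference = "control")
  fr <- coef(fit)
  expect_true(all(fr[!is.na(fr)] == 1))
})

test_that("a planted effect of +3 log2 units yields pooled fold regulation +8", {
  eff <- data.frame(mirna = "sim-miR-0001", IFG = 0, T2D = 3)
  # pair the effect with a balancing one so the global mean is unmoved
  eff <- rbind(eff, data.frame(mirna = "sim-miR-0002", IFG = 0, T2D = -3))
  sim <- simulate_cohort(recovery_sim_config(effects = eff, noise_sd = 0,
                                             offset_sd = 0), seed = 1)
  fit <- mirct_fit(sim$ct, sim$panel, reference = "control")
  fr <- coef(fit)
  expect_equal(fr["sim-miR-0001", "T2D_vs_control"], 8, tolerance = 1e-9)
  expect_equal(fr["sim-miR-0002", "T2D_vs_control"], -8, tolerance = 1e-9)
})

test_that("a seed fully determines the simulated cohort", {
  cfg <- sim_config()
  a <- simulate_cohort(cfg, seed = 1)
  b <- simulate_cohort(cfg, seed = 1)
  c <- simulate_cohort(cfg, seed = 2)
  expect_identical(unclass(a$ct), unclass(b$ct))
  expect_identical(a$truth$offsets, b$truth$offsets)
  expect_false(identical(unclass(a$ct), unclass(c$ct)))
})

test_that("equimolar pooling averages on the linear scale", {
  pan <- tiny_panel()
  ct <- tiny_ct(list(s1 = c("hsa-miR-23a-3p" = 20, "hsa-miR-451a" = 20,
                            "hsa-miR-195-5p" = NA),
                     s2 = c("hsa-miR-23a-3p" = 22, "hsa-miR-451a" = 20,
                            "hsa-miR-195-5p" = 25)),
                c("g", "g"), panel = pan)
  pooled <- pool_samples(ct, "g")
  expect_equal(pooled[["hsa-miR-451a"]], 20)                 # identical inputs
  expect_equal(pooled[["hsa-miR-23a-3p"]],
               -log2((2^-20 + 2^-22) / 2), tolerance = 1e-12)
  expect_equal(round(pooled[["hsa-miR-23a-3p"]], 3), 20.678)
  expect_equal(pooled[["hsa-miR-195-5p"]], 25)               # one sample missing
  expect_equal(attr(pooled, "coverage")[["hsa-miR-195-5p"]], 0.5)

  expect_error(pool_samples(ct, "nope"), "no samples")
})

test_that("pooled Ct lies between the per-sample extremes", {
  sim <- simulate_cohort(sim_config(groups = c(g = 8)), seed = 17)
  pooled <- pool_samples(sim$ct, "g")
  m <- unclass(sim$ct)
  for (a in sample(rownames(m), 50)) {
    v <- m[a, ][!is.na(m[a, ])]
    if (length(v)) {
      expect_gte(pooled[[a]] + 1e-9, min(v))
      expect_lte(pooled[[a]] - 1e-9, max(v))
    } else {
      expect_true(is.na(pooled[[a]]))
    }
  }
})

test_that("hemolysis injection shifts only miR-451a and is caught by QC", {
  prof <- c("hsa-miR-23a-3p" = 26, "hsa-miR-451a" = 23, "hsa-miR-195-5p" = 28)
  pan <- tiny_panel()
  h0 <- hemolysis_index(prof, pan)
  expect_equal(h0$delta_ct, 3); expect_true(h0$pass)

  contaminated <- inject_hemolysis(prof, 6)
  expect_equal(contaminated[["hsa-miR-451a"]], 17)
  expect_equal(contaminated[["hsa-miR-195-5p"]], 28)
  h1 <- hemolysis_index(contaminated, pan)
  expect_equal(h1$delta_ct, 9); expect_false(h1$pass)

  expect_identical(inject_hemolysis(prof, 0), prof)
  expect_error(inject_hemolysis(prof[-2], 3), "absent")
})

test_that("contaminated cohort samples are flagged with full sensitivity and specificity", {
  bad <- c("control_02", "IFG_05", "IFG_07", "T2D_10")
  cfg <- sim_config(hemolysis = list(samples = bad, shift = 6))
  sim <- simulate_cohort(cfg, seed = 23)
  q <- qc_report(sim$ct, sim$panel)
  expect_setequal(q$sample[!q$hemolysis_pass], bad)
})

test_that("global-mean results are invariant to per-sample offsets of any size", {
  # moderate effect sizes keep every assay well inside the detection window,
  # so the offset magnitude is the only thing that changes between runs
  e <- c(seq(0.5, 3, length.out = 10), -seq(0.5, 3, length.out = 10))
  eff <- data.frame(mirna = sprintf("sim-miR-%04d", seq_along(e)),
                    IFG = 0.5 * e, T2D = e)
  base <- recovery_sim_config(effects = eff, noise_sd = 0, offset_sd = 0)
  big <- recovery_sim_config(effects = eff, noise_sd = 0, offset_sd = 3)
  sim0 <- simulate_cohort(base, seed = 5)
  sim1 <- simulate_cohort(big, seed = 5)
  fr0 <- coef(mirct_fit(sim0$ct, sim0$panel, reference = "control"))
  fr1 <- coef(mirct_fit(sim1$ct, sim1$panel, reference = "control"))
  expect_equal(fr0, fr1, tolerance = 1e-9)
})
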