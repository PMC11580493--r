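profile_from_calls <- function(calls, id = "p") {
  # synthesize log2 ratios consistent with the requested calls
  log2r <- ifelse(calls > 0, 0.3, ifelse(calls < 0, -0.3, 0))
  profile_from_log2(log2r, sample_id = id)
}

test_that("profile comparison partitions the union of aberrant bins", {
  a <- profile_from_calls(c(1, 1, -1, 0, 0), "a")
  b <- profile_from_calls(c(1, 0, 1, -1, 0), "b")
  cc <- compare_profiles(a, b)
  expect_equal(cc$shared, 1)
  expect_equal(cc$private_a, 1)
  expect_equal(cc$private_b, 1)
  expect_equal(cc$discordant_direction, 1)
  expect_equal(cc$union, 4)
  expect_equal(cc$shared + cc$private_a + cc$private_b + cc$discordant_direction,
               cc$union)
  expect_equal(cc$shared_fraction + cc$private_a_fraction +
                 cc$private_b_fraction + cc$discordant_fraction, 1)

  # identical profiles: fully shared
  ident <- compare_profiles(a, a)
  expect_equal(ident$shared_fraction, 1)
  expect_equal(ident$private_a + ident$private_b, 0)

  # all aberration on one side
  n <- profile_from_calls(rep(0, 12), "n")
  t7 <- profile_from_calls(c(rep(1, 7), rep(0, 5)), "t")
  one <- compare_profiles(n, t7)
  expect_equal(one$shared, 0)
  expect_equal(one$private_b, 7)
  expect_equal(one$private_b_fraction, 1)

  expect_error(compare_profiles(a, profile_from_calls(rep(0, 7))), "same bin grid")
})

test_that("comparison is symmetric with a/b labels exchanged", {
  set.seed(99)
  for (i in 1:20) {
    a <- profile_from_calls(sample(c(-1, 0, 1), 50, replace = TRUE), "a")
    b <- profile_from_calls(sample(c(-1, 0, 1), 50, replace = TRUE), "b")
    ab <- compare_profiles(a, b)
    ba <- compare_profiles(b, a)
    expect_equal(ab$shared, ba$shared)
    expect_equal(ab$private_a, ba$private_b)
    expect_equal(ab$private_b, ba$private_a)
    expect_equal(ab$discordant_direction, ba$discordant_direction)
  }
})

test_that("serial profiles from the same truth are stable across seeds", {
  grid <- annotated_hg19_grid()
  profs <- lapply(c(21, 22), function(s) {
    cnt <- simulate_counts(sim_spec(template_profile("gbm_7p10q"), 0.4, seed = s), grid)
    run_sample(cnt, grid)$profile
  })
  st <- longitudinal_stability(profs)
  expect_gte(st$min_shared_fraction, 0.8)

  # technical replicate: identical input, identical profile
  rep2 <- longitudinal_stability(list(profs[[1]], profs[[1]]))
  expect_equal(rep2$min_shared_fraction, 1)

  expect_error(longitudinal_stability(profs[1]), "at least two")
})

test_that("arm calls aggregate bin calls at the 60% threshold", {
  grid <- annotated_hg19_grid()
  arms <- hg19_arm_table()

  # all 1p bins deleted -> 1p loss
  log2r <- rep(0, nrow(grid))
  onep <- grid$chrom == "1" & (grid$start + grid$end) / 2 < 121535434
  log2r[onep] <- -0.3
  p <- profile_from_log2(log2r)
  p$scored <- grid$usable & is_autosome(grid)
  ac <- arm_calls(p, grid, arms)
  expect_equal(ac$state[ac$arm == "1p"], "loss")
  expect_true(all(ac$state[ac$arm != "1p"] == "neutral"))

  # neutral profile: every arm neutral
  ac0 <- arm_calls(profile_from_log2(rep(0, nrow(grid))), grid, arms)
  expect_true(all(ac0$state == "neutral"))

  # 50% of arm bins below a 0.6 threshold stays neutral
  idx <- which(onep)
  log2r2 <- rep(0, nrow(grid))
  log2r2[idx[seq_len(floor(length(idx) / 2))]] <- -0.3
  ac2 <- arm_calls(profile_from_log2(log2r2), grid, arms)
  expect_equal(ac2$state[ac2$arm == "1p"], "neutral")

  expect_error(arm_calls(p, grid, arms[arms$chrom != "5", ]), "5")
})

test_that("diagnostic flags fire on their templates and stay quiet otherwise", {
  grid <- annotated_hg19_grid()
  arms_tab <- hg19_arm_table()
  regions <- cdkn2ab_region()
  flags_for <- function(template, f, seed) {
    cnt <- simulate_counts(sim_spec(template_profile(template), f, seed = seed), grid)
    run_sample(cnt, grid, arm_table = arms_tab, regions = regions)$flags
  }

  fg <- flags_for("gbm_7p10q", 0.4, 1)
  expect_true(fg$plus7_minus10)
  expect_false(fg$codel_1p19q)
  expect_false(fg$cdkn2ab_homdel)

  fo <- flags_for("oligo_1p19q", 0.5, 2)
  expect_true(fo$codel_1p19q)
  expect_false(fo$plus7_minus10)

  fh <- flags_for("cdkn2ab_homdel", 0.6, 3)
  expect_true(fh$cdkn2ab_homdel)
  expect_equal(nrow(fh$focal_amplifications), 0L)

  fa <- flags_for("focal_amp", 0.4, 4)
  expect_equal(nrow(fa$focal_amplifications), 1L)
  expect_equal(fa$focal_amplifications$chrom, "12")
  expect_gt(fa$focal_amplifications$max_log2, 0.58)

  fn <- flags_for("neutral", 0, 5)
  expect_false(fn$plus7_minus10 || fn$codel_1p19q || fn$cdkn2ab_homdel || fn$del_6q)
  expect_equal(nrow(fn$focal_amplifications), 0L)

  # flags are deterministic re-runs of the same profile
  expect_identical(unclass(flags_for("gbm_7p10q", 0.4, 1)),
                   unclass(flags_for("gbm_7p10q", 0.4, 1)))

  # missing region input -> NA flag with warning
  cnt <- simulate_counts(sim_spec(template_profile("neutral"), 0, seed = 6), grid)
  res <- run_sample(cnt, grid)
  ac <- arm_calls(res$profile, grid, arms_tab)
  expect_warning(f_na <- diagnostic_flags(ac, res$profile, grid, regions = NULL),
                 "region")
  expect_true(is.na(f_na$cdkn2ab_homdel))
})

test_that("each template's designated flag is specific across seeds", {
  grid <- annotated_hg19_grid()
  arms_tab <- hg19_arm_table()
  regions <- cdkn2ab_region()
  cases <- list(gbm_7p10q = 0.4, oligo_1p19q = 0.4, lymphoma_6q = 0.4,
                cdkn2ab_homdel = 0.6, focal_amp = 0.6)
  designated <- c(gbm_7p10q = "plus7_minus10", oligo_1p19q = "codel_1p19q",
                  lymphoma_6q = "del_6q", cdkn2ab_homdel = "cdkn2ab_homdel",
                  focal_amp = "focal_amp")
  n_seeds <- 100
  for (tmpl in names(cases)) {
    hits <- matrix(FALSE, nrow = n_seeds, ncol = 5,
                   dimnames = list(NULL, c("plus7_minus10", "codel_1p19q",
                                           "cdkn2ab_homdel", "del_6q", "focal_amp")))
    for (s in seq_len(n_seeds)) {
      cnt <- simulate_counts(sim_spec(template_profile(tmpl), cases[[tmpl]],
                                      seed = derive_seed(2024, s)), grid)
      fl <- run_sample(cnt, grid, arm_table = arms_tab, regions = regions)$flags
      hits[s, ] <- c(fl$plus7_minus10, fl$codel_1p19q, fl$cdkn2ab_homdel,
                     fl$del_6q, nrow(fl$focal_amplifications) > 0)
    }
    rates <- colMeans(hits)
    expect_gte(rates[designated[tmpl]], 0.95)
    expect_true(all(rates[setdiff(colnames(hits), designated[tmpl])] <= 0.05))
  }
})
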