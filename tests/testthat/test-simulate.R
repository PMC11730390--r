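test_that("null subject with zero noise gives constant intensity at i0", {
  tr <- subject_truth(0, 0, base = 0, sign = "pos", seed = 1)
  rec <- simulate_subject(tr, noise = noise_off(), i0 = 2)
  expect_true(all(abs(rec$intensity - 2) < 1e-12))
})

test_that("nonpositive baseline intensity is a configuration error", {
  tr <- subject_truth(0.1, 0.1, seed = 1)
  expect_error(simulate_subject(tr, i0 = 0), "i0")
})

test_that("noise-free forward model is recovered by the inverse chain", {
  tr <- subject_truth(0.08, 0.04, sign = "pos", seed = 3)
  rec <- simulate_subject(tr, noise = noise_off())
  pp <- preprocess_recording(rec, config = preprocess_config(
    motion_correct = FALSE, filter_on = FALSE))
  truth <- attr(rec, "truth_conc")
  ep_t <- epoch_and_average(truth, attr(rec, "schedule"))
  for (cond in c("forward", "reverse")) {
    got <- pp$epochs$conditions[[cond]]$hbo
    want <- ep_t$conditions[[cond]]$hbo
    expect_lt(max(abs(got - want)) / max(abs(want)), 1e-6)
    got_r <- pp$epochs$conditions[[cond]]$hbr
    want_r <- ep_t$conditions[[cond]]$hbr
    expect_lt(max(abs(got_r - want_r)) / max(abs(want_r)), 1e-6)
  }
})

test_that("inverted responders are exact sign twins", {
  tr_pos <- subject_truth(0.08, 0.04, sign = "pos", seed = 4)
  tr_inv <- subject_truth(0.08, 0.04, sign = "inv", seed = 4)
  cfg <- preprocess_config(motion_correct = FALSE, filter_on = FALSE)
  ep_p <- preprocess_recording(simulate_subject(tr_pos, noise = noise_off()),
                               config = cfg)$epochs
  ep_i <- preprocess_recording(simulate_subject(tr_inv, noise = noise_off()),
                               config = cfg)$epochs
  expect_equal(ep_i$conditions$forward$hbo, -ep_p$conditions$forward$hbo,
               tolerance = 1e-9)
  # HbR flips oppositely to HbO
  expect_equal(ep_i$conditions$forward$hbr, -ep_p$conditions$forward$hbr,
               tolerance = 1e-9)
  expect_equal(response_sign(ep_p), "pos")
  expect_equal(response_sign(ep_i), "inv")
})

test_that("identical seeds give bit-identical recordings and cohorts", {
  tr <- subject_truth(0.1, 0.05, seed = 12)
  r1 <- simulate_subject(tr)
  r2 <- simulate_subject(tr)
  expect_identical(r1$intensity, r2$intensity)

  c1 <- simulate_cohort(3, 3, seed = 5, recordings = FALSE)
  c2 <- simulate_cohort(3, 3, seed = 5, recordings = FALSE)
  expect_identical(c1$cohort, c2$cohort)
})

test_that("cohort simulation matches the follow-up cohort shape", {
  sim <- simulate_cohort(26, 19, seed = 2, recordings = FALSE)
  expect_equal(nrow(sim$cohort), 45)
  expect_equal(sum(sim$cohort$group == "preterm"), 26)
  expect_equal(sum(sim$cohort$group == "term"), 19)
  expect_true(all(c("z_comprehension", "z_sentence", "z_morphology",
                    "z_stm") %in% names(sim$cohort)))
})

test_that("zero-variance truth distributions give identical amplitudes", {
  td <- cohort_truth_defaults(
    preterm = list(sp_l = c(0.1, 0), sp_r = c(0.05, 0)),
    term = list(sp_l = c(0.2, 0), sp_r = c(0.1, 0)))
  sim <- simulate_cohort(4, 4, truth_dist = td, seed = 3, recordings = FALSE)
  expect_true(all(sim$cohort$true_sp_l[sim$cohort$group == "preterm"] == 0.1))
  expect_true(all(sim$cohort$true_sp_l[sim$cohort$group == "term"] == 0.2))
})

test_that("invalid truth distribution parameters error", {
  expect_error(cohort_truth_defaults(preterm = list(sp_l = c(0.1, -1),
                                                    sp_r = c(0.1, 0.1))),
               "sd")
})

test_that("designed group difference in true SP emerges with n", {
  sim <- simulate_cohort(400, 400, seed = 9, recordings = FALSE)
  m <- tapply(sim$cohort$true_sp_l, sim$cohort$group, mean)
  expect_gt(m[["term"]], m[["preterm"]])
})

test_that("outcome generator honors its coupling contract", {
  # zero noise, positive slope: perfect rank correlation
  m0 <- outcome_model(slope = 1, noise_sd = 0)
  li <- runif(50, -100, 100)
  out <- generate_outcomes(li, "term", m0, seed = 1)
  expect_equal(cor(li, out$z_stm, method = "spearman"), 1)

  # zero slope: no correlation at large n
  mnull <- outcome_model(slope = 0, noise_sd = 1)
  li <- runif(5000, -100, 100)
  out <- generate_outcomes(li, "term", mnull, seed = 2)
  expect_lt(abs(cor(li, out$z_stm, method = "spearman")), 0.05)

  expect_error(generate_outcomes(150, model = m0), "true_li")
})

test_that("implied STM-laterality rank correlation is near its target", {
  rs <- implied_outcome_rank_cor(n = 5e4, seed = 42)
  expect_lt(abs(rs - outcome_model()$target_rs), 0.02)
})

test_that("sentence and morphology scores carry their design correlation", {
  li <- runif(20000, -100, 100)
  out <- generate_outcomes(li, "term", outcome_model(), seed = 4)
  rs <- cor(out$z_sentence, out$z_morphology, method = "spearman")
  expect_lt(abs(rs - 0.52), 0.03)
  # comprehension independent of laterality by default
  expect_lt(abs(cor(li, out$z_comprehension, method = "spearman")), 0.05)
})
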