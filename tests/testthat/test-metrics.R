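test_that("condition means reduce to the designed constants", {
  ep <- make_epochs(fwd = c(1, 1, 1, 1), rev = c(0, 0, 0, 0))
  cm <- condition_mean(ep)
  expect_true(all(cm[, "forward"] == 1))
  expect_true(all(cm[, "reverse"] == 0))

  ep0 <- make_epochs(fwd = numeric(4), rev = numeric(4))
  expect_true(all(condition_mean(ep0) == 0))

  expect_error(condition_mean(ep, channels = 99), "channel")
})

test_that("condition mean matches a loop-based oracle on random epochs", {
  set.seed(17)
  layout <- probe_layout(n_channels = 4)
  time_s <- seq(-2, 24.9, by = 0.1)
  n <- length(time_s)
  mk <- function() list(hbo = matrix(rnorm(n * 4), n, 4),
                        hbr = matrix(rnorm(n * 4), n, 4))
  ep <- structure(list(conditions = list(forward = mk(), reverse = mk()),
                       time_s = time_s,
                       n_trials = c(forward = 10L, reverse = 10L),
                       n_total = c(forward = 10L, reverse = 10L),
                       channel_id = layout$channel_id, layout = layout,
                       fs = 10, rejected = logical(20), notes = character()),
                  class = "epoch_average")
  cm <- condition_mean(ep, response_window = c(0, 25))
  for (ch in 1:4) {
    acc <- 0; k <- 0
    for (i in seq_along(time_s)) if (time_s[i] >= 0 && time_s[i] < 25) {
      acc <- acc + ep$conditions$forward$hbo[i, ch]; k <- k + 1
    }
    expect_equal(cm[ch, "forward"], acc / k, tolerance = 1e-12)
  }
})

test_that("SP metrics follow the channel-mean-first aggregation", {
  # 4-channel toy: per-channel forward-reverse differences
  # L: +0.2, +0.1 -> mean 0.15; R: -0.1, +0.1 -> mean 0.0
  ep <- make_epochs(fwd = c(0.2, 0.1, -0.1, 0.1), rev = c(0, 0, 0, 0))
  s <- speech_discrimination(ep)
  expect_equal(s$sp_l, 0.15)
  expect_equal(s$sp_r, 0)
  expect_equal(s$sp, abs(mean(c(0.2, 0.1, -0.1, 0.1))))

  # identical conditions give zero
  epz <- make_epochs(fwd = c(1, 2, 3, 4), rev = c(1, 2, 3, 4))
  sz <- speech_discrimination(epz)
  expect_equal(c(sz$sp, sz$sp_l, sz$sp_r), c(0, 0, 0))

  # swapping condition labels leaves absolute metrics unchanged
  ep_sw <- make_epochs(fwd = c(0, 0, 0, 0), rev = c(0.2, 0.1, -0.1, 0.1))
  s_sw <- speech_discrimination(ep_sw)
  expect_equal(s_sw$sp_l, s$sp_l)
  expect_equal(s_sw$sp_r, s$sp_r)
  expect_equal(s_sw$sp, s$sp)
})

test_that("signed metrics are algebraic twins of the absolute ones", {
  set.seed(18)
  for (k in 1:20) {
    fwd <- rnorm(4); rev <- rnorm(4)
    ep <- make_epochs(fwd, rev)
    s <- speech_discrimination(ep)
    g <- signed_discrimination(ep)
    expect_equal(abs(g$signed_sp), s$sp, tolerance = 1e-12)
    expect_equal(abs(g$signed_sp_l), s$sp_l, tolerance = 1e-12)
    expect_equal(abs(g$signed_sp_r), s$sp_r, tolerance = 1e-12)
  }
  # pos / inv twins have opposite-signed equal-magnitude metrics
  ep_p <- make_epochs(c(0.3, 0.2, 0.1, 0.2), c(0.1, 0.1, 0.1, 0.1))
  ep_i <- make_epochs(-c(0.3, 0.2, 0.1, 0.2), -c(0.1, 0.1, 0.1, 0.1))
  gp <- signed_discrimination(ep_p); gi <- signed_discrimination(ep_i)
  expect_equal(gp$signed_sp, -gi$signed_sp)
})

test_that("laterality index reproduces its formula and endpoints", {
  expect_equal(laterality_index(0.2, 0), 100)
  expect_equal(laterality_index(0, 0.2), -100)
  expect_equal(laterality_index(0.3, 0.3), 0)
  # independent hand evaluation of ((L-R)/(L+R))*100
  expect_equal(laterality_index(0.17, 0.15), 6.25, tolerance = 1e-10)
  expect_error(laterality_index(-0.1, 0.2), ">= 0")
  li0 <- laterality_index(0, 0)
  expect_true(is.na(li0))
  expect_true(isTRUE(attr(li0, "undefined")))
})

test_that("laterality index obeys antisymmetry, scale invariance and bounds", {
  set.seed(19)
  for (k in 1:200) {
    a <- runif(1, 0, 1); b <- runif(1, 0, 1); kf <- runif(1, 0.01, 50)
    expect_equal(laterality_index(a, b), -laterality_index(b, a),
                 tolerance = 1e-12)
    expect_equal(laterality_index(kf * a, kf * b), laterality_index(a, b),
                 tolerance = 1e-9)
    li <- laterality_index(a, b)
    expect_gte(li, -100); expect_lte(li, 100)
    if (abs(li) == 100) expect_true(a == 0 || b == 0)
  }
  expect_equal(abs(laterality_index(0.4, 0)), 100)
})

test_that("response sign classifies by the forward-condition mean", {
  ep_pos <- make_epochs(c(0.1, 0.1, 0.1, 0.1), numeric(4))
  ep_inv <- make_epochs(-c(0.1, 0.1, 0.1, 0.1), numeric(4))
  expect_equal(response_sign(ep_pos), "pos")
  expect_equal(response_sign(ep_inv), "inv")
  amb <- response_sign(make_epochs(numeric(4), numeric(4)))
  expect_equal(as.character(amb), "pos")
  expect_true(isTRUE(attr(amb, "ambiguous")))
})

test_that("sign classification recovers designed labels on a noisy cohort", {
  set.seed(20)
  n <- 20
  signs <- rep(c("pos", "inv"), each = n / 2)
  hit <- logical(n)
  for (i in seq_len(n)) {
    tr <- subject_truth(0.1, 0.1, base = 0.1, sign = signs[i], seed = 600 + i)
    pp <- preprocess_recording(simulate_subject(tr))
    hit[i] <- identical(as.character(response_sign(pp$epochs)), signs[i])
  }
  expect_gte(mean(hit), 0.95)
})
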