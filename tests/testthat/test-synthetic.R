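test_that("clamp generator is deterministic and respects its ground truth", {
  d1 <- gen_clamp_dataset(noise_sd_pA = 20, seed = 42)
  d2 <- gen_clamp_dataset(noise_sd_pA = 20, seed = 42)
  expect_identical(d1, d2)
  d3 <- gen_clamp_dataset(noise_sd_pA = 20, seed = 43)
  expect_false(identical(d1$i_nA, d3$i_nA))
  # noiseless current at step onset and steady state follow the truth
  d0 <- gen_clamp_dataset()
  truth <- attr(d0, "truth")
  s1 <- d0[d0$step == 1, ]
  g1 <- hcn_steady_state(-65, truth$v_half, truth$s, truth$g_max_nS)
  i0 <- (truth$g_leak_nS * (s1$v2[1] + 65) + g1 * (s1$v2[1] + 35)) / 1000
  expect_equal(s1$i_nA[1], i0, tolerance = 1e-9)
})

test_that("loom spike-train generator has the programmed count structure", {
  tr <- gen_loom_trains(c(0, 50, 100), n_trials = 30, intercept = 5,
                        slope = 0.24, seed = 1)
  win <- attr(tr, "window_ms")
  expect_true(all(tr$time_ms >= win[1] & tr$time_ms <= win[2]))
  counts <- count_loom_trains(tr)
  expect_equal(nrow(counts), 90)
  expect_true(all(counts$spike_count >= 0))
  # expected counts near intercept + slope * coherence
  m <- tapply(counts$spike_count, counts$coherence, mean)
  expect_equal(unname(m["0"]), 5, tolerance = 0.35)
  expect_equal(unname(m["100"]), 29, tolerance = 0.15)
  # identical seeds give identical trains
  expect_identical(gen_loom_trains(50, 5, seed = 9),
                   gen_loom_trains(50, 5, seed = 9))
})

test_that("zero programmed slope yields no coherence dependence", {
  tr <- gen_loom_trains(c(0, 25, 50, 75, 100), n_trials = 30, intercept = 12,
                        slope = 0, seed = 3)
  cp <- coherence_preference(count_loom_trains(tr))
  expect_lt(abs(cp$slope), 2 * cp$slope_se + 1e-9)
})

test_that("rate profile rises toward collision and truncates there", {
  tr <- gen_loom_trains(100, n_trials = 200, intercept = 40, slope = 0,
                        seed = 4)
  win <- attr(tr, "window_ms")
  early <- sum(tr$time_ms < win[2] / 2)
  late <- sum(tr$time_ms >= win[2] / 2)
  expect_gt(late, early * 3)
  expect_lte(max(tr$time_ms), win[2])
})

test_that("negative-binomial dispersion widens trial counts", {
  t1 <- gen_loom_trains(100, n_trials = 200, intercept = 20, slope = 0,
                        dispersion = 0, seed = 5)
  t2 <- gen_loom_trains(100, n_trials = 200, intercept = 20, slope = 0,
                        dispersion = 3, seed = 5)
  v1 <- stats::var(count_loom_trains(t1)$spike_count)
  v2 <- stats::var(count_loom_trains(t2)$spike_count)
  expect_gt(v2, 1.8 * v1)
})

test_that("toy morphologies are reproducible labeled trees", {
  for (kind in c("fan", "rall_symmetric", "asymmetric")) {
    m <- gen_toy_morphology(kind, seed = 2)
    expect_s3_class(m, "neuron_morphology")
    expect_setequal(unique(m$region), c("axon", "SIZ", "trunk", "fieldA"))
    expect_gte(nrow(m), 10)
  }
  expect_identical(gen_toy_morphology("asymmetric", seed = 7),
                   gen_toy_morphology("asymmetric", seed = 7))
  # the rall tree satisfies the 3/2 rule at every branch point
  m <- gen_toy_morphology("rall_symmetric", n_branches = 8)
  kids <- split(seq_len(nrow(m)), m$parent)
  for (p in names(kids)) {
    if (p == "0") next
    ch <- kids[[p]]
    ch <- ch[m$region[ch] == "fieldA"]
    if (length(ch) == 2 && m$region[as.integer(p)] == "fieldA" &&
        m$diam_um[ch[1]] != m$diam_um[as.integer(p)]) {
      expect_equal(sum(m$diam_um[ch]^1.5), m$diam_um[as.integer(p)]^1.5,
                   tolerance = 1e-9)
    }
  }
})
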