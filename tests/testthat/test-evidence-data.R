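test_that("log hazard ratios and standard errors are recovered from printed CIs", {
  # J-ALEX PFS row: 0.37 (0.26-0.52); ln(0.52/0.26)/(2*1.959964)
  r <- derive_log_hr(0.37, 0.26, 0.52)
  expect_lt(abs(r$log_effect - (-0.9943)), 1e-4)
  expect_lt(abs(r$se - 0.1768), 1e-4)
  # symmetric interval around 1
  r <- derive_log_hr(1.0, 0.5, 2.0)
  expect_equal(r$log_effect, 0)
  expect_equal(r$se, log(4) / (2 * qnorm(0.975)), tolerance = 1e-10)

  expect_error(derive_log_hr(0.5, 0.6, 0.7), "inside")
  expect_error(derive_log_hr(0.5, 0.7, 0.6), "exceeds")
  expect_error(derive_log_hr(0.5, 0.5, 0.5), "zero-width")
  expect_error(derive_log_hr(-1, 0.5, 2), "positive")
})

test_that("derive_log_hr is consistent under reciprocal reorientation", {
  set.seed(42)
  for (i in 1:25) {
    lo <- runif(1, 0.1, 0.9); hi <- lo * exp(runif(1, 0.1, 2))
    hr <- exp(runif(1, log(lo), log(hi)))
    a <- derive_log_hr(hr, lo, hi)
    b <- derive_log_hr(1 / hr, 1 / hi, 1 / lo)
    expect_equal(b$log_effect, -a$log_effect)
    expect_equal(b$se, a$se)
  }
})

test_that("event counts are reconstructed by round-half-to-even", {
  expect_identical(reconstruct_events(92.23, 103), 95L)  # 94.997
  expect_identical(reconstruct_events(78.85, 104), 82L)  # 82.004
  expect_identical(reconstruct_events(0, 50), 0L)
  expect_identical(reconstruct_events(100, 50), 50L)
  expect_identical(reconstruct_events(50, 1), 0L)        # 0.5 -> even
  expect_identical(reconstruct_events(50, 3), 2L)        # 1.5 -> even
  expect_error(reconstruct_events(101, 10), "percent")
  expect_error(reconstruct_events(-1, 10), "percent")
})

test_that("networks are assembled with edge counts and connectivity checks", {
  one <- data.frame(trial = "T1", treat_ref = "A", treat_alt = "B",
                    log_effect = 0.1, se = 0.2)
  net <- build_network(one, outcome_spec("x", "contrast_loghr", "lower"))
  expect_s3_class(net, "evidence_network")
  expect_length(net$treatments, 2)
  expect_identical(nrow(net$edges), 1L)

  two <- rbind(one, data.frame(trial = "T2", treat_ref = "C",
                               treat_alt = "D", log_effect = 0, se = 0.2))
  expect_error(build_network(two, outcome_spec("x", "contrast_loghr", "lower")),
               "disconnected")
  expect_error(build_network(one, outcome_spec("x", "contrast_loghr", "lower"),
                             treatment_order = c("A", "C")),
               "unknown treatment")
  expect_error(build_network(transform(one, se = -1),
                             outcome_spec("x", "contrast_loghr", "lower")),
               "positive")
})

test_that("the bundled PFS network matches the published trial map", {
  net <- load_fixture("pfs")
  expect_length(net$treatments, 7)
  expect_identical(nrow(net$trials), 12L)
  want <- data.frame(
    treat1 = c("crizotinib", "crizotinib", "crizotinib", "crizotinib",
               "crizotinib", "alectinib", "ceritinib"),
    treat2 = c("alectinib", "brigatinib", "lorlatinib", "ensartinib",
               "chemotherapy", "chemotherapy", "chemotherapy"),
    n_trials = c(3L, 1L, 1L, 1L, 3L, 1L, 2L))
  got <- net$edges[order(net$edges$treat1, net$edges$treat2), ]
  want <- want[order(want$treat1, want$treat2), ]
  rownames(got) <- rownames(want) <- NULL
  expect_identical(got, want)
})

test_that("fixture networks have the published sizes per outcome", {
  expect_identical(nrow(load_fixture("pfs")$contrast), 12L)
  expect_identical(nrow(load_fixture("os")$contrast), 12L)
  expect_identical(nrow(load_fixture("pfs_bm")$contrast), 12L)
  expect_identical(nrow(load_fixture("orr")$arms), 24L)
  expect_identical(nrow(load_fixture("sae")$arms), 24L)
  # PROFILE1007 reported no discontinuation data
  disc <- load_fixture("discontinuation")
  expect_identical(nrow(disc$trials), 11L)
  expect_false("PROFILE1007" %in% disc$trials$trial)
  expect_match(disc$notes, "CROWN")
  for (oid in c("pfs", "os", "orr", "sae"))
    expect_length(load_fixture(oid)$treatments, 7)
  expect_error(load_fixture("nope"), "unknown outcome")
})

test_that("networks round-trip through the CSV exchange format", {
  for (oid in c("pfs", "orr")) {
    net <- load_fixture(oid)
    tmp <- withr::local_tempfile(fileext = ".csv")
    write_network_csv(net, tmp)
    back <- read_network_csv(tmp, net$outcome,
                             treatment_order = net$treatments)
    if (oid == "pfs") {
      expect_equal(back$contrast$log_effect, net$contrast$log_effect,
                   tolerance = 1e-12)
      expect_equal(back$contrast$se, net$contrast$se, tolerance = 1e-12)
    } else {
      expect_identical(back$arms$events, net$arms$events)
    }
    expect_identical(back$edges, net$edges)
  }
})
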