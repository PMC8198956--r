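# Normalization: nonspot-quartile background correction, empty-vector
# median scaling, and the mean + 3SD positivity rule.

test_that("background is the linear-interpolation first quartile of nonspots", {
  roles <- c("taa", rep("nonspot", 4), rep("empty_vector", 3))
  a <- make_array("b1", "healthy", roles, c(10, 1, 2, 3, 5, 4, 4, 4))
  bc <- background_correct(a)
  expect_equal(bc$background_q1, 1.75)   # quantile(c(1,2,3,5), .25), type 7
  expect_equal(bc$corrected[1], 8.25)
  # constant nonspots at the TAA level: corrected value is zero
  b <- make_array("b2", "healthy", roles, c(7, 7, 7, 7, 7, 9, 9, 9))
  expect_equal(background_correct(b)$corrected[1], 0)
  # values below the quartile clamp at zero, never go negative
  c_ <- make_array("b3", "healthy", roles, c(0.5, 1, 2, 3, 5, 4, 4, 4))
  expect_equal(background_correct(c_)$corrected[1], 0)
})

test_that("normalization divides by the corrected empty-vector median", {
  corrected <- c(8, 2, 4, 6, 0, 0)
  roles <- c("taa", "empty_vector", "empty_vector", "empty_vector",
             "nonspot", "nonspot")
  nm <- normalize_to_empty_vector(corrected, roles, "s")
  expect_equal(nm$ratios[1], 2)                       # 8 / median({2,4,6})
  expect_equal(nm$ratios[3], 1)                       # the median itself
  expect_equal(median(nm$ratios[roles == "empty_vector"]), 1)
  expect_equal(nm$control_summary$empty_vector_median, 4)
  expect_error(normalize_to_empty_vector(c(1, 0, 0, 0),
                                         c("taa", rep("empty_vector", 3)),
                                         "bad"),
               "degenerate")
})

test_that("a hand-worked two-sample cohort reproduces the pipeline matrix", {
  roles <- c("nonspot", "nonspot", "empty_vector", "empty_vector", "taa")
  a <- make_array("h1", "healthy", roles, c(2, 4, 5, 7, 10),
                  feature_ids = c("NS1", "NS2", "EV1", "EV2", "TAA_1"))
  b <- make_array("h2", "crc_nonmet", roles, 3 * c(2, 4, 5, 7, 10),
                  feature_ids = c("NS1", "NS2", "EV1", "EV2", "TAA_1"))
  rm_ <- build_reactivity_matrix(list(h1 = a, h2 = b))
  # straight-line hand computation for sample h1
  q1 <- unname(quantile(c(2, 4), 0.25))               # 2.5
  ev <- c(5, 7) - q1
  expected <- (10 - q1) / median(ev)
  expect_identical(unname(rm_$values["h1", "TAA_1"]), expected)
  expect_equal(rm_$controls$background_q1[1], 2.5)
  expect_equal(rm_$controls$empty_vector_median[1], 3.5)
  # per-array scaling cancels exactly: sample h2 is h1 scaled by 3
  expect_equal(rm_$values["h2", "TAA_1"], rm_$values["h1", "TAA_1"],
               tolerance = 1e-12)
})

test_that("ratios are invariant to scaling one array and the empty-vector
           normalized median is 1", {
  g <- generate_cohort(cohort_config(n_healthy = 2, n_crc_nonmet = 2,
                                     n_crc_met = 2, n_taa = 40,
                                     n_empty_vector = 7, n_nonspot = 9,
                                     array_scale_sd = 0.4, seed = 13))
  rm1 <- build_reactivity_matrix(g$cohort)
  scaled <- g$cohort
  scaled[[1]]$spots$intensity_532 <- scaled[[1]]$spots$intensity_532 * 5.5
  rm2 <- build_reactivity_matrix(scaled)
  expect_equal(rm1$values, rm2$values, tolerance = 1e-12)
  # odd empty-vector count: normalized empty-vector median is exactly 1
  for (a in g$cohort) {
    bc <- background_correct(a)
    nm <- normalize_to_empty_vector(bc$corrected, a$spots$role, a$sample_id)
    expect_identical(median(nm$ratios[a$spots$role == "empty_vector"]), 1)
  }
})

test_that("replicate spots of one feature are averaged after normalization", {
  roles <- c("nonspot", "nonspot", "empty_vector", "empty_vector",
             "empty_vector", "taa", "taa")
  a <- make_array("r1", "healthy", roles, c(0, 0, 1, 2, 3, 4, 8),
                  feature_ids = c("NS1", "NS2", "EV1", "EV2", "EV3",
                                  "TAA_1", "TAA_1"))
  rm_ <- build_reactivity_matrix(list(r1 = a))
  expect_equal(ncol(rm_$values), 1)
  expect_equal(unname(rm_$values["r1", "TAA_1"]), mean(c(4, 8) / 2))
})

test_that("positivity uses the per-sample mean + 3SD rule, strictly", {
  vals <- matrix(c(1.35, 1.30, 0.5), nrow = 1,
                 dimnames = list("s1", c("f1", "f2", "f3")))
  mm <- make_rm(vals, "crc_nonmet", ev_mean = 1, ev_sd = 0.1)
  expect_equal(unname(mm$calls$thresholds["s1"]), 1.3)
  expect_identical(unname(mm$calls$calls["s1", ]), c(TRUE, FALSE, FALSE))
  # all features at the control level with SD > 0: everything negative
  flat <- make_rm(matrix(1, 2, 3, dimnames = list(c("a", "b"),
                                                  c("f1", "f2", "f3"))),
                  c("healthy", "healthy"), ev_mean = 1, ev_sd = 0.2)
  expect_false(any(flat$calls$calls))
})

test_that("positivity is monotone in raw intensity", {
  g <- generate_cohort(cohort_config(n_healthy = 1, n_crc_nonmet = 1,
                                     n_crc_met = 1, n_taa = 30,
                                     n_empty_vector = 5, n_nonspot = 5,
                                     seed = 17))
  rm1 <- build_reactivity_matrix(g$cohort)
  calls1 <- call_positives(rm1)
  raised <- g$cohort
  taa_rows <- which(raised[[1]]$spots$role == "taa")
  raised[[1]]$spots$intensity_532[taa_rows] <-
    raised[[1]]$spots$intensity_532[taa_rows] * 2
  calls2 <- call_positives(build_reactivity_matrix(raised))
  s1 <- rownames(calls1$calls)[1]
  expect_true(all(calls2$calls[s1, ] >= calls1$calls[s1, ]))
})

test_that("a null cohort has few positives, fewer at 3SD than at 2SD", {
  g <- generate_cohort(cohort_config(n_healthy = 10, n_crc_nonmet = 0,
                                     n_crc_met = 0, n_taa = 400,
                                     n_empty_vector = 50, n_nonspot = 50,
                                     background_prevalence = 0, seed = 23))
  rm_ <- build_reactivity_matrix(g$cohort)
  rate3 <- mean(call_positives(rm_, 3)$calls)
  rate2 <- mean(call_positives(rm_, 2)$calls)
  expect_lt(rate3, 0.10)
  expect_lt(rate3, rate2)
})

test_that("reactivity percentages follow the round-half-up convention", {
  vals <- matrix(runif(2 * 2023), nrow = 2,
                 dimnames = list(c("a", "b"), sprintf("F%04d", 1:2023)))
  mm <- make_rm(vals, c("healthy", "healthy"), ev_mean = 2, ev_sd = 1)
  mm$calls$calls[] <- FALSE
  mm$calls$calls["a", 1:48] <- TRUE
  mm$calls$calls["b", 1:1149] <- TRUE
  pc <- reactivity_percentages(mm$calls)
  expect_equal(pc$n_positive, c(48L, 1149L))
  expect_equal(pc$pct, c(2, 57))
  mm$calls$calls[] <- FALSE
  expect_equal(reactivity_percentages(mm$calls)$pct, c(0, 0))
})

test_that("degenerate-control samples are reported together by ID", {
  roles <- c("nonspot", "nonspot", "empty_vector", "empty_vector",
             "empty_vector", "taa")
  good <- make_array("ok", "healthy", roles, c(1, 2, 5, 6, 7, 9),
                     feature_ids = c("NS1", "NS2", "EV1", "EV2", "EV3", "T1"))
  # empty-vector spots at/below the nonspot quartile: corrected median 0
  bad <- make_array("dead", "healthy", roles, c(5, 6, 1, 1, 1, 9),
                    feature_ids = c("NS1", "NS2", "EV1", "EV2", "EV3", "T1"))
  expect_error(build_reactivity_matrix(list(ok = good, dead = bad)), "dead")
  rm_ <- build_reactivity_matrix(list(ok = good, dead = bad),
                                 drop_degenerate = TRUE)
  expect_equal(rownames(rm_$values), "ok")
  expect_equal(rm_$dropped, "dead")
})
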