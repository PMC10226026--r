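test_that("designs encode the structure of both experiments", {
  d1 <- build_design("EXP1")
  expect_equal(d1$n_categories, 3L)
  expect_equal(nrow(d1$contexts), 6L)
  expect_equal(sum(d1$contexts$condition == "0.80-0.20"), 3L)
  expect_equal(sum(d1$contexts$condition == "0.33"), 3L)
  expect_equal(d1$recognition_rules$n_new, 144L)

  d2 <- build_design("EXP2")
  expect_equal(d2$n_categories, 2L)
  expect_equal(table(d2$contexts$condition),
               table(rep(c("0.50-0.50", "0.70-0.30", "0.90-0.10"), 2)))
  expect_equal(d2$recognition_rules$n_new, 80L)

  # contingency vectors sum to 1 in every context
  for (d in list(d1, d2)) {
    a <- counterbalance_assignment(0, d)
    for (ctx in 1:6) {
      expect_equal(sum(context_probs_for_test(d, a, ctx)), 1)
    }
  }
  expect_error(build_design("EXP3"))
})

test_that("counterbalancing is a balanced deterministic rotation", {
  d1 <- build_design("EXP1")
  a0 <- counterbalance_assignment(0, d1)
  expect_identical(a0, counterbalance_assignment(attr(a0, "rotation_length"),
                                                 d1))
  # each category dominant in exactly one 0.80-context, for any index
  for (idx in 0:5) {
    a <- counterbalance_assignment(idx, d1)
    expect_setequal(a[1:3], 1:3)
    expect_true(all(is.na(a[4:6])))
  }
  # over one full cycle the category-by-context tallies are uniform
  cyc <- sapply(0:2, function(i) counterbalance_assignment(i, d1)[1:3])
  expect_true(all(table(row(cyc), cyc) == 1))

  d2 <- build_design("EXP2")
  a <- counterbalance_assignment(0, d2)
  b <- counterbalance_assignment(1, d2)
  expect_setequal(a[1:2], 1:2)
  expect_setequal(a[3:4], 1:2)
  expect_true(all(is.na(a[5:6])))
  expect_false(identical(a[1], b[1]))
  expect_identical(a, counterbalance_assignment(2, d2))
})

test_that("encoding schedules realize the designed trial counts", {
  d1 <- build_design("EXP1")
  enc1 <- generate_encoding_schedule(d1, counterbalance_assignment(0, d1),
                                     seed = 42)
  expect_equal(nrow(enc1), 312L)
  expect_equal(sum(!enc1$is_filler), 144L)
  expect_equal(sum(enc1$condition == "0.80-0.20"), 240L)
  expect_equal(sum(enc1$condition == "0.33"), 72L)

  d2 <- build_design("EXP2")
  enc2 <- generate_encoding_schedule(d2, counterbalance_assignment(0, d2),
                                     seed = 42)
  expect_equal(nrow(enc2), 330L)
  expect_equal(sum(!enc2$is_filler), 100L)
  expect_equal(as.integer(table(enc2$condition)[c("0.90-0.10", "0.70-0.30",
                                                  "0.50-0.50")]),
               c(200L, 70L, 60L))

  # non-filler objects occur exactly once
  for (enc in list(enc1, enc2)) {
    ids <- enc$object_id[!enc$is_filler]
    expect_equal(anyDuplicated(ids), 0L)
  }

  # realized contingency within 1/n of nominal for a dominant context
  a2 <- counterbalance_assignment(0, d2)
  real <- attr(enc2, "realized_contingency")
  dom1 <- real[real$context == 1 & real$category_shown == a2[1], ]
  expect_lt(abs(dom1$prop - 0.90), 1 / 100)

  # seeded determinism
  expect_identical(enc1,
                   generate_encoding_schedule(d1,
                                              counterbalance_assignment(0, d1),
                                              seed = 42))
})

test_that("learning schedules apportion contingencies by largest remainder", {
  d1 <- build_design("EXP1")
  a <- counterbalance_assignment(0, d1)
  sch <- generate_learning_schedule(d1, a, n_trials_per_context = 10,
                                    seed = 1)
  counts <- table(factor(sch$category_shown[sch$context == 1], levels = 1:3))
  expect_equal(sort(as.integer(counts), decreasing = TRUE), c(8L, 1L, 1L))
  expect_equal(as.integer(counts)[a[1]], 8L)

  sch9 <- generate_learning_schedule(d1, a, n_trials_per_context = 9,
                                     seed = 1)
  expect_equal(as.integer(table(sch9$category_shown[sch9$context == 4])),
               c(3L, 3L, 3L))
  expect_identical(sch, generate_learning_schedule(d1, a, 10, seed = 1))
  expect_error(generate_learning_schedule(d1, a, 0, seed = 1))
})

test_that("context counters pool phases and increment within context", {
  d2 <- build_design("EXP2")
  a <- counterbalance_assignment(0, d2)
  learn <- generate_learning_schedule(d2, a, 10, seed = 1)
  enc <- generate_encoding_schedule(d2, a, seed = 2)
  pooled <- pool_phases(learn, enc)
  for (ctx in unique(pooled$context)) {
    tt <- pooled$context_trial[pooled$context == ctx]
    expect_equal(tt, seq_along(tt))
  }
  # encoding continues where learning left off
  first_enc <- pooled[pooled$phase == "ENCODING" & pooled$context == 1, ]
  expect_equal(first_enc$context_trial[1], 11L)
})

test_that("simulated agents follow the softmax and are seeded", {
  d2 <- build_design("EXP2")
  a <- counterbalance_assignment(0, d2)
  sch <- pool_phases(generate_learning_schedule(d2, a, 20, seed = 1),
                     generate_encoding_schedule(d2, a, seed = 2))
  flat <- simulate_agent(model_spec("fLRI"), c(alpha = 0.3, beta = 0), sch,
                         seed = 3)
  # beta = 0: choices uniform over the two categories
  expect_lt(abs(mean(flat$category_chosen == 1) - 0.5), 0.05)

  sharp <- simulate_agent(model_spec("fLRI"), c(alpha = 0.3, beta = 8), sch,
                          seed = 3)
  late <- sharp[sharp$condition == "0.90-0.10", ]
  late <- late[seq(nrow(late) - 79, nrow(late)), ]
  # learned dominant-category preference well above chance
  expect_gt(mean(late$accuracy), 0.65)

  expect_identical(sharp, simulate_agent(model_spec("fLRI"),
                                         c(alpha = 0.3, beta = 8), sch,
                                         seed = 3))
  expect_error(simulate_agent(model_spec("nope"), c(beta = 1), sch, 1))
  expect_error(simulate_agent(model_spec("fLRI"), c(alpha = 2, beta = 1),
                              sch, 1))
})

test_that("recognition generator follows the generative memory model", {
  rec <- tibble::tibble(
    subject = rep(1:40, each = 60),
    object_id = sprintf("o%04d", seq_len(2400)),
    pe = runif(2400),
    po = sample(c(-0.5, 0.5), 2400, replace = TRUE)
  )
  # all-zero coefficients, no random effects: hit probability one half
  out <- simulate_recognition(rec, c(0, 0, 0, 0), c(0, 0, 0, 0),
                              fa_rate = 0.2, seed = 1)
  expect_lt(abs(mean(out$response) - 0.5), 0.03)

  # strong interaction: PE-hit association flips sign with the outcome
  out2 <- simulate_recognition(rec, c(0, 0, 0, 4), c(0, 0, 0, 0),
                               fa_rate = 0.2, seed = 2)
  d <- cbind(rec, hit = out2$response)
  slope_c <- coef(glm(hit ~ pe, binomial, data = d[d$po > 0, ]))["pe"]
  slope_i <- coef(glm(hit ~ pe, binomial, data = d[d$po < 0, ]))["pe"]
  expect_gt(slope_c, 0)
  expect_lt(slope_i, 0)

  expect_identical(out, simulate_recognition(rec, c(0, 0, 0, 0),
                                             c(0, 0, 0, 0), 0.2, seed = 1))
  expect_error(simulate_recognition(rec[, -3], c(0, 0, 0, 0)),
               "pe")
})

test_that("synthetic studies are reproducible and complete", {
  d1 <- build_design("EXP1")
  s <- make_synthetic_study(2, d1, seed = 9)
  s2 <- make_synthetic_study(2, d1, seed = 9)
  expect_identical(s$trials, s2$trials)
  expect_identical(s$recognition, s2$recognition)

  expect_true(all(s$agents$alpha >= 0 & s$agents$alpha <= 1))
  expect_true(all(s$agents$beta >= 0 & s$agents$beta <= 10))

  r1 <- s$recognition[s$recognition$subject == 1, ]
  expect_equal(sum(r1$status == "old"), 144L)
  expect_equal(sum(r1$status == "new"), 144L)
  expect_equal(sum(r1$status == "old" & r1$immediate_subset), 72L)
  # every non-filler encoding item appears exactly once as old
  enc_ids <- s$trials$object_id[s$trials$subject == 1 &
                                  s$trials$phase == "ENCODING" &
                                  !s$trials$is_filler]
  expect_setequal(r1$object_id[r1$status == "old"], enc_ids)

  # adding a subject leaves earlier subjects' streams untouched
  s3 <- make_synthetic_study(3, d1, seed = 9)
  expect_identical(s$trials,
                   s3$trials[s3$trials$subject %in% 1:2, ])
})
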