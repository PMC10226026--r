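test_that("recognition scoring matches signal-detection arithmetic", {
  rec <- tibble::tibble(
    subject = 1,
    object_id = sprintf("o%02d", 1:80),
    status = rep(c("old", "new"), c(40, 40)),
    response = c(rep(1, 30), rep(0, 10), rep(1, 10), rep(0, 30))
  )
  sc <- score_recognition(rec)
  expect_equal(sc$hits, 30L)
  expect_equal(sc$hit_rate, 0.75)
  expect_equal(sc$fa_rate, 0.25)
  expect_equal(sc$dprime,
               qnorm(30.5 / 41) - qnorm(10.5 / 41))

  # equal hit and false-alarm counts: d' exactly zero
  rec0 <- rec
  rec0$response <- c(rep(1, 20), rep(0, 20), rep(1, 20), rep(0, 20))
  expect_equal(score_recognition(rec0)$dprime, 0)

  # large-sample d' approaches the uncorrected z-difference
  expect_equal(dprime(8400, 10000, 1600, 10000),
               qnorm(0.84) - qnorm(0.16), tolerance = 1e-3)
  expect_equal(round(dprime(8400, 10000, 1600, 10000), 2), 1.99)

  expect_error(score_recognition(rec[rec$status == "old", ]), "new")
})

test_that("permutation exclusion keeps discriminators, drops flat responders", {
  make_rec <- function(subject, responses) {
    tibble::tibble(subject = subject,
                   object_id = sprintf("s%d_o%03d", subject,
                                       seq_along(responses)),
                   status = rep(c("old", "new"), c(60, 60)),
                   response = responses)
  }
  rec <- dplyr::bind_rows(
    make_rec(1, rep(c(1, 0), c(60, 60))),   # perfect discrimination
    make_rec(2, rep(1, 120)),               # says old to everything
    make_rec(3, rep(c(1, 0), 60))           # response independent of status
  )
  ex <- permutation_exclusion(rec, n_perm = 300, seed = 4)
  expect_true(ex$included[ex$subject == 1])
  expect_false(ex$included[ex$subject == 2])
  expect_equal(ex$dprime[ex$subject == 2], 0)
  expect_length(attr(ex, "null_distributions")[["3"]], 300)
  expect_error(permutation_exclusion(rec, n_perm = 0))
})

test_that("the analysis table joins PE to memory, item by item", {
  for (exp_id in c("EXP1", "EXP2")) {
    st <- make_synthetic_study(3, build_design(exp_id), seed = 21)
    fits <- fit_study(st$trials, models = "fLRI", seed = 1)
    tr <- derive_pe(st$trials, fits)
    tab <- build_analysis_table(tr, st$recognition, fits)
    n_expected <- if (exp_id == "EXP1") 72L else 100L
    expect_equal(unname(table(tab$subject)),
                 rep(n_expected, 3), ignore_attr = TRUE)
    expect_false(any(grepl("^F_", tab$object_id)))   # no fillers
    expect_setequal(unique(tab$po), c(-0.5, 0.5))
    expect_equal(unique(tab$experiment_code),
                 if (exp_id == "EXP1") 0.5 else -0.5)
    expect_true(all(tab$pe >= 0 & tab$pe <= 1))
    expect_true(all(tab$pe_bin %in% 1:4))
    # quartile bins within a subject differ in size by at most 1
    sizes <- table(tab$subject, tab$pe_bin)
    expect_lte(max(apply(sizes, 1, function(x) diff(range(x)))), 1)

    # subjects can be excluded
    tab2 <- build_analysis_table(tr, st$recognition, fits,
                                 included_subjects = c(1, 3))
    expect_setequal(unique(tab2$subject), c(1, 3))

    # a recognition item with no encoding record is an error
    bad <- st$recognition
    idx <- which(bad$status == "old" & bad$immediate_subset)[1]
    bad$object_id[idx] <- "GHOST"
    expect_error(build_analysis_table(tr, bad, fits), "GHOST")
  }
})

test_that("mixed logistic model recovers structure and reports ORs", {
  tab <- simulate_memory_dataset(24, 100, c(0.4, 0, 0, 1.5),
                                 c(0.4, 0.1, 0.1, 0.1), seed = 31)
  fit <- fit_mixed_logistic(tab, "basic")
  expect_equal(fit$fixed$odds_ratio, exp(fit$fixed$estimate),
               tolerance = 1e-12)
  expect_equal(fit$fixed$wald_chisq, fit$fixed$z^2, tolerance = 1e-12)
  int <- fit$fixed[fit$fixed$term == "pe:po", ]
  expect_gt(int$estimate, 0)
  expect_lt(int$p, 0.05)
  expect_equal(dim(fit$ranef_vcov), c(4L, 4L))
  # random-effect covariance is positive semi-definite
  expect_gte(min(eigen(fit$ranef_vcov, symmetric = TRUE,
                       only.values = TRUE)$values), -1e-8)

  expect_error(fit_mixed_logistic(tab[tab$subject == 1, ]), "2 subjects")
  expect_error(
    fit_mixed_logistic(cbind(tab, alpha = 0.5),
                       hit ~ pe * po + (1 + alpha | subject)),
    "between-subject"
  )
})

test_that("simple slopes split the interaction by prediction outcome", {
  tab <- simulate_memory_dataset(30, 120, c(0, 0, 0, 1.5),
                                 c(0.3, 0, 0, 0), seed = 32)
  ss <- simple_slopes(tab)
  pe_c <- ss$correct$fixed[ss$correct$fixed$term == "pe", ]
  pe_i <- ss$incorrect$fixed[ss$incorrect$fixed$term == "pe", ]
  expect_gt(pe_c$estimate, 0)
  expect_lt(pe_i$estimate, 0)
  expect_gt(pe_c$odds_ratio, 1)
  expect_lt(pe_i$odds_ratio, 1)
  expect_error(simple_slopes(tab[tab$subject == 1, ]), "2 subjects")
})

test_that("binned-PE analysis bins within subject and Bonferroni-corrects", {
  tab <- simulate_memory_dataset(16, 80, c(0.3, 0.8, 0, 0),
                                 c(0.3, 0, 0, 0), seed = 33)
  res <- binned_pe_analysis(tab)
  expect_equal(sort(unique(as.integer(as.character(res$bin_table$pe_bin)))),
               1:4)
  k <- nrow(res$contrasts)
  expect_equal(res$contrasts$p_corrected,
               pmin(res$contrasts$p.value * k, 1))
  expect_true(all(res$contrasts$p_corrected <= 1))

  # a subject with degenerate PE is dropped with a warning
  degen <- tab
  degen$pe[degen$subject == 1] <- 0.5
  expect_warning(binned_pe_analysis(degen), "distinct PE")
})

test_that("signed-PE model recovers a generative positive slope", {
  set.seed(34)
  n_s <- 20; n_i <- 90
  tab <- tibble::tibble(
    subject = rep(seq_len(n_s), each = n_i),
    pe_signed = runif(n_s * n_i, -1, 1)
  )
  u <- rnorm(n_s, 0, 0.3)
  tab$hit <- rbinom(nrow(tab), 1, plogis(0.2 + 1.2 * tab$pe_signed +
                                           u[tab$subject]))
  fit <- signed_pe_analysis(tab)
  sl <- fit$fixed[fit$fixed$term == "pe_signed", ]
  expect_gt(sl$estimate, 0)
  expect_lt(sl$p, 0.05)
  expect_equal(sl$odds_ratio, exp(sl$estimate))
})

test_that("the full pipeline recovers the interaction's direction", {
  st <- make_synthetic_study(14, build_design("EXP2"), seed = 41)
  fits <- fit_study(st$trials, models = "fLRI", seed = 5)
  tr <- derive_pe(st$trials, fits)
  tab <- build_analysis_table(tr, st$recognition, fits)
  fit <- fit_mixed_logistic(tab, "basic")
  int <- fit$fixed[fit$fixed$term == "pe:po", ]
  expect_gt(int$estimate, 0)
  expect_lt(int$p, 0.05)
  ss <- simple_slopes(tab)
  expect_gt(ss$correct$fixed$estimate[2], 0)
  expect_lt(ss$incorrect$fixed$estimate[2], 0)
})
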