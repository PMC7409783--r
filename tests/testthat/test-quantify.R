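test_that("efficiency fitting: closed forms and series validation", {
  # slope -1/log10(2) per 10-fold dilution = perfect doubling -> 100%
  d <- dilution_series(10^(0:4), 20 + log2(10) * (0:4))
  fit <- fit_efficiency(d)
  expect_equal(fit$slope, -log2(10), tolerance = 1e-10)
  expect_equal(fit$efficiency_pct, 100, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # slope -3.0 -> 10^(1/3) - 1 = 115.44%
  d2 <- dilution_series(10^(0:3), 20 + 3 * (0:3))
  expect_equal(fit_efficiency(d2)$efficiency_pct, (10^(1 / 3) - 1) * 100,
               tolerance = 1e-8)

  # replicate-mean Cq is used per level
  d3 <- dilution_series(c(1, 1, 10, 10, 100), c(19.9, 20.1, 23.4, 23.2, 26.6))
  expect_equal(d3$mean_cq, c(20, 23.3, 26.6), tolerance = 1e-12)
  expect_equal(d3$n_reps, c(2L, 2L, 1L))

  # two levels: diagnostic mode with warning, slope = two-point estimate
  expect_warning(f2 <- fit_efficiency(dilution_series(c(1, 10), c(20, 23.5))),
                 "2 dilution")
  expect_equal(f2$slope, -3.5, tolerance = 1e-12)

  # rising-with-template series is invalid
  expect_error(fit_efficiency(dilution_series(10^(0:3), c(26, 24, 22, 20))),
               class = "refstab_domain_error")
})

dd_ds <- function(target_iso, target_crw, ref_iso = rep(15, 5), ref_crw = rep(15, 5),
                  extra = NULL) {
  n <- length(target_iso) + length(target_crw)
  cq <- cbind(tgt = c(target_iso, target_crw), ref1 = c(ref_iso, ref_crw))
  if (!is.null(extra)) cq <- cbind(cq, extra)
  make_ds(cq, rep(c("isolated", "crowded"), c(length(target_iso), length(target_crw))))
}

test_that("delta-delta-Cq: hand-derived fold changes and invariances", {
  # identical groups -> fold change 1, ddCq all 0
  ds <- dd_ds(rep(20, 5), rep(20, 5))
  res <- delta_delta_cq(ds, "tgt", "ref1", "isolated")
  expect_equal(res$fold_change, 1)
  expect_equal(unname(res$delta_delta_cq), rep(0, 10))

  # constant ref 15; target isolated {20,20}, crowded {19,19} -> fold 2
  ds2 <- dd_ds(c(20, 20), c(19, 19), rep(15, 2), rep(15, 2))
  res2 <- delta_delta_cq(ds2, "tgt", "ref1", "isolated")
  expect_equal(res2$fold_change, 2, tolerance = 1e-12)
  expect_equal(unname(res2$rq), c(1, 1, 2, 2))

  # per-sample loading shifts cancel
  cq <- cbind(tgt = with_seed(51, rnorm(10, 24, 0.5)),
              r1 = with_seed(52, rnorm(10, 20, 0.3)),
              r2 = with_seed(53, rnorm(10, 18, 0.3)))
  grp <- rep(c("isolated", "crowded"), each = 5)
  base <- delta_delta_cq(make_ds(cq, grp), "tgt", c("r1", "r2"), "isolated")
  shifted <- delta_delta_cq(make_ds(cq + with_seed(54, rnorm(10, 0, 2)), grp),
                            "tgt", c("r1", "r2"), "isolated")
  expect_equal(shifted$fold_change, base$fold_change, tolerance = 1e-10)
  expect_equal(shifted$p_value, base$p_value, tolerance = 1e-10)

  # swapping groups inverts the fold change (exp_mean method is exactly reciprocal)
  sw <- delta_delta_cq(make_ds(cq, grp), "tgt", c("r1", "r2"), "crowded",
                       method = "exp_mean")
  fw <- delta_delta_cq(make_ds(cq, grp), "tgt", c("r1", "r2"), "isolated",
                       method = "exp_mean")
  expect_equal(sw$fold_change, 1 / fw$fold_change, tolerance = 1e-10)
  expect_equal(sw$p_value, fw$p_value, tolerance = 1e-12)
})

test_that("t test on non-transformed delta-Cq, Student by default, Welch optional", {
  cq <- cbind(tgt = c(20.1, 20.4, 19.8, 20.2, 21.1, 19.0, 19.2, 18.7, 19.1, 19.6),
              ref1 = rep(15, 10))
  grp <- rep(c("isolated", "crowded"), each = 5)
  ds <- make_ds(cq, grp)
  res <- delta_delta_cq(ds, "tgt", "ref1", "isolated")
  dcq <- cq[, "tgt"] - 15
  tt <- t.test(dcq[6:10], dcq[1:5], var.equal = TRUE)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-12)
  expect_equal(res$t_statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$df, 8)
  resw <- delta_delta_cq(ds, "tgt", "ref1", "isolated", var_equal = FALSE)
  expect_equal(resw$p_value, t.test(dcq[6:10], dcq[1:5])$p.value, tolerance = 1e-12)
  # sem on exponentialized values per group
  expect_equal(unname(res$sem["isolated"]),
               sd(res$rq[1:5]) / sqrt(5), tolerance = 1e-12)
})

test_that("multi-reference normalization equals geometric-mean-of-quantities", {
  cq <- cbind(tgt = c(22, 23, 21, 24), r1 = c(18, 19, 18.5, 19.5),
              r2 = c(16, 17.2, 16.4, 17))
  grp <- rep(c("isolated", "crowded"), each = 2)
  res <- delta_delta_cq(make_ds(cq, grp), "tgt", c("r1", "r2"), "isolated")
  dcq_manual <- cq[, "tgt"] - (cq[, "r1"] + cq[, "r2"]) / 2
  expect_equal(unname(res$delta_cq), unname(dcq_manual), tolerance = 1e-12)
})

test_that("efficiency-corrected quantification reduces to plain ddCq at E = 2", {
  cq <- cbind(tgt = with_seed(55, rnorm(10, 24, 0.4)),
              r1 = with_seed(56, rnorm(10, 19, 0.3)))
  grp <- rep(c("isolated", "crowded"), each = 5)
  ds <- make_ds(cq, grp)
  plain <- delta_delta_cq(ds, "tgt", "r1", "isolated")
  e2 <- delta_delta_cq(ds, "tgt", "r1", "isolated",
                       efficiency = c(tgt = 2, r1 = 2))
  expect_equal(e2$fold_change, plain$fold_change, tolerance = 1e-12)
  # an imperfect target efficiency changes the fold change
  e96 <- delta_delta_cq(ds, "tgt", "r1", "isolated",
                        efficiency = c(tgt = 1.9684, r1 = 2))
  expect_false(isTRUE(all.equal(e96$fold_change, plain$fold_change)))
})

test_that("contract errors: self-normalization, missing cells, bad groups", {
  cq <- cbind(tgt = c(20, 21, 22, 23), r1 = c(15, 15, 15, 15))
  ds <- make_ds(cq, rep(c("isolated", "crowded"), each = 2))
  expect_error(delta_delta_cq(ds, "tgt", c("tgt", "r1"), "isolated"),
               class = "refstab_contract_error")
  expect_error(delta_delta_cq(ds, "tgt", "r1", "nope"),
               class = "refstab_contract_error")
  cq_na <- cq; cq_na[2, "r1"] <- NA
  expect_error(delta_delta_cq(make_ds(cq_na, rep(c("isolated", "crowded"), each = 2)),
                              "tgt", "r1", "isolated"),
               "r1", class = "refstab_insufficient_data")
})

test_that("reference-set sensitivity flags significance/direction changes", {
  # target responds by -1 cycle; refs r1..r3 quiet, r4 responds like the target
  with_seed(57, {
    iso <- rnorm(5, 0, 0.15); crw <- rnorm(5, 0, 0.15)
    cq <- cbind(tgt = c(24 + iso, 23 + rnorm(5, 0, 0.15)),
                r1 = rnorm(10, 19, 0.1), r2 = rnorm(10, 18, 0.1),
                r3 = rnorm(10, 20, 0.1),
                r4 = c(rnorm(5, 21, 0.1), rnorm(5, 20, 0.1)))
  })
  ds <- make_ds(cq, rep(c("isolated", "crowded"), each = 5))
  sens <- reference_set_sensitivity(ds, "tgt",
                                    list(good = c("r1", "r2", "r3"),
                                         biased = c("r4")),
                                    "isolated")
  expect_equal(nrow(sens$table), 2)
  expect_true(sens$table$significant[sens$table$set == "good"])
  expect_false(sens$table$significant[sens$table$set == "biased"])
  expect_true(sens$significance_change)
  # identical sets -> identical results
  sens2 <- reference_set_sensitivity(ds, "tgt",
                                     list(a = c("r1", "r2"), b = c("r1", "r2")),
                                     "isolated")
  expect_identical(sens2$table$fold_change[1], sens2$table$fold_change[2])
  # a set containing the target errors
  expect_error(reference_set_sensitivity(ds, "tgt", list(c("tgt", "r1")), "isolated"),
               class = "refstab_contract_error")
})
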