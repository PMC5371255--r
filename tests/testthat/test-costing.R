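test_that("the training ledger reproduces every printed subtotal", {
  expect_equal(base_training$grand_total_kes, 4369168)
  expect_equal(round(base_training$grand_total_usd), 51688)
  sub_kes <- base_training$category_subtotals
  expect_equal(unname(sub_kes[c("Counselor consultants", "Psychiatry",
                                "Per diems", "Training materials",
                                "Conference center", "Furniture",
                                "Equipment")]),
               c(857600, 820000, 1428000, 146980, 581400, 415200, 119988))
  sub_usd <- round(kes_to_usd(sub_kes, base_ctx))
  expect_equal(unname(sub_usd["Counselor consultants"]), 10146)
  expect_equal(unname(sub_usd["Per diems"]), 16893)
})

test_that("the per-site ledger reproduces the printed annual budget", {
  expect_equal(base_site$grand_total_kes, 752555)
  expect_equal(round(base_site$grand_total_usd), 8903)
  sub <- base_site$category_subtotals
  expect_equal(unname(sub[c("Personnel", "Supplies",
                            "Participant Payments")]),
               c(514740, 45815, 192000))
  expect_equal(round(kes_to_usd(sub[["Personnel"]], base_ctx)), 6089)
})

test_that("ledger aggregation is consistent and permutation-invariant", {
  led <- cost_ledger(toy_items, base_ctx)
  expect_equal(led$grand_total_kes, 2 * 500 + 845.3 + 100)
  expect_equal(led$category_subtotals[["X"]], 1845.3)
  expect_equal(led$grand_total_usd,
               kes_to_usd(led$grand_total_kes, base_ctx))
  shuffled <- cost_ledger(toy_items[c(3, 1, 2), ], base_ctx)
  expect_equal(shuffled$grand_total_kes, led$grand_total_kes)
  expect_equal(sort(shuffled$category_subtotals),
               sort(led$category_subtotals))
})

test_that("a stated line total contradicting units x unit cost is rejected", {
  bad <- toy_items
  bad$total_kes <- c(1000, 845.3, 250)
  expect_error(cost_ledger(bad, base_ctx), "inconsistent-line-item")
  ok <- toy_items
  ok$total_kes <- c(1000.4, 845.3, 100)  # within 1 KES rounding
  expect_silent(cost_ledger(ok, base_ctx))
})

test_that("the base schedule enrolls 13,440 participants", {
  expect_equal(total_participants(base_sched), 13440)
  expect_equal(cohort_sizes(base_sched), c(1920, 2880, 2880, 2880, 2880))
  alt <- rollout_schedule(participants_per_site_by_year =
                            c(160, 320, 320, 320, 320))
  expect_equal(total_participants(alt), 12 * (160 + 4 * 320))
})

test_that("the cost stream front-loads training and repeats site budgets", {
  cs <- cost_stream(base_training, base_site, base_sched)
  expect_length(cs$amounts, 5)
  expect_equal(cs$amounts[1],
               base_training$grand_total_usd +
                 12 * base_site$grand_total_usd)
  expect_equal(cs$amounts[1], 158000, tolerance = 0.01)
  expect_equal(cs$amounts[2:5],
               rep(12 * base_site$grand_total_usd, 4))
  no_sites <- cost_stream(base_training, base_site,
                          rollout_schedule(n_sites = 0))
  expect_equal(no_sites$amounts[1], base_training$grand_total_usd)
  expect_equal(no_sites$amounts[2:5], rep(0, 4))
})

test_that("unit cost divides by total participants in both conventions", {
  cs <- cost_stream(base_training, base_site, base_sched)
  undisc <- unit_cost(sum(cs$amounts), base_sched)
  expect_equal(round(undisc), 44)
  disc_total <- sum(discount(cs, 0.03)$amounts)
  expect_equal(unit_cost(disc_total, base_sched), disc_total / 13440)
  expect_lt(unit_cost(disc_total, base_sched), undisc)
  expect_equal(unit_cost(0, base_sched), 0)
})

test_that("doubling enrollment halves unit cost at fixed total cost", {
  doubled <- rollout_schedule(participants_per_site_by_year =
                                2 * c(160, 240, 240, 240, 240))
  expect_equal(total_participants(doubled),
               2 * total_participants(base_sched))
  expect_equal(unit_cost(585868, doubled),
               unit_cost(585868, base_sched) / 2)
})

test_that("ledger scaling multiplies totals, optionally per category", {
  half <- scale_ledger(base_site, 0.5, base_ctx)
  expect_equal(half$grand_total_kes, base_site$grand_total_kes / 2)
  no_pay <- scale_ledger(base_site, 0, base_ctx,
                         categories = "Participant Payments")
  expect_equal(no_pay$grand_total_kes, 752555 - 192000)
  expect_error(scale_ledger(base_site, 1, base_ctx,
                            categories = "No Such Category"),
               "unknown-parameter")
})
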