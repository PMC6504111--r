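# 10-molecule fixture: quality "q" on molecules 1-6; two disjoint boxes
# covering positives {1,2} and {3,4}; nothing else covered.
two_box_fixture <- function() {
  vals <- cbind(x = c(0.1, 0.15, 0.6, 0.65, 0.4, 0.45, 0.9, 0.95, 0.85, 0.8),
                y = c(0.1, 0.15, 0.6, 0.65, 0.9, 0.95, 0.4, 0.45, 0.05, 0.5))
  rownames(vals) <- as.character(1:10)
  labels <- c(setNames(rep(list("q"), 6), 1:6),
              setNames(rep(list("other"), 4), 7:10))
  ds <- odorant_dataset(vals, labels)
  r1 <- so_rule(description(x = c(0.05, 0.2), y = c(0.05, 0.2)), "q")
  r2 <- so_rule(description(x = c(0.55, 0.7), y = c(0.55, 0.7)), "q")
  list(ds = ds, r1 = r1, r2 = r2)
}

test_that("combination metrics: union coverage, error and distance to ideal", {
  fx <- two_box_fixture()
  c1 <- combination_metrics(list(fx$r1), "q", fx$ds)
  expect_equal(c1$precision, 1)
  expect_equal(c1$recall, 2 / 6)
  expect_equal(c1$error, 0)
  expect_equal(c1$distance, 1 - 2 / 6)

  c12 <- combination_metrics(list(fx$r1, fx$r2), "q", fx$ds)
  expect_setequal(c12$union_coverage, as.character(1:4))
  expect_equal(c12$precision, 1)
  expect_equal(c12$recall, 2 / 3)
  expect_equal(c12$distance, 1 / 3)
  # union recall never below any member's recall
  expect_gte(c12$recall, c1$recall)

  # perfect rule covering exactly the positives sits at the ideal point
  perfect <- so_rule(description(), "q")
  ds_pos <- odorant_dataset(fx$ds$values[1:6, ], fx$ds$labels[1:6])
  cp <- combination_metrics(list(perfect), "q", ds_pos)
  expect_equal(cp$error, 0)
  expect_equal(cp$recall, 1)
  expect_equal(cp$distance, 0)

  # empty coverage is flagged, not an error
  nowhere <- so_rule(description(x = c(5, 6)), "q")
  ce <- combination_metrics(list(nowhere), "q", fx$ds)
  expect_equal(ce$precision, 0)
  expect_true("empty_coverage" %in% ce$flags)
})

test_that("select_best picks the dominating 2-rule combination", {
  fx <- two_box_fixture()
  sel <- select_best(list(list(fx$r1, fx$r2)), "q", fx$ds)
  expect_equal(sel$distance, 1 / 3)
  expect_equal(length(sel$best[[1]]$rules), 2)
  # exhaustive search agrees on this small pool
  sel_ex <- select_best(list(list(fx$r1, fx$r2)), "q", fx$ds,
                        strategy = "exhaustive")
  expect_equal(sel_ex$distance, sel$distance)
})

test_that("a single candidate is selected trivially; none yields a flag", {
  fx <- two_box_fixture()
  sel <- select_best(list(list(fx$r1)), "q", fx$ds)
  expect_length(sel$best, 1)
  expect_equal(sel$best[[1]]$distance, 1 - 2 / 6)
  empty <- select_best(list(list()), "q", fx$ds)
  expect_true("no_candidates" %in% empty$flags)
  expect_length(empty$best, 0)
})

test_that("ties at the minimal distance are all retained", {
  fx <- two_box_fixture()
  # r1 and r2 are symmetric: each alone has distance 1 - 2/6
  sel <- select_best(list(`5` = list(fx$r1), `10` = list(fx$r2)), "q", fx$ds,
                     max_rules = 1)
  expect_length(sel$best, 2)
  d <- vapply(sel$best, `[[`, 0, "distance")
  expect_true(all(abs(d - d[1]) < 1e-12))
})

test_that("prefix strategy matches the exhaustive oracle on random pools", {
  set.seed(21)
  for (rep in 1:6) {
    ds <- random_dataset(n = 14, p = 2, seed = 4000 + rep)
    Q <- ds$qualities[1]
    run <- mine_rules(ds, Q, miner_config(min_supp = 2, beam_width = 50,
                                          max_properties = 2,
                                          max_supp = 1000, max_output = 8))
    if (!length(run$rules)) next
    pre <- select_best(run, Q, ds)
    exh <- select_best(run, Q, ds, strategy = "exhaustive")
    # exhaustive is the oracle: prefix can never beat it
    expect_gte(pre$distance, exh$distance - 1e-12)
    # and never beats the best single rule either way
    singles <- vapply(run$rules, function(e)
      combination_metrics(list(e$rule), Q, ds)$distance, 0)
    expect_lte(pre$distance, min(singles) + 1e-12)
  }
})

test_that("group classification follows the printed boundary conventions", {
  expect_equal(classify_group(0.2, 0.7), 1L)
  expect_equal(classify_group(0.5, 0.5), 3L)
  expect_equal(classify_group(0.49999, 0.49999), 2L)
  expect_equal(classify_group(0.6, 0.3), 4L)
  expect_equal(classify_group(0, 1), 1L)
  expect_error(classify_group(1.2, 0.5), "0, 1")
})

test_that("quartile assignment matches a rank-partition oracle", {
  d8 <- setNames(seq(0.1, 0.8, by = 0.1), paste0("q", 1:8))
  q8 <- assign_quartiles(d8)
  expect_equal(as.vector(table(q8)), c(2, 2, 2, 2))

  same <- setNames(rep(0.4, 6), paste0("q", 1:6))
  expect_true(all(assign_quartiles(same) == "Q1"))

  set.seed(3)
  d74 <- setNames(runif(74), paste0("q", 1:74))
  q74 <- assign_quartiles(d74)
  # oracle: sort and split at interpolated quartile ranks
  qs <- quantile(d74, c(0.25, 0.5, 0.75), type = 7)
  oracle <- cut(d74, c(-Inf, qs, Inf), labels = paste0("Q", 1:4))
  expect_identical(as.character(q74), as.character(oracle))
  expect_equal(as.vector(table(q74)), c(19, 18, 18, 19))

  expect_warning(q3 <- assign_quartiles(setNames(1:3, letters[1:3])),
                 "fewer than 4")
  expect_true(all(q3 == "Q1"))
})

test_that("selection report assembles one row per quality", {
  fx <- two_box_fixture()
  sels <- list(select_best(list(list(fx$r1, fx$r2)), "q", fx$ds),
               select_best(list(list(fx$r1)), "q", fx$ds),
               select_best(list(list(fx$r2)), "q", fx$ds),
               select_best(list(list(fx$r1)), "q", fx$ds))
  path <- withr::local_tempfile(fileext = ".csv")
  df <- selection_report(sels, path)
  expect_equal(nrow(df), 4)
  expect_true(all(c("quality", "n_rules", "precision", "recall", "error",
                    "distance", "group", "quartile") %in% names(df)))
  expect_true(file.exists(path))
  expect_equal(df$distance[1], 1 / 3)
})
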