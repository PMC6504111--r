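toy <- toy_dataset()

test_that("enumerate_targets respects max_qual, min_supp and ordering", {
  t1 <- enumerate_targets(toy, max_qual = 1, min_supp = 2)
  expect_identical(t1, list("fruity", "vanillin", "woody"))
  expect_identical(enumerate_targets(toy, max_qual = 1, min_supp = 5), list())
  t2 <- enumerate_targets(toy, max_qual = 2, min_supp = 2)
  keys <- vapply(t2, paste, "", collapse = ",")
  expect_true("fruity,vanillin" %in% keys)      # molecules 5 and 6
  expect_false("fruity,woody" %in% keys)        # only molecule 3
  expect_identical(keys, sort(keys))
})

test_that("refinements shrink bounds to the next observed value", {
  refs <- refine_description(description(), toy,
                             miner_config(max_properties = 3))
  fmt <- vapply(refs, format, "")
  # MW values 128,136,142,150,151,152: lower shrink lands on 136
  expect_true("[136 <= MW <= 152]" %in% fmt)
  expect_true("[128 <= MW <= 151]" %in% fmt)
  # two refinements (lower, upper) per descriptor
  expect_length(refs, 6)

  # descriptors at the max_properties limit: no new conditions introduced
  d <- description(MW = c(128, 152))
  refs2 <- refine_description(d, toy, miner_config(max_properties = 1))
  expect_true(all(vapply(refs2, function(r) r$descriptor, "") == "MW"))

  # single distinct value in coverage: nothing to shrink
  d3 <- description(MW = c(150, 150))
  refs3 <- refine_description(d3, toy, miner_config(max_properties = 1))
  expect_length(refs3, 0)
})

test_that("beam search attains the exhaustive optimum on the toy dataset", {
  cfg <- miner_config(min_supp = 2, beam_width = 1000, max_properties = 3,
                      max_supp = 700, max_output = 10)
  run <- mine_rules(toy, "vanillin", cfg)
  oracle <- oracle_best(toy, "vanillin", min_supp = 2, max_properties = 3)
  expect_equal(run$rules[[1]]$metrics$f_beta, oracle$f_beta)
})

test_that("a target carried by every molecule yields the perfect root rule", {
  vals <- matrix(runif(12), 6, 2,
                 dimnames = list(as.character(1:6), c("x", "y")))
  labels <- setNames(rep(list("allq"), 6), rownames(vals))
  ds <- odorant_dataset(vals, labels)
  run <- mine_rules(ds, "allq", miner_config(min_supp = 1, max_supp = 700))
  m <- run$rules[[1]]$metrics
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  expect_equal(m$f_beta, 1)
  expect_equal(nrow(run$rules[[1]]$rule$description), 0)
})

test_that("emitted rules satisfy every config constraint", {
  set.seed(11)
  for (rep in 1:20) {
    ds <- random_dataset(n = 12, p = 3, seed = 2000 + rep)
    cfg <- miner_config(min_supp = sample(2:4, 1), max_supp = sample(6:10, 1),
                        max_properties = sample(1:3, 1), beam_width = 8,
                        max_output = 20)
    Q <- ds$qualities[1]
    run <- mine_rules(ds, Q, cfg)
    for (e in run$rules) {
      expect_gte(e$metrics$support_D, cfg$min_supp)
      expect_lte(e$metrics$support_D, cfg$max_supp)
      expect_lte(nrow(e$rule$description), cfg$max_properties)
      # rules sorted by f_beta descending
    }
    fb <- vapply(run$rules, function(e) e$metrics$f_beta, 0)
    expect_true(all(diff(fb) <= 1e-12))
    expect_lte(length(run$rules), cfg$max_output)
  }
})

test_that("beam result never exceeds and (with wide beam) equals the oracle", {
  set.seed(31)
  for (rep in 1:8) {
    ds <- random_dataset(n = sample(6:8, 1), p = 3, seed = 3000 + rep)
    Q <- sample(ds$qualities, 1)
    cfg_narrow <- miner_config(min_supp = 2, beam_width = 2,
                               max_properties = 3, max_supp = 1000)
    cfg_wide <- miner_config(min_supp = 2, beam_width = 100000,
                             max_properties = 3, max_supp = 1000)
    oracle <- oracle_best(ds, Q, min_supp = 2, max_properties = 3)
    narrow <- mine_rules(ds, Q, cfg_narrow)
    wide <- mine_rules(ds, Q, cfg_wide)
    if (length(narrow$rules))
      expect_lte(narrow$rules[[1]]$metrics$f_beta, oracle$f_beta + 1e-12)
    expect_equal(wide$rules[[1]]$metrics$f_beta, oracle$f_beta)
  }
})

test_that("mining output is invariant to input row order", {
  ds <- random_dataset(n = 10, p = 3, seed = 77)
  perm <- c(4, 9, 1, 7, 2, 10, 5, 3, 8, 6)
  ds2 <- odorant_dataset(ds$values[perm, ], ds$labels[perm],
                         ids = ds$ids[perm])
  cfg <- miner_config(min_supp = 2, beam_width = 10, max_properties = 3,
                      max_supp = 1000, max_output = 15)
  r1 <- mine_rules(ds, ds$qualities[1], cfg)
  r2 <- mine_rules(ds2, ds$qualities[1], cfg)
  cov1 <- lapply(r1$rules, function(e) sort(e$coverage))
  cov2 <- lapply(r2$rules, function(e) sort(e$coverage))
  expect_identical(cov1, cov2)
  expect_identical(lapply(r1$rules, function(e) e$rule$description),
                   lapply(r2$rules, function(e) e$rule$description))
})

test_that("raising min_supp never adds rules to the feasible set", {
  ds <- random_dataset(n = 12, p = 3, seed = 55)
  Q <- ds$qualities[1]
  covs_at <- function(ms) {
    run <- mine_rules(ds, Q, miner_config(min_supp = ms, beam_width = 100000,
                                          max_properties = 3,
                                          max_supp = 1000, max_output = 1000))
    lapply(run$rules, function(e) sort(e$coverage))
  }
  c2 <- covs_at(2)
  c4 <- covs_at(4)
  expect_true(all(c4 %in% c2))
})

test_that("mine_all mines each eligible target and survives failures", {
  cfg <- miner_config(min_supp = 2, beam_width = 20, max_properties = 3,
                      max_supp = 700)
  runs <- mine_all(toy, cfg)
  expect_identical(names(runs), c("fruity", "vanillin", "woody"))
  expect_true(all(vapply(runs, inherits, TRUE, "MiningRun")))
  # reruns are bit-for-bit identical
  runs2 <- mine_all(toy, cfg)
  expect_identical(lapply(runs, `[[`, "rules"), lapply(runs2, `[[`, "rules"))
})

test_that("ruleset JSON round trips bit-exactly", {
  cfg <- miner_config(min_supp = 2, beam_width = 30, max_properties = 3,
                      max_supp = 700)
  run <- mine_rules(toy, "vanillin", cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_ruleset(run, path)
  back <- read_ruleset(path)
  expect_length(back, length(run$rules))
  for (i in seq_along(back)) {
    expect_identical(back[[i]]$rule$description,
                     run$rules[[i]]$rule$description)
    expect_identical(back[[i]]$rule$qualities, run$rules[[i]]$rule$qualities)
    expect_identical(back[[i]]$metrics$f_beta, run$rules[[i]]$metrics$f_beta)
    expect_identical(back[[i]]$metrics$precision,
                     run$rules[[i]]$metrics$precision)
  }
  # a second write of the re-read rules is byte-identical
  path2 <- withr::local_tempfile(fileext = ".json")
  write_ruleset(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("YAML config accepts the study's printed field names", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("maxoutput: 100", "beamwidth: 30", "MaxQual: 1",
               "MaxProperties: 8", "maxSupp: 700", "XBeta: 110",
               "lBeta: 20", "minSupp: [5, 10, 20, 30]"), path)
  cfg <- read_miner_config(path)
  expect_equal(cfg$max_output, 100L)
  expect_equal(cfg$beam_width, 30L)
  expect_equal(cfg$max_qual, 1L)
  expect_equal(cfg$max_properties, 8L)
  expect_equal(cfg$max_supp, 700L)
  expect_equal(cfg$x_beta, 110)
  expect_equal(cfg$l_beta, 20)
  expect_equal(cfg$min_supp, 5L)
  expect_identical(attr(cfg, "min_supp_sweep"), c(5L, 10L, 20L, 30L))
})

test_that("quantile refinement grid recovers coarse structure", {
  set.seed(9)
  spec <- synthetic_spec(n_molecules = 200, n_descriptors = 3,
                         planted_rules = list(planted_rule(
                           "target",
                           description(d01 = c(0.25, 0.75),
                                       d02 = c(0.25, 0.75)),
                           p_inside = 1, p_outside = 0)),
                         n_background_qualities = 3,
                         mean_labels_per_molecule = 1.5,
                         support_range = c(5, 60), seed = 9)
  gen <- generate_dataset(spec)
  cfg <- miner_config(min_supp = 5, beam_width = 20, max_properties = 4,
                      max_supp = 700, grid = 16)
  run <- mine_rules(gen$dataset, "target", cfg)
  expect_gte(recovery_score(run, gen$truth[[1]], gen$dataset), 0.8)
})
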