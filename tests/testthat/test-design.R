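test_that("full factorial enumeration has the right size and no duplicates", {
  expect_equal(nrow(enumerate_profiles(huimin_attributes())), 324)
  one <- attribute_dictionary(list(
    a = list(levels = c(1, 2, 3), coding = "linear", sign = "+", unit_scale = 1)))
  expect_equal(nrow(enumerate_profiles(one)), 3)
  toy <- enumerate_profiles(toy_attrs2())
  expect_equal(nrow(toy), 4)
  expect_equal(anyDuplicated(toy), 0)
})

test_that("dominance screening follows the hypothesized preference signs", {
  attrs <- huimin_attributes()
  worst <- data.frame(premium = 210, government = "commercial",
                      deductible = 180000, reimbursement = 50,
                      services = "basic", stringsAsFactors = FALSE)
  best <- data.frame(premium = 130, government = "strong",
                     deductible = 120000, reimbursement = 80,
                     services = "expanded1", stringsAsFactors = FALSE)
  expect_true(is_dominated(worst, best, attrs))
  expect_false(is_dominated(best, worst, attrs))
  # identical profiles: no strict improvement
  expect_false(is_dominated(best, best, attrs))
  # expanded packages are mutually incomparable
  e2 <- best; e2$services <- "expanded2"
  expect_false(is_dominated(best, e2, attrs))
  expect_false(is_dominated(e2, best, attrs))
  # moderate and strong government involvement tie
  mod <- best; mod$government <- "moderate"
  expect_false(is_dominated(mod, best, attrs))
})

test_that("the QC set pairs a dominant with a dominated profile", {
  attrs <- huimin_attributes()
  qc <- make_qc_set(attrs)
  expect_equal(nrow(qc), 2)
  expect_true(all(qc$is_qc))
  anames <- names(attrs$attributes)
  expect_true(is_dominated(qc[2, anames], qc[1, anames], attrs))
})

test_that("D-error matches a utility-neutral brute-force oracle and is
           permutation invariant", {
  d <- fx_design()
  de <- d_error(d)
  expect_equal(de, oracle_derror_neutral(d, d$attrs), tolerance = 1e-10)
  # permutation invariance over choice sets
  perm <- d
  sets <- perm$sets[!perm$sets$is_qc, ]
  ord <- unique(sets$set_id)
  relabel <- setNames(sample(ord), ord)
  sets$set_id <- relabel[as.character(sets$set_id)]
  sets <- sets[order(sets$set_id, sets$alt_id), ]
  perm$sets <- rbind(sets, perm$sets[perm$sets$is_qc, ])
  expect_equal(d_error(perm), de, tolerance = 1e-12)
})

test_that("duplicating every choice set halves the D-error", {
  d <- fx_design()
  dup <- d
  sets <- d$sets[!d$sets$is_qc, ]
  extra <- sets
  extra$set_id <- extra$set_id + max(sets$set_id)
  dup$sets <- rbind(sets, extra)
  dup$sets$is_qc <- FALSE
  expect_equal(d_error(dup), d_error(d) / 2, tolerance = 1e-10)
})

test_that("an uninformative design signals non-identification", {
  attrs <- huimin_attributes()
  base <- data.frame(government = "commercial", deductible = 120000,
                     reimbursement = 50, services = "basic",
                     stringsAsFactors = FALSE)
  sets <- do.call(rbind, lapply(1:4, function(s) {
    cbind(set_id = s, block_id = 1L, alt_id = 1:2, is_qc = FALSE,
          premium = c(130, 210), base)
  }))
  d <- hcmdce:::new_choice_design(sets, attrs,
                                  priors = hcmdce:::zero_priors(attrs),
                                  asc_prior = 0)
  expect_error(d_error(d), "not identified")
})

test_that("coordinate exchange reproduces the exhaustive optimum on a
           two-attribute toy", {
  attrs <- toy_attrs2()
  profs <- enumerate_profiles(attrs)
  # exhaustive search over all two-set designs of distinct profile pairs
  # with full level coverage (the dominance screen is off in this classical
  # utility-neutral benchmark, where it would exclude every pairing)
  best <- Inf
  for (i1 in 1:4) for (j1 in 1:4) for (i2 in 1:4) for (j2 in 1:4) {
    if (i1 == j1 || i2 == j2) next
    sets <- data.frame(set_id = rep(1:2, each = 2), block_id = 1L,
                       alt_id = rep(1:2, 2), is_qc = FALSE,
                       a1 = profs$a1[c(i1, j1, i2, j2)],
                       a2 = profs$a2[c(i1, j1, i2, j2)])
    if (!all(c(0, 1) %in% sets$a1) || !all(c(0, 1) %in% sets$a2)) next
    d <- hcmdce:::new_choice_design(sets, attrs,
                                    priors = hcmdce:::zero_priors(attrs),
                                    asc_prior = 0)
    de <- tryCatch(d_error(d), error = function(e) Inf)
    best <- min(best, de)
  }
  out <- generate_design(attrs, n_sets = 2L, n_blocks = 1L, seed = 11L,
                         n_restarts = 20L, screen_dominated = FALSE)
  expect_equal(out$d_error, best, tolerance = 1e-9)
})

test_that("generated designs have the required structure", {
  d <- fx_design()
  attrs <- d$attrs
  exp_sets <- d$sets[!d$sets$is_qc, ]
  expect_equal(length(unique(exp_sets$set_id)), 24)
  expect_equal(sort(unique(exp_sets$block_id)), 1:4)
  expect_true(all(table(exp_sets$block_id) == 12))  # 6 sets x 2 alternatives
  expect_equal(sum(d$sets$is_qc), 2)
  expect_true(block_coverage_ok(d))
  # no experimental set holds a dominated or degenerate pair
  anames <- names(attrs$attributes)
  for (sid in unique(exp_sets$set_id)) {
    pr <- exp_sets[exp_sets$set_id == sid, anames]
    expect_false(isTRUE(all.equal(pr[1, ], pr[2, ], check.attributes = FALSE)))
    expect_false(is_dominated(pr[1, ], pr[2, ], attrs))
    expect_false(is_dominated(pr[2, ], pr[1, ], attrs))
  }
  # monotone improvement and no worse than the random start
  expect_true(all(diff(d$trace$d_error) <= 1e-12))
  expect_lte(d$d_error, d$trace$initial_d_error)
})

test_that("design generation is deterministic and round-trips through CSV", {
  d1 <- generate_design(toy_attrs3(), n_sets = 6L, n_blocks = 2L, seed = 5L,
                        n_restarts = 2L)
  d2 <- generate_design(toy_attrs3(), n_sets = 6L, n_blocks = 2L, seed = 5L,
                        n_restarts = 2L)
  expect_identical(d1$sets, d2$sets)
  expect_equal(d1$d_error, d2$d_error)
  path <- tempfile(fileext = ".csv")
  write_design(d1, path)
  d3 <- read_design(path, toy_attrs3())
  expect_equal(d3$sets$set_id, d1$sets$set_id)
  expect_equal(d_error(d3), d1$d_error, tolerance = 1e-12)
})
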