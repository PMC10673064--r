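test_that("rank_by sorts, tie-breaks by the secondary value, then by name", {
  ref <- reference_ranking()
  # the multivariate hazard ratios contain a genuine tie (1.14 twice),
  # resolved by the smaller p-value
  ranks <- rank_by(setNames(ref$multi_hr, ref$variable),
                   tiebreak = setNames(ref$multi_p, ref$variable))
  expect_equal(unname(ranks[ref$variable]), ref$multi_rank)
  expect_equal(unname(ranks["size"]), 7L)
  expect_equal(unname(ranks["albumin"]), 8L)

  # distinct values, desc: reversed order statistics
  v <- c(a = 3, b = 9, c = 1)
  expect_equal(rank_by(v), c(a = 2L, b = 1L, c = 3L))
  expect_equal(rank_by(v, "asc"), c(a = 2L, b = 3L, c = 1L))

  # fully tied primary: decided by tiebreak then name
  v2 <- c(x = 1, y = 1, z = 1)
  expect_equal(rank_by(v2, tiebreak = c(x = 0.3, y = 0.1, z = 0.3)),
               c(x = 2L, y = 1L, z = 3L))
  expect_error(rank_by(c(a = 1, b = NaN)), "non-finite")
})

test_that("build_rank_table reproduces the published rank columns", {
  ref <- reference_ranking()
  vars <- ref$variable
  km <- lapply(seq_along(vars), function(i)
    structure(list(chi_square = ref$chi_square[i], df = 1L,
                   p_value = ref$logrank_p[i], defined = TRUE),
              class = "logrank_test"))
  names(km) <- vars
  is_ <- setNames(as.list(ref$is_months), vars)
  uni <- lapply(seq_along(vars), function(i)
    structure(list(coefficients = setNames(log(ref$uni_hr[i]), vars[i]),
                   hr = setNames(ref$uni_hr[i], vars[i]),
                   p_value = setNames(ref$uni_p[i], vars[i])),
              class = "cox_fit"))
  names(uni) <- vars
  multi <- structure(list(coefficients = setNames(log(ref$multi_hr), vars),
                          hr = setNames(ref$multi_hr, vars),
                          p_value = setNames(ref$multi_p, vars),
                          ci_lower = setNames(ref$multi_lo, vars),
                          ci_upper = setNames(ref$multi_hi, vars),
                          converged = TRUE),
                     class = "cox_fit")

  tab <- build_rank_table(km, is_, uni, multi)
  expect_equal(tab$km_rank, ref$km_rank)
  expect_equal(tab$is_rank, ref$is_rank)
  expect_equal(tab$uni_rank, ref$uni_rank)
  expect_equal(tab$multi_rank, ref$multi_rank)

  # permuting the input variable order leaves every rank unchanged
  perm <- c(5, 3, 9, 1, 7, 2, 8, 6, 4)
  tab2 <- build_rank_table(km[perm], is_[perm], uni[perm], multi)
  expect_equal(tab2$km_rank[match(vars, tab2$variable)], ref$km_rank)
  expect_equal(tab2$multi_rank[match(vars, tab2$variable)], ref$multi_rank)

  expect_error(build_rank_table(km[-1], is_, uni, multi), "differ")
})

test_that("final ranking reproduces the published overall order", {
  ref <- reference_ranking()
  tab <- structure(data.frame(variable = ref$variable,
                              is_rank = ref$is_rank,
                              multi_rank = ref$multi_rank),
                   class = c("rank_table", "data.frame"))
  fin <- final_ranking(tab, "multivariate")
  expect_equal(unname(fin[ref$variable]), ref$final_rank)
  # named spot checks of the published overall ranks
  expect_equal(unname(fin["margin"]), 1L)
  expect_equal(unname(fin["crp"]), 3L)
  expect_equal(unname(fin["fibrinogen"]), 9L)

  blend <- final_ranking(tab, "mean_is_multivariate")
  expect_equal(unname(blend[c("margin", "nodes", "crp", "asa")]), 1:4)
  expect_error(final_ranking(tab, "nonsense"))
})

test_that("both final methods agree on a two-variable table", {
  tab <- structure(data.frame(variable = c("a", "b"),
                              is_rank = c(1L, 2L), multi_rank = c(1L, 2L)),
                   class = c("rank_table", "data.frame"))
  expect_equal(final_ranking(tab, "multivariate"),
               final_ranking(tab, "mean_is_multivariate"))
})

test_that("the default final rule ignores changes confined to R1a/R1b", {
  ref <- reference_ranking()
  tab <- structure(data.frame(variable = ref$variable,
                              is_rank = ref$is_rank,
                              multi_rank = ref$multi_rank),
                   class = c("rank_table", "data.frame"))
  shuffled <- tab
  shuffled$is_rank <- rev(tab$is_rank)
  expect_equal(final_ranking(tab, "multivariate"),
               final_ranking(shuffled, "multivariate"))
})

test_that("the end-to-end pipeline produces valid permutations and reports", {
  co <- generate_cohort(study_config(seed = 21))
  r <- rank_factors(co)
  tab <- r$table
  expect_equal(nrow(tab), 9L)
  for (col in c("km_rank", "is_rank", "uni_rank", "multi_rank", "final_rank"))
    expect_setequal(tab[[col]], 1:9)

  lines <- render_report(r)
  expect_true(any(grepl("Kaplan-Meier", lines)))
  expect_true(any(grepl("Rank summary", lines)))
  # deterministic: regenerating from the same config renders byte-identically
  r2 <- rank_factors(generate_cohort(study_config(seed = 21)))
  expect_identical(lines, render_report(r2))
  # and a different seed changes the cohort
  expect_false(identical(lines,
                         render_report(rank_factors(
                           generate_cohort(study_config(seed = 22))))))
})

test_that("strong true effects surface near the top of the final ranking", {
  hits <- vapply(1:20, function(s) {
    co <- generate_cohort(study_config(n = 2000, seed = 300 + s))
    fin <- rank_factors(co)$table
    fin$final_rank[fin$variable == "margin"] <= 3 &&
      fin$final_rank[fin$variable == "nodes"] <= 3
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
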