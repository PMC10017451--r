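test_that("the sweep produces one record per step up to the cap", {
  gen <- tiny_dataset(seed = 21, sizes = c(20, 25, 30), n_genes = 40,
                      n_informative = 3)
  rk <- rank_mrmr(gen$dataset)
  cv <- run_ifs(gen$dataset, rk, classifier = "dt", step = 10, cap = 30,
                folds = 5, seed = 1)
  expect_length(cv$records, 3)
  expect_equal(vapply(cv$records, `[[`, numeric(1), "subset_size"),
               c(10, 20, 30))
  # sizes strictly increasing; each evaluation pools one prediction per cell
  expect_true(all(diff(vapply(cv$records, `[[`, numeric(1),
                              "subset_size")) > 0))
  for (r in cv$records)
    expect_equal(sum(r$eval$confusion), nrow(gen$dataset$values))
})

test_that("IFS curves are reproducible and respect the ranking prefix", {
  gen <- tiny_dataset(seed = 22, sizes = c(20, 20, 20), n_genes = 30,
                      n_informative = 3)
  rk <- rank_lasso(gen$dataset)
  cv1 <- run_ifs(gen$dataset, rk, classifier = "rf", step = 10, cap = 20,
                 folds = 4, rf_trees = 30, seed = 9)
  cv2 <- run_ifs(gen$dataset, rk, classifier = "rf", step = 10, cap = 20,
                 folds = 4, rf_trees = 30, seed = 9)
  expect_equal(ifsrank:::curve_wf1(cv1), ifsrank:::curve_wf1(cv2))
  expect_identical(cv1$optimal_index, cv2$optimal_index)
})

test_that("optimal selection takes the max weighted F1, ties to smaller size", {
  incr <- fake_curve(c(10, 20, 30), c(0.5, 0.6, 0.7))
  expect_equal(select_optimal(incr), 3L)
  tied <- fake_curve(c(10, 20, 30), c(0.5, 0.7, 0.7))
  expect_equal(select_optimal(tied), 2L)
  single <- fake_curve(10, 0.4)
  expect_equal(select_optimal(single), 1L)
  empty <- fake_curve(10, 0.4)
  empty$records <- list()
  expect_error(select_optimal(empty), "empty")
})

test_that("feasibility rule matches its definition and the worked example", {
  # large optimum at the cap, earlier record within delta -> feasible
  sizes <- seq(10, 2960, by = 10)
  wf1 <- rep(0.80, length(sizes))
  wf1[sizes == 30] <- 0.845
  wf1[sizes == 2960] <- 0.853
  cv <- fake_curve(sizes, wf1)
  idx <- select_feasible(cv, delta = 0.015, min_optimal_size = 100)
  expect_equal(sizes[idx], 30)      # gap 0.008 <= 0.015 qualifies
  # small optimum -> no feasible classifier is sought
  small <- fake_curve(c(10, 20, 30), c(0.80, 0.82, 0.85))
  expect_true(is.na(select_feasible(small, min_optimal_size = 100)))
  # flat curve with the optimum at the cap -> first record is feasible
  flat <- fake_curve(seq(10, 200, 10), rep(0.9, 20))
  expect_equal(select_feasible(flat, min_optimal_size = 100), NA_integer_)
  # (flat curve: optimum is the FIRST max = size 10 <= 100, so none)
  flat2 <- fake_curve(seq(110, 400, 10), rep(0.9, 30))
  expect_equal(select_feasible(flat2, min_optimal_size = 100), NA_integer_)
  expect_error(select_feasible(small, delta = -0.1), "non-negative")
})

test_that("feasibility agrees with a linear-scan oracle on random curves", {
  withr::with_seed(606, {
    for (rep in 1:25) {
      k <- sample(5:40, 1)
      sizes <- seq(10, by = 10, length.out = k)
      wf1 <- round(runif(k, 0.5, 1), 3)
      cv <- fake_curve(sizes, wf1)
      got <- select_feasible(cv, delta = 0.015, min_optimal_size = 100)
      want <- feasible_oracle(sizes, wf1, 0.015, 100)
      expect_identical(got, want)
    }
  })
})

test_that("SMOTE rows never leak into evaluation", {
  # evaluation must use exactly the original cells: confusion totals match
  # the dataset and every true-label margin matches the class counts
  gen <- tiny_dataset(seed = 23, sizes = c(15, 20, 40), n_genes = 20,
                      n_informative = 2)
  rk <- rank_mrmr(gen$dataset)
  cv <- run_ifs(gen$dataset, rk, classifier = "dt", step = 10, cap = 10,
                folds = 5, seed = 2)
  conf <- cv$records[[1]]$eval$confusion
  expect_equal(unname(rowSums(conf)),
               unname(as.integer(table(gen$dataset$labels))))
})

test_that("run_matrix covers every pair and summarizes them", {
  gen <- tiny_dataset(seed = 24, sizes = c(15, 15, 20), n_genes = 20,
                      n_informative = 2)
  rk <- list(mrmr = rank_mrmr(gen$dataset), lasso = rank_lasso(gen$dataset))
  res <- run_matrix(gen$dataset, rk, classifiers = c("dt", "rf"),
                    step = 10, cap = 20, folds = 3, rf_trees = 20, seed = 5)
  expect_named(res$curves, c("mrmr_dt", "mrmr_rf", "lasso_dt", "lasso_rf"))
  expect_gte(nrow(res$summary), 4)
  expect_true(all(c("ranking", "classifier", "n_features", "ACC", "MCC",
                    "macro_F1", "weighted_F1") %in% colnames(res$summary)))
  # one ranking, one classifier -> a single curve
  res1 <- run_matrix(gen$dataset, rk["mrmr"], classifiers = "dt",
                     step = 10, cap = 10, folds = 3, seed = 5)
  expect_length(res1$curves, 1)
})

test_that("IFS preconditions are enforced", {
  gen <- tiny_dataset(seed = 25, sizes = c(4, 30, 30), n_genes = 20,
                      n_informative = 2)
  rk <- rank_mrmr(gen$dataset)
  expect_error(run_ifs(gen$dataset, rk, "dt", folds = 10, seed = 1),
               "10 folds")
  short <- gene_ranking("mrmr", gen$dataset$gene_ids[1:5], 5:1)
  expect_error(run_ifs(gen$dataset, short, "dt", step = 10, folds = 2,
                       seed = 1), "shorter")
})
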