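test_that("mRMR reproduces the exhaustive greedy oracle on small datasets", {
  withr::with_seed(202, {
    for (rep in 1:5) {
      p <- sample(4:8, 1)
      n <- 120
      labels <- factor(sample(c("a", "b", "c"), n, replace = TRUE))
      m <- matrix(rnorm(n * p, 2, 1), n, p)
      m[labels == "a", 1] <- m[labels == "a", 1] + 2   # one informative gene
      m[m < 0] <- 0
      colnames(m) <- sprintf("g%02d", 1:p)
      rownames(m) <- sprintf("c%03d", 1:n)
      ds <- expr_dataset(m, labels = labels)
      rk <- rank_mrmr(ds, top_n = p)
      disc_cols <- lapply(seq_len(p), function(j)
        as.character(discretize_gene(m[, j])))
      oracle <- mrmr_oracle(disc_cols, as.character(labels), p)
      expect_identical(rk$ordered_genes, colnames(m)[oracle])
    }
  })
})

test_that("mRMR puts a planted gene first and penalizes duplicated copies", {
  gen <- tiny_dataset(seed = 12, sizes = c(80, 80, 80), n_genes = 6,
                      n_informative = 1, effect = 3, dropout = 0.1)
  ds <- gen$dataset
  rk <- rank_mrmr(ds)
  expect_identical(rk$ordered_genes[1], gen$truth$informative_genes)
  # duplicate the top gene and add a second, independent informative gene:
  # the copy is fully redundant and must rank below the independent gene
  m <- ds$values
  m <- cbind(m, copy = m[, rk$ordered_genes[1]])
  m[ds$labels == levels(ds$labels)[2], "G0002"] <-
    m[ds$labels == levels(ds$labels)[2], "G0002"] + 2
  ds2 <- expr_dataset(m, labels = ds$labels)
  rk2 <- rank_mrmr(ds2)
  expect_lt(match("G0002", rk2$ordered_genes),
            match("copy", rk2$ordered_genes))
  # full ordering is a permutation
  expect_setequal(rk2$ordered_genes, ds2$gene_ids)
})

test_that("MCFS tree contributions match hand-computed Gini accounting", {
  # a perfectly separable stump: root Gini 0.5, pure children, IG = 0.5
  df <- data.frame(g = c(1, 2, 3, 4, 11, 12, 13, 14),
                   noise = rep(0, 8),
                   .class = factor(rep(c("a", "b"), each = 4)))
  fit <- rpart::rpart(.class ~ ., df, method = "class",
                      parms = list(split = "gini"),
                      control = rpart::rpart.control(cp = 0, xval = 0,
                                                     minsplit = 2,
                                                     minbucket = 1,
                                                     maxcompete = 0,
                                                     maxsurrogate = 0))
  contrib <- ifsrank:::mcfs_tree_contributions(fit, v = 1)
  expect_named(contrib, "g")
  expect_equal(unname(contrib), 0.5)
  # with v = 0 the node-mass weight drops out; the single split still
  # contributes its impurity decrease
  expect_equal(unname(ifsrank:::mcfs_tree_contributions(fit, v = 0)), 0.5)
})

test_that("MCFS per-tree mass-weighted contributions satisfy the leaf identity", {
  # for v = 1, summing IG * n_node/n_root over all splits telescopes to
  # Gini(root) - sum over leaves of (n_leaf/n_root) * Gini(leaf)
  withr::with_seed(303, {
    for (rep in 1:5) {
      n <- 150
      df <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
      df$.class <- factor(ifelse(df$x1 + rnorm(n, 0, 0.7) > 0, "a",
                                 ifelse(df$x2 > 0.3, "b", "c")))
      fit <- rpart::rpart(.class ~ ., df, method = "class",
                          parms = list(split = "gini"),
                          control = rpart::rpart.control(cp = 0, xval = 0,
                                                         minsplit = 10,
                                                         maxcompete = 0,
                                                         maxsurrogate = 0))
      contrib <- ifsrank:::mcfs_tree_contributions(fit, v = 1)
      gini <- function(y) 1 - sum((table(y) / length(y))^2)
      leaf <- fit$where
      leaf_term <- sum(vapply(split(df$.class, leaf), function(y)
        length(y) / n * gini(y), numeric(1)))
      expect_equal(sum(contrib), gini(df$.class) - leaf_term,
                   tolerance = 1e-10)
    }
  })
})

test_that("MCFS scores genes outside every projection exactly zero", {
  gen <- tiny_dataset(seed = 13, sizes = c(30, 30, 30), n_genes = 20,
                      n_informative = 2)
  rk <- rank_mcfs(gen$dataset, mcfs_params(s = 2, t = 1, m = 3, seed = 5))
  # at most 6 genes can have been seen; the rest must score exactly 0
  expect_gte(sum(rk$scores == 0), 20 - 6)
  expect_true(all(diff(rk$scores) <= 1e-12))   # non-increasing
  expect_setequal(rk$ordered_genes, gen$dataset$gene_ids)
})

test_that("lasso ranking: nulls collapse to zero, planted genes surface", {
  gen0 <- generate_dataset(synth_spec(class_sizes = c(40, 40, 40),
                                      n_genes = 15, n_informative = 0,
                                      seed = 14))
  rk0 <- rank_lasso(gen0$dataset, lambda = 5)   # strong penalty
  expect_true(all(rk0$scores == 0))
  expect_identical(rk0$ordered_genes, gen0$dataset$gene_ids)

  gen <- tiny_dataset(seed = 15, sizes = c(60, 60, 60), n_genes = 20,
                      n_informative = 2, effect = 3, dropout = 0.2)
  rk <- rank_lasso(gen$dataset)
  expect_true(all(gen$truth$informative_genes %in% rk$ordered_genes[1:4]))
  expect_gt(rk$scores[1], 0)

  # duplicating every cell leaves the ranking unchanged
  ds <- gen$dataset
  ds2 <- expr_dataset(rbind(ds$values, ds$values),
                      cell_ids = c(ds$cell_ids, paste0(ds$cell_ids, "_2")),
                      labels = c(as.character(ds$labels),
                                 as.character(ds$labels)))
  rk2 <- rank_lasso(ds2)
  expect_identical(rk2$ordered_genes, rk$ordered_genes)
})

test_that("GBDT split counts conserve the internal node total", {
  gen <- tiny_dataset(seed = 16, sizes = c(50, 50, 50), n_genes = 25,
                      n_informative = 3)
  ds <- gen$dataset
  # a constant gene can never host a split and must score exactly 0
  m <- cbind(ds$values, flatgene = rep(1.5, nrow(ds$values)))
  ds <- expr_dataset(m, labels = ds$labels)
  rk <- rank_gbdt_split(ds, n_rounds = 20, seed = 1)
  expect_true(all(diff(rk$scores) <= 0))
  expect_setequal(rk$ordered_genes, ds$gene_ids)
  flat <- match("flatgene", rk$ordered_genes)
  expect_equal(rk$scores[flat], 0)
  expect_equal(rk$extra$gain[flat], 0)
  # planted genes carry the bulk of the splits
  expect_true(all(gen$truth$informative_genes %in% rk$ordered_genes[1:6]))
})

test_that("PFI ranks a label-leaking gene first, reproducibly", {
  withr::with_seed(404, {
    n <- 150
    labels <- factor(sample(c("a", "b", "c"), n, replace = TRUE))
    m <- matrix(pmax(0, rnorm(n * 10, 2, 1)), n, 10)
    m[, 1] <- as.integer(labels)          # perfect predictor
    colnames(m) <- sprintf("g%02d", 1:10)
    rownames(m) <- sprintf("c%03d", 1:n)
    ds <- expr_dataset(m, labels = labels)
  })
  rk <- rank_pfi(ds, pfi_params(K = 10, seed = 6))
  expect_identical(rk$ordered_genes[1], "g01")
  # determinism under a fixed seed
  rk2 <- rank_pfi(ds, pfi_params(K = 10, seed = 6))
  expect_identical(rk$scores, rk2$scores)
  expect_identical(rk$ordered_genes, rk2$ordered_genes)
})

test_that("PFI null behaviour: unused genes score exactly 1, used nulls stay below signal", {
  # a constant gene can never be routed through, so permuting it leaves
  # every prediction unchanged and its importance ratio is exactly 1
  withr::with_seed(405, {
    n <- 200
    m <- matrix(pmax(0, rnorm(n * 8, 2, 1)), n, 8)
    labels <- factor(sample(c("a", "b", "c"), n, replace = TRUE))
    m[, 1] <- as.integer(labels) + rnorm(n, 0, 0.1)
    m[, 8] <- 1.5
    colnames(m) <- sprintf("g%02d", 1:8)
    rownames(m) <- sprintf("c%03d", 1:n)
    ds <- expr_dataset(m, labels = labels)
  })
  rk <- rank_pfi(ds, pfi_params(K = 5, seed = 7))
  expect_equal(rk$scores[match("g08", rk$ordered_genes)], 1)
  # the strongly predictive gene dominates every null gene
  expect_identical(rk$ordered_genes[1], "g01")
  expect_gt(rk$scores[1], max(rk$scores[-1]))
  # the difference mode is available and gives an all-non-negative profile
  rkd <- rank_pfi(ds, pfi_params(K = 5, mode = "difference", seed = 7))
  expect_equal(rkd$scores[match("g08", rkd$ordered_genes)], 0)
})

test_that("PFI touched-row shortcut equals brute-force forest re-evaluation", {
  gen <- tiny_dataset(seed = 17, sizes = c(30, 40, 50), n_genes = 12,
                      n_informative = 2)
  ds <- gen$dataset
  n <- nrow(ds$values)
  rf <- ranger::ranger(x = ds$values, y = ds$labels, num.trees = 25,
                       seed = 3, num.threads = 1)
  fo <- ifsrank:::flatten_forest(rf)
  base_votes <- ifsrank:::cpp_forest_votes(fo$offsets, fo$left, fo$right,
                                           fo$svar, fo$sval, fo$pred,
                                           ds$values)
  yi <- as.integer(ds$labels)
  for (j in c(1L, 5L)) {
    perm <- withr::with_seed(j, sample.int(n))
    Xp <- ds$values
    Xp[, j] <- Xp[perm, j]
    votes_p <- ifsrank:::cpp_forest_votes(fo$offsets, fo$left, fo$right,
                                          fo$svar, fo$sval, fo$pred, Xp)
    counts_p <- ifsrank:::cpp_vote_counts(votes_p, 3L)
    err_brute <- mean(max.col(counts_p, ties.method = "first") != yi)

    touch <- ifsrank:::cpp_touch_lists(fo$offsets, fo$left, fo$right,
                                       fo$svar, fo$sval, fo$pred, ds$values)
    trees <- integer(0); rows <- list()
    for (t in seq_len(fo$n_trees)) {
      vi <- match(j - 1L, touch[[t]]$vars)
      if (!is.na(vi)) {
        trees <- c(trees, t - 1L)
        rows[[length(rows) + 1L]] <-
          touch[[t]]$rows[(touch[[t]]$offsets[vi] + 1L):touch[[t]]$offsets[vi + 1L]]
      }
    }
    err_fast <- ifsrank:::cpp_pfi_gene(
      fo$offsets, fo$left, fo$right, fo$svar, fo$sval, fo$pred, ds$values,
      j - 1L, matrix(perm, ncol = 1), base_votes,
      ifsrank:::cpp_vote_counts(base_votes, 3L), yi, trees, rows, 3L)
    expect_equal(err_fast, err_brute)
  }
})

test_that("rank_all returns consistent, reproducible permutations", {
  gen <- tiny_dataset(seed = 18, sizes = c(30, 30, 30), n_genes = 15,
                      n_informative = 2)
  ds <- gen$dataset
  cfg <- list(mcfs = mcfs_params(s = 10, t = 2, seed = 1),
              pfi = pfi_params(K = 2, seed = 2))
  all1 <- rank_all(ds, mcfs = cfg$mcfs, pfi = cfg$pfi, gbdt_rounds = 10,
                   seed = 3)
  expect_named(all1, c("mrmr", "mcfs", "lasso", "gbdt_split", "pfi"))
  for (rk in all1) expect_setequal(rk$ordered_genes, ds$gene_ids)
  all2 <- rank_all(ds, mcfs = cfg$mcfs, pfi = cfg$pfi, gbdt_rounds = 10,
                   seed = 3)
  for (m in names(all1))
    expect_identical(all1[[m]]$ordered_genes, all2[[m]]$ordered_genes)
})

test_that("stronger planted effects never worsen median planted rank", {
  effects <- c(0.5, 1, 2)
  med_rank <- vapply(effects, function(es) {
    ranks <- vapply(1:3, function(s) {
      gen <- generate_dataset(synth_spec(class_sizes = c(100, 100, 100),
                                         n_genes = 100, n_informative = 5,
                                         effect_size = es, seed = s))
      rk <- rank_gbdt_split(gen$dataset, n_rounds = 30, seed = s)
      stats::median(match(gen$truth$informative_genes, rk$ordered_genes))
    }, numeric(1))
    stats::median(ranks)
  }, numeric(1))
  expect_true(all(diff(med_rank) <= 0))
})

test_that("ranker input validation", {
  gen <- tiny_dataset(seed = 19, sizes = c(10, 10), n_genes = 5,
                      n_informative = 1)
  ds <- gen$dataset
  expect_error(rank_mrmr(ds, top_n = 0), "positive")
  expect_error(rank_mrmr(ds, top_n = 99), "exceeds")
  expect_error(rank_mcfs(ds, mcfs_params(m = 10, seed = 1)), "exceeds")
  expect_error(pfi_params(K = 0), "K")
  one_class <- expr_dataset(ds$values, labels = rep("a", 20))
  expect_error(rank_lasso(one_class), "two classes")
  expect_error(rank_gbdt_split(one_class), "two classes")
})
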