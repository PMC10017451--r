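ctrl <- rpart::rpart.control(cp = 0, xval = 0, minsplit = 2, minbucket = 1,
                             maxcompete = 0, maxsurrogate = 0,
                             usesurrogate = 0)

test_that("a stump yields two complementary threshold rules", {
  df <- data.frame(G = c(1, 2, 3, 4),
                   .class = factor(c("x", "x", "y", "y")))
  fit <- rpart::rpart(.class ~ G, df, method = "class",
                      parms = list(split = "gini"), control = ctrl)
  rs <- extract_rules(fit)
  expect_length(rs$rules, 2)
  expect_equal(rs$n_leaves, 2)
  expect_equal(as.integer(rs$class_counts), c(1L, 1L))
  preds <- lapply(rs$rules, `[[`, "predicates")
  expect_equal(vapply(preds, nrow, integer(1)), c(1L, 1L))
  expect_setequal(vapply(preds, function(p) p$cmp, character(1)),
                  c("<=", ">"))
  expect_equal(preds[[1]]$threshold, 2.5)
  # boundary convention: a value exactly at the threshold takes <=
  expect_equal(apply_rules(rs, c(G = 2.5)), "x")
  expect_equal(apply_rules(rs, c(G = 3.0)), "y")
})

test_that("a single-leaf tree gives one predicate-free rule", {
  df <- data.frame(G = rep(1, 6), .class = factor(rep(c("a", "a", "b"), 2)))
  fit <- rpart::rpart(.class ~ G, df, method = "class",
                      parms = list(split = "gini"), control = ctrl)
  rs <- extract_rules(fit)
  expect_length(rs$rules, 1)
  expect_equal(nrow(rs$rules[[1]]$predicates), 0)
  expect_equal(rs$rules[[1]]$predicted_class, "a")
  expect_equal(rs$rules[[1]]$support, 6)
  expect_equal(apply_rules(rs, c(G = 99)), "a")
})

test_that("repeated conditions on one gene merge to the tightest interval", {
  p <- data.frame(gene = c("G", "G", "H"), cmp = c("<=", "<=", ">"),
                  threshold = c(5.0, 3.9, 1.2))
  merged <- ifsrank:::merge_predicates(p)
  expect_equal(nrow(merged), 2)
  g <- merged[merged$gene == "G", ]
  expect_equal(g$cmp, "<=")
  expect_equal(g$threshold, 3.9)
  p2 <- data.frame(gene = c("G", "G"), cmp = c(">", ">"),
                   threshold = c(0.5, 2.0))
  expect_equal(ifsrank:::merge_predicates(p2)$threshold, 2.0)
})

test_that("rules reproduce their tree on every training row", {
  withr::with_seed(707, {
    for (rep in 1:6) {
      n <- 120
      p <- sample(3:6, 1)
      m <- matrix(pmax(0, rnorm(n * p, 2, 1.5)), n, p)
      colnames(m) <- sprintf("g%02d", seq_len(p))
      cls <- factor(sample(c("a", "b", "c"), n, replace = TRUE,
                           prob = c(0.2, 0.3, 0.5)))
      m[cls == "a", 1] <- m[cls == "a", 1] + 2
      df <- as.data.frame(m)
      df$.class <- cls
      fit <- rpart::rpart(.class ~ ., df, method = "class",
                          parms = list(split = "gini"), control = ctrl)
      rs <- extract_rules(fit)
      expect_equal(length(rs$rules), sum(fit$frame$var == "<leaf>"))
      tree_pred <- as.character(predict(fit, df, type = "class"))
      rule_pred <- apply(m, 1, function(s) apply_rules(rs, s))
      expect_identical(rule_pred, tree_pred)
      # after merging, at most one bound of each sense per gene per rule
      for (r in rs$rules) {
        if (nrow(r$predicates) > 0) {
          key <- paste(r$predicates$gene, r$predicates$cmp)
          expect_false(any(duplicated(key)))
        }
      }
      # class tallies sum to the rule count
      expect_equal(sum(rs$class_counts), length(rs$rules))
    }
  })
})

test_that("a tampered rule set is detected when no rule fires", {
  df <- data.frame(G = c(1, 2, 3, 4),
                   .class = factor(c("x", "x", "y", "y")))
  fit <- rpart::rpart(.class ~ G, df, method = "class",
                      parms = list(split = "gini"), control = ctrl)
  rs <- extract_rules(fit)
  rs$rules <- rs$rules[1]
  expect_error(apply_rules(rs, c(G = 3.0)), "0 rules")
  expect_error(extract_rules(lm(y ~ x, data.frame(x = 1:3, y = 1:3))),
               "rpart")
})

test_that("mine_rules trains on the balanced optimal subset and formats output", {
  gen <- tiny_dataset(seed = 26, sizes = c(20, 30, 50), n_genes = 15,
                      n_informative = 2)
  rk <- rank_mrmr(gen$dataset)
  mined <- mine_rules(gen$dataset, rk, subset_size = 5, seed = 3)
  rs <- mined$rule_set
  expect_s3_class(rs, "rule_set")
  txt <- format_rules(rs)
  expect_length(txt, length(rs$rules))
  expect_match(txt[1], "^Rule 1: .*=> .* \\(support \\d+, purity")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rules(rs, path)
  tab <- read.delim(path)
  expect_equal(length(unique(tab$rule_id)), length(rs$rules))
})
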