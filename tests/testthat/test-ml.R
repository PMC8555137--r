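# small deterministic corpus shared by the ML-layer tests
ml_corpus <- local({
  corpus <- NULL
  function() {
    if (is.null(corpus))
      corpus <<- generate_corpus(benchmark_config(
        n_background_nodes = 120, n_pathways = 4, seed = 91))
    corpus
  }
})

test_that("feature tables carry five features, labels and injected positives", {
  corpus <- ml_corpus()
  tbl <- build_feature_table(corpus$pathways, corpus$network,
                             margin = 1, seed = 2)
  expect_s3_class(tbl, "feature_table")
  expect_identical(setdiff(names(tbl), c("pathway", "node", "label")),
                   c("f_a0", "f_a25", "f_a50",
                     "prop_anchor", "prop_terminal"))
  expect_true(all(tbl$label %in% 0:1))
  expect_true(all(tbl$f_a0 >= 0 & tbl$f_a0 <= 1))
  # every true-pathway node appears, either as candidate or injected zero row
  for (pw in corpus$pathways) {
    sub <- tbl[tbl$pathway == pw$name, ]
    expect_true(all(pw$truth_nodes %in% sub$node))
    expect_true(all(sub$label[sub$node %in% pw$truth_nodes] == 1))
  }
  # injected rows are all-zero with label 1
  zero <- rowSums(abs(as.matrix(tbl[, c("f_a0", "f_a25", "f_a50",
                                        "prop_anchor",
                                        "prop_terminal")]))) == 0
  expect_true(all(tbl$label[zero] == 1))
})

test_that("a truth node outside every ensemble becomes an all-zero positive", {
  corpus <- ml_corpus()
  pw <- corpus$pathways[[1]]
  # add a phantom truth node that exists in the network but is far away
  phantom <- setdiff(corpus$network$nodes,
                     unlist(lapply(corpus$pathways, `[[`, "truth_nodes")))[1]
  pw2 <- training_pathway(pw$name, c(pw$truth_nodes, phantom),
                          pw$anchors, pw$terminals)
  tbl <- build_feature_table(list(pw2), corpus$network, margin = 1, seed = 2)
  row <- tbl[tbl$node == phantom, ]
  expect_equal(nrow(row), 1)
  expect_equal(unname(unlist(row[, c("f_a0", "f_a25", "f_a50",
                                     "prop_anchor", "prop_terminal")])),
               rep(0, 5))
  expect_equal(row$label, 1L)
})

test_that("a node shared by two pathways contributes one row per pathway", {
  corpus <- ml_corpus()
  pw <- corpus$pathways[[1]]
  twin <- training_pathway("twin", pw$truth_nodes, pw$anchors, pw$terminals)
  tbl <- build_feature_table(list(pw, twin), corpus$network,
                             margin = 1, seed = 2)
  shared <- pw$truth_nodes[1]
  expect_equal(sum(tbl$node == shared), 2)
})

test_that("feature tables are bit-identical for identical seeds", {
  corpus <- ml_corpus()
  t1 <- build_feature_table(corpus$pathways[1:2], corpus$network,
                            margin = 1.2, seed = 7)
  t2 <- build_feature_table(corpus$pathways[1:2], corpus$network,
                            margin = 1.2, seed = 7)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
})

test_that("normalization z-scores by population sd and flags constant columns", {
  tbl <- structure(data.frame(pathway = "p", node = c("a", "b", "c"),
                              f_a0 = c(1, 2, 3), f_a25 = c(5, 5, 5),
                              f_a50 = c(0, 1, 0), prop_anchor = c(0, 2, 4),
                              prop_terminal = c(1, 0, 1),
                              label = c(1L, 0L, 1L)),
                   class = c("feature_table", "data.frame"))
  ntbl <- normalize_features(tbl)
  expect_equal(ntbl$f_a0, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(ntbl$f_a25, c(0, 0, 0))      # constant column zeroed
  norm <- attr(ntbl, "normalization")
  expect_true(norm$constant[["f_a25"]])
  for (cl in c("f_a0", "f_a50", "prop_anchor", "prop_terminal")) {
    expect_lt(abs(mean(ntbl[[cl]])), 1e-8)
    expect_lt(abs(mean(ntbl[[cl]]^2) - 1), 1e-8)
  }
  expect_error(normalize_features(tbl[1, ]), "single-row")
  # idempotence through stored stats: identity stats leave data unchanged
  id_stats <- list(mean = setNames(rep(0, 5), names(norm$mean)),
                   sd = setNames(rep(1, 5), names(norm$mean)),
                   constant = setNames(rep(FALSE, 5), names(norm$mean)))
  again <- normalize_features(ntbl, stats = id_stats)
  expect_equal(again$f_a0, ntbl$f_a0)
})

test_that("AUROC equals the exhaustive pairwise statistic and pROC", {
  set.seed(12)
  for (i in 1:6) {
    n <- sample(10:200, 1)
    labels <- sample(0:1, n, replace = TRUE, prob = c(0.7, 0.3))
    if (length(unique(labels)) < 2) next
    scores <- round(runif(n), 2)  # rounding forces ties
    expect_equal(auroc(scores, labels), brute_auroc(scores, labels),
                 tolerance = 1e-12)
  }
  if (requireNamespace("pROC", quietly = TRUE)) {
    scores <- runif(100); labels <- rbinom(100, 1, 0.4)
    expect_equal(auroc(scores, labels),
                 as.numeric(pROC::auc(pROC::roc(
                   labels, scores, quiet = TRUE,
                   direction = "<", levels = c(0, 1)))),
                 tolerance = 1e-9)
  }
})

test_that("AUPRC of a no-skill ranker equals the positive prevalence", {
  labels <- c(rep(1, 30), rep(0, 70))
  expect_equal(auprc(rep(0.5, 100), labels), 0.3)
  # perfect ranker
  expect_equal(auprc(labels + 0, labels), 1)
  expect_equal(auroc(labels + 0, labels), 1)
})

test_that("training separates separable data and honours feature subsets", {
  n <- 50
  mk <- function(val, lab) data.frame(
    pathway = "p", node = sprintf("%s%02d", lab, 1:n),
    f_a0 = val, f_a25 = val, f_a50 = val,
    prop_anchor = val, prop_terminal = val, label = lab)
  tbl <- structure(rbind(mk(rnorm(n, 1, 0.1), 1L), mk(rnorm(n, -1, 0.1), 0L)),
                   class = c("feature_table", "data.frame"))
  ntbl <- normalize_features(tbl)
  model <- train_classifier(ntbl, "all5", seed = 4)
  expect_equal(auroc(predict(model, tbl), tbl$label), 1.0)
  # prop2 model ignores confidence columns entirely
  m2 <- train_classifier(ntbl, "prop2", seed = 4)
  shuffled <- tbl
  shuffled$f_a0 <- rev(shuffled$f_a0)
  shuffled$f_a25 <- sample(shuffled$f_a25)
  expect_identical(predict(m2, tbl), predict(m2, shuffled))
  # single-class tables are rejected
  one <- structure(mk(rnorm(n), 1L), class = class(tbl))
  expect_error(train_classifier(normalize_features(one)), "both classes")
})

test_that("cross-validation is calibrated: perfect features score 1, null ~0.5", {
  set.seed(88)
  n <- 150
  base <- data.frame(pathway = "p", node = sprintf("n%03d", 1:n))
  lab <- rep(0:1, length.out = n)
  perf <- cbind(base, f_a0 = lab, f_a25 = lab, f_a50 = lab,
                prop_anchor = lab, prop_terminal = lab, label = lab)
  class(perf) <- c("feature_table", "data.frame")
  r <- cross_validate(normalize_features(perf), "all5", seed = 1)
  expect_equal(r$auroc, 1)
  expect_equal(r$auprc, 1)
  expect_equal(r$folds, 5)
  # labels independent of features: AUROC near chance over seeds
  aucs <- vapply(1:6, function(s) {
    with_seed <- function(seed, code) { set.seed(seed); code }
    null_tbl <- with_seed(s, {
      x <- matrix(rnorm(n * 5), n)
      tb <- cbind(base, setNames(as.data.frame(x),
                                 c("f_a0", "f_a25", "f_a50",
                                   "prop_anchor", "prop_terminal")),
                  label = sample(lab))
      class(tb) <- c("feature_table", "data.frame")
      tb
    })
    cross_validate(normalize_features(null_tbl), "all5", seed = s)$auroc
  }, 0)
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("refinement respects thresholds and always keeps the query nodes", {
  corpus <- ml_corpus()
  tbl <- build_feature_table(corpus$pathways, corpus$network,
                             margin = 1, seed = 2)
  model <- train_classifier(normalize_features(tbl), "all5", seed = 2)
  pw <- corpus$pathways[[2]]
  q <- query_instance(corpus$network, pw$anchors, pw$terminals,
                      alpha = 0.25, margin = 1)
  all_kept <- refine(q, model, threshold = 0, seed = 5)
  expect_true(all(all_kept$kept))
  top_only <- refine(q, model, threshold = 1, seed = 5)
  expect_true(all(top_only$score[top_only$kept & !top_only$is_anchor &
                                   !top_only$is_terminal] == 1))
  expect_true(all(top_only$kept[top_only$is_anchor | top_only$is_terminal]))
  expect_true(all(all_kept$score >= 0 & all_kept$score <= 1))
})

test_that("margin tuning reports all feature sets plus the baseline", {
  corpus <- ml_corpus()
  tun <- tune_margin(corpus$pathways[1:3], corpus$network, margins = 1,
                     seed = 3, n_samples = 10)
  expect_equal(nrow(tun$report), 4)
  expect_setequal(tun$report$feature_set,
                  c("all5", "conf3", "prop2", "baseline"))
  expect_equal(tun$best_margin, 1)
  expect_true(all(tun$report$auroc >= 0 & tun$report$auroc <= 1))
})
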