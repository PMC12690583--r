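test_that("positive prevalence matches hand counts by target and cluster", {
  dt <- rbind(make_inter("A", "T1"), make_inter("B", "T1"),
              make_inter("C", "T1"),
              make_inter("D", "T1", "negative"),
              make_inter("E", "T2", "negative", cluster_id = 2),
              make_inter("F", "T2", "negative", cluster_id = 2))
  pp <- positive_prevalence(dt, "target")
  expect_equal(pp[id == "T1", prevalence], 0.75)
  expect_equal(pp[id == "T2", prevalence], 0.0)
  pc <- positive_prevalence(dt, "cluster")
  expect_equal(pc[id == 1, prevalence], 0.75)

  set.seed(41)
  big <- random_records(400, n_targets = 10, seed = 41)
  got <- positive_prevalence(big, "target")
  want <- tapply(big$label == "positive", big$target_id, mean)
  expect_equal(got$prevalence, as.numeric(want[got$id]))
})

test_that("BEDROC: exact endpoints and agreement with the direct-sum oracle", {
  # 10 actives ranked 1-10 of 100 -> 1; ranked last -> 0
  lab <- c(rep(1, 10), rep(0, 90))
  expect_equal(bedroc(100:1, lab), 1.0, tolerance = 1e-9)
  expect_equal(bedroc(1:100, lab), 0.0, tolerance = 1e-9)

  # fixed 20-item list with actives at ranks 1, 4, 15
  sc <- 20:1
  lab20 <- rep(0, 20); lab20[c(1, 4, 15)] <- 1
  expect_equal(bedroc(sc, lab20), bedroc_oracle(sc, lab20, 80.5),
               tolerance = 1e-12)

  # random lists of varying size vs the oracle
  for (s in 1:10) {
    set.seed(s)
    n <- sample(20:500, 1)
    scores <- rnorm(n)
    labels <- rbinom(n, 1, 0.15)
    if (sum(labels) == 0 || sum(labels) == n) next
    got <- bedroc(scores, labels)
    expect_equal(got, bedroc_oracle(scores, labels, 80.5),
                 tolerance = 1e-12)
    expect_gte(got, 0); expect_lte(got, 1)
  }

  # monotonicity: promoting one active never decreases BEDROC
  set.seed(3)
  scores <- sort(runif(80), decreasing = TRUE)
  labels <- rbinom(80, 1, 0.2); labels[1] <- 0; labels[80] <- 1
  base <- bedroc(scores, labels)
  i <- max(which(labels == 1))
  j <- min(which(labels == 0))
  labels2 <- labels; labels2[i] <- 0; labels2[j] <- 1  # move active up
  expect_gte(bedroc(scores, labels2), base)

  expect_error(bedroc(1:5, rep(1, 5)), "degenerate")
  expect_error(bedroc(1:4, c(0, 1, 2, 1)), "binary")
})

test_that("enrichment factor: exact cases, bounds, random expectation 1", {
  lab <- rep(0, 200); lab[c(1, 2)] <- 1
  sc <- 200:1
  expect_equal(enrichment_factor(sc, lab), 100.0)           # both in top 1%
  expect_equal(enrichment_factor(rev(sc), lab, 0.01), 0.0)  # actives at bottom
  expect_equal(enrichment_factor(sc, lab, fraction = 1.0), 1.0)
  expect_error(enrichment_factor(sc, lab, 0), "fraction")

  # EF <= 1 / active_rate on random instances
  for (s in 1:5) {
    set.seed(s)
    labels <- rbinom(300, 1, 0.1)
    if (sum(labels) %in% c(0, 300)) next
    ef <- enrichment_factor(rnorm(300), labels, 0.02)
    expect_gte(ef, 0)
    expect_lte(ef, 300 / sum(labels) + 1e-9)
  }

  # expectation under random ranking ~ 1
  labels <- c(rep(1, 50), rep(0, 450))
  set.seed(2024)
  efs <- vapply(1:2000, function(i)
    enrichment_factor(runif(500), labels, 0.01), numeric(1))
  expect_lt(abs(mean(efs) - 1), 0.1)
})

test_that("top-decile summaries", {
  sc <- data.table::data.table(entity_id = "E1", score = rep(0.99, 100))
  out <- top_decile_scores(sc)
  expect_equal(out$median, 0.99)
  expect_equal(out$n_top, 10L)

  sc2 <- data.table::data.table(entity_id = "E2", score = (1:100) / 100)
  out2 <- top_decile_scores(sc2)
  expect_equal(out2$median, median((91:100) / 100))  # ranks 91-100

  both <- rbind(sc, sc2)
  expect_equal(nrow(top_decile_scores(both)), 2L)
  tiny <- rbind(both, data.table::data.table(entity_id = "E3", score = 0.5))
  expect_warning(out3 <- top_decile_scores(tiny), "fewer than 10")
  expect_false("E3" %in% out3$entity_id)
})

test_that("attention/pocket coverage and IoU", {
  w <- c(0.9, 0.8, 0.1, 0.05, 0.7, 0.6, 0, 0)
  mask_same <- c(1, 1, 0, 0, 1, 1, 0, 0)
  r <- attention_pocket_eval(w, mask_same)
  expect_equal(r$coverage, 1.0); expect_equal(r$iou, 1.0)

  mask_disjoint <- c(0, 0, 1, 1, 0, 0, 1, 1)
  r2 <- attention_pocket_eval(w, mask_disjoint)
  expect_equal(r2$coverage, 0.0); expect_equal(r2$iou, 0.0)

  # pocket of 4, selection of 4, overlap 2 -> coverage 1/2, iou 2/6
  w3 <- c(1, 1, 1, 1, 0.1, 0.1, 0.1, 0.1)
  mask3 <- c(1, 1, 0, 0, 1, 1, 0, 0)
  r3 <- attention_pocket_eval(w3, mask3)
  expect_equal(r3$coverage, 0.5)
  expect_equal(r3$iou, 2 / 6)

  # coverage >= iou on random profiles (both selection rules)
  for (s in 1:20) {
    set.seed(s)
    w <- runif(60); m <- rbinom(60, 1, 0.2)
    if (!any(m == 1)) next
    for (rule in c("topk", "quantile")) {
      r <- attention_pocket_eval(w, m, rule = rule)
      expect_gte(r$coverage, r$iou)
      expect_true(r$iou >= 0 && r$coverage <= 1)
    }
  }
  expect_error(attention_pocket_eval(rep(0, 5), c(1, 0, 0, 0, 0)),
               "all-zero")
  expect_error(attention_pocket_eval(runif(5), rep(0, 5)), "no residues")
})
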