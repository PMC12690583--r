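test_that("rectified half sigmoid: fixed points, grid properties", {
  expect_equal(rectified_half_sigmoid(1), 1.0)
  # independent closed-form evaluation at x = 0: (2-2m)/(1+e^g) + m
  expect_equal(rectified_half_sigmoid(0), 1.2 / (1 + exp(3)) + 0.4,
               tolerance = 1e-12)
  expect_equal(rectified_half_sigmoid(0), 0.45691, tolerance = 1e-4)
  # at x = 2 the sigmoid branch (~1.543) loses to x itself
  expect_equal(rectified_half_sigmoid(2), 2.0)
  expect_error(rectified_half_sigmoid(NA_real_), "finite")
  expect_error(rectified_half_sigmoid(-0.1), "non-negative")

  x <- seq(0, 2, by = 0.01)
  a <- rectified_half_sigmoid(x)
  sig <- 1.2 / (1 + exp(-3 * (x - 1))) + 0.4
  expect_true(all(a >= x - 1e-12))
  expect_true(all(a >= sig - 1e-12))
  expect_true(all(diff(a) >= -1e-12))          # non-decreasing
  expect_true(all(abs(diff(a)) < 0.05))        # continuity on the grid
  expect_true(all((a == x)[x >= sig]))         # identity branch
})

test_that("PN quota matches the round-and-clamp oracle", {
  expect_equal(pn_quota(1.0, 100, 20), 80L)
  expect_equal(pn_quota(rectified_half_sigmoid(0), 100, 0), 46L)
  expect_equal(pn_quota(0.6189, 50, 50), 0L)

  set.seed(77)
  alpha <- runif(1000, 0, 3)
  np <- sample(0:500, 1000, replace = TRUE)
  nn <- sample(0:500, 1000, replace = TRUE)
  got <- pn_quota(alpha, np, nn)
  want <- vapply(seq_len(1000), function(i) {
    raw <- alpha[i] * np[i] - nn[i]
    max(0L, as.integer(floor(raw + 0.5)))  # round half up, clamp at 0
  }, integer(1))
  expect_identical(got, want)
  expect_true(all(got >= 0L))
})

test_that("target profiles: trigger, quota, and the >=0.5-prevalence guarantee", {
  mk <- function(tid, npos, nneg) rbind(
    if (npos > 0) data.table::rbindlist(lapply(seq_len(npos), function(i)
      make_inter(sprintf("%s_p%d", tid, i), tid, "positive"))),
    if (nneg > 0) data.table::rbindlist(lapply(seq_len(nneg), function(i)
      make_inter(sprintf("%s_n%d", tid, i), tid, "negative"))))
  dt <- rbind(mk("T1", 10, 5), mk("T2", 10, 6), mk("T3", 8, 0),
              mk("T4", 3, 9))
  prof <- target_label_profiles(dt)
  expect_true(prof[target_id == "T1", triggered])   # ratio exactly 2:1
  expect_false(prof[target_id == "T2", triggered])  # below trigger
  expect_true(prof[target_id == "T3", triggered])   # no negatives
  expect_equal(prof[target_id == "T1", quota], 0L)  # alpha(1/3)*10-5 rounds to 0
  expect_gt(prof[target_id == "T3", quota], 0L)
  # negative prevalence >= 0.5 entities always get quota 0
  expect_equal(prof[target_id == "T4", quota], 0L)
  set.seed(12)
  np <- sample(1:50, 200, replace = TRUE)
  nn <- np + sample(0:50, 200, replace = TRUE)   # N_N >= N_P
  x <- nn / (np + nn)
  q <- pn_quota(rectified_half_sigmoid(x), np, nn)
  expect_true(all(q == 0L))
})

test_that("eligible clusters: complement sets and two-tier preference", {
  dt <- rbind(make_inter("A", "T", "positive", cluster_id = 1),
              make_inter("B", "T", "negative", cluster_id = 2),
              make_inter("C", "U", "positive", cluster_id = 3),
              make_inter("D", "U", "negative", cluster_id = 4))
  el <- eligible_clusters("T", dt, all_clusters = 1:5)
  expect_setequal(c(el$tier1, el$tier2), 3:5)
  expect_equal(el$tier1, 3L)          # cluster 3 is positive-only overall
  expect_setequal(el$tier2, c(4L, 5L))  # incl. the record-free cluster 5

  # a target touching every cluster has no eligible source
  el2 <- eligible_clusters("T", rbind(dt[target_id == "T"],
                                      make_inter("E", "T", cluster_id = 3),
                                      make_inter("F", "T", cluster_id = 4),
                                      make_inter("G", "T", cluster_id = 5)),
                           all_clusters = 1:5)
  expect_length(c(el2$tier1, el2$tier2), 0)

  el3 <- eligible_clusters("T", dt[0], all_clusters = 1:5)
  expect_setequal(c(el3$tier1, el3$tier2), 1:5)

  flat <- eligible_clusters("T", dt, 1:5, mode = "interaction_free")
  expect_length(flat$tier1, 0)
  expect_setequal(flat$tier2, 3:5)
})

test_that("PN compound sampling obeys quota, per-cluster cap and eligibility", {
  pool <- data.table::data.table(
    compound_id = sprintf("P%02d", 1:12),
    cluster_id = rep(1:4, each = 3))
  elig <- list(tier1 = integer(0), tier2 = c(2L, 3L, 4L))
  out <- sample_pn_compounds("T1", 6, elig, pool, max_per_cluster = 3,
                             seed = 8, family = "Kinase")
  expect_equal(nrow(out), 6L)
  expect_true(all(out$cluster_id %in% 2:4))
  expect_true(all(out[, .N, by = cluster_id]$N <= 3))
  expect_true(all(out$label == "negative" & out$provenance == "putative"))
  expect_true(all(is.na(out$year)))

  expect_equal(nrow(sample_pn_compounds("T1", 0, elig, pool, seed = 1)), 0L)
  expect_identical(sample_pn_compounds("T1", 6, elig, pool, seed = 8),
                   sample_pn_compounds("T1", 6, elig, pool, seed = 8))
  expect_warning(sample_pn_compounds("T1", 50, elig, pool, seed = 8),
                 "shortfall 41")
})

test_that("PN target sampling draws only from untouched families", {
  fam_map <- data.table::data.table(
    target_id = sprintf("T%02d", 1:18),
    family = rep(cpi_families(), 3))
  kin_targets <- fam_map[family == "Kinase", target_id]
  dt <- data.table::rbindlist(lapply(kin_targets, function(t)
    make_inter("A", t, "positive", family = "Kinase", cluster_id = 2)))
  out <- sample_pn_targets("A", dt, fam_map,
                           balance_params(seed = 3), cluster_id = 2)
  expect_gt(nrow(out), 0)
  expect_false("Kinase" %in% out$family)
  expect_true(all(out$provenance == "putative"))
  expect_equal(unique(out$cluster_id), 2L)

  # all six families touched -> nothing to add
  all_fam <- data.table::rbindlist(lapply(1:6, function(i)
    make_inter("B", fam_map$target_id[i], "positive",
               family = fam_map$family[i])))
  expect_equal(nrow(sample_pn_targets("B", all_fam, fam_map)), 0L)

  # balanced compound (N_P = N_N = 4, ratio 1 -> alpha 1 -> quota 0)
  bal <- rbind(
    data.table::rbindlist(lapply(kin_targets[1:4], function(t)
      make_inter("C", t, "positive", family = "Kinase"))),
    data.table::rbindlist(lapply(fam_map[family == "Ion Channel",
                                         target_id][1:3], function(t)
      make_inter("C", t, "negative", family = "Ion Channel"))),
    make_inter("C", fam_map[family == "Others", target_id][1], "negative",
               family = "Others"))
  expect_equal(nrow(sample_pn_targets("C", bal, fam_map)), 0L)
  expect_error(sample_pn_targets("Z", make_inter("Z", "T01", "negative"),
                                 fam_map), "no positive")
})

test_that("balance_dataset: conservation, triggers, and safety", {
  mkt <- function(tid, fam, npos, nneg, cl) data.table::rbindlist(c(
    lapply(seq_len(npos), function(i)
      make_inter(sprintf("%s_p%d", tid, i), tid, "positive", family = fam,
                 cluster_id = cl[(i - 1) %% length(cl) + 1])),
    if (nneg > 0) lapply(seq_len(nneg), function(i)
      make_inter(sprintf("%s_n%d", tid, i), tid, "negative", family = fam,
                 cluster_id = cl[(i - 1) %% length(cl) + 1]))))
  dt <- rbind(mkt("T1", "Kinase", 10, 0, 1:2),
              mkt("T2", "Ion Channel", 10, 6, 3),
              mkt("T3", "Others", 2, 8, 4))
  pool <- data.table::data.table(compound_id = sprintf("X%03d", 1:100),
                                 cluster_id = rep(1:10, each = 10))
  out <- balance_dataset(dt, pool, balance_params(seed = 4))

  # measured rows pass through bit-identical
  expect_equal(sorted_tbl(out[provenance == "measured",
                              names(dt), with = FALSE]), sorted_tbl(dt))
  added <- out[provenance == "putative"]
  expect_true(all(added$label == "negative"))
  # T1 (all positive) triggered; T2 below trigger, T3 negative-dominant
  expect_true("T1" %in% added$target_id)
  expect_false(any(c("T2", "T3") %in% added$target_id))
  # no added pair may touch a cluster with recorded interactions for its target
  for (i in seq_len(nrow(added))) {
    row <- added[i]
    if (row$target_id %in% dt$target_id) {
      touched <- dt[target_id == row$target_id, unique(cluster_id)]
      expect_false(row$cluster_id %in% touched)
    }
  }
  # pair uniqueness across the augmented table
  expect_equal(nrow(unique(out, by = c("compound_id", "target_id"))),
               nrow(out))

  # a table with no positives balances to itself
  negs <- mkt("T9", "Kinase", 0, 5, 1)
  expect_equal(sorted_tbl(balance_dataset(negs, pool,
                                          balance_params(seed = 1))[,
                          names(negs), with = FALSE]),
               sorted_tbl(negs))
})

test_that("balancing deflates positive skew without touching negative-dominant targets", {
  b <- small_bundle(seed = 17, n_targets = 40, n_compounds = 800,
                    n_clusters = 20)
  cur <- curate_records(b$records, props = b$compounds$props)
  model <- fit_cluster_model(b$compounds$fingerprints, K = 20, seed = 17)
  pool <- data.table::data.table(
    compound_id = names(model$assignment),
    cluster_id = as.integer(model$assignment))
  cur[, cluster_id := NULL]
  cur <- pool[cur, on = "compound_id"]
  out <- suppressWarnings(balance_dataset(cur, pool,
                                          balance_params(seed = 17)))
  before <- positive_prevalence(cur, "target")
  after <- positive_prevalence(out, "target")
  expect_lt(sum(after$prevalence > 0.8), sum(before$prevalence > 0.8))
  # negative-dominant targets keep their exact prevalence
  negdom <- before[prevalence <= 0.5, id]
  cmp <- merge(before[id %in% negdom], after[id %in% negdom], by = "id")
  expect_equal(cmp$prevalence.x, cmp$prevalence.y)
})
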