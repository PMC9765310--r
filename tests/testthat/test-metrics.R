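test_that("dsc matches hand-counted overlaps and conventions", {
  g <- matrix(0, 3, 3); g[1:2, 1:2] <- 1          # 4 positives
  expect_equal(dsc(g, g), 1.0)
  p_disjoint <- matrix(0, 3, 3); p_disjoint[3, 3] <- 1
  expect_equal(dsc(p_disjoint, g), 0.0)
  # TP = 2, FP = 2, FN = 2 -> 2*2 / (4 + 2 + 2) = 0.5
  p <- matrix(0, 3, 3); p[1, 1:2] <- 1; p[3, 1:2] <- 1
  expect_equal(dsc(p, g), 0.5)
  expect_equal(dsc(matrix(0, 3, 3), matrix(0, 3, 3)), 1.0)
  expect_equal(dsc(p, g), dsc(g, p))
  expect_error(dsc(matrix(0, 2, 2), g), "shape")
})

test_that("vertical CDR is the ratio of row extents", {
  m <- rect_mask(120, 11:110, 30:80, 41:80, 45:65)  # disc 100 rows, cup 40
  expect_equal(vertical_cdr(m), 0.4)
  m2 <- rect_mask(60, 11:50, 11:50, 11:50, 11:50)   # cup == disc
  expect_equal(vertical_cdr(m2), 1.0)
  empty <- array(0, c(16, 16, 2))
  expect_error(vertical_cdr(empty), "empty disc")
  no_cup <- rect_mask(16, 4:12, 4:12, integer(0), integer(0))
  expect_warning(v <- vertical_cdr(no_cup), "empty cup")
  expect_equal(v, 0)
})

test_that("vertical CDR uses the largest connected component", {
  m <- rect_mask(64, 11:40, 11:40, 16:30, 16:30)
  m[60, 60, 1] <- 1  # speck far below must not stretch the disc diameter
  m[5, 5, 2] <- 1
  expect_equal(vertical_cdr(m), 15 / 30)
})

test_that("cdr_delta composes the per-mask CDRs", {
  g <- rect_mask(64, 11:50, 11:50, 21:40, 21:40)   # CDR 0.5
  p <- rect_mask(64, 11:50, 11:50, 21:36, 21:36)   # CDR 0.4
  expect_equal(cdr_delta(g, g), 0)
  expect_equal(cdr_delta(p, g), 0.1)
  expect_equal(cdr_delta(p, g), abs(vertical_cdr(p) - vertical_cdr(g)))
})

test_that("roc_auc agrees with the pairwise Mann-Whitney oracle", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12),
                       c(0, 0, 0, 1, 1, 1))$auc, 1.0)
  set.seed(8)
  scores <- rnorm(20)
  labels <- rbinom(20, 1, 0.5)
  if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(roc_auc(scores, labels)$auc, mean(pairs), tolerance = 1e-12)
  # invariant under strictly monotone transformation of the scores
  expect_equal(roc_auc(exp(scores), labels)$auc,
               roc_auc(scores, labels)$auc)
  expect_error(roc_auc(scores, rep(1, 20)), "both classes")
})

test_that("roc_auc matches an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  scores <- c(rnorm(30, 1), rnorm(30))
  labels <- rep(c(1, 0), each = 30)
  ref <- suppressMessages(as.numeric(pROC::auc(labels, scores)))
  expect_equal(roc_auc(scores, labels)$auc, ref, tolerance = 1e-10)
})

test_that("uninformative scores give AUC near one half", {
  set.seed(10)
  scores <- runif(500)
  labels <- rbinom(500, 1, 0.5)
  expect_lt(abs(roc_auc(scores, labels)$auc - 0.5), 0.05)
})

test_that("challenge score weights ranks 0.35/0.25/0.4", {
  expect_equal(challenge_score(3, 1, 7), 4.10)
  expect_equal(challenge_score(1, 1, 1), 1.0)
  expect_equal(challenge_score(2, 2, 2), 2.0)
  expect_gt(challenge_score(4, 1, 7), challenge_score(3, 1, 7))
  expect_error(challenge_score(0, 1, 1), ">= 1")
})

test_that("rank_teams ranks higher Dice and lower delta as better", {
  tb <- data.frame(team = c("a", "b"),
                   dsc_cup = c(0.9, 0.8), dsc_disc = c(0.95, 0.90),
                   delta = c(0.05, 0.08))
  r <- rank_teams(tb)
  expect_equal(r$score, c(1.0, 2.0))
  tie <- data.frame(team = c("a", "b"),
                    dsc_cup = c(0.9, 0.9), dsc_disc = c(0.95, 0.90),
                    delta = c(0.05, 0.08))
  rt <- rank_teams(tie)
  expect_equal(rt$rank_cup, c(1.5, 1.5))
  expect_warning(rank_teams(rbind(tb, data.frame(
    team = "c", dsc_cup = NA, dsc_disc = 0.9, delta = 0.1))), "excluding")
  expect_error(rank_teams(tb[1, ]), "two teams")
})

test_that("rank_teams reproduces the published challenge rank columns", {
  tb <- read.csv(system.file("extdata", "table_refuge_challenge.csv",
                             package = "fundusadapt"))
  r <- rank_teams(tb[, c("team", "dsc_cup", "dsc_disc", "delta")])
  r <- r[match(tb$team, r$team), ]
  expect_equal(r$rank_cup, tb$rank_cup)
  expect_equal(r$rank_disc, tb$rank_disc)
  expect_equal(r$rank_delta, tb$rank_delta)
  # the proposed method's own score is consistent with its printed ranks
  expect_equal(r$score[r$team == "proposed"], 4.10)
})

test_that("evaluate_predictions aggregates per-image records", {
  g1 <- rect_mask(32, 6:25, 6:25, 11:20, 11:20)
  g2 <- rect_mask(32, 4:27, 4:27, 11:18, 11:18)
  ev <- evaluate_predictions(list(g1, g2), list(g1, g2))
  expect_equal(nrow(ev$records), 2L)
  expect_equal(ev$summary$mean[ev$summary$metric == "dsc_disc"], 1.0)
  expect_equal(ev$summary$mean[ev$summary$metric == "delta"], 0.0)
  expect_equal(ev$records$dsc_disc,
               2 * ev$records$tp_disc /
                 (2 * ev$records$tp_disc + ev$records$fp_disc +
                    ev$records$fn_disc))
})
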