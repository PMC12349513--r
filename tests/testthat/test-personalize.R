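cands <- function(acc, irr = 1, fat = 1) {
  grid <- expand.grid(checkerboard = c("CB0", "CB1", "CB2", "CB3"),
                      condition = c("SFF", "MFH", "MFF"),
                      stringsAsFactors = FALSE)
  grid$accuracy <- acc
  grid$irritation <- irr
  grid$fatigue <- fat
  grid
}

test_that("total score subtracts the comfort penalties from accuracy", {
  expect_equal(total_score(90, 2, 3), 85)
  expect_equal(total_score(100, 1, 1), 98)
  expect_equal(total_score(75, 5, 5), 65)
  expect_error(total_score(110, 1, 1), "\\[0, 100\\]")
  expect_error(total_score(90, 0, 3), "\\[1, 5\\]")
  expect_error(total_score(90, 2, 6), "\\[1, 5\\]")
})

test_that("assignment selection maximises the total score within each group", {
  cand <- data.frame(
    checkerboard = c("CB1", "CB0", "CB0", "CB2"),
    condition = c("MFH", "MFH", "MFF", "MFF"),
    accuracy = c(88, 85, 80, 75),
    irritation = c(1, 1, 2, 2), fatigue = c(1, 1, 2, 2),
    stringsAsFactors = FALSE)
  a <- select_assignment(cand)
  expect_equal(a$cmds_1_3$checkerboard, "CB1")
  expect_equal(a$cmds_1_3$condition, "MFH")
  expect_equal(a$cmds_4_6$checkerboard, "CB0")
  expect_equal(a$cmds_4_6$condition, "MFF")

  # exact tie broken by stated preference
  tied <- cand
  tied$accuracy[1:2] <- 88
  pref <- data.frame(checkerboard = "CB0", condition = "MFH",
                     stringsAsFactors = FALSE)
  expect_equal(select_assignment(tied, pref)$cmds_1_3$checkerboard, "CB0")
  # without preferences the canonical order decides (CB index first)
  expect_equal(select_assignment(tied)$cmds_1_3$checkerboard, "CB0")
  expect_error(select_assignment(cand[cand$condition == "MFF", ]),
               "both command groups")
})

test_that("selection equals a brute-force enumeration oracle on a random cohort", {
  oracle_pick <- function(cand) {
    sc <- cand$accuracy - cand$irritation - cand$fatigue
    ord <- order(-sc, match(cand$checkerboard, c("CB0", "CB1", "CB2", "CB3")),
                 match(cand$condition, c("SFF", "MFH", "MFF")))
    cand[ord[1], c("checkerboard", "condition")]
  }
  with_seed_local(7, {
    for (user in 1:15) {
      cand <- cands(acc = round(stats::runif(12, 60, 100), 1),
                    irr = sample(1:5, 12, replace = TRUE),
                    fat = sample(1:5, 12, replace = TRUE))
      a <- select_assignment(cand)
      g13 <- cand[cand$condition != "MFF", ]
      g46 <- cand[cand$condition == "MFF", ]
      expect_equal(a$cmds_1_3$checkerboard, oracle_pick(g13)$checkerboard)
      expect_equal(a$cmds_1_3$condition, oracle_pick(g13)$condition)
      expect_equal(a$cmds_4_6$checkerboard, oracle_pick(g46)$checkerboard)
      expect_equal(a$cmds_4_6$condition, oracle_pick(g46)$condition)
    }
  })
})

test_that("selection is invariant to accuracy shifts and reduces to argmax", {
  cand <- cands(acc = seq(60, 93, 3))
  base <- select_assignment(cand)
  shifted <- cand
  shifted$accuracy <- shifted$accuracy + 7
  a2 <- select_assignment(shifted)
  expect_equal(a2$cmds_1_3[c("checkerboard", "condition")],
               base$cmds_1_3[c("checkerboard", "condition")])
  # equal comfort everywhere: the accuracy argmax wins
  g13 <- cand[cand$condition != "MFF", ]
  expect_equal(base$cmds_1_3$accuracy <- NULL, NULL)
  top <- g13[which.max(g13$accuracy), ]
  expect_equal(base$cmds_1_3$checkerboard, top$checkerboard)
})

test_that("channel selection prefers the higher-response channel", {
  # right-lateralised profile: O2 carries the stronger response
  p <- ssvep_profile(amplitude = 2, channel_gain = c(O1 = 0.4, O2 = 1))
  ep <- with_seed_local(5, ssvepdetect:::simulate_labeled_epochs(
    p, c(rep("rest", 6), rep(c("SFF1", "MFH2", "MFF3"), 2))))
  fit <- ssvep_detector(ep)
  expect_equal(select_channel(ep, fit), "O2")

  # symmetric gains tie back to O1
  ps <- ssvep_profile(channel_gain = c(O1 = 1, O2 = 1))
  eps <- with_seed_local(6, ssvepdetect:::simulate_labeled_epochs(
    ps, c(rep("rest", 4), "SFF1", "SFF2")))
  eps$x[, "O2", ] <- eps$x[, "O1", ]  # identical channels: exact tie
  fits <- ssvep_detector(eps)
  expect_equal(select_channel(eps, fits), "O1")
})

test_that("the mutual assignment is the modal per-group choice", {
  mk <- function(cb13, fl13, cb46, ch) {
    structure(list(user = NULL, channel = ch,
                   cmds_1_3 = list(checkerboard = cb13, condition = fl13,
                                   score = NA),
                   cmds_4_6 = list(checkerboard = cb46, condition = "MFF",
                                   score = NA)),
              class = "stimulus_assignment")
  }
  as <- list(mk("CB1", "MFH", "CB0", "O1"), mk("CB1", "MFH", "CB0", "O1"),
             mk("CB0", "SFF", "CB1", "O2"))
  m <- mutual_assignment(as)
  expect_equal(m$cmds_1_3$checkerboard, "CB1")
  expect_equal(m$cmds_1_3$condition, "MFH")
  expect_equal(m$cmds_4_6$checkerboard, "CB0")
  expect_equal(m$channel, "O1")
})
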