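test_that("the canonical frequency table matches the published design", {
  tab <- flicker_table()
  expect_equal(nrow(tab), 9L)
  expect_equal(as.vector(table(tab$condition)[c("SFF", "MFH", "MFF")]),
               c(3L, 3L, 3L))
  mfh1 <- tab[tab$symbol == "MFH1", ]
  expect_equal(mfh1$f1, 7)
  expect_equal(mfh1$fh, 14)
  mff3 <- tab[tab$symbol == "MFF3", ]
  expect_equal(mff3$f1, 13)
  expect_equal(mff3$f2, 17)
  # MFH companions are first harmonics or subharmonics of the fundamental
  mfh <- tab[tab$condition == "MFH", ]
  expect_true(all(mfh$fh == 2 * mfh$f1 | mfh$fh == mfh$f1 / 2))
  # MFF fundamentals are ordered and distinct
  mff <- tab[tab$condition == "MFF", ]
  expect_true(all(mff$f1 < mff$f2))
  # command mapping is bijective within each condition group
  expect_setequal(tab$command_id[tab$condition == "SFF"], 1:3)
  expect_setequal(tab$command_id[tab$condition == "MFH"], 1:3)
  expect_setequal(tab$command_id[tab$condition == "MFF"], 4:6)
})

test_that("frequencies of interest and families are consistent", {
  foi <- frequencies_of_interest()
  expect_equal(foi, c(7, 14, 21, 6.5, 13, 26, 8.5, 17, 34))
  fam <- foi_families()
  expect_equal(fam[["7"]], c(7, 14, 21))
  expect_equal(fam[["13"]], c(6.5, 13, 26))
  expect_equal(fam[["17"]], c(8.5, 17, 34))
  expect_equal(family_of(c(14, 6.5, 34)), c(7, 13, 17))
  expect_equal(stimulus_frequencies("SFF1"), c(7, 14, 21))
  expect_equal(stimulus_frequencies("MFH2"), c(6.5, 13, 26))
  expect_equal(stimulus_frequencies("MFF1"), c(7, 14, 21, 13, 26))
})

test_that("contrast reversal flips exactly the toggled layer's region", {
  on <- render_pattern("CB0", TRUE)
  off <- render_pattern("CB0", FALSE)
  expect_true(all(on + off == 1L))           # exact complements
  expect_setequal(as.vector(on), c(0L, 1L))  # binary raster

  a <- render_pattern("CB2", c(TRUE, FALSE))
  b <- render_pattern("CB2", c(TRUE, TRUE))
  reg <- attr(a, "regions")
  diff <- a != b
  expect_true(all(diff[reg == 2L]))
  expect_true(!any(diff[reg != 2L]))
  # surround of the circle patterns never flickers
  c1 <- render_pattern("CB1", TRUE)
  c0 <- render_pattern("CB1", FALSE)
  outside <- attr(c1, "regions") == 0L
  expect_true(all(c1[outside] == 0L) && all(c0[outside] == 0L))
})

test_that("rendering is deterministic and validates layer states", {
  expect_identical(render_pattern("CB1", TRUE), render_pattern("CB1", TRUE))
  expect_error(render_pattern("CB2", TRUE), "layer state")
  expect_error(render_pattern("CB0", c(TRUE, FALSE)), "layer state")
  expect_error(render_pattern("CB9", TRUE), "unknown checkerboard")
  # each circle layer is non-empty and nested
  reg <- pattern_regions("CB3")
  expect_setequal(sort(unique(as.vector(reg))), 0:3)
})

test_that("frame schedules toggle at the component frequencies", {
  # integer frame ratio: 10 Hz at 60 Hz refresh alternates runs of 3
  tab <- flicker_table()
  fake10 <- tab[tab$symbol == "SFF2", ]
  fake10$f1 <- 10
  s <- frame_schedule(fake10, refresh_hz = 60, duration_s = 1)
  expect_equal(nrow(s), 60L)
  runs <- rle(as.vector(s[, 1]))
  expect_true(all(runs$lengths == 3L))

  # MFF1 carries two independent tracks whose empirical toggle rates match
  s2 <- frame_schedule("MFF1", refresh_hz = 60, duration_s = 5)
  expect_equal(ncol(s2), 2L)
  rates <- apply(s2, 2, function(col) sum(diff(col) != 0) / 2 / 5)
  expect_lt(abs(rates[1] - 7), 1 / 5)
  expect_lt(abs(rates[2] - 13), 1 / 5)
  # duty cycle within one frame of 50%
  expect_true(all(abs(colSums(s2) - nrow(s2) / 2) <= 1 + 1e-9))

  expect_equal(nrow(frame_schedule("SFF1", 60, 0)), 0L)
  expect_error(frame_schedule("MFF3", refresh_hz = 30, duration_s = 1),
               "Nyquist")
})

test_that("a single-component schedule's spectrum peaks at the component frequency", {
  refresh <- 61  # non-integer frame/period ratios
  for (sym in c("SFF1", "SFF2", "SFF3")) {
    s <- frame_schedule(sym, refresh_hz = refresh, duration_s = 5)
    z <- 2 * as.numeric(s[, 1]) - 1
    spec <- Mod(stats::fft(z))^2
    half <- floor(length(z) / 2)
    freqs <- (seq_len(half)) * refresh / length(z)
    peak <- freqs[which.max(spec[2:(half + 1)])]
    f0 <- flicker_components(sym)[1]
    expect_lt(abs(peak - f0), refresh / length(z) + 1e-9)
  }
})

test_that("schedules map onto pattern layers outermost-first", {
  s <- frame_schedule("MFF1", 60, 1)
  l3 <- assign_layers(s, "CB3")
  expect_equal(ncol(l3), 3L)
  expect_equal(l3[, 1], s[, 1], ignore_attr = TRUE)  # f1 outermost
  expect_equal(l3[, 2], s[, 2], ignore_attr = TRUE)
  expect_equal(l3[, 3], s[, 1], ignore_attr = TRUE)  # third layer repeats f1
  l1 <- assign_layers(s, "CB1")
  expect_equal(ncol(l1), 1L)
  expect_equal(l1[, 1], xor(s[, 1], s[, 2]), ignore_attr = TRUE)
})

test_that("the screen layout groups rows by condition and never overlaps", {
  lay <- layout_grid()
  expect_equal(lay$symbol[lay$row == 1 & lay$col == 1], "SFF1")
  expect_equal(lay$condition[order(lay$row)], rep(c("SFF", "MFH", "MFF"), each = 3))
  # pairwise disjoint rectangles
  for (i in 1:8) for (j in (i + 1):9) {
    sep_x <- abs(lay$x_px[i] - lay$x_px[j]) >= lay$w_px[i]
    sep_y <- abs(lay$y_px[i] - lay$y_px[j]) >= lay$h_px[i]
    expect_true(sep_x || sep_y)
  }
  # permuted input is regrouped into the canonical arrangement
  perm <- flicker_table()[c(5, 9, 1, 3, 7, 2, 8, 4, 6), ]
  expect_equal(layout_grid(perm), lay)
  expect_error(layout_grid(flicker_table()[1:5, ]), "canonical")
})
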