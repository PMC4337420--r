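make_ct <- function(dct, group, time, gene = "phm", ref = 18) {
  data.frame(gene = gene, group = group, time = time,
             replicate = seq_along(dct),
             ct_target = ref + dct, ct_reference = ref,
             stringsAsFactors = FALSE)
}

test_that("comparative-Ct worked example: dCt 5 against calibrator at dCt 7 gives 4-fold", {
  ct <- rbind(make_ct(c(7, 7, 7), "ctrl", 0),   # calibrator
              make_ct(5, "ctrl", 8))
  out <- relative_expression(ct, calibrator = list(group = "ctrl", time = 0))
  expect_equal(out$value[out$time == 8], 4.0, tolerance = 1e-12)
  expect_equal(out$value[out$time == 0], c(1, 1, 1), tolerance = 1e-12)
  # classical dCt-scale averaging agrees when calibrator replicates are equal
  out2 <- relative_expression(ct, calibrator = list(group = "ctrl", time = 0),
                              average = "ct")
  expect_equal(out2$value, out$value, tolerance = 1e-12)
})

test_that("calibrator condition has mean value exactly 1 even with replicate scatter", {
  ct <- rbind(make_ct(c(6.4, 7.0, 7.9), "ctrl", 0),
              make_ct(c(5.1, 5.4), "ctrl", 8))
  out <- relative_expression(ct, calibrator = list(group = "ctrl", time = 0))
  expect_equal(mean(out$value[out$time == 0]), 1, tolerance = 1e-14)
  # dCt-scale averaging fixes the geometric mean instead
  out2 <- relative_expression(ct, calibrator = list(group = "ctrl", time = 0),
                              average = "ct")
  expect_equal(exp(mean(log(out2$value[out2$time == 0]))), 1, tolerance = 1e-14)
})

test_that("normalisation is scale-free in the reference and exponential in the target", {
  ct <- rbind(make_ct(c(6.5, 7.5), "ctrl", 0), make_ct(c(5, 6), "ctrl", 8))
  base <- relative_expression(ct, calibrator = list(group = "ctrl", time = 0))

  # shifting target and reference Ct together changes nothing (machine precision)
  shifted <- ct
  shifted$ct_target <- shifted$ct_target + 3.2
  shifted$ct_reference <- shifted$ct_reference + 3.2
  out <- relative_expression(shifted, calibrator = list(group = "ctrl", time = 0))
  expect_equal(out$value, base$value, tolerance = 1e-14)

  # one extra cycle on non-calibrator targets halves their fold change
  plus1 <- ct
  idx <- plus1$time != 0
  plus1$ct_target[idx] <- plus1$ct_target[idx] + 1
  out1 <- relative_expression(plus1, calibrator = list(group = "ctrl", time = 0))
  expect_equal(out1$value[idx], base$value[idx] / 2, tolerance = 1e-14)
})

test_that("missing Ct values and absent calibrators are typed errors", {
  ct <- make_ct(c(7, 7), "ctrl", 0)
  ct$ct_reference[2] <- NA
  expect_error(relative_expression(ct, calibrator = list(group = "ctrl", time = 0)),
               class = "cw_parse_error")
  ct2 <- make_ct(c(7, 7), "ctrl", 0)
  expect_error(relative_expression(ct2, calibrator = list(group = "ctrl", time = 4)),
               class = "cw_config_error")
})

test_that("letter groups satisfy the chain example and the degenerate cases", {
  # three cells A(t=0), B(t=1), C(t=2): A~B ns, B~C ns, A!~C significant
  tc <- data.frame(group = "g",
                   time = rep(c(0, 1, 2), each = 3),
                   replicate = rep(1:3, 3),
                   value = c(1.00, 1.02, 0.98,
                             1.00, 1.15, 1.30,
                             1.30, 1.32, 1.28))
  out <- windowed_letter_groups(tc, window = 2)
  expect_equal(out$letters, c("a", "ab", "b"))
  dec <- attr(out, "decisions")
  expect_equal(nrow(dec), 3L)   # all three pairs lie within the 2-hr window
  expect_equal(dec$significant, c(FALSE, TRUE, FALSE))

  # identical cells share a single letter
  same <- data.frame(group = "g", time = rep(c(0, 2), each = 3),
                     replicate = rep(1:3, 2), value = rep(c(1, 1.1, 0.9), 2))
  out2 <- windowed_letter_groups(same)
  expect_equal(out2$letters, c("a", "a"))

  # all pairs significant: all letters distinct
  far <- data.frame(group = "g", time = rep(c(0, 1, 2), each = 3),
                    replicate = rep(1:3, 3),
                    value = c(1, 1.01, 0.99, 5, 5.01, 4.99, 9, 9.01, 8.99))
  out3 <- windowed_letter_groups(far)
  expect_equal(sort(out3$letters), c("a", "b", "c"))
})

test_that("the sliding window limits comparisons; cross-group only at matched times", {
  tc <- data.frame(group = rep(c("w", "mut"), each = 6),
                   time = rep(rep(c(0, 6), each = 3), 2),
                   replicate = rep(1:3, 4),
                   value = c(1, 1.1, 0.9, 8, 8.1, 7.9,     # w: jumps by 6 hr
                             1, 1.05, 0.95, 8, 8.05, 7.95))
  out <- windowed_letter_groups(tc, window = 2)
  dec <- attr(out, "decisions")
  # within-group pairs 6 hr apart are not compared; cross-group same-time are
  expect_true(all(abs(dec$time_i - dec$time_j) < 1e-8 |
                    dec$group_i == dec$group_j))
  expect_true(all(abs(dec$time_i - dec$time_j) <= 2 + 1e-8))
  expect_equal(nrow(dec), 2L)  # (w,0)-(mut,0) and (w,6)-(mut,6)

  # with all_pairs everything is compared
  out2 <- windowed_letter_groups(tc, window = 2, all_pairs = TRUE)
  expect_equal(nrow(attr(out2, "decisions")), choose(4, 2))
})

test_that("cells with fewer than two replicates are excluded with a warning", {
  tc <- data.frame(group = "g", time = c(0, 0, 2, 2, 4),
                   replicate = c(1, 2, 1, 2, 1),
                   value = c(1, 1.1, 1.2, 1.3, 9))
  expect_warning(out <- windowed_letter_groups(tc),
                 class = "cw_small_cell_warning")
  expect_equal(nrow(out), 2L)
  expect_false(4 %in% out$time)
})

test_that("letter assignments are always consistent with the decision matrix", {
  set.seed(99)
  for (rep in 1:60) {
    s <- sample(2:7, 1)
    sig <- matrix(FALSE, s, s)
    pairs <- which(upper.tri(sig))
    on <- pairs[runif(length(pairs)) < 0.4]
    sig[on] <- TRUE
    sig <- sig | t(sig)
    cols <- critweight:::letters_from_sig(sig)
    syms <- critweight:::letter_symbols(length(cols))
    lets <- vapply(seq_len(s), function(i)
      paste0(syms[vapply(cols, function(col) i %in% col, logical(1))],
             collapse = ""), character(1))
    expect_true(all(nzchar(lets)))
    expect_true(check_letters_consistent(lets, sig))
  }
})
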