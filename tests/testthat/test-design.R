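test_that("one block realises the exact factorial cell counts, any seed", {
  for (seed in c(1, 17, 992)) {
    b1 <- build_block("E1", seed = seed)
    expect_equal(nrow(b1), 60)
    tab <- table(b1$cue_type, b1$target_present)
    expect_equal(tab["valid", "TRUE"][[1]], 32)
    expect_equal(tab["invalid", "TRUE"][[1]], 8)
    expect_equal(tab["neutral", "TRUE"][[1]], 8)
    expect_equal(tab["valid", "FALSE"][[1]], 8)
    expect_equal(tab["invalid", "FALSE"][[1]], 2)
    expect_equal(tab["neutral", "FALSE"][[1]], 2)
    # target sides balanced among target trials
    expect_equal(as.integer(table(b1$target_side[b1$target_present])),
                 c(24L, 24L))

    b2 <- build_block("E2", seed = seed)
    expect_equal(nrow(b2), 60)
    expect_equal(as.integer(table(b2$soa_ms)), c(30L, 30L))
    # per SOA: each cue type gives 8 target trials (2 sides x 4 reps)
    cells <- table(b2$cue_type, b2$soa_ms, b2$target_present)
    expect_equal(sum(!b2$target_present), 12)
    expect_equal(unname(cells["neutral", "100", "TRUE"]), 8L)
    expect_equal(unname(cells["valid", "800", "TRUE"]), 8L)
    expect_equal(unname(cells["invalid", "800", "TRUE"]), 8L)
  }
  expect_error(build_block("E3", seed = 1))
})

test_that("a seed pins the trial order, colours and rotations", {
  a <- build_block("E1", seed = 42)
  b <- build_block("E1", seed = 42)
  expect_identical(a, b)
  c <- build_block("E1", seed = 43)
  expect_false(identical(a$cue_type, c$cue_type) &&
                 identical(a$target_colour_deg, c$target_colour_deg))
})

test_that("sessions stack the published trial counts with a practice block", {
  s1 <- build_session("E1", n_blocks = 7, practice = TRUE, seed = 3)
  expect_equal(sum(s1$block > 0), 420)
  expect_equal(sum(s1$block == 0), 30)
  s2 <- build_session("E2", n_blocks = 8, practice = TRUE, seed = 3)
  expect_equal(sum(s2$block > 0), 480)
  expect_equal(sum(s2$block == 0), 30)
  s3 <- build_session("E1", n_blocks = 1, practice = FALSE, seed = 3)
  expect_equal(nrow(s3), 60)
  # practice trials are a subset of one full design (no duplicated cells
  # beyond the design's multiplicities)
  expect_true(all(table(s1$cue_type[s1$block == 0]) <= c(30, 30, 30)))
})

test_that("tabulation reports 20% catch and 80% spatial validity", {
  sess <- build_session("E1", n_blocks = 7, practice = FALSE, seed = 9)
  tb <- design_tabulate(sess)
  expect_equal(tb$catch_fraction, 0.2)
  expect_equal(tb$spatial_validity, 0.8)
  expect_equal(sum(tb$counts$n), nrow(sess))
  # E2 spatial cues are uninformative: 50% validity
  tb2 <- design_tabulate(build_session("E2", 8, practice = FALSE, seed = 9))
  expect_equal(tb2$catch_fraction, 0.2)
  expect_equal(tb2$spatial_validity, 0.5)
})

test_that("counterbalance arms are mirror images", {
  a <- build_block("E1", seed = 11, counterbalance_arm = "2_right")
  b <- build_block("E1", seed = 11, counterbalance_arm = "2_left")
  # geometry (cue type, sides) is arm-independent
  expect_identical(a$cue_type, b$cue_type)
  expect_identical(a$target_side, b$target_side)
  # symbols swap 2 <-> 5 on spatial cues, H unchanged
  spatial <- a$cue_type != "neutral"
  swap <- c(`2` = "5", `5` = "2")
  expect_identical(unname(swap[a$cue_symbol[spatial]]), b$cue_symbol[spatial])
  expect_true(all(a$cue_symbol[!spatial] == "H"))
})
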