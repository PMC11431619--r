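test_that("generate_onsets respects separation, range and determinism", {
  on <- generate_onsets(120, 270, 0.5, duration = 0.5, seed = 42)
  expect_length(on, 120)
  expect_true(all(diff(on) >= 0.5 - 1e-9))
  expect_true(all(on >= 0) && all(on + 0.5 <= 270))
  expect_identical(on, generate_onsets(120, 270, 0.5, duration = 0.5,
                                       seed = 42))
  expect_false(identical(on, generate_onsets(120, 270, 0.5,
                                             duration = 0.5, seed = 43)))
  # millisecond quantization
  expect_equal(on, round(on, 3))

  single <- generate_onsets(1, 10, 0.5, seed = 1)
  expect_length(single, 1)
  expect_true(single >= 0 && single <= 10)

  expect_error(generate_onsets(100, 10, 0.5, seed = 1), "infeasible")
})

test_that("assign_labels balances levels and errors on indivisible requests", {
  on <- generate_onsets(120, 270, 0.5, seed = 1)
  sched <- assign_labels(on, list(category = c("face", "house"),
                                  action = c("left", "right")), seed = 2)
  expect_s3_class(sched, "event_schedule")
  expect_equal(unname(table(sched$labels$category)), c(60L, 60L),
               ignore_attr = TRUE)
  expect_equal(unname(table(sched$labels$action)), c(60L, 60L),
               ignore_attr = TRUE)

  mono <- assign_labels(generate_onsets(4, 20, 0.5, seed = 1),
                        list(d = "x", e = c("a", "b")), seed = 1)
  expect_true(all(mono$labels$d == "x"))

  tri <- assign_labels(generate_onsets(6, 20, 0.5, seed = 1),
                       list(d = c("a", "b", "c"), e = c("u", "v")),
                       seed = 1)
  expect_equal(unname(table(tri$labels$d)), c(2L, 2L, 2L),
               ignore_attr = TRUE)

  expect_error(assign_labels(generate_onsets(5, 20, 0.5, seed = 1),
                             list(d = c("a", "b"), e = c("u", "v"))),
               "divisible")
})

test_that("twist inverts binary labels event-by-event and is an involution", {
  s <- assign_labels(generate_onsets(8, 30, 0.5, seed = 3),
                     list(category = c("face", "house"),
                          action = c("left", "right")), seed = 3)
  b <- twist(s, "action")
  expect_identical(b$onsets, s$onsets)
  expect_identical(b$labels$category, s$labels$category)
  expect_true(all(b$labels$action != s$labels$action))
  expect_identical(twist(b, "action")$labels, s$labels)

  # visuomotor example: house->right/face->left becomes house->left/face->right
  idx_house <- s$labels$category == "house"
  mapped <- s
  mapped$labels$action <- ifelse(idx_house, "right", "left")
  flipped <- twist(mapped, "action")
  expect_true(all(flipped$labels$action[idx_house] == "left"))
  expect_true(all(flipped$labels$action[!idx_house] == "right"))
})

test_that("permute twist draws identity-free level maps (all derangements)", {
  s <- assign_labels(generate_onsets(12, 40, 0.5, seed = 5),
                     list(d = c("a", "b", "c"), e = c("u", "v")),
                     balance = TRUE, seed = 5)
  expect_error(twist(s, "d", mode = "invert"), "permute")
  # the two derangements of 3 levels, as level maps a,b,c -> ...
  derangements <- list(c("b", "c", "a"), c("c", "a", "b"))
  seen <- character(0)
  for (seed in 1:40) {
    tw <- twist(s, "d", mode = "permute", seed = seed)
    map <- vapply(c("a", "b", "c"),
                  function(l) unique(tw$labels$d[s$labels$d == l]),
                  character(1))
    expect_true(all(map != c("a", "b", "c")))  # identity-free
    hit <- vapply(derangements, identical, logical(1), unname(map))
    expect_true(any(hit))
    seen <- union(seen, paste(map, collapse = ""))
  }
  expect_length(seen, 2)  # both derangements occur across seeds
})

test_that("build_design satisfies the factorial agreement structure", {
  d <- build_design(seed = 1)
  expect_equal(length(d$runs$A1$onsets), 120)
  chk <- validate_design(d)
  expect_true(chk$valid)

  # Agreement pattern: on dimension 1, A1 agrees with A2 and disagrees
  # with B1/B2; on dimension 2, A1 agrees with B1 and disagrees with A2/B2.
  m1 <- agreement_matrix(d, 1)
  m2 <- agreement_matrix(d, 2)
  expect_equal(m1, matrix(c(1, 0, 1, 0, 0, 1, 0, 1, 1, 0, 1, 0,
                            0, 1, 0, 1), 4, 4,
                          dimnames = dimnames(m1)))
  expect_equal(m2, matrix(c(1, 1, 0, 0, 1, 1, 0, 0, 0, 0, 1, 1,
                            0, 0, 1, 1), 4, 4,
                          dimnames = dimnames(m2)))

  # identical timing across runs
  for (k in c("B1", "A2", "B2")) {
    expect_identical(d$runs[[k]]$onsets, d$runs$A1$onsets)
    expect_identical(d$runs[[k]]$durations, d$runs$A1$durations)
  }
})

test_that("regenerating a design from the same seed is bit-exact", {
  expect_identical(build_design(seed = 99), build_design(seed = 99))
  expect_false(identical(build_design(seed = 99)$runs$A1$labels,
                         build_design(seed = 100)$runs$A1$labels))
})

test_that("the validity checker names the run and event of a defect", {
  d <- small_design()
  d$runs$A2$onsets[5] <- d$runs$A2$onsets[5] + 0.01
  chk <- validate_design(d)
  expect_false(chk$valid)
  expect_match(chk$violations, "A2", all = FALSE)
  expect_match(chk$violations, "event 5", all = FALSE)

  d2 <- small_design()
  d2$runs$B1$labels$category[3] <- d2$runs$A1$labels$category[3]
  chk2 <- validate_design(d2)
  expect_false(chk2$valid)
  expect_match(chk2$violations, "B1", all = FALSE)
  expect_match(chk2$violations, "category", all = FALSE)
})

test_that("sub-run splitting records structure without touching labels", {
  d0 <- build_design(n_events = 24, run_length = 60, seed = 5)
  d3 <- build_design(n_events = 24, run_length = 60, seed = 5, split = 3)
  expect_null(d0$split)
  expect_equal(d3$split$n_subruns, 3)
  expect_equal(d3$split$boundaries, c(20, 40))
  expect_identical(lapply(d3$runs, `[[`, "labels"),
                   lapply(d0$runs, `[[`, "labels"))
  expect_true(all(vapply(d3$split$presentation_order,
                         function(o) setequal(o, 1:3), logical(1))))
  expect_error(build_design(split = 5), "split")
})
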