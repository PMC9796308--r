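test_that("ABA/CBA labelling follows the n-2 task repetition rule", {
  expect_equal(classify_bi("colour", "shape", "colour"), "ABA")
  expect_equal(classify_bi("vertical", "shape", "colour"), "CBA")
  expect_error(classify_bi("colour", "colour", "shape"), "invalid sequence")
  expect_error(classify_bi("colour", "shape", "shape"), "invalid sequence")
})

# mapping 1: green, circle, up, left -> key 1; red, triangle, down, right -> 2
m1 <- response_mapping(1)

test_that("the CRS+ worked example is recovered", {
  # N-1: classify shape of a green triangle (key 2); the activated colour
  # rule 'green' maps to key 1 and competes. N: classify colour of a
  # green circle (key 1): the competing rule became relevant.
  n1 <- list(task = "shape", colour = "green", shape = "triangle",
             vertical = "up", horizontal = "left")
  n0 <- list(task = "colour", colour = "green", shape = "circle",
             vertical = "down", horizontal = "right")
  res <- classify_crs(n1, n0, m1)
  expect_equal(res$label, "CRSplus")
  expect_true(res$response_alternation)
  expect_false(res$crc)
})

test_that("a changed relevant feature with a compatible predecessor rule is CRS-", {
  # N-1: shape of a red triangle (key 2); activated colour rule 'red'
  # maps to key 2, compatible. N: colour of a green circle (key 1).
  n1 <- list(task = "shape", colour = "red", shape = "triangle",
             vertical = "up", horizontal = "left")
  n0 <- list(task = "colour", colour = "green", shape = "circle",
             vertical = "down", horizontal = "right")
  res <- classify_crs(n1, n0, m1)
  expect_equal(res$label, "CRSminus")
  expect_true(res$response_alternation)
})

test_that("response repetition makes a trial ineligible for CRS", {
  n1 <- list(task = "shape", colour = "green", shape = "circle",
             vertical = "up", horizontal = "left")     # key 1
  n0 <- list(task = "colour", colour = "green", shape = "triangle",
             vertical = "down", horizontal = "right")  # key 1
  res <- classify_crs(n1, n0, m1)
  expect_equal(res$label, "ineligible")
  expect_false(res$response_alternation)
})

test_that("a repeated feature that competed in N-1 raises the CRC flag", {
  # 'up' repeats between trials and mapped to key 1 against N-1's correct
  # key 2, so its suppression trace contaminates trial N
  n1 <- list(task = "shape", colour = "green", shape = "triangle",
             vertical = "up", horizontal = "left")
  n0 <- list(task = "colour", colour = "green", shape = "circle",
             vertical = "up", horizontal = "right")
  res <- classify_crs(n1, n0, m1)
  expect_equal(res$label, "CRSplus")
  expect_true(res$crc)
})

test_that("trial-level exclusion flags follow the preprocessing rules", {
  rows <- list(
    list(task = "colour", colour = "green", shape = "circle",
         vertical = "up", horizontal = "left"),
    list(task = "shape", colour = "red", shape = "circle",
         vertical = "up", horizontal = "right"),
    list(task = "vertical", colour = "green", shape = "triangle",
         vertical = "down", horizontal = "left"),
    list(task = "colour", colour = "red", shape = "circle",
         vertical = "up", horizontal = "left"),
    list(task = "shape", colour = "green", shape = "triangle",
         vertical = "down", horizontal = "right"),
    list(task = "colour", colour = "red", shape = "triangle",
         vertical = "up", horizontal = "left", correct = FALSE),
    list(task = "vertical", colour = "green", shape = "circle",
         vertical = "down", horizontal = "right", rt = 3500),
    list(task = "horizontal", colour = "red", shape = "circle",
         vertical = "up", horizontal = "left"),
    list(task = "colour", colour = "red", shape = "circle",
         vertical = "up", horizontal = "left"),
    list(task = "shape", colour = "green", shape = "circle",
         vertical = "down", horizontal = "right", rt = 50)
  )
  cl <- classify_trials(make_trials(rows))
  expect_equal(which(cl$excl_first_four), 1:4)
  # error at trial 6 removes trials 7 and 8
  expect_equal(which(cl$excl_post_error), c(7L, 8L))
  expect_equal(which(cl$excl_rt_bounds), c(7L, 10L))
  # trial 9 repeats trial 8's stimulus on all four dimensions
  expect_equal(which(cl$excl_full_repetition), 9L)
  expect_false(cl$rt_included[6])   # errors never enter RT means
  expect_true(cl$pe_included[6])    # but do enter error proportions
  expect_false(any(cl$rt_included[c(7, 9, 10)]))
})

test_that("flags do not leak across block boundaries", {
  rows <- list(
    list(task = "colour", colour = "green", shape = "circle",
         vertical = "up", horizontal = "left", block = 1, trial = 63,
         correct = FALSE),
    list(task = "shape", colour = "green", shape = "circle",
         vertical = "up", horizontal = "left", block = 1, trial = 64),
    list(task = "colour", colour = "green", shape = "circle",
         vertical = "up", horizontal = "left", block = 2, trial = 1),
    list(task = "shape", colour = "red", shape = "triangle",
         vertical = "down", horizontal = "right", block = 2, trial = 2)
  )
  cl <- classify_trials(make_trials(rows))
  expect_true(cl$excl_post_error[2])
  expect_false(cl$excl_post_error[3])        # new block: no carry-over
  expect_false(cl$excl_full_repetition[3])   # stimulus repeat across break
  expect_equal(cl$bi_label, rep("unclassified", 4))
  expect_equal(cl$crs_label[c(1, 3)], c("ineligible", "ineligible"))
})

test_that("classification is idempotent and demands ordered input", {
  tr <- sim_clean_session(seed = 5)
  once <- classify_trials(tr)
  twice <- classify_trials(once)
  expect_identical(once, twice)
  expect_error(classify_trials(tr[rev(seq_len(nrow(tr))), ]),
               "ordering error")
})

test_that("every trial with two same-block predecessors gets exactly one BI label", {
  cl <- classify_trials(sim_clean_session(seed = 6))
  has2 <- cl$trial >= 3
  expect_true(all(cl$bi_label[has2] %in% c("ABA", "CBA")))
  expect_true(all(cl$bi_label[!has2] == "unclassified"))
  expect_equal(sum(cl$bi_label != "unclassified"), 7 * 62)
})

test_that("CRS labels never co-occur with response repetition", {
  cl <- classify_trials(sim_clean_session(seed = 8))
  labelled <- cl$crs_label %in% c("CRSplus", "CRSminus")
  expect_true(all(cl$response_alternation[labelled]))
  # and competitor counts of the predecessor match the label structure:
  # a CRS+ predecessor always held at least one competitor
  expect_true(all(cl$n_competitors_prev[cl$crs_label == "CRSplus"] >= 1))
  expect_true(all(cl$n_competitors_prev[cl$crs_label == "CRSminus"] <= 2))
})
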