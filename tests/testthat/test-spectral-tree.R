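test_that("tree invariants are enforced on construction", {
  # child heavier than parent
  expect_error(spectralTree("x", 300, numeric(), 1,
                            list(list(mz = 350, rel_intensity = 100))),
               "below its parent")
  # intensity outside (0, 100]
  expect_error(spectralTree("x", 300, numeric(), 1,
                            list(list(mz = 250, rel_intensity = 120))),
               "intensities")
  # two base peaks on one level
  expect_error(spectralTree("x", 300, numeric(), 1,
                            list(list(mz = 250, rel_intensity = 100),
                                 list(mz = 240, rel_intensity = 100))),
               "base peak")
  # fragments without a precursor
  expect_error(spectralTree("x", NA, numeric(), 1,
                            list(list(mz = 250, rel_intensity = 100))),
               "precursorMz")
  # fragment-free tree with unknown precursor is fine
  expect_s4_class(spectralTree("x", NA, c(250, 310), 1), "SpectralTree")
})

test_that("neutral losses cover every edge with positive deltas", {
  tr <- spectralTree("c1", 499, numeric(), 3.6,
    list(list(mz = 353, rel_intensity = 100,
              children = list(list(mz = 191, rel_intensity = 100))),
         list(mz = 481, rel_intensity = 30)))
  nl <- neutralLosses(tr)
  expect_equal(nrow(nl), 3L)
  expect_true(all(nl$delta > 0))
  expect_setequal(round(nl$delta), c(146, 162, 18))
  # hierarchical water/CO2 chain
  tr2 <- spectralTree("c6", 187, numeric(), 12.3,
    list(list(mz = 169, rel_intensity = 100,
              children = list(list(mz = 125, rel_intensity = 100)))))
  expect_setequal(neutralLosses(tr2)$delta, c(18, 44))
  # empty tree
  expect_equal(nrow(neutralLosses(spectralTree("e", 100))), 0L)
})

test_that("loss matching picks the nearest rule within tolerance", {
  expect_equal(matchLoss(146.0), "coumaroyl/deoxyhexosyl")
  expect_equal(matchLoss(18.0), "water")
  expect_equal(matchLoss(162.3), "caffeoyl/hexosyl")
  expect_true(is.na(matchLoss(146.6, defaultLossRules(tolerance = 0.5))))
  expect_true(is.na(matchLoss(100)))
  # nearest wins on overlap
  rules <- data.frame(delta = c(15, 18), moiety = c("a", "b"),
                      tolerance = 2)
  expect_equal(matchLoss(16.4, rules), "a")
  expect_equal(matchLoss(16.6, rules), "b")
})
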