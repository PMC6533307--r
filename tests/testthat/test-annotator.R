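# Table of identifications the published spectral dataset must
# reproduce, transcribed independently of the package's own library.
expectedIdentifications <- function() {
  data.frame(
    peak_id = as.character(1:23),
    name = c("3-O-caffeoyl-5-O-p-coumaroylquinic acid",
             "coumaroyloleuropein", "luteolin-O-glucoside",
             "3,5-dicaffeoylquinic acid monohydrate",
             "3,5-dicaffeoylquinic acid", "gallic acid monohydrate",
             "shikimic acid isomer", "methoxyoleuropein isomer",
             "luteolin", "prenyl-dimethoxy-caffeoyl-p-coumaric acid",
             "apigenin", "chrysoeriol", "tricin", "unknown",
             "monohydroxy-octadecaditrienoic acid", "unknown",
             "acacetin", "unknown", "dihydroxy-octadecenoic acid",
             "dihydroxy-octadecatrienoic acid",
             "dihydroxy-octadecatrienoic acid",
             "monohydroxy-octadecadienoic acid",
             "monohydroxy-octadecenoic acid"))
}

test_that("UV windows yield the right candidate classes", {
  expect_true("flavonoid" %in% classifyUv(c(250, 340)))
  expect_true("hydroxycinnamic_acid" %in% classifyUv(c(240, 330)))
  expect_true("hydroxybenzoic_acid" %in% classifyUv(c(250, 270, 320)))
  expect_false("flavonoid" %in% classifyUv(c(240, 310)))
  expect_setequal(classifyUv(numeric()),
                  c("hydroxybenzoic_acid", "hydroxycinnamic_acid",
                    "flavonoid", "hydroxy_fatty_acid"))
  # hydroxy fatty acids impose no UV requirement
  expect_true(all(vapply(list(c(250, 340), c(230, 300), 310),
                         function(uv) "hydroxy_fatty_acid" %in%
                           classifyUv(uv), logical(1))))
})

test_that("hydroxy fatty acid detection gates on mass window and water loss", {
  tr22 <- spectralTree("22", 295, 310, 28.6,
    list(list(mz = 277, rel_intensity = 100),
         list(mz = 265, rel_intensity = 30)))
  a <- detectHydroxyFattyAcid(tr22)
  expect_equal(compoundName(a), "monohydroxy-octadecadienoic acid")
  # non-base water loss still counts (co-dominant CO2 loss channel)
  tr20 <- spectralTree("20", 309, c(270, 320, 350), 27.3,
    list(list(mz = 291, rel_intensity = 50),
         list(mz = 265, rel_intensity = 10),
         list(mz = 247, rel_intensity = 100)))
  expect_equal(compoundName(detectHydroxyFattyAcid(tr20)),
               "dihydroxy-octadecatrienoic acid")
  # flavone aglycone mass in window is never claimed as a fatty acid
  tr_chry <- spectralTree("x", 299, c(250, 330), 17,
    list(list(mz = 281, rel_intensity = 100)))
  expect_null(detectHydroxyFattyAcid(tr_chry))
  # luteolin sits below the mass window
  tr_lut <- spectralTree("y", 285, c(250, 350), 14,
    list(list(mz = 267, rel_intensity = 100)))
  expect_null(detectHydroxyFattyAcid(tr_lut))
})

test_that("quinic acid esters are named from acyl losses and the 191 marker", {
  tr5 <- spectralTree("5", 515, c(240, 330), 11.9,
    list(list(mz = 353, rel_intensity = 100,
              children = list(list(mz = 191, rel_intensity = 100),
                              list(mz = 179, rel_intensity = 40),
                              list(mz = 173, rel_intensity = 10))),
         list(mz = 191, rel_intensity = 4)))
  a5 <- identifyQuinicEster(tr5)
  expect_equal(compoundName(a5), "3,5-dicaffeoylquinic acid")
  expect_true(any(grepl("caffeoyl", evidence(a5))))
  # monohydrate adduct: the +18 rule keys losses off precursor - 18
  tr4 <- spectralTree("4", 533, c(250, 330), 11.8,
    list(list(mz = 353, rel_intensity = 100,
              children = list(list(mz = 191, rel_intensity = 100),
                              list(mz = 179, rel_intensity = 16)))))
  expect_equal(compoundName(identifyQuinicEster(tr4)),
               "3,5-dicaffeoylquinic acid monohydrate")
  # no 191 marker anywhere: rule does not fire
  tr_no <- spectralTree("z", 515, numeric(), 1,
    list(list(mz = 353, rel_intensity = 100)))
  expect_null(identifyQuinicEster(tr_no))
  # failing the regiochemistry intensity key demotes to isomer
  tr_iso <- spectralTree("w", 515, numeric(), 1,
    list(list(mz = 353, rel_intensity = 100,
              children = list(list(mz = 191, rel_intensity = 100)))))
  a_iso <- identifyQuinicEster(tr_iso)
  expect_equal(confidence(a_iso), "tentative_isomer")
  expect_match(compoundName(a_iso), "isomer")
})

test_that("flavones, methoxyflavones and glucosides are identified", {
  tr3 <- spectralTree("3", 447, c(250, 340), 11.2,
    list(list(mz = 285, rel_intensity = 100)))
  a3 <- identifyFlavone(tr3)
  expect_equal(compoundName(a3), "luteolin-O-glucoside")
  tr13 <- spectralTree("13", 329, c(250, 270, 340), 17.5,
    list(list(mz = 314, rel_intensity = 100,
              children = list(list(mz = 299, rel_intensity = 100)))))
  expect_equal(compoundName(identifyFlavone(tr13)), "tricin")
  # methoxyflavone without its methyl chain is not claimed
  tr_nochain <- spectralTree("q", 329, c(250, 270, 340), 17.5,
    list(list(mz = 250, rel_intensity = 100)))
  expect_null(identifyFlavone(tr_nochain))
  # aglycone absent from the library falls through
  tr271 <- spectralTree("r", 271, c(250, 340), 15,
    list(list(mz = 160, rel_intensity = 100)))
  expect_null(identifyFlavone(tr271))
  # no flavone UV gate: same tree as tr3 but hydroxycinnamate bands
  tr_uv <- spectralTree("s", 447, c(240, 310), 11.2,
    list(list(mz = 285, rel_intensity = 100)))
  expect_null(identifyFlavone(tr_uv))
})

test_that("oleuropein derivatives fire on the 539/377 glucosyl signature", {
  tr2 <- spectralTree("2", 685, c(230, 300), 10.6,
    list(list(mz = 539, rel_intensity = 100,
              children = list(list(mz = 377, rel_intensity = 100))),
         list(mz = 523, rel_intensity = 60)))
  a2 <- identifyOleuropeinDerivative(tr2)
  expect_equal(compoundName(a2), "coumaroyloleuropein")
  tr8 <- spectralTree("8", 569, c(250, 270, 320), 13.3,
    list(list(mz = 525, rel_intensity = 100,
              children = list(list(mz = 193, rel_intensity = 100)))))
  a8 <- identifyOleuropeinDerivative(tr8)
  expect_equal(compoundName(a8), "methoxyoleuropein isomer")
  expect_equal(confidence(a8), "tentative_isomer")
  tr_none <- spectralTree("t", 600, numeric(), 1,
    list(list(mz = 400, rel_intensity = 100)))
  expect_null(identifyOleuropeinDerivative(tr_none))
})

test_that("the cascade reproduces the published 23-peak identification", {
  batch <- annotateBatch(exampleSpectralTrees())
  got <- batch$annotations
  exp <- expectedIdentifications()
  expect_equal(got$peak_id, exp$peak_id)
  expect_equal(tolower(got$name), tolower(exp$name))
  expect_equal(unname(batch$counts["phenolic"]), 14L)
  expect_equal(unname(batch$counts["phenolic_acid"]), 8L)
  expect_equal(unname(batch$counts["flavonoid"]), 6L)
  expect_equal(unname(batch$counts["hydroxy_fatty_acid"]), 6L)
  expect_equal(unname(batch$counts["unknown"]), 3L)
  # standards-backed flavones carry the highest confidence
  expect_equal(got$confidence[got$name %in%
                                c("luteolin", "apigenin", "acacetin")],
               rep("standard_matched", 3))
})

test_that("annotation is deterministic and order-independent", {
  trees <- exampleSpectralTrees()
  b1 <- annotateBatch(trees)
  b2 <- annotateBatch(rev(trees))
  expect_identical(b1$counts, b2$counts)
  m <- match(b1$annotations$peak_id, b2$annotations$peak_id)
  expect_identical(b1$annotations$name, b2$annotations$name[m])
  expect_identical(annotate(trees[[5]]), annotate(trees[[5]]))
})

test_that("duplicate peak ids are rejected in batches", {
  trees <- exampleSpectralTrees()[c(1, 1)]
  expect_error(annotateBatch(trees), "duplicate peak id")
})

test_that("annotation never cites a loss larger than the precursor", {
  for (tr in exampleSpectralTrees()) {
    if (is.na(precursorMz(tr))) next
    nl <- neutralLosses(tr)
    expect_true(all(nl$delta > 0))
    expect_true(all(nl$delta < precursorMz(tr)))
  }
})
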