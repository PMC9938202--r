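test_that("a blank DAPI channel yields an empty label map, not an error", {
  seg <- segmentNuclei(matrix(0, 128, 128))
  expect_equal(max(labelMap(seg)), 0)
  expect_equal(nrow(nucleusTable(seg)), 0)
})

test_that("a single nucleus is recovered with tight overlap", {
  fg <- generateField(fieldSpec(nNuclei = 1, touchingFraction = 0, seed = 2))
  seg <- segmentNuclei(channelImage(fg$field, 3))
  tl <- labelMap(fg$truth)
  expect_equal(nrow(nucleusTable(seg)), 1)
  expect_gte(jaccard(labelMap(seg) > 0, tl > 0), 0.8)
  truthCentroid <- c(mean(which(tl > 0, arr.ind = TRUE)[, 2]),
                     mean(which(tl > 0, arr.ind = TRUE)[, 1]))
  got <- unlist(nucleusTable(seg)[1, c("x", "y")])
  expect_lt(sqrt(sum((got - truthCentroid)^2)), 2)
})

test_that("touching nuclei of different brightness are split", {
  ## scan pair seeds until the planted pair differs in tier (DAPI peaks)
  found <- 0
  for (s in 1:12) {
    fg <- generateField(pairFieldSpec(s))
    tl <- labelMap(fg$truth)
    dapi <- channelImage(fg$field, 3)
    peaks <- vapply(1:2, function(i) max(dapi[tl == i]), numeric(1))
    if (abs(diff(peaks)) < 0.2) next
    found <- found + 1
    seg <- segmentNuclei(channelImage(fg$field, 3))
    expect_equal(nrow(nucleusTable(seg)), 2)
    mt <- majorityMatch(labelMap(seg), tl)
    expect_setequal(mt, 1:2)
    for (i in 1:2)
      expect_gte(jaccard(labelMap(seg) == i, tl == mt[i]), 0.7)
    if (found >= 3) break
  }
  expect_gte(found, 1)
})

test_that("objects below the minimum area are dropped", {
  ## a tiny bright blob
  dapi <- matrix(0, 128, 128)
  dapi[60:64, 60:64] <- 1
  seg <- segmentNuclei(dapi, segmentationParams(minArea = 5000))
  expect_equal(nrow(nucleusTable(seg)), 0)
  seg2 <- segmentNuclei(dapi, segmentationParams(minArea = 0))
  expect_gte(nrow(nucleusTable(seg2)), 1)
})

test_that("every retained label satisfies the minimum area", {
  fg <- generateField(fieldSpec(seed = 4))
  for (ma in c(150, 1000, 2500)) {
    seg <- segmentNuclei(channelImage(fg$field, 3),
                         segmentationParams(minArea = ma))
    if (nrow(nucleusTable(seg)) > 0)
      expect_true(all(nucleusTable(seg)$area >= ma))
  }
})

test_that("raising the minimum area never increases the label count", {
  fg <- generateField(fieldSpec(seed = 8))
  dapi <- channelImage(fg$field, 3)
  ns <- vapply(c(0, 150, 800, 2000, 4000, 1e5), function(ma)
    nrow(nucleusTable(segmentNuclei(dapi, segmentationParams(minArea = ma)))),
    integer(1))
  expect_true(all(diff(ns) <= 0))
  expect_equal(ns[length(ns)], 0)
})

test_that("all three brightness tiers are detected on separated nuclei", {
  fg <- generateField(fieldSpec(nNuclei = 12, width = 700, height = 700,
                                touchingFraction = 0, seed = 6))
  seg <- segmentNuclei(channelImage(fg$field, 3))
  tl <- labelMap(fg$truth)
  expect_equal(nrow(nucleusTable(seg)), max(tl))
  mt <- majorityMatch(labelMap(seg), tl)
  expect_setequal(mt, seq_len(max(tl)))
})

test_that("label maps are contiguously numbered with matching tables", {
  fg <- generateField(fieldSpec(seed = 10))
  seg <- segmentNuclei(channelImage(fg$field, 3))
  ids <- setdiff(sort(unique(as.vector(labelMap(seg)))), 0)
  expect_equal(ids, seq_along(ids))
  expect_equal(nucleusTable(seg)$nucleus, ids)
  areas <- tabulate(labelMap(seg), nbins = length(ids))
  expect_equal(nucleusTable(seg)$area, areas)
})

test_that("backends register, resolve, and reject duplicates/unknowns", {
  expect_true("quantise-watershed" %in% segmentationBackends())
  expect_equal(segmentationParams()@backend, "quantise-watershed")
  expect_error(registerBackend("quantise-watershed", identity),
               "already registered")
  expect_error(segmentNuclei(matrix(0, 8, 8),
                             segmentationParams(backend = "nope")),
               "unknown")
  ## the star-convex slot is an interface only until a segmenter is attached
  expect_error(segmentNuclei(matrix(0, 8, 8),
                             segmentationParams(backend = "star-convex")),
               "no star-convex segmenter")
})

test_that("an oracle backend reproduces ground-truth counts end to end", {
  fg <- generateField(fieldSpec(seed = 12))
  nm <- paste0("oracle-", sample.int(1e9, 1))
  registerBackend(nm, function(dapi, params) labelMap(fg$truth))
  seg <- segmentNuclei(channelImage(fg$field, 3),
                       segmentationParams(minArea = 0, backend = nm))
  ss <- detectFieldSpots(fg$field, punctaConfig()@thresholds)
  cct <- assignSpots(ss, seg, 10, "f")
  cc <- as.matrix(cellCounts(cct)[, c("ch1", "ch2", "ch4")])
  expect_equal(unname(cc), unname(trueCounts(fg$truth)))
})
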