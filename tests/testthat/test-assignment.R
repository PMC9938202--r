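## Build a SpotSet and NucleusLabelMap directly for controlled geometry.
makeSpotSet <- function(x, y, channel = 1L, dim = c(64L, 64L)) {
  new("SpotSet",
      spots = data.frame(x = as.integer(x), y = as.integer(y),
                         channel = as.integer(channel),
                         intensity = rep(1, length(x))),
      thresholds = c(ch1 = 0.5, ch2 = 0.5, ch4 = 0.5),
      minSeparation = 2, imageDim = as.integer(dim))
}

discLabels <- function(cx, cy, r, dim = c(64L, 64L)) {
  m <- matrix(0L, dim[1], dim[2])
  for (i in seq_along(cx)) {
    idx <- which(outer((seq_len(dim[1]) - cy[i])^2,
                       (seq_len(dim[2]) - cx[i])^2, "+") <= r[i]^2)
    m[idx] <- i
  }
  asNucleusLabelMap(m)
}

test_that("a spot inside a nucleus is assigned to it at distance zero", {
  labels <- discLabels(30, 30, 8)
  cct <- assignSpots(makeSpotSet(30, 30), labels)
  expect_equal(cellCounts(cct)$ch1, 1)
  expect_equal(unname(unassignedCounts(cct)[["ch1"]]), 0)
})

test_that("the 10-pixel rule is inclusive at exactly 10.0", {
  ## disc edge at x = 38 (centre 30, r 8); spot at x = 48 -> distance 10.0
  labels <- discLabels(30, 30, 8)
  cct <- assignSpots(makeSpotSet(48, 30), labels, maxDist = 10)
  expect_equal(cellCounts(cct)$ch1, 1)
  ## one pixel farther: unassigned
  cct2 <- assignSpots(makeSpotSet(49, 30), labels, maxDist = 10)
  expect_equal(cellCounts(cct2)$ch1, 0)
  expect_equal(unname(unassignedCounts(cct2)[["ch1"]]), 1)
})

test_that("equidistant spots go to the lower nucleus label", {
  ## two discs symmetric about x = 32
  labels <- discLabels(c(22, 42), c(30, 30), c(5, 5))
  cct <- assignSpots(makeSpotSet(32, 30), labels)
  expect_equal(cellCounts(cct)$ch1, c(1, 0))
})

test_that("assignment matches the exhaustive all-pairs oracle", {
  set.seed(2024)
  for (rep in 1:100) {
    dim <- c(48L, 48L)
    n <- sample.int(10, 1)
    labels <- discLabels(runif(n, 8, 40), runif(n, 8, 40),
                         runif(n, 2, 6), dim)
    m <- sample.int(100, 1)
    sp <- data.frame(x = sample.int(48, m, replace = TRUE),
                     y = sample.int(48, m, replace = TRUE),
                     channel = sample(c(1L, 2L, 4L), m, replace = TRUE),
                     intensity = 1)
    ss <- new("SpotSet", spots = sp,
              thresholds = c(ch1 = 0.5, ch2 = 0.5, ch4 = 0.5),
              minSeparation = 0, imageDim = dim)
    cct <- assignSpots(ss, labels, maxDist = 10)
    want <- bruteForceAssign(sp, labelMap(labels), maxDist = 10)
    nl <- nrow(nucleusTable(labels))
    for (ch in c(1, 2, 4)) {
      sel <- sp$channel == ch
      wantCounts <- tabulate(want[sel], nbins = nl)
      expect_equal(cellCounts(cct)[[paste0("ch", ch)]], wantCounts)
      expect_equal(unname(unassignedCounts(cct)[[paste0("ch", ch)]]),
                   sum(sel & want == 0))
    }
    ## conservation: assigned + unassigned = detected
    tot <- colSums(cellCounts(cct)[, c("ch1", "ch2", "ch4"), drop = FALSE]) +
      unassignedCounts(cct)
    expect_equal(unname(tot),
                 as.integer(table(factor(sp$channel, levels = c(1, 2, 4)))))
  }
})

test_that("dimension mismatches are rejected", {
  labels <- discLabels(30, 30, 8, dim = c(64L, 64L))
  ss <- makeSpotSet(10, 10, dim = c(32L, 32L))
  expect_error(assignSpots(ss, labels), "dimensions")
})

test_that("marker positivity follows per-marker thresholds", {
  counts <- data.frame(field_id = "f", nucleus = 1:2, x = 0, y = 0, area = 1,
                       ch1 = c(4L, 0L), ch2 = c(0L, 0L), ch4 = c(2L, 0L))
  fl <- positivity(counts, defaultMarkerMap("A"))
  expect_equal(unname(fl[1, ]), c(TRUE, FALSE, TRUE))   # TH+, zif268-, Arc+
  expect_equal(unname(fl[2, ]), c(FALSE, FALSE, FALSE))
  fl2 <- positivity(counts, defaultMarkerMap("A"), c(TH = 5))
  expect_false(fl2[1, "TH"])
  expect_error(positivity(counts, defaultMarkerMap("A"), c(CD68 = 1)),
               "unknown marker")
  expect_error(positivity(counts, defaultMarkerMap("A"), c(TH = 0)), ">= 1")
})

test_that("ensemble percentages partition every cell and sum to 100", {
  set.seed(7)
  counts <- data.frame(ch1 = rpois(40, 2), ch2 = rpois(40, 1),
                       ch4 = rpois(40, 3))
  pct <- ensemblePercentages(positivity(counts, defaultMarkerMap("B")))
  expect_length(pct, 8)
  expect_equal(sum(pct), 100)
})

test_that("animal aggregation sums fields and group means average animals", {
  mk <- function(tot, id) {
    new("CellCountTable",
        counts = data.frame(field_id = id, nucleus = 1L, x = 1, y = 1,
                            area = 10, ch1 = tot, ch2 = 0L, ch4 = 0L),
        unassigned = c(ch1 = 0, ch2 = 0, ch4 = 0), fieldId = id,
        maxDist = 10)
  }
  s <- aggregateAnimal(list(mk(10L, "f1"), mk(15L, "f2")), "rat01")
  expect_equal(s$total_ch1, 25)
  expect_equal(s$n_fields, 2)
  two <- rbind(s, within(s, total_ch1 <- 35))
  gm <- groupMean(two[, c("total_ch1", "n_cells")], c("HD", "HD"))
  expect_equal(gm$total_ch1, 30)
})

test_that("zero cells give missing percentages with a warning", {
  empty <- new("CellCountTable",
               counts = data.frame(field_id = character(0),
                                   nucleus = integer(0), x = numeric(0),
                                   y = numeric(0), area = numeric(0),
                                   ch1 = integer(0), ch2 = integer(0),
                                   ch4 = integer(0)),
               unassigned = c(ch1 = 0, ch2 = 0, ch4 = 0), fieldId = "f",
               maxDist = 10)
  expect_warning(s <- aggregateAnimal(list(empty), "rat99"), "zero cells")
  expect_true(all(is.na(unlist(s[grep("^pct_", names(s))]))))
})

test_that("planted zif268-negative fraction is recovered exactly", {
  ## low channel-2 abundance so a sizeable fraction of cells is truly
  ## zif268-negative; the detected fraction must match the planted one
  fg <- generateField(fieldSpec(nNuclei = 10, touchingFraction = 0,
                                perChannelLambda = c(5, 0.7, 5),
                                backgroundSigma = 0, seed = 31))
  tc <- trueCounts(fg$truth)
  ss <- detectFieldSpots(fg$field, punctaConfig()@thresholds)
  seg <- segmentNuclei(channelImage(fg$field, 3))
  cct <- assignSpots(ss, seg, 10, "f")
  fl <- positivity(cct, defaultMarkerMap("A"))
  expect_equal(mean(!fl[, "zif268"]), mean(tc[, "ch2"] == 0))
})
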