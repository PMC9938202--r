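test_that("nothing is detected on a flat field", {
  expect_equal(nrow(spots(detectSpots(matrix(0, 64, 64), 1, 0.1))), 0)
})

test_that("a single rendered punctum is found at its centre", {
  img <- matrix(0, 64, 64)
  for (dx in -2:2) for (dy in -2:2)
    img[30 + dy, 41 + dx] <- exp(-(dx^2 + dy^2) / 2)
  f <- dogFilter(img)
  sp <- spots(detectSpots(f, 2, 0.1))
  expect_equal(nrow(sp), 1)
  expect_lte(abs(sp$x - 41) + abs(sp$y - 30), 2)  # within 1 px per axis
  expect_equal(sp$channel, 2L)
})

test_that("raising the threshold never increases the spot count", {
  fg <- generateField(fieldSpec(seed = 11))
  f <- dogFilter(channelImage(fg$field, 1))
  counts <- vapply(c(0.05, 0.15, 0.3, 0.5, 0.8),
                   function(th) nrow(spots(detectSpots(f, 1, th))),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detection is equivariant under image translation", {
  fg <- generateField(fieldSpec(width = 256, height = 256, nNuclei = 5,
                                seed = 5, backgroundSigma = 0))
  img <- channelImage(fg$field, 1)
  sp0 <- spots(detectSpots(dogFilter(img), 1, 0.25))
  dx <- 7L; dy <- 4L  # translate keeping content clear of borders
  shifted <- matrix(0, nrow(img), ncol(img))
  shifted[(1 + dy):nrow(img), (1 + dx):ncol(img)] <-
    img[1:(nrow(img) - dy), 1:(ncol(img) - dx)]
  sp1 <- spots(detectSpots(dogFilter(shifted), 1, 0.25))
  expect_equal(nrow(sp1), nrow(sp0))
  ord0 <- order(sp0$y, sp0$x); ord1 <- order(sp1$y, sp1$x)
  expect_equal(sp1$x[ord1], sp0$x[ord0] + dx)
  expect_equal(sp1$y[ord1], sp0$y[ord0] + dy)
})

test_that("close detections are suppressed, brighter spot wins", {
  f <- matrix(0, 32, 32)
  f[16, 16] <- 1; f[16, 17] <- 0.8   # 1 px apart
  sp <- spots(detectSpots(f, 1, 0.1, minSeparation = 2))
  expect_equal(nrow(sp), 1)
  expect_equal(sp$x, 16L)
})

test_that("detected counts equal ground truth on clean synthetic fields", {
  for (s in c(3, 9)) {
    fg <- generateField(fieldSpec(seed = s, backgroundSigma = 0))
    ss <- detectFieldSpots(fg$field, punctaConfig()@thresholds)
    byCh <- table(factor(spots(ss)$channel, levels = c(1, 2, 4)))
    trueByCh <- table(factor(fg$truth@dots$channel, levels = c(1, 2, 4)))
    expect_equal(as.integer(byCh), as.integer(trueByCh))
    ## every detection sits exactly on a planted molecule
    key <- paste(spots(ss)$x, spots(ss)$y, spots(ss)$channel)
    trueKey <- paste(fg$truth@dots$x, fg$truth@dots$y, fg$truth@dots$channel)
    expect_setequal(key, trueKey)
  }
})

test_that("spot sets validate their threshold invariant", {
  expect_error(new("SpotSet",
                   spots = data.frame(x = 1L, y = 1L, channel = 1L,
                                      intensity = 0.1),
                   thresholds = c(ch1 = 0.5), minSeparation = 2,
                   imageDim = c(10L, 10L)),
               "exceed")
})
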