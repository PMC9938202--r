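test_that("an empty spec yields an all-zero field and empty truth", {
  fg <- generateField(fieldSpec(nNuclei = 0, backgroundSigma = 0, seed = 1))
  expect_true(all(fg$field@data == 0))
  expect_true(all(labelMap(fg$truth) == 0))
  expect_equal(nrow(trueCounts(fg$truth)), 0)
  expect_equal(nrow(fg$truth@dots), 0)
})

test_that("true counts equal the rendered owned molecules per channel", {
  fg <- generateField(fieldSpec(seed = 7))
  owned <- fg$truth@dots[fg$truth@dots$nucleus > 0, ]
  for (k in c(1, 2, 4)) {
    expect_equal(sum(trueCounts(fg$truth)[, paste0("ch", k)]),
                 sum(owned$channel == k))
  }
  ## per nucleus too
  tab <- table(factor(owned$nucleus, levels = seq_len(nrow(trueCounts(fg$truth)))),
               factor(owned$channel, levels = c(1, 2, 4)))
  expect_equal(unname(as.matrix(tab)), unname(trueCounts(fg$truth)))
})

test_that("generation is bit-exact under a fixed seed and differs across seeds", {
  a <- generateField(fieldSpec(seed = 5))
  b <- generateField(fieldSpec(seed = 5))
  c <- generateField(fieldSpec(seed = 6))
  expect_identical(a$field@data, b$field@data)
  expect_identical(a$truth@dots, b$truth@dots)
  expect_false(identical(a$truth@dots, c$truth@dots))
})

test_that("every owned molecule lies within the assignment radius of its nucleus", {
  fg <- generateField(fieldSpec(seed = 13))
  tl <- labelMap(fg$truth)
  owned <- fg$truth@dots[fg$truth@dots$nucleus > 0, ]
  ## owned dots are placed in the nucleus interior: distance 0
  expect_true(all(tl[cbind(owned$y, owned$x)] == owned$nucleus))
  ## stray dots are out of reach of every nucleus
  far <- fg$truth@dots[fg$truth@dots$nucleus == 0, ]
  px <- which(tl > 0, arr.ind = TRUE)
  for (i in seq_len(nrow(far))) {
    d2 <- min((px[, 2] - far$x[i])^2 + (px[, 1] - far$y[i])^2)
    expect_gt(sqrt(d2), 10)
  }
})

test_that("same-channel molecules honour the minimum separation", {
  fg <- generateField(fieldSpec(seed = 21))
  for (ch in c(1, 2, 4)) {
    d <- fg$truth@dots[fg$truth@dots$channel == ch, ]
    if (nrow(d) < 2) next
    dist2 <- as.matrix(dist(cbind(d$x, d$y)))^2
    diag(dist2) <- Inf
    expect_gte(min(dist2), 16)  # >= 4 px apart
  }
})

test_that("impossible placement raises an explicit error", {
  expect_error(generateField(fieldSpec(width = 200, height = 200,
                                       nNuclei = 40, seed = 1)),
               "placement|too small")
})

test_that("the DAPI channel carries the three brightness tiers", {
  fg <- generateField(fieldSpec(nNuclei = 30, width = 768, height = 768,
                                touchingFraction = 0, backgroundSigma = 0,
                                seed = 2))
  tl <- labelMap(fg$truth)
  dapi <- channelImage(fg$field, 3)
  peak <- vapply(seq_len(max(tl)), function(i) max(dapi[tl == i]),
                 numeric(1))
  ## peaks cluster near the three tier levels
  tiers <- fieldSpec()@brightnessTiers
  assigned <- vapply(peak, function(p) which.min(abs(tiers - p)), integer(1))
  expect_setequal(unique(assigned), 1:3)
  expect_true(all(abs(peak - tiers[assigned]) < 0.12))
})
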