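test_that("Kruskal-Wallis matches the textbook rank-sum value", {
  res <- kruskalWallis(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(res$H, 3.857143, tolerance = 1e-6)
  expect_equal(res$df, 1)
  expect_false(res$degenerate)
})

test_that("Kruskal-Wallis without ties equals the rank-sum formula", {
  set.seed(99)
  for (rep in 1:25) {
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k), function(i) runif(sample(3:8, 1)))
    expect_equal(kruskalWallis(groups)$H, kwRankSum(groups),
                 tolerance = 1e-10)
  }
})

test_that("identical groups and degenerate data give H = 0", {
  expect_equal(kruskalWallis(list(c(1, 2, 3), c(1, 2, 3)))$H, 0)
  deg <- kruskalWallis(list(c(2, 2), c(2, 2, 2)))
  expect_equal(deg$H, 0)
  expect_true(deg$degenerate)
  expect_error(kruskalWallis(list(numeric(0), 1:3)), "observations")
})

test_that("pairwise follow-ups are two-group contrasts", {
  res <- kruskalWallis(list(HD = c(9, 10, 12), LD = c(1, 2, 3),
                            IM = c(5, 6, 7)), pairwise = TRUE)
  expect_equal(nrow(res$pairwise), 3)
  hdld <- res$pairwise[res$pairwise$group1 == "HD" &
                         res$pairwise$group2 == "LD", ]
  expect_equal(hdld$H, kruskalWallis(list(c(9, 10, 12), c(1, 2, 3)))$H)
})

test_that("BH q-values equal the closed-form step-up minima", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  set.seed(123)
  for (rep in 1:1000) {
    p <- runif(sample(3:30, 1))
    expect_equal(p.adjust(p, "BH"), bhStepUp(p), tolerance = 1e-12)
  }
})

test_that("Spearman is +-1 on monotone data and equals Pearson on ranks", {
  beh <- data.frame(animal_id = sprintf("r%d", 1:5), session = 1,
                    phase = "training", intake_ml = 1:5)
  up <- data.frame(animal_id = sprintf("r%d", 1:5), m = c(2, 4, 6, 8, 10))
  cm <- spearmanBH(beh, up)
  expect_equal(unname(cm@r[1, 1]), 1)
  down <- data.frame(animal_id = sprintf("r%d", 1:5), m = c(10, 8, 6, 4, 2))
  expect_equal(unname(spearmanBH(beh, down)@r[1, 1]), -1)
  ## mid-rank equivalence on noisy data with ties
  set.seed(4)
  x <- sample(1:8, 12, replace = TRUE)
  y <- sample(1:8, 12, replace = TRUE)
  beh2 <- data.frame(animal_id = sprintf("r%02d", 1:12), session = 1,
                     phase = "training", intake_ml = x)
  m2 <- data.frame(animal_id = sprintf("r%02d", 1:12), m = y)
  expect_equal(unname(spearmanBH(beh2, m2)@r[1, 1]),
               cor(rank(x), rank(y)), tolerance = 1e-12)
})

test_that("constant vectors yield missing cells, and q >= p holds", {
  beh <- data.frame(animal_id = rep(sprintf("r%d", 1:6), each = 2),
                    session = rep(1:2, 6), phase = "training",
                    intake_ml = c(rbind(rep(5, 6), 1:6)))
  met <- data.frame(animal_id = sprintf("r%d", 1:6), m = c(3, 1, 4, 1, 5, 9))
  cm <- spearmanBH(beh, met)
  expect_true(is.na(cm@r["s1", "m"]))      # session 1 intake constant
  expect_false(is.na(cm@r["s2", "m"]))
  expect_true(all(cm@q >= cm@p, na.rm = TRUE))
})

test_that("quartile phenotyping picks floor(N/4) per tail by final-3 mean", {
  beh <- do.call(rbind, lapply(1:8, function(i)
    data.frame(animal_id = sprintf("r%d", i), session = 1:5,
               phase = "training", intake_ml = i)))
  ph <- phenotypeQuartiles(beh)
  expect_equal(sort(ph$animal_id[ph$phenotype == "HD"]), c("r7", "r8"))
  expect_equal(sort(ph$animal_id[ph$phenotype == "LD"]), c("r1", "r2"))
  expect_equal(sum(ph$phenotype == "intermediate"), 4)
  expect_error(phenotypeQuartiles(beh[beh$animal_id %in%
                                        c("r1", "r2", "r3"), ]),
               "at least 4")
})

test_that("ties still produce full quartiles via the documented tie-break", {
  beh <- do.call(rbind, lapply(1:8, function(i)
    data.frame(animal_id = sprintf("r%d", i), session = 1:5,
               phase = "training", intake_ml = 7)))
  ph <- phenotypeQuartiles(beh)
  expect_equal(sum(ph$phenotype == "HD"), 2)
  expect_equal(sum(ph$phenotype == "LD"), 2)
  ## deterministic: animal_id order decides
  expect_equal(sort(ph$animal_id[ph$phenotype == "HD"]), c("r1", "r2"))
})

test_that("phenotyping is invariant to row permutation", {
  coh <- generateBehavior(behaviorSpec(nAnimals = 16, seed = 5))
  tab <- intakeTable(coh)
  ph1 <- phenotypeQuartiles(tab)
  set.seed(1)
  ph2 <- phenotypeQuartiles(tab[sample.int(nrow(tab)), ])
  expect_equal(ph1, ph2)
})

test_that("noise-free planted escalators are labelled HD exactly", {
  coh <- generateBehavior(behaviorSpec(nAnimals = 48, noiseSd = 0, seed = 11))
  ph <- phenotypeQuartiles(coh)
  expect_equal(sort(ph$animal_id[ph$phenotype == "HD"]),
               escalators(coh))
  expect_equal(sum(ph$phenotype == "HD"), 12)
  expect_equal(sum(ph$phenotype == "LD"), 12)
})

test_that("correlation with a coupled metric turns on at the onset session", {
  sp <- behaviorSpec(nAnimals = 48, noiseSd = 0, escalationOnset = 8,
                     seed = 17)
  coh <- generateBehavior(sp)
  fw <- finalWindowMean(coh)
  ## metric planted as a decreasing monotone function of final drinking
  met <- data.frame(animal_id = names(fw), arc = 1000 - 5 * fw)
  cm <- spearmanBH(coh, met)
  train <- grep("^s", rownames(cm@r), value = TRUE)
  sess <- as.integer(sub("s", "", train))
  pre <- train[sess < sp@escalationOnset]
  post <- train[sess >= sp@escalationOnset]
  expect_true(all(is.na(cm@sig[pre, "arc"])))   # constant pre-onset intake
  expect_true(all(cm@sig[post, "arc"]))
  expect_true(all(cm@r[post, "arc"] < 0))
})
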