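test_that("extractTiles crops centered tiles and reflect-pads at borders", {
  img <- array(0, dim = c(200, 200, 3))
  img[, , 1] <- matrix(seq_len(200), 200, 200)          # row index as red
  cand <- data.frame(id = c(1L, 2L), row = c(100, 2), col = c(100, 100))
  tiles <- extractTiles(img, cand, side = 100L)
  expect_length(tiles, 2L)
  expect_equal(dim(tiles[[1]]), c(100L, 100L, 3L))
  expect_equal(attr(tiles[[1]], "id"), 1L)
  ## interior crop: rows 50..149 of the image
  expect_equal(tiles[[1]][, 1, 1], as.numeric(50:149))
  ## border crop: reflected rows never index outside the image
  expect_true(all(tiles[[2]][, , 1] >= 1 & tiles[[2]][, , 1] <= 200))
  ## the tile center pixel (position half + 1) carries the candidate's row
  expect_equal(tiles[[2]][51, 51, 1], 2)
  expect_equal(tiles[[1]][51, 51, 1], 100)
  expect_equal(length(extractTiles(img, cand[0, ])), 0L)
})

test_that("the rule classifier separates synthetic bud from non-bud tiles", {
  dat <- generateClassifierTiles(15, 15, noiseSd = 0, seed = 4)
  model <- ruleBudClassifier()
  res <- classifyTiles(model, dat$tiles)
  expect_equal(res$id, seq_along(dat$tiles))
  expect_true(all(res$p_bud %in% c(0, 1)))
  expect_equal(res$label, dat$labels)
})

test_that("rule classifier rejects each morphology violation in isolation", {
  model <- ruleBudClassifier()
  mkTile <- function(sup, density = 0.9) {
    dab <- matrix(0, 100, 100); dab[sup] <- density
    renderDensities(matrix(0, 100, 100), dab, round = FALSE)
  }
  disc <- budquant:::paintDisc(matrix(FALSE, 100, 100), 50, 50, 12)
  ## compact disc of in-gate area and density passes
  expect_equal(classifyTiles(model, list(structure(mkTile(disc), id = 1L)))$label,
               "bud")
  ## too small (debris)
  tiny <- budquant:::paintDisc(matrix(FALSE, 100, 100), 50, 50, 5)
  expect_equal(classifyTiles(model, list(structure(mkTile(tiny), id = 1L)))$label,
               "not_bud")
  ## faint staining fails the density gate
  expect_equal(classifyTiles(model,
                 list(structure(mkTile(disc, density = 0.2), id = 1L)))$label,
               "not_bud")
  ## elongated streak fails eccentricity/solidity
  streak <- matrix(FALSE, 100, 100)
  for (tpos in seq(-38, 38, by = 1.5))
    streak <- budquant:::paintDisc(streak, 50 + tpos, 50, 3.5)
  expect_equal(classifyTiles(model, list(structure(mkTile(streak), id = 1L)))$label,
               "not_bud")
  ## blank tile is not a bud
  blank <- renderDensities(matrix(0, 100, 100), matrix(0, 100, 100))
  expect_equal(classifyTiles(model, list(structure(blank, id = 1L)))$label,
               "not_bud")
})

test_that("shape features match hand-computed values", {
  ## filled 21x21 square: solidity 1 (hull through pixel centers is 20x20,
  ## capped at 1), eccentricity 0 by symmetry
  pts <- expand.grid(r = 1:21, c = 1:21)
  sf <- budquant:::shapeFeatures(pts$r, pts$c)
  expect_equal(sf$solidity, 1)
  expect_equal(sf$eccentricity, 0, tolerance = 1e-12)
  ## a 1-px-wide line has eccentricity 1 and the solidity guard kicks in
  sfLine <- budquant:::shapeFeatures(rep(5, 30), 1:30)
  expect_equal(sfLine$eccentricity, 1)
  ## an L of pixels is far from convex
  rr <- c(1:20, rep(20, 19)); cc <- c(rep(1, 20), 2:20)
  sfL <- budquant:::shapeFeatures(rr, cc)
  expect_lt(sfL$solidity, 0.5)
})

test_that("CNN training is deterministic and learns the desk-scale task", {
  dat <- generateClassifierTiles(20, 20, seed = 10)
  m1 <- trainBudCNN(dat$tiles, dat$labels, epochs = 3, seed = 3)
  m2 <- trainBudCNN(dat$tiles, dat$labels, epochs = 3, seed = 3)
  expect_identical(m1@weights, m2@weights)
  expect_gte(m1@meta$accuracy, 0.9)
  ## held-out tiles from a different seed
  test <- generateClassifierTiles(10, 10, seed = 11)
  pred <- classifyTiles(m1, test$tiles)
  expect_true(all(pred$p_bud >= 0 & pred$p_bud <= 1))
  expect_gte(mean(pred$label == test$labels), 0.9)
})

test_that("CNN training rejects single-class labels and bad tile sizes", {
  dat <- generateClassifierTiles(3, 3, seed = 1)
  expect_error(trainBudCNN(dat$tiles, rep("bud", 6)), "both classes")
  small <- list(array(0, dim = c(50, 50, 3)))
  expect_error(trainBudCNN(small, "bud"), "both classes|100")
  m <- trainBudCNN(dat$tiles, dat$labels, epochs = 1, seed = 1)
  expect_error(classifyTiles(m, small), "100")
})

test_that("CNN checkpoints round-trip through JSON exactly enough", {
  dat <- generateClassifierTiles(4, 4, seed = 2)
  m <- trainBudCNN(dat$tiles, dat$labels, epochs = 1, seed = 2)
  path <- tempfile(fileext = ".json")
  saveBudCNN(m, path)
  m2 <- loadBudCNN(path)
  for (nm in names(m@weights))
    expect_equal(m2@weights[[nm]], m@weights[[nm]], tolerance = 1e-12)
  p1 <- classifyTiles(m, dat$tiles)$p_bud
  p2 <- classifyTiles(m2, dat$tiles)$p_bud
  expect_equal(p2, p1, tolerance = 1e-10)
})

test_that("maxpool backward routes gradients to the argmax positions", {
  x <- array(stats::rnorm(8 * 8 * 2), c(8, 8, 2))
  p <- budquant:::maxpool2(x)
  g <- array(1, dim(p$out))
  back <- budquant:::maxpool2Back(g, p$arg, dim(x))
  ## exactly one gradient unit per pooling window
  expect_equal(sum(back), length(p$out))
  ## gradient lands only where the input attains the window maximum
  expect_true(all(x[back > 0] %in% p$out))
})

test_that("im2col/col2im are adjoint", {
  set.seed(3)
  x <- array(stats::rnorm(10 * 10 * 2), c(10, 10, 2))
  cols <- budquant:::im2col(x, 3L)
  g <- matrix(stats::rnorm(length(cols)), nrow(cols), ncol(cols))
  back <- budquant:::col2im(g, dim(x), 3L)
  ## <im2col(x), g> == <x, col2im(g)>
  expect_equal(sum(cols * g), sum(x * back), tolerance = 1e-10)
})
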