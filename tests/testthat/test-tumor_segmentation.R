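test_that("the network separates well-separated clusters almost perfectly", {
  set.seed(2)
  n <- 1000
  X <- rbind(matrix(rnorm(n * 10, 0), n), matrix(rnorm(n * 10, 2), n))
  y <- rep(c(0, 1), each = n)
  m <- train_classifier(X, y, seed = 5)
  expect_gte(mean((predict(m, X) >= 0.5) == y), 0.99)
  expect_lt(m$training$final_loss, 0.1)

  # determinism: identical seed gives identical weights
  m2 <- train_classifier(X, y, seed = 5)
  expect_identical(m$weights, m2$weights)
  expect_identical(m$biases, m2$biases)
})

test_that("training rejects single-class labels and non-finite features", {
  X <- matrix(rnorm(50), 5)
  expect_error(train_classifier(X, rep(0, 5)), class = "ctb_training_error")
  X[3, 2] <- NA
  expect_error(train_classifier(X, c(0, 1, 0, 1, 0)),
               class = "ctb_validation_error")
})

test_that("probabilities live strictly inside (0,1) and thresholding is monotone", {
  set.seed(8)
  X <- matrix(rnorm(200 * 10), 200)
  y <- as.integer(X[, 1] > 0)
  m <- train_classifier(X, y, epochs = 200)
  d <- c(10, 5, 4)
  roi_arr <- array(FALSE, d)
  roi_arr[sample(prod(d), 200)] <- TRUE
  idx <- which(roi_arr, arr.ind = TRUE)
  feats <- as.data.frame(X[seq_len(nrow(idx)), ])
  names(feats) <- feature_names()
  feats$z <- idx[, 1]; feats$y <- idx[, 2]; feats$x <- idx[, 3]
  roi <- ct_mask(roi_arr)

  m_all <- classify_voxels(m, feats, roi, threshold = 0)
  m_none <- classify_voxels(m, feats, roi, threshold = 1)
  expect_identical(sum(m_all$data), nrow(feats))
  expect_identical(sum(m_none$data), 0L)
  prev <- m_all$data
  for (th in c(0.25, 0.5, 0.75)) {
    cur <- classify_voxels(m, feats, roi, threshold = th)$data
    expect_true(all(prev | !cur)) # raising threshold never adds voxels
    prev <- cur
  }
})

test_that("voxel classification on an unseen phantom reaches F1 >= 0.85", {
  model <- trained_model()
  ph <- make_phantom(easy_config(501))
  liver <- ph$truth$liver_mask
  feats <- feature_map(ph$pre, liver, window = desk_window)
  raw <- classify_voxels(model, feats, liver)
  truth <- ph$truth$tumor_mask_pre$data
  tp <- sum(raw$data & truth)
  f1 <- 2 * tp / (sum(raw$data) + sum(truth))
  expect_gte(f1, 0.85)
})

test_that("morphological clean-up fills holes, removes specks and respects radii 0", {
  d <- c(13, 13, 13)
  cube <- array(FALSE, d); cube[3:11, 3:11, 3:11] <- TRUE
  holey <- cube; holey[7, 7, 7] <- FALSE
  out <- postprocess_mask(ct_mask(holey), 1, 1)
  expect_true(out$data[7, 7, 7])
  expect_false(any(out$data & !cube))           # opening never grows past it
  expect_gte(sum(out$data & cube), sum(cube) * 0.85) # corners may round off

  speck <- array(FALSE, d); speck[6, 6, 6] <- TRUE
  expect_identical(sum(postprocess_mask(ct_mask(speck), 1, 1)$data), 0L)

  m <- ct_mask(holey)
  expect_identical(postprocess_mask(m, 0, 0)$data, m$data)
  expect_error(postprocess_mask(m, -1, 0), class = "ctb_contract_error")
})

test_that("closing is extensive, opening anti-extensive, composite near-idempotent", {
  set.seed(19)
  for (i in 1:4) {
    d <- c(16, 16, 16)
    arr <- array(runif(prod(d)) < 0.4, d)
    arr <- binary_close(arr, 1) # mild coherence, as real masks have
    expect_true(all(binary_close(arr, 1)[arr]))        # extensive
    expect_true(all(arr[binary_open(arr, 1)]))         # anti-extensive
    p1 <- postprocess_mask(ct_mask(arr), 1, 1)
    p2 <- postprocess_mask(p1, 1, 1)
    expect_lte(abs(sum(p2$data) - sum(p1$data)), 0.01 * max(sum(p1$data), 1))
  }
})

test_that("refinement edits apply exactly, idempotently, and reject conflicts", {
  d <- c(8, 8, 8)
  arr <- array(FALSE, d); arr[4, 4, 4] <- TRUE; arr[5, 5, 5] <- TRUE
  m <- ct_mask(arr)

  expect_identical(apply_refinement(m, data.frame())$data, m$data)

  edits <- data.frame(z = c(1, 2, 3, 4, 5), y = c(1, 2, 3, 4, 5),
                      x = c(1, 2, 3, 4, 5),
                      action = c("add", "add", "add", "remove", "remove"))
  out <- apply_refinement(m, edits)
  expect_identical(sum(out$data), sum(m$data) + 3L - 2L)
  expect_identical(apply_refinement(out, edits)$data, out$data) # idempotent

  conflict <- data.frame(z = c(2, 2), y = c(2, 2), x = c(2, 2),
                         action = c("add", "remove"))
  expect_error(apply_refinement(m, conflict), class = "ctb_validation_error")
  oob <- data.frame(z = 9, y = 1, x = 1, action = "add")
  expect_error(apply_refinement(m, oob), class = "ctb_validation_error")
})

test_that("JSON serialization round-trips the classifier exactly", {
  set.seed(31)
  X <- matrix(rnorm(100 * 10), 100)
  y <- as.integer(X[, 2] > 0)
  m <- train_classifier(X, y, epochs = 100)
  f <- tempfile(fileext = ".json")
  save_classifier(m, f)
  m2 <- load_classifier(f)
  expect_identical(predict(m2, X), predict(m, X))
  expect_equal(m2$weights, m$weights)
  expect_equal(unname(m2$center), unname(m$center))
})
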