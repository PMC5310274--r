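test_that("parameter counts match the closed-form gate bookkeeping", {
  expect_identical(count_parameters(rnn_spec("gru", 10)), 524L)
  expect_identical(count_parameters(rnn_spec("gru", 20)), 1644L)
  expect_identical(count_parameters(rnn_spec("lstm", 10)), 684L)
  expect_identical(count_parameters(rnn_spec("lstm", 20)), 2164L)
  expect_identical(count_parameters(rnn_spec("rnn", 10)), 194L)
  # and equal the number of scalar entries actually allocated
  for (ty in c("rnn", "gru", "lstm")) for (H in c(1L, 3L, 8L)) {
    spec <- rnn_spec(ty, H)
    p <- init_params(spec, seed = 1)
    expect_identical(rnnbias:::n_param_entries(p), count_parameters(spec))
  }
})

test_that("initialisation is seeded, bias-free and scale-controlled", {
  spec <- rnn_spec("lstm", 6)
  p1 <- init_params(spec, seed = 5)
  p2 <- init_params(spec, seed = 5)
  expect_identical(p1, p2)
  expect_false(identical(p1, init_params(spec, seed = 6)))
  expect_true(all(vapply(p1[c("bi", "bf", "di", "c")],
                         function(m) all(m == 0), TRUE)))
  p0 <- init_params(spec, seed = 1, init_scale = 0)
  expect_true(all(vapply(p0, function(m) all(m == 0), TRUE)))
})

test_that("cell_forward closed forms hold at zero parameters", {
  z4 <- rep(0, 4)
  rnn0 <- init_params(rnn_spec("rnn", 5), seed = 1, init_scale = 0)
  expect_equal(cell_forward(rnn0, z4, rep(0.3, 5)), rep(0, 5))
  gru0 <- init_params(rnn_spec("gru", 5), seed = 1, init_scale = 0)
  v <- c(0.4, -0.2, 0.1, 0.8, -0.5)
  expect_equal(cell_forward(gru0, z4, v), 0.5 * v)  # z = sigma(0) = 1/2
  lstm0 <- init_params(rnn_spec("lstm", 5), seed = 1, init_scale = 0)
  st <- cell_forward(lstm0, z4, NULL)
  expect_equal(st$h, rep(0, 5))
  expect_equal(st$c, rep(0, 5))
})

test_that("output distribution is a shifted-invariant softmax", {
  spec <- rnn_spec("rnn", 3)
  p <- init_params(spec, seed = 1, init_scale = 0)
  expect_equal(unname(output_distribution(p, rep(0, 3))), rep(0.25, 4))
  p$c <- matrix(c(log(2), 0, 0, 0))
  expect_equal(unname(output_distribution(p, rep(0, 3))),
               c(0.4, 0.2, 0.2, 0.2))
  p2 <- p
  p2$c <- p2$c + 3.7     # softmax shift invariance
  expect_equal(output_distribution(p, rep(0, 3)),
               output_distribution(p2, rep(0, 3)))
})

test_that("sequence probabilities factorise and normalise over all strings", {
  p0 <- init_params(rnn_spec("gru", 4), seed = 1, init_scale = 0)
  expect_equal(sequence_log_prob(p0, strrep("A", 21)), 21 * log(0.25))
  # single symbol = first-step output from the zero state
  p <- init_params(rnn_spec("lstm", 4), seed = 2, init_scale = 0.4)
  h1 <- cell_forward(p, rep(0, 4), NULL)
  expect_equal(sequence_log_prob(p, "G"),
               log(output_distribution(p, h1)[["G"]]))
  # enumeration oracle: total probability mass is 1 for L = 1, 2, 3
  for (ty in c("rnn", "gru", "lstm")) {
    pr <- init_params(rnn_spec(ty, 5), seed = 7, init_scale = 0.6)
    for (L in 1:3)
      expect_equal(sum(exp(sequence_log_probs(pr, enum_seqs(L)))), 1,
                   tolerance = 1e-10)
  }
})

test_that("perplexity has its closed-form limits and log-base consistency", {
  p0 <- init_params(rnn_spec("gru", 6), seed = 1, init_scale = 0)
  seqs <- rand_seqs(40, 21, seed = 8)
  expect_equal(perplexity(p0, seqs), 4, tolerance = 1e-12)
  # a model putting probability ~1/2 on A and C, evaluated on {A,C} strings
  p <- init_params(rnn_spec("rnn", 2), seed = 1, init_scale = 0)
  p$c <- matrix(c(0, 0, -50, -50))
  ac <- apply(matrix(sample(c("A", "C"), 30 * 7, replace = TRUE), 30, 7), 1,
              paste, collapse = "")
  expect_equal(perplexity(p, ac), 2, tolerance = 1e-9)
  # 2^(mean NLL / ln 2) equals the reported perplexity
  pr <- init_params(rnn_spec("lstm", 5), seed = 3, init_scale = 0.5)
  nll <- rnnbias:::mean_nll(pr, seqs)
  expect_equal(perplexity(pr, seqs), 2^(nll / log(2)), tolerance = 1e-12)
})

test_that("prediction error rate sits at chance for uniform data", {
  p0 <- init_params(rnn_spec("gru", 6), seed = 1, init_scale = 0)
  n <- 300L; L <- 21L
  seqs <- rand_seqs(n, L, seed = 12)
  err <- prediction_error_rate(p0, seqs)
  sigma <- sqrt(0.75 * 0.25 / (n * L))
  expect_lt(abs(err - 0.75), 3 * sigma)
  expect_error(prediction_error_rate(p0, character()), "non-empty")
  expect_error(perplexity(p0, character()), "non-empty")
})

test_that("models survive a lossless save/load round trip", {
  ds <- list(train = rand_seqs(60, 9, seed = 2),
             validation = rand_seqs(20, 9, seed = 3))
  m <- train_model(rnn_spec("gru", 4), ds, train_config(epochs = 2, seed = 4))
  path <- tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(m2$params, m$params)   # bit-identical parameters
  probe <- rand_seqs(5, 9, seed = 9)
  expect_identical(sequence_log_probs(m2, probe), sequence_log_probs(m, probe))
  expect_identical(m2$selected_epoch, m$selected_epoch)

  # tampered shape is rejected
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$params$V$dim <- c(2L, 8L)
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(obj, bad, digits = I(17), auto_unbox = TRUE)
  expect_error(load_model(bad), "shape")

  # parameters of one unit type cannot masquerade as another
  obj2 <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj2$spec$unit_type <- "lstm"
  bad2 <- tempfile(fileext = ".json")
  jsonlite::write_json(obj2, bad2, digits = I(17), auto_unbox = TRUE)
  expect_error(load_model(bad2), "does not match")
})
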