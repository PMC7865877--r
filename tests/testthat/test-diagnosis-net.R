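test_that("segmentation partitions the recording", {
  cfg <- network_config(segment_length = 1280)
  s1 <- segment_recording(numeric(2560), cfg)
  expect_equal(ncol(s1), 2)

  x <- rnorm(1300)
  expect_warning(s2 <- segment_recording(x[1:1000], cfg), "zero-padding")
  s3 <- segment_recording(x, cfg)
  expect_equal(ncol(s3), 2)
  expect_equal(sum(s3[, 2] == 0), 1260)
  # concatenating the unpadded parts restores the record
  expect_equal(as.numeric(s3)[seq_along(x)], x)
})

test_that("configuration contracts are enforced", {
  expect_error(network_config(segment_length = 1000), "divisible")
  expect_error(network_config(n_stages = 4), "32")
  expect_error(build_network(network_config(segment_length = 1300)), "divisible")
})

test_that("the built network has the stated architecture", {
  net <- build_network(test_net_config(), seed = 1)
  expect_s3_class(net, "ecg_network")
  expect_equal(count_conv_layers(net), 32)
  expect_length(net$params$stages, 8)
  for (s in net$params$stages) {
    expect_length(s$blocks, 2)
    for (b in s$blocks) {
      expect_equal(dim(b$conv1$W)[1], 16)
      expect_equal(dim(b$conv2$W)[1], 16)
    }
  }
  # filter doubling every two stages
  widths <- vapply(net$params$stages, function(s) dim(s$blocks[[1]]$conv1$W)[3],
                   numeric(1))
  expect_equal(widths, 4 * 2^((0:7) %/% 2))
  # parameter count is a frozen deterministic function of the config
  expect_equal(n_parameters(net), 166478)
  expect_equal(n_parameters(build_reverse_lead_network(test_net_config(1L), seed = 1)),
               166307)
})

test_that("untrained forward emits one probability per class in [0, 1]", {
  net <- build_network(test_net_config(), seed = 2)
  x <- syn_rec(duration = 4.096, seed = 1)$record$samples
  expect_warning(p <- predict_diagnosis(net, x), "not been trained")
  expect_length(p$probabilities, 20)
  expect_named(p$probabilities, diagnosis_items()$abbr)
  expect_true(all(p$probabilities >= 0 & p$probabilities <= 1))

  rl <- build_reverse_lead_network(test_net_config(1L), seed = 2)
  suppressWarnings(pr <- predict_diagnosis(rl, x))
  expect_length(pr$probabilities, 1)
  expect_true(pr$probabilities >= 0 && pr$probabilities <= 1)

  # doubling the recording length changes only the segment count, not arity
  x2 <- syn_rec(duration = 8.192, seed = 1)$record$samples
  suppressWarnings(p2 <- predict_diagnosis(net, x2))
  expect_length(p2$probabilities, 20)
})

test_that("training input contracts are enforced", {
  net <- build_reverse_lead_network(test_net_config(1L), seed = 1)
  x <- list(rnorm(512))
  expect_error(train_network(net, list(), matrix(0, 0, 1)), "empty")
  expect_error(train_network(net, x, matrix(0.5, 1, 1)), "0/1")
  expect_error(train_network(net, x, matrix(0, 1, 3)), "classes")
})

test_that("training is deterministic and overfits a tiny memorisable set", {
  xs <- lapply(1:8, function(i) {
    syn_rec(duration = 4.096, heart_rate = 75, seed = i,
            reversed = i %% 2 == 0)$record$samples
  })
  y <- matrix(as.numeric(seq_len(8) %% 2 == 0), 8, 1)
  cfg <- test_net_config(1L, dropout = 0)
  # overfit sanity (epoch budget scaled down; convergence target unchanged)
  net <- build_reverse_lead_network(cfg, seed = 1)
  net <- train_network(net, xs, y, epochs = 70, batch_size = 8, lr = 1e-2, seed = 2)
  expect_lt(tail(net$loss_trace, 1), 0.05)
  # loss is non-increasing (within tolerance) over the early epochs
  expect_true(all(diff(net$loss_trace[1:20]) < 1e-3))

  net2 <- build_reverse_lead_network(cfg, seed = 1)
  net2 <- train_network(net2, xs, y, epochs = 5, batch_size = 8, lr = 1e-2, seed = 2)
  net3 <- build_reverse_lead_network(cfg, seed = 1)
  net3 <- train_network(net3, xs, y, epochs = 5, batch_size = 8, lr = 1e-2, seed = 2)
  expect_identical(net2$loss_trace, net3$loss_trace)
})

test_that("a small net separates tachycardia from bradycardia rate classes", {
  items <- diagnosis_items()$abbr
  mk <- function(n, seed0) {
    lapply(seq_len(n), function(i) {
      tachy <- i %% 2 == 0
      lr <- syn_rec(duration = 4.096, seed = seed0 + i,
                    rhythm = if (tachy) "sinus_tachycardia" else "sinus_bradycardia")
      list(x = lr$record$samples,
           y = as.numeric(items == if (tachy) "SNT" else "SNB"),
           tachy = tachy)
    })
  }
  tr <- mk(60, 100)
  te <- mk(30, 7000)
  net <- build_network(test_net_config(), seed = 1)
  net <- train_network(net, lapply(tr, `[[`, "x"),
                       do.call(rbind, lapply(tr, `[[`, "y")),
                       epochs = 12, lr = 1e-2, seed = 2)
  preds <- lapply(te, function(e) predict_diagnosis(net, e$x))
  tachy <- vapply(te, `[[`, logical(1), "tachy")
  snt_calls <- vapply(preds, function(p) p$calls[["SNT"]], logical(1))
  expect_gte(mean(snt_calls[tachy]), 0.9)      # recall on held-out tachycardia
  expect_lte(mean(snt_calls[!tachy]), 0.1)     # and it is not called on brady
})

test_that("call threshold is inclusive at the boundary", {
  stub <- stub_model("AF")
  rec <- syn_rec(duration = 5, seed = 1)$record
  d <- ecgflow:::pipeline_predict(stub, rec, threshold = 1.0)
  expect_true(d$calls[["AF"]])       # probability 1.0 >= threshold 1.0
  expect_false(d$calls[["SN"]])
})

test_that("evaluate matches brute-force metrics and pairwise AUC", {
  # perfect classifier
  truth <- matrix(c(1, 0, 1, 0, 1, 0), 6, 2)
  m <- evaluate_diagnoses(truth, truth)
  expect_true(all(m$accuracy == 1 & m$precision == 1 & m$recall == 1 &
                  m$f1 == 1 & m$roc_auc == 1))

  # six-recording worked example against exhaustive pair counting
  probs <- matrix(c(0.9, 0.2, 0.8, 0.4, 0.6, 0.1), ncol = 1)
  y <- matrix(c(1, 0, 1, 0, 0, 1), ncol = 1)
  m2 <- evaluate_diagnoses(probs, y)
  expect_equal(m2$roc_auc, pairwise_auc(probs[, 1], y[, 1]))

  # random instances with <= 20 recordings: full metric agreement
  set.seed(31)
  for (k in 1:8) {
    n <- sample(4:20, 1)
    probs <- matrix(runif(n * 3), n, 3)
    y <- matrix(rbinom(n * 3, 1, 0.4), n, 3)
    m3 <- evaluate_diagnoses(probs, y)
    for (j in 1:3) {
      o <- brute_metrics(probs[, j], y[, j])
      expect_equal(m3$accuracy[j], o$accuracy)
      expect_equal(m3$precision[j], o$precision)
      expect_equal(m3$recall[j], o$recall)
      expect_equal(m3$f1[j], o$f1)
      expect_equal(m3$roc_auc[j], o$roc_auc)
    }
  }

  # label-independent scores give chance-level AUC
  set.seed(5)
  p <- runif(2000)
  y <- rbinom(2000, 1, 0.5)
  auc <- evaluate_diagnoses(matrix(p), matrix(y))$roc_auc
  expect_gte(auc, 0.45)
  expect_lte(auc, 0.55)

  # item with single-class truth: AUC absent
  m4 <- evaluate_diagnoses(matrix(runif(5)), matrix(rep(1, 5)))
  expect_true(is.na(m4$roc_auc))
})
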