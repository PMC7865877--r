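# Residual CNN + recurrent multilabel diagnosis network.  Architecture: the
# recording is split into fixed-length segments; each segment runs through 32
# one-dimensional convolutional layers (kernel 16) grouped into 8 stages of 4,
# every 2 layers residually connected, the first convolution of each stage
# (and a max-pool on the shortcut) halving the temporal length, the filter
# count doubling every 2 stages, with pre-activation batch norm / ReLU /
# dropout before each convolution.  After a global average over the remaining
# temporal samples, one GRU layer consumes the per-segment embedding sequence
# and a dense sigmoid head emits one probability per diagnostic item.

#' The 20 diagnostic items
#'
#' Abbreviations, full names, and group/subgroup of the 20 rhythm and
#' conduction items the diagnosis network scores.
#'
#' @return data.frame with columns `abbr`, `name`, `group`, `subgroup`.
#' @export
diagnosis_items <- function() {
  data.frame(
    abbr = c("SN", "SNA", "SNT", "SNB",
             "PVC", "PJC", "PAC", "VT", "SVT", "AFL", "AF", "WPW",
             "VE", "AE", "JE", "AVBI", "AVBII", "AVBIII", "LBBB", "RBBB"),
    name = c("Sinus Rhythm", "Sinus Arrhythmia", "Sinus Tachycardia",
             "Sinus Bradycardia", "Premature Ventricular Contraction",
             "Premature Junctional Contraction", "Premature Atrial Contraction",
             "Ventricular Tachycardia", "Supraventricular Tachycardia",
             "Atrial Flutter", "Atrial Fibrillation",
             "Wolff-Parkinson-White Syndrome", "Ventricular Escape",
             "Atrial Escape", "Junctional Escape",
             "First Degree Atrioventricular Block",
             "Second Degree Atrioventricular Block",
             "Third Degree Atrioventricular Block",
             "Left Bundle Branch Block", "Right Bundle Branch Block"),
    group = c("Sinus Rhythm", "Sinus Rhythm", "Sinus Rhythm", "Sinus Rhythm",
              rep("Tachyarrhythmia", 8), rep("Bradyarrhythmia", 8)),
    subgroup = c("Sinus Rhythm", rep("Sinus Abnormality", 3),
                 rep("Premature Beat", 3), rep("Tachycardia", 2),
                 rep("Flutter and Fibrillation", 2), "Pre-excitation",
                 rep("Escape Beat", 3), rep("Atrioventricular Block", 3),
                 rep("Intraventricular Block", 2)),
    stringsAsFactors = FALSE
  )
}

#' Network configuration
#'
#' @param n_stages number of stages (8); each stage holds `convs_per_stage`
#'   convolutional layers (4), i.e. two residual blocks of two convolutions.
#' @param convs_per_stage convolutions per stage (4).
#' @param kernel_size convolution kernel length (16).
#' @param base_filters channels of the first two stages; doubles every two
#'   stages thereafter.
#' @param segment_length samples per segment; must be divisible by
#'   `2^n_stages` because each stage halves the temporal length.
#' @param dropout_rate dropout before each convolution during training.
#' @param recurrent_hidden GRU hidden size.
#' @param n_classes output probabilities per recording (20 for diagnosis, 1
#'   for the reverse-lead detector).
#' @return list of class `network_config`.
#' @export
network_config <- function(n_stages = 8, convs_per_stage = 4, kernel_size = 16,
                           base_filters = 32, segment_length = 1280,
                           dropout_rate = 0.2, recurrent_hidden = 64,
                           n_classes = 20) {
  if (n_stages * convs_per_stage != 32) {
    stop("n_stages x convs_per_stage must equal 32", call. = FALSE)
  }
  if (segment_length %% (2^n_stages) != 0) {
    stop(sprintf("segment_length must be divisible by 2^%d = %d", n_stages,
                 2^n_stages), call. = FALSE)
  }
  structure(list(n_stages = n_stages, convs_per_stage = convs_per_stage,
                 kernel_size = kernel_size, base_filters = base_filters,
                 segment_length = as.integer(segment_length),
                 dropout_rate = dropout_rate,
                 recurrent_hidden = as.integer(recurrent_hidden),
                 n_classes = as.integer(n_classes)),
            class = "network_config")
}

#' Split a recording into fixed-length segments
#'
#' Consecutive non-overlapping segments of `segment_length` samples; a final
#' partial segment is zero-padded.  A recording shorter than one segment
#' yields a single zero-padded segment with a warning.
#'
#' @param record an [ecg_record()] or numeric vector.
#' @param config a [network_config()].
#' @return matrix (segment_length x n_segments), segments in order.
#' @export
segment_recording <- function(record, config) {
  x <- if (is_ecg_record(record)) record$samples else as.numeric(record)
  L <- config$segment_length
  n <- length(x)
  if (n < L) warning("recording shorter than one segment; zero-padding")
  n_seg <- max(1L, as.integer(ceiling(n / L)))
  out <- matrix(0, L, n_seg)
  for (s in seq_len(n_seg)) {
    i0 <- (s - 1L) * L + 1L
    i1 <- min(n, s * L)
    if (i0 <= n) out[seq_len(i1 - i0 + 1L), s] <- x[i0:i1]
  }
  out
}

stage_filters <- function(config) {
  config$base_filters * 2^((seq_len(config$n_stages) - 1L) %/% 2L)
}

new_bn <- function(C) {
  list(params = list(gamma = rep(1, C), beta = rep(0, C)),
       state = list(rm = rep(0, C), rv = rep(1, C)))
}

new_conv <- function(K, Cin, Cout) {
  sd <- sqrt(2 / (K * Cin))
  list(W = array(stats::rnorm(K * Cin * Cout, 0, sd), c(K, Cin, Cout)),
       b = rep(0, Cout))
}

#' Build the diagnosis network
#'
#' Instantiates the residual CNN-RNN described above with randomly
#' initialised weights (He initialisation for convolutions); deterministic
#' given `seed`.
#'
#' @param config a [network_config()].
#' @param seed integer seed for weight initialisation.
#' @return object of class `ecg_network`.
#' @export
build_network <- function(config = network_config(), seed = 1L) {
  with_seed(seed, {
    filters <- stage_filters(config)
    K <- config$kernel_size
    H <- config$recurrent_hidden
    params <- list(stages = vector("list", config$n_stages))
    state <- list(stages = vector("list", config$n_stages))
    c_in <- 1L
    for (s in seq_len(config$n_stages)) {
      c_out <- filters[s]
      blocks_p <- vector("list", 2)
      blocks_s <- vector("list", 2)
      for (b in 1:2) {
        stride <- if (b == 1L) 2L else 1L
        cin_b <- if (b == 1L) c_in else c_out
        bn1 <- new_bn(cin_b)
        bn2 <- new_bn(c_out)
        blocks_p[[b]] <- list(
          bn1 = bn1$params,
          conv1 = new_conv(K, cin_b, c_out),
          bn2 = bn2$params,
          conv2 = new_conv(K, c_out, c_out),
          proj = if (cin_b != c_out) new_conv(1L, cin_b, c_out) else NULL
        )
        blocks_s[[b]] <- list(bn1 = bn1$state, bn2 = bn2$state)
      }
      params$stages[[s]] <- list(blocks = blocks_p)
      state$stages[[s]] <- list(blocks = blocks_s)
      c_in <- c_out
    }
    c_fin <- filters[config$n_stages]
    fb <- new_bn(c_fin)
    params$final_bn <- fb$params
    state$final_bn <- fb$state
    u <- 1 / sqrt(H)
    gmat <- function(r, c) matrix(stats::runif(r * c, -u, u), r, c)
    params$gru <- list(Wz = gmat(H, c_fin), Uz = gmat(H, H), bz = rep(0, H),
                       Wr = gmat(H, c_fin), Ur = gmat(H, H), br = rep(0, H),
                       Wn = gmat(H, c_fin), Un = gmat(H, H), bn = rep(0, H))
    params$dense <- list(W = matrix(stats::rnorm(config$n_classes * H, 0, 0.01),
                                    config$n_classes, H),
                         b = rep(0, config$n_classes))
    structure(list(config = config, params = params, state = state,
                   trained = FALSE, seed = as.integer(seed)),
              class = "ecg_network")
  })
}

#' Build the reverse-lead detector network
#'
#' Same architecture as the diagnosis network with a single sigmoid output:
#' 1 = electrode polarity reversed, 0 = correct.
#'
#' @inheritParams build_network
#' @export
build_reverse_lead_network <- function(config = network_config(n_classes = 1),
                                       seed = 1L) {
  config$n_classes <- 1L
  build_network(config, seed)
}

#' @export
print.ecg_network <- function(x, ...) {
  cat(sprintf("<ecg_network> %d stages x %d convs (kernel %d), %s -> %d classes\n",
              x$config$n_stages, x$config$convs_per_stage, x$config$kernel_size,
              paste(stage_filters(x$config), collapse = "/"), x$config$n_classes))
  cat(sprintf("  segment_length %d, GRU hidden %d, %s, %d parameters\n",
              x$config$segment_length, x$config$recurrent_hidden,
              if (x$trained) "trained" else "untrained", n_parameters(x)))
  invisible(x)
}

#' Number of main-path convolutional layers
#' @param net an `ecg_network`.
#' @export
count_conv_layers <- function(net) {
  n <- 0L
  for (s in net$params$stages) for (b in s$blocks) n <- n + 2L
  n
}

#' Total trainable parameter count
#' @param net an `ecg_network`.
#' @export
n_parameters <- function(net) {
  tot <- 0L
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else tot <<- tot + length(x)
    invisible(NULL)
  }
  walk(net$params)
  tot
}

# forward through one residual block; returns out, cache, updated state
block_fw <- function(A, bp, bs, stride, train, dropout) {
  f1 <- bn_fw(A, bp$bn1$gamma, bp$bn1$beta, bs$bn1, train)
  r1 <- relu_fw(f1$out)
  d1 <- dropout_fw(r1$out, dropout, train)
  c1 <- conv1d_fw(d1$out, bp$conv1$W, bp$conv1$b, stride)
  f2 <- bn_fw(c1$out, bp$bn2$gamma, bp$bn2$beta, bs$bn2, train)
  r2 <- relu_fw(f2$out)
  d2 <- dropout_fw(r2$out, dropout, train)
  c2 <- conv1d_fw(d2$out, bp$conv2$W, bp$conv2$b, 1L)
  sc <- A
  mp <- NULL
  if (stride == 2L) {
    mpf <- maxpool2_fw(sc)
    sc <- mpf$out
    mp <- mpf$cache
  }
  pj <- NULL
  if (!is.null(bp$proj)) {
    pjf <- conv1d_fw(sc, bp$proj$W, bp$proj$b, 1L)
    sc <- pjf$out
    pj <- pjf$cache
  }
  list(out = c2$out + sc,
       state = list(bn1 = f1$state, bn2 = f2$state),
       cache = list(f1 = f1$cache, r1 = r1$cache, d1 = d1$cache, c1 = c1$cache,
                    f2 = f2$cache, r2 = r2$cache, d2 = d2$cache, c2 = c2$cache,
                    mp = mp, pj = pj, stride = stride))
}

block_bw <- function(dY, bp, cache) {
  # shortcut branch
  dsc <- dY
  gproj <- NULL
  if (!is.null(cache$pj)) {
    pb <- conv1d_bw(dsc, cache$pj)
    gproj <- list(W = pb$dW, b = pb$db)
    dsc <- pb$dA
  }
  if (!is.null(cache$mp)) dsc <- maxpool2_bw(dsc, cache$mp)
  # main branch
  b2 <- conv1d_bw(dY, cache$c2)
  dd2 <- dropout_bw(b2$dA, cache$d2)
  dr2 <- relu_bw(dd2, cache$r2)
  bb2 <- bn_bw(dr2, cache$f2)
  b1 <- conv1d_bw(bb2$dA, cache$c1)
  dd1 <- dropout_bw(b1$dA, cache$d1)
  dr1 <- relu_bw(dd1, cache$r1)
  bb1 <- bn_bw(dr1, cache$f1)
  grads <- list(bn1 = list(gamma = bb1$dgamma, beta = bb1$dbeta),
                conv1 = list(W = b1$dW, b = b1$db),
                bn2 = list(gamma = bb2$dgamma, beta = bb2$dbeta),
                conv2 = list(W = b2$dW, b = b2$db),
                proj = gproj)
  list(dA = bb1$dA + dsc, grads = grads)
}

# full forward: X (L, 1, N) with N = S segments x R records, segment index
# fastest.  Returns probabilities (n_classes, R).
net_forward <- function(net, X, S, R, train = FALSE) {
  cfg <- net$config
  caches <- list(stages = vector("list", cfg$n_stages))
  state <- net$state
  A <- X
  for (s in seq_len(cfg$n_stages)) {
    bl <- vector("list", 2)
    for (b in 1:2) {
      stride <- if (b == 1L) 2L else 1L
      r <- block_fw(A, net$params$stages[[s]]$blocks[[b]],
                    state$stages[[s]]$blocks[[b]], stride, train,
                    cfg$dropout_rate)
      A <- r$out
      state$stages[[s]]$blocks[[b]] <- r$state
      bl[[b]] <- r$cache
    }
    caches$stages[[s]] <- bl
  }
  fbn <- bn_fw(A, net$params$final_bn$gamma, net$params$final_bn$beta,
               state$final_bn, train)
  state$final_bn <- fbn$state
  frl <- relu_fw(fbn$out)
  g <- gap_fw(frl$out)                       # vector over (C, N)
  E <- g$out
  dim(E) <- c(length(E) / (S * R), S, R)
  gr <- gru_fw(E, net$params$gru)
  h <- gr$out                                # (H, R)
  logits <- net$params$dense$W %*% h + net$params$dense$b
  probs <- sigmoid(logits)
  list(probs = probs, state = state,
       caches = list(stages = caches$stages, fbn = fbn$cache, frl = frl$cache,
                     gap = g$cache, gru = gr$cache, h = h, S = S, R = R))
}

# backward from dlogits; returns gradient tree matching net$params
net_backward <- function(net, caches, dlogits) {
  cfg <- net$config
  gdense <- list(W = tcrossprod(dlogits, caches$h), b = rowSums(dlogits))
  dh <- crossprod(net$params$dense$W, dlogits)
  gb <- gru_bw(dh, caches$gru)
  dE <- gb$dX
  dim(dE) <- c(dim(dE)[1], caches$S * caches$R)
  dA <- gap_bw(dE, caches$gap)
  dA <- relu_bw(dA, caches$frl)
  fb <- bn_bw(dA, caches$fbn)
  dA <- fb$dA
  gstages <- vector("list", cfg$n_stages)
  for (s in rev(seq_len(cfg$n_stages))) {
    gbl <- vector("list", 2)
    for (b in 2:1) {
      r <- block_bw(dA, net$params$stages[[s]]$blocks[[b]],
                    caches$stages[[s]][[b]])
      dA <- r$dA
      gbl[[b]] <- r$grads
    }
    gstages[[s]] <- list(blocks = gbl)
  }
  list(stages = gstages,
       final_bn = list(gamma = fb$dgamma, beta = fb$dbeta),
       gru = gb$grads, dense = gdense)
}

# assemble a batch of recordings (list of sample vectors) into the (L, 1, N)
# input tensor; all recordings must yield the same number of segments
batch_tensor <- function(xs, config) {
  segs <- lapply(xs, segment_recording, config = config)
  S <- unique(vapply(segs, ncol, integer(1)))
  if (length(S) != 1L) {
    stop("recordings in one batch must have equal segment counts", call. = FALSE)
  }
  X <- array(unlist(segs), c(config$segment_length, 1L, S * length(xs)))
  list(X = X, S = S, R = length(xs))
}

#' Train a diagnosis (or reverse-lead) network
#'
#' Minimises the mean per-class binary cross-entropy with Adam.  Training is
#' deterministic given `seed` (weight initialisation is part of the network;
#' shuffling and dropout draw from the seeded stream).
#'
#' @param net an `ecg_network` from [build_network()].
#' @param x list of recordings (numeric vectors or [ecg_record()]s), all of
#'   equal duration.
#' @param y label matrix (n_recordings x n_classes) of 0/1, or a vector for
#'   single-output networks; columns must follow [diagnosis_items()] order
#'   for 20-class networks.
#' @param epochs,batch_size,lr training schedule.
#' @param seed integer; drives shuffling and dropout.
#' @param verbose print the per-epoch loss.
#' @return the trained network, with the per-epoch mean loss in `$loss_trace`.
#' @export
train_network <- function(net, x, y, epochs = 10, batch_size = 16, lr = 1e-3,
                          seed = 1L, verbose = FALSE) {
  if (length(x) == 0L) stop("empty training set", call. = FALSE)
  y <- as.matrix(y)
  if (ncol(y) == 1L && net$config$n_classes > 1L) {
    stop("label matrix must have one column per class", call. = FALSE)
  }
  if (nrow(y) != length(x)) stop("x and y sizes differ", call. = FALSE)
  if (ncol(y) != net$config$n_classes) {
    stop("label matrix has wrong number of classes", call. = FALSE)
  }
  if (any(!y %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  xs <- lapply(x, function(e) if (is_ecg_record(e)) e$samples else as.numeric(e))
  # prior-probability bias initialisation: start each class head at the logit
  # of its base rate so rare/constant classes exert no gradient pressure on
  # the shared trunk (otherwise the recurrent state saturates early)
  if (!isTRUE(net$trained)) {
    net$params$dense$b <- stats::qlogis(pmin(pmax(colMeans(y), 1e-3), 1 - 1e-3))
  }
  with_seed(seed, {
    opt <- adam_init(net$params)
    n <- length(xs)
    trace <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (i0 in seq(1, n, by = batch_size)) {
        idx <- ord[i0:min(n, i0 + batch_size - 1L)]
        bt <- batch_tensor(xs[idx], net$config)
        fw <- net_forward(net, bt$X, bt$S, bt$R, train = TRUE)
        net$state <- fw$state
        yb <- t(y[idx, , drop = FALSE])            # (n_classes, R)
        p <- pmin(pmax(fw$probs, 1e-12), 1 - 1e-12)
        loss <- -mean(yb * log(p) + (1 - yb) * log(1 - p))
        losses <- c(losses, loss)
        dlogits <- (fw$probs - yb) / length(yb)
        grads <- net_backward(net, fw$caches, dlogits)
        upd <- adam_step(net$params, grads, opt, lr = lr)
        net$params <- upd$params
        opt <- upd$state
      }
      trace[ep] <- mean(losses)
      if (verbose) message(sprintf("epoch %d/%d loss %.5f", ep, epochs, trace[ep]))
    }
    net$trained <- TRUE
    net$loss_trace <- trace
    net
  })
}

#' Predict diagnosis probabilities for one recording
#'
#' @param net a (preferably trained) `ecg_network`.
#' @param record an [ecg_record()] or numeric vector.
#' @param threshold call threshold; probabilities at or above it are called
#'   positive.
#' @return list of class `diagnosis_result`: `probabilities` and `calls`
#'   (named by item for 20-class networks), `threshold`.
#' @export
predict_diagnosis <- function(net, record, threshold = 0.5) {
  if (!isTRUE(net$trained)) {
    warning("network has not been trained; probabilities are from random weights")
  }
  xs <- if (is_ecg_record(record)) record$samples else as.numeric(record)
  bt <- batch_tensor(list(xs), net$config)
  p <- as.numeric(net_forward(net, bt$X, bt$S, bt$R, train = FALSE)$probs)
  if (net$config$n_classes == 20L) names(p) <- diagnosis_items()$abbr
  structure(list(probabilities = p, calls = p >= threshold,
                 threshold = threshold),
            class = "diagnosis_result")
}

#' @export
print.diagnosis_result <- function(x, ...) {
  pos <- names(x$calls)[x$calls]
  if (is.null(pos)) pos <- as.character(which(x$calls))
  cat("<diagnosis_result> called:",
      if (length(pos)) paste(pos, collapse = ", ") else "(none)", "\n")
  invisible(x)
}
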