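#' Configure a sleep-scoring network
#'
#' Builds the configuration for the three-branch convolutional feature
#' extractor and its scoring head.  The extractor runs two branches over the
#' raw EEG epoch -- a narrow-filter branch tuned to high-frequency content
#' and a wide-filter branch tuned to low-frequency content -- and one
#' wide-filter branch over the RMS-filtered EMG epoch.  The `full` variant
#' scores each epoch from a context window of consecutive epochs with a
#' two-layer bidirectional LSTM plus an FC shortcut on the target epoch,
#' combined by element-wise addition before a 3-way softmax.  The
#' `pretrain_head` variant replaces the scoring head with a per-epoch
#' softmax; the `rescoring` variant keeps the FC path and softmax but omits
#' the recurrent block entirely, so it judges each epoch in isolation.
#'
#' `scale` multiplies all width hyperparameters (channel counts, LSTM units,
#' FC units) relative to the full-size network (1024 LSTM units per layer,
#' half per direction, and a 1024-unit FC layer); `scale = 1/8` gives a
#' desk-sized model trainable on a laptop CPU.  Branch filter geometry
#' defaults follow the published deep human-sleep scorer that inspired the
#' architecture: narrow first-layer filters of half a second with stride
#' rate/16, wide filters of four seconds with stride rate/2.  Every number
#' can be overridden.
#'
#' @param sampling_rate Samples per second (Hz).
#' @param epoch_length Epoch duration in seconds.
#' @param context Number of consecutive epochs the full scoring head reads
#'   (odd; the scored epoch sits at the center).
#' @param scale Width multiplier (1 = full published size).
#' @param lstm_units Total LSTM units per layer (split across the two
#'   directions); default `round(1024 * scale)` rounded to an even number.
#' @param fc_units Units in the fully-connected shortcut layer; default
#'   `round(1024 * scale)`.
#' @param ch1,ch2 Channels after the first and after the later convolution
#'   blocks; defaults `64 * scale` and `128 * scale`.
#' @param dropout_rate Dropout probability used during training (0 disables).
#' @param variant One of `"full"`, `"pretrain_head"`, `"rescoring"`.
#' @param narrow_geom,wide_geom Optional lists overriding branch geometry:
#'   `k1` (first filter length), `s1` (its stride), `p1` (first pooling
#'   width), `k2` (later filter length), `p2` (final pooling width).
#' @param normalize Z-score EEG and RMS-EMG per record before the network.
#' @param rms_mode Moving-RMS flavour used in preprocessing; see
#'   [moving_rms()].
#' @return A `sleep_model_config` object.
#' @seealso [sleep_model()], [preprocess_record()]
#' @export
sleep_model_config <- function(sampling_rate = 250, epoch_length = 20,
                               context = 25, scale = 1, lstm_units = NULL,
                               fc_units = NULL, ch1 = NULL, ch2 = NULL,
                               dropout_rate = 0.5,
                               variant = c("full", "pretrain_head", "rescoring"),
                               narrow_geom = NULL, wide_geom = NULL,
                               normalize = TRUE,
                               rms_mode = c("paper", "standard")) {
  variant <- match.arg(variant)
  rms_mode <- match.arg(rms_mode)
  stopifnot(sampling_rate >= 2, epoch_length > 0, scale > 0,
            context >= 1, context %% 2 == 1,
            dropout_rate >= 0, dropout_rate < 1)
  rate <- as.integer(sampling_rate)
  samples <- as.integer(round(rate * epoch_length))

  lstm_units <- lstm_units %||% max(2L, 2L * round(1024 * scale / 2))
  if (lstm_units %% 2 != 0) {
    abort("lstm_units must be even (units are split across directions)")
  }
  fc_units <- fc_units %||% max(1L, round(1024 * scale))
  ch1 <- ch1 %||% max(1L, round(64 * scale))
  ch2 <- ch2 %||% max(1L, round(128 * scale))

  nar <- modifyList(list(k1 = max(2L, round(rate / 2)),
                         s1 = max(1L, rate %/% 16L),
                         p1 = 8L, k2 = 8L, p2 = 4L),
                    narrow_geom %||% list())
  wid <- modifyList(list(k1 = as.integer(min(4L * rate, samples)),
                         s1 = max(1L, rate %/% 2L),
                         p1 = 4L, k2 = 6L, p2 = 2L),
                    wide_geom %||% list())

  check_geom <- function(g, name) {
    if (g$k1 > samples) {
      abort(sprintf("%s branch filter (k1 = %d) longer than epoch (%d samples)",
                    name, g$k1, samples))
    }
    l1 <- (samples - g$k1) %/% g$s1 + 1L
    lp1 <- l1 %/% g$p1
    lp2 <- lp1 %/% g$p2
    if (lp2 < 1L) {
      abort(sprintf("%s branch collapses to zero length; reduce pooling", name))
    }
    lp2
  }
  out_nar <- check_geom(nar, "narrow")
  out_wid <- check_geom(wid, "wide")
  feature_dim <- as.integer(ch2 * out_nar + 2L * ch2 * out_wid)

  structure(list(
    sampling_rate = rate, epoch_length = epoch_length, context = as.integer(context),
    scale = scale, samples_per_epoch = samples,
    lstm_units = as.integer(lstm_units), lstm_per_dir = as.integer(lstm_units / 2L),
    fc_units = as.integer(fc_units), ch1 = as.integer(ch1), ch2 = as.integer(ch2),
    n_classes = 3L, dropout_rate = dropout_rate, variant = variant,
    narrow_geom = lapply(nar, as.integer), wide_geom = lapply(wid, as.integer),
    feature_dim = feature_dim, normalize = normalize, rms_mode = rms_mode
  ), class = "sleep_model_config")
}

#' @export
print.sleep_model_config <- function(x, ...) {
  cat(sprintf(
    "<sleep_model_config> variant=%s  %d Hz x %gs epochs, context %d\n",
    x$variant, x$sampling_rate, x$epoch_length, x$context))
  cat(sprintf("  scale %.4g: ch1=%d ch2=%d, lstm %d (%d/dir), fc %d, feature dim %d\n",
              x$scale, x$ch1, x$ch2, x$lstm_units, x$lstm_per_dir,
              x$fc_units, x$feature_dim))
  invisible(x)
}

# Uniform fan-in initialization: W ~ U(-sqrt(1/fan_in), +sqrt(1/fan_in)).
# LSTM forget-gate biases start at 1 (standard remedy for early vanishing
# memory); all other biases start at 0.
init_params <- function(config, seed) {
  set.seed(seed)
  uinit <- function(nr, nc, fan_in = nc) {
    s <- sqrt(1 / fan_in)
    matrix(runif(nr * nc, -s, s), nr, nc)
  }
  zerob <- function(n) matrix(0, n, 1)
  g <- function(geom) geom
  p <- list()
  branch <- function(prefix, geom) {
    k1 <- geom$k1; k2 <- geom$k2
    p[[paste0(prefix, "_W1")]] <<- uinit(config$ch1, k1)
    p[[paste0(prefix, "_b1")]] <<- zerob(config$ch1)
    p[[paste0(prefix, "_W2a")]] <<- uinit(config$ch2, config$ch1 * k2)
    p[[paste0(prefix, "_b2a")]] <<- zerob(config$ch2)
    p[[paste0(prefix, "_W2b")]] <<- uinit(config$ch2, config$ch2 * k2)
    p[[paste0(prefix, "_b2b")]] <<- zerob(config$ch2)
    p[[paste0(prefix, "_W2c")]] <<- uinit(config$ch2, config$ch2 * k2)
    p[[paste0(prefix, "_b2c")]] <<- zerob(config$ch2)
  }
  branch("nar", config$narrow_geom)
  branch("wid", config$wide_geom)
  branch("emg", config$wide_geom)

  fd <- config$feature_dim
  h <- config$lstm_per_dir
  if (config$variant == "pretrain_head") {
    p$head_Wp <- uinit(config$n_classes, fd)
    p$head_bp <- zerob(config$n_classes)
  } else {
    p$fc_W <- uinit(config$fc_units, fd)
    p$fc_b <- zerob(config$fc_units)
    p$out_W <- uinit(config$n_classes, config$fc_units)
    p$out_b <- zerob(config$n_classes)
  }
  if (config$variant == "full") {
    lstm <- function(name, input_dim) {
      p[[paste0(name, "_W")]] <<- uinit(4 * h, input_dim)
      p[[paste0(name, "_U")]] <<- uinit(4 * h, h)
      b <- zerob(4 * h)
      b[(h + 1):(2 * h), 1] <- 1  # forget gate
      p[[paste0(name, "_b")]] <<- b
    }
    lstm("lstm1f", fd); lstm("lstm1b", fd)
    lstm("lstm2f", 2 * h); lstm("lstm2b", 2 * h)
    p$proj_W <- uinit(config$fc_units, 2 * h)
    p$proj_b <- zerob(config$fc_units)
  }
  p
}

#' Create a sleep-scoring model
#'
#' Instantiates the network described by a [sleep_model_config()] with
#' seeded random initial weights.
#'
#' @param config A `sleep_model_config`.
#' @param seed Integer seed for weight initialization.
#' @return A `sleep_model` object (untrained).
#' @examples
#' cfg <- sleep_model_config(sampling_rate = 50, epoch_length = 2, scale = 1 / 32)
#' m <- sleep_model(cfg, seed = 1)
#' @export
sleep_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sleep_model_config"))
  structure(list(config = config, params = init_params(config, seed),
                 trained = FALSE, history = NULL),
            class = "sleep_model")
}

#' @export
print.sleep_model <- function(x, ...) {
  cat(sprintf("<sleep_model> variant=%s, %s, %d parameters\n",
              x$config$variant, if (x$trained) "trained" else "untrained",
              n_parameters(x)))
  invisible(x)
}

#' Total number of trainable parameters
#' @param model A `sleep_model`.
#' @return Integer count of scalar parameters.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' Does the model contain recurrent (LSTM) parameters?
#' @param model A `sleep_model`.
#' @return `TRUE` if any LSTM weight matrices are present.
#' @export
has_recurrent_parameters <- function(model) {
  any(grepl("^lstm", names(model$params)))
}

# config in the exact shape the compiled engine expects
cfg_cpp <- function(config, dropout = NULL) {
  list(samples_per_epoch = config$samples_per_epoch,
       ch1 = config$ch1, ch2 = config$ch2,
       narrow_geom = config$narrow_geom, wide_geom = config$wide_geom,
       lstm_per_dir = config$lstm_per_dir, fc_units = config$fc_units,
       n_classes = config$n_classes,
       dropout_rate = dropout %||% config$dropout_rate)
}

softmax_cols_r <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# CNN features for a preprocessed epoch set (columns = epochs)
model_features <- function(model, epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (!isTRUE(epochs$preprocessed)) {
    abort("epochs must come from preprocess_record()")
  }
  if (nrow(epochs$eeg) != model$config$samples_per_epoch) {
    abort(sprintf(
      "epoch length mismatch: model expects %d samples per epoch, got %d",
      model$config$samples_per_epoch, nrow(epochs$eeg)))
  }
  cpp_extract_features(epochs$eeg, epochs$emg, model$params, cfg_cpp(model$config))
}

head_probs <- function(model, feat) {
  cfg <- model$config
  if (cfg$variant == "pretrain_head") {
    softmax_cols_r(model$params$head_Wp %*% feat +
                     as.vector(model$params$head_bp))
  } else if (cfg$variant == "rescoring") {
    q <- pmax(model$params$fc_W %*% feat + as.vector(model$params$fc_b), 0)
    softmax_cols_r(model$params$out_W %*% q + as.vector(model$params$out_b))
  } else {
    abort("full variant needs context windows; use predict()")
  }
}

prediction_tibble <- function(epoch_index, probs) {
  stage <- apply(probs, 2, which.max)  # first max: WAKE < NREM < REM tie order
  tibble(epoch = as.integer(epoch_index),
         p_wake = probs[1, ], p_nrem = probs[2, ], p_rem = probs[3, ],
         stage = stage_factor(stage))
}

#' Score epochs with a sleep-scoring model
#'
#' For the `full` variant, slides a context window across the preprocessed
#' epochs and scores the center epoch of each window; the first and last
#' `(context - 1) / 2` epochs of the record cannot be centered and are
#' reported as unscored (they are absent from the result; the total epoch
#' count is carried in the `n_epochs` attribute).  The `pretrain_head` and
#' `rescoring` variants score every epoch independently.
#'
#' Inference is deterministic: dropout is disabled.
#'
#' @param object A `sleep_model`.
#' @param epochs An `epoch_set` from [preprocess_record()].
#' @param ... Unused.
#' @return A tibble with columns `epoch` (0-based index into the record),
#'   `p_wake`, `p_nrem`, `p_rem` (softmax certainties) and `stage` (argmax
#'   label, ties broken WAKE < NREM < REM).
#' @export
predict.sleep_model <- function(object, epochs, ...) {
  cfg <- object$config
  feat <- model_features(object, epochs)
  n <- ncol(feat)
  if (cfg$variant %in% c("pretrain_head", "rescoring")) {
    probs <- head_probs(object, feat)
    out <- prediction_tibble(seq_len(n) - 1L, probs)
  } else {
    half <- cfg$context %/% 2
    if (n < cfg$context) {
      warn(sprintf("record has %d epochs but the context window needs %d; nothing scored",
                   n, cfg$context))
      out <- prediction_tibble(integer(0), matrix(numeric(0), 3, 0))
    } else {
      starts <- seq_len(n - cfg$context + 1L)
      probs <- cpp_predict_full(feat, starts, cfg$context, object$params,
                                cfg_cpp(cfg, dropout = 0))
      out <- prediction_tibble(starts - 1L + half, probs)
    }
  }
  attr(out, "n_epochs") <- n
  attr(out, "record_id") <- epochs$record_id
  class(out) <- c("stage_prediction", class(out))
  out
}

MODEL_FILE_VERSION <- 1L

#' Save / load a sleep-scoring model
#'
#' The on-disk file is a single RDS container embedding the format version,
#' the full [sleep_model_config()] and all weights, so a load reproduces
#' predictions bit-identically.
#'
#' @param model A `sleep_model`.
#' @param path File path.
#' @return `load_model()` returns the `sleep_model`; `save_model()` its path,
#'   invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "sleep_model"))
  saveRDS(list(format = "sleepscorer_model", version = MODEL_FILE_VERSION,
               config = model$config, params = model$params,
               trained = model$trained, history = model$history),
          path, version = 3)
  invisible(path)
}

#' @rdname save_model
#' @param expect_variant If given, loading a model of any other variant is an
#'   error (guards against e.g. using a rescoring model as the main scorer).
#' @export
load_model <- function(path, expect_variant = NULL) {
  obj <- readRDS(path)
  if (!identical(obj$format, "sleepscorer_model")) {
    abort("not a sleepscorer model file")
  }
  if (obj$version > MODEL_FILE_VERSION) {
    abort(sprintf("model file version %d is newer than supported (%d)",
                  obj$version, MODEL_FILE_VERSION))
  }
  if (!is.null(expect_variant) && !identical(obj$config$variant, expect_variant)) {
    abort(sprintf("model variant mismatch: file contains '%s', expected '%s'",
                  obj$config$variant, expect_variant))
  }
  structure(list(config = obj$config, params = obj$params,
                 trained = obj$trained, history = obj$history),
            class = "sleep_model")
}

#' @export
tidy.sleep_model <- function(x, ...) {
  tibble(term = names(x$params),
         rows = vapply(x$params, nrow, integer(1)),
         cols = vapply(x$params, ncol, integer(1)),
         n = vapply(x$params, length, integer(1)))
}

#' @export
glance.sleep_model <- function(x, ...) {
  tibble(variant = x$config$variant, scale = x$config$scale,
         n_parameters = n_parameters(x), trained = x$trained,
         sampling_rate = x$config$sampling_rate,
         epoch_length = x$config$epoch_length, context = x$config$context)
}
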