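#' Build an untrained denoiser
#'
#' Constructs the per-image encoder-decoder. Each encoder level applies a
#' 3x3 convolution, spatial batch normalization and ReLU, then halves the
#' spatial size with 2x2 max pooling while doubling the channel count; the
#' decoder mirrors this with nearest-neighbour upsampling, convolution, and
#' concatenation of the matching encoder features (skip connections); a
#' final 1x1 convolution with a sigmoid produces the output, so every
#' output pixel lies strictly inside (0, 1). Weight initialization is
#' He-normal and fully determined by \code{seed}.
#'
#' @param inputShape integer length-2 (height, width); both must be at least
#'   \code{2^depth}. Inputs whose sides are not multiples of \code{2^depth}
#'   are mirror-padded internally and cropped back.
#' @param depth number of pooling levels (default 3).
#' @param baseChannels feature maps at the first level (default 32).
#' @param seed integer weight-initialization seed.
#' @return an untrained \linkS4class{DenoiserModel}.
#' @examples
#' m <- buildDenoiser(c(64, 64), seed = 1)
#' nParameters(m)
#' @export
buildDenoiser <- function(inputShape, depth = 3L, baseChannels = 32L, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  inputShape <- as.integer(inputShape)
  depth <- as.integer(depth); baseChannels <- as.integer(baseChannels)
  if (length(inputShape) != 2L || any(!is.finite(inputShape)))
    stop("inputShape must be (height, width)", call. = FALSE)
  if (any(inputShape < 2^depth))
    .stopf("input %d x %d is smaller than 2^depth = %d in at least one axis",
           inputShape[1], inputShape[2], 2^depth)
  w <- .net_init(depth, baseChannels, as.integer(seed))
  new("DenoiserModel", weights = w, depth = depth,
      baseChannels = baseChannels, inputShape = inputShape,
      seed = as.integer(seed), trained = FALSE)
}

#' @rdname DenoiserModel-class
#' @export
setMethod("modelWeights", "DenoiserModel", function(object) object@weights)

#' @rdname DenoiserModel-class
#' @export
setMethod("modelDepth", "DenoiserModel", function(object) object@depth)

#' @rdname DenoiserModel-class
#' @export
setMethod("baseChannels", "DenoiserModel", function(object) object@baseChannels)

#' @rdname DenoiserModel-class
#' @export
setMethod("nParameters", "DenoiserModel", function(object) {
  w <- object@weights
  keep <- !grepl("\\.(rmean|rvar)$", names(w))
  sum(vapply(w[keep], length, integer(1)))
})

setMethod("show", "DenoiserModel", function(object) {
  cat(sprintf("DenoiserModel depth = %d, base channels = %d\n",
              object@depth, object@baseChannels))
  cat(sprintf("  built for %d x %d, %s, %d trainable parameters\n",
              object@inputShape[1], object@inputShape[2],
              if (object@trained) "trained" else "untrained",
              nParameters(object)))
})

#' Training objective
#'
#' The regularized noise-to-noise loss:
#' \deqn{L = \mathrm{mean}((p - t)^2) +
#'       \lambda\, \mathrm{mean}(|\partial_x p| + |\partial_y p|)}
#' with forward finite differences and edge replication (the difference
#' across the last row/column is zero). The first term is the data term,
#' the second an anisotropic total-variation penalty controlling smoothness.
#'
#' @param prediction,target numeric matrices (or
#'   \linkS4class{MicroscopyImage}s) of one shape.
#' @param lambdaReg smoothness weight \eqn{\lambda \ge 0}.
#' @return named list with \code{total}, \code{mse} and \code{reg};
#'   \code{total = mse + lambdaReg * reg}.
#' @examples
#' p <- matrix(0.5, 8, 8)
#' denoiserLoss(p, p + 0.1, lambdaReg = 0)$total  # 0.01
#' @export
denoiserLoss <- function(prediction, target, lambdaReg = 0) {
  p <- .as_pixels(prediction); t <- .as_pixels(target)
  if (!identical(dim(p), dim(t)))
    .stopf("prediction (%d x %d) and target (%d x %d) shapes differ",
           nrow(p), ncol(p), nrow(t), ncol(t))
  if (lambdaReg < 0) stop("lambdaReg must be >= 0", call. = FALSE)
  mse <- mean((p - t)^2)
  dx <- cbind(p[, -1, drop = FALSE] - p[, -ncol(p), drop = FALSE], 0)
  dy <- rbind(p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE], 0)
  reg <- mean(abs(dx) + abs(dy))
  list(total = mse + lambdaReg * reg, mse = mse, reg = reg)
}

#' Train the denoiser on a single frame
#'
#' Zero-shot training: the model learns to predict rendition B from
#' rendition A of a median-pre-filtered \linkS4class{NoisePair} built from
#' the frame itself — no clean reference and no external dataset. One Adam
#' step is taken per epoch (the training set is the single pair, batch size
#' 1). Both renditions are clamped to \eqn{[0, 1]} before entering the
#' sigmoid-output network. All randomness is fixed by the configuration
#' seed, so two runs with one configuration produce identical weights and
#' identical loss traces.
#'
#' With \code{dataTarget = "raw"} the data term is anchored to the raw frame
#' instead of rendition B (\code{raw} must then be supplied), an alternative
#' reading of the objective in which the network reconstructs the input
#' image directly.
#'
#' @param pair a \linkS4class{NoisePair}, normally after [medianPrefilter()].
#' @param config a \linkS4class{TrainingConfig}.
#' @param raw optional normalized \linkS4class{MicroscopyImage}; required
#'   target when \code{config@dataTarget == "raw"}.
#' @param depth,baseChannels architecture of the model to build; see
#'   [buildDenoiser()].
#' @return list with elements \code{model} (a trained
#'   \linkS4class{DenoiserModel}) and \code{history} (a
#'   \linkS4class{TrainingHistory}); with \code{epochs = 0} the initialized
#'   model is returned with empty traces.
#' @export
trainZeroShot <- function(pair, config = TrainingConfig(), raw = NULL,
                          depth = 3L, baseChannels = 32L) {
  stopifnot(is(pair, "NoisePair"), is(config, "TrainingConfig"))
  validObject(config)
  if (!isFiltered(pair))
    warning("training on an unfiltered pair; medianPrefilter is the ",
            "intended pre-processing", call. = FALSE)
  if (config@batchSize != 1L)
    warning("the training set is a single image pair; batchSize ",
            config@batchSize, " behaves as 1", call. = FALSE)
  A <- pmin(pmax(pairA(pair)@pixels, 0), 1)
  Btarget <- if (config@dataTarget == "raw") {
    if (is.null(raw))
      stop("dataTarget = 'raw' needs the raw frame", call. = FALSE)
    .as_pixels(raw)
  } else pmin(pmax(pairB(pair)@pixels, 0), 1)

  model <- buildDenoiser(dim(A), depth = depth, baseChannels = baseChannels,
                         seed = config@seed)
  .train_model(model, A, Btarget, config)
}

# shared trainer used by trainZeroShot and the pipeline (which may override
# architecture hyperparameters)
.train_model <- function(model, A, Btarget, config) {
  if (config@epochs == 0L) {
    hist <- new("TrainingHistory", loss = numeric(0), mse = numeric(0),
                reg = numeric(0), lambdaReg = config@lambdaReg)
    return(list(model = model, history = hist))
  }
  m <- 2^model@depth
  pa <- .pad_to_multiple(A, m)
  pb <- .pad_to_multiple(Btarget, m)
  out <- .net_train(model@weights, pa$pixels, pb$pixels,
                    as.integer(config@epochs), config@learningRate,
                    config@lambdaReg, model@depth, model@baseChannels)
  trained <- initialize(model, weights = out$weights, trained = TRUE)
  hist <- new("TrainingHistory", loss = out$loss, mse = out$mse,
              reg = out$reg, lambdaReg = config@lambdaReg)
  list(model = trained, history = hist)
}

#' @rdname TrainingConfig-class
#' @param learningRate,epochs,batchSize,lambdaReg,seed,dataTarget see the
#'   class slots.
#' @export
TrainingConfig <- function(learningRate = 0.001, epochs = 100L,
                           batchSize = 1L, lambdaReg = 0, seed = 1L,
                           dataTarget = c("pair", "raw")) {
  new("TrainingConfig", learningRate = learningRate,
      epochs = as.integer(epochs), batchSize = as.integer(batchSize),
      lambdaReg = lambdaReg, seed = as.integer(seed),
      dataTarget = match.arg(dataTarget))
}

setMethod("show", "TrainingConfig", function(object) {
  cat(sprintf(paste0("TrainingConfig: Adam, lr = %g, epochs = %d, batch = %d,",
                     " lambda = %g, seed = %d, target = %s\n"),
              object@learningRate, object@epochs, object@batchSize,
              object@lambdaReg, object@seed, object@dataTarget))
})

#' @rdname TrainingHistory-class
#' @export
setMethod("lossTrace", "TrainingHistory", function(object) {
  data.frame(epoch = seq_along(object@loss), loss = object@loss,
             mse = object@mse, reg = object@reg)
})

setMethod("show", "TrainingHistory", function(object) {
  n <- length(object@loss)
  if (n == 0) cat("TrainingHistory: empty (no epochs run)\n")
  else cat(sprintf("TrainingHistory: %d epochs, loss %.3g -> %.3g\n",
                   n, object@loss[1], object@loss[n]))
})

#' @rdname denoise
#' @details Inference runs the network in evaluation mode: batch
#'   normalization uses the running statistics accumulated during training,
#'   so the output is deterministic and independent of any batch context.
#'   Inputs whose sides are not multiples of \code{2^depth} are
#'   mirror-padded, denoised, and cropped back. The input is clamped to
#'   \eqn{[0, 1]} before the forward pass.
#' @export
setMethod("denoise", "DenoiserModel", function(model, img) {
  p <- .as_pixels(img)
  if (any(dim(p) < 2^model@depth))
    .stopf("input %d x %d is too small for a depth-%d model (needs >= %d)",
           nrow(p), ncol(p), model@depth, 2^model@depth)
  p <- pmin(pmax(p, 0), 1)
  pad <- .pad_to_multiple(p, 2^model@depth)
  out <- .net_predict(model@weights, pad$pixels, model@depth,
                      model@baseChannels)
  out <- out[seq_len(pad$h), seq_len(pad$w), drop = FALSE]
  if (is(img, "MicroscopyImage"))
    new("MicroscopyImage", pixels = out, sourceDtype = img@sourceDtype,
        sourceRange = img@sourceRange, normalized = TRUE)
  else
    MicroscopyImage(out, sourceRange = c(0, 1), normalized = TRUE)
})

#' Save / load a trained denoiser
#'
#' The checkpoint is a directory holding the flat parameter arrays in a
#' binary blob (little-endian doubles) plus a JSON sidecar with the
#' architecture hyperparameters, so a checkpoint fully reconstructs the
#' model.
#'
#' @param model a \linkS4class{DenoiserModel}.
#' @param path checkpoint directory (created if needed).
#' @return \code{saveDenoiser}: \code{path}, invisibly;
#'   \code{loadDenoiser}: the restored \linkS4class{DenoiserModel}.
#' @export
saveDenoiser <- function(model, path) {
  stopifnot(is(model, "DenoiserModel"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  w <- model@weights
  meta <- list(
    depth = model@depth, baseChannels = model@baseChannels,
    inputShape = model@inputShape, seed = model@seed,
    trained = model@trained,
    tensors = lapply(w, function(x) {
      d <- dim(x); if (is.null(d)) d <- length(x); as.integer(d)
    })
  )
  jsonlite::write_json(meta, file.path(path, "architecture.json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(file.path(path, "weights.bin"), "wb")
  on.exit(close(con))
  for (x in w) writeBin(as.numeric(x), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname saveDenoiser
#' @export
loadDenoiser <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "architecture.json"),
                              simplifyVector = TRUE)
  con <- file(file.path(path, "weights.bin"), "rb")
  on.exit(close(con))
  w <- lapply(meta$tensors, function(d) {
    d <- as.integer(d)
    v <- readBin(con, "numeric", n = prod(d), size = 8L, endian = "little")
    if (length(d) > 1L) dim(v) <- d
    v
  })
  new("DenoiserModel", weights = w, depth = as.integer(meta$depth),
      baseChannels = as.integer(meta$baseChannels),
      inputShape = as.integer(meta$inputShape),
      seed = as.integer(meta$seed), trained = isTRUE(meta$trained))
}
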