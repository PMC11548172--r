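#' Simulate a phantom benchmark pair
#'
#' Writes \code{clean.tif} (ground truth), \code{noisy.tif} (corrupted
#' observation) and \code{spec.json} (the full generating specification,
#' which round-trips through [readSpecJSON()]) into \code{outDir}.
#'
#' @param outDir output directory, created if needed.
#' @param phantom a \linkS4class{PhantomSpec}.
#' @param noise a \linkS4class{NoiseSpec}.
#' @return named character vector of the artifact paths, invisibly.
#' @export
runSimulate <- function(outDir, phantom = PhantomSpec(),
                        noise = NoiseSpec()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  clean <- makePhantom(phantom)
  noisy <- corruptImage(clean, noise)
  paths <- c(clean = file.path(outDir, "clean.tif"),
             noisy = file.path(outDir, "noisy.tif"),
             spec = file.path(outDir, "spec.json"))
  writeFrame(clean, paths[["clean"]], dtype = "float")
  writeFrame(noisy, paths[["noisy"]], dtype = "float")
  writeSpecJSON(phantom, noise, paths[["spec"]])
  invisible(paths)
}

#' Run the full zero-shot denoising pipeline on one frame
#'
#' Executes read, normalize, pair generation, median pre-filtering,
#' zero-shot training, inference, quality metrics and post-processing, and
#' writes six artifacts into \code{outDir}: \code{denoised.tif},
#' \code{postprocessed.tif}, \code{metrics.json}, \code{frc.csv},
#' \code{history.csv} and \code{config.json}. Metrics are computed on the
#' pre-post-processing output; when \code{reference} is given they are
#' evaluated against that clean frame (\code{"reference"} regime),
#' otherwise against the raw input (\code{"reference-free"}). Any stage
#' failure aborts with the stage name and removes partial outputs. Two runs
#' with the same configuration and seed produce bit-identical artifacts.
#'
#' @param input path to a TIFF frame, or a \linkS4class{MicroscopyImage}.
#' @param outDir output directory.
#' @param reference optional path to (or frame of) clean ground truth.
#' @param noiseSigma pair-generation noise level (chosen default 0.05;
#'   the source recipe does not state it).
#' @param medianKernel pre-/post-filter kernel size (3 in the source
#'   recipe).
#' @param epochs,learningRate,batchSize,lambdaReg,dataTarget training
#'   settings, see \linkS4class{TrainingConfig}; defaults follow the
#'   published recipe (100 / 0.001 / 1) with \code{lambdaReg = 0}.
#' @param depth,baseChannels architecture, see [buildDenoiser()].
#' @param seed global seed: the pair uses \code{seed}, weight
#'   initialization \code{seed + 1}.
#' @param frcThreshold FRC cutoff criterion.
#' @param inferenceInput \code{"filtered"} (default) applies the trained
#'   network to the median-filtered normalized frame — the domain it was
#'   trained on; \code{"raw"} applies it to the unfiltered frame.
#' @param roi apply ROI masking during post-processing?
#' @param roiThreshold optional fixed ROI threshold; \code{NULL} (default)
#'   derives the threshold with Otsu's criterion.
#' @param pLow,pHigh contrast-stretch percentiles.
#' @param edges also write \code{edges.tif} (Canny map, 8-bit)?
#' @param edgeLow,edgeHigh Canny hysteresis thresholds.
#' @param modality free-text label recorded in \code{config.json}.
#' @return named character vector of artifact paths, invisibly.
#' @export
runDenoise <- function(input, outDir, reference = NULL,
                       noiseSigma = 0.05, medianKernel = 3L,
                       epochs = 100L, learningRate = 0.001,
                       batchSize = 1L, lambdaReg = 0,
                       dataTarget = "pair", depth = 3L,
                       baseChannels = 32L, seed = 1L,
                       frcThreshold = 1 / 7,
                       inferenceInput = c("filtered", "raw"),
                       roi = TRUE, roiThreshold = NULL, pLow = 1, pHigh = 99,
                       edges = FALSE, edgeLow = 0.1, edgeHigh = 0.3,
                       modality = "") {
  inferenceInput <- match.arg(inferenceInput)
  seed <- as.integer(seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  raw <- stage("read", {
    img <- if (is.character(input)) readFrame(input) else input
    stopifnot(is(img, "MicroscopyImage"))
    img
  })
  norm <- stage("normalize", .as_normalized(raw))
  ref <- if (!is.null(reference)) stage("read-reference", {
    r <- if (is.character(reference)) readFrame(reference) else reference
    .as_normalized(r)
  })
  pair <- stage("make-pair", makeNoisePair(norm, sigma = noiseSigma,
                                           seed = seed))
  pair <- stage("median-prefilter", medianPrefilter(pair, medianKernel))
  cfg <- TrainingConfig(learningRate = learningRate, epochs = epochs,
                        batchSize = batchSize, lambdaReg = lambdaReg,
                        seed = seed + 1L, dataTarget = dataTarget)
  fit <- stage("train", trainZeroShot(pair, cfg, raw = norm,
                                      depth = depth,
                                      baseChannels = baseChannels))
  infIn <- if (inferenceInput == "raw") norm
  else MicroscopyImage(medianFilter2D(norm, medianKernel),
                       sourceRange = c(0, 1), normalized = TRUE)
  den <- stage("denoise", denoise(fit$model, infIn))
  rep <- stage("report", qualityReport(norm, den, reference = ref,
                                       withFrc = TRUE,
                                       frcThreshold = frcThreshold))
  post <- stage("postprocess", {
    m <- if (roi) tryCatch(
      if (is.null(roiThreshold)) roiMask(den)
      else roiMask(den, method = "fixed", threshold = roiThreshold),
      error = function(e) NULL) else NULL
    applyPostprocessing(den, mask = m, pLow = pLow, pHigh = pHigh,
                        kernel = medianKernel)
  })
  edgeMap <- if (edges) stage("edges", cannyEdges(post, edgeLow, edgeHigh))

  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(denoised = file.path(outDir, "denoised.tif"),
             postprocessed = file.path(outDir, "postprocessed.tif"),
             metrics = file.path(outDir, "metrics.json"),
             frc = file.path(outDir, "frc.csv"),
             history = file.path(outDir, "history.csv"),
             config = file.path(outDir, "config.json"))
  if (edges) paths[["edges"]] <- file.path(outDir, "edges.tif")
  stage("write", {
    on_fail <- function(e) { unlink(paths); stop(e) }
    tryCatch({
      writeFrame(den, paths[["denoised"]], dtype = "float")
      writeFrame(post, paths[["postprocessed"]], dtype = "float")
      jsonlite::write_json(reportMetrics(rep), paths[["metrics"]],
                           auto_unbox = TRUE, digits = NA)
      utils::write.csv(as.data.frame(rep@frc), paths[["frc"]],
                       row.names = FALSE)
      utils::write.csv(lossTrace(fit$history), paths[["history"]],
                       row.names = FALSE)
      cfgOut <- list(
        package = "ZSDenoise",
        version = as.character(utils::packageVersion("ZSDenoise")),
        input = if (is.character(input)) input else "<in-memory frame>",
        reference = if (is.character(reference)) reference
          else if (is.null(reference)) NULL else "<in-memory frame>",
        noise_sigma = noiseSigma, median_kernel = medianKernel,
        epochs = epochs, learning_rate = learningRate,
        batch_size = batchSize, lambda_reg = lambdaReg,
        data_target = dataTarget, depth = depth,
        base_channels = baseChannels, seed = seed,
        frc_threshold = frcThreshold, inference_input = inferenceInput,
        roi = roi, roi_threshold = roiThreshold,
        stretch_percentiles = c(pLow, pHigh),
        edges = edges, modality = modality,
        source_dtype = sourceDtype(raw),
        source_range = sourceRange(raw))
      jsonlite::write_json(cfgOut, paths[["config"]], auto_unbox = TRUE,
                           digits = NA, null = "null")
      if (edges)
        writeFrame(matrix(as.numeric(edgeMap), nrow(edgeMap),
                          ncol(edgeMap)),
                   paths[["edges"]], dtype = "uint8")
    }, error = on_fail)
  })
  invisible(paths)
}

#' Standalone metric computation between two frames
#'
#' Reads two frames of one shape, brings each onto the normalized scale
#' (float data already in \eqn{[0, 1]} pass through unchanged; integer data
#' are min-max normalized), and writes
#' \code{metrics.json} (and \code{frc.csv} when \code{withFrc}) without any
#' training. The first image plays the raw/reference role the report is
#' computed against.
#'
#' @param imageA,imageB TIFF paths or \linkS4class{MicroscopyImage}s; B is
#'   compared against A.
#' @param outDir output directory.
#' @param withFrc also compute and write the FRC curve?
#' @param frcThreshold cutoff criterion.
#' @param peak PSNR peak.
#' @return named character vector of artifact paths, invisibly.
#' @export
runEvaluate <- function(imageA, imageB, outDir, withFrc = FALSE,
                        frcThreshold = 1 / 7, peak = 1.0) {
  get <- function(x) {
    img <- if (is.character(x)) readFrame(x) else x
    .as_normalized(img)
  }
  a <- get(imageA); b <- get(imageB)
  rep <- qualityReport(a, b, reference = NULL, peak = peak,
                       withFrc = withFrc, frcThreshold = frcThreshold)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(metrics = file.path(outDir, "metrics.json"))
  jsonlite::write_json(reportMetrics(rep), paths[["metrics"]],
                       auto_unbox = TRUE, digits = NA)
  if (withFrc) {
    paths[["frc"]] <- file.path(outDir, "frc.csv")
    utils::write.csv(as.data.frame(rep@frc), paths[["frc"]],
                     row.names = FALSE)
  }
  invisible(paths)
}
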