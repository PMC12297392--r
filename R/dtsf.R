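#' Run one ThyroFEN extractor on an image
#'
#' A ThyroFEN unit is a single feature-extraction/segmentation network
#' producing a per-pixel thyroid probability map. The output carries
#' provenance: the extractor id and a digest of the network parameters, so
#' ensemble manifests can identify which weights produced which map.
#'
#' @param img image matrix matching the network input size.
#' @param net a `tnet` or `tnet_fit`.
#' @param id optional extractor id (defaults to the parameter digest).
#' @return list of class `thyrofen_output` with `prob_map`,
#'   `extractor_id`, `params_digest`.
#' @export
thyrofen_extract <- function(img, net, id = NULL) {
  if (inherits(net, "tnet_fit")) net <- net$net
  dg <- params_digest(net)
  structure(list(prob_map = predict(net, img),
                 extractor_id = id %||% dg,
                 params_digest = dg),
            class = "thyrofen_output")
}

params_digest <- function(net) {
  h <- 0
  for (nm in sort(ls(net$params)))
    for (a in net$params[[nm]])
      h <- (h * 31 + sum(abs(a)) %% 1e6) %% 1e9
  sprintf("%.0f", h * 1e6 %% 1e9)
}

#' Normalize raw ensemble weights
#'
#' @param raw non-negative weights, at least one positive.
#' @return numeric vector of class `dtsf_weights` summing to 1.
#' @export
normalize_weights <- function(raw) {
  if (any(raw < 0)) stop("weights must be non-negative")
  s <- sum(raw)
  if (s <= 0) stop("at least one weight must be positive")
  structure(raw / s, class = "dtsf_weights")
}

#' DTSF weighted combination of extractor outputs
#'
#' Pixelwise convex combination `sum_i w_i * map_i` of the probability maps;
#' with normalized weights the result stays within the pixelwise envelope
#' of the inputs.
#'
#' @param outputs list of `thyrofen_output` objects (or plain probability
#'   matrices).
#' @param weights a [normalize_weights()] vector of matching length.
#' @return combined probability matrix.
#' @export
dtsf_combine <- function(outputs, weights) {
  maps <- lapply(outputs, function(o)
    if (inherits(o, "thyrofen_output")) o$prob_map else
      unclass_mat(as.matrix(o)))
  if (length(maps) != length(weights))
    stop("need one weight per extractor output")
  for (m in maps[-1]) check_same_shape(maps[[1]], m)
  out <- 0
  for (i in seq_along(maps)) out <- out + weights[i] * maps[[i]]
  unclass(out)
}

#' Fit ensemble weights from validation performance
#'
#' Weights are a softmax over per-extractor mean validation Dice
#' (threshold 0.5), `w_i = softmax(tau * Dice_i)`: monotone in extractor
#' quality, uniform when extractors tie, and concentrating on the best
#' extractor as `tau` grows.
#'
#' @param outputs_per_image list over extractors; each element a list of
#'   probability maps (one per validation image, same order as `truths`).
#' @param truths list of binary masks.
#' @param tau softmax temperature (default 10).
#' @return `dtsf_weights` with attribute `dice` (per-extractor mean Dice).
#' @export
fit_ensemble_weights <- function(outputs_per_image, truths, tau = 10) {
  if (!length(truths)) stop("empty validation set")
  dice <- vapply(outputs_per_image, function(maps) {
    if (length(maps) != length(truths))
      stop("each extractor needs one map per validation image")
    mean(mapply(function(p, g) evaluate(p, g)$dice, maps, truths))
  }, 0)
  z <- exp(tau * (dice - max(dice)))
  w <- normalize_weights(z)
  attr(w, "dice") <- dice
  w
}

#' Ensemble manifest I/O
#'
#' The manifest records extractor ids/digests, fitted weights and the
#' softmax temperature as JSON.
#'
#' @param weights a `dtsf_weights` vector.
#' @param extractors character ids (e.g. parameter digests).
#' @param path output JSON path.
#' @param tau temperature used to fit the weights.
#' @return path, invisibly.
#' @export
write_ensemble_manifest <- function(weights, extractors, path, tau = 10) {
  jsonlite::write_json(list(extractors = extractors,
                            weights = as.numeric(weights), tau = tau),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
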