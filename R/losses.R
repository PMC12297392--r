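#' Soft set cardinalities between a probability map and a binary mask
#'
#' For a pixelwise prediction `p` in `[0,1]` and ground truth `g` in `{0,1}`
#' the soft cardinalities are `|P^G| = sum(p*g)`, `|P-G| = sum(p*(1-g))`,
#' `|G-P| = sum((1-p)*g)`, `|P| = sum(p)` and `|G| = sum(g)`. The identity
#' `|P| = |P^G| + |P-G|` holds exactly.
#'
#' @param p numeric matrix of probabilities in `[0, 1]`.
#' @param g binary matrix of the same shape.
#' @return list with `inter`, `p_minus_g`, `g_minus_p`, `size_p`, `size_g`.
#' @export
soft_cardinalities <- function(p, g) {
  check_same_shape(p, g)
  p <- unclass_mat(as.matrix(p)); g <- unclass_mat(as.matrix(g))
  if (min(p) < 0 || max(p) > 1) stop("probabilities must lie in [0, 1]")
  if (!all(g %in% c(0, 1))) stop("ground truth must be binary")
  list(inter = sum(p * g),
       p_minus_g = sum(p * (1 - g)),
       g_minus_p = sum((1 - p) * g),
       size_p = sum(p),
       size_g = sum(g))
}

#' Tversky index
#'
#' `TI = (|P^G| + eps) / (|P^G| + alpha*|P-G| + beta*|G-P| + eps)`.
#' `alpha` weights false positives, `beta` false negatives; with
#' `alpha = beta = 0.5` the index equals the Dice coefficient identically.
#'
#' @inheritParams soft_cardinalities
#' @param alpha,beta positive asymmetry weights.
#' @param epsilon smoothing constant (default 1e-6).
#' @return scalar in `(0, 1]`.
#' @export
tversky_index <- function(p, g, alpha = 0.7, beta = 0.3, epsilon = 1e-6) {
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be > 0")
  s <- soft_cardinalities(p, g)
  (s$inter + epsilon) /
    (s$inter + alpha * s$p_minus_g + beta * s$g_minus_p + epsilon)
}

#' Dice coefficient (soft)
#'
#' `(2|P^G| + eps) / (|P| + |G| + eps)`; when both masks are empty the
#' smoothed ratio returns 1 by convention.
#'
#' @inheritParams tversky_index
#' @return scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(p, g, epsilon = 1e-6) {
  s <- soft_cardinalities(p, g)
  (2 * s$inter + epsilon) / (s$size_p + s$size_g + epsilon)
}

#' Loss parameter set for the Banerjee compound loss
#'
#' The three mixture weights default to the published 0.23 / 0.65 / 0.12
#' split; the Tversky asymmetry defaults to `alpha = 0.7`, `beta = 0.3`
#' (false-negative weighted, appropriate for small lesions) and the focal
#' exponent to `gamma = 0.75`.
#'
#' @param w_tversky,w_dice,w_focal non-negative mixture weights.
#' @param alpha,beta Tversky asymmetry weights (> 0).
#' @param gamma focal exponent (> 0).
#' @param epsilon ratio smoothing (> 0).
#' @return list of class `tatha_loss_params`.
#' @export
loss_params <- function(w_tversky = 0.23, w_dice = 0.65, w_focal = 0.12,
                        alpha = 0.7, beta = 0.3, gamma = 0.75,
                        epsilon = 1e-6) {
  if (any(c(w_tversky, w_dice, w_focal) < 0)) stop("weights must be >= 0")
  if (alpha <= 0 || beta <= 0) stop("alpha, beta must be > 0")
  if (gamma <= 0) stop("gamma must be > 0")
  if (epsilon <= 0) stop("epsilon must be > 0")
  structure(list(w_tversky = w_tversky, w_dice = w_dice, w_focal = w_focal,
                 alpha = alpha, beta = beta, gamma = gamma,
                 epsilon = epsilon),
            class = "tatha_loss_params")
}

#' Banerjee compound segmentation loss
#'
#' `L = w_t * (1 - TI) + w_d * (1 - Dice) + w_f * (1 - TI)^gamma` with the
#' default weights (0.23, 0.65, 0.12). The loss is 0 when prediction and
#' truth coincide and tends to `w_t + w_d + w_f` (1 with defaults) for
#' disjoint non-empty masks as `epsilon -> 0`. It is differentiable in `p`
#' on the open unit interval.
#'
#' @inheritParams soft_cardinalities
#' @param params a [loss_params()] list.
#' @return scalar loss value.
#' @seealso [banerjee_loss_grad()] for the analytic pixelwise gradient.
#' @export
banerjee_loss <- function(p, g, params = loss_params()) {
  ti <- tversky_index(p, g, params$alpha, params$beta, params$epsilon)
  dc <- dice_coefficient(p, g, params$epsilon)
  params$w_tversky * (1 - ti) + params$w_dice * (1 - dc) +
    params$w_focal * (1 - ti)^params$gamma
}

#' Analytic gradient of the Banerjee loss with respect to the prediction
#'
#' Returns `dL/dp` as a matrix of the prediction's shape; used by the
#' training loop (chained through the sigmoid head).
#'
#' @inheritParams banerjee_loss
#' @return list with `loss` (scalar) and `grad` (matrix `dL/dp`).
#' @export
banerjee_loss_grad <- function(p, g, params = loss_params()) {
  check_same_shape(p, g)
  p <- unclass_mat(as.matrix(p)); g <- unclass_mat(as.matrix(g))
  eps <- params$epsilon
  inter <- sum(p * g)
  pmg <- sum(p * (1 - g))
  gmp <- sum((1 - p) * g)
  dt <- inter + params$alpha * pmg + params$beta * gmp + eps
  ti <- (inter + eps) / dt
  sp <- sum(p); sg <- sum(g)
  dd <- sp + sg + eps
  dc <- (2 * inter + eps) / dd
  # dTI/dp = [g*dt - (inter+eps)*(g + alpha*(1-g) - beta*g)] / dt^2
  dti <- (g * dt - (inter + eps) * (g + params$alpha * (1 - g) -
                                      params$beta * g)) / dt^2
  ddc <- (2 * g * dd - (2 * inter + eps)) / dd^2
  fgrad <- if (params$gamma == 1) dti else
    params$gamma * (1 - ti)^(params$gamma - 1) * dti
  loss <- params$w_tversky * (1 - ti) + params$w_dice * (1 - dc) +
    params$w_focal * (1 - ti)^params$gamma
  grad <- -params$w_tversky * dti - params$w_dice * ddc -
    params$w_focal * fgrad
  list(loss = loss, grad = grad)
}
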