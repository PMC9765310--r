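# All training objectives as pure, individually testable functions.
# Convention for adversarial terms: discriminator outputs a patch grid of
# probabilities; domain label 1 means "source/new-source", 0 means
# "enhanced/target".  Batches are lists of prediction maps; the
# discriminator is applied inside the loss so each operation mirrors its
# defining equation.

EPS_CLAMP <- 1e-7

clamp01 <- function(p) pmin(pmax(p, EPS_CLAMP), 1 - EPS_CLAMP)

#' Binary cross-entropy of a probability grid against a domain label
#'
#' Mean over the grid of `-(y log p + (1 - y) log(1 - p))`.  Probabilities
#' at exactly 0 or 1 are clamped by `1e-7` so the loss stays finite.
#'
#' @param p array/matrix of probabilities in `(0, 1)`.
#' @param label scalar 0 or 1 (or an array of per-entry labels).
#' @return nonnegative scalar.
#' @export
bce <- function(p, label) {
  p <- clamp01(p)
  mean(-(label * log(p) + (1 - label) * log(1 - p)))
}

#' Multi-label mask segmentation loss
#'
#' Mean binary cross-entropy over all pixels of both structure channels
#' (disc and cup are scored as independent labels so both can be positive
#' at one pixel — the cup is always inside the disc).
#'
#' @param p_m `H x W x 2` predicted probabilities.
#' @param y_m `H x W x 2` binary ground truth.
#' @return nonnegative scalar.
#' @export
mask_loss <- function(p_m, y_m) {
  if (!all(dim(p_m) == dim(y_m))) stop("mask_loss: shape mismatch",
                                       call. = FALSE)
  bce_elementwise(p_m, y_m)
}

bce_elementwise <- function(p, y) {
  p <- clamp01(p)
  mean(-(y * log(p) + (1 - y) * log(1 - p)))
}

#' Boundary regression loss
#'
#' Mean squared error between predicted and reference soft boundary maps.
#'
#' @param p_b,y_b `H x W x 2` real arrays in `[0, 1]`.
#' @return nonnegative scalar.
#' @export
boundary_loss <- function(p_b, y_b) {
  if (!all(dim(p_b) == dim(y_b))) stop("boundary_loss: shape mismatch",
                                       call. = FALSE)
  mean((y_b - p_b)^2)
}

disc_apply_batch <- function(disc, batch) {
  lapply(batch, function(x) discriminator_forward(disc, x)$probs)
}

#' Discriminator objective: source vs enhanced boundaries
#'
#' `(1/N) [sum LD(D(p_b_source), 1) + sum LD(D(p_b_enhanced), 0)]` with `N`
#' the per-domain batch size (source and enhanced images are generated 1:1).
#'
#' @param disc a patch discriminator, see [build_discriminator()].
#' @param p_b_source,p_b_enhanced nonempty lists of boundary prediction maps.
#' @return nonnegative scalar.
#' @export
disc_loss_b_plus <- function(disc, p_b_source, p_b_enhanced) {
  stopifnot(length(p_b_source) >= 1, length(p_b_enhanced) >= 1)
  n <- length(p_b_source)
  (sum(vapply(disc_apply_batch(disc, p_b_source), bce, numeric(1), label = 1)) +
   sum(vapply(disc_apply_batch(disc, p_b_enhanced), bce, numeric(1),
              label = 0))) / n
}

#' Adversarial objective pushing enhanced boundaries toward the source
#'
#' @param disc the source-vs-enhanced boundary discriminator.
#' @param p_b_enhanced nonempty list of enhanced-domain boundary predictions.
#' @return mean of `LD(D(p), 1)` over the batch.
#' @export
adv_loss_b_plus <- function(disc, p_b_enhanced) {
  stopifnot(length(p_b_enhanced) >= 1)
  mean(vapply(disc_apply_batch(disc, p_b_enhanced), bce, numeric(1),
              label = 1))
}

#' Discriminator objective: new-source vs target boundaries
#'
#' Each domain term is normalized by its own batch size (`N_U` new-source
#' images, `N_T` target images).
#'
#' @param disc the new-source-vs-target boundary discriminator.
#' @param p_b_new_source,p_b_target nonempty lists of boundary predictions.
#' @return nonnegative scalar.
#' @export
disc_loss_b <- function(disc, p_b_new_source, p_b_target) {
  stopifnot(length(p_b_new_source) >= 1, length(p_b_target) >= 1)
  mean(vapply(disc_apply_batch(disc, p_b_new_source), bce, numeric(1),
              label = 1)) +
    mean(vapply(disc_apply_batch(disc, p_b_target), bce, numeric(1),
                label = 0))
}

#' Adversarial objective pushing target boundaries toward the new source
#'
#' @param disc the new-source-vs-target boundary discriminator.
#' @param p_b_target nonempty list of target-domain boundary predictions.
#' @return mean of `LD(D(p), 1)` over the batch.
#' @export
adv_loss_b <- function(disc, p_b_target) {
  stopifnot(length(p_b_target) >= 1)
  mean(vapply(disc_apply_batch(disc, p_b_target), bce, numeric(1), label = 1))
}

#' Discriminator objective: new-source vs target masks
#'
#' @param disc the mask discriminator.
#' @param p_m_new_source,p_m_target nonempty lists of mask probability maps.
#' @return nonnegative scalar.
#' @export
disc_loss_m <- function(disc, p_m_new_source, p_m_target) {
  stopifnot(length(p_m_new_source) >= 1, length(p_m_target) >= 1)
  mean(vapply(disc_apply_batch(disc, p_m_new_source), bce, numeric(1),
              label = 1)) +
    mean(vapply(disc_apply_batch(disc, p_m_target), bce, numeric(1),
                label = 0))
}

#' Adversarial objective pushing target masks toward the new source
#'
#' @param disc the mask discriminator.
#' @param p_m_target nonempty list of target-domain mask probability maps.
#' @return mean of `LD(D(p), 1)` over the batch.
#' @export
adv_loss_m <- function(disc, p_m_target) {
  stopifnot(length(p_m_target) >= 1)
  mean(vapply(disc_apply_batch(disc, p_m_target), bce, numeric(1), label = 1))
}

#' Assemble the total segmentation objective
#'
#' Combines the supervised terms with the weighted adversarial sum:
#' `L_adv = L_adv_m + L_adv_b + L_adv_b_plus` and
#' `L_total = L_m + L_b + lambda_adv * L_adv`.
#'
#' @param L_m,L_b supervised mask and boundary losses.
#' @param L_adv_m,L_adv_b,L_adv_b_plus adversarial components (before
#'   weighting); use 0 for disabled branches.
#' @param lambda_adv adversarial weight.
#' @return a `loss_report` list holding every component and the totals.
#' @export
total_loss <- function(L_m, L_b, L_adv_m = 0, L_adv_b = 0, L_adv_b_plus = 0,
                       lambda_adv = 0.01) {
  comps <- c(L_m = L_m, L_b = L_b, L_adv_m = L_adv_m, L_adv_b = L_adv_b,
             L_adv_b_plus = L_adv_b_plus)
  bad <- names(comps)[!is.finite(comps)]
  if (length(bad)) {
    stop("total_loss: non-finite component(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  L_adv <- L_adv_m + L_adv_b + L_adv_b_plus
  structure(list(L_m = L_m, L_b = L_b, L_adv_m = L_adv_m, L_adv_b = L_adv_b,
                 L_adv_b_plus = L_adv_b_plus, L_adv = L_adv,
                 lambda_adv = lambda_adv,
                 L_total = L_m + L_b + lambda_adv * L_adv),
            class = "loss_report")
}
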