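# Least-squares adversarial, cycle-consistency, and identity losses, and
# their weighted total. All losses average (rather than sum) over pixels or
# patch positions so the weights are resolution-independent.

#' Loss weights for the total generator objective
#'
#' Defaults are the published training setting: `lambda_cyc = 10`,
#' `lambda_id = 5`, `lambda_adv = 1`.
#'
#' @param lambda_adv,lambda_cyc,lambda_id Non-negative weights.
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(lambda_adv = 1, lambda_cyc = 10, lambda_id = 5) {
  stopifnot(lambda_adv >= 0, lambda_cyc >= 0, lambda_id >= 0)
  structure(list(lambda_adv = lambda_adv, lambda_cyc = lambda_cyc,
                 lambda_id = lambda_id), class = "loss_weights")
}

#' Least-squares discriminator loss
#'
#' LSGAN objective for one discriminator: real patches are pushed toward 1,
#' fake patches toward 0, and the sum is halved (the reference CycleGAN
#' convention, which slows the discriminator relative to the generator):
#' `0.5 * (mean((real - 1)^2) + mean(fake^2))`. Fake scores should come from
#' the replay buffer and are treated as constants with respect to the
#' generator.
#'
#' @param real_scores,fake_scores Patch score maps from [discriminate()].
#' @return Scalar loss, `>= 0`, zero only for a perfect discriminator.
#' @export
adversarial_loss_d <- function(real_scores, fake_scores) {
  0.5 * (mean((real_scores - 1)^2) + mean(fake_scores^2))
}

#' Least-squares generator adversarial loss
#'
#' `mean((fake - 1)^2)`: the generator is rewarded when the discriminator
#' scores its output as real.
#'
#' @param fake_scores Patch score map of a generated image.
#' @return Scalar loss.
#' @export
adversarial_loss_g <- function(fake_scores) mean((fake_scores - 1)^2)

check_same_shape <- function(a, b, what) {
  if (!identical(dim(a) %||% length(a), dim(b) %||% length(b))) {
    stop("shape mismatch in ", what)
  }
}

#' Cycle-consistency loss
#'
#' Mean absolute error of both reconstruction cycles:
#' `mean(|x - x_cycled|) + mean(|y - y_cycled|)`, where `x_cycled` is the
#' image after translating to the other domain and back.
#'
#' @param x,y Original images from the two domains.
#' @param x_cycled,y_cycled Their round-trip reconstructions.
#' @return Scalar loss.
#' @export
cycle_loss <- function(x, x_cycled, y, y_cycled) {
  check_same_shape(x, x_cycled, "cycle_loss")
  check_same_shape(y, y_cycled, "cycle_loss")
  mean(abs(x - x_cycled)) + mean(abs(y - y_cycled))
}

#' Identity loss
#'
#' The generator applied to a sample already in its target domain should
#' return it unchanged: `mean(|G_AB(y) - y|) + mean(|G_BA(x) - x|)` for
#' `y` in domain B and `x` in domain A.
#'
#' @param y Domain-B image; `g_on_y` the A-to-B generator applied to it.
#' @param x Domain-A image; `g_on_x` the B-to-A generator applied to it.
#' @param g_on_y,g_on_x Generator outputs.
#' @return Scalar loss.
#' @export
identity_loss <- function(y, g_on_y, x, g_on_x) {
  check_same_shape(y, g_on_y, "identity_loss")
  check_same_shape(x, g_on_x, "identity_loss")
  mean(abs(g_on_y - y)) + mean(abs(g_on_x - x))
}

#' Weighted total generator loss
#'
#' `lambda_adv * adv + lambda_cyc * cyc + lambda_id * id`.
#'
#' @param adv_g,cyc,id Scalar loss components.
#' @param weights A [loss_weights()] object.
#' @return Scalar total.
#' @export
total_generator_loss <- function(adv_g, cyc, id, weights = loss_weights()) {
  stopifnot(is.finite(adv_g), is.finite(cyc), is.finite(id))
  weights$lambda_adv * adv_g + weights$lambda_cyc * cyc + weights$lambda_id * id
}

# Gradient helpers (d loss / d argument), matching the averaged forms above.
d_lsgan_toward <- function(scores, target) 2 * (scores - target) / length(scores)
d_mae <- function(pred, ref) sign(pred - ref) / length(pred)
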