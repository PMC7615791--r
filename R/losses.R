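# Probabilities entering a log are clamped one-sidedly away from the
# singular end, so exact closed forms (perfect prediction -> 0) still hold.
PROB_EPS <- 1e-7

clamp_prob <- function(p) clamp(p, PROB_EPS, 1 - PROB_EPS)

#' Adversarial encoder loss
#'
#' Batch mean of `log(1 - D(H))`; minimized when the discriminator is
#' fooled into `D(H) -> 1`.
#'
#' @param d_fake vector of discriminator outputs on encoder latents.
#' @return scalar.
#' @export
loss_enc <- function(d_fake) mean(log(1 - pmin(d_fake, 1 - PROB_EPS)))

#' Discriminator loss
#'
#' Batch mean of `-log(1 - D(H_fake)) - log(D(X_real))`; minimized when
#' fakes score 0 and prior samples score 1.
#'
#' @param d_fake discriminator outputs on encoder latents.
#' @param d_real discriminator outputs on samples from the label
#'   distribution.
#' @return scalar.
#' @export
loss_dis <- function(d_fake, d_real) {
  mean(-log(1 - pmin(d_fake, 1 - PROB_EPS))) +
    mean(-log(pmax(d_real, PROB_EPS)))
}

#' Classifier cross-entropy loss
#'
#' Negative log-likelihood `-sum(y * log C(H))` averaged over the batch
#' (one-hot `y`); zero iff the true class gets probability 1.
#'
#' @param prob matrix (or vector) of predicted class probabilities, one row
#'   per sample.
#' @param y_onehot matching one-hot labels.
#' @return scalar >= 0.
#' @export
loss_cla <- function(prob, y_onehot) {
  if (is.vector(prob)) prob <- matrix(prob, 1L)
  if (is.vector(y_onehot)) y_onehot <- matrix(y_onehot, 1L)
  -mean(rowSums(y_onehot * log(pmax(prob, PROB_EPS))))
}

#' Reconstruction loss
#'
#' Mean elementwise absolute difference (L1 normalized by element count)
#' between the original and reconstructed BFN.
#'
#' @param A_ori,A_rec equal-shape matrices.
#' @return scalar >= 0.
#' @export
loss_rec <- function(A_ori, A_rec) {
  stopifnot(all(dim(A_ori) == dim(A_rec)))
  mean(abs(A_rec - A_ori))
}

#' Node-representation consistency loss
#'
#' Mean L1 distance between the latent representation `H` and its
#' re-encoding `H_hat = E(G(H), F)` through the reconstructed network.
#'
#' @param H,H_hat equal-shape latent matrices.
#' @return scalar >= 0.
#' @export
loss_nrc <- function(H, H_hat) {
  stopifnot(all(dim(H) == dim(H_hat)))
  mean(abs(H_hat - H))
}
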