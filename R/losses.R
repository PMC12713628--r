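## Loss primitives shared by both models. The composite objective is
##   total = sequence + target + class + 2*score + attention + matrix + KL
## with matrix = alpha*distance + beta*structure + (1-alpha-beta)*adjacency;
## binary cross-entropy covers sequence/target/class/structure/adjacency,
## mean squared error covers score/attention/distance, and the KL term is
## the closed-form divergence of the diagonal-Gaussian posterior from the
## standard normal prior.

BCE_EPS <- 1e-7

#' Mean weighted binary cross-entropy
#'
#' Elementwise \code{-w * (y*log(x) + (1-y)*log(1-x))}, averaged over all
#' elements. Predictions are clipped into \code{(eps, 1-eps)} first.
#'
#' @param x predictions (any numeric array), clipped to (0,1).
#' @param y targets of the same shape (typically 0/1).
#' @param w non-negative weights (scalar or same shape; default 1).
#' @param eps clipping bound (default 1e-7).
#' @return scalar mean loss.
#' @examples
#' bceLoss(0.5, 1)        # log(2)
#' @export
bceLoss <- function(x, y, w = 1, eps = BCE_EPS) {
  if (length(x) != length(y))
    stop("prediction/target shape mismatch", call. = FALSE)
  xc <- pmin(pmax(as.numeric(x), eps), 1 - eps)
  mean(-w * (as.numeric(y) * log(xc) + (1 - as.numeric(y)) * log(1 - xc)))
}

#' Mean squared error
#'
#' @param x,y numeric arrays of identical shape.
#' @return scalar mean of squared differences.
#' @examples
#' mseLoss(c(0, 1), c(1, 1))  # 0.5
#' @export
mseLoss <- function(x, y) {
  if (length(x) != length(y))
    stop("prediction/target shape mismatch", call. = FALSE)
  mean((as.numeric(x) - as.numeric(y))^2)
}

#' Closed-form KL divergence of a diagonal Gaussian from N(0, I)
#'
#' \code{-1/2 * sum(1 + logvar - mu^2 - exp(logvar))}, summed over latent
#' dimensions. Non-negative, and zero exactly when \code{mu = 0},
#' \code{logvar = 0}.
#'
#' @param mu mean vector, or a [LatentDistribution-class].
#' @param logvar log-variance vector (ignored when \code{mu} is a
#'   \code{LatentDistribution}).
#' @return scalar KL divergence.
#' @examples
#' klGaussian(1, 0)  # 0.5
#' @export
klGaussian <- function(mu, logvar = NULL) {
  if (is(mu, "LatentDistribution")) { logvar <- mu@logvar; mu <- mu@mu }
  if (length(mu) != length(logvar))
    stop("mu and logvar must have equal length", call. = FALSE)
  -0.5 * sum(1 + logvar - mu^2 - exp(logvar))
}

#' Loss weights for the matrix term
#'
#' @param alpha weight of the distance component (default 0.3).
#' @param beta weight of the structure component (default 0.4); the
#'   adjacency component gets \code{1 - alpha - beta}.
#' @param scoreMultiplier weight of the score term in the composite loss
#'   (default 2).
#' @return named list validated so \code{alpha, beta >= 0} and
#'   \code{alpha + beta <= 1}.
#' @export
lossWeights <- function(alpha = 0.3, beta = 0.4, scoreMultiplier = 2) {
  if (alpha < 0 || beta < 0)
    stop("alpha and beta must be non-negative", call. = FALSE)
  if (alpha + beta > 1)
    stop("alpha + beta must not exceed 1", call. = FALSE)
  list(alpha = alpha, beta = beta, scoreMultiplier = scoreMultiplier)
}

#' Convex combination of the three matrix-loss components
#'
#' \code{alpha*distance + beta*structure + (1-alpha-beta)*adjacency} with
#' defaults alpha = 0.3, beta = 0.4 (structure weighted most, reflecting the
#' emphasis on the aptamer's own fold over the target matrices).
#'
#' @param distance,structure,adjacency non-negative component losses.
#' @param weights a [lossWeights()] list.
#' @return scalar matrix loss.
#' @export
matrixLoss <- function(distance, structure, adjacency, weights = lossWeights()) {
  if (any(c(distance, structure, adjacency) < 0))
    stop("matrix-loss components must be non-negative", call. = FALSE)
  weights$alpha * distance + weights$beta * structure +
    (1 - weights$alpha - weights$beta) * adjacency
}

#' Composite training loss with its breakdown
#'
#' Sums the seven components, doubling (by default) the score term --
#' generated-sequence quality is judged by the score head, so its gradient
#' is weighted more heavily.
#'
#' @param sequence,target,class,score,attention,matrix,kl non-negative
#'   component losses.
#' @param weights a [lossWeights()] list (uses \code{scoreMultiplier}).
#' @return scalar total, with the named breakdown attached as attribute
#'   \code{"breakdown"}.
#' @export
compositeLoss <- function(sequence, target, class, score, attention, matrix,
                          kl, weights = lossWeights()) {
  parts <- c(sequence = sequence, target = target, class = class,
             score = score, attention = attention, matrix = matrix, kl = kl)
  if (any(parts < 0))
    stop("negative loss component: ",
         paste(names(parts)[parts < 0], collapse = ", "), call. = FALSE)
  total <- sequence + target + class + weights$scoreMultiplier * score +
    attention + matrix + kl
  attr(total, "breakdown") <- parts
  total
}
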