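# Segmentation-quality metrics: a Rand index over non-adjacent position
# pairs against a reference labeling, and Hellinger-distance comparison of
# two segmentations of the same profile under fitted per-segment negative
# binomial distributions.

#' Convert breakpoints to a per-position segment labeling
#'
#' @param breaks strictly increasing segment ends in `[1, n-1]` (1-based
#'   inclusive-end convention).
#' @param n series length.
#' @return integer labels of length n, non-decreasing, starting at 1.
#' @examples
#' labels_from_breakpoints(3, 6)   # 1 1 1 2 2 2
#' @export
labels_from_breakpoints <- function(breaks, n) {
  breaks <- as.integer(breaks)
  if (length(breaks)) {
    if (is.unsorted(breaks, strictly = TRUE) ||
        breaks[1L] < 1L || breaks[length(breaks)] > n - 1L)
      stop("'breaks' must be strictly increasing within [1, n-1]")
  }
  rep.int(seq_len(length(breaks) + 1L),
          diff(c(0L, breaks, as.integer(n))))
}

#' Rand index between two segment labelings over non-adjacent pairs
#'
#' Pairwise agreement between two labelings of positions 1..n, computed over
#' the pairs \eqn{(s,t)} with \eqn{t \ge s+2}:
#' \deqn{I = 2 \sum_{t \ge s+2} [1\{C_t=C_s\}1\{\hat C_t=\hat C_s\} +
#'   1\{C_t \ne C_s\}1\{\hat C_t \ne \hat C_s\}] / ((n-1)(n-2)).}
#' Adjacent pairs are excluded so that identical labelings score exactly 1
#' with the \eqn{(n-1)(n-2)} normalization. Both labelings must be
#' segment-contiguous (non-decreasing); the implementation uses an O(n)
#' run-length formulation of the quadratic pair sum.
#'
#' @param true_labels,est_labels integer labelings of equal length n >= 3,
#'   non-decreasing.
#' @return the index, in `[0, 1]`.
#' @examples
#' rand_index(c(1, 1, 2, 2), c(1, 2, 2, 2))  # 2/3
#' @export
rand_index <- function(true_labels, est_labels) {
  n <- length(true_labels)
  if (length(est_labels) != n) stop("labelings differ in length")
  if (n < 3L) stop("need at least 3 positions")
  if (is.unsorted(true_labels) || is.unsorted(est_labels))
    stop("labelings must be non-decreasing (segment-contiguous)")
  # pairs (s,t), t >= s+2, inside runs of constant label
  p2 <- function(len) sum((len - 1) * (len - 2) / 2)
  ra <- rle(as.vector(true_labels))$lengths
  rb <- rle(as.vector(est_labels))$lengths
  chg <- diff(true_labels) != 0 | diff(est_labels) != 0
  rj <- rle(cumsum(c(0L, as.integer(chg))))$lengths
  total <- (n - 1) * (n - 2) / 2
  both_same <- p2(rj)
  both_diff <- total - p2(ra) - p2(rb) + both_same
  2 * (both_same + both_diff) / ((n - 1) * (n - 2))
}

#' Hellinger distance between two negative binomial distributions
#'
#' Closed form for NB\eqn{(\phi, \theta)} with pmf
#' \eqn{P(y) = {y+\phi-1 \choose y} \theta^{\phi} (1-\theta)^y}: the
#' Bhattacharyya coefficient is
#' \eqn{BC = [\sqrt{\theta_1\theta_2} /
#'   (1 - \sqrt{(1-\theta_1)(1-\theta_2)})]^{\phi}}
#' (from the generating function of the pmf square-root product), and
#' \eqn{H = \sqrt{1 - BC}}.
#'
#' @param theta1,theta2 success probabilities in (0, 1); vectorized.
#' @param phi positive dispersion.
#' @return Hellinger distance(s) in `[0, 1]`.
#' @export
hellinger_nb <- function(theta1, theta2, phi) {
  if (any(theta1 <= 0 | theta1 >= 1 | theta2 <= 0 | theta2 >= 1))
    stop("'theta' values must lie strictly inside (0, 1)")
  if (any(phi <= 0)) stop("'phi' must be positive")
  # 1 - sqrt((1-t1)(1-t2)) loses precision when both theta are small;
  # multiply through by the conjugate: denom = 1 - (1-t1)(1-t2)
  x <- sqrt((1 - theta1) * (1 - theta2))
  denom <- theta1 + theta2 - theta1 * theta2
  bc <- (sqrt(theta1 * theta2) * (1 + x) / denom)^phi
  h <- sqrt(pmax(0, 1 - bc))
  # equal parameters give identical distributions: the distance is exactly 0
  h[theta1 == theta2] <- 0
  h
}

#' Per-position Hellinger comparison of two segmentations of one profile
#'
#' Fits a negative binomial to every segment of each segmentation (plug-in
#' \eqn{\hat\theta_r = \phi / (\phi + \bar y_r)}) and computes, at every
#' position, the Hellinger distance between the two fitted distributions;
#' the overall score is the positional average \eqn{\sum_t H_t / n}.
#'
#' @param breaks_a,breaks_b breakpoints (1-based inclusive segment ends) of
#'   the two segmentations.
#' @param y the common count series.
#' @param phi NB dispersion used for both fits.
#' @return list with `H` (length-n vector of per-position distances) and
#'   `score`.
#' @export
hellinger_profile <- function(breaks_a, breaks_b, y, phi) {
  n <- length(y)
  la <- labels_from_breakpoints(breaks_a, n)
  lb <- labels_from_breakpoints(breaks_b, n)
  theta_fit <- function(lab) {
    means <- tapply(y, lab, mean)
    pmin(pmax(phi / (phi + means), 1e-12), 1 - 1e-12)
  }
  tha <- theta_fit(la)
  thb <- theta_fit(lb)
  H <- hellinger_nb(tha[la], thb[lb], phi)
  list(H = unname(H), score = mean(H))
}
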