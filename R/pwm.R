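# Position weight matrices: log2-odds construction from count matrices and
# exact threshold calibration via dynamic programming over the discretised
# score distribution under an i.i.d. background.

#' Uniform base background
#' @return Named numeric vector (A, C, G, T) of 0.25 each.
#' @export
uniform_background <- function() {
  stats::setNames(rep(0.25, 4), .BASE_CHARS)
}

validate_background <- function(q) {
  if (length(q) != 4L) stop_fmt("background must have 4 frequencies (A,C,G,T)")
  if (any(q <= 0)) stop_fmt("background frequencies must all be positive")
  if (abs(sum(q) - 1) > 1e-8) stop_fmt("background frequencies must sum to 1")
  stats::setNames(as.numeric(q), .BASE_CHARS)
}

validate_pcm <- function(pcm) {
  if (!is.matrix(pcm) || nrow(pcm) != 4L || ncol(pcm) < 1L) {
    stop_fmt("count matrix must be 4 x L with L >= 1")
  }
  if (any(pcm < 0)) stop_fmt("count matrix has negative entries")
  if (any(colSums(pcm) <= 0)) stop_fmt("count matrix has a zero-sum column")
  invisible(TRUE)
}

#' Build a log2-odds position weight matrix from a count matrix
#'
#' Column-wise, counts are turned into frequencies with a background-
#' distributed pseudocount, `f[b,i] = (c[b,i] + pseudocount * q[b]) /
#' (N[i] + pseudocount)` with `N[i]` the column sum, and weights are
#' `log2(f[b,i] / q[b])`. The returned PWM is uncalibrated (no hit threshold)
#' until [calibrate_threshold()] is applied.
#'
#' @param pcm 4 x L count matrix, rows A, C, G, T.
#' @param background Base frequencies (A, C, G, T), each > 0, summing to 1.
#' @param pseudocount Positive scalar, distributed by background frequency.
#' @param name Motif name; defaults to the matrix's `name` attribute.
#' @return An object of class `pwm`.
#' @export
build_pwm <- function(pcm, background = uniform_background(), pseudocount = 0.8,
                      name = NULL) {
  validate_pcm(pcm)
  q <- validate_background(background)
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount <= 0) {
    stop_fmt("pseudocount must be a positive scalar")
  }
  N <- colSums(pcm)
  f <- sweep(pcm, 1, q * pseudocount, `+`)
  f <- sweep(f, 2, N + pseudocount, `/`)
  w <- log2(sweep(f, 1, q, `/`))
  rownames(w) <- .BASE_CHARS
  structure(
    list(weights = w,
         background = q,
         pseudocount = pseudocount,
         length = ncol(w),
         motif = name %||% attr(pcm, "name") %||% "motif",
         threshold = NA_real_,
         alpha = NA_real_,
         granularity = NA_real_,
         attained_p = NA_real_),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s': length %d, max score %.3f bits\n",
              x$motif, x$length, pwm_max_score(x)))
  if (is.na(x$threshold)) {
    cat("  threshold: uncalibrated\n")
  } else {
    cat(sprintf("  threshold %.4f (alpha %.3g, attained p %.3g)\n",
                x$threshold, x$alpha, x$attained_p))
  }
  invisible(x)
}

#' Maximum achievable PWM score
#' @param pwm A `pwm` object.
#' @return Numeric scalar, the sum of per-column maxima.
#' @export
pwm_max_score <- function(pwm) sum(apply(pwm$weights, 2, max))

#' Minimum achievable PWM score
#' @param pwm A `pwm` object.
#' @return Numeric scalar, the sum of per-column minima.
#' @export
pwm_min_score <- function(pwm) sum(apply(pwm$weights, 2, min))

#' Consensus word of a PWM or count matrix
#'
#' @param x A `pwm` object or a 4 x L count matrix.
#' @return Character scalar: the per-column argmax base.
#' @export
consensus_word <- function(x) {
  m <- if (inherits(x, "pwm")) x$weights else x
  paste(.BASE_CHARS[apply(m, 2, which.max)], collapse = "")
}

# Exact distribution of the discretised PWM score of a random L-mer under the
# background: convolve per-column probability mass functions on an integer
# grid of step `granularity`. Returns grid scores (integer units) and pmf.
score_distribution <- function(pwm, background = NULL, granularity = 1e-3) {
  q <- validate_background(background %||% pwm$background)
  wi <- round(pwm$weights / granularity)
  lo <- 0L; hi <- 0L
  p <- 1
  for (j in seq_len(ncol(wi))) {
    col <- wi[, j]
    new_lo <- lo + min(col)
    new_hi <- hi + max(col)
    np <- numeric(new_hi - new_lo + 1L)
    for (b in 1:4) {
      sh <- col[b] - min(col)
      idx <- seq_along(p) + sh
      np[idx] <- np[idx] + p * q[b]
    }
    p <- np
    lo <- new_lo
    hi <- new_hi
  }
  list(scores = seq.int(lo, hi), pmf = p, granularity = granularity)
}

#' Calibrate a PWM hit threshold to a target p-value
#'
#' Computes the exact distribution of the score of a random L-mer under the
#' background by dynamic programming on a discretised score grid (step
#' `granularity`, in bits), and sets the threshold to the smallest grid score
#' `s` with `P(score >= s) <= alpha`, lowered by `L * granularity / 2` to
#' absorb the worst-case per-column rounding error. The attained tail
#' probability on the grid is stored as `attained_p`.
#'
#' @param pwm A `pwm` object from [build_pwm()].
#' @param alpha Target match p-value, in (0, 1].
#' @param granularity Score discretisation step in bits.
#' @param background Optional override of the PWM's background.
#' @return The PWM with `threshold`, `alpha`, `granularity` and `attained_p` set.
#' @export
calibrate_threshold <- function(pwm, alpha = 1e-4, granularity = 1e-3,
                                background = NULL) {
  if (!inherits(pwm, "pwm")) stop_fmt("expected a pwm object")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    stop_fmt("alpha must lie in (0, 1]")
  }
  if (!is.null(background)) {
    pwm$background <- validate_background(background)
  }
  dist <- score_distribution(pwm, granularity = granularity)
  tail <- rev(cumsum(rev(dist$pmf)))
  # candidate thresholds are achievable (positive-mass) scores, so the
  # attained p is the exact tail of a realisable word score
  k <- which(tail <= alpha & dist$pmf > 0)[1]
  slack <- pwm$length * granularity / 2
  if (is.na(k)) {
    # alpha below the probability of the best word: nothing can pass
    pwm$threshold <- (dist$scores[length(dist$scores)] + 1L) * granularity + slack
    pwm$attained_p <- 0
  } else {
    pwm$threshold <- dist$scores[k] * granularity - slack
    pwm$attained_p <- tail[k]
  }
  pwm$alpha <- alpha
  pwm$granularity <- granularity
  pwm
}

is_calibrated <- function(pwm) inherits(pwm, "pwm") && !is.na(pwm$threshold)
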