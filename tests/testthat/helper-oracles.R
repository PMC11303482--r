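# Shared fixtures and independent oracles used across the suite.

# A strongly informative 4-column count matrix (consensus ACGT) for tiny tests
tiny_pcm <- function() {
  m <- rbind(A = c(9, 0, 0, 0), C = c(0, 9, 0, 0),
             G = c(0, 0, 9, 0), T = c(0, 0, 0, 9))
  attr(m, "name") <- "TINY"
  m
}

calibrated_tiny_pwm <- function(alpha = 1e-3) {
  calibrate_threshold(build_pwm(tiny_pcm()), alpha = alpha)
}

calibrated_sox9_pwm <- function(alpha = 1e-4,
                                background = uniform_background()) {
  calibrate_threshold(build_pwm(example_sox9_pcm(), background = background),
                      alpha = alpha)
}

random_dna <- function(n, seed, gc = 0.5) {
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  peakmotifs:::with_seed(seed, {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
          collapse = "")
  })
}

# Independent scanner oracle: naive per-window rescoring loop, no shared code
# with the vectorised scanner.
naive_scan <- function(pwm, sequence, both_strands = TRUE) {
  L <- pwm$length
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  rows <- list()
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  if (n >= L) {
    for (s in 0:(n - L)) {
      win <- chars[(s + 1):(s + L)]
      if (any(win == "N")) next
      sc <- sum(vapply(seq_len(L), function(k) pwm$weights[win[k], k], numeric(1)))
      if (sc >= pwm$threshold) {
        rows[[length(rows) + 1]] <- data.frame(start = s, end = s + L,
                                               strand = "+", score = sc)
      }
      if (both_strands) {
        rc <- rev(unname(comp[win]))
        sc2 <- sum(vapply(seq_len(L), function(k) pwm$weights[rc[k], k], numeric(1)))
        if (sc2 >= pwm$threshold) {
          rows[[length(rows) + 1]] <- data.frame(start = s, end = s + L,
                                                 strand = "-", score = sc2)
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), score = numeric()))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$strand == "-"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exhaustive enumeration of all 4^L words: exact tail probability of the true
# (undiscretised) score under an i.i.d. background.
enumerate_tail <- function(pwm, background, threshold) {
  L <- pwm$length
  words <- as.matrix(expand.grid(rep(list(1:4), L)))
  sc <- numeric(nrow(words))
  for (k in seq_len(L)) sc <- sc + pwm$weights[words[, k], k]
  pr <- matrix(background[words], nrow(words), L)
  sum(apply(pr, 1, prod)[sc >= threshold])
}

small_genome_with_peaks <- function(seed = 7, len = 50000, n_peaks = 50) {
  g <- generate_genome(len, gc = 0.45, seed = seed)
  pk <- generate_peaks(g, n_peaks, length_mean = 200, length_sd = 30,
                       seed = seed + 1)
  list(genome = g, peaks = pk)
}
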