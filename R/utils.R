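# Internal helpers: reproducible RNG scoping, base coding, small validators.

# Run `code` under `seed`, restoring the caller's RNG state afterwards so
# generators are pure functions of (parameters, seed).
with_seed <- function(seed, code) {
  seed <- as.integer(seed)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# One master seed -> n child seeds by a fixed split (parallel-safe determinism).
derive_seeds <- function(master, n) {
  with_seed(master, sample.int(2147483646L, n))
}

.BASE_CODE <- local({
  v <- rep(NA_integer_, 256L)
  v[utf8ToInt("A")] <- 1L
  v[utf8ToInt("C")] <- 2L
  v[utf8ToInt("G")] <- 3L
  v[utf8ToInt("T")] <- 4L
  v[utf8ToInt("N")] <- 0L
  v
})

.BASE_CHARS <- c("A", "C", "G", "T")

# DNA string -> integer codes (A=1, C=2, G=3, T=4, N=0); errors on anything else
seq_to_codes <- function(s) {
  codes <- .BASE_CODE[utf8ToInt(s)]
  if (anyNA(codes)) {
    bad <- unique(strsplit(s, "")[[1]])
    bad <- setdiff(bad, c("A", "C", "G", "T", "N"))
    stop("sequence contains characters outside {A,C,G,T,N}: ",
         paste(bad, collapse = ", "))
  }
  codes
}

codes_to_seq <- function(codes) {
  intToUtf8(c(78L, 65L, 67L, 71L, 84L)[codes + 1L])
}

#' Reverse complement of a DNA string
#'
#' Plain-string reverse complement over the alphabet A, C, G, T, N.
#'
#' @param s Character vector of DNA strings.
#' @return Character vector of reverse-complemented strings.
#' @export
reverse_complement <- function(s) {
  vapply(chartr("ACGTN", "TGCAN", s), function(x) {
    intToUtf8(rev(utf8ToInt(x)))
  }, character(1), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)
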