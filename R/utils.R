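#' Round half away from zero
#'
#' Fixed-convention rounding for report tables: halves always round up in
#' magnitude (so 48.25 -> 48.3 at one decimal), unlike [base::round()]'s
#' round-half-even.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Signal an insufficient-data result
#'
#' Several estimators decline to produce a result below a minimum number of
#' observations; they return this sentinel instead of guessing.
#'
#' @param what short label of the quantity that could not be estimated.
#' @param n number of observations available.
#' @param required minimum required.
#' @return object of class `sd_insufficient`.
#' @export
insufficient_data <- function(what, n, required) {
  structure(list(what = what, n = n, required = required),
            class = "sd_insufficient")
}

#' Test for the insufficient-data sentinel
#' @param x any object.
#' @return logical scalar.
#' @export
is_insufficient <- function(x) inherits(x, "sd_insufficient")

#' @export
print.sd_insufficient <- function(x, ...) {
  cat(sprintf("<insufficient data for %s: %d observation(s), %d required>\n",
              x$what, x$n, x$required))
  invisible(x)
}

# reverse complement for plain character vectors (ACGT only)
revcomp_chr <- function(x) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(x, function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                     collapse = ""), character(1),
                USE.NAMES = FALSE))
}

# random DNA with a given GC content
random_dna <- function(n, gc = 0.53) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# stop with a consistent message prefix
sd_stop <- function(...) stop(sprintf(...), call. = FALSE)

# simple union-find over 1..n
union_find <- function(n) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  list(
    union = function(i, j) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
      invisible(NULL)
    },
    components = function() vapply(seq_len(n), find, integer(1))
  )
}
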