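#' @useDynLib brxrscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median nls coef rnorm runif sd setNames approx
#' @importFrom utils read.delim write.table head modifyList
NULL

#' Round a ratio to a two-decimal percentage
#'
#' Percentages throughout the reporting layer are formatted as
#' `100 * num / den` rounded to two decimal places with banker's rounding
#' (round-half-even, the IEEE default used by [base::round()]).
#'
#' @param num numerator (count).
#' @param den denominator (count); `den == 0` yields `NaN`.
#' @return numeric percentage rounded to 2 dp.
#' @examples
#' percent2(212, 347) # 61.1
#' percent2(70, 210)  # 33.33
#' @export
percent2 <- function(num, den) {
  round(100 * num / den, 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
assert_that <- function(ok, msg, class = "brxrscan_validation_error") {
  if (!isTRUE(ok)) {
    stop(structure(
      class = c(class, "error", "condition"),
      list(message = msg, call = sys.call(-1))
    ))
  }
  invisible(TRUE)
}

parse_error <- function(msg) {
  stop(structure(
    class = c("brxrscan_parse_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' @noRd
empty_df <- function(...) {
  cols <- list(...)
  as.data.frame(lapply(cols, function(type) vector(type, 0L)),
                stringsAsFactors = FALSE)
}

# deterministic child seeds: fan a root seed out so that one element's
# stream does not perturb another's (kept below 2^31)
child_seed <- function(seed, key) {
  ints <- utf8ToInt(paste0(key))
  h <- as.double(seed %% 2147483647L)
  for (i in ints) {
    h <- (h * 31 + i) %% 2147483562
  }
  as.integer(h %% 2147483562) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
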