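# Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

sigmoid <- function(x) stats::plogis(x)

#' Numerically stable softplus
#'
#' Computes `log(1 + exp(x))` without overflow for large `x`.
#'
#' @param x numeric vector.
#' @return numeric vector of the same length.
#' @keywords internal
softplus <- function(x) {
  out <- ifelse(x > 30, x + log1p(exp(-x)), log1p(exp(x)))
  out
}

# Stop with a consistent error class so callers/tests can target failures.
abort <- function(msg, class) {
  stop(structure(class = c(class, "coexpanel_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && abs(x - round(x)) < tol
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 for identical partitions (up to relabeling), around 0 for independent
#' ones. Used for parameter-recovery checks against planted panel labels.
#'
#' @param a,b integer or factor vectors of equal length.
#' @return a single numeric value in \[-1, 1\].
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1))
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) {
    abort("labelings must have equal length", "coexpanel_input_error")
  }
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
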