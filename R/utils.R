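#' @keywords internal
"_PACKAGE"

#' @importFrom Matrix readMM writeMM t rowSums colSums colMeans rowMeans
#' @importFrom stats cor cutree dist hclust phyper p.adjust pt pnorm prcomp
#'   kmeans rnorm runif rlnorm rnbinom rmultinom sd var as.dist setNames
#'   quantile rgamma
#' @importFrom utils read.delim write.table head tail
NULL

.log_levels <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)

#' Stage logger
#'
#' Prints a tagged message when the requested level is at or above the
#' threshold in `options(airetonic.log_level = ...)` (default "info").
#'
#' @param stage character tag for the pipeline stage or operation.
#' @param msg message text (sprintf-style with `...`).
#' @param level one of "debug", "info", "warn".
#' @param ... sprintf arguments.
#' @return invisibly, the formatted message.
#' @export
at_log <- function(stage, msg, ..., level = "info") {
  level <- match.arg(level, names(.log_levels))
  thr <- getOption("airetonic.log_level", "info")
  if (!thr %in% names(.log_levels)) thr <- "info"
  txt <- sprintf("[%s] %s", stage, sprintf(msg, ...))
  if (.log_levels[[level]] >= .log_levels[[thr]]) message(txt)
  invisible(txt)
}

#' Derive a stage-specific random seed
#'
#' Every stochastic stage draws from a seed derived deterministically from
#' the global seed and the stage name, so stages are independently
#' reproducible.  The result is always a valid 32-bit integer seed.
#'
#' @param seed global integer seed.
#' @param stage stage name (character).
#' @return integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 31 + b) %% 1000003
  as.integer(((abs(as.numeric(seed)) %% 1000003) * 1009 + h) %% 2147483647)
}

# Polynomial content hash used to tag pipeline outputs with their config.
config_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 means identical partitions, ~0 means chance-level agreement.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0L)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (max_idx - expected)
}

# Row means / variances for a subset of columns of a dense matrix.
.row_mean_var <- function(mat, idx) {
  n <- length(idx)
  m <- rowMeans(mat[, idx, drop = FALSE])
  v <- rowSums((mat[, idx, drop = FALSE] - m)^2) / (n - 1)
  list(mean = m, var = v, n = n)
}
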