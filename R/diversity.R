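# Transcriptomic diversity as Hill numbers of order 0.
#
# Gene richness of a cell population as a function of UMIs considered:
# hypergeometric interpolation below the observed depth, Chao1-anchored
# extrapolation above it, multinomial bootstrap standard errors, and
# Wald-type Z comparisons against a reference population at a common
# evaluation depth.  Only order q = 0 (richness) is supported; the API
# carries q for future orders but rejects anything else.

#' Pooled gene abundance of a cell population
#'
#' @param cm a [count_matrix].
#' @param population cell type label.
#' @return named integer vector of per-gene summed UMIs over the
#'   population's cells, zero-total genes removed.
#' @export
pooled_abundance <- function(cm, population) {
  stopifnot(inherits(cm, "count_matrix"))
  sel <- cm$cell_meta$cell_type == population
  if (!any(sel)) stop("empty population: ", population)
  ab <- colSums(as.matrix(cm$counts[sel, , drop = FALSE]))
  ab <- ab[ab > 0]
  if (length(ab) == 0) stop("population has no expressed genes: ", population)
  ab
}

#' Interpolated (rarefied) gene richness
#'
#' Expected richness in a random subsample of m UMIs:
#' E[S_m] = sum_g (1 - C(N - n_g, m) / C(N, m)), computed in log space.
#' Exact at m = N.
#'
#' @param abundance named non-negative integer abundance vector.
#' @param m_grid integer depths with 1 <= m <= N.
#' @param q Hill order; only 0 supported.
#' @return numeric vector of expected richness values, one per depth.
#' @export
rarefy_richness <- function(abundance, m_grid, q = 0) {
  if (q != 0) stop("only Hill order q = 0 (richness) is supported")
  abundance <- abundance[abundance > 0]
  N <- sum(abundance)
  if (any(m_grid < 1 | m_grid > N))
    stop("interpolation depths must satisfy 1 <= m <= N; use extrapolate_richness beyond N")
  vapply(m_grid, function(m) {
    sum(1 - exp(lchoose(N - abundance, m) - lchoose(N, m)))
  }, numeric(1))
}

#' Chao1 asymptotic richness
#'
#' S_est = S_obs + f1^2 / (2 f2) when doubletons exist, otherwise
#' S_obs + f1 (f1 - 1) / 2.
#'
#' @param abundance abundance vector.
#' @return list with `S_obs`, `f1`, `f2`, `S_est`.
#' @export
chao1 <- function(abundance) {
  abundance <- abundance[abundance > 0]
  S_obs <- length(abundance)
  f1 <- sum(abundance == 1)
  f2 <- sum(abundance == 2)
  S_est <- if (f2 > 0) S_obs + f1^2 / (2 * f2) else S_obs + f1 * (f1 - 1) / 2
  list(S_obs = S_obs, f1 = f1, f2 = f2, S_est = S_est)
}

#' Extrapolated gene richness beyond the observed depth
#'
#' Chao1-anchored extrapolation: with f0_hat = S_est - S_obs unseen genes,
#' S(N + m*) = S_obs + f0_hat (1 - (1 - f1 / (N f0_hat + f1))^m*).
#' With no singletons the curve is flat at S_obs (flagged, not an error);
#' the curve is monotone and bounded by S_est.
#'
#' @param abundance abundance vector.
#' @param m_grid absolute depths with m > N (m* = m - N extra UMIs).
#' @param q Hill order; only 0 supported.
#' @return numeric vector of extrapolated richness values; attribute
#'   `flat` is TRUE when f1 = 0.
#' @export
extrapolate_richness <- function(abundance, m_grid, q = 0) {
  if (q != 0) stop("only Hill order q = 0 (richness) is supported")
  abundance <- abundance[abundance > 0]
  N <- sum(abundance)
  if (any(m_grid <= N)) stop("extrapolation depths must exceed N")
  ch <- chao1(abundance)
  f0 <- ch$S_est - ch$S_obs
  mstar <- m_grid - N
  if (ch$f1 == 0 || f0 == 0) {
    out <- rep(ch$S_obs, length(m_grid))
    attr(out, "flat") <- TRUE
    return(out)
  }
  out <- ch$S_obs + f0 * (1 - (1 - ch$f1 / (N * f0 + ch$f1))^mstar)
  attr(out, "flat") <- FALSE
  out
}

# Point estimate across a mixed interpolation/extrapolation grid.
.richness_curve <- function(abundance, m_grid) {
  N <- sum(abundance)
  qd <- numeric(length(m_grid))
  lo <- m_grid <= N
  if (any(lo)) qd[lo] <- rarefy_richness(abundance, m_grid[lo])
  if (any(!lo)) qd[!lo] <- extrapolate_richness(abundance, m_grid[!lo])
  qd
}

#' Bootstrap standard errors for the richness curve
#'
#' Multinomial bootstrap over the estimated complete abundance
#' distribution: observed relative abundances are shrunk by the estimated
#' sample coverage (Chat = 1 - f1/N) and the remaining probability mass is
#' split equally over f0_hat unseen genes; each replicate redraws N UMIs
#' and recomputes the curve.
#'
#' @param abundance abundance vector.
#' @param m_grid depths (interpolation and/or extrapolation).
#' @param n_boot bootstrap replicates (default 200, minimum 50).
#' @param seed integer seed.
#' @return data.frame with `m`, `se`, `lo`, `hi` (95% normal interval
#'   around the point estimate).
#' @export
diversity_se <- function(abundance, m_grid, n_boot = 200, seed = 1) {
  if (n_boot < 50) stop("n_boot must be >= 50")
  abundance <- abundance[abundance > 0]
  N <- sum(abundance)
  ch <- chao1(abundance)
  Chat <- 1 - ch$f1 / N
  f0 <- max(0L, round(ch$S_est - ch$S_obs))
  p <- abundance / N
  if (f0 > 0 && Chat < 1) {
    p <- c(p * Chat, rep((1 - Chat) / f0, f0))
  }
  set.seed(seed)
  boot <- matrix(NA_real_, n_boot, length(m_grid))
  for (b in seq_len(n_boot)) {
    x <- as.vector(stats::rmultinom(1, N, p))
    boot[b, ] <- .richness_curve(x[x > 0], m_grid)
  }
  est <- .richness_curve(abundance, m_grid)
  se <- apply(boot, 2, stats::sd)
  data.frame(m = m_grid, se = se, lo = est - 1.96 * se, hi = est + 1.96 * se)
}

#' Rarefaction/extrapolation curve for one population
#'
#' @param abundance named abundance vector (e.g. from [pooled_abundance]).
#' @param m_grid depths; default 20 points from 1 to
#'   `extrapolation_factor * N`.
#' @param n_boot bootstrap replicates for the SE (default 200).
#' @param seed integer seed.
#' @param population label recorded in the result.
#' @param extrapolation_factor upper end of the default grid as a multiple
#'   of N (default 2, the standard extrapolation limit guidance).
#' @return object of class `rarefaction_result`: data.frame with `m`, `qD`,
#'   `se`, `lo`, `hi`, `regime` (interp/extrap); attributes `S_obs`,
#'   `N_total`, `chao1`, `f1`, `f2`, `population`.
#' @export
diversity_curve <- function(abundance, m_grid = NULL, n_boot = 200, seed = 1,
                            population = "population",
                            extrapolation_factor = 2) {
  abundance <- abundance[abundance > 0]
  N <- sum(abundance)
  if (is.null(m_grid)) {
    m_grid <- unique(round(c(seq(1, N, length.out = 12), N,
                             seq(N, extrapolation_factor * N, length.out = 9)[-1])))
  }
  m_grid <- sort(unique(as.integer(m_grid)))
  qd <- .richness_curve(abundance, m_grid)
  band <- diversity_se(abundance, m_grid, n_boot = n_boot, seed = seed)
  ch <- chao1(abundance)
  out <- data.frame(m = m_grid, qD = qd, se = band$se, lo = band$lo, hi = band$hi,
                    regime = ifelse(m_grid <= N, "interp", "extrap"),
                    stringsAsFactors = FALSE)
  attr(out, "S_obs") <- ch$S_obs
  attr(out, "N_total") <- N
  attr(out, "chao1") <- ch$S_est
  attr(out, "f1") <- ch$f1
  attr(out, "f2") <- ch$f2
  attr(out, "population") <- population
  class(out) <- c("rarefaction_result", "data.frame")
  out
}

#' Wald-type Z comparison of richness against a reference population
#'
#' At a common evaluation depth m*, the SE of each curve is recovered from
#' its confidence-interval half-width (/1.96) and
#' Z = (qD_a - qD_ref) / sqrt(se_a^2 + se_ref^2) with a two-sided normal
#' p, Holm-adjusted across the non-reference populations.
#'
#' @param results named list of `rarefaction_result` objects sharing
#'   `m_star` in their grids.
#' @param reference name of the reference population.
#' @param m_star evaluation depth; must be present in every curve.
#' @return data.frame with population, reference, qD, qD_ref, Z, p,
#'   holm_p, m_star.
#' @export
compare_to_reference <- function(results, reference, m_star) {
  if (!reference %in% names(results))
    stop("reference population absent: ", reference)
  pick <- function(r) {
    i <- match(m_star, r$m)
    if (is.na(i)) stop("evaluation depth m*=", m_star, " not on a shared grid")
    list(qD = r$qD[i], se = (r$hi[i] - r$lo[i]) / (2 * 1.96))
  }
  ref <- pick(results[[reference]])
  pops <- setdiff(names(results), reference)
  rows <- lapply(pops, function(pop) {
    a <- pick(results[[pop]])
    z <- if (a$qD == ref$qD) 0 else (a$qD - ref$qD) / sqrt(a$se^2 + ref$se^2)
    data.frame(population = pop, reference = reference, qD = a$qD,
               qD_ref = ref$qD, Z = z, p = 2 * stats::pnorm(-abs(z)),
               m_star = m_star, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$holm_p <- adjust_holm(out$p)
  out
}
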