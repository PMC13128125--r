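#' Jensen-Shannon divergence between two abundance profiles
#'
#' Treats each relative-abundance profile as a probability distribution
#' over a taxon set and computes
#' `JSD(P, Q) = D_KL(P || M) / 2 + D_KL(Q || M) / 2` with mixture
#' `M = (P + Q) / 2` and `D_KL(P || M) = sum_b P(b) log(P(b) / M(b))`,
#' using the convention `0 log 0 = 0`. JSD is symmetric and bounded by
#' `log(2)` (in the chosen base). Named vectors are outer-joined on their
#' taxon names with zeros for absent taxa; unnamed vectors must have equal
#' length.
#'
#' @param p,q Non-negative numeric vectors summing to 1 within 1e-9
#'   (optionally named by taxon).
#' @param base Logarithm base; the default `exp(1)` reports nats, `2`
#'   reports bits.
#' @return A single non-negative number, at most `log(2, base)`.
#' @examples
#' jsd(c(0.5, 0.5), c(1, 0))  # 0.2157 nats
#' @export
jsd <- function(p, q, base = exp(1)) {
  if (!is.null(names(p)) || !is.null(names(q))) {
    if (is.null(names(p)) || is.null(names(q)))
      stop("either both or neither profile may be named")
    taxa <- union(names(p), names(q))
    pp <- stats::setNames(rep(0, length(taxa)), taxa); pp[names(p)] <- p
    qq <- stats::setNames(rep(0, length(taxa)), taxa); qq[names(q)] <- q
    p <- pp; q <- qq
  }
  if (length(p) != length(q)) stop("profiles must share one taxon set")
  if (any(p < 0) || any(q < 0)) stop("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9)
    stop("profiles must sum to 1 within 1e-9")
  m <- (p + q) / 2
  kl <- function(a) {
    nz <- a > 0
    sum(a[nz] * log(a[nz] / m[nz], base = base))
  }
  (kl(p) + kl(q)) / 2
}

#' Pairwise Jensen-Shannon distance matrix
#'
#' @param table Numeric matrix or data frame, rows = samples, columns =
#'   taxa (relative abundances; metadata columns must be removed first).
#' @param base Logarithm base (see [jsd()]).
#' @return Symmetric matrix with zero diagonal and `jsd` entries, with the
#'   input row names.
#' @export
pairwise_jsd <- function(table, base = exp(1)) {
  m <- as.matrix(table)
  if (nrow(m) < 2L) stop("need at least 2 samples")
  n <- nrow(m)
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    out[i, j] <- out[j, i] <- jsd(m[i, ], m[j, ], base = base)
  out
}

#' Aggregate a JSD matrix by site groups and compare with Mann-Whitney U
#'
#' Splits the pairwise divergences into the three groups used to compare
#' gut locations: all unordered base-base pairs, all tip-tip pairs, and
#' all base-tip cross pairs, then runs one-sided Mann-Whitney U tests
#' between the groups. The tested direction is a required argument: the
#' biological question fixes which tail is of interest (e.g. "are
#' cross-site distances larger than within-base distances?") and no
#' default is meaningful. An exact test is used for group sizes up to 20
#' without ties; otherwise the normal approximation with tie correction.
#'
#' @param dist_matrix Symmetric divergence matrix from [pairwise_jsd()].
#' @param sites Character vector per sample, values `"base"` or `"tip"`.
#' @param alternative `"less"` or `"greater"`: the alternative hypothesis
#'   for the first-named group relative to the second in each comparison.
#' @return List with `groups` (named list of divergence vectors
#'   `base_base`, `tip_tip`, `base_tip`) and `tests` (data frame of
#'   pairwise group comparisons and one-sided p-values; comparisons with a
#'   group of fewer than 2 values are skipped with a warning).
#' @export
grouped_comparison <- function(dist_matrix, sites,
                               alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(sites) != nrow(dist_matrix))
    stop("'sites' must label every row of the matrix")
  if (!all(sites %in% c("base", "tip")))
    stop("'sites' values must be 'base' or 'tip'")
  ut <- upper.tri(dist_matrix)
  pair_site <- function(s1, s2) {
    sel <- ut & outer(sites == s1, sites == s2) |
           ut & outer(sites == s2, sites == s1)
    dist_matrix[sel]
  }
  groups <- list(base_base = pair_site("base", "base"),
                 tip_tip = pair_site("tip", "tip"),
                 base_tip = pair_site("base", "tip"))
  combos <- utils::combn(names(groups), 2L)
  rows <- list()
  for (k in seq_len(ncol(combos))) {
    g1 <- combos[1, k]; g2 <- combos[2, k]
    a <- groups[[g1]]; b <- groups[[g2]]
    if (length(a) < 2L || length(b) < 2L) {
      warning("skipping ", g1, " vs ", g2, ": a group has fewer than 2 values")
      next
    }
    p <- if (length(unique(c(a, b))) == 1L) 1 else
      suppressWarnings(stats::wilcox.test(a, b, alternative = alternative,
                                          exact = (length(a) <= 20 && length(b) <= 20 &&
                                                   !anyDuplicated(c(a, b))))$p.value)
    rows[[k]] <- data.frame(group1 = g1, group2 = g2,
                            n1 = length(a), n2 = length(b),
                            alternative = alternative, p_value = p)
  }
  list(groups = groups, tests = do.call(rbind, rows))
}
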