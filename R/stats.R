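#' Two-tailed Wilcoxon rank-sum comparison
#'
#' Rank-sum test with midranks for ties. For combined sample sizes of 12 or
#' fewer the two-tailed p-value is computed by exhaustive enumeration of all
#' group assignments; otherwise the normal approximation with tie correction
#' and continuity correction is used. The standardized statistic z is
#' reported in both branches (group `a` ranking high gives positive z).
#'
#' @param a,b numeric samples.
#' @param exact force (TRUE) or suppress (FALSE) exact enumeration; NULL
#'   switches automatically at n1 + n2 <= 12.
#' @return object of class `group_comparison`: list(z, p, p_adj = NA,
#'   n1, n2, statistic, method).
#' @export
wilcoxon_ranksum <- function(a, b, exact = NULL) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1 || n2 < 1) stop("empty sample")
  N <- n1 + n2
  r <- rank(c(a, b))
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  z <- if (sigma2 > 0) {
    cc <- sign(W - mu) * 0.5
    (W - mu - cc) / sqrt(sigma2)
  } else 0
  use_exact <- if (is.null(exact)) N <= 12 else isTRUE(exact)
  if (use_exact) {
    sums <- combn(N, n1, function(ix) sum(r[ix]))
    # two-tailed: assignments at least as extreme on either side
    p <- mean(abs(sums - mu) >= abs(W - mu) - 1e-9)
    method <- "exact"
  } else {
    p <- if (sigma2 > 0) 2 * pnorm(-abs(z)) else 1
    method <- "normal"
  }
  structure(list(z = z, p = min(p, 1), p_adj = NA_real_, n1 = n1, n2 = n2,
                 statistic = W, method = method),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum (%s): Z(%d,%d) = %.3f, p = %.4g",
              x$method, x$n1, x$n2, x$z, x$p))
  if (!is.na(x$p_adj)) cat(sprintf(", p_adj = %.4g", x$p_adj))
  cat("\n")
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone in the sorted order, capped at 1,
#' returned in the original input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same length and order.
#' @export
fdr_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' TFCE parameters
#'
#' @param E cluster-extent exponent.
#' @param H height exponent.
#' @param dh integration step; NULL uses max(|map|)/100.
#' @param connectivity neighbourhood (only 6-connectivity in 3D supported).
#' @return an object of class `tfce_params`.
#' @export
tfce_params <- function(E = 0.5, H = 2.0, dh = NULL, connectivity = 6) {
  stopifnot(E > 0, H > 0, is.null(dh) || dh > 0, connectivity == 6)
  structure(list(E = E, H = H, dh = dh, connectivity = connectivity),
            class = "tfce_params")
}

#' Threshold-free cluster enhancement
#'
#' For every voxel, integrates extent^E * height^H over thresholds from 0 up
#' to the voxel's value, where the extent is the size of the 6-connected
#' suprathreshold cluster containing the voxel. Positive and negative tails
#' are enhanced separately and their signs preserved.
#'
#' @param stat_map numeric 3D array.
#' @param params a [tfce_params()].
#' @param mask logical 3D array; voxels outside it are ignored and zero in
#'   the output.
#' @return enhanced 3D array.
#' @export
tfce_enhance <- function(stat_map, params = tfce_params(),
                         mask = array(TRUE, dim(stat_map))) {
  stopifnot(length(dim(stat_map)) == 3, all(dim(mask) == dim(stat_map)))
  if (any(!is.finite(stat_map[mask]))) stop("non-finite values inside mask")
  dh <- params$dh
  if (is.null(dh)) {
    mx <- max(abs(stat_map[mask]), 0)
    if (mx == 0) return(array(0, dim(stat_map)))
    dh <- mx / 100
  }
  dims <- dim(stat_map)
  pos <- pmax(stat_map, 0)
  neg <- pmax(-stat_map, 0)
  enh <- tfce_cpp(as.numeric(pos), as.integer(dims), as.logical(mask),
                  params$E, params$H, dh) -
         tfce_cpp(as.numeric(neg), as.integer(dims), as.logical(mask),
                  params$E, params$H, dh)
  array(enh, dims)
}

#' Randomization test with TFCE correction for voxel maps
#'
#' Two-group comparison of voxelwise maps: the observed statistic is the
#' absolute difference of group means per voxel, TFCE-enhanced; the null is
#' the distribution of the maximum enhanced statistic across relabellings of
#' the group assignment (exhaustive when all relabellings number at most
#' `n_perm`, Monte-Carlo otherwise). The returned voxelwise p-values are
#' family-wise error corrected.
#'
#' @param maps_a,maps_b lists of 3D arrays (one map per subject).
#' @param mask logical 3D array.
#' @param n_perm number of permutations.
#' @param params a [tfce_params()].
#' @param seed RNG seed for Monte-Carlo permutation draws.
#' @return list(p = 3D array of corrected p (NA outside mask),
#'   observed = enhanced observed map, null_max, n_perm_used, exhaustive).
#' @export
permutation_test <- function(maps_a, maps_b, mask, n_perm = 5000,
                             params = tfce_params(), seed = 1L) {
  na <- length(maps_a); nb <- length(maps_b)
  if (na < 2 || nb < 2) stop("need at least two maps per group")
  dims <- dim(maps_a[[1]])
  X <- vapply(c(maps_a, maps_b), function(m) as.numeric(m)[which(mask)],
              numeric(sum(mask)))
  if (all(apply(X, 1, function(r) max(r) - min(r)) == 0))
    stop("degenerate input: all maps identical")
  N <- na + nb
  labels_a <- seq_len(na)
  # fixed integration step from the observed statistic keeps the enhancement
  # comparable across permutations
  stat_vec <- function(ia) {
    abs(rowMeans(X[, ia, drop = FALSE]) -
        rowMeans(X[, setdiff(seq_len(N), ia), drop = FALSE]))
  }
  obs <- stat_vec(labels_a)
  dh <- params$dh
  if (is.null(dh)) dh <- max(obs, .Machine$double.eps) / 100
  enhance <- function(v) {
    m <- array(0, dims)
    m[which(mask)] <- v
    tfce_cpp(as.numeric(m), as.integer(dims), as.logical(mask),
             params$E, params$H, dh)[which(mask)]
  }
  obs_enh <- enhance(obs)

  n_comb <- choose(N, na)
  exhaustive <- n_comb <= n_perm
  perms <- if (exhaustive) {
    asplit(combn(N, na), 2)
  } else {
    with_seed(seed, replicate(n_perm, sample(N, na), simplify = FALSE))
  }
  null_max <- vapply(perms, function(ia) max(enhance(stat_vec(ia))),
                     numeric(1))
  if (!exhaustive) null_max <- c(null_max, max(obs_enh))  # include observed
  pv <- vapply(obs_enh, function(v) mean(null_max >= v - 1e-12), numeric(1))
  p <- array(NA_real_, dims)
  p[which(mask)] <- pv
  observed <- array(0, dims)
  observed[which(mask)] <- obs_enh
  list(p = p, observed = observed, null_max = null_max,
       n_perm_used = length(null_max), exhaustive = exhaustive)
}
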