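#' Permutation family-wise error control for a seed covariance fit
#'
#' Controls the family-wise error of the mass-univariate seed regression by
#' permuting the seed series across subjects and recording, per
#' permutation, the maximum |t| over all fitted voxels (`method =
#' "height"`, the default), the largest suprathreshold cluster size at the
#' `forming_p` threshold (`method = "extent"`), or both in a single
#' permutation sweep (`method = "both"`, declaring a voxel significant
#' when either correction does — the conventional "height or extent"
#' reporting rule for smoothed maps). With covariates present, seed and
#' response are first residualized on the nuisance design and the
#' residualized seed is permuted and re-residualized (Freedman-Lane
#' style), so nuisance structure is not broken by the permutation.
#'
#' The unpermuted statistic is included in the null set, making the
#' procedure exact under exchangeability: FWE p-values are
#' `(1 + #{perm >= s}) / (n_permutations + 1)` and significance means
#' `p_fwe <= alpha`.
#'
#' @param fit a [seed_covariance()] object.
#' @param n_permutations number of random permutations (>= 100).
#' @param alpha target family-wise error rate (default 0.05).
#' @param forming_p uncorrected two-sided voxel threshold used to form
#'   clusters and to flag voxels in reports (default 0.001).
#' @param method `"height"` (peak-level), `"extent"` (cluster-level) or
#'   `"both"`.
#' @param rng_seed integer seed for the permutation stream.
#' @param batch permutations per block (memory control).
#' @return object of class `fwe_report`: critical values (`threshold` for
#'   |t|, `threshold_extent` for cluster size where applicable), the
#'   permutation null distribution(s), per-voxel FWE p-values (height
#'   methods), the significant voxel set, and a cluster table of
#'   suprathreshold peaks (MNI mm, z, p_fwe, cluster size).
#' @export
fwe_threshold <- function(fit, n_permutations = 1000, alpha = 0.05,
                          forming_p = 0.001,
                          method = c("height", "extent", "both"),
                          rng_seed = 1L, batch = 250L) {
  stopifnot(inherits(fit, "seedcov"))
  method <- match.arg(method)
  P <- as.integer(n_permutations)
  if (P < 100) stop("need at least 100 permutations")
  if ((P + 1) * alpha < 1)
    stop("too few permutations for alpha = ", alpha,
         ": need at least ", ceiling(1 / alpha) - 1, " permutations")
  do_h <- method %in% c("height", "both")
  do_e <- method %in% c("extent", "both")
  n <- fit$n_subjects
  df <- fit$df
  X <- fit$X
  s <- X[, 2]
  Z <- X[, -2, drop = FALSE]

  # residualize seed and response on the nuisance design
  ZtZi <- chol2inv(chol(crossprod(Z)))
  hz <- function(M) M - Z %*% (ZtZi %*% crossprod(Z, M))
  s_r <- drop(hz(matrix(s)))
  Yr <- hz(fit$Y)
  ynorm <- sqrt(colSums(Yr^2))
  good <- ynorm > 0
  Yn <- sweep(Yr[, good, drop = FALSE], 2, ynorm[good], `/`)

  r2t <- function(r) {
    r <- pmin(pmax(r, -1), 1)
    r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  }
  t_form <- stats::qt(forming_p / 2, df, lower.tail = FALSE)
  # |r| equivalent of the forming t threshold, for cheap thresholding
  r_form <- t_form / sqrt(t_form^2 + df)

  lin_all <- fit$fit_cols[good]
  obs_tg <- fit$t[lin_all]

  max_cluster <- function(tvec, lin) {
    supra <- which(abs(tvec) > t_form)
    if (length(supra) == 0) return(0)
    max(.cluster_sizes(lin[supra], fit$grid$dims))
  }

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(rng_seed)
  null_h <- if (do_h) numeric(P)
  null_e <- if (do_e) numeric(P)
  done <- 0L
  while (done < P) {
    nb <- min(batch, P - done)
    S <- matrix(0, n, nb)
    for (b in seq_len(nb)) S[, b] <- s_r[sample.int(n)]
    S <- hz(S)
    sn <- sqrt(colSums(S^2))
    S <- sweep(S, 2, pmax(sn, .Machine$double.eps), `/`)
    R <- crossprod(S, Yn)
    aR <- abs(R)
    for (b in seq_len(nb)) {
      row <- aR[b, ]
      if (do_h) null_h[done + b] <- r2t(max(row))
      if (do_e) {
        supra <- which(row > r_form)
        null_e[done + b] <-
          if (length(supra) == 0) 0
          else max(.cluster_sizes(lin_all[supra], fit$grid$dims))
      }
    }
    done <- done + nb
  }

  # p of statistic s within a null set (unpermuted value included)
  p_within <- function(s, null_sorted, m) {
    (m - findInterval(s - 1e-12, null_sorted)) / m
  }

  sig_h <- sig_e <- integer(0)
  p_fwe <- thr_h <- thr_e <- NULL
  if (do_h) {
    obs_h <- max(abs(obs_tg), 0)
    null_all_h <- sort(c(obs_h, null_h))
    k <- floor(alpha * (P + 1))
    thr_h <- sort(null_all_h, decreasing = TRUE)[k]
    p_fwe <- rep(NA_real_, length(fit$t))
    p_fwe[lin_all] <- p_within(abs(obs_tg), null_all_h, P + 1)
    sig_h <- lin_all[p_fwe[lin_all] <= alpha & !is.na(obs_tg)]
  }
  if (do_e) {
    obs_e <- max_cluster(obs_tg, lin_all)
    null_all_e <- sort(c(obs_e, null_e))
    thr_e <- sort(null_all_e, decreasing = TRUE)[floor(alpha * (P + 1))]
    supra <- lin_all[abs(obs_tg) > t_form & !is.na(obs_tg)]
    if (length(supra) > 0) {
      memb <- .cluster_membership(supra, fit$grid$dims)
      sizes <- tabulate(memb)
      sig_e <- supra[p_within(sizes[memb], null_all_e, P + 1) <= alpha]
    }
  }
  sig_lin <- sort(union(sig_h, sig_e))

  clusters <- .cluster_table(fit, sig_lin, p_fwe, P)
  structure(list(
    seed_name = fit$seed_name,
    voxelwise_p_uncorrected = forming_p,
    fwe_p = alpha,
    method = switch(method,
                    height = "permutation_maxT",
                    extent = "permutation_maxClusterSize",
                    both = "permutation_maxT_or_maxClusterSize"),
    n_permutations = P,
    threshold = if (do_h) thr_h else thr_e,
    threshold_extent = thr_e,
    threshold_z = if (do_h) t_to_z(thr_h, df) else NA_real_,
    df = df,
    null_max = if (do_h) null_h else null_e,
    null_max_extent = null_e,
    p_fwe = p_fwe,
    n_significant = length(sig_lin),
    significant_voxels = sig_lin,
    significant_voxels_height = sig_h,
    significant_voxels_extent = sig_e,
    any_significant = length(sig_lin) > 0,
    clusters = clusters,
    rng_seed = rng_seed
  ), class = "fwe_report")
}

#' @export
print.fwe_report <- function(x, ...) {
  cat("Permutation FWE report ('", x$seed_name, "'), method ", x$method,
      "\n", sep = "")
  cat("  ", x$n_permutations, " permutations, alpha = ", x$fwe_p,
      ", forming p = ", x$voxelwise_p_uncorrected, "\n", sep = "")
  cat("  critical value = ", format(x$threshold, digits = 5),
      ", significant voxels = ", x$n_significant, "\n", sep = "")
  if (nrow(x$clusters) > 0) {
    cat("  clusters:\n")
    print(x$clusters, row.names = FALSE)
  }
  invisible(x)
}

# sizes of 6-connected components among the given linear voxel indices
.cluster_sizes <- function(lin, dims) {
  tabulate(.cluster_membership(lin, dims))
}

.cluster_membership <- function(lin, dims) {
  m <- length(lin)
  if (m == 1) return(1L)
  co <- arrayInd(lin, dims)
  off <- c(1L, dims[1], dims[1] * dims[2])
  edges <- NULL
  for (a in 1:3) {
    ok <- co[, a] < dims[a]
    nb <- match(lin[ok] + off[a], lin)
    hit <- !is.na(nb)
    if (any(hit))
      edges <- rbind(edges, cbind(which(ok)[hit], nb[hit]))
  }
  g <- igraph::make_empty_graph(n = m, directed = FALSE)
  if (!is.null(edges))
    g <- igraph::add_edges(g, as.vector(t(edges)))
  igraph::components(g)$membership
}

# peak table for significant voxels of a thresholded fit
.cluster_table <- function(fit, sig_lin, p_fwe, P) {
  empty <- data.frame(cluster = integer(0), size = integer(0),
                      x = numeric(0), y = numeric(0), z_mm = numeric(0),
                      z = numeric(0), p_fwe = numeric(0))
  if (length(sig_lin) == 0) return(empty)
  memb <- .cluster_membership(sig_lin, fit$grid$dims)
  out <- lapply(sort(unique(memb)), function(k) {
    vox <- sig_lin[memb == k]
    peak <- vox[which.max(abs(fit$z[vox]))]
    mm <- voxel_to_mni(fit$grid, arrayInd(peak, fit$grid$dims)[1, ])
    data.frame(cluster = k, size = sum(memb == k),
               x = mm[1], y = mm[2], z_mm = mm[3],
               z = fit$z[peak],
               p_fwe = if (!is.null(p_fwe)) p_fwe[peak] else NA_real_)
  })
  do.call(rbind, out)
}
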