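# Community comparison from first principles: Bray-Curtis dissimilarity,
# one-factor perMANOVA with a permutation null, and non-metric
# multidimensional scaling (Kruskal stress-1, isotonic regression via
# pool-adjacent-violators, iterative majorization with a monotone-stress
# safeguard).

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` over non-negative rows.
#'
#' @param x numeric matrix, rows = samples (e.g. an RRA table)
#' @return symmetric n x n matrix with zero diagonal, entries in \[0, 1\]
#' @export
bray_curtis <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("Bray-Curtis needs non-negative data")
  if (any(rowSums(x) == 0)) {
    stop("all-zero row(s): dissimilarity undefined for ",
         paste(rownames(x)[rowSums(x) == 0], collapse = ", "))
  }
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- sum(abs(x[i, ] - x[j, ])) / sum(x[i, ] + x[j, ])
    }
  }
  d
}

# Sum of squared within-group dissimilarities divided by group size,
# computed for many label permutations at once.  D2 = squared distance
# matrix; perm = n x P matrix of label vectors (integer groups).
.ss_within <- function(D2, perm, groups) {
  P <- ncol(perm)
  ssw <- numeric(P)
  for (g in groups) {
    Z <- perm == g
    ng <- colSums(Z)
    # 1'_g D2 1_g = 2 * sum of within-group pairs
    q <- colSums((D2 %*% Z) * Z)
    ssw <- ssw + q / (2 * ng)
  }
  ssw
}

#' One-factor perMANOVA on a distance matrix
#'
#' Partitions the total sum of squared dissimilarities
#' (`SS_total = sum_{i<j} d_ij^2 / n`) into between- and within-group
#' components, forms the pseudo-F statistic
#' `F = (SS_between / (a - 1)) / (SS_within / (n - a))` and estimates its
#' null distribution by unrestricted permutation of the group labels.  The
#' reported p-value includes the observed statistic:
#' `p = (1 + #permuted F >= F_obs) / (1 + n_perm)`.
#'
#' @param d distance matrix (n x n, symmetric) or `dist`
#' @param groups factor-like group labels, >= 2 groups of >= 2 members
#' @param n_perm number of random permutations (default 999), ignored when
#'   `exhaustive = TRUE`
#' @param seed integer seed for the permutation stream
#' @param exhaustive enumerate all `n!` label permutations (exact test;
#'   only sensible for n <= 9)
#' @return object of class `permanova_result`: list with `f`, `r_squared`,
#'   `p_value`, `n_perm`, `seed`, `ss` (components) and `df`
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1, exhaustive = FALSE) {
  d <- as.matrix(d)
  n <- nrow(d)
  groups <- as.integer(factor(groups))
  stopifnot(length(groups) == n)
  tabn <- table(groups)
  if (length(tabn) < 2) stop("need at least two groups")
  if (any(tabn < 2)) stop("singleton group(s) not allowed")
  a <- length(tabn)
  D2 <- d^2
  ss_total <- sum(D2[upper.tri(D2)]) / n
  glev <- sort(unique(groups))
  f_stat <- function(lab_mat) {
    ssw <- .ss_within(D2, lab_mat, glev)
    ssb <- ss_total - ssw
    (ssb / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- f_stat(matrix(groups, ncol = 1))
  ssw_obs <- .ss_within(D2, matrix(groups, ncol = 1), glev)
  if (exhaustive) {
    perms <- .all_permutations(n)
    lab <- apply(perms, 2, function(p) groups[p])
    f_perm <- f_stat(lab)
    n_perm_eff <- ncol(perms) - 1 # observed ordering is among them
    p <- (1 + sum(f_perm[-1] >= f_obs)) / (1 + n_perm_eff)
  } else {
    lab <- with_seed(seed, {
      matrix(unlist(lapply(seq_len(n_perm), function(i) sample(groups))),
             nrow = n)
    })
    f_perm <- f_stat(lab)
    p <- (1 + sum(f_perm >= f_obs)) / (1 + n_perm)
    n_perm_eff <- n_perm
  }
  structure(list(f = f_obs, r_squared = (ss_total - ssw_obs) / ss_total,
                 p_value = p, n_perm = n_perm_eff, seed = seed,
                 ss = c(total = ss_total, within = ssw_obs,
                        between = ss_total - ssw_obs),
                 df = c(between = a - 1, within = n - a)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("perMANOVA: F=%.4g R2=%.4g p=%.4g (%d permutations)\n",
              x$f, x$r_squared, x$p_value, x$n_perm))
  invisible(x)
}

# All permutations of 1..n as an n x n! matrix (identity first).
.all_permutations <- function(n) {
  if (n > 9) stop("exhaustive enumeration limited to n <= 9")
  rec <- function(v) {
    if (length(v) == 1) return(matrix(v, 1, 1))
    out <- NULL
    for (i in seq_along(v)) {
      sub <- rec(v[-i])
      out <- cbind(out, rbind(rep(v[i], ncol(sub)), sub))
    }
    out
  }
  rec(seq_len(n))
}

# Weighted pool-adjacent-violators: non-decreasing fit of y with weights w.
pava <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  if (n == 0) return(numeric(0))
  vals <- y; wts <- w; sizes <- rep(1L, n); m <- 0L
  for (i in seq_len(n)) {
    m <- m + 1L
    vals[m] <- y[i]; wts[m] <- w[i]; sizes[m] <- 1L
    while (m > 1L && vals[m - 1L] > vals[m]) {
      tw <- wts[m - 1L] + wts[m]
      vals[m - 1L] <- (wts[m - 1L] * vals[m - 1L] + wts[m] * vals[m]) / tw
      wts[m - 1L] <- tw
      sizes[m - 1L] <- sizes[m - 1L] + sizes[m]
      m <- m - 1L
    }
  }
  rep(vals[seq_len(m)], sizes[seq_len(m)])
}

# Kruskal stress-1 of a configuration against input dissimilarities.
# Ties in the input dissimilarities are averaged within tie blocks before
# isotonic regression.  Returns the stress and the disparities.
.nmds_stress <- function(delta_rank_order, tie_block, conf_d) {
  dvec <- conf_d[delta_rank_order]
  dhat_block <- tapply(dvec, tie_block, mean)
  dhat <- pava(as.numeric(dhat_block),
               w = as.numeric(table(tie_block)))[tie_block]
  s <- sqrt(sum((dvec - dhat)^2) / sum(dvec^2))
  dh <- numeric(length(dvec))
  dh[seq_along(dvec)] <- dhat
  list(stress = s, dhat_ordered = dh)
}

#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Minimizes Kruskal stress-1 between configuration distances and the
#' monotone (isotonic) regression of those distances on the rank order of
#' the input dissimilarities.  Each start (the first is classical MDS, the
#' rest random) is refined by iterative majorization (Guttman transform)
#' with step halving, guaranteeing a non-increasing stress trace within a
#' start; the best final stress over all starts is returned.
#'
#' @param d dissimilarity matrix (n x n) or `dist`, n >= 4
#' @param k embedding dimension (default 2)
#' @param n_starts number of starts (default 20)
#' @param max_iter iterations per start (default 300)
#' @param tol stress-improvement convergence tolerance (default 1e-6)
#' @param seed integer seed for the random starts
#' @return object of class `nmds_result`: list with `points` (n x k,
#'   centered), `stress`, `converged`, `best_start`, `stress_trace` (of the
#'   winning start), `seed`
#' @export
nmds <- function(d, k = 2, n_starts = 20, max_iter = 300, tol = 1e-6,
                 seed = 1) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 4) stop("nmds needs at least 4 points")
  if (!isTRUE(all.equal(d, t(d))) || any(diag(d) != 0)) {
    stop("d must be a symmetric dissimilarity matrix with zero diagonal")
  }
  iu <- which(upper.tri(d))
  delta <- d[iu]
  ord <- order(delta)
  tie_block <- as.integer(factor(delta[ord])) # ties share a block

  conf_dist_vec <- function(X) as.matrix(dist(X))[iu]

  run_start <- function(X) {
    X <- scale(X, center = TRUE, scale = FALSE)
    dv <- conf_dist_vec(X)
    st <- .nmds_stress(ord, tie_block, dv)
    trace <- st$stress
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      # disparities in original pair order
      dhat <- numeric(length(dv))
      dhat[ord] <- st$dhat_ordered
      # Guttman transform with the current disparities
      B <- matrix(0, n, n)
      dm <- matrix(0, n, n); dm[iu] <- dv; dm <- dm + t(dm)
      dhm <- matrix(0, n, n); dhm[iu] <- dhat; dhm <- dhm + t(dhm)
      ratio <- ifelse(dm > 0, dhm / dm, 0)
      B <- -ratio
      diag(B) <- -rowSums(B)
      X_new <- B %*% X / n
      # step-halving safeguard: accept only non-increasing stress
      step <- 1
      repeat {
        X_try <- X + step * (X_new - X)
        dv_try <- conf_dist_vec(X_try)
        st_try <- .nmds_stress(ord, tie_block, dv_try)
        if (st_try$stress <= trace[length(trace)] + 1e-15) break
        step <- step / 2
        if (step < 1e-4) { st_try <- st; dv_try <- dv; X_try <- X; break }
      }
      improved <- trace[length(trace)] - st_try$stress
      X <- X_try; dv <- dv_try; st <- st_try
      trace <- c(trace, st$stress)
      if (improved >= 0 && improved < tol) { converged <- TRUE; break }
    }
    list(X = scale(X, center = TRUE, scale = FALSE), stress = st$stress,
         trace = trace, converged = converged)
  }

  starts <- with_seed(seed, {
    s <- list(cmdscale(d, k = k))
    if (ncol(s[[1]]) < k) { # degenerate classical MDS: pad with noise
      s[[1]] <- cbind(s[[1]], matrix(rnorm(n * (k - ncol(s[[1]])), sd = 1e-3),
                                     n))
    }
    for (i in seq_len(max(0, n_starts - 1))) {
      s[[i + 1]] <- matrix(rnorm(n * k), n, k)
    }
    s
  })
  fits <- lapply(starts, run_start)
  best <- which.min(vapply(fits, `[[`, numeric(1), "stress"))
  fit <- fits[[best]]
  pts <- fit$X
  rownames(pts) <- rownames(d)
  structure(list(points = pts, stress = fit$stress,
                 converged = fit$converged, best_start = best,
                 stress_trace = fit$trace, seed = seed),
            class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("NMDS: stress=%.5f converged=%s (best start %d of trace length %d)\n",
              x$stress, x$converged, x$best_start, length(x$stress_trace)))
  invisible(x)
}
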