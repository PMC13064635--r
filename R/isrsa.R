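#' Pairwise similarity matrix from per-subject observations
#'
#' Converts Euclidean distances between subjects' observations (absolute
#' difference for scalars) to similarity scores on (0, 1]:
#' \deqn{s_{ij} = 1 / (1 + d(S_i, S_j)).}
#'
#' @param values numeric vector (one scalar per subject) or matrix
#'   (subjects x features).
#' @param scale if TRUE z-score the input before computing distances
#'   (default FALSE: raw scale, as in the similarity formula).
#' @return symmetric n x n matrix of class \code{"harm_similarity"} with unit
#'   diagonal and entries in (0, 1].
#' @examples
#' similarity_matrix(c(-10, -8, 0))   # off-diagonals 1/3, 1/11, 1/9
#' @export
similarity_matrix <- function(values, scale = FALSE) {
  x <- if (is.matrix(values)) values else matrix(values, ncol = 1)
  if (nrow(x) < 2) stop("need at least 2 subjects")
  if (any(!is.finite(x))) stop("non-finite values in input")
  if (scale) x <- base::scale(x)
  d <- as.matrix(stats::dist(x))
  s <- 1 / (1 + d)
  rownames(s) <- colnames(s) <- rownames(x) %||% seq_len(nrow(x))
  structure(s, class = c("harm_similarity", "matrix", "array"),
            label = deparse(substitute(values))[1])
}

# indices of all unordered subject pairs (i < j)
dyad_index <- function(n) {
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
}

#' Voxelwise dyadic regression of neural similarity on parameter similarity
#'
#' For every voxel, neural similarity between each unordered pair of subjects
#' (the \code{1/(1+d)} transform of the absolute difference of their betas at
#' that voxel) is regressed on similarity in the agreeability parameter with
#' similarity in the maximin parameter as a covariate.  Because every subject
#' appears in \eqn{n - 1} dyads, the model includes multi-membership random
#' intercepts: each dyad loads on both members' subject intercepts, which
#' share one variance component.  The mixed model is estimated by REML using
#' a one-time eigendecomposition of the dyad membership Gram matrix, so the
#' per-voxel cost is a one-dimensional variance-ratio optimisation.
#'
#' Inference for the agreeability-similarity coefficient is a Wald normal
#' approximation by default; \code{n_perm > 0} adds a subject-level
#' permutation test (shuffling agreeability values over subjects and
#' rebuilding the similarity matrix) whose p-value is returned alongside.
#'
#' @param betas subjects x voxels matrix (e.g.
#'   \code{\link{generate_beta_maps}}).
#' @param phi_sim,alpha_sim subject similarity matrices from
#'   \code{\link{similarity_matrix}}.
#' @param method \code{"lmm"} (multi-membership random intercepts, default)
#'   or \code{"ols"} (no random effects; mainly for oracle checks).
#' @param n_perm number of subject-level permutations (0 = none).
#' @param seed seed for the permutation test.
#' @return data.frame of class \code{"harm_dyadic"}: one row per voxel with
#'   \code{estimate} (agreeability-similarity coefficient), \code{se},
#'   \code{t}, \code{p}, optional \code{p_perm}, and \code{undefined}
#'   (TRUE where the voxel's neural similarity had zero variance; such
#'   voxels carry NA statistics rather than failing).
#' @export
dyadic_regress_voxelwise <- function(betas, phi_sim, alpha_sim,
                                     method = c("lmm", "ols"),
                                     n_perm = 0, seed = 1L) {
  method <- match.arg(method)
  B <- as.matrix(betas)
  n <- nrow(B)
  if (n < 3) stop("need at least 3 subjects (>= 3 dyads)")
  if (!all(dim(phi_sim) == n) || !all(dim(alpha_sim) == n))
    stop("similarity matrices must match the number of subjects")
  ij <- dyad_index(n)
  X <- cbind(intercept = 1, phi_sim = phi_sim[ij],
             alpha_sim = alpha_sim[ij])
  Y <- 1 / (1 + abs(B[ij[, 1], , drop = FALSE] - B[ij[, 2], , drop = FALSE]))
  res <- dyadic_lmm(Y, X, ij, n, method)
  out <- data.frame(voxel = seq_len(ncol(B)), estimate = res$beta,
                    se = res$se, t = res$t, p = res$p,
                    undefined = res$undefined)
  if (n_perm > 0) {
    phi_col <- 2L
    cnt <- rep(0L, ncol(B))
    obs <- abs(res$t)
    with_seed(seed, for (b in seq_len(n_perm)) {
      perm <- sample.int(n)
      Xp <- X
      Xp[, phi_col] <- phi_sim[perm, perm][ij]
      rp <- dyadic_lmm(Y, Xp, ij, n, method)
      cnt <- cnt + as.integer(abs(rp$t) >= obs & !is.na(rp$t))
    })
    out$p_perm <- ifelse(is.na(obs), NA_real_, (cnt + 1) / (n_perm + 1))
  }
  attr(out, "grid_dim") <- attr(betas, "grid_dim")
  class(out) <- c("harm_dyadic", "data.frame")
  out
}

# Mixed (or OLS) fit of many response vectors sharing one design.
# Y: dyads x voxels, X: dyads x p, ij: dyad membership.  Returns the
# phi_sim coefficient statistics per voxel.
dyadic_lmm <- function(Y, X, ij, n, method = "lmm") {
  D <- nrow(X); p <- ncol(X)
  undef <- apply(Y, 2, function(y) stats::var(y) == 0)
  beta <- se <- tv <- pv <- rep(NA_real_, ncol(Y))
  ok <- which(!undef)
  if (method == "ols") {
    XtXi <- solve(crossprod(X))
    bh <- XtXi %*% crossprod(X, Y[, ok, drop = FALSE])
    fitted <- X %*% bh
    rss <- colSums((Y[, ok, drop = FALSE] - fitted)^2)
    s2 <- rss / (D - p)
    beta[ok] <- bh[2, ]
    se[ok] <- sqrt(XtXi[2, 2] * s2)
  } else {
    # multi-membership incidence: dyad d loads on subjects ij[d,1], ij[d,2]
    Z <- matrix(0, D, n)
    Z[cbind(seq_len(D), ij[, 1])] <- 1
    Z[cbind(seq_len(D), ij[, 2])] <- 1
    K <- tcrossprod(Z)
    eg <- eigen(K, symmetric = TRUE)
    U <- eg$vectors; ev <- pmax(eg$values, 0)
    Xr <- crossprod(U, X)
    Yr <- crossprod(U, Y[, ok, drop = FALSE])
    reml_stats <- function(yr, lambda) {
      w <- 1 / (1 + lambda * ev)
      XtWX <- crossprod(Xr, Xr * w)
      XtWy <- crossprod(Xr, yr * w)
      bh <- solve(XtWX, XtWy)
      rss <- sum(w * (yr - Xr %*% bh)^2)
      s2 <- rss / (D - p)                     # REML scale
      crit <- -0.5 * (sum(log(1 + lambda * ev)) + (D - p) * log(rss) +
                        determinant(XtWX, logarithm = TRUE)$modulus)
      list(crit = as.numeric(crit), bh = bh, s2 = s2, XtWX = XtWX)
    }
    for (v in ok) {
      yr <- Yr[, match(v, ok)]
      opt <- stats::optimize(function(ll) -reml_stats(yr, exp(ll))$crit,
                             interval = c(-12, 8))
      st <- reml_stats(yr, exp(opt$minimum))
      covb <- solve(st$XtWX) * st$s2
      beta[v] <- st$bh[2]
      se[v] <- sqrt(covb[2, 2])
    }
  }
  tv <- beta / se
  pv <- 2 * stats::pnorm(-abs(tv))
  list(beta = beta, se = se, t = tv, p = pv, undefined = undef)
}

#' Benjamini-Hochberg FDR thresholding
#'
#' @param p vector of p-values in [0, 1] (NAs allowed; they never survive).
#' @param q FDR level (default 0.05).
#' @return list with \code{adjusted} (BH-adjusted values), \code{survivors}
#'   (logical, adjusted < q).
#' @examples
#' fdr_threshold(c(0.01, 0.02, 0.03, 0.04))$survivors   # all TRUE
#' @export
fdr_threshold <- function(p, q = 0.05) {
  if (length(p) == 0) stop("empty p-value vector")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = "BH")
  list(adjusted = adj, survivors = !is.na(adj) & adj < q)
}

#' Extract contiguous voxel clusters
#'
#' Labels connected components of surviving voxels on the 3-D grid and
#' discards components smaller than \code{min_size}.
#'
#' @param survivors logical vector (length prod(grid_dim)) or logical 3-D
#'   array of surviving voxels.
#' @param grid_dim integer length-3 grid dimensions (taken from the array if
#'   omitted).
#' @param min_size minimum cluster size in voxels (default 5).
#' @param connectivity 6 (face), 18 (face+edge) or 26 (face+edge+corner)
#'   neighbourhood; default 6.
#' @return list with \code{labels} (integer 3-D array, 0 = background),
#'   \code{clusters} (data.frame with \code{label}, \code{size}).
#' @export
extract_clusters <- function(survivors, grid_dim = NULL, min_size = 5,
                             connectivity = 6) {
  if (is.array(survivors) && length(dim(survivors)) == 3)
    grid_dim <- dim(survivors)
  if (is.null(grid_dim)) stop("grid geometry unknown; supply grid_dim")
  stopifnot(length(grid_dim) == 3, prod(grid_dim) == length(survivors))
  mask <- array(as.logical(survivors), dim = grid_dim)
  offs <- neighbour_offsets(connectivity)
  labels <- array(0L, dim = grid_dim)
  lab <- 0L
  sizes <- integer(0)
  idx <- which(mask & labels == 0L, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    start <- idx[r, ]
    if (labels[start[1], start[2], start[3]] != 0L) next
    lab <- lab + 1L
    queue <- matrix(start, ncol = 3)
    labels[start[1], start[2], start[3]] <- lab
    sz <- 1L
    while (nrow(queue) > 0) {
      cur <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      nb <- sweep(offs, 2, cur, "+")
      keep <- nb[, 1] >= 1 & nb[, 1] <= grid_dim[1] &
        nb[, 2] >= 1 & nb[, 2] <= grid_dim[2] &
        nb[, 3] >= 1 & nb[, 3] <= grid_dim[3]
      nb <- nb[keep, , drop = FALSE]
      for (q in seq_len(nrow(nb))) {
        v <- nb[q, ]
        if (mask[v[1], v[2], v[3]] && labels[v[1], v[2], v[3]] == 0L) {
          labels[v[1], v[2], v[3]] <- lab
          queue <- rbind(queue, v)
          sz <- sz + 1L
        }
      }
    }
    sizes[lab] <- sz
  }
  small <- which(sizes < min_size)
  if (length(small)) {
    labels[labels %in% small] <- 0L
  }
  keep_labs <- setdiff(which(sizes >= min_size), 0L)
  relab <- array(0L, dim = grid_dim)
  clusters <- data.frame(label = integer(0), size = integer(0))
  if (length(keep_labs)) {
    ord <- keep_labs[order(sizes[keep_labs], decreasing = TRUE)]
    for (i in seq_along(ord)) relab[labels == ord[i]] <- i
    clusters <- data.frame(label = seq_along(ord), size = sizes[ord])
  }
  list(labels = relab, clusters = clusters)
}

neighbour_offsets <- function(connectivity = 6) {
  all_off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  all_off <- all_off[rowSums(all_off != 0) > 0, , drop = FALSE]
  manh <- rowSums(abs(all_off))
  switch(as.character(connectivity),
         "6" = all_off[manh == 1, , drop = FALSE],
         "18" = all_off[manh <= 2, , drop = FALSE],
         "26" = all_off,
         stop("connectivity must be 6, 18 or 26"))
}

#' Full IS-RSA analysis
#'
#' Runs the voxelwise dyadic regression of neural similarity on
#' agreeability-parameter similarity (controlling maximin similarity),
#' applies Benjamini-Hochberg FDR thresholding to the agreeability
#' coefficient's p-values, and extracts contiguous surviving clusters of at
#' least \code{min_cluster} voxels.
#'
#' @param betas subjects x voxels beta-map matrix with a \code{grid_dim}
#'   attribute (see \code{\link{generate_beta_maps}}) or an explicit
#'   \code{grid_dim} argument.
#' @param phi,alpha per-subject parameter vectors (similarity matrices are
#'   built with \code{\link{similarity_matrix}}), or ready-made similarity
#'   matrices.
#' @param q FDR level (default 0.05).
#' @param min_cluster minimum cluster size (default 5).
#' @param connectivity cluster connectivity (default 6).
#' @param grid_dim optional grid dimensions.
#' @param scale z-score parameters before the distance computation
#'   (default FALSE).
#' @param ... passed to \code{\link{dyadic_regress_voxelwise}}.
#' @return list of class \code{"harm_isrsa"}: \code{voxels} (the dyadic
#'   regression table with BH-adjusted \code{q} values), \code{survivors},
#'   \code{clusters}, \code{labels} (3-D label array), \code{settings}.
#' @export
isrsa <- function(betas, phi, alpha, q = 0.05, min_cluster = 5,
                  connectivity = 6, grid_dim = NULL, scale = FALSE, ...) {
  grid_dim <- grid_dim %||% attr(betas, "grid_dim")
  if (is.null(grid_dim)) stop("grid geometry unknown; supply grid_dim")
  as_sim <- function(v) if (inherits(v, "harm_similarity") || is.matrix(v)) v
                        else similarity_matrix(v, scale = scale)
  phi_sim <- as_sim(phi); alpha_sim <- as_sim(alpha)
  vox <- dyadic_regress_voxelwise(betas, phi_sim, alpha_sim, ...)
  fdr <- fdr_threshold(vox$p, q = q)
  vox$q <- fdr$adjusted
  cl <- extract_clusters(fdr$survivors, grid_dim = grid_dim,
                         min_size = min_cluster, connectivity = connectivity)
  vox$cluster <- as.integer(cl$labels)[vox$voxel]
  structure(list(voxels = vox, survivors = fdr$survivors,
                 clusters = cl$clusters, labels = cl$labels,
                 settings = list(q = q, min_cluster = min_cluster,
                                 connectivity = connectivity,
                                 grid_dim = grid_dim)),
            class = "harm_isrsa")
}

#' @export
print.harm_isrsa <- function(x, ...) {
  cat("IS-RSA dyadic regression over", nrow(x$voxels), "voxels\n")
  cat("  FDR q <", x$settings$q, ":", sum(x$survivors), "surviving voxels;",
      nrow(x$clusters), "cluster(s) of >=", x$settings$min_cluster,
      "voxels\n")
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE)
  invisible(x)
}
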