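# GMM-UBM detector. The universal background model (UBM) is a diagonal-
# covariance Gaussian mixture trained by EM on background audio; the target
# model shares the UBM's weights and variances and differs only in its means,
# which are shifted toward the target data by classical MAP ("means-only")
# adaptation with relevance factor r. Frames are scored by the
# log-likelihood ratio log p(x|target) - log p(x|UBM).

#' Train a diagonal-covariance Gaussian mixture (the UBM)
#'
#' EM with k-means++ initialisation, a per-dimension variance floor at
#' `floor_frac` of the global variance, and re-seeding of emptied components
#' from the highest-variance component. The training log-likelihood is
#' non-decreasing; iteration stops when its relative improvement falls below
#' `tol` or after `max_iter` passes.
#'
#' @param x feature matrix (n_frames x d), standardized.
#' @param k number of mixture components (64 is the desk-scale default; the
#'   full-scale configuration uses 512).
#' @param seed integer seed for initialisation.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @param floor_frac variance floor as a fraction of global variance.
#' @return a `ubm_model`: `weights`, `means` (k x d), `variances` (k x d),
#'   `loglik_trace`, `k`, `seed`.
#' @export
train_ubm <- function(x, k = 64, seed = 1L, tol = 1e-5, max_iter = 200,
                      floor_frac = 1e-4) {
  n <- nrow(x); d <- ncol(x)
  if (k > n) stop("k = ", k, " exceeds the number of frames (", n, ")")
  gvar <- apply(x, 2, stats::var)
  vfloor <- pmax(floor_frac * gvar, 1e-10)
  withr::with_seed(seed, {
    x2 <- x^2
    mu <- kmeanspp_centers(x, k)
    sigma2 <- matrix(rep(gvar, each = k), k, d)
    w <- rep(1 / k, k)
    ll_trace <- numeric(0)
    prev <- -Inf
    for (iter in seq_len(max_iter)) {
      e <- gmm_posteriors(x, w, mu, sigma2, x2)
      ll <- e$loglik
      ll_trace <- c(ll_trace, ll)
      nk <- colSums(e$post)
      empty <- which(nk < 1e-8)
      if (length(empty)) {
        big <- which.max(rowSums(sigma2))
        for (j in empty) {
          mu[j, ] <- mu[big, ] + stats::rnorm(d, 0, sqrt(sigma2[big, ]) / 10)
          sigma2[j, ] <- sigma2[big, ]
          nk[j] <- 1e-8
        }
        message("re-seeded ", length(empty), " empty component(s) at iter ", iter)
      }
      w <- nk / sum(nk)
      mu <- crossprod(e$post, x) / nk
      ex2 <- crossprod(e$post, x2) / nk
      sigma2 <- pmax(ex2 - mu^2, rep(vfloor, each = k))
      if (is.finite(prev) && (ll - prev) < tol * abs(ll)) break
      prev <- ll
    }
    structure(list(weights = w, means = mu, variances = sigma2,
                   loglik_trace = ll_trace, k = k, seed = seed),
              class = "ubm_model")
  })
}

# k-means++ seeding (uses current RNG stream)
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k - 1) + 1) {
    p <- d2 / sum(d2)
    centers[j, ] <- x[sample.int(n, 1, prob = p), ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

# log densities per component: n x k matrix, and posteriors/loglik.
# x2 = x^2 may be passed in to avoid recomputation across EM iterations.
gmm_logdens <- function(x, mu, sigma2, x2 = NULL) {
  d <- ncol(x)
  if (is.null(x2)) x2 <- x^2
  inv <- 1 / sigma2                       # k x d
  a <- x2 %*% t(inv)                      # n x k
  b <- x %*% t(mu * inv)                  # n x k
  cst <- rowSums(mu^2 * inv) + rowSums(log(sigma2)) + d * log(2 * pi)
  -0.5 * sweep(a - 2 * b, 2, cst, `+`)
}

gmm_posteriors <- function(x, w, mu, sigma2, x2 = NULL) {
  lg <- sweep(gmm_logdens(x, mu, sigma2, x2), 2, log(w), `+`)
  m <- lg[cbind(seq_len(nrow(lg)), max.col(lg, ties.method = "first"))]
  e <- exp(lg - m)
  s <- rowSums(e)
  list(post = e / s, logdens = m + log(s),
       loglik = sum(m + log(s)))
}

#' Mixture log-density of frames under a model
#'
#' Full log-sum-exp over components.
#' @param x feature matrix.
#' @param model a `ubm_model` or `target_model`.
#' @return numeric vector of per-frame log densities (nats).
#' @export
gmm_loglik_frames <- function(x, model) {
  gmm_posteriors(x, model$weights, model$means, model$variances)$logdens
}

#' Derive the target model by means-only MAP adaptation
#'
#' For each component k with soft count `n_k` and posterior-weighted data
#' mean `E_k`, the adapted mean is
#' `alpha_k * E_k + (1 - alpha_k) * m_k` with
#' `alpha_k = n_k / (n_k + r)`. Weights and variances are shared with the
#' UBM untouched.
#'
#' @param ubm a trained `ubm_model`.
#' @param x target feature matrix, standardized with the UBM's statistics.
#' @param relevance_factor the MAP relevance factor r (default 16, the
#'   speaker-verification convention).
#' @return a `target_model` (same fields as the UBM plus `relevance_factor`).
#' @export
adapt_means <- function(ubm, x, relevance_factor = 16) {
  if (nrow(x) == 0) stop("no target frames to adapt on")
  e <- gmm_posteriors(x, ubm$weights, ubm$means, ubm$variances)
  nk <- colSums(e$post)
  ek <- crossprod(e$post, x)
  ek[nk > 0, ] <- ek[nk > 0, ] / nk[nk > 0]
  alpha <- nk / (nk + relevance_factor)
  means <- alpha * ek + (1 - alpha) * ubm$means
  means[nk == 0, ] <- ubm$means[nk == 0, ]   # alpha = 0: untouched
  structure(list(weights = ubm$weights, means = means,
                 variances = ubm$variances, k = ubm$k,
                 relevance_factor = relevance_factor),
            class = "target_model")
}

#' Score frames by log-likelihood ratio
#'
#' `llr = log p(x | target) - log p(x | UBM)`; only active frames receive a
#' score (inactive frames carry `NA`).
#'
#' @param feats a `frame_features` object from [extract_features()]
#'   (standardized with the UBM's feature statistics).
#' @param ubm `ubm_model`.
#' @param target `target_model`.
#' @return a `frame_scores` list: `llr`, `frame_start_s`, `active_mask`.
#' @export
score_frames <- function(feats, ubm, target) {
  if (ncol(feats$features) != ncol(ubm$means))
    stop("feature dimension mismatch with the model")
  llr <- rep(NA_real_, nrow(feats$features))
  act <- feats$active_mask
  if (any(act)) {
    xa <- feats$features[act, , drop = FALSE]
    llr[act] <- gmm_loglik_frames(xa, target) - gmm_loglik_frames(xa, ubm)
  }
  structure(list(llr = llr, frame_start_s = feats$frame_start_s,
                 active_mask = act),
            class = "frame_scores")
}

#' Threshold frame scores into decisions
#'
#' @param scores a `frame_scores` object.
#' @param threshold decision threshold theta (nats); a frame is positive
#'   when `llr >= theta`. Inactive frames are always negative.
#' @return logical vector of per-frame decisions.
#' @export
decide <- function(scores, threshold) {
  out <- !is.na(scores$llr) & scores$llr >= threshold
  out
}

# ---- model persistence ------------------------------------------------------

#' Save / load detector models as JSON
#'
#' Weights, means and variances are stored in full double precision
#' (ASCII JSON, versioned), together with seed, k, and relevance factor /
#' threshold metadata if present.
#'
#' @param model `ubm_model` or `target_model`.
#' @param path file path.
#' @return the path / the model.
#' @export
write_model_json <- function(model, path) {
  obj <- list(format = "quero-gmm-1", class = class(model)[1],
              k = model$k, weights = model$weights,
              means = as.vector(model$means),
              variances = as.vector(model$variances),
              d = ncol(model$means),
              seed = model$seed, relevance_factor = model$relevance_factor)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "quero-gmm-1")) stop("unrecognised model file")
  k <- obj$k; d <- obj$d
  structure(list(weights = obj$weights,
                 means = matrix(obj$means, k, d),
                 variances = matrix(obj$variances, k, d),
                 k = k, seed = obj$seed,
                 relevance_factor = obj$relevance_factor),
            class = obj$class)
}

#' Calibrate the decision threshold on a development scene
#'
#' Sweeps candidate thresholds over quantiles of the active-frame scores,
#' smooths each decision sequence into events and picks the threshold with
#' the best event-level F1 against the ground-truth annotations. The paper
#' trail for theta (it is a free parameter of the detector, never a copied
#' constant) is the returned sweep table.
#'
#' @param scores `frame_scores` for the development scene.
#' @param annotations ground-truth annotation data.frame (target rows used).
#' @param n_grid number of candidate thresholds.
#' @return list `threshold`, `f1`, `sweep` (data.frame theta/precision/
#'   recall/f1).
#' @export
calibrate_threshold <- function(scores, annotations, n_grid = 41) {
  s <- scores$llr[scores$active_mask & !is.na(scores$llr)]
  grid <- unique(stats::quantile(s, seq(0.05, 0.995, length.out = n_grid)))
  rows <- lapply(grid, function(th) {
    ev <- smooth_decisions(decide(scores, th), scores$frame_start_s)
    m <- match_events(ev, annotations)
    pr <- if (m$H + m$I > 0) m$H / (m$H + m$I) else NA_real_
    rc <- if (m$N > 0) m$H / m$N else NA_real_
    f1 <- if (!is.na(pr) && !is.na(rc) && pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
    data.frame(theta = th, precision = pr, recall = rc, f1 = f1)
  })
  sweep <- do.call(rbind, rows)
  best <- which.max(sweep$f1)
  list(threshold = sweep$theta[best], f1 = sweep$f1[best], sweep = sweep)
}
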