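# One-dimensional Gaussian mixture machinery for unsupervised essentiality
# calling. EM with k-means++ seeding, full per-component variances, and
# AIC/BIC model-selection tables.

kmeanspp_centers <- function(x, k) {
  centers <- numeric(k)
  centers[1L] <- x[sample.int(length(x), 1L)]
  d2 <- (x - centers[1L])^2
  if (k > 1L) for (j in 2:k) {
    if (sum(d2) == 0) centers[j] <- x[sample.int(length(x), 1L)]
    else centers[j] <- x[sample.int(length(x), 1L, prob = d2)]
    d2 <- pmin(d2, (x - centers[j])^2)
  }
  centers
}

em_gaussian_1d <- function(x, mu0, var_floor, max_iter = 500L, tol = 1e-8) {
  n <- length(x)
  k <- length(mu0)
  w <- rep(1 / k, k)
  mu <- mu0
  s2 <- rep(max(stats::var(x) / k, var_floor), k)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    logd <- vapply(seq_len(k), function(j)
      stats::dnorm(x, mu[j], sqrt(s2[j]), log = TRUE) + log(w[j]),
      numeric(n))
    mx <- do.call(pmax, as.data.frame(logd))
    p <- exp(logd - mx)
    rs <- rowSums(p)
    ll <- sum(mx + log(rs))
    r <- p / rs
    nk <- colSums(r)
    nk[nk < 1e-10] <- 1e-10
    w <- nk / n
    mu <- colSums(r * x) / nk
    dev2 <- (matrix(x, n, k) - matrix(mu, n, k, byrow = TRUE))^2
    s2 <- pmax(colSums(r * dev2) / nk, var_floor)
    if (abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  list(weights = w, means = mu, variances = s2, loglik = ll, iter = it,
       responsibilities = r)
}

#' Fit Gaussian mixture models over a range of component counts
#'
#' Fits a one-dimensional `k`-component Gaussian mixture to the values (best
#' of `n_init` EM runs with k-means++ seeding) for every candidate `k`, and
#' tabulates AIC and BIC. The selected `k` follows an automated elbow
#' convention: take the largest `k` whose BIC improvement over `k - 1` is at
#' least `rel_tol` (default 2%) of the improvement from one to two
#' components; degenerate data (all values identical) falls back to a
#' single component with a warning. The selection is a default, not a
#' verdict; callers can classify under any fitted `k`.
#'
#' @param x Numeric values (e.g. per-feature linear densities); NAs dropped.
#' @param k_candidates Component counts to fit; candidates needing more than
#'   `length(x)/10` components are skipped.
#' @param n_init EM restarts per candidate.
#' @param seed RNG seed (recorded in the fit).
#' @param rel_tol Elbow threshold relative to the k=1 to k=2 improvement.
#' @param max_iter,tol EM iteration controls.
#' @return A `tn_mixfit`: list of per-k fits, an AIC/BIC table, and
#'   `selected_k`.
#' @export
fit_mixture <- function(x, k_candidates = 1:8, n_init = 10L, seed = NULL,
                        rel_tol = 0.02, max_iter = 500L, tol = 1e-8) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 10L) stop("need at least 10 data points")
  k_candidates <- sort(unique(as.integer(k_candidates)))
  feasible <- k_candidates[k_candidates * 10L <= n]
  if (length(feasible) < length(k_candidates))
    warning("dropping candidate k with fewer than 10 points per component")
  k_candidates <- feasible
  degenerate <- stats::var(x) == 0
  if (degenerate) {
    warning("all values identical; single-component fallback")
    k_candidates <- 1L
  }
  var_floor <- max(1e-12, 1e-6 * stats::var(x))
  fits <- list()
  with_seed(seed, {
    for (k in k_candidates) {
      if (degenerate) {
        fits[[as.character(k)]] <- list(k = 1L, weights = 1,
                                        means = mean(x),
                                        variances = var_floor,
                                        loglik = sum(stats::dnorm(
                                          x, mean(x), sqrt(var_floor),
                                          log = TRUE)),
                                        aic = NA_real_, bic = NA_real_)
        next
      }
      best <- NULL
      for (i in seq_len(n_init)) {
        f <- em_gaussian_1d(x, kmeanspp_centers(x, k), var_floor,
                            max_iter, tol)
        if (is.null(best) || f$loglik > best$loglik) best <- f
      }
      npar <- 3L * k - 1L
      best$k <- k
      best$aic <- -2 * best$loglik + 2 * npar
      best$bic <- -2 * best$loglik + log(n) * npar
      best$responsibilities <- NULL
      fits[[as.character(k)]] <- best
    }
  })
  tab <- data.frame(k = k_candidates,
                    loglik = vapply(fits, `[[`, 0, "loglik"),
                    aic = vapply(fits, `[[`, 0, "aic"),
                    bic = vapply(fits, `[[`, 0, "bic"))
  selected <- k_candidates[1L]
  if (length(k_candidates) > 1L) {
    d <- -diff(tab$bic)           # improvement moving to the next candidate
    base <- d[1L]
    if (is.finite(base) && base > 0) {
      ok <- d >= rel_tol * base
      run <- which(!ok)
      last <- if (length(run)) run[1L] - 1L else length(d)
      selected <- k_candidates[1L + last]
    }
  }
  structure(list(fits = fits, table = tab, selected_k = selected,
                 seed = seed, n = n),
            class = "tn_mixfit")
}

#' @export
print.tn_mixfit <- function(x, ...) {
  cat(sprintf("<tn_mixfit> n=%d, candidates k={%s}, selected k=%d\n",
              x$n, paste(x$table$k, collapse = ","), x$selected_k))
  print(x$table, row.names = FALSE)
  invisible(x)
}

category_labels <- function(k) {
  if (k == 4L) c("E", "F1", "F2", "NE")
  else if (k == 2L) c("E", "NE")
  else paste0("C", seq_len(k))
}

#' Assign essentiality categories from a mixture fit
#'
#' Components are ordered by ascending mean so the lowest-density component
#' maps to E and the highest to NE (`E < F1 < F2 < NE` for `k = 4`,
#' `E < NE` for `k = 2`). Each feature takes the argmax-posterior component;
#' posterior ties break toward the more essential category.
#'
#' @param values Named numeric vector of per-feature values (LD).
#' @param fit A `tn_mixfit`.
#' @param k Component count to classify under (default the fit's selection).
#' @return A data.frame: `feature_id`, `ld`, `category`, and one posterior
#'   column per category.
#' @export
classify <- function(values, fit, k = fit$selected_k) {
  f <- fit$fits[[as.character(k)]]
  if (is.null(f)) stop("no fit with k = ", k)
  kk <- length(f$means)
  ord <- order(f$means)
  w <- f$weights[ord]; mu <- f$means[ord]; s2 <- f$variances[ord]
  labs <- category_labels(kk)
  v <- as.numeric(values)
  post <- matrix(NA_real_, length(v), kk)
  ok <- !is.na(v)
  if (any(ok)) {
    logd <- vapply(seq_len(kk), function(j)
      stats::dnorm(v[ok], mu[j], sqrt(s2[j]), log = TRUE) + log(w[j]),
      numeric(sum(ok)))
    logd <- matrix(logd, ncol = kk)
    mx <- apply(logd, 1L, max)
    p <- exp(logd - mx)
    post[ok, ] <- p / rowSums(p)
  }
  hard <- apply(post, 1L, function(r) if (all(is.na(r))) NA_integer_
                else which.max(r))   # first max = most essential on ties
  out <- data.frame(feature_id = if (is.null(names(values)))
                      as.character(seq_along(values)) else names(values),
                    ld = v, category = labs[hard],
                    stringsAsFactors = FALSE)
  colnames(post) <- paste0("post_", labs)
  cbind(out, as.data.frame(post))
}

#' @rdname classify
#' @export
classify_binary <- function(values, fit) classify(values, fit, k = 2L)

#' Filter regulatory elements eligible for essentiality calling
#'
#' Keeps elements at least `min_len` bp long, not overlapping any E or F1
#' gene, and with at most `max_repeat` of their sequence repeat-flagged.
#'
#' @param elements `tn_features` rows for the candidate elements (must carry
#'   `pct_repeated`).
#' @param genes `tn_features` rows for genes.
#' @param gene_calls Data.frame with `feature_id` and `category` for genes.
#' @param min_len Minimum element length (bp).
#' @param max_repeat Maximum repeated fraction.
#' @return The eligible subset of `elements`.
#' @export
filter_regulatory <- function(elements, genes, gene_calls,
                              min_len = 5L, max_repeat = 0.25) {
  if (!"pct_repeated" %in% names(elements))
    stop("elements need a pct_repeated column (see annotate_pct_repeated)")
  ef <- genes$id %in% gene_calls$feature_id[gene_calls$category %in% c("E", "F1")]
  eg <- genes[ef, , drop = FALSE]
  keep_len <- (elements$end - elements$start + 1L) >= min_len
  keep_rep <- elements$pct_repeated <= max_repeat
  if (nrow(eg)) {
    ov <- IRanges::countOverlaps(
      IRanges::IRanges(elements$start, elements$end),
      IRanges::IRanges(eg$start, eg$end)) > 0L
  } else ov <- rep(FALSE, nrow(elements))
  elements[keep_len & keep_rep & !ov, , drop = FALSE]
}

#' Stringent essential-regulatory cut
#'
#' Post-hoc filter applied after classification: retains E/F1 calls whose
#' linear density does not exceed `max_ld` (default 0.4).
#'
#' @param calls Data.frame from [classify()].
#' @param max_ld LD ceiling.
#' @return The retained subset of `calls`.
#' @export
stringent_essential <- function(calls, max_ld = 0.4) {
  calls[!is.na(calls$category) & calls$category %in% c("E", "F1") &
          !is.na(calls$ld) & calls$ld <= max_ld, , drop = FALSE]
}

#' Dump mixture models as JSON
#' @param fit A `tn_mixfit`.
#' @param path Output path.
#' @export
write_mixfit_json <- function(fit, path) {
  dump <- list(selected_k = fit$selected_k, seed = fit$seed,
               table = fit$table,
               models = lapply(fit$fits, function(f)
                 f[c("k", "weights", "means", "variances", "loglik",
                     "aic", "bic")]))
  jsonlite::write_json(dump, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
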