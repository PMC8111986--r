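# Virtual microdissection: KL-divergence NMF (multiplicative updates, Brunet
# variant), rank diagnostics, immune-factor identification, exemplar genes.

kl_divergence <- function(x, wh) {
  # D(X || WH) with the 0*log0 = 0 convention
  pos <- x > 0
  sum(x[pos] * log(x[pos] / wh[pos])) - sum(x) + sum(wh)
}

# SVD-based non-negative seeding (NNDSVD, Boutsidis & Gallopoulos 2008);
# zeros are lifted to a small positive value so multiplicative updates can
# move every entry
nndsvd_init <- function(x, k) {
  s <- svd(x, nu = k, nv = k)
  n <- nrow(x); m <- ncol(x)
  w <- matrix(0, n, k); h <- matrix(0, k, m)
  w[, 1] <- sqrt(s$d[1]) * abs(s$u[, 1])
  h[1, ] <- sqrt(s$d[1]) * abs(s$v[, 1])
  if (k > 1) for (j in 2:k) {
    u <- s$u[, j]; v <- s$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    nup <- sqrt(sum(up^2)); nun <- sqrt(sum(un^2))
    nvp <- sqrt(sum(vp^2)); nvn <- sqrt(sum(vn^2))
    if (nup * nvp >= nun * nvn) {
      scale <- sqrt(s$d[j] * nup * nvp)
      w[, j] <- scale * up / max(nup, 1e-12)
      h[j, ] <- scale * vp / max(nvp, 1e-12)
    } else {
      scale <- sqrt(s$d[j] * nun * nvn)
      w[, j] <- scale * un / max(nun, 1e-12)
      h[j, ] <- scale * vn / max(nvn, 1e-12)
    }
  }
  floor_val <- mean(x) * 1e-3
  w[w <= 0] <- floor_val; h[h <= 0] <- floor_val
  list(w = w, h = h)
}

nmf_single_run <- function(x, k, max_iter, tol, seed, eps = 1e-12, init = "random") {
  if (init == "nndsvd") {
    start <- nndsvd_init(x, k)
    w <- start$w; h <- start$h
  } else {
    set.seed(seed)
    n <- nrow(x); m <- ncol(x)
    w <- matrix(stats::runif(n * k, 0.1, 1), n, k)
    h <- matrix(stats::runif(k * m, 0.1, 1), k, m)
  }
  n <- nrow(x)
  trace <- numeric(max_iter)
  prev <- Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    wh <- w %*% h
    h <- h * (t(w) %*% (x / (wh + eps))) / (colSums(w) + eps)
    wh <- w %*% h
    w <- w * ((x / (wh + eps)) %*% t(h)) / rep(rowSums(h) + eps, each = n)
    d <- kl_divergence(x, w %*% h + eps)
    trace[it] <- d
    if (is.finite(prev) && abs(prev - d) <= tol * max(1, abs(prev))) {
      converged <- TRUE
      break
    }
    prev <- d
  }
  list(w = w, h = h, trace = trace[seq_len(it)], divergence = trace[it],
       converged = converged, seed = seed)
}

#' Non-negative matrix factorization by KL multiplicative updates
#'
#' Factorizes a non-negative gene-by-sample matrix as `X ~ W %*% H`
#' (gene-by-k basis, k-by-sample coefficients) by minimizing generalized
#' Kullback-Leibler divergence with the classic multiplicative updates.
#' Basis columns are rescaled to unit L1 norm with compensating scaling of
#' `H`. A small epsilon (1e-12) inside update denominators guards against
#' division by zero.
#'
#' Initialization: the default `"nndsvd"` seeds the updates from the
#' non-negative double SVD, a deterministic start that reliably lands in
#' the basin where overlapping compartments (e.g. samples loading on both
#' immune and stroma factors) stay separated. `"random"` runs
#' `n_restarts` uniform random starts and keeps the one with the lowest
#' final divergence; note that on weakly identifiable data the lowest
#' divergence local optimum can be a slightly mixed solution, which is why
#' it is not the default.
#'
#' @param expr non-negative numeric matrix with dimnames; rows that are all
#'   zero must be removed beforehand (see [filter_variable_genes()]).
#' @param k number of factors; must be < min(dim(expr)).
#' @param n_restarts random restarts (default 5; only used with
#'   `init = "random"`).
#' @param max_iter maximum multiplicative-update iterations per restart.
#' @param tol relative divergence-change convergence tolerance.
#' @param seed integer seed; restart r uses a sub-seed derived from it.
#' @param init `"nndsvd"` (deterministic, default) or `"random"`.
#' @return an object of class `factor_model`: list with `W`, `H`, `k`,
#'   `trace` (per-iteration divergence of the winning restart, non-increasing),
#'   `divergence`, `restart_seeds`, `restart_divergences`, `best_restart`,
#'   `converged`, and `immune_factor` (NA until identified).
#' @seealso [identify_immune_factor()], [exemplar_genes()], [rank_diagnostics()]
#' @export
nmf <- function(expr, k, n_restarts = 5, max_iter = 500, tol = 1e-6, seed = 1,
                init = c("nndsvd", "random")) {
  assert_matrix(expr, "expr")
  init <- match.arg(init)
  if (any(expr < 0)) abort("expr contains negative entries; NMF requires non-negative input")
  if (any(rowSums(expr) == 0)) abort("expr contains all-zero rows; filter them first")
  if (k < 1 || k >= min(dim(expr))) abort("k must be in [1, min(dim(expr)) - 1]")
  if (init == "nndsvd") n_restarts <- 1L
  seeds <- vapply(seq_len(n_restarts), function(r) derive_seed(seed, r), numeric(1))
  runs <- lapply(seeds, function(s)
    nmf_single_run(expr, k, max_iter, tol, s, init = init))
  divs <- vapply(runs, `[[`, numeric(1), "divergence")
  best <- which.min(divs)
  fit <- runs[[best]]
  if (!fit$converged)
    warning("NMF did not converge within max_iter; returning best iterate",
            call. = FALSE)
  scal <- colSums(fit$w)
  w <- sweep(fit$w, 2, scal, "/")
  h <- sweep(fit$h, 1, scal, "*")
  dimnames(w) <- list(rownames(expr), paste0("factor", seq_len(k)))
  dimnames(h) <- list(paste0("factor", seq_len(k)), colnames(expr))
  structure(list(W = w, H = h, k = k,
                 trace = fit$trace, divergence = fit$divergence,
                 init = init, restart_seeds = seeds, restart_divergences = divs,
                 best_restart = best, converged = fit$converged,
                 immune_factor = NA_integer_),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("factor_model: %d genes x %d samples, k = %d\n",
              nrow(x$W), ncol(x$H), x$k))
  cat(sprintf("  KL divergence %.4g (best of %d restarts%s)\n",
              x$divergence, length(x$restart_seeds),
              if (x$converged) ", converged" else ", NOT converged"))
  if (!is.na(x$immune_factor))
    cat(sprintf("  immune factor: %d\n", x$immune_factor))
  invisible(x)
}

#' Select the most variable genes by median absolute deviation
#'
#' Standard pre-filter before virtual microdissection: keeps the `n` genes
#' with the largest MAD across samples (ties broken by gene identifier) and
#' drops all-zero rows.
#'
#' @param expr gene-by-sample matrix.
#' @param n number of genes to keep (default 1500).
#' @return the row-subset matrix.
#' @export
filter_variable_genes <- function(expr, n = 1500) {
  assert_matrix(expr, "expr")
  mads <- apply(expr, 1, stats::mad)
  keep <- order(-mads, rownames(expr), method = "radix")[seq_len(min(n, nrow(expr)))]
  out <- expr[sort(keep), , drop = FALSE]
  out[rowSums(out) > 0, , drop = FALSE]
}

#' Factorization-rank diagnostics (consensus cophenetic correlation)
#'
#' For each candidate rank, runs `n_runs` NMF fits from different random
#' starts, builds the sample-by-sample connectivity consensus (fraction of
#' runs in which two samples share the dominant factor), and reports the
#' cophenetic correlation of the consensus matrix together with the best
#' relative Frobenius reconstruction error.
#'
#' @param expr non-negative matrix.
#' @param k_range integer vector of ranks to evaluate.
#' @param n_runs runs per rank; with `n_runs = 1` the cophenetic correlation
#'   is 1 by construction and the result is flagged degenerate.
#' @param seed integer seed.
#' @param max_iter per-run iteration cap (diagnostics need stability, not
#'   full convergence).
#' @return data.frame with columns `k`, `cophenetic`, `reconstruction_error`,
#'   `degenerate`.
#' @export
rank_diagnostics <- function(expr, k_range, n_runs = 10, seed = 1, max_iter = 300) {
  if (length(k_range) == 0) abort("k_range is empty")
  res <- lapply(k_range, function(k) {
    conn <- matrix(0, ncol(expr), ncol(expr))
    best_err <- Inf
    for (r in seq_len(n_runs)) {
      # random starts on purpose: run-to-run variability is what the
      # consensus stability of each rank is measured against
      fit <- nmf(expr, k, n_restarts = 1, max_iter = max_iter,
                 seed = derive_seed(seed, k * 1000 + r), init = "random")
      cl <- apply(fit$H, 2, which.max)
      conn <- conn + outer(cl, cl, "==")
      err <- norm(expr - fit$W %*% fit$H, "F") / norm(expr, "F")
      best_err <- min(best_err, err)
    }
    cons <- conn / n_runs
    coph <- if (n_runs == 1) 1 else {
      d <- stats::as.dist(1 - cons)
      if (max(d) == 0) 1 else stats::cor(d, stats::cophenetic(stats::hclust(d, "average")))
    }
    data.frame(k = k, cophenetic = coph, reconstruction_error = best_err,
               degenerate = n_runs == 1)
  })
  do.call(rbind, res)
}

#' Identify the immune factor of a factorization
#'
#' The immune factor is the one whose per-sample coefficients correlate
#' most strongly (Pearson) with an immune enrichment score, i.e. the factor
#' that tracks immune-cell content across the cohort.
#'
#' @param model a [nmf()] `factor_model`.
#' @param immune_scores numeric vector of immune enrichment scores named by
#'   sample (e.g. one row of [ssgsea_scores()]); must cover the model's
#'   samples.
#' @return the model with `immune_factor` set and a `factor_correlations`
#'   element appended.
#' @export
identify_immune_factor <- function(model, immune_scores) {
  samples <- colnames(model$H)
  if (!all(samples %in% names(immune_scores)))
    abort("immune_scores does not cover all model samples")
  sc <- immune_scores[samples]
  if (stats::sd(sc) == 0) abort("immune score is constant across samples; correlation undefined")
  if (model$k == 1) {
    model$immune_factor <- 1L
    model$factor_correlations <- stats::cor(model$H[1, ], sc)
    return(model)
  }
  cors <- apply(model$H, 1, function(h) {
    if (stats::sd(h) == 0) -Inf else stats::cor(h, sc)
  })
  ord <- sort(cors, decreasing = TRUE)
  if (is.finite(ord[1]) && is.finite(ord[2]) && abs(ord[1] - ord[2]) < 1e-9)
    abort("ambiguous immune factor: two factors correlate equally with the immune score")
  model$immune_factor <- as.integer(which.max(cors))
  model$factor_correlations <- cors
  model
}

#' Exemplar genes of a factor
#'
#' Ranks genes by their basis weight on the chosen factor and keeps those
#' whose weight is at least `min_ratio` times their largest weight on any
#' other factor (the specificity ratio; infinite when all other weights are
#' zero). Returns at most `m` genes, in descending weight order. The
#' selection is fully deterministic given the model.
#'
#' @param model a `factor_model`.
#' @param factor factor index (defaults to the identified immune factor).
#' @param m maximum number of exemplars (default 150).
#' @param min_ratio minimum specificity ratio (default 2).
#' @return data.frame `gene`, `weight`, `specificity_ratio`, descending by
#'   weight.
#' @export
exemplar_genes <- function(model, factor = model$immune_factor, m = 150, min_ratio = 2) {
  if (is.na(factor) || factor < 1 || factor > model$k) abort("invalid factor index")
  if (m < 1) abort("m must be >= 1")
  w <- model$W
  wf <- w[, factor]
  other <- if (model$k == 1) rep(0, nrow(w)) else
    apply(w[, -factor, drop = FALSE], 1, max)
  ratio <- ifelse(other == 0, Inf, wf / other)
  pass <- ratio >= min_ratio & wf > 0
  if (!any(pass))
    abort("no gene passes min_ratio = %g; lower min_ratio", min_ratio)
  ord <- order(-wf, rownames(w), method = "radix")
  ord <- ord[pass[ord]]
  ord <- ord[seq_len(min(m, length(ord)))]
  data.frame(gene = rownames(w)[ord], weight = unname(wf[ord]),
             specificity_ratio = unname(ratio[ord]), row.names = NULL)
}
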