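# Constrained four-component coverage mixture, fitted by EM.
#
# Components over integer depth d:
#   err   : Poisson(lambda), lambda clamped to [0, 10]; its M-step uses only
#           responsibilities at depths below 10.
#   dup   : Normal(mu/2, dup_sd)    -- mean tied, never free
#   hap   : Normal(mu,   hap_sd)
#   col_k : Normal(k*mu, col_sd_k)  -- k = 2 .. n_collapsed+1, means tied
# Gaussian densities are evaluated at the integer depths without a
# continuity correction. Mixing weights are free and renormalised after
# every M-step.

ERR_LAMBDA_MAX <- 10     # upper clamp on the Poisson mean (reads)
ERR_MSTEP_MAX_DEPTH <- 10  # lambda M-step uses depths strictly below this
SD_FLOOR <- 0.5          # reads; avoids zero-variance spikes

#' Options controlling the mixture fit
#'
#' @param init_coverage Starting haploid mean for EM, in reads. `NULL`
#'   (default) uses the count-weighted mean depth of the histogram.
#' @param max_iter Maximum EM iterations.
#' @param tol Relative log-likelihood change declaring convergence.
#' @param n_collapsed Number of collapsed sub-components; sub-component k
#'   has mean `(k+1) * hap_mean` for k = 1..n_collapsed.
#' @param min_mass Minimum number of bases below which a single-depth
#'   histogram is rejected as degenerate (fall back to the whole-genome
#'   model instead).
#' @param seed Optional integer recorded with the fit (the EM itself is
#'   deterministic).
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(init_coverage = NULL, max_iter = 300L, tol = 1e-6,
                        n_collapsed = 4L, min_mass = 1e4, seed = NULL) {
  stopifnot(max_iter >= 1, tol > 0, n_collapsed >= 1)
  structure(list(init_coverage = init_coverage, max_iter = as.integer(max_iter),
                 tol = tol, n_collapsed = as.integer(n_collapsed),
                 min_mass = min_mass, seed = seed),
            class = "fit_options")
}

# Component mean multipliers for the Gaussian family (dup, hap, col_k).
gauss_multipliers <- function(n_collapsed) {
  c(dup = 0.5, hap = 1, setNames(2:(n_collapsed + 1),
                                 paste0("col", 2:(n_collapsed + 1))))
}

component_names <- function(n_collapsed) {
  c("err", names(gauss_multipliers(n_collapsed)))
}

# Log density matrix (length(depths) x n components) for given parameters.
mixture_log_dens <- function(depths, err_lambda, hap_mean, sds, n_collapsed) {
  cm <- gauss_multipliers(n_collapsed)
  L <- matrix(NA_real_, length(depths), 1 + length(cm),
              dimnames = list(NULL, component_names(n_collapsed)))
  L[, "err"] <- dpois(depths, max(err_lambda, 1e-8), log = TRUE)
  for (j in seq_along(cm))
    L[, names(cm)[j]] <- dnorm(depths, cm[j] * hap_mean, sds[j], log = TRUE)
  L
}

#' Fit the constrained coverage mixture by expectation-maximization
#'
#' Fits the four-component model (Poisson erroneous + tied Gaussian
#' duplicated/haploid/collapsed family) to a coverage histogram. The
#' duplicated mean is exactly half the haploid mean and collapsed
#' sub-component k has mean exactly k times the haploid mean; these are
#' derived, never free. The Poisson mean is clamped to `[0, 10]` and its
#' M-step uses only the coverages below 10.
#'
#' @param hist A `cov_hist`.
#' @param opts A [fit_options()] list.
#' @return An object of class `cov_mixture` with elements `err_lambda`,
#'   `hap_mean`, `hap_sd`, `dup_sd`, `collapsed_sds`, `weights` (named over
#'   err/dup/hap/col_k, summing to 1), `loglik`, `loglik_trace`,
#'   `iterations`, `converged`.
#' @export
fit_mixture <- function(hist, opts = fit_options()) {
  stopifnot(inherits(hist, "cov_hist") || is.data.frame(hist))
  d <- hist$depth
  n <- hist$count
  keep <- n > 0
  d <- d[keep]; n <- n[keep]
  if (length(d) == 0) stop("empty coverage histogram")
  N <- sum(n)
  if (length(d) == 1 && N < opts$min_mass)
    stop(structure(class = c("asmflag_degenerate_fit", "error", "condition"),
                   list(message = paste0(
                     "histogram has a single depth (", d, ") and only ", N,
                     " bases; fall back to the whole-genome model"),
                     call = sys.call(-1))))
  K <- opts$n_collapsed
  cm <- gauss_multipliers(K)
  mu <- opts$init_coverage
  if (is.null(mu)) mu <- sum(d * n) / N
  mu <- max(mu, 1)
  lambda <- 1
  sds <- pmax(rep(mu / 8, length(cm)), SD_FLOOR)
  names(sds) <- names(cm)
  w <- c(err = 0.05, dup = 0.05, hap = 0.80,
         setNames(rep(0.10 / K, K), names(cm)[-(1:2)]))
  ll_trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  iter <- 0
  below <- d < ERR_MSTEP_MAX_DEPTH
  for (iter in seq_len(opts$max_iter)) {
    # E-step (zero weights stay zero: log weight -Inf)
    L <- mixture_log_dens(d, lambda, mu, sds, K)
    A <- sweep(L, 2, ifelse(w > 0, log(w), -Inf), "+")
    m <- apply(A, 1, max)
    m[!is.finite(m)] <- 0
    P <- exp(A - m)
    rs <- rowSums(P)
    R <- P / rs
    ll <- sum(n * (m + log(rs)))
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) <= opts$tol * (abs(ll_prev) + 1e-12)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
    # M-step
    nR <- n * R
    W <- colSums(nR)
    w <- W / N
    # Poisson mean from depths below the cutoff only, clamped to [0, 10]
    den <- sum(nR[below, "err"])
    if (den > 0)
      lambda <- min(max(sum(nR[below, "err"] * d[below]) / den, 0),
                    ERR_LAMBDA_MAX)
    # tied haploid mean: weighted least squares across the Gaussian family
    gn <- names(cm)
    Ag <- colSums(nR[, gn, drop = FALSE] * d)
    Bg <- W[gn]
    num <- sum(cm / sds^2 * Ag)
    denm <- sum(cm^2 / sds^2 * Bg)
    if (denm > 0) mu <- max(num / denm, 1)  # haploid coverage below 1 is noise
    # per-component standard deviations, floored
    for (j in seq_along(cm)) {
      if (Bg[j] > 1e-12) {
        v <- sum(nR[, gn[j]] * (d - cm[j] * mu)^2) / Bg[j]
        sds[j] <- max(sqrt(v), SD_FLOOR)
      }
    }
  }
  structure(list(
    err_lambda = lambda,
    hap_mean = mu,
    hap_sd = unname(sds["hap"]),
    dup_sd = unname(sds["dup"]),
    collapsed_sds = sds[-(1:2)],
    n_collapsed = K,
    weights = w / sum(w),
    loglik = ll_trace[length(ll_trace)],
    loglik_trace = ll_trace,
    iterations = iter,
    converged = converged,
    init_coverage = if (is.null(opts$init_coverage)) sum(d * n) / N
                    else opts$init_coverage,
    total_bases = N), class = "cov_mixture")
}

#' @export
print.cov_mixture <- function(x, ...) {
  cat("Constrained coverage mixture (", x$n_collapsed,
      " collapsed sub-components)\n", sep = "")
  cat(sprintf("  err: Poisson(lambda = %.3f), weight %.4f\n",
              x$err_lambda, x$weights["err"]))
  cat(sprintf("  dup: N(%.2f, %.2f), weight %.4f\n",
              x$hap_mean / 2, x$dup_sd, x$weights["dup"]))
  cat(sprintf("  hap: N(%.2f, %.2f), weight %.4f\n",
              x$hap_mean, x$hap_sd, x$weights["hap"]))
  for (k in 2:(x$n_collapsed + 1))
    cat(sprintf("  col%d: N(%.2f, %.2f), weight %.4f\n", k,
                k * x$hap_mean, x$collapsed_sds[[paste0("col", k)]],
                x$weights[[paste0("col", k)]]))
  cat(sprintf("  loglik %.2f after %d iteration(s)%s\n", x$loglik,
              x$iterations, if (x$converged) " (converged)" else ""))
  invisible(x)
}

# Weighted log scores (weight x density, log scale) per sub-component.
model_log_scores <- function(model, depths) {
  sds <- c(dup = model$dup_sd, hap = model$hap_sd, model$collapsed_sds)
  L <- mixture_log_dens(depths, model$err_lambda, model$hap_mean, sds,
                        model$n_collapsed)
  w <- model$weights[colnames(L)]
  sweep(L, 2, ifelse(w > 0, log(w), -Inf), "+")
}

#' Posterior component probabilities at given depths
#'
#' The E-step of the fit, exposed: P(component | depth) proportional to
#' weight times density (Poisson pmf for the erroneous component, Gaussian
#' density otherwise).
#'
#' @param model A `cov_mixture`.
#' @param depth Integer vector of depths (>= 0).
#' @return Matrix with one row per depth and one column per sub-component
#'   (`err`, `dup`, `hap`, `col2`, ...); rows sum to 1.
#' @export
component_posteriors <- function(model, depth) {
  stopifnot(all(depth >= 0))
  A <- model_log_scores(model, depth)
  m <- apply(A, 1, max)
  P <- exp(A - m)
  P / rowSums(P)
}

#' Map every depth to its most probable component label
#'
#' For each depth in `0:max_depth`, picks the label with the highest
#' weighted mixture density. Collapsed sub-components pool (their weighted
#' densities sum) into the single label `Col`. Ties break in the order
#' Hap > Dup > Col > Err.
#'
#' @param model A `cov_mixture`.
#' @param max_depth Largest depth the table must cover (at least the
#'   maximum observed depth of the track to be labelled).
#' @return An `assignment_table`: data.frame with columns `depth`
#'   (`0:max_depth`) and `label` (factor over Err/Dup/Hap/Col).
#' @export
assign_components <- function(model, max_depth) {
  depths <- 0:max_depth
  A <- model_log_scores(model, depths)
  m <- apply(A, 1, max)
  P <- exp(A - m)           # proportional within each row
  col_cols <- grep("^col", colnames(P), value = TRUE)
  S <- cbind(Hap = P[, "hap"], Dup = P[, "dup"],
             Col = rowSums(P[, col_cols, drop = FALSE]),
             Err = P[, "err"])
  pick <- max.col(S, ties.method = "first")  # column order encodes tie-break
  structure(data.frame(depth = depths,
                       label = flag_factor(colnames(S)[pick])),
            class = c("assignment_table", "data.frame"))
}

#' Refit the mixture with a scaled starting coverage
#'
#' Reruns [fit_mixture()] with the EM starting haploid mean set to
#' `init_multiplier` times the count-weighted mean depth of `hist`. Used for
#' satellite-biased regions where the expected coverage deviates from the
#' genome average.
#'
#' @param hist A `cov_hist`.
#' @param init_multiplier Positive ratio applied to the mean coverage.
#' @param opts A [fit_options()]; its `init_coverage` is overridden.
#' @return A `cov_mixture`.
#' @export
refit_with_init <- function(hist, init_multiplier, opts = fit_options()) {
  stopifnot(init_multiplier > 0)
  opts$init_coverage <- init_multiplier * hist_mean_depth(hist)
  fit_mixture(hist, opts)
}

#' Serialize / deserialize a fitted mixture as JSON
#'
#' @param model A `cov_mixture`.
#' @param path File path.
#' @return `write_model_json()` returns `path` invisibly;
#'   `read_model_json()` returns a `cov_mixture`.
#' @export
write_model_json <- function(model, path) {
  x <- unclass(model)
  x$loglik_trace <- NULL
  x$weights <- as.list(x$weights)             # keep component names
  x$collapsed_sds <- as.list(x$collapsed_sds)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$collapsed_sds <- unlist(x$collapsed_sds)
  x$weights <- unlist(x$weights)
  x$loglik_trace <- numeric(0)
  structure(x, class = "cov_mixture")
}

#' Export an assignment table as two-column TSV
#'
#' @param table An `assignment_table` from [assign_components()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assignment_tsv <- function(table, path) {
  utils::write.table(data.frame(depth = table$depth,
                                label = as.character(table$label)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
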