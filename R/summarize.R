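# Summarize one parameter given its per-chain draw vectors: pooled
# median, equal-tailed interval (type-7 quantiles), PSRF and ESS.
summarize_chains <- function(chain_list, level = 0.95) {
  pooled <- unlist(chain_list, use.names = FALSE)
  a <- (1 - level) / 2
  q <- stats::quantile(pooled, c(a, 1 - a), names = FALSE, type = 7)
  if (length(chain_list) >= 2 && length(chain_list[[1]]) >= 10) {
    gr <- gelman_rubin(chain_list)
  } else {
    gr <- c(psrf = NA_real_, upper = NA_real_)
  }
  ess <- if (stats::var(pooled) == 0) length(pooled) else
    effective_sample_size(chain_list)
  data.frame(median = stats::median(pooled), lower = q[1], upper = q[2],
             psrf = gr[["psrf"]], psrf_upper = gr[["upper"]], ess = ess,
             row.names = NULL)
}

chains_of <- function(object, parameter) {
  if (!parameter %in% object$par_names) {
    stop(sprintf("unknown parameter: %s", parameter), call. = FALSE)
  }
  lapply(object$draws, function(d) d[, parameter])
}

#' Posterior summary of a fitted social-influence model
#'
#' For every parameter: the posterior median and equal-tailed credible
#' interval computed on draws pooled across chains (type-7 quantiles),
#' plus the Gelman-Rubin PSRF (point estimate and upper confidence
#' limit) and the autocorrelation-based effective sample size combined
#' across chains.
#'
#' @param object An [influence_fit()].
#' @param level Credible level (default 0.95).
#' @param ... Unused.
#' @return A data frame of class `summary.influence_fit` with columns
#'   `parameter`, `median`, `lower`, `upper`, `psrf`, `psrf_upper`,
#'   `ess`.
#' @export
summary.influence_fit <- function(object, level = 0.95, ...) {
  stopifnot(level > 0, level < 1)
  rows <- lapply(object$par_names, function(p) {
    cbind(parameter = p, summarize_chains(chains_of(object, p), level))
  })
  out <- do.call(rbind, rows)
  attr(out, "level") <- level
  class(out) <- c("summary.influence_fit", "data.frame")
  out
}

#' @export
print.summary.influence_fit <- function(x, digits = 3, max_rows = 12, ...) {
  lvl <- attr(x, "level")
  cat(sprintf("Posterior summary (%g%% equal-tailed credible intervals)\n",
              100 * lvl))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  show <- !grepl("^u\\[", df$parameter)
  print(df[show, ], row.names = FALSE)
  if (any(!show)) {
    cat(sprintf("  (+ %d participant random effects not shown)\n",
                sum(!show)))
  }
  invisible(x)
}

#' Posterior contrast between two conditions' influence parameters
#'
#' Computes the draw-wise difference `beta[a] - beta[b]` (same chain,
#' same kept iteration) and summarizes it like
#' [summary.influence_fit()].
#'
#' @param object An [influence_fit()].
#' @param a,b Condition names (e.g. `"face"`, `"hand"`).
#' @param level Credible level (default 0.95).
#' @return A one-row data frame with columns `parameter` (`"a - b"`),
#'   `median`, `lower`, `upper`, `psrf`, `psrf_upper`, `ess`.
#' @export
contrast <- function(object, a, b, level = 0.95) {
  stopifnot(inherits(object, "influence_fit"))
  for (cn in c(a, b)) {
    if (!cn %in% object$conditions) {
      stop(sprintf("unknown condition: %s", cn), call. = FALSE)
    }
  }
  diff_chains <- lapply(object$draws, function(d) {
    d[, sprintf("beta[%s]", a)] - d[, sprintf("beta[%s]", b)]
  })
  cbind(parameter = sprintf("%s - %s", a, b),
        summarize_chains(diff_chains, level))
}

#' In-sample fit check: predicted vs observed final ratings
#'
#' Computes per-trial posterior-mean predictions (conditional on each
#' participant's own random-effect draws), their Pearson correlation
#' with the observed final ratings, and the squared correlation
#' (pseudo-R^2).
#'
#' @param object An [influence_fit()].
#' @return An object of class `influence_fit_check`: a list with
#'   `correlation`, `pseudo_r2`, `n`, and the per-trial `predicted` and
#'   `observed` unit-scale ratings.
#' @export
fit_check <- function(object) {
  stopifnot(inherits(object, "influence_fit"))
  predicted <- fitted(object)
  observed <- object$trials$final_u
  if (stats::var(observed) == 0) {
    stop("observed final ratings have zero variance: correlation undefined",
         call. = FALSE)
  }
  r <- stats::cor(predicted, observed)
  structure(list(correlation = r, pseudo_r2 = r^2, n = length(observed),
                 predicted = predicted, observed = observed),
            class = "influence_fit_check")
}

#' @export
print.influence_fit_check <- function(x, ...) {
  cat(sprintf(
    "Predicted vs observed final ratings: correlation %.3f, pseudo-R2 %.3f (N = %d)\n",
    x$correlation, x$pseudo_r2, x$n))
  invisible(x)
}
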